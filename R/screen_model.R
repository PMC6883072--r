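# Screen data model: guide library manifest, sample sheet and count matrix,
# plus readers/writers and cross-validation of the three.

#' Controlled vocabulary for screen annotations
#'
#' Treatments and dose levels accepted in a sample sheet.  `vehicle` samples
#' must carry dose level `none`; drug-treated samples are annotated with the
#' dose-response-derived level (`ED50` or `ED75`) they were cultured at.
#'
#' @format Character vectors.
#' @name screen-vocabulary
NULL

#' @rdname screen-vocabulary
#' @export
TREATMENT_LEVELS <- c("vehicle", "brigatinib", "ceritinib")

#' @rdname screen-vocabulary
#' @export
DOSE_LEVELS <- c("none", "ED50", "ED75")

.validate_protospacers <- function(protospacer) {
  bad <- which(!grepl("^[ACGT]{20}$", protospacer))
  if (length(bad)) {
    stop("malformed protospacer (must be 20 uppercase A/C/G/T) at row",
         if (length(bad) > 1) "s" else "", " ",
         paste(utils::head(bad, 5L), collapse = ", "),
         if (length(bad) > 5) " ..." else "", call. = FALSE)
  }
  invisible(TRUE)
}

#' Construct a guide library manifest
#'
#' A manifest is an ordered table of guides, each tying a unique `guide_id`
#' to a gene symbol and a 20-nt protospacer.  Protospacers must be unique
#' across the library: exact-match counting cannot disambiguate duplicated
#' sequences, so duplicates are a hard error unless `collapse_duplicates`
#' keeps the first occurrence (the collapse is reported via `message()`).
#'
#' @param guide_id Character vector of unique guide identifiers.
#' @param gene Character vector of gene symbols (treated as opaque strings).
#' @param protospacer Character vector of 20-nt sequences over A/C/G/T.
#' @param name,version Provenance note stored with the manifest.
#' @param collapse_duplicates Keep the first occurrence of a duplicated
#'   protospacer instead of erroring.
#' @return A `guide_library` data frame with columns `guide_id`, `gene`,
#'   `protospacer` and a `provenance` attribute.
#' @export
guide_library <- function(guide_id, gene, protospacer,
                          name = "guide library", version = "1",
                          collapse_duplicates = FALSE) {
  df <- data.frame(guide_id = as.character(guide_id),
                   gene = as.character(gene),
                   protospacer = as.character(protospacer),
                   stringsAsFactors = FALSE)
  if (anyNA(df) || any(df == ""))
    stop("manifest fields must be non-missing, non-empty strings")
  .validate_protospacers(df$protospacer)
  dup_id <- duplicated(df$guide_id)
  if (any(dup_id))
    stop("duplicate guide_id: ", paste(unique(df$guide_id[dup_id]), collapse = ", "))
  dup_ps <- duplicated(df$protospacer)
  if (any(dup_ps)) {
    if (!collapse_duplicates)
      stop("duplicate protospacer(s) at row(s) ",
           paste(which(dup_ps), collapse = ", "),
           "; set collapse_duplicates = TRUE to keep first occurrences")
    message("collapsing ", sum(dup_ps),
            " duplicate protospacer(s); keeping first occurrences")
    df <- df[!dup_ps, , drop = FALSE]
    rownames(df) <- NULL
  }
  structure(df, class = c("guide_library", "data.frame"),
            provenance = list(name = name, version = version))
}

#' Load a guide library manifest from a delimited file
#'
#' @param path TSV (or CSV, by extension) with header columns `guide_id`,
#'   `gene`, `protospacer`.
#' @inheritParams guide_library
#' @return A [guide_library] preserving the file's row order.
#' @export
load_library <- function(path, collapse_duplicates = FALSE) {
  if (!file.exists(path)) stop("library file not found: ", path)
  reader <- if (grepl("\\.csv$", path, ignore.case = TRUE)) read.csv else read.delim
  df <- reader(path, colClasses = "character", comment.char = "#",
               check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("guide_id", "gene", "protospacer")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("library file missing column(s): ", paste(miss, collapse = ", "))
  guide_library(df$guide_id, df$gene, df$protospacer,
                name = basename(path), version = "file",
                collapse_duplicates = collapse_duplicates)
}

#' Write a guide library manifest to TSV
#'
#' @param manifest A [guide_library].
#' @param path Output path.
#' @export
write_library <- function(manifest, path) {
  write.table(as.data.frame(manifest), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Guides indexed by gene
#'
#' @param manifest A [guide_library].
#' @return Named list mapping each gene symbol to its guide IDs.
#' @export
guides_by_gene <- function(manifest) {
  split(manifest$guide_id, manifest$gene)
}

#' @export
print.guide_library <- function(x, ...) {
  prov <- attr(x, "provenance")
  cat(sprintf("guide_library: %d guides / %d genes (%s, v%s)\n",
              nrow(x), length(unique(x$gene)), prov$name, prov$version))
  print(utils::head(as.data.frame(x)), ...)
  invisible(x)
}

#' Condition label for a treatment/dose pair
#'
#' Vehicle collapses to `"vehicle"`; drug treatments are labelled
#' `"<treatment>_<dose_level>"` (e.g. `"brigatinib_ED50"`).
#'
#' @param treatment,dose_level Character vectors.
#' @return Character vector of condition labels.
#' @export
condition_label <- function(treatment, dose_level) {
  ifelse(treatment == "vehicle", "vehicle",
         paste(treatment, dose_level, sep = "_"))
}

#' Construct a validated sample sheet
#'
#' @param df Data frame with columns `sample_id`, `cell_line`, `treatment`,
#'   `dose_level`, `replicate`, `timepoint_days` and optionally `source`
#'   (FASTQ path(s), `;`-separated, or a count-file reference).
#' @return A `sample_sheet` data frame.  Day-14 conditions with a replicate
#'   count other than two trigger a warning (the screen design uses
#'   duplicate populations).
#' @export
sample_sheet <- function(df) {
  need <- c("sample_id", "cell_line", "treatment", "dose_level",
            "replicate", "timepoint_days")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("sample sheet missing column(s): ", paste(miss, collapse = ", "))
  if (is.null(df$source)) df$source <- NA_character_
  df <- df[, c(need, "source")]
  df$sample_id <- as.character(df$sample_id)
  df$cell_line <- as.character(df$cell_line)
  df$treatment <- as.character(df$treatment)
  df$dose_level <- as.character(df$dose_level)
  df$replicate <- as.integer(df$replicate)
  df$timepoint_days <- as.integer(df$timepoint_days)
  df$source <- as.character(df$source)

  dup <- duplicated(df$sample_id)
  if (any(dup))
    stop("duplicate sample_id: ", paste(unique(df$sample_id[dup]), collapse = ", "))
  bad_tr <- setdiff(unique(df$treatment), TREATMENT_LEVELS)
  if (length(bad_tr))
    stop("unknown treatment value(s): ", paste(bad_tr, collapse = ", "),
         " (allowed: ", paste(TREATMENT_LEVELS, collapse = ", "), ")")
  bad_dl <- setdiff(unique(df$dose_level), DOSE_LEVELS)
  if (length(bad_dl))
    stop("unknown dose_level value(s): ", paste(bad_dl, collapse = ", "))
  if (any(df$treatment == "vehicle" & df$dose_level != "none"))
    stop("vehicle samples must have dose_level 'none'")
  if (any(df$timepoint_days == 0 & df$treatment != "vehicle"))
    stop("day-0 samples must carry treatment 'vehicle'")
  if (!all(df$timepoint_days %in% c(0L, 14L)))
    stop("timepoint_days must be 0 or 14")
  if (any(is.na(df$replicate)) || any(df$replicate < 1L))
    stop("replicate must be an integer >= 1")

  d14 <- df[df$timepoint_days == 14L, , drop = FALSE]
  if (nrow(d14)) {
    cond <- paste(d14$cell_line, condition_label(d14$treatment, d14$dose_level))
    nrep <- table(cond)
    off <- nrep[nrep != 2L]
    if (length(off))
      warning("condition(s) without two replicates: ",
              paste(sprintf("%s (n=%d)", names(off), as.integer(off)),
                    collapse = "; "), call. = FALSE)
  }
  structure(df, class = c("sample_sheet", "data.frame"))
}

#' Load a sample sheet from CSV
#'
#' @param path CSV with the [sample_sheet] columns.
#' @return A validated `sample_sheet`.
#' @export
load_sample_sheet <- function(path) {
  if (!file.exists(path)) stop("sample sheet not found: ", path)
  df <- read.csv(path, colClasses = "character", comment.char = "#",
                 check.names = FALSE, stringsAsFactors = FALSE)
  sample_sheet(df)
}

#' Write a sample sheet to CSV
#'
#' @param sheet A [sample_sheet].
#' @param path Output path.
#' @export
write_sample_sheet <- function(sheet, path) {
  write.table(as.data.frame(sheet), path, sep = ",",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

.check_count_values <- function(x) {
  if (any(is.na(x))) stop("count matrix contains missing values")
  if (any(x < 0)) stop("count matrix contains negative entries")
  if (any(abs(x - round(x)) > 1e-8)) stop("count matrix contains non-integer entries")
  invisible(TRUE)
}

#' Read a guide-by-sample count matrix
#'
#' Tab-delimited with a header; first column `guide_id`, one column per
#' sample.  Entries must be non-negative integers.  Lines starting with `#`
#' are ignored.
#'
#' @param path Input TSV.
#' @param manifest Optional [guide_library]; if given, the row IDs must
#'   match the manifest exactly (same set).
#' @return Integer matrix with guide IDs as row names and sample IDs as
#'   column names.
#' @export
read_counts <- function(path, manifest = NULL) {
  if (!file.exists(path)) stop("count file not found: ", path)
  df <- read.delim(path, comment.char = "#", check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (names(df)[1] != "guide_id")
    stop("first column of a count file must be 'guide_id'")
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("count matrix contains non-numeric entries")
  .check_count_values(m)
  storage.mode(m) <- "integer"
  rownames(m) <- ids
  if (!is.null(manifest) && !setequal(ids, manifest$guide_id))
    stop("count matrix guide IDs do not match the manifest")
  m
}

#' Write a count matrix to TSV
#'
#' @param counts Integer matrix (guides x samples) with dimnames.
#' @param path Output TSV.
#' @param comment Optional character vector written as leading `#` lines.
#' @export
write_counts <- function(counts, path, comment = NULL) {
  .check_count_values(counts)
  con <- file(path, "w")
  on.exit(close(con))
  if (length(comment)) writeLines(paste0("# ", comment), con)
  writeLines(paste(c("guide_id", colnames(counts)), collapse = "\t"), con)
  body <- apply(counts, 1L, paste, collapse = "\t")
  writeLines(paste(rownames(counts), body, sep = "\t"), con)
  invisible(path)
}

#' Cross-validate manifest, sample sheet and count matrix
#'
#' Pure report-returning check: ID mismatches between the three objects are
#' errors, day-14 conditions with a single replicate are warnings, and
#' zero-count guides per sample are tallied as information.
#'
#' @param manifest A [guide_library].
#' @param sheet A [sample_sheet].
#' @param counts Integer count matrix.
#' @return A `screen_validation` list with elements `errors`, `warnings`,
#'   `zero_count_guides` (per-sample tally) and `ok`.
#' @export
validate_screen <- function(manifest, sheet, counts) {
  errors <- character(0)
  warnings <- character(0)

  extra_g <- setdiff(rownames(counts), manifest$guide_id)
  if (length(extra_g))
    errors <- c(errors, paste0("count rows absent from manifest: ",
                               paste(utils::head(extra_g, 5L), collapse = ", "),
                               if (length(extra_g) > 5) " ..."))
  miss_g <- setdiff(manifest$guide_id, rownames(counts))
  if (length(miss_g))
    errors <- c(errors, paste0("manifest guides absent from counts: ",
                               paste(utils::head(miss_g, 5L), collapse = ", "),
                               if (length(miss_g) > 5) " ..."))
  extra_s <- setdiff(colnames(counts), sheet$sample_id)
  if (length(extra_s))
    errors <- c(errors, paste0("count columns absent from sample sheet: ",
                               paste(extra_s, collapse = ", ")))
  miss_s <- setdiff(sheet$sample_id, colnames(counts))
  if (length(miss_s))
    errors <- c(errors, paste0("sheet samples absent from counts: ",
                               paste(miss_s, collapse = ", ")))

  d14 <- sheet[sheet$timepoint_days == 14L, , drop = FALSE]
  if (nrow(d14)) {
    cond <- paste(d14$cell_line, condition_label(d14$treatment, d14$dose_level))
    nrep <- table(cond)
    single <- nrep[nrep == 1L]
    if (length(single))
      warnings <- c(warnings, paste0("single replicate for condition(s): ",
                                     paste(names(single), collapse = "; ")))
  }
  zero <- colSums(counts == 0L)
  structure(list(errors = errors, warnings = warnings,
                 zero_count_guides = zero, ok = length(errors) == 0L),
            class = "screen_validation")
}

#' @export
print.screen_validation <- function(x, ...) {
  cat("screen validation:", if (x$ok) "OK" else "FAILED", "\n")
  if (length(x$errors)) cat("errors:\n", paste(" -", x$errors, collapse = "\n"), "\n")
  if (length(x$warnings)) cat("warnings:\n", paste(" -", x$warnings, collapse = "\n"), "\n")
  invisible(x)
}
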