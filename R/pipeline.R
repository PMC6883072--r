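# End-to-end orchestration: simulate (or load) a screen, optionally round
# it through FASTQ emission and counting, call hits, and write a run
# directory with a machine-readable manifest.  All randomness flows from
# the config seed, so identical configs produce byte-identical outputs.

#' Pipeline run configuration
#'
#' Either simulate a screen (`library_path = NULL`) or analyse existing
#' inputs (`library_path`, `sample_sheet_path`, `counts_path`).  A YAML
#' file with the same keys can seed the configuration; explicit arguments
#' override file values.
#'
#' @param n_genes,guides_per_gene,coverage,planted_genes,rescue,replicates,depth
#'   Simulation parameters (see [screen_sim_config]).
#' @param threshold Fold-change enrichment threshold (strict `>`).
#' @param min_guides Minimum enriched guides per gene hit.
#' @param levels Dose level(s) used for the candidate intersection.
#' @param norm A [norm_config].
#' @param fastq Route simulated counts through FASTQ emission and
#'   exact-match counting (exercises the full read path).
#' @param anchor An [anchor_config] for FASTQ emission/counting.
#' @param library_path,sample_sheet_path,counts_path Existing inputs; when
#'   all three are given the simulation stage is skipped.
#' @param seed Integer seed for the whole run.
#' @param yaml Optional YAML file of defaults.
#' @return A `run_config` list.
#' @export
run_config <- function(n_genes = 300L, guides_per_gene = 3L, coverage = 500,
                       planted_genes = 5L, rescue = 1, replicates = 2L,
                       depth = 2e6, threshold = 1.5, min_guides = 2L,
                       levels = c("ED50", "ED75"), norm = norm_config(),
                       fastq = FALSE, anchor = anchor_config(),
                       library_path = NULL, sample_sheet_path = NULL,
                       counts_path = NULL, seed = 1L, yaml = NULL) {
  cfg <- as.list(environment())
  cfg$yaml <- NULL
  if (!is.null(yaml)) {
    if (!file.exists(yaml)) stop("config file not found: ", yaml)
    file_cfg <- yaml::read_yaml(yaml)
    supplied <- names(match.call())[-1]
    for (key in setdiff(names(file_cfg), c(supplied, "yaml"))) {
      if (!key %in% names(cfg)) stop("unknown config key in YAML: ", key)
      cfg[[key]] <- file_cfg[[key]]
    }
  }
  cfg$seed <- as.integer(cfg$seed)
  if (is.na(cfg$seed)) stop("seed must be an integer")
  paths <- c(cfg$library_path, cfg$sample_sheet_path, cfg$counts_path)
  if (length(paths) && any(!file.exists(paths)))
    stop("configured input path(s) not found: ",
         paste(paths[!file.exists(paths)], collapse = ", "))
  structure(cfg, class = "run_config")
}

.config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  plain <- lapply(config, function(x) if (is.list(x)) unclass(x) else x)
  jsonlite::write_json(plain, tmp, auto_unbox = TRUE, digits = NA,
                       null = "null")
  unname(tools::md5sum(tmp))
}

#' Run the full screen pipeline
#'
#' Simulate (or load), optionally count from FASTQ, normalize, compute
#' fold changes, call gene hits with significance, intersect candidates,
#' and write everything plus a JSON run manifest (config, package version,
#' seed, output checksums) into `out_dir`.  Deterministic given config:
#' re-running with the same config yields byte-identical outputs.
#'
#' @param config A [run_config].
#' @param out_dir Output directory (created; must not contain a previous
#'   manifest unless `overwrite`).
#' @param overwrite Allow writing into a directory with existing outputs.
#' @return Invisibly, a list with the key tables (`candidates`,
#'   `gene_hits`, `guide_enrichment`, `validation`) and `paths` of all
#'   files written.
#' @export
run_pipeline <- function(config, out_dir, overwrite = FALSE) {
  if (!inherits(config, "run_config")) stop("config must be a run_config")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest_path <- file.path(out_dir, "run_manifest.json")
  if (file.exists(manifest_path) && !overwrite)
    stop("output directory already contains a run; set overwrite = TRUE")
  hash <- .config_hash(config)
  hdr <- paste0("config_hash: ", hash)

  simulate <- is.null(config$library_path)
  if (simulate) {
    lib <- make_library(config$n_genes, config$guides_per_gene,
                        seed = config$seed)
    sim_cfg <- screen_sim_config(
      n_genes = config$n_genes, guides_per_gene = config$guides_per_gene,
      coverage = config$coverage, planted_genes = config$planted_genes,
      rescue = config$rescue, replicates = config$replicates,
      depth = config$depth, seed = config$seed + 1L)
    sim <- simulate_screen(lib, sim_cfg)
    sheet <- sim$samples
    counts <- sim$counts
    truth <- sim$truth
  } else {
    lib <- load_library(config$library_path)
    sheet <- load_sample_sheet(config$sample_sheet_path)
    counts <- read_counts(config$counts_path, manifest = lib)
    truth <- NULL
  }

  qc <- NULL
  if (isTRUE(config$fastq)) {
    fq_dir <- file.path(out_dir, "fastq")
    dir.create(fq_dir, showWarnings = FALSE)
    for (i in seq_len(nrow(sheet))) {
      sid <- sheet$sample_id[i]
      fq <- file.path(fq_dir, paste0(sid, ".fastq.gz"))
      emit_fastq(counts[, sid], lib, fq, config = config$anchor,
                 seed = config$seed + 1L + i)
      sheet$source[i] <- fq
    }
    counted <- count_screen(sheet, lib, config$anchor)
    counts <- counted$counts
    qc <- counted$qc
    # record sources relative to the run directory so identical configs
    # produce byte-identical sheets regardless of out_dir
    sheet$source <- file.path("fastq", basename(sheet$source))
  }

  validation <- validate_screen(lib, sheet, counts)
  if (!validation$ok)
    stop("screen validation failed: ",
         paste(validation$errors, collapse = "; "))

  avg <- average_replicates(counts, sheet)
  nl <- normalize_and_log(avg, config$norm)
  per_rep <- normalize_and_log(
    counts[, sheet$sample_id[sheet$timepoint_days == 14L], drop = FALSE],
    config$norm)

  treated <- setdiff(colnames(avg), "vehicle")
  guide_tbl <- NULL
  gene_tbl <- NULL
  reg_tbl <- NULL
  for (cond in treated) {
    gt <- guide_fold_changes(nl, lib, cond, threshold = config$threshold)
    pv <- gene_significance_all(per_rep$log, sheet, lib, cond)
    gh <- call_gene_hits(gt, lib, min_guides = config$min_guides,
                         p_values = pv)
    rd <- regression_diagnostic(nl, cond)
    guide_tbl <- rbind(guide_tbl, gt)
    gene_tbl <- rbind(gene_tbl, gh)
    reg_tbl <- rbind(reg_tbl, data.frame(condition = cond, slope = rd$slope,
                                         intercept = rd$intercept,
                                         r_squared = rd$r_squared))
  }
  candidates <- candidate_genes(gene_tbl, levels = config$levels)
  gene_tbl$candidate <- gene_tbl$gene %in% candidates

  write_tsv <- function(df, name) {
    p <- file.path(out_dir, name)
    con <- file(p, "w")
    writeLines(paste0("# ", hdr), con)
    close(con)
    suppressWarnings(
      write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE,
                  append = TRUE))
    p
  }
  paths <- c(
    library = write_library(lib, file.path(out_dir, "library.tsv")),
    samples = write_sample_sheet(sheet, file.path(out_dir, "samples.csv")),
    counts = write_counts(counts, file.path(out_dir, "counts.tsv"),
                          comment = hdr),
    guide_enrichment = write_tsv(guide_tbl, "guide_enrichment.tsv"),
    gene_hits = write_tsv(gene_tbl, "gene_hits.tsv"),
    candidates = write_tsv(data.frame(gene = candidates), "candidates.tsv"),
    regression = write_tsv(reg_tbl, "regression.tsv"))
  if (!is.null(qc)) paths <- c(paths, qc = write_tsv(qc, "counting_qc.tsv"))
  if (!is.null(truth)) {
    tp <- file.path(out_dir, "truth.json")
    jsonlite::write_json(truth, tp, auto_unbox = TRUE, digits = NA)
    paths <- c(paths, truth = tp)
  }

  manifest <- list(
    package = "crisprares",
    version = as.character(utils::packageVersion("crisprares")),
    config = lapply(unclass(config), function(x) if (is.list(x)) unclass(x) else x),
    config_hash = hash,
    seed = config$seed,
    outputs = as.list(setNames(unname(tools::md5sum(paths)), names(paths))))
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  paths <- c(paths, manifest = manifest_path)

  invisible(list(candidates = candidates, gene_hits = gene_tbl,
                 guide_enrichment = guide_tbl, validation = validation,
                 qc = qc, paths = paths))
}
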