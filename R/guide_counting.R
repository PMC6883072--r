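# Guide quantification from single-end FASTQ reads by exact protospacer
# matching.  The library prep places a 1-8 nt stagger, then a constant
# anchor, then the 20-nt protospacer on each forward read, so anchor-based
# extraction is the default locator; a full-offset scan is the fallback
# when no anchor is configured.  No mismatch tolerance and no
# reverse-complement search (the construct is directional).

#' Default anchor sequence
#'
#' The U6-cassette suffix that immediately precedes the protospacer in
#' common lentiviral gRNA vectors.  It has no self-overlap under shifts of
#' 1-8 nt, so a random stagger cannot create a spurious earlier occurrence.
#'
#' @export
DEFAULT_ANCHOR <- "GGAAAGGACGAAACACCG"

#' Read-structure configuration for guide extraction
#'
#' @param anchor Constant sequence expected immediately 5' of the
#'   protospacer; empty string switches extraction to full-offset scanning.
#' @param max_stagger Maximum stagger offset (nt) before the anchor.
#' @param read_length Expected read length (nt); informational, reads of
#'   other lengths are still processed.
#' @return An `anchor_config` list.
#' @export
anchor_config <- function(anchor = DEFAULT_ANCHOR, max_stagger = 8L,
                          read_length = 100L) {
  if (nchar(anchor) > 0 && !grepl("^[ACGT]+$", anchor))
    stop("anchor must be over A/C/G/T")
  max_stagger <- as.integer(max_stagger)
  if (is.na(max_stagger) || max_stagger < 0L) stop("max_stagger must be >= 0")
  read_length <- as.integer(read_length)
  if (is.na(read_length) || read_length < 20L + nchar(anchor))
    stop("read_length too short for anchor + 20-nt protospacer")
  structure(list(anchor = anchor, max_stagger = max_stagger,
                 read_length = read_length), class = "anchor_config")
}

# Vectorised resolution of reads to guide IDs.  Returns a data.frame with
# guide_id (NA unless matched) and status in {matched, unmatched, ambiguous}.
.resolve_reads <- function(reads, manifest, config) {
  n <- length(reads)
  guide_id <- rep(NA_character_, n)
  status <- rep("unmatched", n)
  if (n == 0L)
    return(data.frame(guide_id = character(0), status = character(0),
                      stringsAsFactors = FALSE))
  len <- nchar(reads)
  protos <- manifest$protospacer
  ids <- manifest$guide_id

  if (nchar(config$anchor) > 0) {
    la <- nchar(config$anchor)
    pos <- rep(NA_integer_, n)                # anchor start, 1-based
    for (s in 0:config$max_stagger) {
      open <- is.na(pos) & len >= s + la + 20L
      if (!any(open)) next
      hit <- open & substr(reads, s + 1L, s + la) == config$anchor
      pos[hit] <- s + 1L
    }
    has <- !is.na(pos)
    if (any(has)) {
      ps <- substr(reads[has], pos[has] + la, pos[has] + la + 19L)
      idx <- match(ps, protos)
      ok <- !is.na(idx)
      w <- which(has)[ok]
      guide_id[w] <- ids[idx[ok]]
      status[w] <- "matched"
    }
  } else {
    # scan every offset; a read matches only if exactly one library guide
    # matches at exactly one offset
    nmatch <- integer(n)
    first <- rep(NA_character_, n)
    maxoff <- max(len) - 20L
    if (maxoff >= 0L) {
      for (s in 0:maxoff) {
        cand <- len >= s + 20L
        if (!any(cand)) break
        km <- substr(reads, s + 1L, s + 20L)
        idx <- match(km, protos)
        m <- cand & !is.na(idx)
        if (!any(m)) next
        new <- m & nmatch == 0L
        first[new] <- ids[idx[new]]
        nmatch[m] <- nmatch[m] + 1L
      }
    }
    one <- nmatch == 1L
    guide_id[one] <- first[one]
    status[one] <- "matched"
    status[nmatch > 1L] <- "ambiguous"
  }
  data.frame(guide_id = guide_id, status = status, stringsAsFactors = FALSE)
}

#' Resolve read sequences to library guides
#'
#' With a non-empty anchor, the first anchor occurrence within the stagger
#' window locates the protospacer and the following 20-mer must match a
#' library guide exactly.  With an empty anchor every offset is scanned and
#' a read is matched only when exactly one guide matches at exactly one
#' offset; anything else is ambiguous.  Reads too short for an extraction
#' are unmatched, not errors.
#'
#' @param reads Character vector of read sequences.
#' @param manifest A [guide_library].
#' @param config An [anchor_config].
#' @return Data frame with one row per read: `guide_id` (`NA` unless
#'   matched) and `status` (`matched`/`unmatched`/`ambiguous`).
#' @export
extract_protospacer <- function(reads, manifest, config = anchor_config()) {
  .resolve_reads(toupper(as.character(reads)), manifest, config)
}

.read_fastq_seqs <- function(path) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path)
  seqs <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fastq"),
    error = function(e) stop("failed to parse FASTQ '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  as.character(seqs)
}

.empty_qc <- function() {
  data.frame(total_reads = 0L, matched_reads = 0L, ambiguous_reads = 0L,
             unmatched_reads = 0L, match_rate = 0)
}

#' Count library guides in one sample's FASTQ file(s)
#'
#' Multiple files are summed.  QC satisfies the conservation identity
#' matched + ambiguous + unmatched = total, and `match_rate` is 0 for an
#' empty sample.
#'
#' @param fastq Character vector of FASTQ paths (plain or gzipped).
#' @param manifest A [guide_library].
#' @param config An [anchor_config].
#' @return List with `counts` (named integer vector over the manifest's
#'   guides) and `qc` (one-row data frame).
#' @export
count_sample <- function(fastq, manifest, config = anchor_config()) {
  counts <- setNames(integer(nrow(manifest)), manifest$guide_id)
  qc <- .empty_qc()
  for (f in fastq) {
    reads <- .read_fastq_seqs(f)
    res <- .resolve_reads(reads, manifest, config)
    idx <- match(res$guide_id[res$status == "matched"], manifest$guide_id)
    counts <- counts + tabulate(idx, nbins = nrow(manifest))
    qc$total_reads <- qc$total_reads + length(reads)
    qc$matched_reads <- qc$matched_reads + sum(res$status == "matched")
    qc$ambiguous_reads <- qc$ambiguous_reads + sum(res$status == "ambiguous")
    qc$unmatched_reads <- qc$unmatched_reads + sum(res$status == "unmatched")
  }
  qc$match_rate <- if (qc$total_reads > 0) qc$matched_reads / qc$total_reads else 0
  list(counts = counts, qc = qc)
}

.is_fastq_source <- function(s) grepl("\\.(fastq|fq)(\\.gz)?$", s, ignore.case = TRUE)

#' Count a whole screen from its sample sheet
#'
#' Each sample's `source` is either one or more FASTQ paths separated by
#' `;`, or a count-file reference `path.tsv` / `path.tsv#column` whose
#' column (default: the sample ID) is copied through.  Copied-through
#' columns are reported in QC as fully matched.  Columns are processed
#' independently, so sample order is irrelevant.
#'
#' @param sheet A [sample_sheet] with resolvable sources.
#' @param manifest A [guide_library].
#' @param config An [anchor_config].
#' @return List with `counts` (guides x samples integer matrix) and `qc`
#'   (one row per sample).
#' @export
count_screen <- function(sheet, manifest, config = anchor_config()) {
  G <- nrow(manifest)
  counts <- matrix(0L, G, nrow(sheet),
                   dimnames = list(manifest$guide_id, sheet$sample_id))
  qc <- NULL
  for (i in seq_len(nrow(sheet))) {
    sid <- sheet$sample_id[i]
    src <- sheet$source[i]
    if (is.na(src) || !nzchar(src))
      stop("sample '", sid, "' has no source")
    parts <- trimws(strsplit(src, ";", fixed = TRUE)[[1]])
    if (all(.is_fastq_source(parts))) {
      missing <- parts[!file.exists(parts)]
      if (length(missing))
        stop("missing FASTQ for sample '", sid, "': ",
             paste(missing, collapse = ", "))
      res <- count_sample(parts, manifest, config)
      counts[, sid] <- res$counts
      row <- res$qc
    } else {
      ref <- strsplit(parts[1], "#", fixed = TRUE)[[1]]
      if (!file.exists(ref[1]))
        stop("missing count file for sample '", sid, "': ", ref[1])
      cm <- read_counts(ref[1])
      col <- if (length(ref) > 1) ref[2] else sid
      if (!col %in% colnames(cm))
        stop("column '", col, "' not found in ", ref[1], " for sample '", sid, "'")
      v <- cm[match(manifest$guide_id, rownames(cm)), col]
      if (anyNA(v))
        stop("count file for sample '", sid, "' lacks manifest guides")
      counts[, sid] <- v
      row <- data.frame(total_reads = sum(v), matched_reads = sum(v),
                        ambiguous_reads = 0L, unmatched_reads = 0L,
                        match_rate = if (sum(v) > 0) 1 else 0)
    }
    row <- cbind(sample_id = sid, row)
    qc <- rbind(qc, row)
  }
  rownames(qc) <- NULL
  list(counts = counts, qc = qc)
}
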