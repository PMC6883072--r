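# Enrichment analysis for a day-14 screen: raw replicate counts are
# averaged per condition, normalized to total guide read count, and
# log-transformed; guides with fold change strictly greater than the
# threshold (default 1.5) against vehicle are enriched, genes with at
# least `min_guides` enriched guides are hits, and candidates are genes
# hit by both drugs at a given dose level.

#' Normalization configuration
#'
#' @param scale Target column total after normalization (default 1e6, i.e.
#'   reads per million).
#' @param pseudocount Added before the log transform and inside fold-change
#'   ratios (default 1).
#' @param log_base Base of the log transform, 2 or 10 (default 2).
#' @return A `norm_config` list.
#' @export
norm_config <- function(scale = 1e6, pseudocount = 1, log_base = 2) {
  if (!is.numeric(scale) || scale <= 0) stop("scale must be > 0")
  if (!is.numeric(pseudocount) || pseudocount < 0) stop("pseudocount must be >= 0")
  if (!log_base %in% c(2, 10)) stop("log_base must be 2 or 10")
  structure(list(scale = scale, pseudocount = pseudocount,
                 log_base = log_base), class = "norm_config")
}

#' Average raw replicate counts per condition
#'
#' Arithmetic mean of raw counts across biological replicates of each
#' day-14 condition, computed before normalization (averaging first is the
#' pipeline's stated order of operations; see [normalize_and_log]).
#'
#' @param counts Guide x sample count matrix.
#' @param sheet A [sample_sheet].
#' @param timepoint Timepoint (days) whose samples form the analysis
#'   conditions; defaults to 14.  Day-0 samples are QC-only and excluded.
#' @param normalize_first Scale each replicate column to `config$scale`
#'   before averaging.  The default (`FALSE`) averages raw counts, the
#'   pipeline's canonical order; normalizing first makes downstream
#'   results invariant to per-replicate sequencing depth.
#' @param config A [norm_config] (used only when `normalize_first`).
#' @return Numeric matrix, guides x conditions (see [condition_label]).
#' @export
average_replicates <- function(counts, sheet, timepoint = 14L,
                               normalize_first = FALSE,
                               config = norm_config()) {
  sub <- sheet[sheet$timepoint_days == timepoint, , drop = FALSE]
  if (!nrow(sub)) stop("no samples at timepoint ", timepoint)
  missing <- setdiff(sub$sample_id, colnames(counts))
  if (length(missing))
    stop("samples absent from count matrix: ", paste(missing, collapse = ", "))
  if (normalize_first) {
    totals <- colSums(counts)
    if (any(totals <= 0)) stop("all-zero sample column(s)")
    counts <- sweep(counts, 2L, totals, "/") * config$scale
  }
  cond <- condition_label(sub$treatment, sub$dose_level)
  out <- vapply(split(sub$sample_id, cond), function(sids)
    rowMeans(counts[, sids, drop = FALSE]), numeric(nrow(counts)))
  rownames(out) <- rownames(counts)
  out
}

#' Normalize to total guide read count and log-transform
#'
#' Each column is scaled to sum to `scale` (so columns are comparable
#' regardless of sequencing depth), then shifted by the pseudocount and
#' log-transformed.
#'
#' @param counts Numeric matrix (guides x conditions or guides x samples);
#'   every column must have a positive total.
#' @param config A [norm_config].
#' @return List with `normalized` and `log` matrices plus the `config`.
#' @export
normalize_and_log <- function(counts, config = norm_config()) {
  totals <- colSums(counts)
  if (any(totals <= 0))
    stop("all-zero column(s): ",
         paste(colnames(counts)[totals <= 0], collapse = ", "))
  normalized <- sweep(counts, 2L, totals, "/") * config$scale
  logmat <- log(normalized + config$pseudocount, base = config$log_base)
  list(normalized = normalized, log = logmat, config = config)
}

#' Per-guide fold changes against vehicle
#'
#' Fold change is the pseudocount-stabilized ratio of normalized
#' abundances, `(treated + p) / (vehicle + p)`; a guide is enriched iff its
#' fold change strictly exceeds the threshold.
#'
#' @param normlog Result of [normalize_and_log] on condition-averaged
#'   counts.
#' @param manifest A [guide_library] supplying guide-to-gene mapping.
#' @param treated_condition Condition label of the drug-treated column.
#' @param dmso_condition Condition label of the vehicle column.
#' @param threshold Enrichment threshold on the fold change (strict `>`).
#' @return Data frame with one row per guide: normalized and log
#'   abundances in both conditions, `fold_change`, `diff_log` and the
#'   `enriched` flag.
#' @export
guide_fold_changes <- function(normlog, manifest, treated_condition,
                               dmso_condition = "vehicle", threshold = 1.5) {
  norm <- normlog$normalized
  for (cond in c(dmso_condition, treated_condition))
    if (!cond %in% colnames(norm)) stop("condition not present: ", cond)
  idx <- match(rownames(norm), manifest$guide_id)
  if (anyNA(idx)) stop("guides absent from manifest")
  p <- normlog$config$pseudocount
  fc <- (norm[, treated_condition] + p) / (norm[, dmso_condition] + p)
  data.frame(
    guide_id = rownames(norm),
    gene = manifest$gene[idx],
    condition = treated_condition,
    norm_dmso = norm[, dmso_condition],
    norm_treated = norm[, treated_condition],
    log_dmso = normlog$log[, dmso_condition],
    log_treated = normlog$log[, treated_condition],
    fold_change = fc,
    diff_log = normlog$log[, treated_condition] - normlog$log[, dmso_condition],
    enriched = fc > threshold,
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Call gene-level hits from guide enrichment
#'
#' A gene is enriched when at least `min_guides` of its guides are
#' enriched ("multiple gRNAs exceeding the threshold").
#'
#' @param guide_tbl Output of [guide_fold_changes].
#' @param manifest A [guide_library].
#' @param min_guides Minimum number of enriched guides (default 2).
#' @param p_values Optional named per-gene p-values (see
#'   [gene_significance]) carried into the table.
#' @return Data frame with one row per gene: `n_guides_total`,
#'   `n_guides_enriched`, `max_fold_change`, `enriched`, `p_value`.
#' @export
call_gene_hits <- function(guide_tbl, manifest, min_guides = 2L,
                           p_values = NULL) {
  if (anyNA(guide_tbl$gene)) stop("guide(s) without a gene annotation")
  sp <- split(seq_len(nrow(guide_tbl)), guide_tbl$gene)
  genes <- names(sp)
  n_tot <- vapply(sp, length, integer(1))
  n_enr <- vapply(sp, function(i) sum(guide_tbl$enriched[i]), integer(1))
  max_fc <- vapply(sp, function(i) max(guide_tbl$fold_change[i]), numeric(1))
  pv <- if (is.null(p_values)) rep(NA_real_, length(genes))
        else unname(p_values[genes])
  data.frame(
    gene = genes,
    condition = guide_tbl$condition[1],
    n_guides_total = n_tot,
    n_guides_enriched = n_enr,
    max_fold_change = max_fc,
    enriched = n_enr >= min_guides,
    p_value = pv,
    row.names = NULL, stringsAsFactors = FALSE)
}

# Unpaired two-sided Student's t with an explicit zero-variance guard:
# both groups constant and equal -> t = 0, p = 1; constant but different
# -> t = Inf, p = 0.
.student_t <- function(x, y, var_equal = TRUE) {
  if (length(x) < 2L || length(y) < 2L)
    stop("each group needs at least 2 values")
  if (var(x) == 0 && var(y) == 0) {
    if (isTRUE(all.equal(mean(x), mean(y))))
      return(list(statistic = 0, p_value = 1))
    return(list(statistic = Inf, p_value = 0))
  }
  ht <- t.test(x, y, var.equal = var_equal)
  list(statistic = unname(ht$statistic), p_value = ht$p.value)
}

#' Per-gene significance of enrichment
#'
#' Unpaired two-sided Student's t-test comparing a gene's log-normalized
#' per-replicate guide abundances between vehicle and a treated condition.
#' The gene's guides are pooled across replicates (3 guides x 2 replicates
#' = 6 values per arm at the screen's design scale); equal variances are
#' assumed by default.
#'
#' @param log_per_sample Guide x sample matrix of log-normalized counts
#'   (per replicate, i.e. [normalize_and_log] applied to the raw count
#'   matrix).
#' @param sheet A [sample_sheet].
#' @param manifest A [guide_library].
#' @param gene Gene symbol.
#' @param treated_condition,dmso_condition Condition labels.
#' @param var_equal Assume equal variances (classic Student's t).
#' @return List with `statistic` and `p_value`.
#' @export
gene_significance <- function(log_per_sample, sheet, manifest, gene,
                              treated_condition, dmso_condition = "vehicle",
                              var_equal = TRUE) {
  gids <- manifest$guide_id[manifest$gene == gene]
  if (!length(gids)) stop("gene not in manifest: ", gene)
  d14 <- sheet[sheet$timepoint_days == 14L, , drop = FALSE]
  cond <- condition_label(d14$treatment, d14$dose_level)
  s_tr <- d14$sample_id[cond == treated_condition]
  s_dm <- d14$sample_id[cond == dmso_condition]
  if (!length(s_tr)) stop("condition not present: ", treated_condition)
  if (!length(s_dm)) stop("condition not present: ", dmso_condition)
  x <- as.vector(log_per_sample[gids, s_tr, drop = FALSE])
  y <- as.vector(log_per_sample[gids, s_dm, drop = FALSE])
  .student_t(x, y, var_equal = var_equal)
}

#' Per-gene significance for every gene
#'
#' @inheritParams gene_significance
#' @return Named numeric vector of two-sided p-values.
#' @export
gene_significance_all <- function(log_per_sample, sheet, manifest,
                                  treated_condition,
                                  dmso_condition = "vehicle",
                                  var_equal = TRUE) {
  genes <- unique(manifest$gene)
  vapply(genes, function(g)
    gene_significance(log_per_sample, sheet, manifest, g, treated_condition,
                      dmso_condition, var_equal)$p_value,
    numeric(1))
}

#' Candidate genes by dual-drug intersection
#'
#' At a given dose level, candidates are genes enriched under both drugs;
#' with several levels the per-level candidate sets are unioned (the
#' screen's overall candidate list).
#'
#' @param gene_hits Data frame of gene hits covering all required
#'   conditions (rows from [call_gene_hits], concatenated).
#' @param levels Dose level(s), e.g. `"ED50"` or `c("ED50", "ED75")`.
#' @param drugs Treatments intersected at each level.
#' @return Sorted character vector of candidate gene symbols.
#' @export
candidate_genes <- function(gene_hits, levels = "ED50",
                            drugs = c("brigatinib", "ceritinib")) {
  per_level <- lapply(levels, function(lv) {
    sets <- lapply(drugs, function(d) {
      cond <- condition_label(d, lv)
      sub <- gene_hits[gene_hits$condition == cond, , drop = FALSE]
      if (!nrow(sub)) stop("missing condition in gene hits: ", cond)
      sub$gene[sub$enriched]
    })
    Reduce(intersect, sets)
  })
  sort(unique(unlist(per_level)))
}

#' Overlap of candidate sets across cell lines
#'
#' @param sets Named list of candidate gene vectors (one per cell line).
#' @return Sorted character vector of genes present in every set.
#' @export
candidate_overlap <- function(sets) {
  sort(Reduce(intersect, sets))
}

#' Rank guides by fold change
#'
#' Stable descending sort on fold change, ties broken by lexicographic
#' guide ID.
#'
#' @param guide_tbl Output of [guide_fold_changes].
#' @return The table reordered, with a `rank` column prepended.
#' @export
rank_guides <- function(guide_tbl) {
  ord <- order(-guide_tbl$fold_change, guide_tbl$guide_id)
  out <- guide_tbl[ord, , drop = FALSE]
  rownames(out) <- NULL
  cbind(rank = seq_len(nrow(out)), out)
}

#' Regression diagnostic of treated on vehicle log abundance
#'
#' Ordinary least squares of treated log-normalized abundance on vehicle
#' log-normalized abundance; a large positive residual flags an enrichment
#' outlier.
#'
#' @param normlog Result of [normalize_and_log] on condition-averaged
#'   counts.
#' @param treated_condition,dmso_condition Condition labels.
#' @return List with `condition`, `slope`, `intercept`, `r_squared` and
#'   named per-guide `residuals` (which sum to zero).
#' @export
regression_diagnostic <- function(normlog, treated_condition,
                                  dmso_condition = "vehicle") {
  logm <- normlog$log
  for (cond in c(dmso_condition, treated_condition))
    if (!cond %in% colnames(logm)) stop("condition not present: ", cond)
  if (nrow(logm) < 2L) stop("need at least 2 guides")
  x <- logm[, dmso_condition]
  y <- logm[, treated_condition]
  if (var(x) == 0) stop("zero variance in vehicle log abundances")
  fit <- lm(y ~ x)
  list(condition = treated_condition,
       slope = unname(coef(fit)[2]),
       intercept = unname(coef(fit)[1]),
       r_squared = 1 - sum(resid(fit)^2) / sum((y - mean(y))^2),
       residuals = setNames(resid(fit), rownames(logm)))
}
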