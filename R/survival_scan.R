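# Expression-cutoff survival association: Kaplan-Meier estimation,
# log-rank testing, an exhaustive "scan" over admissible expression
# cutoffs with within-gene Bonferroni correction, and a multi-gene driver.

#' Kaplan-Meier survival estimate
#'
#' Product-limit estimator; the median is the smallest time at which the
#' estimated survival drops to 0.5 or below (`NA` when the curve never
#' reaches 0.5).
#'
#' @param time Positive event/censoring times.
#' @param event Event indicator (1 = event, 0 = censored).
#' @return A `km_fit` list: `time`, `surv`, `n_risk`, `n_event`, `n`,
#'   `median` and `survfun` (right-continuous step function).
#' @export
km_estimate <- function(time, event) {
  if (!length(time)) stop("no records")
  if (any(time <= 0)) stop("times must be > 0")
  if (!all(event %in% c(0, 1))) stop("event must be 0 or 1")
  sf <- survival::survfit(survival::Surv(time, event) ~ 1)
  med <- sf$time[sf$surv <= 0.5 + 1e-12]
  med <- if (length(med)) med[1] else NA_real_
  structure(list(time = sf$time, surv = sf$surv, n_risk = sf$n.risk,
                 n_event = sf$n.event, n = length(time), median = med,
                 survfun = stepfun(sf$time, c(1, sf$surv), right = FALSE)),
            class = "km_fit")
}

#' @export
print.km_fit <- function(x, ...) {
  cat(sprintf("Kaplan-Meier estimate: n=%d, events=%d, median=%s\n",
              x$n, sum(x$n_event),
              if (is.na(x$median)) "not reached" else format(x$median)))
  invisible(x)
}

#' Two-group log-rank (Mantel-Cox) test
#'
#' @param time Positive event/censoring times.
#' @param event Event indicator (1 = event, 0 = censored).
#' @param group Two-level grouping vector.
#' @return List with the 1-df chi-square `statistic`, two-sided `p_value`,
#'   and per-group observed/expected event counts.
#' @export
logrank_test <- function(time, event, group) {
  group <- as.factor(group)
  if (nlevels(droplevels(group)) != 2L) stop("need exactly 2 non-empty groups")
  if (sum(event) < 1) stop("need at least one event")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  list(statistic = unname(sd$chisq),
       p_value = pchisq(sd$chisq, df = 1, lower.tail = FALSE),
       observed = sd$obs, expected = sd$exp)
}

#' Optimal expression cutoff by exhaustive scan
#'
#' Every cutoff at the midpoint between consecutive distinct expression
#' values is tested by log-rank (low vs high expression), subject to both
#' groups containing at least `max(3, min_group_fraction * n)` subjects.
#' The best cutoff minimizes the raw log-rank p-value (ties broken toward
#' the smaller cutoff), and the within-gene Bonferroni-corrected p-value
#' multiplies by the number of cutoffs actually tested.
#'
#' @param expression Per-subject expression values (no missing values).
#' @param time Positive event/censoring times.
#' @param event Event indicator (1 = event, 0 = censored).
#' @param min_group_fraction Minimum group size as a fraction of the
#'   cohort (floored at 3 subjects per side).
#' @return A `scan_result` list: `best_cutoff`, `raw_p`,
#'   `n_cutoffs_tested`, `corrected_p`, group sizes at the best cutoff and
#'   the per-cutoff table.
#' @export
scan_cutoff <- function(expression, time, event, min_group_fraction = 0.05) {
  n <- length(expression)
  if (anyNA(expression)) stop("missing expression values")
  if (length(time) != n || length(event) != n)
    stop("expression, time and event must have equal length")
  vals <- sort(unique(expression))
  if (length(vals) < 2L) stop("constant expression: no valid cutoff")
  if (sum(event) < 1) stop("need at least one event")
  cuts <- (vals[-1] + vals[-length(vals)]) / 2
  min_n <- max(3L, ceiling(min_group_fraction * n))
  p <- rep(NA_real_, length(cuts))
  for (i in seq_along(cuts)) {
    high <- expression > cuts[i]
    if (min(sum(high), sum(!high)) < min_n) next
    grp_events <- c(sum(event[high]), sum(event[!high]))
    if (sum(grp_events) < 1) next
    p[i] <- logrank_test(time, event, high)$p_value
  }
  tested <- !is.na(p)
  if (!any(tested))
    stop("no admissible cutoff (group-size constraint unmet)")
  m <- sum(tested)
  best <- which.min(p)                     # first minimum = smallest cutoff
  high <- expression > cuts[best]
  structure(list(best_cutoff = cuts[best], raw_p = p[best],
                 n_cutoffs_tested = m,
                 corrected_p = min(1, p[best] * m),
                 n_high = sum(high), n_low = sum(!high),
                 cutoffs = data.frame(cutoff = cuts[tested], p = p[tested])),
            class = "scan_result")
}

#' @export
print.scan_result <- function(x, ...) {
  cat(sprintf("scan: best cutoff %.4g (n_low=%d, n_high=%d), raw p=%.3g, corrected p=%.3g over %d cutoffs\n",
              x$best_cutoff, x$n_low, x$n_high, x$raw_p, x$corrected_p,
              x$n_cutoffs_tested))
  invisible(x)
}

#' Scan every gene of an expression matrix against survival
#'
#' Runs [scan_cutoff] per gene; per-gene errors (e.g. constant expression)
#' are recorded, not fatal.  With `across_gene_correction` a second
#' Bonferroni factor equal to the number of genes is applied on top of the
#' within-gene correction.
#'
#' @param expression Subjects x genes numeric matrix (column names are the
#'   gene symbols).
#' @param time Positive event/censoring times.
#' @param event Event indicator (1 = event, 0 = censored).
#' @param alpha Significance level for the reported fraction.
#' @param across_gene_correction Apply the across-gene Bonferroni factor.
#' @param min_group_fraction Passed to [scan_cutoff].
#' @return A `survival_screen` list with the per-gene `results` data
#'   frame, `n_significant` and `fraction_significant` at `alpha`.
#' @export
screen_genes <- function(expression, time, event, alpha = 0.05,
                         across_gene_correction = FALSE,
                         min_group_fraction = 0.05) {
  expression <- as.matrix(expression)
  genes <- colnames(expression)
  if (is.null(genes)) genes <- paste0("gene", seq_len(ncol(expression)))
  n_genes <- ncol(expression)
  rows <- lapply(seq_len(n_genes), function(j) {
    res <- tryCatch(
      scan_cutoff(expression[, j], time, event, min_group_fraction),
      error = function(e) e)
    if (inherits(res, "error")) {
      return(data.frame(gene = genes[j], best_cutoff = NA_real_,
                        raw_p = NA_real_, n_cutoffs_tested = NA_integer_,
                        corrected_p = NA_real_, final_p = NA_real_,
                        error = conditionMessage(res),
                        stringsAsFactors = FALSE))
    }
    fp <- if (across_gene_correction) min(1, res$corrected_p * n_genes)
          else res$corrected_p
    data.frame(gene = genes[j], best_cutoff = res$best_cutoff,
               raw_p = res$raw_p, n_cutoffs_tested = res$n_cutoffs_tested,
               corrected_p = res$corrected_p, final_p = fp,
               error = NA_character_, stringsAsFactors = FALSE)
  })
  results <- do.call(rbind, rows)
  results$significant <- !is.na(results$final_p) & results$final_p < alpha
  n_sig <- sum(results$significant)
  structure(list(results = results, n_genes = n_genes,
                 n_significant = n_sig,
                 fraction_significant = n_sig / n_genes,
                 alpha = alpha,
                 across_gene_correction = across_gene_correction),
            class = "survival_screen")
}

#' @export
print.survival_screen <- function(x, ...) {
  cat(sprintf("survival screen: %d/%d genes significant at alpha=%.3g (%s correction)\n",
              x$n_significant, x$n_genes, x$alpha,
              if (x$across_gene_correction) "within- and across-gene"
              else "within-gene"))
  invisible(x)
}
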