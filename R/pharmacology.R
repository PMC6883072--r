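# Dose-response and drug-combination pharmacology: plate normalization,
# four-parameter logistic (4PL) fits with EDx inversion, Bliss-independence
# combination indices for fixed pairs, dose matrices and apoptosis
# endpoints, delta-delta-Ct quantification and the ellipsoid tumor-volume
# formula.

#' Construct a viability plate
#'
#' Long-form container for one cell line x drug plate: dosed wells
#' (including dose 0 = vehicle) and buffer-only background wells.
#'
#' @param dose_nM Dose per well (nM); must include 0 (vehicle wells) and at
#'   least 3 distinct positive doses.
#' @param signal Raw reader signal per well, same length as `dose_nM`.
#' @param background Raw signal of buffer-only wells.
#' @return A `viability_plate` list.
#' @export
viability_plate <- function(dose_nM, signal, background) {
  if (length(dose_nM) != length(signal))
    stop("dose_nM and signal must have equal length")
  if (!any(dose_nM == 0)) stop("vehicle wells (dose 0) are required")
  if (length(unique(dose_nM[dose_nM > 0])) < 3L)
    stop("need at least 3 distinct positive doses")
  if (!length(background)) stop("background wells are required")
  if (anyNA(c(dose_nM, signal, background)))
    stop("plate values must be non-missing")
  structure(list(dose_nM = as.numeric(dose_nM),
                 signal = as.numeric(signal),
                 background = as.numeric(background)),
            class = "viability_plate")
}

#' Read a viability plate from CSV
#'
#' Columns `dose_nM`, `signal`, `well_type` with `well_type` in
#' `sample`/`vehicle`/`background` (vehicle rows must carry dose 0).
#'
#' @param path Input CSV.
#' @return A [viability_plate].
#' @export
read_plate <- function(path) {
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("dose_nM", "signal", "well_type")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("plate file missing column(s): ", paste(miss, collapse = ", "))
  bad <- setdiff(unique(df$well_type), c("sample", "vehicle", "background"))
  if (length(bad)) stop("unknown well_type: ", paste(bad, collapse = ", "))
  if (any(df$well_type == "vehicle" & df$dose_nM != 0))
    stop("vehicle wells must have dose 0")
  keep <- df$well_type != "background"
  viability_plate(df$dose_nM[keep], df$signal[keep],
                  df$signal[df$well_type == "background"])
}

#' Background-subtract and normalize a plate to percent viability
#'
#' The mean background signal is subtracted from every well and each well
#' is expressed as a percentage of the mean background-subtracted vehicle
#' signal, so vehicle wells average to exactly 100.
#'
#' @param plate A [viability_plate].
#' @return Data frame with `dose_nM` and `viability` (%) per well.
#' @export
normalize_viability <- function(plate) {
  bg <- mean(plate$background)
  s <- plate$signal - bg
  veh <- mean(s[plate$dose_nM == 0])
  if (veh <= 0) stop("mean background-subtracted vehicle signal must be > 0")
  data.frame(dose_nM = plate$dose_nM, viability = 100 * s / veh)
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares fit of `V(c) = bottom + (top - bottom) / (1 + (c/ec50)^hill)`
#' on log10 dose, with constraints `0 <= bottom, top <= 110` and
#' `hill > 0`.  Vehicle (dose 0) wells are excluded from the fit (log dose
#' undefined); they enter only through [normalize_viability].
#' Non-convergence or a degenerate fit (vanishing span, midpoint at the
#' box bounds) is flagged, not thrown.
#'
#' @param dose Doses (nM); at least 4 distinct positive values.
#' @param viability Percent viability per well (same length).
#' @return A `dose_response_fit` list: `top`, `bottom`, `ec50`, `hill`,
#'   `converged`, `rss`, `n` and the data used.
#' @export
fit_4pl <- function(dose, viability) {
  keep <- dose > 0
  dose <- dose[keep]
  viability <- viability[keep]
  if (length(unique(dose)) < 4L)
    stop("need at least 4 distinct positive doses")
  ld <- log10(dose)
  top0 <- max(viability)
  bot0 <- min(viability)
  half <- (top0 + bot0) / 2
  le0 <- ld[which.min(abs(viability - half))]
  lo <- c(top = 0, bottom = 0, le50 = min(ld) - 2, hill = 1e-3)
  hi <- c(top = 110, bottom = 110, le50 = max(ld) + 2, hill = 20)
  start <- c(top = min(max(top0, 0), 110), bottom = min(max(bot0, 0), 110),
             le50 = le0, hill = 1)
  residfun <- function(p) {
    viability - (p["bottom"] + (p["top"] - p["bottom"]) /
                   (1 + 10^(p["hill"] * (ld - p["le50"]))))
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(par = start, fn = residfun, lower = lo, upper = hi,
                       control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    return(structure(list(top = NA_real_, bottom = NA_real_, ec50 = NA_real_,
                          hill = NA_real_, converged = FALSE, rss = NA_real_,
                          n = length(dose), message = conditionMessage(fit),
                          dose = dose, viability = viability),
                     class = "dose_response_fit"))
  }
  cf <- fit$par
  # info codes 1-3 signal convergence in the Levenberg-Marquardt sense
  conv <- fit$info %in% 1:3
  degenerate <- (cf["top"] - cf["bottom"]) < 1 ||
    cf["le50"] <= lo["le50"] + 1e-6 || cf["le50"] >= hi["le50"] - 1e-6
  structure(list(top = unname(cf["top"]), bottom = unname(cf["bottom"]),
                 ec50 = unname(10^cf["le50"]), hill = unname(cf["hill"]),
                 converged = conv && !degenerate,
                 rss = sum(fit$fvec^2), n = length(dose),
                 message = if (degenerate) "degenerate fit (unidentifiable midpoint or span)" else NA_character_,
                 dose = dose, viability = viability),
            class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat(sprintf("4PL fit (n=%d): top=%.3g bottom=%.3g ec50=%.4g nM hill=%.3g [%s]\n",
              x$n, x$top, x$bottom, x$ec50, x$hill,
              if (isTRUE(x$converged)) "converged" else "NOT converged"))
  invisible(x)
}

#' Predict viability from a 4PL fit
#'
#' @param fit A `dose_response_fit`.
#' @param dose Doses (nM).
#' @return Predicted percent viability.
#' @export
predict_4pl <- function(fit, dose) {
  fit$bottom + (fit$top - fit$bottom) / (1 + (dose / fit$ec50)^fit$hill)
}

#' Effective dose for an x% viability reduction
#'
#' Inverts the fitted curve on its span: the returned dose reduces the
#' fitted response by x% of (top - bottom), which for a normalized fit
#' (top 100, bottom 0) is the dose at viability `100 - x`.  Closed form:
#' `ec50 * (x / (100 - x))^(1/hill)`, so ED50 equals the fitted midpoint.
#'
#' @param fit A `dose_response_fit`.
#' @param x Percent effect in (0, 100).
#' @return Dose in nM.
#' @export
edx <- function(fit, x) {
  if (!is.numeric(x) || any(x <= 0) || any(x >= 100))
    stop("x must lie strictly between 0 and 100")
  fit$ec50 * (x / (100 - x))^(1 / fit$hill)
}

#' Compare ED50 groups by unpaired Student's t-test
#'
#' ED50s are compared on the log10 scale by default (doses are
#' log-normally distributed across replicate fits).
#'
#' @param ed50_a,ed50_b Numeric vectors of ED50s (nM), or lists of
#'   `dose_response_fit` objects (their ED50s are extracted).
#' @param log_scale Compare log10-transformed values.
#' @return List with `statistic` and two-sided `p_value`.
#' @export
compare_ed50 <- function(ed50_a, ed50_b, log_scale = TRUE) {
  as_ed <- function(v) {
    if (is.list(v) && !is.numeric(v))
      v <- vapply(v, function(f) edx(f, 50), numeric(1))
    as.numeric(v)
  }
  a <- as_ed(ed50_a)
  b <- as_ed(ed50_b)
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least 2 replicate ED50s")
  if (log_scale) {
    a <- log10(a)
    b <- log10(b)
  }
  .student_t(a, b, var_equal = TRUE)
}

#' Bliss combination index for fractional effects
#'
#' `CI = (Ea + Eb - Ea*Eb) / Eab`: the Bliss-expected combined effect of
#' two independent drugs over the observed combined effect.  `CI < 1`
#' indicates synergy, `CI = 1` (within `tol`) additivity and `CI > 1`
#' antagonism.
#'
#' @param ea,eb Monotherapy fractional effects in `[0, 1]`.
#' @param eab Observed combined fractional effect in `(0, 1]`.
#' @param tol Tolerance for the additivity call.
#' @return Data frame (`synergy_pair`) with `ea`, `eb`, `eab`, `ci`,
#'   `call`; vectorized over its inputs.
#' @export
bliss_ci <- function(ea, eb, eab, tol = 1e-9) {
  n <- max(length(ea), length(eb), length(eab))
  ea <- rep_len(as.numeric(ea), n)
  eb <- rep_len(as.numeric(eb), n)
  eab <- rep_len(as.numeric(eab), n)
  if (any(ea < 0 | ea > 1) || any(eb < 0 | eb > 1))
    stop("Ea and Eb must lie in [0, 1]")
  if (any(eab < 0 | eab > 1)) stop("Eab must lie in [0, 1]")
  if (any(eab == 0)) stop("Eab = 0: combination index undefined")
  ci <- (ea + eb - ea * eb) / eab
  call <- ifelse(abs(ci - 1) <= tol, "additive",
                 ifelse(ci < 1, "synergy", "antagonism"))
  structure(data.frame(ea = ea, eb = eb, eab = eab, ci = ci, call = call,
                       stringsAsFactors = FALSE),
            class = c("synergy_pair", "data.frame"))
}

#' Fractional effect from percent viability
#'
#' `E = 1 - V/100`, clipped to `[0, 1]` (clipping is reported via a
#' warning, e.g. wells that read above vehicle).
#'
#' @param viability Percent viability normalized to vehicle.
#' @return Fractional effects in `[0, 1]`.
#' @export
effects_from_viability <- function(viability) {
  e <- 1 - viability / 100
  out <- pmin(1, pmax(0, e))
  nclip <- sum(out != e)
  if (nclip > 0)
    warning("clipped ", nclip, " effect value(s) to [0, 1]", call. = FALSE)
  out
}

#' Bliss combination indices over a dose matrix
#'
#' Monotherapy effects are read from the zero row and zero column of the
#' same inhibition matrix; a CI is computed for every cell with both doses
#' positive.  Cells with zero combined effect get an undefined (`NA`) CI.
#'
#' @param dose_a,dose_b Dose grids for drugs A (rows) and B (columns); each
#'   must contain 0 exactly once.
#' @param inhibition Fractional-inhibition matrix in `[0, 1]`,
#'   `length(dose_a)` x `length(dose_b)`.
#' @param tol Tolerance for the additivity call.
#' @return List with `ci` (matrix, `NA` on the monotherapy row/column and
#'   undefined cells), `call` (character matrix) and `n_undefined`.
#' @export
bliss_matrix <- function(dose_a, dose_b, inhibition, tol = 1e-9) {
  if (!is.matrix(inhibition) ||
      nrow(inhibition) != length(dose_a) || ncol(inhibition) != length(dose_b))
    stop("inhibition must be a length(dose_a) x length(dose_b) matrix")
  if (any(inhibition < 0 | inhibition > 1))
    stop("inhibition values must lie in [0, 1]")
  zi <- which(dose_a == 0)
  zj <- which(dose_b == 0)
  if (length(zi) != 1L || length(zj) != 1L)
    stop("dose grids must contain 0 exactly once (monotherapy row/column)")
  ea <- inhibition[, zj]
  eb <- inhibition[zi, ]
  ci <- matrix(NA_real_, length(dose_a), length(dose_b),
               dimnames = list(dose_a, dose_b))
  call <- matrix(NA_character_, length(dose_a), length(dose_b),
                 dimnames = list(dose_a, dose_b))
  for (i in seq_along(dose_a)) {
    if (i == zi) next
    for (j in seq_along(dose_b)) {
      if (j == zj) next
      eab <- inhibition[i, j]
      if (eab == 0) {
        call[i, j] <- "undefined"
        next
      }
      v <- (ea[i] + eb[j] - ea[i] * eb[j]) / eab
      ci[i, j] <- v
      call[i, j] <- if (abs(v - 1) <= tol) "additive"
                    else if (v < 1) "synergy" else "antagonism"
    }
  }
  list(ci = ci, call = call,
       n_undefined = sum(call == "undefined", na.rm = TRUE))
}

#' Bliss interaction on apoptosis endpoints
#'
#' Apoptotic fractions are first corrected for the vehicle baseline,
#' `E = (f - f_dmso) / (1 - f_dmso)` clipped to `[0, 1]`, so that
#' monotherapy and combination effects live on the `[0, 1]` scale Bliss
#' independence requires; the combination index is then computed as for
#' viability.  A combination with no drug-attributable effect has an
#' undefined CI.
#'
#' @param f_dmso,f_a,f_b,f_ab Apoptotic fractions in `[0, 1]` for vehicle,
#'   drug A, drug B and the combination.
#' @return One-row data frame with `ea`, `eb`, `eab`, `ci`, `call`
#'   (`call = "undefined"`, `ci = NA` when `eab = 0`).
#' @export
apoptosis_interaction <- function(f_dmso, f_a, f_b, f_ab) {
  f <- c(f_dmso, f_a, f_b, f_ab)
  if (any(f < 0 | f > 1)) stop("apoptotic fractions must lie in [0, 1]")
  if (f_dmso >= 1) stop("vehicle apoptotic fraction must be < 1")
  eff <- function(x) min(1, max(0, (x - f_dmso) / (1 - f_dmso)))
  ea <- eff(f_a)
  eb <- eff(f_b)
  eab <- eff(f_ab)
  if (eab == 0) {
    return(data.frame(ea = ea, eb = eb, eab = eab, ci = NA_real_,
                      call = "undefined", stringsAsFactors = FALSE))
  }
  as.data.frame(bliss_ci(ea, eb, eab))
}

#' Relative quantification by delta-delta-Ct
#'
#' `fold = 2^-ddCt` with
#' `ddCt = (Ct_target,sample - Ct_ref,sample) - (Ct_target,control - Ct_ref,control)`,
#' the reference gene (e.g. GAPDH) normalizing each arm.
#'
#' @param ct_target_sample,ct_ref_sample Target and reference Ct in the
#'   sample of interest.
#' @param ct_target_control,ct_ref_control Target and reference Ct in the
#'   control sample.
#' @return Fold change relative to control; vectorized.
#' @export
ddct_fold <- function(ct_target_sample, ct_ref_sample,
                      ct_target_control, ct_ref_control) {
  ddct <- (ct_target_sample - ct_ref_sample) -
    (ct_target_control - ct_ref_control)
  2^(-ddct)
}

#' Ellipsoid tumor volume
#'
#' Modified ellipsoid formula `V = a * b^2 / 2` with `a >= b` the two
#' caliper measurements (mm); inputs given in the wrong order are swapped
#' with a warning.
#'
#' @param a,b Caliper length and width (mm), non-negative; vectorized.
#' @return Volume in mm^3.
#' @export
ellipsoid_volume <- function(a, b) {
  if (any(a < 0) || any(b < 0)) stop("measurements must be non-negative")
  swap <- b > a
  if (any(swap)) {
    warning("reordered ", sum(swap),
            " measurement pair(s) so that a >= b", call. = FALSE)
    tmp <- a[swap]
    a[swap] <- b[swap]
    b[swap] <- tmp
  }
  a * b^2 / 2
}
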