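test_that("plate normalization subtracts background and anchors vehicle at 100", {
  plate <- viability_plate(dose_nM = c(0, 0, 100, 300, 1000),
                           signal = c(1050, 1050, 550, 300, 50),
                           background = c(50, 50))
  nv <- normalize_viability(plate)
  expect_equal(nv$viability[nv$dose_nM == 100], 50)    # (550-50)/(1050-50)
  expect_equal(nv$viability[nv$dose_nM == 1000], 0)    # at background -> 0%
  expect_equal(mean(nv$viability[nv$dose_nM == 0]), 100)

  bad <- viability_plate(c(0, 0, 1, 3, 10), rep(40, 5), background = 50)
  expect_error(normalize_viability(bad), "vehicle signal")
})

test_that("4PL fits recover noiseless truth to high precision", {
  pl <- simulate_dose_response(ec50 = 100, hill = 1, cv = 0)
  nv <- normalize_viability(pl)
  fit <- fit_4pl(nv$dose_nM, nv$viability)
  expect_true(fit$converged)
  expect_equal(fit$ec50, 100, tolerance = 1e-6)
  expect_equal(fit$hill, 1, tolerance = 1e-6)
  expect_equal(fit$top, 100, tolerance = 1e-6)
  expect_equal(fit$bottom, 0, tolerance = 1e-4)

  # steeper curve, shifted midpoint
  pl2 <- simulate_dose_response(ec50 = 30, hill = 2.5, cv = 0)
  nv2 <- normalize_viability(pl2)
  fit2 <- fit_4pl(nv2$dose_nM, nv2$viability)
  expect_equal(fit2$ec50, 30, tolerance = 1e-6)
  expect_equal(fit2$hill, 2.5, tolerance = 1e-6)
})

test_that("flat viability yields a flagged, not thrown, degenerate fit", {
  doses <- c(1, 3, 10, 30, 100, 300, 1000, 3000)
  fit <- fit_4pl(doses, rep(100, 8))
  expect_s3_class(fit, "dose_response_fit")
  expect_false(fit$converged)
})

test_that("noisy plates recover ec50 within a reasonable band", {
  pl <- simulate_dose_response(ec50 = 100, hill = 1, cv = 0.05,
                               seed = 101)
  nv <- normalize_viability(pl)
  fit <- fit_4pl(nv$dose_nM, nv$viability)
  expect_true(fit$converged)
  expect_lt(abs(fit$ec50 - 100) / 100, 0.15)
})

test_that("edx inverts the fitted curve in closed form", {
  fit <- structure(list(top = 100, bottom = 0, ec50 = 100, hill = 1,
                        converged = TRUE), class = "dose_response_fit")
  expect_equal(edx(fit, 50), 100)                 # ED50 is the midpoint
  expect_equal(edx(fit, 75), 300, tolerance = 1e-9)
  expect_equal(edx(fit, 10), 100 / 9, tolerance = 1e-9)
  # V(edx(x)) = 100 - x across the span
  for (x in c(5, 10, 25, 50, 75, 90, 95))
    expect_equal(predict_4pl(fit, edx(fit, x)), 100 - x, tolerance = 1e-9)
  fit$hill <- 3.2
  for (x in c(10, 50, 90))
    expect_equal(predict_4pl(fit, edx(fit, x)), 100 - x, tolerance = 1e-9)
  expect_error(edx(fit, 0), "between 0 and 100")
  expect_error(edx(fit, 100), "between 0 and 100")
})

test_that("ED50 comparisons behave like an unpaired t-test on log dose", {
  expect_equal(compare_ed50(c(100, 110, 90), c(100, 110, 90))$p_value, 1)
  res <- compare_ed50(c(100, 100, 100), c(300, 300, 300.1))
  expect_lt(res$p_value, 1e-6)
  sw <- compare_ed50(c(300, 300, 300.1), c(100, 100, 100))
  expect_equal(sw$p_value, res$p_value)
  expect_error(compare_ed50(100, c(1, 2)), "at least 2")
})

test_that("Bliss combination index follows the independence arithmetic", {
  null <- bliss_ci(0.5, 0.5, 0.75)
  expect_equal(null$ci, 1)
  expect_equal(null$call, "additive")
  syn <- bliss_ci(0.2, 0.3, 0.6)
  expect_equal(syn$ci, 0.44 / 0.6, tolerance = 1e-12)
  expect_equal(syn$call, "synergy")
  ant <- bliss_ci(0.2, 0.3, 0.3)
  expect_equal(ant$ci, 0.44 / 0.3, tolerance = 1e-12)
  expect_equal(ant$call, "antagonism")
  expect_error(bliss_ci(0.2, 0.3, 0), "undefined")
  expect_error(bliss_ci(1.2, 0.3, 0.5), "\\[0, 1\\]")

  # CI decreases strictly as the observed combined effect grows
  eabs <- seq(0.1, 1, by = 0.1)
  cis <- bliss_ci(0.3, 0.4, eabs)$ci
  expect_true(all(diff(cis) < 0))
})

test_that("effects from viability clip to [0,1] with a warning", {
  expect_equal(effects_from_viability(100), 0)
  expect_equal(effects_from_viability(25), 0.75)
  expect_warning(e <- effects_from_viability(104), "clipped")
  expect_equal(e, 0)
})

test_that("matrix CI reads monotherapies from the zero row/column", {
  doses <- c(0, 1, 3, 10, 30, 100, 300, 1000)
  sim <- simulate_synergy_matrix(ec50_a = 30, ec50_b = 100, kappa = 1, cv = 0)
  bm <- bliss_matrix(sim$dose_a, sim$dose_b, sim$inhibition)
  defined <- !is.na(bm$ci)
  expect_true(any(defined))
  expect_equal(unname(bm$ci[defined]), rep(1, sum(defined)), tolerance = 1e-12)
  # monotherapy row/column carries no CI
  expect_true(all(is.na(bm$ci[1, ])))
  expect_true(all(is.na(bm$ci[, 1])))

  # a single cell with extra kill turns synergistic; others stay additive
  inh <- sim$inhibition
  inh[5, 5] <- min(1, inh[5, 5] * 1.3)
  bm2 <- bliss_matrix(sim$dose_a, sim$dose_b, inh)
  expect_lt(bm2$ci[5, 5], 1)
  expect_equal(bm2$call[5, 5], "synergy")
  others <- bm2$ci[-1, -1][-which(row(bm2$ci[-1, -1]) == 4 & col(bm2$ci[-1, -1]) == 4)]
  expect_true(all(abs(others[!is.na(others)] - 1) <= 1e-9))

  # zero-effect monotherapies with a killing combination -> CI 0
  inh0 <- matrix(0, 2, 2)
  inh0[2, 2] <- 0.5
  bm3 <- bliss_matrix(c(0, 10), c(0, 10), inh0)
  expect_equal(bm3$ci[2, 2], 0)
})

test_that("apoptosis interaction corrects for the vehicle baseline", {
  # no drug effect anywhere -> undefined CI
  none <- apoptosis_interaction(0.1, 0.1, 0.1, 0.1)
  expect_true(is.na(none$ci))
  expect_equal(none$call, "undefined")
  # zero baseline reduces to the viability case
  red <- apoptosis_interaction(0, 0.5, 0.5, 0.75)
  expect_equal(red$ci, 1)
  # worked baseline-corrected example
  ex <- apoptosis_interaction(0.2, 0.6, 0.6, 0.9)
  expect_equal(ex$ea, 0.5)
  expect_equal(ex$eab, 0.875)
  expect_equal(ex$ci, 0.75 / 0.875, tolerance = 1e-12)
  expect_error(apoptosis_interaction(1, 0.5, 0.5, 0.6), "< 1")
})

test_that("delta-delta-Ct and tumor volume formulas are exact", {
  expect_equal(ddct_fold(5, 5, 7, 7), 1)          # ddCt 0 -> fold 1
  expect_equal(ddct_fold(4, 5, 5, 5), 2)          # ddCt -1 -> fold 2
  expect_equal(ddct_fold(9, 5, 7, 5), 0.25)       # ddCt 2 -> fold 0.25
  expect_equal(ellipsoid_volume(10, 5), 125)
  expect_equal(ellipsoid_volume(0, 0), 0)
  expect_warning(v <- ellipsoid_volume(5, 10), "reordered")
  expect_equal(v, 125)
  expect_error(ellipsoid_volume(-1, 1), "non-negative")
})
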