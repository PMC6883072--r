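test_that("replicate averaging is the arithmetic mean of raw counts", {
  lib <- toy_manifest(1L, 3L)
  ss <- toy_sheet()
  m <- matrix(0L, 3, 4, dimnames = list(lib$guide_id, ss$sample_id))
  m[1, ] <- c(10L, 30L, 0L, 6L)
  avg <- average_replicates(m, ss)
  expect_equal(avg["G001_g1", "vehicle"], 20)
  expect_equal(avg["G001_g1", "brigatinib_ED50"], 3)

  # single replicate passes through
  ss1 <- suppressWarnings(sample_sheet(as.data.frame(ss)[-2, ]))
  avg1 <- average_replicates(m[, ss1$sample_id], ss1)
  expect_equal(avg1["G001_g1", "vehicle"], 10)
})

test_that("normalization conserves the scale constant and is proportion-based", {
  m <- cbind(a = c(10, 30, 60), b = c(20, 60, 120))
  nl <- normalize_and_log(m, norm_config(scale = 1e6))
  expect_equal(nl$normalized[, "a"], c(1e5, 3e5, 6e5), ignore_attr = TRUE)
  # proportional columns normalize identically (depth invariance)
  expect_equal(nl$normalized[, "a"], nl$normalized[, "b"])
  expect_equal(colSums(nl$normalized), c(a = 1e6, b = 1e6))
  # zero count with pseudocount 1, base 2 -> log value 0
  m0 <- cbind(a = c(0, 10))
  nl0 <- normalize_and_log(m0, norm_config(scale = 1, pseudocount = 1, log_base = 2))
  expect_equal(nl0$log[1, "a"], 0, ignore_attr = TRUE)
  expect_error(normalize_and_log(cbind(a = c(0, 0))), "all-zero")
})

test_that("normalized columns sum to the scale for random matrices", {
  withr::with_seed(7, {
    for (i in 1:20) {
      m <- matrix(rpois(60, sample(5:500, 1)) + 1L, nrow = 12)
      colnames(m) <- paste0("s", 1:5)
      sc <- sample(c(1e4, 1e6), 1)
      nl <- normalize_and_log(m, norm_config(scale = sc))
      expect_equal(colSums(nl$normalized), rep(sc, 5), tolerance = 1e-9,
                   ignore_attr = TRUE)
    }
  })
})

test_that("fold-change enrichment uses a strict >1.5 threshold", {
  lib <- toy_manifest(1L, 3L)
  norm <- cbind(vehicle = c(100, 100, 100),
                brigatinib_ED50 = c(160, 150, 100))
  rownames(norm) <- lib$guide_id
  nl <- list(normalized = norm, log = log2(norm),
             config = norm_config(pseudocount = 0))
  gt <- guide_fold_changes(nl, lib, "brigatinib_ED50")
  expect_equal(gt$fold_change, c(1.6, 1.5, 1.0))
  expect_equal(gt$enriched, c(TRUE, FALSE, FALSE))  # exactly 1.5 is NOT enriched
  expect_equal(gt$diff_log, log2(gt$fold_change))

  # identical columns -> all fold changes 1, none enriched
  nl2 <- list(normalized = cbind(vehicle = norm[, 1], brigatinib_ED50 = norm[, 1]),
              log = log2(cbind(vehicle = norm[, 1], brigatinib_ED50 = norm[, 1])),
              config = norm_config(pseudocount = 0))
  gt2 <- guide_fold_changes(nl2, lib, "brigatinib_ED50")
  expect_true(all(gt2$fold_change == 1))
  expect_false(any(gt2$enriched))
})

test_that("gene hits require at least min_guides enriched guides", {
  lib <- toy_manifest(3L, 3L)
  fcs <- c(2.0, 1.6, 1.0,   # gene 1: 2 enriched -> hit
           4.0, 1.2, 1.1,   # gene 2: 1 enriched -> no hit
           1.6, 1.6, 1.6)   # gene 3: 3 enriched -> hit
  gt <- data.frame(guide_id = lib$guide_id, gene = lib$gene,
                   condition = "brigatinib_ED50", fold_change = fcs,
                   enriched = fcs > 1.5, stringsAsFactors = FALSE)
  gh <- call_gene_hits(gt, lib, min_guides = 2L)
  expect_equal(gh$enriched, c(TRUE, FALSE, TRUE))
  expect_equal(gh$n_guides_enriched, c(2L, 1L, 3L))
  expect_equal(gh$max_fold_change, c(2.0, 4.0, 1.6))
})

test_that("gene significance matches the textbook pooled t-test", {
  lib <- toy_manifest(1L, 3L)
  ss <- toy_sheet()
  logm <- matrix(0, 3, 4, dimnames = list(lib$guide_id, ss$sample_id))
  x <- c(5, 5, 5, 5, 5, 5.0001)  # treated (3 guides x 2 reps)
  y <- rep(1, 6)                 # vehicle
  logm[, c("brig_r1", "brig_r2")] <- x
  logm[, c("veh_r1", "veh_r2")] <- y
  res <- gene_significance(logm, ss, lib, "G001", "brigatinib_ED50")
  # independent oracle: textbook equal-variance t
  sp2 <- (5 * var(x) + 5 * var(y)) / 10
  t_exp <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / 6 + 1 / 6))
  p_exp <- 2 * pt(abs(t_exp), df = 10, lower.tail = FALSE)
  expect_equal(res$statistic, t_exp, tolerance = 1e-12)
  expect_equal(res$p_value, p_exp, tolerance = 1e-12)
  expect_lt(res$p_value, 1e-6)

  # identical groups -> t = 0, p = 1 (zero-variance guard)
  logm[] <- 3
  res0 <- gene_significance(logm, ss, lib, "G001", "brigatinib_ED50")
  expect_equal(res0$p_value, 1)
  expect_equal(res0$statistic, 0)

  # label swap symmetry
  logm[, c("brig_r1", "brig_r2")] <- y
  logm[, c("veh_r1", "veh_r2")] <- x
  res_sw <- gene_significance(logm, ss, lib, "G001", "brigatinib_ED50")
  expect_equal(res_sw$p_value, res$p_value)
})

test_that("candidate genes are the dual-drug intersection per dose level", {
  mk <- function(cond, genes, enr) data.frame(
    gene = genes, condition = cond, enriched = enr, stringsAsFactors = FALSE)
  genes <- c("PIM1", "MET", "SAGE1")
  hits <- rbind(
    mk("brigatinib_ED50", genes, c(TRUE, TRUE, FALSE)),
    mk("ceritinib_ED50", genes, c(TRUE, FALSE, FALSE)),
    mk("brigatinib_ED75", genes, c(TRUE, FALSE, TRUE)),
    mk("ceritinib_ED75", genes, c(TRUE, FALSE, TRUE)))
  expect_equal(candidate_genes(hits, "ED50"), "PIM1")   # MET brig-only: excluded
  expect_equal(candidate_genes(hits, "ED75"), c("PIM1", "SAGE1"))
  expect_equal(candidate_genes(hits, c("ED50", "ED75")), c("PIM1", "SAGE1"))
  expect_error(candidate_genes(hits[hits$condition != "ceritinib_ED50", ], "ED50"),
               "missing condition")
  # cross-cell-line overlap
  expect_equal(candidate_overlap(list(A = c("PIM1", "MET"), B = "PIM1")), "PIM1")
})

test_that("guide ranking is descending with lexicographic tie-break", {
  gt <- data.frame(guide_id = c("g_b", "g_a", "g_c"),
                   fold_change = c(1.2, 3.0, 3.0),
                   diff_log = log2(c(1.2, 3.0, 3.0)),
                   stringsAsFactors = FALSE)
  rk <- rank_guides(gt)
  expect_equal(rk$guide_id, c("g_a", "g_c", "g_b"))
  expect_equal(rk$rank, 1:3)
  # with no pseudocount, top-ranked guide has maximal diff_log
  expect_equal(which.max(rk$diff_log), 1L)
})

test_that("regression diagnostic recovers exact linear relations", {
  lib <- toy_manifest(1L, 3L)
  logm <- cbind(vehicle = c(0, 1, 2), brigatinib_ED50 = c(0, 1, 2))
  rownames(logm) <- lib$guide_id
  nl <- list(normalized = 2^logm, log = logm, config = norm_config())
  rd <- regression_diagnostic(nl, "brigatinib_ED50")
  expect_equal(rd$slope, 1, tolerance = 1e-12)
  expect_equal(rd$intercept, 0, tolerance = 1e-12)
  expect_equal(sum(rd$residuals), 0, tolerance = 1e-12)

  nl$log[, 2] <- nl$log[, 1] + 2
  rd2 <- regression_diagnostic(nl, "brigatinib_ED50")
  expect_equal(rd2$slope, 1, tolerance = 1e-12)
  expect_equal(rd2$intercept, 2, tolerance = 1e-12)

  # closed-form OLS on {(0,0),(1,2),(2,4)}
  nl$log[, 2] <- c(0, 2, 4)
  rd3 <- regression_diagnostic(nl, "brigatinib_ED50")
  expect_equal(rd3$slope, 2, tolerance = 1e-12)
  expect_equal(rd3$intercept, 0, tolerance = 1e-12)

  nl$log[, 1] <- 1
  expect_error(regression_diagnostic(nl, "brigatinib_ED50"), "zero variance")
})

test_that("hit calls are invariant to count scaling and guide permutation, and monotone", {
  lib <- toy_manifest(4L, 3L)
  ss <- toy_sheet()
  m <- toy_counts(lib, ss, seed = 5)
  m[1:3, c("brig_r1", "brig_r2")] <- m[1:3, c("brig_r1", "brig_r2")] * 5L
  call_from <- function(counts, manifest) {
    avg <- average_replicates(counts, ss)
    nl <- normalize_and_log(avg)
    gt <- guide_fold_changes(nl, manifest, "brigatinib_ED50")
    call_gene_hits(gt, manifest)
  }
  base <- call_from(m, lib)
  expect_true(base$enriched[base$gene == "G001"])

  # depth invariance: scaling a condition's replicates by k changes nothing
  m_scaled <- m
  m_scaled[, c("brig_r1", "brig_r2")] <- m_scaled[, c("brig_r1", "brig_r2")] * 7L
  scaled <- call_from(m_scaled, lib)
  expect_equal(scaled$enriched, base$enriched)
  expect_equal(scaled$max_fold_change, base$max_fold_change, tolerance = 1e-12)

  # with per-replicate normalization first, even a single scaled sample
  # leaves normalized values, fold changes and calls untouched
  call_norm_first <- function(counts) {
    avg <- average_replicates(counts, ss, normalize_first = TRUE)
    nl <- normalize_and_log(avg)
    gt <- guide_fold_changes(nl, lib, "brigatinib_ED50")
    call_gene_hits(gt, lib)
  }
  m_one <- m
  m_one[, "brig_r1"] <- m_one[, "brig_r1"] * 7L
  expect_equal(call_norm_first(m_one), call_norm_first(m), tolerance = 1e-12)

  # permutation invariance: reordering guides permutes, not changes, calls
  perm <- withr::with_seed(6, sample(nrow(lib)))
  lib_p <- guide_library(lib$guide_id[perm], lib$gene[perm],
                         lib$protospacer[perm])
  perm_hits <- call_from(m[perm, ], lib_p)
  expect_equal(perm_hits[order(perm_hits$gene), ],
               base[order(base$gene), ], ignore_attr = TRUE)

  # monotonicity: raising an enriched guide's treated count keeps it enriched
  gidx <- which(lib$gene == "G001")
  m_up <- m
  m_up[gidx[1], c("brig_r1", "brig_r2")] <-
    m_up[gidx[1], c("brig_r1", "brig_r2")] + 500L
  up <- call_from(m_up, lib)
  expect_true(up$enriched[up$gene == "G001"])
})
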