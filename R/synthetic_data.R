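# Seeded generators for every input the pipeline consumes: pooled-screen
# selection dynamics with planted resistance genes, FASTQ reads with the
# stagger/anchor/protospacer structure, dose-response plates, synergy
# matrices under a Bliss null or an injected interaction, and survival
# cohorts.  Every generator is a pure function of its arguments and seed.

.rand_seqs <- function(n, width) {
  m <- matrix(sample(c("A", "C", "G", "T"), n * width, replace = TRUE),
              nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

#' Generate a synthetic guide library
#'
#' Distinct random 20-mers, `guides_per_gene` per gene, with gene symbols
#' `GENE00001...`.  The full-scale default mirrors a genome-wide CRISPRa
#' library (23,430 coding isoforms x 3 guides).
#'
#' @param n_genes Number of genes (default 23430).
#' @param guides_per_gene Guides per gene (default 3).
#' @param seed Optional integer seed; the same seed reproduces the same
#'   manifest exactly.
#' @return A [guide_library].
#' @export
make_library <- function(n_genes = 23430L, guides_per_gene = 3L, seed = NULL) {
  if (n_genes < 1L) stop("n_genes must be >= 1")
  if (guides_per_gene < 1L) stop("guides_per_gene must be >= 1")
  n <- n_genes * guides_per_gene
  if (n > 4^20) stop("requested guide count exceeds distinct 20-mer capacity")
  if (!is.null(seed)) withr::local_seed(seed)
  protos <- unique(.rand_seqs(n, 20L))
  while (length(protos) < n)
    protos <- unique(c(protos, .rand_seqs(n - length(protos), 20L)))
  genes <- rep(sprintf("GENE%05d", seq_len(n_genes)), each = guides_per_gene)
  gid <- paste0(genes, "_g", rep(seq_len(guides_per_gene), times = n_genes))
  guide_library(gid, genes, protos[seq_len(n)],
                name = "synthetic pooled CRISPRa library", version = "sim")
}

#' Configuration for the pooled-screen selection simulator
#'
#' Defaults reflect the screen design the pipeline targets: 3 guides per
#' gene at 500 transduced cells per guide, duplicate day-14 populations
#' per condition, and drug selection at ED50/ED75-equivalent pressure for
#' 14 days.  Drug potency is expressed as the per-day kill fraction of
#' non-rescued cells; fully rescued cells (rescue strength 1) grow as
#' under vehicle.
#'
#' @param n_genes,guides_per_gene Library dimensions.
#' @param coverage Cells per guide at transduction.
#' @param sigma Log-normal dispersion of initial per-guide abundance
#'   (transduction/MOI variability folded into the initial state).
#' @param n_days Days of drug selection.
#' @param growth_rate Per-day multiplicative growth of unselected cells.
#' @param kill_ed50,kill_ed75 Per-day kill fraction of non-rescued cells
#'   at ED50- and ED75-equivalent drug pressure.
#' @param planted_genes Character vector of resistance genes to plant, or
#'   a single integer count (genes then drawn at random from the library).
#' @param rescue Rescue strength in `[0, 1]` (1 = full resistance), scalar
#'   or named per planted gene.
#' @param replicates Biological replicates per day-14 condition.
#' @param depth Sequenced reads per sample (multinomial size).
#' @param replicate_cv Coefficient of variation of the multiplicative
#'   gamma noise applied per replicate to final abundances.
#' @param cell_line Cell-line annotation written to the sample sheet.
#' @param seed Integer seed.
#' @return A `screen_sim_config` list.
#' @export
screen_sim_config <- function(n_genes = 300L, guides_per_gene = 3L,
                              coverage = 500, sigma = 0.5, n_days = 14L,
                              growth_rate = 1.4, kill_ed50 = 0.2,
                              kill_ed75 = 0.35, planted_genes = character(0),
                              rescue = 1, replicates = 2L, depth = 2e6,
                              replicate_cv = 0.15, cell_line = "SH-SY5Y",
                              seed = 1L) {
  stopifnot(n_genes >= 1, guides_per_gene >= 1, coverage > 0, sigma >= 0,
            n_days >= 1, growth_rate > 0,
            kill_ed50 >= 0, kill_ed50 < 1, kill_ed75 >= 0, kill_ed75 < 1,
            all(rescue >= 0), all(rescue <= 1),
            replicates >= 1, replicate_cv >= 0)
  if (depth <= 0) stop("sequencing depth must be > 0")
  structure(list(n_genes = as.integer(n_genes),
                 guides_per_gene = as.integer(guides_per_gene),
                 coverage = coverage, sigma = sigma,
                 n_days = as.integer(n_days), growth_rate = growth_rate,
                 kill_ed50 = kill_ed50, kill_ed75 = kill_ed75,
                 planted_genes = planted_genes, rescue = rescue,
                 replicates = as.integer(replicates), depth = depth,
                 replicate_cv = replicate_cv, cell_line = cell_line,
                 seed = as.integer(seed)),
            class = "screen_sim_config")
}

#' Simulate a 14-day pooled CRISPRa selection screen
#'
#' Initial per-guide cell counts are log-normal around the configured
#' coverage.  Each day, cells grow by `growth_rate` and drug-treated
#' populations are thinned: a guide's survival factor is
#' `(1 - kill) + kill * rescue(gene)`, so non-rescued guides deplete and
#' fully rescued guides track vehicle.  Final abundances receive
#' replicate-specific multiplicative gamma noise and each sample is
#' sequenced as one multinomial draw of `depth` reads.  A day-0 sample is
#' drawn from the initial abundances.  Conditions simulated: vehicle and
#' both drugs at both dose levels, `replicates` each.
#'
#' @param manifest A [guide_library]; must match the config's dimensions.
#' @param config A [screen_sim_config].
#' @param seed Optional override of `config$seed`.
#' @return A list with `counts` (guides x samples integer matrix),
#'   `samples` (a [sample_sheet]), `truth` (per-guide expected abundances
#'   and per-gene planted/rescue table) and the `config`.
#' @export
simulate_screen <- function(manifest, config = screen_sim_config(),
                            seed = NULL) {
  if (nrow(manifest) != config$n_genes * config$guides_per_gene)
    stop("manifest size does not match config")
  if (is.null(seed)) seed <- config$seed
  withr::local_seed(seed)

  G <- nrow(manifest)
  genes <- unique(manifest$gene)
  planted <- config$planted_genes
  if (is.numeric(planted) && length(planted) == 1L)
    planted <- sample(genes, planted)
  if (length(bad <- setdiff(planted, genes)))
    stop("planted genes not in library: ", paste(bad, collapse = ", "))
  rescue_gene <- setNames(rep(0, length(genes)), genes)
  if (length(planted)) {
    r <- config$rescue
    if (is.null(names(r))) r <- setNames(rep_len(r, length(planted)), planted)
    rescue_gene[planted] <- r[planted]
  }

  x <- rlnorm(G, 0, config$sigma)
  n0 <- config$coverage * x / mean(x)
  rg <- rescue_gene[manifest$gene]

  conds <- data.frame(
    treatment = c("vehicle", "brigatinib", "brigatinib", "ceritinib", "ceritinib"),
    dose_level = c("none", "ED50", "ED75", "ED50", "ED75"),
    kill = c(0, config$kill_ed50, config$kill_ed75,
             config$kill_ed50, config$kill_ed75),
    stringsAsFactors = FALSE)

  expected <- vapply(seq_len(nrow(conds)), function(k) {
    s <- (1 - conds$kill[k]) + conds$kill[k] * rg
    n0 * (config$growth_rate * s)^config$n_days
  }, numeric(G))
  colnames(expected) <- condition_label(conds$treatment, conds$dose_level)

  shape <- if (config$replicate_cv > 0) 1 / config$replicate_cv^2 else Inf
  sample_ids <- "day0"
  counts <- matrix(0L, G, 1L + nrow(conds) * config$replicates,
                   dimnames = list(manifest$guide_id, NULL))
  counts[, 1L] <- rmultinom(1L, config$depth, n0)[, 1L]
  rows <- data.frame(sample_id = "day0", cell_line = config$cell_line,
                     treatment = "vehicle", dose_level = "none",
                     replicate = 1L, timepoint_days = 0L,
                     source = NA_character_, stringsAsFactors = FALSE)
  col <- 1L
  for (k in seq_len(nrow(conds))) {
    lab <- condition_label(conds$treatment[k], conds$dose_level[k])
    for (r in seq_len(config$replicates)) {
      col <- col + 1L
      lam <- expected[, k]
      if (config$replicate_cv > 0)
        lam <- lam * rgamma(G, shape = shape, rate = shape)
      counts[, col] <- rmultinom(1L, config$depth, lam)[, 1L]
      sid <- paste0(lab, "_rep", r)
      sample_ids <- c(sample_ids, sid)
      rows <- rbind(rows, data.frame(
        sample_id = sid, cell_line = config$cell_line,
        treatment = conds$treatment[k], dose_level = conds$dose_level[k],
        replicate = r, timepoint_days = 14L, source = NA_character_,
        stringsAsFactors = FALSE))
    }
  }
  colnames(counts) <- sample_ids

  truth <- list(
    guides = data.frame(guide_id = manifest$guide_id, gene = manifest$gene,
                        initial_cells = n0, expected,
                        check.names = FALSE, stringsAsFactors = FALSE),
    genes = data.frame(gene = genes, planted = genes %in% planted,
                       rescue = unname(rescue_gene),
                       stringsAsFactors = FALSE),
    seed = seed)
  list(counts = counts, samples = sample_sheet(rows), truth = truth,
       config = config)
}

#' Emit a synthetic FASTQ file from a per-guide tally
#'
#' One read per count unit: a random 1..`max_stagger` nt stagger, the
#' constant anchor, the guide's 20-nt protospacer and random filler up to
#' `read_length`, with a constant quality string.  Reads are written in
#' shuffled order.  With `error_rate > 0`, per-base substitutions are
#' applied after construction; the returned tally always reports the
#' intended (pre-error) counts.
#'
#' @param counts Named non-negative integer vector over the manifest's
#'   guide IDs (unnamed vectors are taken in manifest order).
#' @param manifest A [guide_library].
#' @param path Output FASTQ path (`.gz` for gzip).
#' @param config An [anchor_config]; the anchor must be non-empty and
#'   `max_stagger >= 1`.
#' @param error_rate Per-base substitution probability.
#' @param seed Optional integer seed.
#' @return Invisibly, a list with `path` and the intended `tally`.
#' @export
emit_fastq <- function(counts, manifest, path, config = anchor_config(),
                       error_rate = 0, seed = NULL) {
  if (is.null(names(counts))) {
    if (length(counts) != nrow(manifest))
      stop("unnamed counts must have one entry per manifest guide")
    names(counts) <- manifest$guide_id
  }
  counts <- counts[manifest$guide_id]
  if (anyNA(counts) || any(counts < 0)) stop("counts must be non-negative")
  la <- nchar(config$anchor)
  if (la == 0L || config$max_stagger < 1L)
    stop("emit_fastq needs a non-empty anchor and max_stagger >= 1")
  if (!is.null(seed)) withr::local_seed(seed)

  n <- sum(counts)
  tally <- counts
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  if (n == 0L) {
    return(invisible(list(path = path, tally = tally)))
  }
  proto <- rep(manifest$protospacer, times = counts)
  stag <- sample.int(config$max_stagger, n, replace = TRUE)
  rand <- .rand_seqs(n, config$read_length)
  fill_len <- config$read_length - stag - la - 20L
  if (any(fill_len < 0)) stop("read_length too short for stagger + anchor + protospacer")
  reads <- paste0(substr(rand, 1L, stag), config$anchor, proto,
                  substr(rand, stag + 1L, stag + fill_len))
  if (error_rate > 0) {
    nerr <- rbinom(n, config$read_length, error_rate)
    for (i in which(nerr > 0L)) {
      pos <- sample.int(config$read_length, nerr[i])
      sub <- sample(c("A", "C", "G", "T"), nerr[i], replace = TRUE)
      r <- strsplit(reads[i], "", fixed = TRUE)[[1]]
      r[pos] <- sub
      reads[i] <- paste(r, collapse = "")
    }
  }
  reads <- reads[sample.int(n)]
  qual <- strrep("I", config$read_length)
  writeLines(as.vector(rbind(paste0("@read", seq_len(n)), reads, "+", qual)),
             con)
  invisible(list(path = path, tally = tally))
}

#' Simulate a dose-response viability plate
#'
#' Well signals follow `background + span * V(c)/100 * (1 + N(0, cv))`
#' where `V` is the configured 4PL truth; background wells get the same
#' relative noise.  The default dose series is the log-scale ladder
#' 0, 1, 3, 10, 30, 100, 300, 1000, 3000 nM.
#'
#' @param ec50,hill,top,bottom True 4PL parameters (viability %).
#' @param doses Dose series (nM), including 0.
#' @param cv Relative noise (coefficient of variation).
#' @param replicates Wells per dose.
#' @param background True background signal; `n_background` wells.
#' @param span Signal span corresponding to 100% viability.
#' @param n_background Number of buffer-only wells.
#' @param seed Optional integer seed.
#' @return A [viability_plate] with a `truth` attribute.
#' @export
simulate_dose_response <- function(ec50, hill = 1, top = 100, bottom = 0,
                                   doses = c(0, 1, 3, 10, 30, 100, 300,
                                             1000, 3000),
                                   cv = 0, replicates = 3, background = 50,
                                   span = 1000, n_background = 3,
                                   seed = NULL) {
  if (!is.null(seed)) withr::local_seed(seed)
  d <- rep(doses, each = replicates)
  v <- bottom + (top - bottom) / (1 + (d / ec50)^hill)
  sig <- background + span * v / 100 * (1 + rnorm(length(d), 0, cv))
  bg <- background * (1 + rnorm(n_background, 0, cv))
  plate <- viability_plate(d, sig, bg)
  attr(plate, "truth") <- list(ec50 = ec50, hill = hill, top = top,
                               bottom = bottom)
  plate
}

#' Simulate an 8x8 synergy inhibition matrix
#'
#' Monotherapy effects come from each drug's 4PL (top 100, bottom 0);
#' combined effects follow `Eab = min(1, kappa * (Ea + Eb - Ea*Eb))`, so
#' `kappa = 1` is the exact Bliss null, `kappa > 1` injects synergy and
#' `kappa < 1` antagonism.  Multiplicative noise is applied to the
#' inhibition values and clipped to `[0, 1]`.
#'
#' @param ec50_a,hill_a,ec50_b,hill_b Monotherapy 4PL parameters.
#' @param kappa Interaction multiplier (>= 0).
#' @param cv Relative noise on inhibition values.
#' @param doses_a,doses_b Dose grids including 0 (default 8-point
#'   log-scale ladders).
#' @param seed Optional integer seed.
#' @return List with `dose_a`, `dose_b`, `inhibition` matrix and `kappa`.
#' @export
simulate_synergy_matrix <- function(ec50_a, hill_a = 1, ec50_b, hill_b = 1,
                                    kappa = 1, cv = 0,
                                    doses_a = c(0, 1, 3, 10, 30, 100, 300, 1000),
                                    doses_b = c(0, 1, 3, 10, 30, 100, 300, 1000),
                                    seed = NULL) {
  if (kappa < 0) stop("kappa must be >= 0")
  if (!is.null(seed)) withr::local_seed(seed)
  eff <- function(d, ec50, h) {
    r <- (d / ec50)^h
    r / (1 + r)
  }
  ea <- eff(doses_a, ec50_a, hill_a)
  eb <- eff(doses_b, ec50_b, hill_b)
  M <- outer(ea, eb, function(a, b) pmin(1, kappa * (a + b - a * b)))
  M[, doses_b == 0] <- ea
  M[doses_a == 0, ] <- rep(eb, each = sum(doses_a == 0))
  if (cv > 0) {
    M <- M * (1 + matrix(rnorm(length(M), 0, cv), nrow(M)))
    M <- pmin(1, pmax(0, M))
  }
  dimnames(M) <- list(doses_a, doses_b)
  list(dose_a = doses_a, dose_b = doses_b, inhibition = M, kappa = kappa)
}

#' Simulate an expression-survival cohort
#'
#' Expression is standard normal; event times are exponential with hazard
#' `baseline_hazard * exp(beta * expression)` under independent
#' exponential censoring, so `beta = 0` gives a null cohort with no
#' expression-survival link.
#'
#' @param n Cohort size (>= 10).
#' @param beta Log hazard ratio per expression unit.
#' @param censor_rate Rate of the independent exponential censoring time
#'   (0 disables censoring).
#' @param baseline_hazard Baseline event hazard.
#' @param seed Optional integer seed.
#' @return Data frame with `subject_id`, `expression`, `time`, `event`.
#' @export
simulate_survival <- function(n, beta = 0, censor_rate = 0.02,
                              baseline_hazard = 0.1, seed = NULL) {
  if (n < 10L) stop("n must be >= 10")
  if (!is.null(seed)) withr::local_seed(seed)
  expr <- rnorm(n)
  t_ev <- rexp(n, baseline_hazard * exp(beta * expr))
  t_c <- if (censor_rate > 0) rexp(n, censor_rate) else rep(Inf, n)
  data.frame(subject_id = sprintf("S%04d", seq_len(n)),
             expression = expr,
             time = pmin(t_ev, t_c),
             event = as.integer(t_ev <= t_c),
             stringsAsFactors = FALSE)
}
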