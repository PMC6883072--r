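---
title: "Methods: pooled CRISPRa resistance-screen analysis and combination pharmacology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pooled CRISPRa resistance-screen analysis and combination pharmacology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crisprares)
```

## The problem

Pooled CRISPR activation (CRISPRa) screens discover drug-resistance genes
by transducing a cell population with a genome-wide guide library, growing
it under drug selection, and sequencing the integrated guide cassettes:
guides that activate a rescuing gene rise in relative abundance.
`crisprares` implements the full desk-side analysis of such a screen —
exact-match guide quantification from reads, normalization,
fold-enrichment hit calling with a multi-guide gene rule, and dual-drug
candidate intersection — together with the pharmacology computations that
accompany resistance-gene validation (dose–response fitting and effective
doses, Bliss-independence combination analysis, ΔΔCt quantification,
tumor volumes) and an expression-cutoff survival scan for prioritizing
hits against patient cohorts.  Because raw screen sequencing of this kind
is frequently not deposited, the package ships seeded generators for
every input it consumes; they define the study conditions under which the
pipeline is validated.

## Guide quantification

Reads are single-end, 100 nt, with a variable 1–8 nt stagger (introduced
by the library PCR primers to diversify early sequencing cycles),
followed by a constant vector-derived anchor and the 20-nt protospacer.
`count_sample()` locates the first anchor occurrence within the stagger
window and requires the following 20-mer to match a library protospacer
*exactly*; there is no mismatch tolerance and no reverse-complement
search, because the construct is directional and error-tolerant matching
would redistribute counts unpredictably.  When no anchor is configured,
every offset is scanned and a read is counted only if exactly one guide
matches at exactly one offset; anything else is ambiguous.  Reads too
short for an extraction are unmatched data, not errors.  Per sample the
QC identity `matched + ambiguous + unmatched = total` always holds.

The default anchor, `GGAAAGGACGAAACACCG`, is the U6-cassette suffix that
immediately precedes the protospacer in common lentiviral guide vectors.
It has no self-overlap under shifts of 1–8 nt, so a random stagger can
never create a spurious earlier anchor occurrence — this is what makes
the emit-then-count round trip exact rather than merely probable.

## Enrichment and hit calling

The enrichment statistic follows a deliberately simple, auditable recipe:

1. **Average** raw counts across the biological replicates of each
   day-14 condition (vehicle is a condition).  Averaging raw counts
   *before* normalization is the canonical order here; the alternative —
   normalize each replicate to a common total first — is available as
   `average_replicates(normalize_first = TRUE)` and makes results
   invariant to per-replicate sequencing depth.
2. **Normalize** each condition to a common total (`scale`, default 1e6,
   i.e. reads per million).  The scale and the pseudocount (default 1,
   added before the log and inside fold-change ratios) are conventions,
   not measurements, and both are configurable via `norm_config()`.
3. **Log-transform** (base 2 by default; base 10 available) for the
   regression diagnostic and the per-gene significance test.
4. **Fold change** per guide is the pseudocount-stabilized ratio of
   normalized treated over vehicle abundance; a guide is enriched iff
   its fold change is *strictly* greater than the threshold (default
   1.5 — "greater than 1.5-fold" means 1.5 exactly is not enriched).
5. **Gene rule**: a gene is a hit when at least `min_guides` (default 2
   of its 3) guides are enriched.  "Multiple guides" is read minimally
   as ≥ 2.
6. **Candidates**: genes hit under *both* drugs at a given dose level;
   candidate sets from several levels are unioned, and candidate sets
   from different cell lines can be intersected with
   `candidate_overlap()`.

Alongside the fold rule, `gene_significance()` reports an unpaired
two-sided Student's t-test per gene comparing log-normalized
per-replicate abundances between vehicle and treatment, pooling the
gene's guides across replicates (3 guides × 2 replicates = 6 values per
arm at design scale).  The pooling unit is a design choice — the test
could equally be run per guide — and equal variances are assumed by
default.  The candidate rule remains the fold rule plus intersection;
p-values are reported with the hits, not used to gate them.  The
pipeline carries no empirical false-positive control from non-targeting
guides (the library design assumed here has none); instead, the
simulator's null screens characterize the false-positive behaviour
directly.

Day-0 samples are carried for coverage QC only; the enrichment contrast
is treated versus vehicle at day 14.

## The screen simulator

`simulate_screen()` models selection as deterministic exponential
growth/kill plus two noise stages, which captures the signal the hit
caller tests at a small fraction of the complexity of a per-cell
birth–death process:

* initial per-guide abundance is log-normal (σ = 0.5) around the
  configured coverage of 500 cells per guide, folding transduction and
  low-MOI variability into the initial state;
* each day, cells multiply by `growth_rate` (1.4/day) and drug-treated
  populations retain the fraction `(1 − kill) + kill × rescue(gene)`,
  where `rescue ∈ [0, 1]` is the planted resistance strength (1 = the
  guide's gene fully rescues);
* final abundances get per-replicate multiplicative gamma noise
  (CV 0.15), and each sample is one multinomial draw of `depth` reads
  (2 × 10⁶ by default), so column sums equal the depth exactly.

Drug pressure is expressed directly as a per-day kill fraction rather
than a concentration: 0.2/day at the ED50-equivalent level and 0.35/day
at ED75.  These values were chosen once, a priori, to reproduce the
qualitative separation a successful screen shows between vehicle and
drug-treated populations: over 14 days they deplete sensitive cells to
~4% (ED50) and ~0.2% (ED75) of their vehicle trajectory, which at 5
planted genes in 300 gives fully rescued guides a ~16-fold normalized
enrichment — far above the 1.5 threshold — while unrescued guides sit
below 1.  What the simulator does *not* model: clonal interference,
guide-level activation heterogeneity beyond the scalar rescue strength,
off-target activity, PCR jackpotting, or sequencing error (available
separately in `emit_fastq(error_rate = )`).  Passing the recovery tests
therefore shows the pipeline recovers planted truth under these
dynamics, not that real screens are free of those artifacts.

## Dose–response and synergy

`normalize_viability()` subtracts the mean buffer-only background and
expresses each well relative to the mean background-subtracted vehicle
signal, so vehicle averages to exactly 100%.  `fit_4pl()` fits

$$V(c) = \mathrm{bottom} + \frac{\mathrm{top} - \mathrm{bottom}}
{1 + (c/\mathrm{ec50})^{h}}$$

by Levenberg–Marquardt least squares on log10 dose with box constraints
0 ≤ bottom, top ≤ 110 and h > 0, initialized at the data extremes with
the midpoint at the dose nearest half-range and h = 1.  Vehicle wells
are excluded from the fit (log 0 undefined); they act only through
normalization.  Degenerate data (e.g. flat viability) yield a flagged,
not thrown, non-converged fit.  The optimizer is driven directly
(`minpack.lm::nls.lm`), which keeps perfect zero-residual fits — common
with noiseless synthetic plates — from failing in post-hoc model
bookkeeping.  Effective doses invert the fitted span in closed form,
`EDx = ec50 · (x/(100−x))^{1/h}`, so ED50 is the fitted midpoint and the
x% is read relative to the fitted span for fits with bottom > 0.  ED50
groups are compared by unpaired t-test on log10 doses (ED50s are
log-normal across replicate fits; the scale choice is ours).

On plate noise: with the default design (8 positive doses in technical
triplicate) and 5% multiplicative well noise, the unweighted
least-squares ec50 estimate has a relative-error SD of about 5–6% with a
left-skewed tail; roughly 8% of plates land outside ±15% of truth.
That spread is a property of the estimator at this design — the misses
are global optima, and relative weighting widens rather than narrows
them — so single-plate ED50s should be treated as ±15%-class estimates
and replicate fits compared via `compare_ed50()`.

Drug combinations use Bliss independence: the expected combined effect
of independent drugs is `Ea + Eb − Ea·Eb`, and the combination index
`CI = (Ea + Eb − Ea·Eb)/Eab` scores observed combinations (CI < 1
synergy, = 1 additive within 1e-9, > 1 antagonism).  For 8 × 8 dose
matrices the monotherapy effects are read from the zero row/column of
the same plate, replicate-averaged inhibition is scored by default, and
zero-effect combinations are reported as undefined rather than fatal.
Apoptosis endpoints are first corrected for the vehicle baseline,
`E = (f − f₀)/(1 − f₀)` clipped to [0, 1], which puts monotherapy and
combination effects on the [0, 1] scale Bliss requires; the baseline
correction is a design choice.

## Survival cutoff scan

For each gene, `scan_cutoff()` tests every cutoff at midpoints between
consecutive distinct expression values, subject to both groups holding
at least `max(3, 5% of n)` subjects — the floor prevents degenerate
extreme splits.  Group separation is scored by the standard Mantel–Cox
log-rank test (tied event times contribute jointly at their shared
time), and the minimal p-value is Bonferroni-corrected by the number of
cutoffs actually tested.  Scanning for a best cutoff is a multiplicity
machine, and the correction universe is ambiguous in common practice —
cutoffs, genes, or both — so the package applies the within-gene cutoff
correction always and offers the across-gene factor as an explicit flag
in `screen_genes()`, reporting both.  Bonferroni over highly correlated
cutoff tests is conservative: on null cohorts (no expression–survival
link) the realized fraction of genes passing α = 0.05 is typically
1–4%.  Kaplan–Meier curves and medians come from the product-limit
estimator, with the median defined as the smallest time at which
survival reaches 0.5.

## Numerical and validation choices

* Ties in guide ranking break lexicographically by guide ID; ties in
  the cutoff scan resolve to the smallest cutoff.
* Zero-variance t-test inputs are handled explicitly: equal constant
  groups give p = 1, unequal constant groups p → 0.
* All generators are pure functions of (arguments, seed); the pipeline
  derives every internal seed from the run seed, and its run manifest
  excludes timestamps so reruns are byte-identical.
* Validation problem sizes: recovery and null screens use 300 genes × 3
  guides at 500× coverage, 2 replicates, depth 2 × 10⁶ over 20 seeds;
  the counting oracle uses 10⁵ reads over a 1,000-guide library for 5
  seeds; the scan oracle brute-forces cohorts of n ≤ 50 and its
  operating characteristics use 500 null cohorts (n = 80) and 100
  strong-effect cohorts (n = 200).  The genome-wide default library
  (23,430 genes × 3 guides) is exercised once through the writer/loader
  round trip.

## Limitations

The simulator's selection model is deterministic between its two noise
stages, so it understates the variance of real screens with strong
clonal dynamics; the exact-match counter will undercount on platforms
with high substitution rates (by design — the QC match rate makes the
loss visible); the survival scan assumes complete expression data and
right-censoring independent of expression; and the Bliss analysis takes
fractional effects at face value, with no dose–effect interpolation
between grid points.
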