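# Small in-code fixtures shared across the suite.

# Deterministic toy manifest: n_genes x guides_per_gene with fixed,
# hand-distinct protospacers (base-4 encoding of the guide index).
toy_manifest <- function(n_genes = 3L, guides_per_gene = 3L) {
  n <- n_genes * guides_per_gene
  protos <- vapply(seq_len(n) - 1L, function(i) {
    digits <- integer(20)
    for (k in 20:1) {
      digits[k] <- i %% 4L
      i <- i %/% 4L
    }
    paste(c("A", "C", "G", "T")[digits + 1L], collapse = "")
  }, character(1))
  genes <- rep(sprintf("G%03d", seq_len(n_genes)), each = guides_per_gene)
  gid <- paste0(genes, "_g", rep(seq_len(guides_per_gene), n_genes))
  guide_library(gid, genes, protos, name = "toy", version = "test")
}

# Minimal two-condition sample sheet (vehicle + one drug, 2 reps each).
toy_sheet <- function(cell_line = "SH-SY5Y") {
  sample_sheet(data.frame(
    sample_id = c("veh_r1", "veh_r2", "brig_r1", "brig_r2"),
    cell_line = cell_line,
    treatment = c("vehicle", "vehicle", "brigatinib", "brigatinib"),
    dose_level = c("none", "none", "ED50", "ED50"),
    replicate = c(1L, 2L, 1L, 2L),
    timepoint_days = 14L,
    stringsAsFactors = FALSE))
}

# Count matrix aligned to a manifest and sheet.
toy_counts <- function(manifest, sheet, seed = 1L) {
  withr::with_seed(seed, {
    m <- matrix(rpois(nrow(manifest) * nrow(sheet), 100),
                nrow = nrow(manifest),
                dimnames = list(manifest$guide_id, sheet$sample_id))
    storage.mode(m) <- "integer"
    m
  })
}

write_tmp_tsv <- function(df, ext = ".tsv") {
  path <- withr::local_tempfile(fileext = ext, .local_envir = parent.frame())
  sep <- if (ext == ".csv") "," else "\t"
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  path
}
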