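# In-code fixtures shared across tests.

# Small marker map: m markers on one chromosome at the given positions.
fix_map <- function(pos, chrom = "1", gentrain = 0.9,
                    ids = sprintf("m%02d", seq_along(pos))) {
  marker_map(data.frame(marker_id = ids, chrom = chrom, pos = pos,
                        gentrain = gentrain))
}

# Genotype matrix from a list of per-sample call vectors.
fix_geno <- function(calls_by_sample, ids = NULL, map = NULL) {
  m <- do.call(cbind, calls_by_sample)
  rownames(m) <- ids %||% sprintf("m%02d", seq_len(nrow(m)))
  colnames(m) <- names(calls_by_sample)
  snpkit::geno_matrix(m, map)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# The ten-marker QC fixture: each marker either passes all four criteria or
# violates an enumerated subset. Survivors: ok1, ok2, ok3, ok4.
qc_fixture_stats <- function() {
  data.frame(
    marker_id    = c("ok1", "ok2", "ok3", "ok4", "gt_low", "gt_edge",
                     "miss_hi", "het_hi", "maf_low", "multi_bad"),
    missing_rate = c(0.00, 0.10, 0.19, 0.05, 0.00, 0.00,
                     0.20, 0.00, 0.00, 0.25),
    het_rate     = c(0.00, 0.04, 0.00, 0.049, 0.00, 0.00,
                     0.00, 0.05, 0.00, 0.10),
    maf          = c(0.30, 0.06, 0.25, 0.051, 0.30, 0.30,
                     0.30, 0.30, 0.05, NA),
    n_alleles    = c(2L, 2L, 2L, 2L, 2L, 2L, 2L, 2L, 2L, 3L),
    maf_defined  = c(rep(TRUE, 9L), FALSE),
    gentrain     = c(0.90, 0.60, 0.51, 0.99, 0.40, 0.50,
                     0.90, 0.90, 0.90, 0.90),
    stringsAsFactors = FALSE)
}
qc_fixture_survivors <- c("ok1", "ok2", "ok3", "ok4")
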