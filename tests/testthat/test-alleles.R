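# Fixture: one haplotype gene over 30 markers plus one unfavorable-
# representative SNP gene, on a hand-built matrix.
alleles_fixture <- function() {
  hap_ids <- sprintf("h%02d", 1:30)
  rep_hap <- rep("AA", 30)
  carrier <- rep_hap                                   # exact match
  off <- rep_hap; off[15] <- "GG"                      # one hom mismatch
  hetero <- rep_hap; hetero[3] <- "AG"                 # het at one marker
  sparse <- rep_hap; sparse[1:9] <- "NN"               # 30% missing
  calls <- list(carrier = c(carrier, "CC"),
                off = c(off, "CC"),
                hetero = c(hetero, "CC"),
                sparse = c(sparse, "TT"))
  g <- fix_geno(calls, ids = c(hap_ids, "alk1"))
  hap <- gene_def("Bph18like", "12", "haplotype", hap_ids, rep_hap,
                  TRUE, "brown_planthopper")
  # representative carries the UNFAVORABLE allele: a match is unfavorable
  alk <- gene_def("ALKlike", "6", "snp", "alk1", "CC", FALSE, "quality",
                  "Minghui 63")
  list(geno = g, hap = hap, alk = alk)
}

test_that("haplotype match against a favorable representative is favorable", {
  fx <- alleles_fixture()
  expect_equal(call_gene(fx$geno, "carrier", fx$hap)$status, "favorable")
  cl <- call_gene(fx$geno, "off", fx$hap)
  expect_equal(cl$status, "unfavorable")
  expect_equal(cl$n_mismatch, 1)
})

test_that("matching an unfavorable representative flips the orientation", {
  fx <- alleles_fixture()
  # carrier/off/hetero all carry CC = the unfavorable representative allele
  expect_equal(call_gene(fx$geno, "carrier", fx$alk)$status, "unfavorable")
  # sparse carries TT, differing from the representative: favorable
  expect_equal(call_gene(fx$geno, "sparse", fx$alk)$status, "favorable")
})

test_that("missing fraction above the threshold gives undetermined; het gives heterozygous", {
  fx <- alleles_fixture()
  cl <- call_gene(fx$geno, "sparse", fx$hap, max_missing = 0.2)
  expect_equal(cl$status, "undetermined")   # 9/30 = 0.3 > 0.2
  expect_equal(cl$n_missing, 9)
  expect_equal(call_gene(fx$geno, "sparse", fx$hap, max_missing = 0.5)$status,
               "favorable")
  expect_equal(call_gene(fx$geno, "hetero", fx$hap)$status, "heterozygous")
})

test_that("statuses partition the cohort for every gene", {
  fx <- alleles_fixture()
  calls <- call_alleles(fx$geno, list(fx$hap, fx$alk))
  for (g in unique(calls$gene)) {
    st <- calls$status[calls$gene == g]
    expect_equal(length(st), ncol(fx$geno))
    expect_true(all(st %in% c("favorable", "unfavorable", "heterozygous",
                              "undetermined")))
  }
})

test_that("flipping the representative orientation swaps favorable and unfavorable", {
  fx <- alleles_fixture()
  flipped <- fx$hap
  flipped$representative_is_favorable <- FALSE
  a <- call_alleles(fx$geno, list(fx$hap))
  b <- call_alleles(fx$geno, list(flipped))
  det <- a$status %in% c("favorable", "unfavorable")
  expect_equal(b$status[det],
               ifelse(a$status[det] == "favorable", "unfavorable", "favorable"))
  expect_equal(b$status[!det], a$status[!det])
})

test_that("frequency percentages round half-up to one decimal", {
  mk <- function(n_fav, n) {
    data.frame(sample_id = sprintf("s%03d", seq_len(n)), gene = "g",
               status = c(rep("favorable", n_fav),
                          rep("unfavorable", n - n_fav)),
               n_missing = 0, n_mismatch = 0)
  }
  expect_equal(frequency_report(mk(1, 158))$percent, 0.6)
  expect_equal(frequency_report(mk(145, 154))$percent, 94.2)
  expect_equal(frequency_report(mk(0, 77))$percent, 0)
  # denominator policy: undetermined calls drop out under "determinate"
  calls <- mk(3, 10)
  calls$status[10] <- "undetermined"
  expect_equal(frequency_report(calls)$n_total, 10)
  expect_equal(frequency_report(calls, "determinate")$n_total, 9)
})

test_that("per-variety favorable counts match a planted histogram", {
  genes <- data.frame(gene = sprintf("Pi_%d", 1:4), chrom = as.character(1:4),
                      marker_type = "snp", n_markers = 1,
                      representative_is_favorable = TRUE,
                      trait_category = "blast",
                      carriers = c(10, 6, 3, 1))
  cfg <- sim_config(seed = 31, n_markers = 200, group_sizes = c(2L, 3L, 15L),
                    n_wild = 0L, dup_clusters = list(), genes = genes)
  x <- generate_collection(cfg)
  calls <- call_alleles(x$geno, x$catalog)
  pv <- per_variety_counts(calls, x$catalog, "blast")
  truth_counts <- rowSums(vapply(x$truth$carriers,
                                 function(cs) pv$per_sample$sample_id %in% cs,
                                 logical(nrow(pv$per_sample))))
  expect_equal(pv$per_sample$n_favorable, unname(truth_counts))
  expect_equal(sum(pv$proportions), 1)
  planted_bins <- table(factor(ifelse(truth_counts >= 4, "4+", truth_counts),
                               levels = c("0", "1", "2", "3", "4+")))
  expect_equal(unname(pv$proportions), as.numeric(planted_bins) / 20)
  expect_error(per_variety_counts(calls, x$catalog, "fragrance"),
               class = "snpkit_bad_trait")
})

test_that("co-occurrence is bounded by the member gene frequencies", {
  genes <- data.frame(gene = c("Wx", "ALK"), chrom = c("6", "6"),
                      marker_type = "snp", n_markers = 1,
                      representative_is_favorable = c(TRUE, TRUE),
                      trait_category = "quality",
                      carriers = c(30, 20))
  cfg <- sim_config(seed = 8, n_markers = 100, group_sizes = c(2L, 3L, 35L),
                    n_wild = 0L, dup_clusters = list(), genes = genes)
  x <- generate_collection(cfg)
  calls <- call_alleles(x$geno, x$catalog)
  fr <- frequency_report(calls)
  both <- co_occurrence(calls, c("Wx", "ALK"))
  expect_lte(both$percent, min(fr$percent))
  single <- co_occurrence(calls, "Wx")
  expect_equal(single$percent, fr$percent[fr$gene == "Wx"])
  expect_equal(both$n_favorable,
               length(intersect(x$truth$carriers$Wx, x$truth$carriers$ALK)))
  expect_error(co_occurrence(calls, character(0)),
               class = "snpkit_empty_gene_set")
})

test_that("planted carrier counts are recovered exactly with complete gene markers", {
  genes <- data.frame(gene = "G1", chrom = "1", marker_type = "haplotype",
                      n_markers = 5, representative_is_favorable = TRUE,
                      trait_category = "blast", carriers = 7)
  cfg <- sim_config(seed = 13, n_markers = 100, group_sizes = c(2L, 3L, 10L),
                    n_wild = 0L, dup_clusters = list(),
                    missing_rate = 0.1, genes = genes)
  x <- generate_collection(cfg)
  fr <- frequency_report(call_alleles(x$geno, x$catalog))
  expect_equal(fr$n_favorable, 7)
  expect_equal(fr$n_total, 15)
})
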