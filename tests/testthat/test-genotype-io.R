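test_that("ingest canonicalizes calls without altering allele content", {
  m <- matrix(c("GA", "NN", "TT", "CA", "AG", "TC"), nrow = 3,
              dimnames = list(c("m01", "m02", "m03"), c("s1", "s2")))
  g <- geno_matrix(m)
  expect_equal(unname(g[, "s1"]), c("AG", "NN", "TT"))
  expect_equal(unname(g[, "s2"]), c("AC", "AG", "CT"))
  # only within-call order changes: the multiset of allele pairs is preserved
  sort_pair <- function(x) paste(sort(strsplit(x, "")[[1]]), collapse = "")
  expect_setequal(unname(vapply(as.vector(g), sort_pair, character(1))),
                  unname(vapply(as.vector(m), sort_pair, character(1))))
})

test_that("malformed calls and referential violations raise named conditions", {
  m <- matrix("AA", 1, 1, dimnames = list("m01", "s1"))
  bad <- m; bad[1, 1] <- "AX"
  expect_error(geno_matrix(bad), class = "snpkit_bad_call")
  map <- fix_map(c(100, 200))
  orphan <- matrix("AA", 1, 1, dimnames = list("unknown", "s1"))
  expect_error(geno_matrix(orphan, map), class = "snpkit_unmapped_marker")
  short <- matrix("AA", 1, 1, dimnames = list("m01", "s1"))
  expect_error(geno_matrix(short, map), class = "snpkit_dimension_mismatch")
  expect_error(marker_map(data.frame(marker_id = c("a", "a"), chrom = "1",
                                     pos = c(1, 2))),
               class = "snpkit_duplicate_marker")
  expect_error(marker_map(data.frame(marker_id = c("a", "b"), chrom = "1",
                                     pos = c(5, 5))),
               class = "snpkit_duplicate_position")
})

test_that("write -> read -> write round trip is byte-identical", {
  map <- fix_map(c(100, 2000, 30000), gentrain = c(0.91, NA, 0.5))
  g <- fix_geno(list(s1 = c("AG", "NN", "TT"), s2 = c("AA", "CC", "TT")),
                map = map)
  d <- withr::local_tempdir()
  p1 <- file.path(d, "g1.tsv"); mp1 <- file.path(d, "m1.tsv")
  write_genotypes(g, map, p1, mp1)
  x <- read_genotypes(p1, mp1)
  p2 <- file.path(d, "g2.tsv"); mp2 <- file.path(d, "m2.tsv")
  write_genotypes(x$geno, x$map, p2, mp2)
  expect_identical(readLines(p1), readLines(p2))
  expect_identical(readLines(mp1), readLines(mp2))
  expect_identical(unclass(x$geno)[, ], unclass(g)[, ])
})

test_that("gene catalog validation enforces arity, traits and chromosomes", {
  expect_s3_class(
    gene_def("Bph18", "12", "haplotype", sprintf("b%02d", 1:30),
             rep("AA", 30), TRUE, "brown_planthopper"),
    "gene_def")
  expect_error(gene_def("X", "1", "snp", c("a", "b"), c("AA", "AA"),
                        TRUE, "blast"),
               class = "snpkit_bad_gene")
  expect_error(gene_def("X", "1", "haplotype", c("a", "b"), "AA",
                        TRUE, "blast"),
               class = "snpkit_haplotype_length")
  expect_error(gene_def("X", "1", "snp", "a", "AA", TRUE, "yield"),
               class = "snpkit_bad_trait")
  map <- fix_map(c(100, 200), chrom = "2", ids = c("a", "b"))
  gd <- gene_def("X", "1", "haplotype", c("a", "b"), c("AA", "AA"),
                 TRUE, "blast")
  expect_error(validate_catalog(list(gd), map),
               class = "snpkit_gene_chrom_mismatch")
})

test_that("gene catalog JSON round-trips through the reader", {
  gd <- gene_def("Pizt", "6", "indel", "pz1", "II", TRUE, "blast", "Toride 1")
  d <- withr::local_tempdir()
  p <- file.path(d, "cat.json")
  write_gene_catalog(list(gd), p)
  back <- read_gene_catalog(p)
  expect_length(back, 1)
  expect_identical(back[[1]]$representative, "II")
  expect_identical(back[[1]]$marker_type, "indel")
  expect_false(is.na(back[[1]]$representative_variety))
})

test_that("shipped starter catalog parses and is structurally valid", {
  p <- system.file("extdata", "starter_gene_catalog_synthetic.json",
                   package = "snpkit")
  cat <- read_gene_catalog(p)
  expect_gt(length(cat), 20)
  types <- vapply(cat, `[[`, character(1), "marker_type")
  expect_true(all(types %in% c("haplotype", "snp", "indel")))
  nm <- vapply(cat, function(g) length(g$markers), integer(1))
  expect_true(all(nm[types != "haplotype"] == 1L))
})

test_that("VCF import maps GT fields to canonical diploid calls", {
  skip_if_not_installed("vcfR")
  d <- withr::local_tempdir()
  vcf <- file.path(d, "x.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2",
    "1\t100\tv1\tA\tG\t.\tPASS\t.\tGT\t0/1\t1/1",
    "1\t200\tv2\tT\tTA\t.\tPASS\t.\tGT\t0/0\t./.",
    "2\t150\tv3\tC\tCT,G\t.\tPASS\t.\tGT\t1/0\t2/2"), vcf)
  x <- read_genotypes_vcf(vcf)
  expect_equal(unname(x$geno["v1", ]), c("AG", "GG"))
  expect_equal(unname(x$geno["v2", ]), c("TT", "NN"))
  expect_equal(unname(x$geno["v3", ]), c("CI", "GG"))
})
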