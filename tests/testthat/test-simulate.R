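test_that("generation is deterministic for a fixed seed, on disk too", {
  cfg <- sim_config(seed = 101, n_markers = 300)
  x1 <- generate_collection(cfg)
  x2 <- generate_collection(cfg)
  expect_identical(unclass(x1$geno)[, ], unclass(x2$geno)[, ])
  expect_identical(x1$truth, x2$truth)
  d1 <- file.path(withr::local_tempdir(), "a")
  d2 <- file.path(withr::local_tempdir(), "b")
  write_collection(x1, d1)
  write_collection(x2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  # a different seed changes the calls
  x3 <- generate_collection(sim_config(seed = 102, n_markers = 300))
  expect_false(identical(unclass(x1$geno)[, ], unclass(x3$geno)[, ]))
})

test_that("emitted files pass the package's own validation", {
  genes <- data.frame(gene = "G1", chrom = "2", marker_type = "haplotype",
                      n_markers = 4, representative_is_favorable = TRUE,
                      trait_category = "blast", carriers = 5)
  x <- generate_collection(sim_config(seed = 55, n_markers = 300, genes = genes))
  d <- withr::local_tempdir()
  write_collection(x, d)
  back <- read_genotypes(file.path(d, "genotypes.tsv"), file.path(d, "map.tsv"))
  expect_identical(unclass(back$geno)[, ], unclass(x$geno)[, ])
  meta <- read_sample_meta(file.path(d, "samples.tsv"), back$geno)
  expect_identical(meta$sample_id, x$meta$sample_id)
  cat <- read_gene_catalog(file.path(d, "catalog.json"), back$map)
  expect_length(cat, 1)
})

test_that("wild heterozygosity lands within three binomial errors of its rate", {
  x <- generate_collection(sim_config(seed = 77, missing_rate = 0))
  M <- sum(startsWith(rownames(x$geno), "mk_"))
  for (w in names(x$truth$wild_het_rate)) {
    r <- x$truth$wild_het_rate[[w]]
    st <- classify_calls(x$geno, w)
    realized <- mean(st == "het")
    se <- sqrt(r * (1 - r) / M)
    expect_lt(abs(realized - r), 3 * se + 1 / M)
  }
})

test_that("between-group distances exceed within-group distances", {
  x <- generate_collection(sim_config(seed = 6, resid_het_range = c(0, 0),
                                      missing_rate = 0))
  d <- distance_matrix(x$geno)$d
  grp <- x$truth$groups[colnames(d)]
  cult <- x$meta$sample_id[x$meta$class %in% c("local", "introduced")]
  cult <- setdiff(cult, x$meta$sample_id[x$truth$groups == "1"])  # exclude het-overlaid group
  within <- c(); between <- c()
  for (i in seq_along(cult)) for (j in seq_along(cult)) {
    if (i >= j) next
    v <- d[cult[i], cult[j]]
    if (grp[cult[i]] == grp[cult[j]]) within <- c(within, v) else between <- c(between, v)
  }
  expect_gt(min(between), max(within))
  # and the scale matches the mutation model: within ~ 2 p_within, between ~ 2 p_div (1 - p_div)
  expect_equal(mean(within), 2 * 0.02, tolerance = 0.5)
  expect_equal(mean(between), 2 * 0.2 * (1 - 0.2), tolerance = 0.25)
})

test_that("infeasible configurations are rejected", {
  expect_error(sim_config(p_div = 1.2), class = "snpkit_bad_config")
  expect_error(sim_config(group_sizes = c(0L, 5L)), class = "snpkit_bad_config")
  genes <- data.frame(gene = "G", chrom = "1", marker_type = "snp",
                      n_markers = 1, representative_is_favorable = TRUE,
                      trait_category = "blast", carriers = 999)
  expect_error(sim_config(genes = genes), class = "snpkit_bad_config")
  expect_error(sim_config(n_wild = 9L, group_sizes = c(5L, 5L, 33L)),
               class = "snpkit_bad_config")
})

test_that("near-duplicate cluster members are closer than ordinary group mates", {
  x <- generate_collection(sim_config(seed = 23, resid_het_range = c(0, 0),
                                      missing_rate = 0))
  d <- distance_matrix(x$geno)$d
  dup <- x$meta$sample_id[x$meta$class == "introduced"]
  plain3 <- setdiff(x$meta$sample_id[x$truth$groups == "3" &
                                       x$meta$class == "local"], dup)
  dup_d <- d[dup, dup][upper.tri(diag(length(dup)))]
  plain_d <- d[plain3, plain3][upper.tri(diag(length(plain3)))]
  expect_lt(max(dup_d), min(plain_d))
})
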