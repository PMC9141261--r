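test_that("call classification covers nucleotide and indel alphabets", {
  g <- fix_geno(list(s = c("AG", "AA", "NN", "DI", "II")))
  st <- classify_calls(g, "s")
  expect_equal(unname(st), c("het", "hom", "missing", "het", "hom"))
})

test_that("segmentation places boundaries at inter-marker midpoints", {
  seg <- segment_chromosome(c("hom", "hom", "het", "het", "het", "hom"),
                            c(10, 20, 30, 40, 50, 60),
                            chrom_length = 100, min_run = 3)
  expect_equal(seg$start, c(1, 26, 56))
  expect_equal(seg$end, c(25, 55, 100))
  expect_equal(seg$state, c("hom", "het", "hom"))
})

test_that("short het runs are absorbed and missing calls are transparent", {
  seg <- segment_chromosome(c("hom", "het", "missing", "hom"),
                            c(10, 20, 30, 40), 100, min_run = 3)
  expect_equal(nrow(seg), 1)
  expect_equal(seg$state, "hom")
  expect_equal(attr(seg, "absorbed"), 1L)
  # min_run = 1 disables smoothing
  seg1 <- segment_chromosome(c("hom", "het", "missing", "hom"),
                             c(10, 20, 30, 40), 100, min_run = 1)
  expect_equal(seg1$state, c("hom", "het", "hom"))
})

test_that("degenerate chromosomes are handled", {
  all_hom <- segment_chromosome(rep("hom", 5), c(1, 5, 10, 20, 30), 1000)
  expect_equal(all_hom[, c("start", "end")], data.frame(start = 1L, end = 1000L))
  none <- segment_chromosome(rep("missing", 3), c(1, 2, 3), 500)
  expect_true(none$low_confidence)
  expect_equal(none$state, "hom")
  expect_error(segment_chromosome(c("hom", "hom"), c(10, 10), 100),
               class = "snpkit_unsorted")
})

test_that("segments tile each chromosome exactly and het bp is monotone in min_run", {
  x <- generate_collection(sim_config(seed = 4, n_markers = 600))
  lens <- rice_chrom_lengths()
  seg3 <- background_segments(x$geno, x$map, lens, min_run = 3)
  bp <- tapply(seg3$end - seg3$start + 1,
               list(seg3$sample_id, seg3$chrom), sum)
  for (ch in colnames(bp)) expect_true(all(bp[, ch] == lens[[ch]]))
  seg5 <- background_segments(x$geno, x$map, lens, min_run = 5)
  het_bp <- function(s) sum((s$end - s$start + 1)[s$state == "het"])
  expect_lte(het_bp(seg5), het_bp(seg3))
})

test_that("planted het blocks are recovered within one inter-marker gap per edge", {
  cfg <- sim_config(seed = 9, n_markers = 1000, group_sizes = c(1L, 1L, 6L),
                    n_wild = 0L, dup_clusters = list(),
                    resid_het_range = c(0.03, 0.03), missing_rate = 0)
  x <- generate_collection(cfg)
  seg <- background_segments(x$geno, x$map)
  prof <- het_profile(seg)
  genome_bp <- sum(rice_chrom_lengths())
  max_gap <- max(unlist(lapply(split(x$map$pos, x$map$chrom), function(p) diff(sort(p)))))
  for (s in colnames(x$geno)) {
    planted <- x$truth$het_blocks[x$truth$het_blocks$sample_id == s, ]
    planted_bp <- sum(planted$end - planted$start + 1)
    got_bp <- sum((seg$end - seg$start + 1)[seg$sample_id == s & seg$state == "het"])
    expect_lt(abs(got_bp - planted_bp), 2 * nrow(planted) * max_gap + 1)
    # every planted block lies inside one recovered het segment
    for (b in seq_len(nrow(planted))) {
      hit <- seg$sample_id == s & seg$chrom == planted$chrom[b] &
        seg$state == "het" & seg$start <= planted$start[b] &
        seg$end >= planted$end[b]
      expect_true(any(hit))
    }
  }
  # a sample generated at 3% het bp reports a genome fraction inside [1%, 5%]
  gf <- prof$het_fraction[prof$chrom == "genome"]
  expect_true(all(gf >= 0.01 & gf <= 0.05))
})

test_that("an all-het wild accession shows a saturated het profile", {
  cfg <- sim_config(seed = 12, n_markers = 500, group_sizes = c(3L, 1L, 1L),
                    n_wild = 3L, wild_het_range = c(1, 1),
                    dup_clusters = list(), missing_rate = 0,
                    resid_het_range = c(0, 0))
  x <- generate_collection(cfg)
  st <- classify_calls(x$geno, "WILD1")
  expect_true(all(st == "het"))
  seg <- background_segments(x$geno, x$map, samples = "WILD1")
  prof <- het_profile(seg)
  expect_gt(prof$het_fraction[prof$chrom == "genome"], 0.95)
})

test_that("BED export converts to 0-based half-open coordinates", {
  seg <- data.frame(sample_id = "s", chrom = "1", start = 1, end = 100,
                    state = "hom", n_markers = 3, low_confidence = FALSE)
  p <- file.path(withr::local_tempdir(), "seg.bed")
  write_segments_bed(seg, p)
  expect_equal(readLines(p)[2], "1\t0\t100\ts\thom")
})
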