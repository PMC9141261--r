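# Per-marker statistics, the four-threshold array QC filter, and
# inter-marker gap / density summaries.

#' Per-marker quality statistics
#'
#' Computes, on the full sample set, each marker's missing rate (missing
#' calls / samples), heterozygosity rate (het calls / non-missing calls) and
#' minor allele frequency. MAF counts two allele copies per homozygote and
#' one of each per heterozygote; markers with more than two observed alleles
#' are flagged multi-allelic (the array design is biallelic) and their MAF is
#' `NA`, as is the MAF of all-missing markers.
#'
#' @param geno a [geno_matrix()].
#' @param map optional [marker_map()] supplying GenTrain scores.
#' @return a `marker_stats` data.frame with columns `marker_id`,
#'   `missing_rate`, `het_rate`, `maf`, `n_alleles`, `maf_defined`,
#'   `gentrain`.
#' @export
compute_marker_stats <- function(geno, map = NULL) {
  if (ncol(geno) < 1L) snp_stop("snpkit_no_samples", "genotype matrix has no samples")
  g <- unclass(geno)
  miss <- g == .missing_call
  n_samp <- ncol(g)
  n_obs <- n_samp - rowSums(miss)
  a1 <- substr(g, 1L, 1L); dim(a1) <- dim(g)
  a2 <- substr(g, 2L, 2L); dim(a2) <- dim(g)
  het <- (a1 != a2) & !miss
  het_rate <- ifelse(n_obs > 0L, rowSums(het) / n_obs, NA_real_)
  counts <- sapply(.allele_alphabet, function(L) {
    rowSums(((a1 == L) + (a2 == L)) * !miss)
  })
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1L,
                                             dimnames = list(NULL, .allele_alphabet))
  n_alleles <- rowSums(counts > 0L)
  total <- rowSums(counts)
  minor <- total - apply(counts, 1L, max)
  maf <- ifelse(n_obs == 0L | n_alleles > 2L, NA_real_, minor / pmax(total, 1L))
  out <- data.frame(marker_id = rownames(g),
                    missing_rate = rowSums(miss) / n_samp,
                    het_rate = het_rate,
                    maf = maf,
                    n_alleles = as.integer(n_alleles),
                    maf_defined = !is.na(maf),
                    gentrain = NA_real_,
                    stringsAsFactors = FALSE)
  if (!is.null(map)) out$gentrain <- map$gentrain[match(out$marker_id, map$marker_id)]
  rownames(out) <- NULL
  class(out) <- c("marker_stats", "data.frame")
  out
}

#' Apply the four-threshold marker filter
#'
#' A marker is kept iff it passes *all* of: GenTrain > `gentrain_min`,
#' missing rate < `missing_max`, heterozygosity rate < `het_max` and
#' MAF > `maf_min`. All four inequalities are strict, so boundary markers
#' (e.g. GenTrain exactly 0.5) are rejected. Statistics are computed once on
#' the full matrix and the filters applied jointly, so the result does not
#' depend on marker order or on the order the criteria are written in.
#' Missing GenTrain fails the GenTrain criterion and undefined MAF
#' (all-missing or multi-allelic markers) fails the MAF criterion —
#' conservative in both cases.
#'
#' @param stats a `marker_stats` data.frame from [compute_marker_stats()].
#' @param gentrain_min,missing_max,het_max,maf_min thresholds in \[0,1\];
#'   defaults are the standard array-QC values 0.5, 0.20, 0.05, 0.05.
#' @return a `qc_filter` list: `kept` and `rejected` marker id vectors, a
#'   per-criterion rejection `tally` (one marker may be tallied under several
#'   criteria), and the logical failure matrix `fails`.
#' @export
filter_markers <- function(stats, gentrain_min = 0.5, missing_max = 0.20,
                           het_max = 0.05, maf_min = 0.05) {
  th <- c(gentrain_min = gentrain_min, missing_max = missing_max,
          het_max = het_max, maf_min = maf_min)
  if (any(!is.finite(th)) || any(th < 0) || any(th > 1)) {
    snp_stop("snpkit_bad_threshold", "filter thresholds must lie in [0, 1]")
  }
  fails <- cbind(
    gentrain = !(stats$gentrain > gentrain_min) | is.na(stats$gentrain),
    missing  = !(stats$missing_rate < missing_max),
    het      = !(stats$het_rate < het_max) | is.na(stats$het_rate),
    maf      = !(stats$maf > maf_min) | is.na(stats$maf)
  )
  rownames(fails) <- stats$marker_id
  keep <- rowSums(fails) == 0L
  structure(list(kept = stats$marker_id[keep],
                 rejected = stats$marker_id[!keep],
                 tally = colSums(fails),
                 thresholds = th,
                 fails = fails),
            class = "qc_filter")
}

#' @export
print.qc_filter <- function(x, ...) {
  cat(sprintf("<qc_filter> kept %d / %d markers\n",
              length(x$kept), length(x$kept) + length(x$rejected)))
  cat("  rejections per criterion (a marker may fail several):\n")
  for (nm in names(x$tally)) cat(sprintf("    %-8s %d\n", nm, x$tally[[nm]]))
  invisible(x)
}

#' Inter-marker gap and marker-density summary
#'
#' Gaps are bp differences between adjacent markers within a chromosome
#' (never across chromosomes). For each threshold the genome-wide fraction
#' of gaps strictly shorter than it is reported ("shorter than 20 kb" is a
#' strict inequality). Density is the count of markers per half-open window
#' `[k*w + 1, (k+1)*w]`; only occupied windows are listed, and the counts
#' sum to the number of mapped markers.
#'
#' @param map a [marker_map()].
#' @param thresholds_bp numeric vector of gap thresholds in bp.
#' @param window_bp density window width in bp (default 100 kb).
#' @return a `gap_summary` list: `gaps` (per-chromosome sorted gap vectors),
#'   `fractions` (named by threshold; `NA` when there are no gaps),
#'   `n_gaps`, `mean_per_window`, and `window_counts`
#'   (data.frame chrom / window_start / count).
#' @export
gap_summary <- function(map, thresholds_bp = c(2000, 20000), window_bp = 100000L) {
  chroms <- attr(map, "chrom_levels") %||% chrom_order_levels(map$chrom)
  gaps <- lapply(chroms, function(ch) {
    pos <- sort(map$pos[map$chrom == ch])
    if (length(pos) < 2L) integer(0) else diff(pos)
  })
  names(gaps) <- chroms
  all_gaps <- unlist(gaps, use.names = FALSE)
  if (!length(all_gaps)) {
    fractions <- stats::setNames(rep(NA_real_, length(thresholds_bp)),
                                 paste0("lt_", thresholds_bp))
  } else {
    fractions <- stats::setNames(
      vapply(thresholds_bp, function(t) mean(all_gaps < t), numeric(1L)),
      paste0("lt_", thresholds_bp))
  }
  wc <- do.call(rbind, lapply(chroms, function(ch) {
    pos <- map$pos[map$chrom == ch]
    if (!length(pos)) return(NULL)
    idx <- (pos - 1L) %/% window_bp
    tab <- table(idx)
    data.frame(chrom = ch,
               window_start = as.integer(names(tab)) * window_bp + 1L,
               count = as.integer(tab), stringsAsFactors = FALSE)
  }))
  structure(list(gaps = gaps, fractions = fractions,
                 n_gaps = length(all_gaps),
                 thresholds_bp = thresholds_bp, window_bp = window_bp,
                 mean_per_window = nrow(map) / max(1L, sum(
                   vapply(chroms, function(ch) {
                     p <- map$pos[map$chrom == ch]
                     if (!length(p)) 0L else (max(p) - 1L) %/% window_bp + 1L
                   }, numeric(1L)))),
                 window_counts = wc),
            class = "gap_summary")
}

#' Export a gap summary
#'
#' Writes the gap fractions as JSON and the per-window marker counts as a
#' TSV (`chrom`, `window_start`, `count`) suitable for density plotting.
#'
#' @param gs a `gap_summary`.
#' @param json_path,tsv_path output paths (either may be `NULL` to skip).
#' @export
write_gap_summary <- function(gs, json_path = NULL, tsv_path = NULL) {
  if (!is.null(json_path)) {
    jsonlite::write_json(list(n_gaps = gs$n_gaps,
                              window_bp = gs$window_bp,
                              mean_per_window = gs$mean_per_window,
                              fractions = as.list(gs$fractions)),
                         json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  if (!is.null(tsv_path)) {
    wc <- gs$window_counts
    writeLines(c("chrom\twindow_start\tcount",
                 paste(wc$chrom, wc$window_start, wc$count, sep = "\t")),
               tsv_path)
  }
  invisible(NULL)
}
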