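# Graphical-genotyping background maps: classify calls, segment chromosomes
# into homozygous/heterozygous fragments, summarise heterozygosity.

#' Classify one sample's calls as hom / het / missing
#'
#' A call is heterozygous iff its two allele characters differ (this covers
#' indel markers, e.g. `"DI"`), missing iff it is `"NN"`, homozygous
#' otherwise.
#'
#' @param geno a [geno_matrix()].
#' @param sample sample id or column index.
#' @return named character vector over markers with values `"hom"`,
#'   `"het"`, `"missing"`.
#' @export
classify_calls <- function(geno, sample) {
  x <- geno[, sample]
  state <- ifelse(x == .missing_call, "missing",
                  ifelse(substr(x, 1L, 1L) == substr(x, 2L, 2L), "hom", "het"))
  stats::setNames(state, rownames(geno))
}

#' Segment one chromosome into hom/het fragments
#'
#' Works on the non-missing calls only (missing calls are transparent and do
#' not break runs). Maximal runs of equal state are found; heterozygous runs
#' supported by fewer than `min_run` calls are treated as noise and absorbed
#' into the homozygous context (`min_run = 1` disables smoothing; absorbed
#' call counts are reported in the `absorbed` attribute). Boundaries between
#' adjacent segments are placed at the inter-marker midpoint (rounded down),
#' the first segment starts at bp 1 and the last ends at `chrom_length`, so
#' the segments tile the chromosome exactly. A chromosome with no
#' non-missing call yields a single homozygous segment flagged low
#' confidence.
#'
#' @param states character vector of `"hom"`/`"het"`/`"missing"` per marker.
#' @param positions bp positions, strictly increasing, same length.
#' @param chrom_length chromosome length in bp.
#' @param min_run minimum het calls to declare a het segment (default 3).
#' @return data.frame with columns `start`, `end`, `state`, `n_markers`,
#'   `low_confidence`.
#' @export
segment_chromosome <- function(states, positions, chrom_length, min_run = 3L) {
  if (length(states) != length(positions)) {
    snp_stop("snpkit_dimension_mismatch", "states and positions differ in length")
  }
  if (is.unsorted(positions, strictly = TRUE)) {
    snp_stop("snpkit_unsorted", "marker positions must be strictly increasing")
  }
  if (min_run < 1L) snp_stop("snpkit_bad_threshold", "min_run must be >= 1")
  keep <- states != "missing"
  st <- states[keep]
  pos <- positions[keep]
  absorbed <- 0L
  if (!length(st)) {
    return(structure(data.frame(start = 1L, end = as.integer(chrom_length),
                                state = "hom", n_markers = 0L,
                                low_confidence = TRUE),
                     absorbed = absorbed))
  }
  # smooth: short het runs become hom
  r <- rle(st)
  short_het <- r$values == "het" & r$lengths < min_run
  absorbed <- sum(r$lengths[short_het])
  r$values[short_het] <- "hom"
  st <- inverse.rle(r)
  r <- rle(st)  # re-merge adjacent hom runs
  ends_idx <- cumsum(r$lengths)
  starts_idx <- c(1L, utils::head(ends_idx, -1L) + 1L)
  nseg <- length(r$lengths)
  # boundary between segment s and s+1: midpoint of flanking markers
  bounds <- if (nseg > 1L) {
    as.integer((pos[ends_idx[-nseg]] + pos[starts_idx[-1L]]) %/% 2L)
  } else integer(0)
  start <- c(1L, bounds + 1L)
  end <- c(bounds, as.integer(chrom_length))
  structure(data.frame(start = start, end = end, state = r$values,
                       n_markers = r$lengths, low_confidence = FALSE),
            absorbed = absorbed)
}

#' Background segments for samples across the genome
#'
#' Applies [classify_calls()] and [segment_chromosome()] per sample and
#' chromosome.
#'
#' @param geno a [geno_matrix()].
#' @param map a [marker_map()].
#' @param chrom_lengths named numeric vector of chromosome lengths in bp
#'   (default [rice_chrom_lengths()]); every map chromosome must be listed
#'   and no marker may lie beyond its chromosome's length.
#' @param min_run see [segment_chromosome()].
#' @param samples sample ids (default: all).
#' @return data.frame with columns `sample_id`, `chrom`, `start`, `end`,
#'   `state`, `n_markers`, `low_confidence`; total absorbed het calls in
#'   attribute `absorbed`.
#' @export
background_segments <- function(geno, map, chrom_lengths = rice_chrom_lengths(),
                                min_run = 3L, samples = NULL) {
  if (is.null(samples)) samples <- colnames(geno)
  chroms <- attr(map, "chrom_levels") %||% chrom_order_levels(map$chrom)
  missing_len <- setdiff(chroms, names(chrom_lengths))
  if (length(missing_len)) {
    snp_stop("snpkit_missing_chrom_length",
             sprintf("no length for chromosome(s): %s", paste(missing_len, collapse = ", ")))
  }
  over <- map$pos > chrom_lengths[map$chrom]
  if (any(over)) {
    snp_stop("snpkit_bad_position",
             sprintf("marker %s lies beyond its chromosome length",
                     map$marker_id[over][1L]))
  }
  absorbed <- 0L
  res <- vector("list", length(samples) * length(chroms))
  idx <- 0L
  for (s in samples) {
    state_all <- classify_calls(geno, s)
    for (ch in chroms) {
      sel <- map$chrom == ch
      seg <- segment_chromosome(state_all[map$marker_id[sel]], map$pos[sel],
                                chrom_lengths[[ch]], min_run)
      absorbed <- absorbed + attr(seg, "absorbed")
      seg <- cbind(sample_id = s, chrom = ch, seg)
      idx <- idx + 1L
      res[[idx]] <- seg
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  structure(out, absorbed = absorbed, chrom_lengths = chrom_lengths[chroms])
}

#' Per-sample heterozygosity profile
#'
#' For each sample: the fraction of each chromosome's bp covered by
#' heterozygous segments, and the genome-wide fraction (total het bp over
#' total genome bp). Segments must tile every chromosome exactly.
#'
#' @param segments output of [background_segments()] (or any data.frame with
#'   the same columns).
#' @param chrom_lengths named lengths; defaults to the attribute carried by
#'   `segments`.
#' @return data.frame with columns `sample_id`, `chrom` (or `"genome"`),
#'   `het_fraction`.
#' @export
het_profile <- function(segments, chrom_lengths = attr(segments, "chrom_lengths")) {
  if (is.null(chrom_lengths)) {
    snp_stop("snpkit_missing_chrom_length", "chromosome lengths are required")
  }
  segments$bp <- segments$end - segments$start + 1
  out <- list()
  for (s in unique(segments$sample_id)) {
    seg_s <- segments[segments$sample_id == s, ]
    het_bp <- numeric(0)
    for (ch in names(chrom_lengths)) {
      seg <- seg_s[seg_s$chrom == ch, ]
      seg <- seg[order(seg$start), ]
      len <- chrom_lengths[[ch]]
      ok <- nrow(seg) > 0 && seg$start[1L] == 1 && seg$end[nrow(seg)] == len &&
        all(seg$start[-1L] == utils::head(seg$end, -1L) + 1)
      if (!ok) {
        snp_stop("snpkit_tiling_violation",
                 sprintf("segments of sample %s do not tile chromosome %s", s, ch))
      }
      het_bp[[ch]] <- sum(seg$bp[seg$state == "het"])
      out[[length(out) + 1L]] <- data.frame(sample_id = s, chrom = ch,
                                            het_fraction = het_bp[[ch]] / len)
    }
    out[[length(out) + 1L]] <- data.frame(sample_id = s, chrom = "genome",
                                          het_fraction = sum(het_bp) / sum(chrom_lengths))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Export background segments as BED-like TSV
#'
#' BED uses 0-based half-open coordinates, so the 1-based inclusive `start`
#' is written as `start - 1` and `end` stays as is.
#'
#' @param segments output of [background_segments()].
#' @param path output path.
#' @export
write_segments_bed <- function(segments, path) {
  writeLines(c("#chrom\tstart\tend\tsample_id\tstate",
               paste(segments$chrom, segments$start - 1L, segments$end,
                     segments$sample_id, segments$state, sep = "\t")),
             path)
  invisible(path)
}

#' Export a heterozygosity profile as TSV
#'
#' @param profile output of [het_profile()].
#' @param path output path.
#' @export
write_het_profile <- function(profile, path) {
  writeLines(c("sample_id\tchrom\thet_fraction",
               paste(profile$sample_id, profile$chrom,
                     fmt6(profile$het_fraction), sep = "\t")),
             path)
  invisible(path)
}
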