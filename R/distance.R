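# Pairwise polymorphic-SNP-ratio distances between samples.

#' Polymorphic-SNP-ratio distance between two samples
#'
#' The distance between two lines is the ratio of polymorphic SNPs: the
#' proportion of pairwise-complete markers (non-missing in both samples) at
#' which the canonical genotype calls differ. A heterozygous call is its own
#' genotype state, so `"AG"` differs from both `"AA"` and `"GG"`. In
#' `"allele-sharing"` mode a pair of calls sharing exactly one allele
#' contributes a half mismatch instead of a full one (an IBS convention);
#' the default is the plain mismatch ratio.
#'
#' @param geno a [geno_matrix()].
#' @param i,j sample ids or column indices.
#' @param mode `"mismatch"` (default) or `"allele-sharing"`.
#' @return distance in \[0,1\].
#' @export
pairwise_distance <- function(geno, i, j, mode = c("mismatch", "allele-sharing")) {
  mode <- match.arg(mode)
  gi <- geno[, i]; gj <- geno[, j]
  ok <- gi != .missing_call & gj != .missing_call
  if (!any(ok)) {
    snp_stop("snpkit_undefined_distance",
             sprintf("no pairwise-complete markers for samples %s and %s", i, j))
  }
  gi <- gi[ok]; gj <- gj[ok]
  if (mode == "mismatch") return(mean(gi != gj))
  w <- .mismatch_weights(gi, gj)
  mean(w)
}

# Allele-sharing mismatch weight: 0 identical, 0.5 share exactly one allele,
# 1 share none. Calls are canonical two-character strings.
.mismatch_weights <- function(gi, gj) {
  eq <- gi == gj
  a1 <- substr(gi, 1L, 1L); a2 <- substr(gi, 2L, 2L)
  b1 <- substr(gj, 1L, 1L); b2 <- substr(gj, 2L, 2L)
  share <- (a1 == b1) | (a1 == b2) | (a2 == b1) | (a2 == b2)
  ifelse(eq, 0, ifelse(share, 0.5, 1))
}

#' Pairwise distance matrix for all samples
#'
#' Applies [pairwise_distance()] to every sample pair. The result is
#' symmetric with a zero diagonal; entries are defined only where at least
#' one pairwise-complete marker exists (otherwise an error naming the pair
#' is raised). The companion matrix `n_valid` records how many markers each
#' distance is based on.
#'
#' @inheritParams pairwise_distance
#' @return a `snp_dist` list with elements `d` (distance matrix), `n_valid`
#'   (integer matrix) and `mode`.
#' @export
distance_matrix <- function(geno, mode = c("mismatch", "allele-sharing")) {
  mode <- match.arg(mode)
  if (ncol(geno) < 2L) snp_stop("snpkit_too_few_samples", "need at least two samples")
  g <- unclass(geno)
  s <- colnames(g)
  n <- length(s)
  # integer-encode calls once; fast pairwise compares
  lev <- sort(unique(as.vector(g)))
  code <- matrix(match(g, lev), nrow = nrow(g))
  miss_code <- match(.missing_call, lev)
  obs <- if (is.na(miss_code)) matrix(TRUE, nrow(g), ncol(g)) else code != miss_code
  d <- matrix(0, n, n, dimnames = list(s, s))
  nv <- matrix(0L, n, n, dimnames = list(s, s))
  diag(nv) <- as.integer(colSums(obs))
  use_weights <- mode == "allele-sharing"
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      ok <- obs[, i] & obs[, j]
      m <- sum(ok)
      if (m == 0L) {
        snp_stop("snpkit_undefined_distance",
                 sprintf("no pairwise-complete markers for samples %s and %s",
                         s[i], s[j]))
      }
      if (use_weights) {
        val <- mean(.mismatch_weights(g[ok, i], g[ok, j]))
      } else {
        val <- mean(code[ok, i] != code[ok, j])
      }
      d[i, j] <- d[j, i] <- val
      nv[i, j] <- nv[j, i] <- m
    }
  }
  structure(list(d = d, n_valid = nv, mode = mode), class = "snp_dist")
}

#' @export
print.snp_dist <- function(x, ...) {
  cat(sprintf("<snp_dist> %d samples, mode = %s\n", nrow(x$d), x$mode))
  cat(sprintf("  distance range: %.4f .. %.4f\n",
              min(x$d[upper.tri(x$d)]), max(x$d[upper.tri(x$d)])))
  invisible(x)
}

#' @export
as.matrix.snp_dist <- function(x, ...) x$d

#' @export
as.dist.snp_dist <- function(m, diag = FALSE, upper = FALSE) {
  stats::as.dist(m$d, diag = diag, upper = upper)
}

#' Write a distance matrix as square TSV
#'
#' Sample ids form the header row and first column; distances are written
#' with six decimals so output is diffable.
#'
#' @param d a `snp_dist` or numeric matrix.
#' @param path output path.
#' @export
write_distance_matrix <- function(d, path) {
  m <- if (inherits(d, "snp_dist")) d$d else d
  lines <- c(paste(c("sample_id", colnames(m)), collapse = "\t"),
             vapply(seq_len(nrow(m)), function(i) {
               paste(c(rownames(m)[i], fmt6(m[i, ])), collapse = "\t")
             }, character(1L)))
  writeLines(lines, path)
  invisible(path)
}
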