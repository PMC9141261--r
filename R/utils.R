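# Shared helpers: classed error conditions, rounding, call-string handling.

#' Signal a classed snpkit error
#'
#' All validation failures in the package raise conditions with a distinct
#' class (prefixed `snpkit_`) so callers can catch specific failure modes.
#'
#' @param class character scalar, the specific condition class.
#' @param msg error message.
#' @noRd
snp_stop <- function(class, msg) {
  stop(errorCondition(msg, class = c(class, "snpkit_error")))
}

#' Round half away from zero
#'
#' Percentages in cohort reports are rounded half-up (2.25 -> 2.3), the
#' convention used in breeding summary tables, not the IEC half-to-even rule
#' of [base::round()].
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
#' @examples
#' round_half_up(94.1558, 1) # 94.2
#' round_half_up(0.25, 1)    # 0.3
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  # small epsilon guards against representation error in x * p for values
  # that are exact halves at the target precision
  floor(x * p + 0.5 + 1e-9) / p
}

# Valid single-character allele symbols: nucleotides plus insertion/deletion
# symbols so one caller handles SNP and indel markers alike.
.allele_alphabet <- c("A", "C", "G", "T", "I", "D")
.missing_call <- "NN"

#' Canonicalize diploid call strings
#'
#' Calls are unordered diploid genotypes written as two allele characters in
#' alphabetical order (`"GA"` becomes `"AG"`); the missing code is `"NN"`.
#' Phase is never represented. Invalid strings raise a
#' `snpkit_bad_call` error.
#'
#' @param x character vector of two-character call strings.
#' @return canonicalized character vector.
#' @export
#' @examples
#' canonicalize_calls(c("GA", "NN", "TT", "ID"))
canonicalize_calls <- function(x) {
  x <- as.character(x)
  bad <- is.na(x) | nchar(x) != 2L
  a1 <- substr(x, 1L, 1L)
  a2 <- substr(x, 2L, 2L)
  ok_pair <- a1 %in% .allele_alphabet & a2 %in% .allele_alphabet
  is_miss <- x == .missing_call
  if (any(bad | (!ok_pair & !is_miss))) {
    offenders <- unique(x[bad | (!ok_pair & !is_miss)])
    snp_stop("snpkit_bad_call",
             sprintf("malformed diploid call(s): %s",
                     paste(utils::head(offenders, 5L), collapse = ", ")))
  }
  swap <- !is_miss & a1 > a2
  x[swap] <- paste0(a2[swap], a1[swap])
  x
}

#' Reference chromosome lengths for rice
#'
#' Lengths in bp of the 12 *Oryza sativa* chromosomes (IRGSP-1.0 assembly),
#' used as the default coordinate frame for background maps and the
#' synthetic-collection generator.
#'
#' @return named numeric vector, names `"1"`..`"12"`.
#' @export
rice_chrom_lengths <- function() {
  c("1" = 43270923, "2" = 35937250, "3" = 36413819, "4" = 35502694,
    "5" = 29958434, "6" = 31248787, "7" = 29697621, "8" = 28443022,
    "9" = 23012720, "10" = 23207287, "11" = 29021106, "12" = 27531856)
}

# Order chromosome labels: numeric labels numerically, others lexically after.
chrom_order_levels <- function(labels) {
  u <- unique(as.character(labels))
  num <- suppressWarnings(as.numeric(u))
  u[order(is.na(num), num, u)]
}

# Fixed-format numbers for diffable output files.
fmt6 <- function(x) sprintf("%.6f", x)
fmt_pct <- function(x) sprintf("%.1f", x)
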