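# Favorable-allele calling against a functional-gene catalog, and cohort
# frequency / co-occurrence reports.

#' Call one gene for one sample
#'
#' The sample's calls at the gene's markers are compared with the
#' representative haplotype. If the fraction of missing calls exceeds
#' `max_missing` (or no call is non-missing) the status is `undetermined`.
#' Otherwise, if any non-missing call is heterozygous the status is
#' `heterozygous`. Otherwise the sample *matches* iff every non-missing call
#' equals the representative call, and the status is `favorable` when the
#' match agrees with the representative's orientation — match of a favorable
#' representative, or mismatch of an unfavorable representative (a donor
#' known to carry the non-functional allele) — else `unfavorable`.
#'
#' @param geno a [geno_matrix()].
#' @param sample sample id.
#' @param gene a [gene_def()].
#' @param max_missing maximum tolerated missing fraction over the gene's
#'   markers (default 0.2).
#' @return an `allele_call` list: `sample_id`, `gene`, `status`,
#'   `n_missing`, `n_mismatch`.
#' @export
call_gene <- function(geno, sample, gene, max_missing = 0.2) {
  absent <- setdiff(gene$markers, rownames(geno))
  if (length(absent)) {
    snp_stop("snpkit_unknown_gene_marker",
             sprintf("%s: marker(s) absent from genotype matrix: %s", gene$gene,
                     paste(utils::head(absent, 5L), collapse = ", ")))
  }
  v <- geno[gene$markers, sample]
  miss <- v == .missing_call
  n_missing <- sum(miss)
  obs <- v[!miss]
  rep_obs <- gene$representative[!miss]
  n_mismatch <- sum(obs != rep_obs)
  status <- if (n_missing / length(v) > max_missing || !length(obs)) {
    "undetermined"
  } else if (any(substr(obs, 1L, 1L) != substr(obs, 2L, 2L))) {
    "heterozygous"
  } else {
    match <- all(obs == rep_obs)
    if (match == gene$representative_is_favorable) "favorable" else "unfavorable"
  }
  structure(list(sample_id = sample, gene = gene$gene, status = status,
                 n_missing = n_missing, n_mismatch = n_mismatch),
            class = "allele_call")
}

#' Call all catalog genes for a cohort
#'
#' @inheritParams call_gene
#' @param catalog list of [gene_def()] objects.
#' @param samples sample ids (default: all columns of `geno`).
#' @return an `allele_calls` data.frame with columns `sample_id`, `gene`,
#'   `status`, `n_missing`, `n_mismatch`.
#' @export
call_alleles <- function(geno, catalog, samples = NULL, max_missing = 0.2) {
  if (is.null(samples)) samples <- colnames(geno)
  rows <- vector("list", length(catalog) * length(samples))
  i <- 0L
  for (gd in catalog) {
    for (s in samples) {
      cl <- call_gene(geno, s, gd, max_missing)
      i <- i + 1L
      rows[[i]] <- data.frame(sample_id = cl$sample_id, gene = cl$gene,
                              status = cl$status, n_missing = cl$n_missing,
                              n_mismatch = cl$n_mismatch,
                              stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("allele_calls", "data.frame")
  out
}

# Denominator for cohort percentages: "evaluated" counts every sample the
# gene was called on (undetermined and heterozygous included);
# "determinate" restricts to favorable + unfavorable calls.
.denominator <- function(status, policy) {
  switch(policy,
         evaluated = length(status),
         determinate = sum(status %in% c("favorable", "unfavorable")))
}

#' Cohort favorable-allele frequency report
#'
#' Per gene: the number of favorable calls, the denominator, and the
#' percentage rounded half-up to one decimal (the convention of printed
#' breeding tables). Heterozygous and undetermined calls are never counted
#' as favorable; the default denominator policy counts every evaluated
#' sample, and `"determinate"` restricts the denominator to
#' favorable + unfavorable calls. The policy is explicit because published
#' cohort tables are not always consistent about whether control and wild
#' accessions are in the denominator.
#'
#' @param calls an `allele_calls` data.frame.
#' @param denominator `"evaluated"` (default) or `"determinate"`.
#' @return a `frequency_report` data.frame with columns `gene`,
#'   `n_favorable`, `n_total`, `percent`.
#' @export
frequency_report <- function(calls, denominator = c("evaluated", "determinate")) {
  denominator <- match.arg(denominator)
  if (!nrow(calls)) snp_stop("snpkit_empty_cohort", "no allele calls supplied")
  genes <- unique(calls$gene)
  out <- do.call(rbind, lapply(genes, function(g) {
    st <- calls$status[calls$gene == g]
    n_fav <- sum(st == "favorable")
    n_tot <- .denominator(st, denominator)
    data.frame(gene = g, n_favorable = n_fav, n_total = n_tot,
               percent = if (n_tot > 0) round_half_up(100 * n_fav / n_tot, 1) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- c("frequency_report", "data.frame")
  out
}

#' Favorable-allele counts per variety within a trait category
#'
#' Counts, for every sample, how many genes of the category it carries in
#' the favorable state, and summarises the cohort as a proportion table over
#' the count bins 0, 1, 2, 3 and 4+ (the usual presentation for resistance
#' gene stacking).
#'
#' @param calls an `allele_calls` data.frame.
#' @param catalog list of [gene_def()] (supplies gene -> category mapping).
#' @param category a trait category present in the catalog.
#' @return list with `per_sample` (data.frame `sample_id`, `n_favorable`)
#'   and `proportions` (named numeric over bins `0`,`1`,`2`,`3`,`4+`,
#'   summing to 1).
#' @export
per_variety_counts <- function(calls, catalog, category) {
  genes <- vapply(catalog, `[[`, character(1L), "gene")
  cats <- vapply(catalog, `[[`, character(1L), "trait_category")
  sel_genes <- genes[cats == category]
  if (!length(sel_genes)) {
    snp_stop("snpkit_bad_trait",
             sprintf("no catalog gene has trait category '%s'", category))
  }
  cc <- calls[calls$gene %in% sel_genes, ]
  samples <- unique(calls$sample_id)
  n_fav <- vapply(samples, function(s) {
    sum(cc$status[cc$sample_id == s] == "favorable")
  }, integer(1L))
  bins <- ifelse(n_fav >= 4L, "4+", as.character(n_fav))
  lev <- c("0", "1", "2", "3", "4+")
  prop <- stats::setNames(as.numeric(table(factor(bins, levels = lev))) / length(samples), lev)
  list(per_sample = data.frame(sample_id = samples, n_favorable = n_fav,
                               stringsAsFactors = FALSE, row.names = NULL),
       proportions = prop)
}

#' Percentage of varieties favorable for every gene in a set
#'
#' The co-occurrence percentage is the share of samples whose status is
#' `favorable` for *all* genes in `genes`, with the same denominator policy
#' and half-up rounding as [frequency_report()]. For a singleton set it
#' equals that gene's report percentage, and it can never exceed the
#' minimum of the member genes' percentages.
#'
#' @param calls an `allele_calls` data.frame.
#' @param genes character vector of gene names (non-empty).
#' @param denominator `"evaluated"` or `"determinate"`.
#' @return list with `n_favorable`, `n_total`, `percent`.
#' @export
co_occurrence <- function(calls, genes, denominator = c("evaluated", "determinate")) {
  denominator <- match.arg(denominator)
  if (!length(genes)) snp_stop("snpkit_empty_gene_set", "gene set is empty")
  missing <- setdiff(genes, unique(calls$gene))
  if (length(missing)) {
    snp_stop("snpkit_bad_gene",
             sprintf("gene(s) not called: %s", paste(missing, collapse = ", ")))
  }
  cc <- calls[calls$gene %in% genes, ]
  samples <- unique(cc$sample_id)
  all_fav <- vapply(samples, function(s) {
    st <- cc$status[cc$sample_id == s]
    length(st) == length(genes) && all(st == "favorable")
  }, logical(1L))
  n_tot <- if (denominator == "evaluated") {
    length(samples)
  } else {
    # determinate for the whole set: every member gene call determinate
    sum(vapply(samples, function(s) {
      all(cc$status[cc$sample_id == s] %in% c("favorable", "unfavorable"))
    }, logical(1L)))
  }
  n_fav <- sum(all_fav)
  list(n_favorable = n_fav, n_total = n_tot,
       percent = if (n_tot > 0) round_half_up(100 * n_fav / n_tot, 1) else NA_real_)
}

#' Write allele calls as TSV
#'
#' @param calls an `allele_calls` data.frame.
#' @param path output path.
#' @export
write_allele_calls <- function(calls, path) {
  writeLines(c("sample_id\tgene\tstatus\tn_missing\tn_mismatch",
               paste(calls$sample_id, calls$gene, calls$status,
                     calls$n_missing, calls$n_mismatch, sep = "\t")),
             path)
  invisible(path)
}

#' Write a frequency report as JSON
#'
#' @param report a `frequency_report`.
#' @param path output path.
#' @export
write_frequency_report <- function(report, path) {
  out <- lapply(seq_len(nrow(report)), function(i) {
    list(gene = report$gene[i], n_favorable = report$n_favorable[i],
         n_total = report$n_total[i],
         percent = as.numeric(fmt_pct(report$percent[i])))
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
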