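# Readers, writers and validators for the package's text formats:
# genotype matrix (TSV), marker map (TSV), sample metadata (TSV) and
# functional-gene catalog (JSON).

#' Construct and validate a marker map
#'
#' A marker map records, per array marker, its chromosome, 1-based bp
#' position and (optionally) the vendor GenTrain clustering-quality score.
#' Markers are returned sorted by (chromosome, position); two markers at the
#' same position on one chromosome are rejected.
#'
#' @param df data.frame with columns `marker_id`, `chrom`, `pos` and
#'   optionally `gentrain` (real in \[0,1\], `NA` allowed).
#' @return a `marker_map` (sorted data.frame).
#' @export
marker_map <- function(df) {
  need <- c("marker_id", "chrom", "pos")
  if (!all(need %in% names(df))) {
    snp_stop("snpkit_bad_map",
             sprintf("marker map must have columns %s", paste(need, collapse = ", ")))
  }
  df$marker_id <- as.character(df$marker_id)
  df$chrom <- as.character(df$chrom)
  df$pos <- as.integer(df$pos)
  if (!"gentrain" %in% names(df)) df$gentrain <- NA_real_
  df$gentrain <- as.numeric(df$gentrain)
  if (anyDuplicated(df$marker_id)) {
    snp_stop("snpkit_duplicate_marker",
             sprintf("duplicate marker id(s): %s",
                     paste(utils::head(unique(df$marker_id[duplicated(df$marker_id)]), 5L),
                           collapse = ", ")))
  }
  if (any(is.na(df$pos)) || any(df$pos <= 0L)) {
    snp_stop("snpkit_bad_position", "marker positions must be positive integers")
  }
  gt <- df$gentrain[!is.na(df$gentrain)]
  if (any(gt < 0 | gt > 1)) {
    snp_stop("snpkit_bad_gentrain", "GenTrain scores must lie in [0, 1]")
  }
  lev <- chrom_order_levels(df$chrom)
  df <- df[order(match(df$chrom, lev), df$pos, df$marker_id), , drop = FALSE]
  dup_pos <- duplicated(df[, c("chrom", "pos")])
  if (any(dup_pos)) {
    snp_stop("snpkit_duplicate_position",
             sprintf("markers share a position: chrom %s pos %d",
                     df$chrom[dup_pos][1L], df$pos[dup_pos][1L]))
  }
  rownames(df) <- NULL
  attr(df, "chrom_levels") <- lev
  class(df) <- c("marker_map", "data.frame")
  df
}

#' Construct and validate a genotype matrix
#'
#' The genotype matrix holds one unordered diploid call per (marker, sample):
#' two allele characters from `{A,C,G,T,I,D}` in alphabetical order, or the
#' missing code `"NN"`. Calls are canonicalized on ingest (`"GA"` becomes
#' `"AG"`); phase is never represented. When a [marker_map()] is supplied the
#' rows are reordered to the map's (chromosome, position) order and
#' referential integrity is enforced.
#'
#' @param calls character matrix, rows = markers (rownames are marker ids),
#'   columns = samples (colnames are sample ids).
#' @param map optional [marker_map()].
#' @return a `geno_matrix` (character matrix).
#' @export
geno_matrix <- function(calls, map = NULL) {
  if (!is.matrix(calls) || !is.character(calls)) {
    snp_stop("snpkit_bad_matrix", "calls must be a character matrix")
  }
  if (is.null(rownames(calls)) || is.null(colnames(calls))) {
    snp_stop("snpkit_bad_matrix", "calls must have marker rownames and sample colnames")
  }
  if (anyDuplicated(rownames(calls))) {
    snp_stop("snpkit_duplicate_marker", "duplicate marker ids in genotype matrix")
  }
  if (anyDuplicated(colnames(calls))) {
    snp_stop("snpkit_duplicate_sample", "duplicate sample ids in genotype matrix")
  }
  canon <- canonicalize_calls(as.vector(calls))
  g <- matrix(canon, nrow = nrow(calls), dimnames = dimnames(calls))
  if (!is.null(map)) {
    missing_in_map <- setdiff(rownames(g), map$marker_id)
    if (length(missing_in_map)) {
      snp_stop("snpkit_unmapped_marker",
               sprintf("marker(s) absent from map: %s",
                       paste(utils::head(missing_in_map, 5L), collapse = ", ")))
    }
    missing_in_g <- setdiff(map$marker_id, rownames(g))
    if (length(missing_in_g)) {
      snp_stop("snpkit_dimension_mismatch",
               sprintf("map marker(s) absent from genotype matrix: %s",
                       paste(utils::head(missing_in_g, 5L), collapse = ", ")))
    }
    g <- g[map$marker_id, , drop = FALSE]
  }
  class(g) <- c("geno_matrix", class(g))
  g
}

#' @export
`[.geno_matrix` <- function(x, ...) {
  out <- NextMethod()
  if (is.matrix(out)) class(out) <- unique(c("geno_matrix", class(out)))
  out
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("<geno_matrix> %d markers x %d samples\n", nrow(x), ncol(x)))
  miss <- mean(x == .missing_call)
  cat(sprintf("  missing calls: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' Read a marker map TSV
#'
#' Expected columns: `marker_id`, `chrom`, `pos`, `gentrain` (tab-separated,
#' header row). Missing GenTrain values are written/read as `NA`.
#'
#' @param path file path.
#' @return a [marker_map()].
#' @export
read_marker_map <- function(path) {
  if (!file.exists(path)) snp_stop("snpkit_missing_file", sprintf("no such file: %s", path))
  df <- utils::read.delim(path, colClasses = "character", check.names = FALSE)
  df$pos <- as.integer(df$pos)
  df$gentrain <- suppressWarnings(as.numeric(df$gentrain))
  marker_map(df)
}

#' Read a genotype matrix with its marker map
#'
#' The genotype file is a TSV whose first column is `marker_id` and whose
#' remaining columns are one per sample, with a header row of sample ids.
#' Calls are canonicalized, markers are cross-checked against and ordered by
#' the map. Each failure mode raises a distinct condition class
#' (`snpkit_bad_call`, `snpkit_duplicate_marker`, `snpkit_unmapped_marker`,
#' `snpkit_dimension_mismatch`).
#'
#' @param path genotype TSV path.
#' @param map_path marker map TSV path.
#' @return list with elements `geno` ([geno_matrix()]) and `map`
#'   ([marker_map()]).
#' @export
read_genotypes <- function(path, map_path) {
  if (!file.exists(path)) snp_stop("snpkit_missing_file", sprintf("no such file: %s", path))
  map <- read_marker_map(map_path)
  df <- utils::read.delim(path, colClasses = "character", check.names = FALSE)
  if (names(df)[1L] != "marker_id") {
    snp_stop("snpkit_bad_header", "first genotype column must be 'marker_id'")
  }
  if (ncol(df) < 2L) {
    snp_stop("snpkit_dimension_mismatch", "genotype file has no sample columns")
  }
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df$marker_id
  list(geno = geno_matrix(m, map), map = map)
}

#' Write a genotype matrix and marker map as canonical TSV
#'
#' Output is deterministic: markers in map order, calls canonical, GenTrain
#' written with up to 15 significant digits so that `write(read(x))` is
#' byte-identical for files produced by this writer.
#'
#' @param geno a [geno_matrix()].
#' @param map a [marker_map()].
#' @param path genotype TSV output path.
#' @param map_path marker map TSV output path.
#' @return invisibly, the two paths.
#' @export
write_genotypes <- function(geno, map, path, map_path) {
  g <- geno[map$marker_id, , drop = FALSE]
  header <- paste(c("marker_id", colnames(g)), collapse = "\t")
  body <- vapply(seq_len(nrow(g)), function(i) {
    paste(c(rownames(g)[i], g[i, ]), collapse = "\t")
  }, character(1L))
  writeLines(c(header, body), path)
  gt <- ifelse(is.na(map$gentrain), "NA",
               vapply(map$gentrain, function(v) format(v, digits = 15), character(1L)))
  map_lines <- c("marker_id\tchrom\tpos\tgentrain",
                 paste(map$marker_id, map$chrom, map$pos, gt, sep = "\t"))
  writeLines(map_lines, map_path)
  invisible(c(path, map_path))
}

.sample_classes <- c("local", "wild", "introduced", "control")

#' Construct and validate sample metadata
#'
#' @param df data.frame with columns `sample_id`, `class` (one of `local`,
#'   `wild`, `introduced`, `control`) and `display_name`.
#' @param geno optional [geno_matrix()]; sample ids must then be a subset of
#'   its columns.
#' @return a `sample_meta` data.frame.
#' @export
sample_meta <- function(df, geno = NULL) {
  need <- c("sample_id", "class", "display_name")
  if (!all(need %in% names(df))) {
    snp_stop("snpkit_bad_meta",
             sprintf("sample metadata must have columns %s", paste(need, collapse = ", ")))
  }
  df <- as.data.frame(df)[, need]
  df$sample_id <- as.character(df$sample_id)
  df$class <- as.character(df$class)
  df$display_name <- as.character(df$display_name)
  if (anyDuplicated(df$sample_id)) {
    snp_stop("snpkit_duplicate_sample", "duplicate sample ids in metadata")
  }
  bad <- setdiff(unique(df$class), .sample_classes)
  if (length(bad)) {
    snp_stop("snpkit_bad_class",
             sprintf("unknown sample class(es): %s", paste(bad, collapse = ", ")))
  }
  if (!is.null(geno)) {
    extra <- setdiff(df$sample_id, colnames(geno))
    if (length(extra)) {
      snp_stop("snpkit_unknown_sample",
               sprintf("metadata sample(s) absent from genotypes: %s",
                       paste(utils::head(extra, 5L), collapse = ", ")))
    }
  }
  rownames(df) <- NULL
  class(df) <- c("sample_meta", "data.frame")
  df
}

#' Read / write sample metadata TSV
#'
#' @param path file path.
#' @param geno optional [geno_matrix()] for cross-validation.
#' @return a `sample_meta` data.frame.
#' @export
read_sample_meta <- function(path, geno = NULL) {
  if (!file.exists(path)) snp_stop("snpkit_missing_file", sprintf("no such file: %s", path))
  sample_meta(utils::read.delim(path, colClasses = "character", check.names = FALSE), geno)
}

#' @rdname read_sample_meta
#' @param meta a `sample_meta` data.frame.
#' @export
write_sample_meta <- function(meta, path) {
  writeLines(c("sample_id\tclass\tdisplay_name",
               paste(meta$sample_id, meta$class, meta$display_name, sep = "\t")),
             path)
  invisible(path)
}

.trait_categories <- c("brown_planthopper", "blast", "bacterial_blight",
                       "virus", "quality", "fragrance")

#' Construct and validate a functional-gene definition
#'
#' A gene is genotyped either by a single causal SNP/indel marker or by a
#' haplotype over several array markers. The representative haplotype is the
#' canonical call vector of a reference variety, and
#' `representative_is_favorable` records whether matching that haplotype is
#' the favorable state (e.g. the reference allele of a quality gene) or the
#' unfavorable one (e.g. a donor carrying the non-functional allele).
#'
#' @param gene gene name.
#' @param chrom chromosome label.
#' @param marker_type one of `"haplotype"`, `"snp"`, `"indel"`.
#' @param markers ordered character vector of marker ids (length >= 1; exactly
#'   1 for `snp`/`indel`).
#' @param representative character vector of canonical calls, same length as
#'   `markers`.
#' @param representative_is_favorable logical scalar.
#' @param trait_category one of `brown_planthopper`, `blast`,
#'   `bacterial_blight`, `virus`, `quality`, `fragrance`.
#' @param representative_variety display name of the reference variety.
#' @return a `gene_def` list.
#' @export
gene_def <- function(gene, chrom, marker_type, markers, representative,
                     representative_is_favorable, trait_category,
                     representative_variety = NA_character_) {
  marker_type <- match.arg(marker_type, c("haplotype", "snp", "indel"))
  markers <- as.character(markers)
  representative <- canonicalize_calls(as.character(representative))
  if (!length(markers)) {
    snp_stop("snpkit_bad_gene", sprintf("%s: gene needs at least one marker", gene))
  }
  if (length(representative) != length(markers)) {
    snp_stop("snpkit_haplotype_length",
             sprintf("%s: representative haplotype has %d calls for %d markers",
                     gene, length(representative), length(markers)))
  }
  if (marker_type %in% c("snp", "indel") && length(markers) != 1L) {
    snp_stop("snpkit_bad_gene",
             sprintf("%s: marker_type '%s' requires exactly one marker", gene, marker_type))
  }
  if (!trait_category %in% .trait_categories) {
    snp_stop("snpkit_bad_trait",
             sprintf("%s: unknown trait category '%s'", gene, trait_category))
  }
  structure(list(gene = as.character(gene), chrom = as.character(chrom),
                 marker_type = marker_type, markers = markers,
                 representative = representative,
                 representative_is_favorable = isTRUE(representative_is_favorable),
                 trait_category = trait_category,
                 representative_variety = as.character(representative_variety)),
            class = "gene_def")
}

#' Validate a gene catalog against a marker map
#'
#' Checks that each gene's markers exist in the map and lie on the gene's
#' declared chromosome.
#'
#' @param catalog list of [gene_def()] objects.
#' @param map a [marker_map()].
#' @return the catalog, invisibly.
#' @export
validate_catalog <- function(catalog, map) {
  for (gd in catalog) {
    missing <- setdiff(gd$markers, map$marker_id)
    if (length(missing)) {
      snp_stop("snpkit_unknown_gene_marker",
               sprintf("%s: marker(s) not in map: %s", gd$gene,
                       paste(utils::head(missing, 5L), collapse = ", ")))
    }
    chroms <- map$chrom[match(gd$markers, map$marker_id)]
    if (any(chroms != gd$chrom)) {
      snp_stop("snpkit_gene_chrom_mismatch",
               sprintf("%s: declared on chromosome %s but has markers on %s",
                       gd$gene, gd$chrom,
                       paste(unique(chroms[chroms != gd$chrom]), collapse = ", ")))
    }
  }
  invisible(catalog)
}

#' Read a functional-gene catalog (JSON)
#'
#' The catalog is a JSON array of objects with keys `gene`, `chrom`,
#' `marker_type`, `markers`, `representative`, `representative_is_favorable`,
#' `trait_category`, `representative_variety`.
#'
#' @param path JSON file path.
#' @param map optional [marker_map()]; when supplied the catalog is
#'   cross-validated with [validate_catalog()].
#' @return list of [gene_def()] objects.
#' @export
read_gene_catalog <- function(path, map = NULL) {
  if (!file.exists(path)) snp_stop("snpkit_missing_file", sprintf("no such file: %s", path))
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  catalog <- lapply(raw, function(x) {
    gene_def(gene = x$gene, chrom = x$chrom, marker_type = x$marker_type,
             markers = unlist(x$markers), representative = unlist(x$representative),
             representative_is_favorable = isTRUE(x$representative_is_favorable),
             trait_category = x$trait_category,
             representative_variety = x$representative_variety %||% NA_character_)
  })
  if (!is.null(map)) validate_catalog(catalog, map)
  catalog
}

#' Write a functional-gene catalog (JSON)
#'
#' @param catalog list of [gene_def()] objects.
#' @param path output path.
#' @export
write_gene_catalog <- function(catalog, path) {
  out <- lapply(catalog, function(gd) {
    list(gene = gd$gene, chrom = gd$chrom, marker_type = gd$marker_type,
         markers = gd$markers, representative = gd$representative,
         representative_is_favorable = gd$representative_is_favorable,
         trait_category = gd$trait_category,
         representative_variety = gd$representative_variety)
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Import diploid genotypes from a VCF (convenience reader)
#'
#' Maps diploid `GT` fields to canonical two-character calls using REF/ALT
#' alleles; multi-character alleles are encoded with the `I`/`D` indel
#' symbols (insertion/deletion relative to REF). This is a convenience
#' importer; the native interchange format is the TSV pair read by
#' [read_genotypes()]. Requires the suggested package `vcfR`.
#'
#' @param path VCF file path.
#' @return list with `geno` and `map` (GenTrain is `NA`).
#' @export
read_genotypes_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    snp_stop("snpkit_missing_dependency", "package 'vcfR' is required for VCF import")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  gt <- vcfR::extract.gt(v, element = "GT")
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0(fix[, "CHROM"], "_", fix[, "POS"])[is.na(ids) | ids == "."]
  allele_sym <- function(a, ref) {
    ifelse(nchar(a) == 1L & a %in% c("A", "C", "G", "T"), a,
           ifelse(nchar(a) > nchar(ref), "I", "D"))
  }
  n <- nrow(gt)
  calls <- matrix(.missing_call, nrow = n, ncol = ncol(gt),
                  dimnames = list(ids, colnames(gt)))
  for (i in seq_len(n)) {
    alleles <- c(fix[i, "REF"], strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1L]])
    syms <- allele_sym(alleles, fix[i, "REF"])
    row <- gt[i, ]
    parts <- strsplit(row, "[/|]")
    calls[i, ] <- vapply(parts, function(p) {
      if (length(p) != 2L || any(is.na(p)) || any(p == ".")) return(.missing_call)
      paste(sort(syms[as.integer(p) + 1L]), collapse = "")
    }, character(1L))
  }
  map <- marker_map(data.frame(marker_id = ids, chrom = fix[, "CHROM"],
                               pos = as.integer(fix[, "POS"]), gentrain = NA_real_))
  list(geno = geno_matrix(calls, map), map = map)
}
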