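# End-to-end orchestration: QC -> distance/tree/groups -> background map ->
# functional alleles, with a consolidated, diffable report bundle.

#' Default pipeline configuration
#'
#' Returns the full configuration list with every tunable at its default;
#' user configs (YAML) are merged over this, so the manifest always echoes
#' the complete effective settings.
#'
#' @return named list.
#' @export
default_run_config <- function() {
  list(
    genotypes = NULL, map = NULL, samples = NULL, catalog = NULL,
    out_dir = NULL,
    qc = list(gentrain_min = 0.5, missing_max = 0.2, het_max = 0.05, maf_min = 0.05),
    gaps = list(thresholds_bp = c(2000, 20000), window_bp = 100000),
    tree = list(k = 3, distance = "mismatch"),
    background = list(min_run = 3, chrom_lengths = NULL),
    alleles = list(max_missing = 0.2, denominator = "evaluated")
  )
}

.merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(base[[nm]]) && is.list(user[[nm]])) {
      base[[nm]] <- .merge_config(base[[nm]], user[[nm]])
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

#' Read a pipeline configuration file (YAML)
#'
#' @param path YAML file; keys mirror [default_run_config()].
#' @return merged configuration list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) snp_stop("snpkit_missing_file", sprintf("no such file: %s", path))
  .merge_config(default_run_config(), yaml::read_yaml(path))
}

.stage <- function(name, expr, out_dir) {
  tryCatch(expr, error = function(e) {
    writeLines(sprintf("FAILED at stage '%s': %s", name, conditionMessage(e)),
               file.path(out_dir, "FAILED"))
    stop(errorCondition(
      sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
      class = c("snpkit_stage_error", "snpkit_error"),
      stage = name))
  })
}

#' Run the full analysis pipeline
#'
#' Reads the inputs, applies the marker filter, computes the gap summary on
#' the kept markers, builds the distance matrix and neighbor-joining tree on
#' the kept markers and extracts `k` groups, segments every sample's
#' chromosomes into hom/het fragments, and — when a gene catalog is supplied
#' — calls favorable alleles on the full (unfiltered) matrix, since catalog
#' markers tag deliberately rare alleles that a MAF filter would discard.
#'
#' The report bundle written to `out_dir` contains `qc.json`, `kept.txt`,
#' `gaps.tsv`, `dist.tsv`, `tree.nwk`, `groups.tsv`, `segments.bed`,
#' `het.tsv`, `calls.tsv`, `freq.json` and `manifest.json` (package version,
#' effective configuration and its hash). All floats use fixed formatting,
#' so identical inputs and configuration yield a byte-identical bundle. A
#' stage failure aborts with a condition naming the stage and leaves a
#' `FAILED` marker next to any partial outputs.
#'
#' @param config a configuration list (see [default_run_config()]) or the
#'   path of a YAML file.
#' @param out_dir output directory; overrides `config$out_dir`.
#' @return invisibly, a list with the in-memory stage results.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  cfg <- if (is.character(config)) read_run_config(config) else
    .merge_config(default_run_config(), config)
  out_dir <- out_dir %||% cfg$out_dir
  if (is.null(out_dir)) snp_stop("snpkit_bad_config", "out_dir is required")
  cfg$out_dir <- out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  unlink(file.path(out_dir, "FAILED"))

  io <- .stage("genotype_io", {
    if (is.null(cfg$genotypes) || is.null(cfg$map)) {
      snp_stop("snpkit_bad_config", "genotypes and map paths are required")
    }
    x <- read_genotypes(cfg$genotypes, cfg$map)
    x$meta <- if (!is.null(cfg$samples)) read_sample_meta(cfg$samples, x$geno) else NULL
    x$catalog <- if (!is.null(cfg$catalog)) read_gene_catalog(cfg$catalog, x$map) else NULL
    x
  }, out_dir)

  qc <- .stage("marker_qc", {
    stats <- compute_marker_stats(io$geno, io$map)
    filt <- do.call(filter_markers, c(list(stats), cfg$qc))
    kept_map <- marker_map(io$map[io$map$marker_id %in% filt$kept, , drop = FALSE])
    gs <- gap_summary(kept_map, cfg$gaps$thresholds_bp, cfg$gaps$window_bp)
    writeLines(filt$kept, file.path(out_dir, "kept.txt"))
    jsonlite::write_json(
      list(thresholds = as.list(filt$thresholds),
           n_markers = nrow(stats), n_kept = length(filt$kept),
           rejection_tally = as.list(filt$tally),
           gap_fractions = lapply(as.list(gs$fractions),
                                  function(v) if (is.na(v)) NULL else v)),
      file.path(out_dir, "qc.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write_gap_summary(gs, tsv_path = file.path(out_dir, "gaps.tsv"))
    list(stats = stats, filter = filt, kept_map = kept_map, gaps = gs)
  }, out_dir)

  tree <- .stage("distance_tree", {
    g_kept <- io$geno[qc$filter$kept, , drop = FALSE]
    d <- distance_matrix(g_kept, mode = cfg$tree$distance)
    t <- neighbor_joining(d)
    grp <- cut_groups(t, cfg$tree$k)
    write_distance_matrix(d, file.path(out_dir, "dist.tsv"))
    write_newick(t, file.path(out_dir, "tree.nwk"))
    writeLines(c("sample_id\tgroup", paste(grp$sample_id, grp$group, sep = "\t")),
               file.path(out_dir, "groups.tsv"))
    list(dist = d, tree = t, groups = grp)
  }, out_dir)

  bg <- .stage("background_map", {
    lens <- cfg$background$chrom_lengths
    lens <- if (is.null(lens)) rice_chrom_lengths() else unlist(lens)
    g_kept <- io$geno[qc$filter$kept, , drop = FALSE]
    seg <- background_segments(g_kept, qc$kept_map, lens,
                               min_run = cfg$background$min_run)
    prof <- het_profile(seg)
    write_segments_bed(seg, file.path(out_dir, "segments.bed"))
    write_het_profile(prof, file.path(out_dir, "het.tsv"))
    list(segments = seg, profile = prof)
  }, out_dir)

  al <- if (!is.null(io$catalog)) .stage("functional_alleles", {
    calls <- call_alleles(io$geno, io$catalog, max_missing = cfg$alleles$max_missing)
    freq <- frequency_report(calls, denominator = cfg$alleles$denominator)
    write_allele_calls(calls, file.path(out_dir, "calls.tsv"))
    write_frequency_report(freq, file.path(out_dir, "freq.json"))
    list(calls = calls, freq = freq)
  }, out_dir) else NULL

  .stage("manifest", {
    cfg_echo <- cfg
    cfg_echo$out_dir <- NULL  # location-independent: identical inputs give identical bundles
    cfg_json <- jsonlite::toJSON(cfg_echo, auto_unbox = TRUE, digits = NA, null = "null")
    tmp <- tempfile(); writeLines(as.character(cfg_json), tmp)
    h <- unname(tools::md5sum(tmp)); unlink(tmp)
    jsonlite::write_json(list(package = "snpkit",
                              version = as.character(utils::packageVersion("snpkit")),
                              config = cfg_echo, config_md5 = h),
                         file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  }, out_dir)

  invisible(list(io = io, qc = qc, tree = tree, background = bg, alleles = al,
                 config = cfg))
}
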