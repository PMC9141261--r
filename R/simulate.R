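# Seeded generator of synthetic germplasm collections with known ground
# truth: planted group structure, a wild-dominated divergent group, residual
# heterozygous fragments, near-duplicate clusters and exact favorable-allele
# carrier counts.

#' Configuration for the synthetic-collection generator
#'
#' The defaults describe a desk-scale collection mirroring the shape of a
#' highland rice breeding panel at roughly 1/20 array scale: 2,000 biallelic
#' markers over the 12 rice chromosomes and 43 samples in three groups.
#' Group `wild_group` (default group 1) is the wild-dominated group found in
#' such collections: `n_wild` wild accessions carrying outcrossing-derived
#' heterozygosity plus a few "companion" varieties with elevated residual
#' heterozygosity that cluster with them; the other groups are cultivated
#' inbred varieties, the largest containing a near-duplicate cluster of
#' introduced elite varieties. Default group sizes 5/5/33.
#'
#' @param seed integer RNG seed; the whole collection is a deterministic
#'   function of the configuration.
#' @param n_markers number of background array markers.
#' @param chrom_lengths named chromosome lengths in bp.
#' @param group_sizes integer vector of group sizes. Wild accessions,
#'   companions, duplicate-cluster members and the control are members of
#'   their group and counted inside these sizes.
#' @param p_div fraction of markers at which each group founder differs from
#'   the shared base haplotype.
#' @param p_within fraction of markers mutated in each variety relative to
#'   its group founder.
#' @param n_wild number of wild accessions (inside
#'   `group_sizes[wild_group]`).
#' @param wild_group index of the wild-dominated group.
#' @param wild_het_range range the per-wild heterozygous call fraction is
#'   drawn from.
#' @param companion_het_range het call fraction range of the non-wild
#'   members of the wild group.
#' @param resid_het_range range of the genome bp fraction planted as
#'   residual heterozygous blocks in each inbred variety.
#' @param missing_rate per-call missing probability on background markers
#'   (gene markers are kept complete so planted carrier counts are exact).
#' @param dup_clusters list of near-duplicate cluster specs, each a list
#'   with `group`, `size`, `p_dup` (mutual divergence).
#' @param include_control add one control variety (a plain member of
#'   `control_group` with class `"control"`).
#' @param control_group group of the control; default the largest group.
#' @param genes `NULL`, or a data.frame with columns `gene`, `chrom`,
#'   `marker_type` (`haplotype`/`snp`/`indel`), `n_markers`,
#'   `representative_is_favorable`, `trait_category`, `carriers` (exact
#'   number of samples planted with the representative haplotype) and
#'   optionally `representative_variety`.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_markers = 2000L,
                       chrom_lengths = rice_chrom_lengths(),
                       group_sizes = c(5L, 5L, 33L),
                       p_div = 0.2,
                       p_within = 0.02,
                       n_wild = 3L,
                       wild_group = 1L,
                       wild_het_range = c(0.2, 0.6),
                       companion_het_range = c(0.1, 0.3),
                       resid_het_range = c(0, 0.05),
                       missing_rate = 0.02,
                       dup_clusters = list(list(group = 3L, size = 3L, p_dup = 0.002)),
                       include_control = FALSE,
                       control_group = NULL,
                       genes = NULL) {
  cfg <- list(seed = as.integer(seed), n_markers = as.integer(n_markers),
              chrom_lengths = chrom_lengths, group_sizes = as.integer(group_sizes),
              p_div = p_div, p_within = p_within, n_wild = as.integer(n_wild),
              wild_group = as.integer(wild_group), wild_het_range = wild_het_range,
              companion_het_range = companion_het_range,
              resid_het_range = resid_het_range, missing_rate = missing_rate,
              dup_clusters = dup_clusters, include_control = isTRUE(include_control),
              control_group = control_group, genes = genes)
  probs <- c(p_div, p_within, missing_rate, wild_het_range,
             companion_het_range, resid_het_range)
  if (any(probs < 0 | probs > 1)) {
    snp_stop("snpkit_bad_config", "all probabilities must lie in [0, 1]")
  }
  if (any(cfg$group_sizes < 1L)) {
    snp_stop("snpkit_bad_config", "group sizes must be >= 1")
  }
  if (cfg$n_wild > 0L) {
    if (cfg$wild_group > length(cfg$group_sizes) ||
        cfg$n_wild > cfg$group_sizes[cfg$wild_group]) {
      snp_stop("snpkit_bad_config", "wild accessions exceed their group size")
    }
  }
  for (dc in cfg$dup_clusters) {
    if (dc$group > length(cfg$group_sizes) || dc$size > cfg$group_sizes[dc$group]) {
      snp_stop("snpkit_bad_config", "duplicate cluster exceeds its group")
    }
  }
  n_cohort <- sum(cfg$group_sizes)
  if (!is.null(genes) && any(genes$carriers > n_cohort)) {
    snp_stop("snpkit_bad_config", "gene carrier count exceeds cohort size")
  }
  class(cfg) <- "sim_config"
  cfg
}

# Allocate markers to chromosomes proportionally to length (largest
# remainder method), at least 2 per chromosome when possible.
.allocate_markers <- function(n, lengths) {
  share <- n * lengths / sum(lengths)
  base <- pmax(2L, as.integer(floor(share)))
  deficit <- n - sum(base)
  if (deficit > 0) {
    frac <- share - floor(share)
    extra <- order(frac, decreasing = TRUE)
    idx <- rep_len(extra, deficit)
    for (i in idx) base[i] <- base[i] + 1L
  } else if (deficit < 0) {
    ord <- order(base, decreasing = TRUE)
    i <- 1L
    while (deficit < 0) {
      if (base[ord[i]] > 2L) { base[ord[i]] <- base[ord[i]] - 1L; deficit <- deficit + 1L }
      i <- if (i == length(ord)) 1L else i + 1L
    }
  }
  base
}

#' Generate a synthetic collection
#'
#' Deterministic for a fixed configuration (including seed). Markers are
#' placed uniformly at random per chromosome and sorted; a base haplotype of
#' homozygous calls is drawn per marker; each group founder mutates a
#' `p_div` fraction of markers to the alternate homozygote; each variety
#' mutates a `p_within` fraction of its founder; wild accessions (and the
#' wild group's companion varieties) receive heterozygous calls at their
#' sampled rate; the other inbred varieties receive residual heterozygous
#' blocks covering a sampled genome-bp fraction (the planted blocks are
#' recorded in the truth object); missing calls are sprinkled on background
#' markers; and gene markers are appended with the representative haplotype
#' planted in exactly the configured number of carriers (complete and
#' homozygous, so planted frequencies are exact).
#'
#' @param cfg a [sim_config()].
#' @return a `sim_collection` list: `geno`, `map`, `meta`, `catalog`
#'   (list of [gene_def()], empty when no genes configured) and `truth`
#'   (list with `groups`, `het_blocks`, `carriers`, `wild_het_rate`).
#' @export
generate_collection <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  chroms <- names(cfg$chrom_lengths)
  alloc <- .allocate_markers(cfg$n_markers, cfg$chrom_lengths)
  map_df <- do.call(rbind, lapply(seq_along(chroms), function(ci) {
    m <- alloc[ci]
    pos <- sort(sample.int(cfg$chrom_lengths[[ci]], m))
    data.frame(marker_id = sprintf("mk_%s_%05d", chroms[ci], seq_len(m)),
               chrom = chroms[ci], pos = pos,
               gentrain = round(stats::runif(m, 0.55, 1), 4),
               stringsAsFactors = FALSE)
  }))
  M <- nrow(map_df)
  nt <- c("A", "C", "G", "T")
  ref <- sample(nt, M, replace = TRUE)
  alt <- nt[((match(ref, nt) - 1L + sample.int(3L, M, replace = TRUE)) %% 4L) + 1L]
  hom_ref <- paste0(ref, ref)
  hom_alt <- paste0(alt, alt)
  het <- canonicalize_calls(paste0(ref, alt))

  n_groups <- length(cfg$group_sizes)
  founders <- lapply(seq_len(n_groups), function(g) {
    calls <- hom_ref
    idx <- sample.int(M, as.integer(round(cfg$p_div * M)))
    calls[idx] <- hom_alt[idx]
    calls
  })
  mutate_from <- function(parent, p) {
    calls <- parent
    idx <- sample.int(M, as.integer(round(p * M)))
    calls[idx] <- ifelse(calls[idx] == hom_ref[idx], hom_alt[idx], hom_ref[idx])
    calls
  }
  overlay_het <- function(calls, rate) {
    idx <- sample.int(M, as.integer(round(rate * M)))
    calls[idx] <- het[idx]
    calls
  }

  control_group <- cfg$control_group %||% which.max(cfg$group_sizes)
  sample_id <- character(0); klass <- character(0); group_of <- integer(0)
  het_overlaid <- logical(0)   # wilds + companions: no residual-block planting
  calls_list <- list()
  wild_het_rate <- numeric(0)
  vn <- 0L
  for (g in seq_len(n_groups)) {
    n_total <- cfg$group_sizes[g]
    n_wild_here <- if (g == cfg$wild_group) cfg$n_wild else 0L
    dcs <- Filter(function(dc) dc$group == g, cfg$dup_clusters)
    n_dup <- sum(vapply(dcs, function(dc) dc$size, integer(1L)))
    has_ctrl <- cfg$include_control && g == control_group
    n_plain <- n_total - n_wild_here - n_dup - as.integer(has_ctrl)
    if (n_plain < 0L) snp_stop("snpkit_bad_config", "group too small for its members")
    for (i in seq_len(n_plain)) {
      vn <- vn + 1L
      calls <- mutate_from(founders[[g]], cfg$p_within)
      is_companion <- g == cfg$wild_group && cfg$n_wild > 0L
      if (is_companion) {
        r <- stats::runif(1L, cfg$companion_het_range[1L], cfg$companion_het_range[2L])
        calls <- overlay_het(calls, r)
      }
      sample_id <- c(sample_id, sprintf("V%03d", vn))
      klass <- c(klass, "local"); group_of <- c(group_of, g)
      het_overlaid <- c(het_overlaid, is_companion)
      calls_list[[length(calls_list) + 1L]] <- calls
    }
    for (dc in dcs) {
      dup_founder <- mutate_from(founders[[g]], cfg$p_within)
      for (i in seq_len(dc$size)) {
        vn <- vn + 1L
        sample_id <- c(sample_id, sprintf("V%03d", vn))
        klass <- c(klass, "introduced"); group_of <- c(group_of, g)
        het_overlaid <- c(het_overlaid, FALSE)
        calls_list[[length(calls_list) + 1L]] <- mutate_from(dup_founder, dc$p_dup)
      }
    }
    if (has_ctrl) {
      sample_id <- c(sample_id, "CONTROL")
      klass <- c(klass, "control"); group_of <- c(group_of, g)
      het_overlaid <- c(het_overlaid, FALSE)
      calls_list[[length(calls_list) + 1L]] <- mutate_from(founders[[g]], cfg$p_within)
    }
    for (w in seq_len(n_wild_here)) {
      r <- stats::runif(1L, cfg$wild_het_range[1L], cfg$wild_het_range[2L])
      wild_het_rate <- c(wild_het_rate, r)
      calls <- overlay_het(mutate_from(founders[[g]], cfg$p_within), r)
      sample_id <- c(sample_id, sprintf("WILD%d", w))
      klass <- c(klass, "wild"); group_of <- c(group_of, g)
      het_overlaid <- c(het_overlaid, TRUE)
      calls_list[[length(calls_list) + 1L]] <- calls
    }
  }
  names(wild_het_rate) <- sample_id[klass == "wild"]
  geno <- do.call(cbind, calls_list)
  dimnames(geno) <- list(map_df$marker_id, sample_id)
  S <- ncol(geno)

  # residual heterozygous blocks in inbred varieties (not the wild group's
  # het-overlaid samples, whose heterozygosity is already planted)
  genome_bp <- sum(cfg$chrom_lengths)
  chrom_idx <- split(seq_len(M), map_df$chrom)[chroms]
  blocks <- list()
  for (s in which(!het_overlaid)) {
    target <- stats::runif(1L, cfg$resid_het_range[1L], cfg$resid_het_range[2L]) * genome_bp
    placed <- 0
    tries <- 0L
    while (placed < target && tries < 200L) {
      tries <- tries + 1L
      ci <- sample.int(length(chroms), 1L, prob = cfg$chrom_lengths / genome_bp)
      rows <- chrom_idx[[ci]]
      L <- sample(5:15, 1L)
      if (length(rows) < L) next
      start <- sample.int(length(rows) - L + 1L, 1L)
      sel <- rows[start:(start + L - 1L)]
      if (any(geno[sel, s] == het[sel])) next  # avoid overlapping an existing block
      geno[sel, s] <- het[sel]
      blocks[[length(blocks) + 1L]] <- data.frame(
        sample_id = sample_id[s], chrom = chroms[ci],
        start = map_df$pos[sel[1L]], end = map_df$pos[sel[L]],
        n_markers = L, stringsAsFactors = FALSE)
      placed <- placed + (map_df$pos[sel[L]] - map_df$pos[sel[1L]] + 1)
    }
  }
  het_blocks <- if (length(blocks)) do.call(rbind, blocks) else
    data.frame(sample_id = character(0), chrom = character(0),
               start = integer(0), end = integer(0), n_markers = integer(0))

  if (cfg$missing_rate > 0) {
    mask <- stats::runif(M * S) < cfg$missing_rate
    geno[mask] <- .missing_call
  }

  # gene markers: appended complete and homozygous so carrier counts are exact
  catalog <- list()
  carriers <- list()
  if (!is.null(cfg$genes)) {
    gdf <- cfg$genes
    occupied <- split(map_df$pos, map_df$chrom)
    gene_rows <- list()
    for (gi in seq_len(nrow(gdf))) {
      gene <- gdf$gene[gi]; ch <- as.character(gdf$chrom[gi])
      k <- as.integer(gdf$n_markers[gi])
      mtype <- as.character(gdf$marker_type[gi])
      len <- cfg$chrom_lengths[[ch]]
      repeat {
        pos <- sort(sample.int(len, k))
        if (!any(pos %in% occupied[[ch]])) break
      }
      occupied[[ch]] <- c(occupied[[ch]], pos)
      ids <- sprintf("%s_M%02d", gene, seq_len(k))
      if (mtype == "indel") {
        g_ref <- rep("I", k); g_alt <- rep("D", k)
      } else {
        g_ref <- sample(nt, k, replace = TRUE)
        g_alt <- nt[((match(g_ref, nt) - 1L + sample.int(3L, k, replace = TRUE)) %% 4L) + 1L]
      }
      rep_call <- paste0(g_ref, g_ref)
      alt_call <- paste0(g_alt, g_alt)
      carr <- sort(sample(sample_id, as.integer(gdf$carriers[gi])))
      block <- matrix(rep(alt_call, S), nrow = k, dimnames = list(ids, sample_id))
      block[, carr] <- rep_call
      gene_rows[[gi]] <- list(
        map = data.frame(marker_id = ids, chrom = ch, pos = pos,
                         gentrain = round(stats::runif(k, 0.8, 1), 4),
                         stringsAsFactors = FALSE),
        calls = block)
      rv <- if ("representative_variety" %in% names(gdf)) gdf$representative_variety[gi] else NA_character_
      catalog[[gene]] <- gene_def(gene = gene, chrom = ch, marker_type = mtype,
                                  markers = ids, representative = rep_call,
                                  representative_is_favorable = isTRUE(gdf$representative_is_favorable[gi]),
                                  trait_category = as.character(gdf$trait_category[gi]),
                                  representative_variety = rv)
      carriers[[gene]] <- carr
    }
    map_df <- rbind(map_df, do.call(rbind, lapply(gene_rows, `[[`, "map")))
    geno <- rbind(geno, do.call(rbind, lapply(gene_rows, `[[`, "calls")))
  }

  map <- marker_map(map_df)
  g <- geno_matrix(geno, map)
  meta <- sample_meta(data.frame(sample_id = sample_id, class = klass,
                                 display_name = sample_id,
                                 stringsAsFactors = FALSE), g)
  truth <- list(groups = stats::setNames(as.character(group_of), sample_id),
                het_blocks = het_blocks,
                carriers = carriers,
                wild_het_rate = wild_het_rate)
  structure(list(geno = g, map = map, meta = meta,
                 catalog = unname(catalog), truth = truth, config = cfg),
            class = "sim_collection")
}

#' Write a synthetic collection to a directory
#'
#' Emits `genotypes.tsv`, `map.tsv`, `samples.tsv`, `catalog.json` (when
#' genes were planted) and `truth.json`, all in the package's interchange
#' formats, so a generated collection round-trips through the readers.
#'
#' @param x a `sim_collection`.
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
write_collection <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_genotypes(x$geno, x$map, file.path(dir, "genotypes.tsv"),
                  file.path(dir, "map.tsv"))
  write_sample_meta(x$meta, file.path(dir, "samples.tsv"))
  if (length(x$catalog)) write_gene_catalog(x$catalog, file.path(dir, "catalog.json"))
  truth <- list(groups = as.list(x$truth$groups),
                het_blocks = x$truth$het_blocks,
                carriers = x$truth$carriers,
                wild_het_rate = as.list(x$truth$wild_het_rate))
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  invisible(dir)
}
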