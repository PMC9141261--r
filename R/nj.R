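# Neighbor-joining tree construction (Studier-Keppler selection criterion),
# Newick export, and group extraction by cutting long internal edges.

#' Build an unrooted neighbor-joining tree
#'
#' Canonical agglomerative NJ with the Studier-Keppler O(n^3) selection
#' criterion: at each step the pair minimising
#' `Q(i,j) = (n-2) d(i,j) - R_i - R_j` (with `R_i = sum_k d(i,k)`) is
#' joined; branch lengths are
#' `l_i = d(i,j)/2 + (R_i - R_j) / (2(n-2))`, `l_j = d(i,j) - l_i`, and the
#' new node's distances are `d(u,k) = (d(i,k) + d(j,k) - d(i,j)) / 2`.
#' Ties in Q are broken by the smallest (row, column) index pair in the
#' current matrix order (input order; newly created nodes rank last).
#' Negative branch lengths are clamped to zero and the pre-clamp values
#' recorded in the `clamped` attribute. The final two nodes are connected by
#' a single edge of their remaining distance, yielding an unrooted binary
#' tree in which every internal node has degree three.
#'
#' On an additive distance matrix NJ reconstructs the generating tree and
#' branch lengths exactly.
#'
#' @param d a `snp_dist` from [distance_matrix()], a symmetric numeric
#'   matrix with labelled rows, or a [stats::dist].
#' @return an `nj_tree`, structurally an ape-style `phylo` list (`edge`,
#'   `edge.length`, `Nnode`, `tip.label`) with attribute `clamped`
#'   (data.frame of pre-clamp negative lengths, empty when none occurred).
#' @export
neighbor_joining <- function(d) {
  D <- if (inherits(d, "snp_dist")) d$d else as.matrix(d)
  n <- nrow(D)
  if (is.null(rownames(D))) rownames(D) <- colnames(D) <- paste0("t", seq_len(n))
  labels <- rownames(D)
  if (n < 3L) snp_stop("snpkit_nj_too_few", "neighbor joining needs at least 3 samples")
  if (any(!is.finite(D))) {
    snp_stop("snpkit_undefined_distance", "distance matrix contains undefined entries")
  }
  ids <- seq_len(n)              # active node ids; tips are 1..n
  cur <- D
  next_id <- n + 1L
  ep <- ec <- integer(0)         # edge parent / child (internal ids)
  el <- numeric(0)
  clamped_node <- integer(0); clamped_len <- numeric(0)
  add_edge <- function(parent, child, len) {
    if (len < 0) {
      clamped_node <<- c(clamped_node, child)
      clamped_len <<- c(clamped_len, len)
      len <- 0
    }
    ep <<- c(ep, parent); ec <<- c(ec, child); el <<- c(el, len)
  }
  while (length(ids) > 2L) {
    m <- nrow(cur)
    R <- rowSums(cur)
    Q <- (m - 2) * cur - outer(R, R, `+`)
    diag(Q) <- Inf
    Q[lower.tri(Q)] <- Inf
    hits <- which(Q == min(Q), arr.ind = TRUE)
    hit <- hits[order(hits[, 1L], hits[, 2L])[1L], ]
    i <- hit[[1L]]; j <- hit[[2L]]
    dij <- cur[i, j]
    li <- dij / 2 + (R[i] - R[j]) / (2 * (m - 2))
    lj <- dij - li
    u <- next_id; next_id <- next_id + 1L
    add_edge(u, ids[i], li)
    add_edge(u, ids[j], lj)
    dn <- (cur[i, ] + cur[j, ] - dij) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    cur <- rbind(cbind(cur[keep, keep, drop = FALSE], dn[keep]), c(dn[keep], 0))
    ids <- c(ids[keep], u)
  }
  # connect the final two nodes; the later-created node is used as the root
  # of the edge orientation (a degree-3 internal node, not a true root)
  root <- max(ids)
  other <- ids[ids != root]
  add_edge(root, other, cur[1L, 2L])
  # renumber internal nodes to the phylo convention: tips 1..n, root n+1,
  # remaining internal nodes in preorder; edges listed cladewise
  nn <- n - 2L
  new_id <- integer(2L * n - 2L)
  new_id[seq_len(n)] <- seq_len(n)
  kids <- split(seq_along(ep), ep)
  edge_order <- integer(0)
  counter <- n + 1L
  walk <- function(node) {
    new_id[node] <<- counter
    counter <<- counter + 1L
    for (e in kids[[as.character(node)]]) {
      edge_order <<- c(edge_order, e)
      ch <- ec[e]
      if (ch > n) walk(ch)
    }
  }
  walk(root)
  edge <- cbind(new_id[ep[edge_order]], new_id[ec[edge_order]])
  tree <- structure(list(edge = edge, edge.length = el[edge_order],
                         Nnode = nn, tip.label = labels),
                    class = c("nj_tree", "phylo"))
  attr(tree, "order") <- "cladewise"
  attr(tree, "clamped") <- data.frame(node = new_id[clamped_node],
                                      original_length = clamped_len)
  tree
}

# Quote a Newick label when it contains structural characters or blanks.
quote_newick_label <- function(x) {
  # `]` first so the bracket expression parses as intended under POSIX rules
  needs <- grepl("[][ \t():;,']", x)
  x[needs] <- paste0("'", gsub("'", "''", x[needs]), "'")
  x
}

#' Serialize a tree to Newick
#'
#' Branch lengths are written with fixed precision (default six decimals)
#' and the children of every node are ordered by their smallest descendant
#' leaf label, so the output is deterministic. Labels containing blanks or
#' Newick syntax characters are single-quoted.
#'
#' @param tree an `nj_tree` (or any phylo-style list).
#' @param digits decimals for branch lengths.
#' @return Newick string terminated by `";"`.
#' @export
to_newick <- function(tree, digits = 6L) {
  fmt <- paste0("%.", digits, "f")
  n <- length(tree$tip.label)
  edge <- tree$edge
  len <- tree$edge.length
  total <- n + tree$Nnode
  # smallest descendant tip label per node: preorder reversed visits every
  # child subtree before its parent edge is folded in
  minlab <- rep(NA_character_, total)
  minlab[seq_len(n)] <- tree$tip.label
  for (e in rev(seq_len(nrow(edge)))) {
    p <- edge[e, 1L]; ch <- edge[e, 2L]
    minlab[p] <- if (is.na(minlab[p])) minlab[ch] else min(minlab[p], minlab[ch])
  }
  kids <- split(seq_len(nrow(edge)), edge[, 1L])
  build <- function(node) {
    if (node <= n) return(quote_newick_label(tree$tip.label[node]))
    es <- kids[[as.character(node)]]
    es <- es[order(minlab[edge[es, 2L]])]
    parts <- vapply(es, function(e) {
      paste0(build(edge[e, 2L]), ":", sprintf(fmt, len[e]))
    }, character(1L))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  paste0(build(n + 1L), ";")
}

#' Write a tree as a Newick file
#'
#' @param tree an `nj_tree`.
#' @param path output path.
#' @param digits decimals for branch lengths.
#' @export
write_newick <- function(tree, path, digits = 6L) {
  writeLines(to_newick(tree, digits), path)
  invisible(path)
}

#' Cut a tree into k groups
#'
#' Removes the `k - 1` internal edges of greatest length (ties broken by
#' edge index in the tree's edge table); the connected components of the
#' remaining forest define the groups. In the degenerate regime where that
#' leaves fewer than `k` leaf-bearing components (e.g. `k` close to the leaf
#' count, where a binary tree has only `n - 3` internal edges), the longest
#' remaining edges whose removal still separates leaves are cut greedily
#' until `k` groups exist. Groups are labelled with Roman numerals I, II,
#' ... in decreasing size order, ties broken by smallest member label.
#'
#' @param tree an `nj_tree`.
#' @param k number of groups, `1 <= k <=` leaf count.
#' @return data.frame with columns `sample_id` and `group`; the indices of
#'   the removed edges are in attribute `cut_edges`.
#' @export
cut_groups <- function(tree, k) {
  n <- length(tree$tip.label)
  if (k < 1L || k > n) {
    snp_stop("snpkit_bad_k", sprintf("k must be between 1 and %d", n))
  }
  edge <- tree$edge
  ne <- nrow(edge)
  total <- n + tree$Nnode
  removed <- rep(FALSE, ne)
  comp_of <- function() {
    parent <- seq_len(total)
    find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
    for (e in which(!removed)) {
      a <- find(edge[e, 1L]); b <- find(edge[e, 2L])
      if (a != b) parent[a] <- b
    }
    vapply(seq_len(total), find, integer(1L))
  }
  n_tip_groups <- function(cmp) length(unique(cmp[seq_len(n)]))
  internal <- which(edge[, 2L] > n)
  ord <- internal[order(-tree$edge.length[internal], internal)]
  take <- utils::head(ord, k - 1L)
  removed[take] <- TRUE
  cmp <- comp_of()
  while (n_tip_groups(cmp) < k) {
    cand <- which(!removed)
    cand <- cand[order(-tree$edge.length[cand], cand)]
    advanced <- FALSE
    for (e in cand) {
      removed[e] <- TRUE
      cmp2 <- comp_of()
      if (n_tip_groups(cmp2) > n_tip_groups(cmp)) {
        cmp <- cmp2
        advanced <- TRUE
        break
      }
      removed[e] <- FALSE
    }
    if (!advanced) break  # cannot split further (all leaves isolated)
  }
  tip_comp <- cmp[seq_len(n)]
  comps <- unique(tip_comp)
  sizes <- vapply(comps, function(cc) sum(tip_comp == cc), integer(1L))
  min_lab <- vapply(comps, function(cc) min(tree$tip.label[tip_comp == cc]), character(1L))
  comps <- comps[order(-sizes, min_lab)]
  label <- as.character(utils::as.roman(seq_along(comps)))
  out <- data.frame(sample_id = tree$tip.label,
                    group = label[match(tip_comp, comps)],
                    stringsAsFactors = FALSE)
  attr(out, "cut_edges") <- which(removed)
  out
}
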