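# Independent tree machinery for checking neighbor joining: random additive
# trees, path-length distance matrices, exhaustive topology enumeration and
# a least-squares branch-length oracle. Deliberately naive; none of it
# touches the package's NJ code path.

# Random unrooted binary tree on n leaves (edge data.frame a, b, len), built
# by inserting each new leaf on a uniformly chosen edge.
random_additive_tree <- function(n, min_len = 0.05, max_len = 1) {
  stopifnot(n >= 3)
  edges <- data.frame(a = rep(n + 1L, 3L), b = 1:3)
  next_int <- n + 2L
  for (leaf in seq(4L, length.out = max(0L, n - 3L))) {
    e <- sample.int(nrow(edges), 1L)
    old <- edges[e, ]
    u <- next_int; next_int <- next_int + 1L
    edges <- rbind(edges[-e, ],
                   data.frame(a = c(old$a, u, u), b = c(u, old$b, leaf)))
  }
  edges$len <- stats::runif(nrow(edges), min_len, max_len)
  edges
}

# Path-length distances between leaves 1..n by breadth-first traversal.
tree_dist_matrix <- function(edges, n, labels = LETTERS[seq_len(n)]) {
  nodes <- max(edges$a, edges$b)
  adj <- vector("list", nodes)
  for (i in seq_len(nrow(edges))) {
    a <- edges$a[i]; b <- edges$b[i]; l <- edges$len[i]
    adj[[a]] <- rbind(adj[[a]], c(b, l))
    adj[[b]] <- rbind(adj[[b]], c(a, l))
  }
  D <- matrix(0, n, n, dimnames = list(labels, labels))
  for (s in seq_len(n)) {
    dist <- rep(NA_real_, nodes); dist[s] <- 0
    queue <- s
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      nb <- adj[[v]]
      for (r in seq_len(NROW(nb))) {
        w <- nb[r, 1L]
        if (is.na(dist[w])) { dist[w] <- dist[v] + nb[r, 2L]; queue <- c(queue, w) }
      }
    }
    D[s, ] <- dist[seq_len(n)]
  }
  D
}

# All unrooted binary topologies on leaves 1..n (1, 3, 15, 105 for n=3..6).
enumerate_topologies <- function(n) {
  trees <- list(list(edges = data.frame(a = rep(n + 1L, 3L), b = 1:3),
                     next_int = n + 2L))
  for (leaf in seq(4L, length.out = max(0L, n - 3L))) {
    acc <- list()
    for (t in trees) {
      for (e in seq_len(nrow(t$edges))) {
        old <- t$edges[e, ]
        u <- t$next_int
        acc[[length(acc) + 1L]] <- list(
          edges = rbind(t$edges[-e, ],
                        data.frame(a = c(old$a, u, u), b = c(u, old$b, leaf))),
          next_int = u + 1L)
      }
    }
    trees <- acc
  }
  lapply(trees, `[[`, "edges")
}

# Leaves on the b-side of each edge (edge frame trees).
.edge_leafsets <- function(edges, n) {
  nodes <- max(edges$a, edges$b)
  adj <- vector("list", nodes)
  for (i in seq_len(nrow(edges))) {
    adj[[edges$a[i]]] <- c(adj[[edges$a[i]]], i)
    adj[[edges$b[i]]] <- c(adj[[edges$b[i]]], i)
  }
  lapply(seq_len(nrow(edges)), function(i) {
    # collect leaves reachable from b without crossing edge i
    seen_edges <- i
    frontier <- edges$b[i]
    leaves <- integer(0)
    while (length(frontier)) {
      v <- frontier[1L]; frontier <- frontier[-1L]
      if (v <= n) leaves <- c(leaves, v)
      for (e in adj[[v]]) {
        if (e %in% seen_edges) next
        seen_edges <- c(seen_edges, e)
        frontier <- c(frontier, setdiff(c(edges$a[e], edges$b[e]), v))
      }
    }
    sort(leaves)
  })
}

# Canonical split label set: the side not containing the smallest label,
# as a comma-joined sorted string.
.canon_split <- function(side, all_labels) {
  if (min(all_labels) %in% side) side <- setdiff(all_labels, side)
  paste(sort(side), collapse = ",")
}

# Canonical non-trivial splits of an edge-frame topology.
topo_splits <- function(edges, n, labels = LETTERS[seq_len(n)]) {
  sets <- .edge_leafsets(edges, n)
  keep <- vapply(sets, function(s) length(s) >= 2L && length(s) <= n - 2L, logical(1L))
  sort(unique(vapply(sets[keep], function(s) .canon_split(labels[s], labels),
                     character(1L))))
}

# Canonical splits of any phylo-style tree (edge matrix, tips 1..n);
# recursion-based, so no assumption about edge ordering.
phylo_splits <- function(tree) {
  n <- length(tree$tip.label)
  kids <- split(tree$edge[, 2L], tree$edge[, 1L])
  desc <- function(v) {
    if (v <= n) return(v)
    unlist(lapply(kids[[as.character(v)]], desc))
  }
  internal_children <- tree$edge[, 2L][tree$edge[, 2L] > n]
  out <- vapply(internal_children, function(v) {
    s <- desc(v)
    if (length(s) < 2L || length(s) > n - 2L) return(NA_character_)
    .canon_split(tree$tip.label[s], tree$tip.label)
  }, character(1L))
  sort(unique(out[!is.na(out)]))
}
nj_splits <- phylo_splits

# Least-squares branch-length fit of a topology to a distance matrix;
# returns the residual sum of squares and fitted lengths.
ls_fit_topology <- function(edges, D) {
  n <- nrow(D)
  sets <- .edge_leafsets(edges, n)
  pairs <- which(upper.tri(D), arr.ind = TRUE)
  X <- vapply(sets, function(s) {
    (pairs[, 1L] %in% s) != (pairs[, 2L] %in% s)
  }, logical(nrow(pairs)))
  X <- matrix(as.numeric(X), nrow = nrow(pairs))
  y <- D[upper.tri(D)]
  fit <- stats::lsfit(X, y, intercept = FALSE)
  list(rss = sum(fit$residuals^2), lengths = fit$coefficients)
}

# Exhaustive oracle: the topology (split set) with minimal LS residual.
oracle_best_splits <- function(D) {
  n <- nrow(D)
  topos <- enumerate_topologies(n)
  rss <- vapply(topos, function(tp) ls_fit_topology(tp, D)$rss, numeric(1L))
  topo_splits(topos[[which.min(rss)]], n, labels = rownames(D))
}

# Leaf-to-leaf path lengths of an nj_tree, for additivity checks.
nj_path_dists <- function(tree) {
  n <- length(tree$tip.label)
  edges <- data.frame(a = tree$edge[, 1L], b = tree$edge[, 2L],
                      len = tree$edge.length)
  tree_dist_matrix(edges, n, labels = tree$tip.label)
}
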