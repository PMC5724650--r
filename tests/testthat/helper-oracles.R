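# Independent oracles used to verify the package's metric code. These are
# deliberately written against different machinery than the implementation:
# ancestor sets walked by hand, BFS path lengths from igraph, split sets
# from graph components after edge deletion.

sorted_c <- function(x) sort(x, method = "radix")

# Canonical tip-pair bookkeeping matching the package's contract.
pair_names <- function(labels) {
  lab <- sorted_c(labels)
  idx <- combn(length(lab), 2)
  paste(lab[idx[1, ]], lab[idx[2, ]], sep = "|")
}

# Parent map and per-node ancestor chains (node -> root), by raw edge walk.
oracle_ancestors <- function(tree) {
  n_node <- ape::Ntip(tree) + tree$Nnode
  parent <- integer(n_node)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  lapply(seq_len(n_node), function(v) {
    path <- integer(0)
    while (parent[v] != 0) { v <- parent[v]; path <- c(path, v) }
    path
  })
}

# Brute-force KC m/M entries via pairwise ancestor-set intersection:
# the MRCA is the shared ancestor with the longest own ancestor chain.
oracle_kc_mm <- function(tree) {
  lab <- sorted_c(tree$tip.label)
  tip_ids <- match(lab, tree$tip.label)
  anc <- oracle_ancestors(tree)
  elen <- tree$edge.length
  edge_child <- tree$edge[, 2]
  n <- length(lab)
  idx <- combn(n, 2)
  m <- M <- numeric(ncol(idx))
  for (p in seq_len(ncol(idx))) {
    i <- tip_ids[idx[1, p]]; j <- tip_ids[idx[2, p]]
    common <- intersect(anc[[i]], anc[[j]])
    depths <- lengths(anc)[common]
    mrca <- common[which.max(depths)]
    m[p] <- max(depths)  # edges from root to MRCA
    # sum edge lengths down the root -> MRCA chain
    chain <- c(rev(anc[[mrca]]), mrca)[-1]  # nodes below root on the chain
    M[p] <- sum(elen[match(chain, edge_child)])
  }
  pendant <- elen[match(tip_ids, edge_child)]
  list(m = c(m, rep(1, n)), M = c(M, pendant),
       names = c(pair_names(lab), lab))
}

# Tip-to-tip edge counts by breadth-first search on the undirected graph.
oracle_path_counts <- function(tree) {
  g <- igraph::graph_from_edgelist(tree$edge, directed = FALSE)
  lab <- sorted_c(tree$tip.label)
  tip_ids <- match(lab, tree$tip.label)
  d <- igraph::distances(g, v = tip_ids, to = tip_ids)
  idx <- combn(length(lab), 2)
  out <- d[cbind(idx[1, ], idx[2, ])]
  names(out) <- pair_names(lab)
  out
}

# Internal nodes on the path between two tips (igraph shortest path),
# combined child counts: independent route to Abouheif / sumDD entries.
oracle_dd <- function(tree, combine) {
  g <- igraph::graph_from_edgelist(tree$edge, directed = FALSE)
  n <- ape::Ntip(tree)
  dd <- tabulate(tree$edge[, 1], nbins = n + tree$Nnode)
  lab <- sorted_c(tree$tip.label)
  tip_ids <- match(lab, tree$tip.label)
  idx <- combn(length(lab), 2)
  out <- apply(idx, 2, function(p) {
    path <- as.integer(igraph::shortest_paths(
      g, from = tip_ids[p[1]], to = tip_ids[p[2]])$vpath[[1]])
    combine(dd[path[path > n]])
  })
  names(out) <- pair_names(lab)
  out
}

# Splits by deleting each edge and reading the component containing a
# reference set of tips; returns canonical keys (side with smallest label).
oracle_splits <- function(tree, nontrivial = TRUE, with_lengths = FALSE) {
  g <- igraph::graph_from_edgelist(tree$edge, directed = FALSE)
  n <- ape::Ntip(tree)
  lab_all <- sorted_c(tree$tip.label)
  keys <- character(nrow(tree$edge))
  for (e in seq_len(nrow(tree$edge))) {
    g2 <- igraph::delete_edges(g, igraph::get_edge_ids(g, tree$edge[e, ]))
    comp <- igraph::components(g2)$membership
    side <- tree$tip.label[comp[seq_len(n)] == comp[tree$edge[e, 2]]]
    if (!(lab_all[1] %in% side)) side <- setdiff(tree$tip.label, side)
    keys[e] <- paste(sorted_c(side), collapse = "|")
  }
  if (with_lengths) {
    agg <- rowsum(tree$edge.length, keys)
    return(stats::setNames(agg[, 1], rownames(agg)))
  }
  sizes <- lengths(strsplit(keys, "|", fixed = TRUE))
  if (nontrivial) keys <- keys[sizes >= 2 & sizes <= n - 2]
  unique(keys)
}

oracle_rf <- function(t1, t2) {
  s1 <- oracle_splits(t1); s2 <- oracle_splits(t2)
  length(setdiff(s1, s2)) + length(setdiff(s2, s1))
}

oracle_bs_dist <- function(t1, t2) {
  v1 <- oracle_splits(t1, with_lengths = TRUE)
  v2 <- oracle_splits(t2, with_lengths = TRUE)
  keys <- union(names(v1), names(v2))
  a <- ifelse(keys %in% names(v1), v1[keys], 0)
  b <- ifelse(keys %in% names(v2), v2[keys], 0)
  sqrt(sum((a - b)^2))
}

# Canonical topology string: children sorted recursively by their own
# canonical string; equal strings <=> isomorphic labelled rooted trees.
canonical_topology <- function(tree) {
  n <- ape::Ntip(tree)
  children <- split(tree$edge[, 2], tree$edge[, 1])
  rec <- function(v) {
    if (v <= n) return(tree$tip.label[v])
    paste0("(", paste(sorted_c(vapply(children[[as.character(v)]], rec,
                                      character(1))), collapse = ","), ")")
  }
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])[1]
  rec(root)
}

# Small random collections for property tests.
rand_collection <- function(n_trees, n_tips, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tree_collection(lapply(seq_len(n_trees), function(i) random_tree(n_tips)))
}
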