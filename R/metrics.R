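#' @name tree-vectors
#' @title Metric feature vectors for a single tree
#'
#' @description
#' Each supported tree metric maps a rooted, labelled tree to a vector of
#' labelled numbers; the distance between two trees is then a norm of the
#' difference between their vectors. Entries are always reported in the
#' canonical pair order: tip labels sorted lexicographically (C collation),
#' pairs `(i, j)` with `label_i < label_j` enumerated as
#' (1,2), (1,3), ..., (n-1,n), named `"label_i|label_j"`.
#'
#' * [kc_vector()] — the Kendall-Colijn construction. For each tip pair the
#'   topological entry `m` is the number of edges on the path from the root
#'   to the pair's MRCA, and the length entry `M` is the sum of branch
#'   lengths along that same path. Each vector is completed by `n` per-tip
#'   slots, equal to 1 in `m` and to the tip's pendant branch length in `M`.
#'   The returned vector is the blend `(1 - lambda) * m + lambda * M`, so
#'   `lambda = 0` compares pure topology and `lambda = 1` pure branch
#'   lengths. Requires a rooted tree (binary root); `lambda > 0` requires
#'   branch lengths.
#' * [path_vector()] — Steel-Penny path difference: entry for pair
#'   `(i, j)` is the number of edges on the path from tip `i` to tip `j`.
#' * [branch_score_vector()] — Kuhner-Felsenstein branch score: a sparse
#'   map from each bipartition (split) of the tip set to the length of the
#'   edge inducing it, on the unrooted tree (the two root-adjacent edges
#'   induce the same split and their lengths are summed). Distances treat
#'   splits absent from a tree as having length 0.
#' * [abouheif_vector()] — Abouheif's dissimilarity: entry for `(i, j)` is
#'   the product, over internal nodes on the path from `i` to `j`, of each
#'   node's number of direct descendants (children).
#' * [sum_dd_vector()] — as Abouheif but summing the child counts.
#'
#' @param tree a `phylo` object.
#' @param lambda blend weight in `[0, 1]` between topology (`m`) and branch
#'   lengths (`M`); default 0 (pure topology).
#' @return an object of class `tree_vector`: a list with `metric_id`,
#'   `lambda` (KC only, otherwise `NA`), `entries` (named numeric vector),
#'   `n_tips` and `tip_labels` (canonical order).
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
#' kc_vector(tr, lambda = 0)$entries   # (A|B, A|C, B|C, A, B, C)
#' path_vector(tr)$entries
NULL

new_tree_vector <- function(metric_id, entries, n_tips, tip_labels,
                            lambda = NA_real_) {
  structure(list(metric_id = metric_id, lambda = lambda,
                 entries = entries, n_tips = n_tips,
                 tip_labels = tip_labels),
            class = "tree_vector")
}

#' @export
print.tree_vector <- function(x, ...) {
  cat(sprintf("<tree_vector: %s%s, %d tips, %d entries>\n", x$metric_id,
              if (!is.na(x$lambda)) sprintf(" (lambda = %g)", x$lambda) else "",
              x$n_tips, length(x$entries)))
  print(utils::head(x$entries, 10))
  if (length(x$entries) > 10) cat("...\n")
  invisible(x)
}

# MRCA node-id matrix indexed in canonical label order.
mrca_canonical <- function(tree, labels) {
  ape::mrca(tree)[labels, labels, drop = FALSE]
}

#' @rdname tree-vectors
#' @export
kc_vector <- function(tree, lambda = 0) {
  stopifnot(inherits(tree, "phylo"))
  if (!is.numeric(lambda) || length(lambda) != 1L || is.na(lambda) ||
      lambda < 0 || lambda > 1)
    stop_precondition("lambda must be a single number in [0, 1]")
  if (!check_rooted(tree))
    stop_precondition(
      "the Kendall-Colijn vector needs a rooted tree (binary root); %s",
      "root the tree or use a split-based metric")
  if (lambda > 0 && !has_lengths(tree))
    stop_precondition(
      "lambda > 0 requires branch lengths, which this tree lacks")

  cp <- canonical_pairs(tree$tip.label)
  depths <- node_depths(tree)
  mr <- mrca_canonical(tree, cp$labels)
  mrca_ids <- mr[cbind(cp$i, cp$j)]
  tip_ids <- match(cp$labels, tree$tip.label)

  m <- c(depths$counts[mrca_ids], rep(1, length(cp$labels)))
  if (lambda > 0) {
    pendant <- tree$edge.length[match(tip_ids, tree$edge[, 2L])]
    M <- c(depths$lengths[mrca_ids], pendant)
    entries <- (1 - lambda) * m + lambda * M
  } else {
    entries <- m
  }
  names(entries) <- c(cp$names, cp$labels)
  new_tree_vector("kc", entries, length(cp$labels), cp$labels, lambda)
}

#' @rdname tree-vectors
#' @export
path_vector <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  cp <- canonical_pairs(tree$tip.label)
  depths <- node_depths(tree)
  mr <- mrca_canonical(tree, cp$labels)
  tip_ids <- match(cp$labels, tree$tip.label)
  di <- depths$counts[tip_ids[cp$i]]
  dj <- depths$counts[tip_ids[cp$j]]
  entries <- di + dj - 2 * depths$counts[mr[cbind(cp$i, cp$j)]]
  names(entries) <- cp$names
  new_tree_vector("path", entries, length(cp$labels), cp$labels)
}

# Tip-label sets below each edge's child, as a logical matrix over the
# canonical label order; rows follow tree$edge.
edge_clades <- function(tree) {
  tree <- stats::reorder(tree, "cladewise")
  n <- ape::Ntip(tree)
  n_node <- n + tree$Nnode
  lab <- sort_c(tree$tip.label)
  below <- matrix(FALSE, n_node, n)
  below[cbind(seq_len(n), match(tree$tip.label, lab))] <- TRUE
  e <- tree$edge
  for (i in rev(seq_len(nrow(e))))  # postorder accumulation
    below[e[i, 1L], ] <- below[e[i, 1L], ] | below[e[i, 2L], ]
  list(tree = tree, clades = below[e[, 2L], , drop = FALSE], labels = lab)
}

# Canonical split keys for every edge: the side of the bipartition holding
# the lexicographically smallest label (hence the smaller side in C
# collation), as "lab1|lab2|...". Root-adjacent edges on a rooted tree (and
# a pendant edge opposite them) share a key, i.e. the same unrooted split.
edge_split_keys <- function(ec) {
  cl <- ec$clades
  flip <- !cl[, 1L]  # side must contain the smallest canonical label
  cl[flip, ] <- !cl[flip, , drop = FALSE]
  apply(cl, 1L, function(r) paste(ec$labels[r], collapse = "|"))
}

# Non-trivial unrooted splits (both sides of size >= 2), unique keys.
nontrivial_splits <- function(tree) {
  ec <- edge_clades(tree)
  sz <- rowSums(ec$clades)
  n <- length(ec$labels)
  keys <- edge_split_keys(ec)
  unique(keys[sz >= 2 & sz <= n - 2])
}

#' @rdname tree-vectors
#' @export
branch_score_vector <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (!has_lengths(tree))
    stop_precondition("the branch score needs branch lengths")
  ec <- edge_clades(tree)
  keys <- edge_split_keys(ec)
  agg <- rowsum(ec$tree$edge.length, keys)  # merges root-adjacent edges
  entries <- agg[, 1L]
  names(entries) <- rownames(agg)
  new_tree_vector("bs", entries, length(ec$labels), ec$labels)
}

# Shared path-walk for the direct-descendant metrics: applies `combine`
# (prod or sum) to the child counts of the internal nodes on each tip-pair
# path (both MRCA-side ancestor chains, MRCA counted once).
dd_path_vector <- function(tree, combine, metric_id) {
  stopifnot(inherits(tree, "phylo"))
  cp <- canonical_pairs(tree$tip.label)
  n_node <- ape::Ntip(tree) + tree$Nnode
  dd <- tabulate(tree$edge[, 1L], nbins = n_node)
  parent <- integer(n_node)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  tip_ids <- match(cp$labels, tree$tip.label)
  anc <- lapply(tip_ids, function(t) {
    path <- integer(0)
    while (parent[t] != 0L) { t <- parent[t]; path <- c(path, t) }
    path
  })
  mr <- mrca_canonical(tree, cp$labels)
  entries <- mapply(function(i, j) {
    a <- mr[i, j]
    ai <- anc[[i]]; aj <- anc[[j]]
    nodes <- c(ai[seq_len(match(a, ai))],          # up to and incl. MRCA
               aj[seq_len(match(a, aj) - 1L)])     # up to, excl., MRCA
    combine(dd[nodes])
  }, cp$i, cp$j)
  names(entries) <- cp$names
  new_tree_vector(metric_id, entries, length(cp$labels), cp$labels)
}

#' @rdname tree-vectors
#' @export
abouheif_vector <- function(tree) dd_path_vector(tree, prod, "abouheif")

#' @rdname tree-vectors
#' @export
sum_dd_vector <- function(tree) dd_path_vector(tree, sum, "sumdd")
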