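# Generators of random trees and island-structured tree collections with
# known ground truth, emulating the structure of multi-method / posterior
# tree samples (several clusters of similar topologies) without external
# data. All randomness flows through R's global RNG; passing `seed` makes
# any generator call reproducible on its own.

maybe_seed <- function(seed) if (!is.null(seed)) set.seed(as.integer(seed))

#' Random rooted binary tree
#'
#' Uniform random sequential pair-joining (a coalescent-style topology):
#' starting from `n_tips` singleton lineages, two lineages chosen uniformly
#' at random are joined under a new parent until one tree remains. Branch
#' lengths are i.i.d. exponential with rate `rate`; tips are labelled
#' `"t1" ... "tn"`.
#'
#' @param n_tips number of tips (>= 2).
#' @param seed optional integer seed (`NULL` uses the current RNG state).
#' @param rate rate of the exponential branch-length distribution.
#' @return a rooted binary `phylo` with branch lengths.
#' @examples
#' random_tree(5, seed = 42)
#' @export
random_tree <- function(n_tips, seed = NULL, rate = 1) {
  if (n_tips < 2) stop_input("n_tips must be >= 2, got %d", n_tips)
  maybe_seed(seed)
  n <- as.integer(n_tips)
  n_edge <- 2L * n - 2L
  edge <- matrix(0L, n_edge, 2L)
  roots <- seq_len(n)          # current subtree roots
  row <- 0L
  for (j in seq_len(n - 1L)) {
    pick <- sample.int(length(roots), 2L)
    parent <- 2L * n - j       # last join gets id n + 1 (the root)
    edge[row + 1L, ] <- c(parent, roots[pick[1L]])
    edge[row + 2L, ] <- c(parent, roots[pick[2L]])
    row <- row + 2L
    roots <- c(roots[-pick], parent)
  }
  tree <- structure(
    list(edge = edge, edge.length = stats::rexp(n_edge, rate = rate),
         tip.label = paste0("t", seq_len(n)), Nnode = n - 1L),
    class = "phylo")
  stats::reorder(tree, "cladewise")
}

#' Perturb a tree by random NNI moves
#'
#' Applies `moves` nearest-neighbour-interchange moves, each across an
#' internal edge of the *unrooted* topology chosen uniformly at random.
#' The two edges incident to the (degree-2) root count as a single
#' internal edge: a move across it exchanges a subtree from one side of
#' the root with one from the other, while a move across an ordinary
#' internal edge exchanges the edge's "sibling" subtree with one of its
#' "nephews". Root-adjacent swaps are never performed as plain sibling
#' swaps, which would only re-root the tree without changing the unrooted
#' topology. Each move therefore replaces exactly one non-trivial split,
#' so a single move always has Robinson-Foulds distance 2 from its input
#' (later moves can revert earlier ones). Branch lengths of the edges
#' touched by a move are redrawn from the exponential distribution.
#'
#' @param tree a rooted binary `phylo` with >= 4 tips (no internal edge
#'   exists below that, so no NNI move is defined).
#' @param moves number of NNI moves (>= 0); 0 returns the tree unchanged.
#' @param seed optional integer seed.
#' @param rate rate of the exponential used to redraw affected lengths.
#' @return a rooted binary `phylo` on the same tip set.
#' @export
nni_perturb <- function(tree, moves, seed = NULL, rate = 1) {
  stopifnot(inherits(tree, "phylo"))
  if (moves < 0) stop_input("moves must be >= 0")
  if (!ape::is.binary(tree) || !check_rooted(tree))
    stop_input("nni_perturb needs a rooted binary tree")
  maybe_seed(seed)
  if (moves == 0) return(tree)
  n <- ape::Ntip(tree)
  if (n < 4) stop_input("NNI needs >= 4 tips, got %d", n)
  edge <- tree$edge
  len <- tree$edge.length
  root <- root_node(tree)
  for (mv in seq_len(moves)) {
    root_rows <- which(edge[, 1L] == root)
    # ordinary internal edges: internal child, non-root internal parent
    ordinary <- which(edge[, 2L] > n & edge[, 1L] != root)
    # the merged root edge is internal iff both root children are internal
    virtual_root <- all(edge[root_rows, 2L] > n)
    pick <- sample.int(length(ordinary) + virtual_root, 1L)
    if (pick <= length(ordinary)) {
      r <- ordinary[pick]
      u <- edge[r, 1L]; v <- edge[r, 2L]
      rows_v <- which(edge[, 1L] == v)              # children of v
      row_s <- setdiff(which(edge[, 1L] == u), r)   # v's sibling edge
      row_c <- rows_v[sample.int(2L, 1L)]           # nephew to swap
      edge[row_s, 1L] <- v
      edge[row_c, 1L] <- u
      touched <- c(r, row_s, row_c)
    } else {
      # swap one grandchild from each side of the root
      v <- edge[root_rows[1L], 2L]; s <- edge[root_rows[2L], 2L]
      row_cv <- which(edge[, 1L] == v)[sample.int(2L, 1L)]
      row_cs <- which(edge[, 1L] == s)[sample.int(2L, 1L)]
      edge[row_cv, 1L] <- s
      edge[row_cs, 1L] <- v
      touched <- c(root_rows, row_cv, row_cs)
    }
    if (!is.null(len)) len[touched] <- stats::rexp(length(touched),
                                                   rate = rate)
  }
  tree$edge <- edge
  tree$edge.length <- len
  attr(tree, "order") <- NULL
  stats::reorder(tree, "cladewise")
}

#' Simulate an island-structured tree collection with known ground truth
#'
#' Draws `n_islands` base trees (rejection-sampled until all pairwise
#' Robinson-Foulds distances are at least `min_rf`, so islands cannot
#' overlap by construction), then populates each island with
#' `trees_per_island` NNI-perturbed copies of its base tree
#' (`nni_moves` moves each). The defaults (4 islands of 50 trees on 20
#' tips, 2 NNI moves per tree, exponential(1) branch lengths) emulate a
#' posterior-style sample with four distinct clusters of topologies.
#'
#' @param n_tips tips per tree.
#' @param n_islands number of islands.
#' @param trees_per_island members per island.
#' @param nni_moves NNI moves applied to each member (island tightness).
#' @param rate exponential rate for branch lengths.
#' @param min_rf minimum pairwise RF distance between base trees.
#' @param seed optional integer seed.
#' @return list with `collection` (a [tree_collection()], trees named
#'   `"island<g>_tree<i>"`), `labels` (generating island of each tree) and
#'   `base_trees` (the unperturbed island centres).
#' @examples
#' sim <- make_islands(n_tips = 10, n_islands = 2, trees_per_island = 5,
#'                     seed = 7)
#' table(sim$labels)
#' @export
make_islands <- function(n_tips = 20, n_islands = 4, trees_per_island = 50,
                         nni_moves = 2, rate = 1, min_rf = 4, seed = NULL) {
  if (n_tips < 4 || n_islands < 1 || trees_per_island < 1 || nni_moves < 0)
    stop_input("invalid island specification")
  maybe_seed(seed)

  base <- list(random_tree(n_tips, rate = rate))
  attempts <- 0L
  while (length(base) < n_islands) {
    cand <- random_tree(n_tips, rate = rate)
    attempts <- attempts + 1L
    if (all(vapply(base, function(b) rf_distance(b, cand) >= min_rf,
                   logical(1)))) {
      base <- c(base, list(cand))
    } else if (attempts > 1000L) {
      stop_input(
        "could not draw %d base trees with pairwise RF >= %d in 1000 attempts",
        n_islands, min_rf)
    }
  }

  trees <- vector("list", n_islands * trees_per_island)
  labels <- integer(length(trees))
  nm <- character(length(trees))
  k <- 0L
  for (g in seq_len(n_islands)) {
    for (i in seq_len(trees_per_island)) {
      k <- k + 1L
      trees[[k]] <- nni_perturb(base[[g]], nni_moves, rate = rate)
      labels[k] <- g
      nm[k] <- sprintf("island%d_tree%d", g, i)
    }
  }
  list(collection = tree_collection(trees, names = nm),
       labels = labels,
       base_trees = structure(base, class = "multiPhylo"))
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items:
#' 1 for identical partitions (up to label renaming), about 0 for
#' independent ones. Used to score recovery of the generating islands.
#'
#' @param a,b vectors of cluster labels (equal length).
#' @return numeric scalar.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop_input("label vectors differ in length")
  tab <- table(a, b)
  n <- length(a)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  expected <- sum_a * sum_b / comb2(n)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)  # degenerate: both partitions trivial
  (sum_ij - expected) / (max_index - expected)
}
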