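# Internal helpers shared across modules.

# Locale-independent (C collation) sort, used everywhere a canonical label
# order or split key is needed so results do not depend on the session locale.
sort_c <- function(x) sort(x, method = "radix")

# Error constructors: CLI front end maps these condition classes to exit
# codes (input error -> 2, violated metric/pipeline precondition -> 3).
stop_input <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("treeislands_input_error", "treeislands_error")))
}

stop_precondition <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("treeislands_precondition_error", "treeislands_error")))
}

# Root node id of an ape phylo object (tips are 1..n, root is n + 1 once
# the tree is in cladewise order, but we locate it structurally).
root_node <- function(tree) {
  parents <- unique(tree$edge[, 1L])
  setdiff(parents, tree$edge[, 2L])[1L]
}

has_lengths <- function(tree) !is.null(tree$edge.length)

# Node depths from the root, as edge counts and as branch-length sums.
# Returns a list with $counts (integer) and, when lengths are present,
# $lengths (numeric); both indexed by node id.
node_depths <- function(tree) {
  n_node <- ape::Ntip(tree) + tree$Nnode
  cnt <- numeric(n_node)
  len <- if (has_lengths(tree)) numeric(n_node) else NULL
  # edges in cladewise order guarantee parents are visited before children
  tree <- stats::reorder(tree, "cladewise")
  e <- tree$edge
  for (i in seq_len(nrow(e))) {
    cnt[e[i, 2L]] <- cnt[e[i, 1L]] + 1
    if (!is.null(len)) len[e[i, 2L]] <- len[e[i, 1L]] + tree$edge.length[i]
  }
  list(counts = cnt, lengths = len)
}

# Canonical (sorted) tip labels and the matching canonical order of
# unordered tip pairs (1,2), (1,3), ..., (n-1,n) over that sorted list.
canonical_pairs <- function(labels) {
  lab <- sort_c(labels)
  n <- length(lab)
  if (n < 2) stop_input("at least 2 tips are required, got %d", n)
  idx <- utils::combn(n, 2L)
  list(labels = lab,
       i = idx[1L, ], j = idx[2L, ],
       names = paste(lab[idx[1L, ]], lab[idx[2L, ]], sep = "|"))
}
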