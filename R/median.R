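# Geometric median trees: per-island summaries that are always actual
# members of the sample (never a synthetic consensus), so they cannot
# exhibit implausible features such as negative branch lengths.

#' Geometric median tree(s) of each island
#'
#' For every island, the Kendall-Colijn lambda-vectors of the member trees
#' are averaged and the median tree(s) are the member(s) whose vector lies
#' closest (Euclidean distance) to that mean vector. The mean vector
#' itself generally corresponds to no tree and is never converted back to
#' one. All co-minimal members are reported as ties (distances within a
#' relative tolerance of `1e-9` of the minimum count as tied).
#'
#' @param coll a [tree_collection()]; trees must be rooted (binary root),
#'   with branch lengths if `lambda > 0`.
#' @param partition an `island_partition` from [find_islands()], or `NULL`
#'   to treat the whole collection as one island.
#' @param lambda KC blend weight in `[0, 1]`.
#' @return a list of class `median_result_list` with one `median_result`
#'   per island: `island_id`, `member_indices` (positions in the
#'   collection), `median_indices` (subset of members attaining the
#'   minimum, all ties), `mean_vector` (named numeric, KC vector layout)
#'   and `distances_to_mean` (named by tree, same order as members).
#' @examples
#' sim <- make_islands(n_tips = 10, n_islands = 2, trees_per_island = 6,
#'                     seed = 1)
#' emb <- tree_pcoa(distance_matrix(sim$collection, "kc"), n_axes = 2)
#' part <- find_islands(emb, k = 2)
#' med <- median_tree(sim$collection, part)
#' med[[1]]$median_indices
#' @export
median_tree <- function(coll, partition = NULL, lambda = 0) {
  stopifnot(inherits(coll, "tree_collection"))
  n <- length(coll$trees)
  if (is.null(partition)) {
    labels <- rep(1L, n)
  } else {
    stopifnot(inherits(partition, "island_partition"))
    if (length(partition$labels) != n)
      stop_input("partition covers %d trees but the collection has %d",
                 length(partition$labels), n)
    labels <- as.integer(partition$labels)
  }

  vecs <- do.call(rbind, lapply(seq_len(n), function(k) {
    tryCatch(kc_vector(coll$trees[[k]], lambda = lambda)$entries,
             treeislands_precondition_error = function(e)
               stop_precondition("tree %d: %s", k, conditionMessage(e)))
  }))

  out <- lapply(sort(unique(labels)), function(g) {
    members <- which(labels == g)
    mean_vec <- colMeans(vecs[members, , drop = FALSE])
    d <- sqrt(colSums((t(vecs[members, , drop = FALSE]) - mean_vec)^2))
    names(d) <- coll$names[members]
    tol <- 1e-9 * max(min(d), 1)
    medians <- members[d <= min(d) + tol]
    structure(list(island_id = g, member_indices = members,
                   median_indices = medians, mean_vector = mean_vec,
                   distances_to_mean = d),
              class = "median_result")
  })
  class(out) <- "median_result_list"
  out
}

#' @export
print.median_result <- function(x, ...) {
  cat(sprintf("<median_result: island %d, %d members, median tree(s): %s>\n",
              x$island_id, length(x$member_indices),
              paste(x$median_indices, collapse = ", ")))
  invisible(x)
}

#' @export
print.median_result_list <- function(x, ...) {
  for (r in x) print(r)
  invisible(x)
}

#' Write one median tree per island
#'
#' Computes [median_tree()] and writes the median of each island (the
#' lowest-index member on ties) to a Newick file, named
#' `island_<id>_median`. The written trees are verbatim members of the
#' input collection. Optionally writes the per-tree distances to the
#' island mean vector as TSV.
#'
#' @inheritParams median_tree
#' @param path output Newick file.
#' @param distances_path optional TSV (columns `tree`, `island`,
#'   `distance_to_mean`).
#' @return the `median_result_list`, invisibly.
#' @export
summarise_islands <- function(coll, partition = NULL, lambda = 0, path,
                              distances_path = NULL) {
  res <- median_tree(coll, partition, lambda)
  med_trees <- lapply(res, function(r) coll$trees[[min(r$median_indices)]])
  names(med_trees) <- vapply(res, function(r)
    sprintf("island_%d_median", r$island_id), character(1))
  class(med_trees) <- "multiPhylo"
  ape::write.tree(med_trees, file = path, digits = 12, tree.names = TRUE)
  if (!is.null(distances_path)) {
    df <- do.call(rbind, lapply(res, function(r)
      data.frame(tree = names(r$distances_to_mean),
                 island = r$island_id,
                 distance_to_mean = unname(r$distances_to_mean))))
    utils::write.table(df, distances_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(res)
}
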