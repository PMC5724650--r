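# Detection of "tree islands": clusters of mutually similar topologies in
# a landscape of phylogenies, by agglomerative hierarchical clustering.

linkage_to_hclust <- function(linkage) {
  switch(linkage,
         single = "single", complete = "complete",
         upgma = "average", ward = "ward.D2",
         stop_input("unknown linkage '%s'", linkage))
}

# Dissimilarity used for clustering: Euclidean distances over the retained
# landscape axes ("projected distances"), or the raw tree distances.
island_dist <- function(x) {
  if (inherits(x, "tree_landscape")) {
    list(d = stats::dist(x$coordinates), basis = "mds_coordinates",
         n_axes = x$n_axes_retained, names = rownames(x$coordinates))
  } else {
    dm <- coerce_distmat(x)
    list(d = stats::as.dist(dm$values), basis = "raw_distances",
         n_axes = NA_integer_, names = dm$tree_names)
  }
}

#' Identify tree islands by hierarchical clustering
#'
#' Cuts an agglomerative clustering (single, complete, UPGMA/average, or
#' Ward's criterion on squared Euclidean distances, "ward.D2") into exactly
#' `k` groups. The default input is a landscape embedding, so trees are
#' clustered on their projected (MDS) distances; passing a `tree_distmat`
#' clusters on the raw tree distances instead.
#'
#' @param x a `tree_landscape` (clusters on retained MDS axes) or a
#'   `tree_distmat` (clusters on raw distances).
#' @param k number of islands, `1 <= k <= n_trees`.
#' @param linkage one of `"ward"` (default), `"single"`, `"complete"`,
#'   `"upgma"`.
#' @return an object of class `island_partition`: list with `labels`
#'   (named integer vector in `1..k`, every label used), `k`, `linkage`,
#'   `basis` (`"mds_coordinates"` or `"raw_distances"`) and `n_axes_used`.
#' @examples
#' sim <- make_islands(n_tips = 10, n_islands = 2, trees_per_island = 8,
#'                     seed = 1)
#' emb <- tree_pcoa(distance_matrix(sim$collection, "kc"), n_axes = 2)
#' part <- find_islands(emb, k = 2)
#' table(part$labels, sim$labels)
#' @export
find_islands <- function(x, k, linkage = c("ward", "single", "complete",
                                           "upgma")) {
  linkage <- match.arg(linkage)
  inp <- island_dist(x)
  n <- length(inp$names)
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k > n)
    stop_precondition("k must be in [1, n_trees] = [1, %d]", n)
  hc <- stats::hclust(inp$d, method = linkage_to_hclust(linkage))
  labels <- stats::cutree(hc, k = as.integer(k))
  names(labels) <- inp$names
  structure(list(labels = labels, k = as.integer(k), linkage = linkage,
                 basis = inp$basis, n_axes_used = inp$n_axes,
                 heights = hc$height),
            class = "island_partition")
}

#' @export
print.island_partition <- function(x, ...) {
  cat(sprintf("<island_partition: %d trees in %d islands (%s linkage, on %s)>\n",
              length(x$labels), x$k, x$linkage, x$basis))
  print(table(island = x$labels))
  invisible(x)
}

#' Agglomeration heights of the island dendrogram
#'
#' The `n_trees - 1` merge heights, in merge order (nondecreasing for
#' single, complete, UPGMA and Ward linkage on a metric input). A large gap
#' between the last and second-to-last merge suggests well-separated
#' islands and helps choose `k` by inspection.
#'
#' @inheritParams find_islands
#' @return numeric vector of `n_trees - 1` heights.
#' @export
cut_heights <- function(x, linkage = c("ward", "single", "complete",
                                       "upgma")) {
  linkage <- match.arg(linkage)
  inp <- island_dist(x)
  stats::hclust(inp$d, method = linkage_to_hclust(linkage))$height
}

#' Mean silhouette width for a range of island counts
#'
#' A diagnostic helper for choosing `k` by inspection: larger mean
#' silhouette widths indicate better-separated islands. Never applied
#' automatically; `k` remains a user decision.
#'
#' @inheritParams find_islands
#' @param ks integer vector of candidate island counts (each in
#'   `[2, n_trees - 1]`).
#' @return named numeric vector of mean silhouette widths, one per `k`.
#' @export
silhouette_widths <- function(x, ks = 2:6, linkage = c("ward", "single",
                                                       "complete", "upgma")) {
  if (!requireNamespace("cluster", quietly = TRUE))
    stop_input("the 'cluster' package is required for silhouette_widths()")
  linkage <- match.arg(linkage)
  inp <- island_dist(x)
  n <- length(inp$names)
  ks <- ks[ks >= 2 & ks <= n - 1]
  hc <- stats::hclust(inp$d, method = linkage_to_hclust(linkage))
  out <- vapply(ks, function(k) {
    sil <- cluster::silhouette(stats::cutree(hc, k = k), inp$d)
    mean(sil[, "sil_width"])
  }, numeric(1))
  names(out) <- ks
  out
}

#' Write island assignments as TSV (+ JSON metadata)
#'
#' @param part an `island_partition`.
#' @param path output TSV (columns `tree`, `island`).
#' @param meta_path optional JSON sidecar recording linkage, k and basis.
#' @return `path`, invisibly.
#' @export
write_islands <- function(part, path, meta_path = NULL) {
  stopifnot(inherits(part, "island_partition"))
  utils::write.table(
    data.frame(tree = names(part$labels), island = unname(part$labels)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(meta_path))
    jsonlite::write_json(
      list(linkage = part$linkage, k = part$k, basis = part$basis,
           n_axes_used = part$n_axes_used),
      meta_path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
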