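#' Pairwise tree distances for a collection
#'
#' Computes the symmetric matrix of pairwise distances between all trees in
#' a collection under one of the supported metrics:
#'
#' * `"kc"` — Euclidean distance between Kendall-Colijn lambda-blended
#'   vectors ([kc_vector()]); `lambda = 0` (default) compares topology only.
#' * `"rf"` — Robinson-Foulds distance: the size of the symmetric
#'   difference of the two trees' non-trivial unrooted split sets (raw
#'   count, not normalised or halved).
#' * `"path"` / `"path_l1"` — Steel-Penny path difference: l2 (resp. the
#'   Williams-Clifford l1) norm of the difference of tip-to-tip edge-count
#'   vectors ([path_vector()]).
#' * `"bs"` — Kuhner-Felsenstein branch score: square root of the sum of
#'   squared branch-length differences over the union of splits, absent
#'   splits contributing length 0 ([branch_score_vector()]).
#' * `"abouheif"` / `"sumdd"` — Euclidean distance between direct-
#'   descendant path vectors ([abouheif_vector()], [sum_dd_vector()]).
#'
#' @param coll a [tree_collection()].
#' @param metric one of `"kc"`, `"rf"`, `"path"`, `"path_l1"`, `"bs"`,
#'   `"abouheif"`, `"sumdd"`.
#' @param lambda KC blend weight in `[0, 1]`; ignored by other metrics.
#' @return an object of class `tree_distmat`: list with `values` (dense
#'   symmetric numeric matrix, zero diagonal, tree names as dimnames),
#'   `metric_id`, `lambda` (`NA` unless KC) and `tree_names`.
#' @examples
#' sim <- make_islands(n_tips = 10, n_islands = 2, trees_per_island = 5,
#'                     seed = 1)
#' dm <- distance_matrix(sim$collection, metric = "kc", lambda = 0)
#' round(as.matrix(dm)[1:4, 1:4], 2)
#' @export
distance_matrix <- function(coll,
                            metric = c("kc", "rf", "path", "path_l1", "bs",
                                       "abouheif", "sumdd"),
                            lambda = 0) {
  stopifnot(inherits(coll, "tree_collection"))
  metric <- match.arg(metric)

  per_tree <- function(fun) {
    lapply(seq_along(coll$trees), function(k) {
      tryCatch(fun(coll$trees[[k]]),
               treeislands_precondition_error = function(e)
                 stop_precondition("tree %d: %s", k, conditionMessage(e)))
    })
  }
  stack <- function(vecs) {
    do.call(rbind, lapply(vecs, function(v) v$entries))
  }
  sparse_stack <- function(vecs) {
    keys <- sort_c(unique(unlist(lapply(vecs, function(v) names(v$entries)))))
    X <- matrix(0, length(vecs), length(keys), dimnames = list(NULL, keys))
    for (k in seq_along(vecs)) X[k, names(vecs[[k]]$entries)] <- vecs[[k]]$entries
    X
  }

  D <- switch(metric,
    kc = as.matrix(stats::dist(stack(per_tree(function(t)
           kc_vector(t, lambda = lambda))))),
    path = as.matrix(stats::dist(stack(per_tree(path_vector)))),
    path_l1 = as.matrix(stats::dist(stack(per_tree(path_vector)),
                                    method = "manhattan")),
    abouheif = as.matrix(stats::dist(stack(per_tree(abouheif_vector)))),
    sumdd = as.matrix(stats::dist(stack(per_tree(sum_dd_vector)))),
    bs = as.matrix(stats::dist(sparse_stack(per_tree(branch_score_vector)))),
    rf = {
      splits <- per_tree(function(t) nontrivial_splits(t))
      keys <- unique(unlist(splits))
      X <- matrix(0, length(splits), length(keys),
                  dimnames = list(NULL, keys))
      for (k in seq_along(splits)) X[k, splits[[k]]] <- 1
      # symmetric split-set difference == Manhattan distance on incidence
      as.matrix(stats::dist(X, method = "manhattan"))
    })

  dimnames(D) <- list(coll$names, coll$names)
  diag(D) <- 0
  structure(list(values = D, metric_id = metric,
                 lambda = if (metric == "kc") lambda else NA_real_,
                 tree_names = coll$names),
            class = "tree_distmat")
}

#' Robinson-Foulds distance between two trees
#'
#' The raw symmetric-difference count of non-trivial bipartitions on the
#' unrooted split sets of the two trees (trivial single-tip splits are
#' excluded; rooted input is unrooted implicitly). For two binary trees on
#' `n` tips the value is an even integer bounded by `2(n - 3)`.
#'
#' @param t1,t2 `phylo` trees on identical tip-label sets.
#' @return nonnegative integer.
#' @examples
#' a <- ape::read.tree(text = "((A,B),(C,D));")
#' b <- ape::read.tree(text = "((A,C),(B,D));")
#' rf_distance(a, b)  # 2
#' @export
rf_distance <- function(t1, t2) {
  stopifnot(inherits(t1, "phylo"), inherits(t2, "phylo"))
  if (!identical(sort_c(t1$tip.label), sort_c(t2$tip.label)))
    stop_input("trees have different tip-label sets; symmetric difference: {%s}",
               paste(sort_c(c(setdiff(t1$tip.label, t2$tip.label),
                              setdiff(t2$tip.label, t1$tip.label))),
                     collapse = ", "))
  s1 <- nontrivial_splits(t1)
  s2 <- nontrivial_splits(t2)
  length(setdiff(s1, s2)) + length(setdiff(s2, s1))
}

#' @export
as.matrix.tree_distmat <- function(x, ...) x$values

#' @export
as.dist.tree_distmat <- function(m, diag = FALSE, upper = FALSE)
  stats::as.dist(m$values, diag = diag, upper = upper)

#' @export
print.tree_distmat <- function(x, ...) {
  cat(sprintf("<tree_distmat: %d trees, metric = %s%s>\n",
              nrow(x$values), x$metric_id,
              if (!is.na(x$lambda)) sprintf(" (lambda = %g)", x$lambda) else ""))
  cat(sprintf("  distance range: [%g, %g]\n",
              min(x$values[upper.tri(x$values)]),
              max(x$values[upper.tri(x$values)])))
  invisible(x)
}

#' Write a distance matrix to disk
#'
#' @param dm a `tree_distmat`.
#' @param path output file.
#' @param format `"tsv"` (header row and column of tree names) or
#'   `"phylip"` (square PHYLIP distance matrix).
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(dm, path, format = c("tsv", "phylip")) {
  stopifnot(inherits(dm, "tree_distmat"))
  format <- match.arg(format)
  if (format == "tsv") {
    df <- data.frame(tree = rownames(dm$values), dm$values,
                     check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("%5d", nrow(dm$values)), con)
    for (i in seq_len(nrow(dm$values)))
      writeLines(paste(c(sprintf("%-10s", rownames(dm$values)[i]),
                         sprintf("%.9g", dm$values[i, ])), collapse = "  "),
                 con)
  }
  invisible(path)
}
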