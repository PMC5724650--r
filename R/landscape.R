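# Metric MDS (PCoA) of tree distance matrices, with Cailliez correction
# for non-Euclidean metrics such as Robinson-Foulds.

# Gower-centred inner-product matrix B = -1/2 J D^2 J.
gower_center <- function(D) {
  A <- -0.5 * D * D
  n <- nrow(A)
  J <- diag(n) - matrix(1 / n, n, n)
  J %*% A %*% J
}

coerce_distmat <- function(dm) {
  if (inherits(dm, "tree_distmat")) return(dm)
  D <- as.matrix(dm)
  structure(list(values = D, metric_id = "unknown", lambda = NA_real_,
                 tree_names = rownames(D) %||% paste0("tree_", seq_len(nrow(D)))),
            class = "tree_distmat")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Cailliez correction of a distance matrix
#'
#' Finds the smallest constant `c` such that adding `c` to every
#' off-diagonal entry yields a Euclidean distance matrix, i.e. one whose
#' Gower-centred form has no negative eigenvalue. `c` is the largest real
#' eigenvalue of the standard `2n x 2n` companion matrix of the Cailliez
#' construction; when the input is already Euclidean (most negative centred
#' eigenvalue above `-tol` times the largest), `c = 0` and the matrix is
#' returned unchanged.
#'
#' @param dm a `tree_distmat` (or plain symmetric matrix).
#' @param tol relative tolerance on negative centred eigenvalues below
#'   which the matrix is deemed Euclidean already.
#' @return list with `dm` (corrected `tree_distmat`) and `constant`.
#' @export
cailliez <- function(dm, tol = 1e-8) {
  dm <- coerce_distmat(dm)
  D <- dm$values
  n <- nrow(D)
  ev <- eigen(gower_center(D), symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) >= -tol * max(max(ev), .Machine$double.eps))
    return(list(dm = dm, constant = 0))

  delta1 <- gower_center(D)
  A2 <- -0.5 * D
  J <- diag(n) - matrix(1 / n, n, n)
  delta2 <- J %*% A2 %*% J
  companion <- rbind(cbind(matrix(0, n, n), 2 * delta1),
                     cbind(-diag(n), -4 * delta2))
  lam <- eigen(companion, only.values = TRUE)$values
  cc <- max(Re(lam[abs(Im(lam)) < 1e-8 * (1 + max(abs(Re(lam))))]))
  Dc <- D + cc
  diag(Dc) <- 0
  dm$values <- Dc
  list(dm = dm, constant = cc)
}

#' Project a tree distance matrix into Euclidean landscape coordinates
#'
#' Classical metric multidimensional scaling (principal coordinate
#' analysis): the squared-distance matrix is Gower double-centred, the
#' centred matrix is eigendecomposed, and coordinates are eigenvectors
#' scaled by the square roots of their positive eigenvalues, ordered by
#' descending eigenvalue. Non-Euclidean inputs (negative centred
#' eigenvalues beyond tolerance) are first made Euclidean by the
#' [cailliez()] additive correction when `correction = "auto"` (the
#' default) or `"always"`; the constant used is recorded in the result
#' (0 when no correction was needed).
#'
#' Axis signs are made deterministic by forcing the largest-magnitude
#' coordinate on each axis to be positive.
#'
#' @param dm a `tree_distmat`.
#' @param n_axes number of axes to retain (default 3); silently truncated,
#'   with a warning, to the number of positive eigenvalues.
#' @param correction `"auto"`, `"never"` or `"always"`.
#' @param tol relative tolerance used both to detect non-Euclidean input
#'   and to zero out eigenvalues within `+/- tol * max` of 0.
#' @return an object of class `tree_landscape`: list with `coordinates`
#'   (`n_trees x n_axes_retained`, columns `Axis1`, `Axis2`, ...),
#'   `eigenvalues` (full spectrum, descending), `n_axes_retained`,
#'   `cailliez_constant` and `metric_id`.
#' @examples
#' sim <- make_islands(n_tips = 10, n_islands = 2, trees_per_island = 5,
#'                     seed = 1)
#' emb <- tree_pcoa(distance_matrix(sim$collection, "kc"), n_axes = 2)
#' head(emb$coordinates)
#' @export
tree_pcoa <- function(dm, n_axes = 3,
                      correction = c("auto", "never", "always"),
                      tol = 1e-8) {
  dm <- coerce_distmat(dm)
  correction <- match.arg(correction)
  n <- nrow(dm$values)
  if (n < 2) stop_precondition("need at least 2 trees to build a landscape")
  if (n_axes < 1 || n_axes > n - 1)
    stop_precondition("n_axes must be in [1, n_trees - 1] = [1, %d]", n - 1)

  cc <- 0
  if (correction != "never") {
    corr <- cailliez(dm, tol = tol)
    if (correction == "always" || corr$constant > 0) {
      dm <- corr$dm
      cc <- corr$constant
    }
  }

  eig <- eigen(gower_center(dm$values), symmetric = TRUE)
  vals <- eig$values
  # eigenvalues numerically indistinguishable from 0 are treated as 0
  zero_tol <- tol * max(abs(vals), .Machine$double.eps)
  vals[abs(vals) < zero_tol] <- 0
  n_pos <- sum(vals > 0)

  keep <- min(n_axes, n_pos)
  if (keep < n_axes)
    warning(sprintf(
      "only %d positive eigenvalues; retaining %d axes instead of %d",
      n_pos, keep, n_axes))
  if (keep == 0) {
    coords <- matrix(0, n, 1, dimnames = list(dm$tree_names, "Axis1"))
    keep <- 1L
  } else {
    coords <- eig$vectors[, seq_len(keep), drop = FALSE] %*%
      diag(sqrt(vals[seq_len(keep)]), keep)
    # deterministic axis orientation
    for (a in seq_len(keep)) {
      s <- sign(coords[which.max(abs(coords[, a])), a])
      if (s < 0) coords[, a] <- -coords[, a]
    }
    dimnames(coords) <- list(dm$tree_names, paste0("Axis", seq_len(keep)))
  }

  structure(list(coordinates = coords, eigenvalues = vals,
                 n_axes_retained = ncol(coords),
                 cailliez_constant = cc, metric_id = dm$metric_id),
            class = "tree_landscape")
}

#' @export
print.tree_landscape <- function(x, ...) {
  cat(sprintf("<tree_landscape: %d trees, %d axes (metric = %s)>\n",
              nrow(x$coordinates), x$n_axes_retained, x$metric_id))
  pr <- scree(x)
  cat("  variance represented by retained axes:",
      paste(sprintf("%.1f%%", 100 * utils::head(pr, x$n_axes_retained)),
            collapse = ", "), "\n")
  if (x$cailliez_constant > 0)
    cat(sprintf("  Cailliez constant: %g\n", x$cailliez_constant))
  invisible(x)
}

#' Scree proportions of a landscape embedding
#'
#' Proportions of each positive eigenvalue relative to the sum of positive
#' eigenvalues, in descending order; sums to 1. Used to judge how many
#' axes carry structured variation.
#'
#' @param emb a `tree_landscape` from [tree_pcoa()].
#' @return numeric vector of proportions (one per positive eigenvalue).
#' @export
scree <- function(emb) {
  stopifnot(inherits(emb, "tree_landscape"))
  pos <- emb$eigenvalues[emb$eigenvalues > 0]
  if (length(pos) == 0) return(numeric(0))
  pos / sum(pos)
}

#' Write landscape coordinates, eigenvalues and scree proportions as TSV
#'
#' @param emb a `tree_landscape`.
#' @param coords_path,eigen_path,meta_path output files (TSV, TSV, JSON);
#'   any may be `NULL` to skip.
#' @return invisibly, the paths written.
#' @export
write_landscape <- function(emb, coords_path = NULL, eigen_path = NULL,
                            meta_path = NULL) {
  stopifnot(inherits(emb, "tree_landscape"))
  if (!is.null(coords_path)) {
    df <- data.frame(tree = rownames(emb$coordinates), emb$coordinates,
                     check.names = FALSE)
    utils::write.table(df, coords_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(eigen_path)) {
    pr <- scree(emb)
    df <- data.frame(axis = seq_along(emb$eigenvalues),
                     eigenvalue = emb$eigenvalues,
                     scree_proportion = c(pr, rep(NA_real_,
                       length(emb$eigenvalues) - length(pr))))
    utils::write.table(df, eigen_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(meta_path)) {
    jsonlite::write_json(
      list(metric_id = emb$metric_id,
           n_axes_retained = emb$n_axes_retained,
           cailliez_constant = emb$cailliez_constant),
      meta_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(c(coords_path, eigen_path, meta_path))
}
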