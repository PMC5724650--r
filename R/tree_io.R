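#' Build a validated tree collection
#'
#' A tree collection is an ordered set of rooted, labelled trees describing
#' the same taxa: every tree must carry exactly the same set of unique,
#' non-empty tip labels. All vector constructions downstream use the
#' canonical (lexicographically sorted, C collation) tip order stored in the
#' collection, so distances never depend on the order tips appear in a file.
#'
#' @param trees a `multiPhylo` object, a list of `phylo` objects, or a
#'   single `phylo`.
#' @param names optional character vector of per-tree identifiers; defaults
#'   to any names carried by `trees`, else `"tree_1"`, `"tree_2"`, ...
#' @return an object of class `tree_collection` with elements `trees`
#'   (`multiPhylo`), `names`, `canonical_labels` (sorted tip labels) and
#'   `has_lengths` (logical per tree; trees without branch lengths are only
#'   usable with topology-only metrics, e.g. the KC metric at lambda = 0).
#' @examples
#' tc <- tree_collection(ape::rmtree(5, 8))
#' tc
#' @export
tree_collection <- function(trees, names = NULL) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  trees <- unclass(trees)
  if (length(trees) == 0L) stop_input("empty tree collection")
  if (!all(vapply(trees, inherits, logical(1), "phylo")))
    stop_input("all elements must be 'phylo' trees")

  if (is.null(names)) names <- base::names(trees)
  if (is.null(names)) names <- paste0("tree_", seq_along(trees))
  if (length(names) != length(trees))
    stop_input("'names' must have one entry per tree (%d trees, %d names)",
               length(trees), length(names))

  ref <- trees[[1L]]$tip.label
  if (anyDuplicated(ref) || any(!nzchar(ref)))
    stop_input("tree 1 has duplicated or empty tip labels")
  ref_sorted <- sort_c(ref)
  for (k in seq_along(trees)) {
    lab <- trees[[k]]$tip.label
    if (anyDuplicated(lab) || any(!nzchar(lab)))
      stop_input("tree %d has duplicated or empty tip labels", k)
    if (!identical(sort_c(lab), ref_sorted)) {
      diff <- sort_c(c(setdiff(lab, ref), setdiff(ref, lab)))
      stop_input(
        "tree %d has a different tip-label set; symmetric difference: {%s}",
        k, paste(diff, collapse = ", "))
    }
    el <- trees[[k]]$edge.length
    if (!is.null(el) && any(el < 0))
      stop_input("tree %d has negative branch lengths", k)
  }

  structure(
    list(trees = structure(trees, class = "multiPhylo"),
         names = as.character(names),
         canonical_labels = ref_sorted,
         has_lengths = vapply(trees, has_lengths, logical(1))),
    class = "tree_collection")
}

#' @export
print.tree_collection <- function(x, ...) {
  cat(sprintf("<tree_collection: %d trees, %d tips>\n",
              length(x$trees), length(x$canonical_labels)))
  cat("  tips:", paste(utils::head(x$canonical_labels, 6), collapse = ", "),
      if (length(x$canonical_labels) > 6) "..." else "", "\n")
  cat(sprintf("  branch lengths present: %d/%d trees\n",
              sum(x$has_lengths), length(x$trees)))
  invisible(x)
}

#' @export
length.tree_collection <- function(x) length(x$trees)

#' Read a collection of trees from Newick or NEXUS
#'
#' Reads one or more trees from a multi-tree Newick file (one tree per
#' semicolon, possibly several per line) or a NEXUS file with a TREES block
#' (TRANSLATE tables are resolved to the original labels before
#' validation). Quoted labels, internal node labels (treated as support
#' annotations and ignored by all metrics) and exponent notation in branch
#' lengths are accepted.
#'
#' @param path file to read.
#' @param format `"auto"` (sniff for a `#NEXUS` header), `"newick"` or
#'   `"nexus"`.
#' @return a [tree_collection()].
#' @export
read_trees <- function(path, format = c("auto", "newick", "nexus")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_input("file not found: %s", path)
  if (format == "auto") {
    head_line <- toupper(trimws(readLines(path, n = 1L, warn = FALSE)))
    format <- if (length(head_line) && startsWith(head_line, "#NEXUS"))
      "nexus" else "newick"
  }
  trees <- tryCatch(
    if (format == "nexus") ape::read.nexus(path) else ape::read.tree(path),
    error = function(e) stop_input("could not parse %s as %s: %s",
                                   path, format, conditionMessage(e)))
  if (is.null(trees)) stop_input("no trees found in %s", path)
  if (inherits(trees, "phylo")) trees <- c(trees)  # promote to multiPhylo
  if (!is.null(attr(trees, "TipLabel")))           # expand compressed labels
    trees <- ape::.uncompressTipLabel(trees)
  tree_collection(trees)
}

#' Write a tree collection as Newick
#'
#' One tree per line; re-reading the file yields trees with identical
#' topology and labels, and branch lengths equal to printed precision.
#' The default 12 significant digits keep distance matrices computed
#' before and after a round-trip equal entrywise to better than 1e-9.
#'
#' @param coll a [tree_collection()].
#' @param path output file.
#' @param digits significant digits for branch lengths.
#' @return `path`, invisibly.
#' @export
write_trees <- function(coll, path, digits = 12) {
  stopifnot(inherits(coll, "tree_collection"))
  out <- vapply(coll$trees, ape::write.tree, character(1), digits = digits)
  ok <- tryCatch({ writeLines(out, path); TRUE },
                 error = function(e) FALSE)
  if (!ok) stop_input("cannot write to %s", path)
  invisible(path)
}

#' Is a tree rooted through a binary root?
#'
#' `TRUE` iff the root node has out-degree exactly 2. A basal trifurcation
#' (e.g. `"(A,B,C);"`) is reported as unrooted: such trees are acceptable
#' for split-based metrics (RF, branch score) and tip-path metrics, but the
#' Kendall-Colijn vector needs a well-defined root-to-MRCA path, so KC
#' construction rejects them.
#'
#' @param tree a `phylo` object.
#' @return logical scalar.
#' @examples
#' check_rooted(ape::read.tree(text = "((A,B),C);"))  # TRUE
#' check_rooted(ape::read.tree(text = "(A,B,C);"))    # FALSE
#' @export
check_rooted <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  sum(tree$edge[, 1L] == root_node(tree)) == 2L
}
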