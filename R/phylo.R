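#' Neighbour-joining tree from a strain distance matrix
#'
#' Builds an unrooted neighbour-joining tree (Saitou-Nei agglomeration with
#' the Studier-Keppler distance update, via [ape::nj]) from a symmetric
#' non-negative distance matrix. On additive (tree-metric) distances NJ
#' recovers the generating tree exactly. Negative branch-length estimates,
#' which NJ can produce on non-additive data, are clamped to 0; the number
#' of clamped edges is recorded in the `"clampedEdges"` attribute and a
#' warning is emitted.
#'
#' @param d Symmetric numeric matrix with zero diagonal and non-negative
#'   finite entries, labelled with taxon names, or a [stats::dist] object.
#' @return An [ape::phylo] tree (unrooted), with attribute `clampedEdges`.
#' @examples
#' d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
#'             dimnames = list(LETTERS[1:3], LETTERS[1:3]))
#' njTree(d)
#' @seealso [rootAtOutgroup()], [writeNewick()]
#' @export
njTree <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  stopIfNot(is.matrix(d) && is.numeric(d), "d must be a numeric matrix")
  if (nrow(d) != ncol(d)) stop("distance matrix must be square")
  if (nrow(d) < 3L) stop("at least 3 taxa are required")
  if (is.null(rownames(d))) stop("distance matrix must have taxon labels")
  if (!identical(rownames(d), colnames(d)))
    stop("row and column taxon labels must match")
  if (any(!is.finite(d))) stop("distances must be finite")
  if (any(d < 0)) stop("distances must be non-negative")
  if (any(abs(d - t(d)) > 1e-8 * (1 + max(d))))
    stop("distance matrix must be symmetric")
  if (any(diag(d) != 0)) stop("distance matrix diagonal must be zero")

  tr <- ape::nj(as.dist(d))
  neg <- tr$edge.length < 0
  if (any(neg)) {
    warning(sum(neg), " negative NJ branch length(s) clamped to 0")
    tr$edge.length[neg] <- 0
  }
  attr(tr, "clampedEdges") <- sum(neg)
  tr
}

#' Root a tree at the midpoint of an outgroup's pendant edge
#'
#' Places the root on the branch leading to the named outgroup leaf, at the
#' midpoint of that pendant edge, so the total tree length is conserved.
#'
#' @param tree An [ape::phylo] tree whose tips include `outgroup`.
#' @param outgroup Taxon label of the outgroup leaf.
#' @return A rooted [ape::phylo] tree.
#' @examples
#' d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
#'             dimnames = list(LETTERS[1:3], LETTERS[1:3]))
#' rootAtOutgroup(njTree(d), "C")
#' @export
rootAtOutgroup <- function(tree, outgroup) {
  stopIfNot(inherits(tree, "phylo"), "tree must be an ape phylo object")
  if (!outgroup %in% tree$tip.label)
    stop("outgroup '", outgroup, "' is not a tip of the tree")
  rooted <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  rootNode <- length(rooted$tip.label) + 1L
  tipIdx <- match(outgroup, rooted$tip.label)
  ogEdge <- which(rooted$edge[, 1] == rootNode & rooted$edge[, 2] == tipIdx)
  sibEdge <- setdiff(which(rooted$edge[, 1] == rootNode), ogEdge)
  stopIfNot(length(ogEdge) == 1L && length(sibEdge) == 1L,
            "unexpected root structure after rooting")
  half <- rooted$edge.length[ogEdge] / 2
  rooted$edge.length[ogEdge] <- half
  rooted$edge.length[sibEdge] <- rooted$edge.length[sibEdge] + half
  rooted
}

#' Write a tree to a Newick file
#'
#' Serializes with branch lengths (`:` separators, trailing semicolon) via
#' [ape::write.tree]; writing, re-reading and writing again is a fixpoint.
#'
#' @param tree An [ape::phylo] tree.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeNewick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read a Newick tree file
#'
#' @param path Newick file path.
#' @return An [ape::phylo] tree.
#' @export
readNewick <- function(path) {
  stopIfNot(file.exists(path), "no such file: ", path)
  ape::read.tree(path)
}
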