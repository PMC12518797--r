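#' Default five-species Apis host phylogeny
#'
#' Returns the rooted, ultrametric host tree used throughout the package:
#' the two dwarf honeybees (subgenus Micrapis) *A. florea* and
#' *A. andreniformis* are sisters, the giant honeybee *A. dorsata* is sister
#' to the cavity-nesting pair *A. mellifera* + *A. cerana*. Branch lengths
#' are scaled so every root-to-tip path has length 1; they stand in for a
#' time-calibrated mitochondrial phylogeny and can be replaced by reading any
#' 5-taxon Newick tree with [ape::read.tree()].
#'
#' @return An [ape::phylo] object with 5 tips named
#'   `A_florea`, `A_andreniformis`, `A_dorsata`, `A_mellifera`, `A_cerana`.
#' @examples
#' tr <- default_host_tree()
#' ape::is.ultrametric(tr)
#' @export
default_host_tree <- function() {
  ape::read.tree(text = paste0(
    "((A_florea:0.25,A_andreniformis:0.25):0.75,",
    "(A_dorsata:0.6,(A_mellifera:0.35,A_cerana:0.35):0.25):0.4);"
  ))
}

#' Patristic distance matrix of a phylogeny
#'
#' Sum of branch lengths along the path between every pair of tips.
#'
#' @param tree an [ape::phylo] object with branch lengths.
#' @return A symmetric `DistanceMatrix` (labelled numeric matrix) with zero
#'   diagonal.
#' @examples
#' patristic_matrix(default_host_tree())
#' @export
patristic_matrix <- function(tree) {
  if (!inherits(tree, "phylo")) stop("'tree' must be a phylo object")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(is.na(tree$edge.length))) stop("tree has missing branch lengths")
  stats::cophenetic(tree)
}
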