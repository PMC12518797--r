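# TSV / Newick plumbing. Trees go through ape; tables are plain TSV with a
# header row, distance matrices square TSV with the labels as both the header
# and the first column.

#' Read / write a square distance matrix as TSV
#'
#' @param path file path.
#' @return `read_distance_tsv`: a labelled symmetric matrix.
#' @export
read_distance_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, row.names = 1L)
  check_dm(as.matrix(df), path)
}

#' @rdname read_distance_tsv
#' @param dm labelled square matrix.
#' @export
write_distance_tsv <- function(dm, path) {
  dm <- check_dm(dm)
  df <- data.frame(label = rownames(dm), dm, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write the MAG tip map as TSV
#'
#' Columns `tip_id`, `mag_id`, `host_species`, `is_outgroup` (0/1), plus any
#' extra metadata columns, as exchanged with the Newick symbiont trees.
#'
#' @param path file path.
#' @return `read_tip_map`: a data frame.
#' @export
read_tip_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  df$is_outgroup <- as.logical(df$is_outgroup)
  df
}

#' @rdname read_tip_map
#' @param tip_map data frame to write.
#' @export
write_tip_map <- function(tip_map, path) {
  tm <- tip_map
  tm$is_outgroup <- as.integer(tm$is_outgroup)
  utils::write.table(tm, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a symbiont tree set to disk
#'
#' Writes the tree as Newick and the tip map as TSV next to it.
#'
#' @param tree_set a [symbiont_tree_set()].
#' @param prefix output path prefix; writes `<prefix>.nwk` and
#'   `<prefix>_tips.tsv`.
#' @return The two paths, invisibly.
#' @export
write_tree_set <- function(tree_set, prefix) {
  stopifnot(inherits(tree_set, "symbiont_tree_set"))
  nwk <- paste0(prefix, ".nwk")
  tsv <- paste0(prefix, "_tips.tsv")
  ape::write.tree(tree_set$tree, nwk)
  write_tip_map(tree_set$tip_map, tsv)
  invisible(c(tree = nwk, tips = tsv))
}

#' Read a symbiont tree set from disk
#'
#' @param tree_path Newick file.
#' @param tips_path tip-map TSV.
#' @return A [symbiont_tree_set()].
#' @export
read_tree_set <- function(tree_path, tips_path) {
  symbiont_tree_set(ape::read.tree(tree_path), read_tip_map(tips_path))
}
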