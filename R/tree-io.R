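#' Read and validate a rooted bifurcating tree
#'
#' Parses a Newick file (or literal string) with [ape::read.tree()] and
#' enforces the invariants the downstream comparative methods assume: a
#' rooted, strictly bifurcating topology, unique tip labels and non-negative
#' branch lengths.
#'
#' Trees without branch lengths are accepted only with
#' `all_lengths_one = TRUE`, which assigns unit length to every edge (the
#' speciational convention: change concentrated at speciation events).
#' Polytomies are rejected unless `resolve = TRUE`, in which case they are
#' resolved into arbitrary bifurcations with zero-length internal edges via
#' [ape::multi2di()].
#'
#' @param file path to a Newick file. Exactly one of `file`/`text`.
#' @param text a literal Newick string instead of a file.
#' @param all_lengths_one set every branch length to 1, and accept trees
#'   that carry no lengths at all.
#' @param resolve resolve polytomies to zero-length bifurcations instead of
#'   failing.
#' @return an [ape] `"phylo"` object passing [validate_tree()].
#' @examples
#' tr <- read_tree(text = "((A:1,B:1):1,C:2);")
#' ape::Ntip(tr)
#' @seealso [reference_tree()] for the packaged 15-species topologies.
#' @export
read_tree <- function(file = NULL, text = NULL, all_lengths_one = FALSE,
                      resolve = FALSE) {
  if (is.null(file) == is.null(text))
    stop("supply exactly one of 'file' or 'text'")
  tree <- tryCatch(
    if (is.null(text)) ape::read.tree(file) else ape::read.tree(text = text),
    error = function(e) stop("Newick parse error: ", conditionMessage(e),
                             call. = FALSE),
    warning = function(w) stop("Newick parse error: ", conditionMessage(w),
                               call. = FALSE)
  )
  if (is.null(tree)) stop("Newick parse error: no tree found")
  if (inherits(tree, "multiPhylo")) tree <- tree[[1L]]
  if (all_lengths_one) tree$edge.length <- rep(1, nrow(tree$edge))
  if (resolve && !ape::is.binary(tree)) {
    had_lengths <- !is.null(tree$edge.length)
    tree <- ape::multi2di(tree)
    if (had_lengths) tree$edge.length[is.na(tree$edge.length)] <- 0
  }
  validate_tree(tree)
  tree
}

#' Validate the tree invariants assumed by the comparative methods
#'
#' @param tree a `"phylo"` object.
#' @param require_lengths demand branch lengths on every edge.
#' @return `tree`, invisibly, if valid; otherwise an error.
#' @export
validate_tree <- function(tree, require_lengths = TRUE) {
  if (!inherits(tree, "phylo")) stop("not a \"phylo\" object")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  if (!ape::is.binary(tree))
    stop("tree contains polytomies; use resolve = TRUE to force ",
         "zero-length bifurcations")
  if (require_lengths) {
    if (is.null(tree$edge.length))
      stop("tree has no branch lengths; use all_lengths_one = TRUE for a ",
           "speciational (unit-length) tree")
    if (anyNA(tree$edge.length) || any(tree$edge.length < 0))
      stop("negative or missing branch lengths")
  }
  invisible(tree)
}

#' Write a tree to a Newick file
#'
#' Thin wrapper over [ape::write.tree()] so that `write_tree(read_tree(f))`
#' round-trips topology and branch lengths.
#'
#' @param tree a `"phylo"` object.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_tree <- function(tree, file) {
  validate_tree(tree, require_lengths = FALSE)
  ape::write.tree(tree, file = file)
  invisible(file)
}

# Match a named trait vector against a tree's tips; errors on mismatch,
# returns values ordered as tree$tip.label.
match_trait <- function(tree, trait, what = "trait") {
  if (is.null(names(trait))) stop(what, " must be named by tip label")
  missing <- setdiff(tree$tip.label, names(trait))
  extra <- setdiff(names(trait), tree$tip.label)
  if (length(missing) || length(extra))
    stop(what, " does not match tree tips",
         if (length(missing)) paste0("; missing: ",
                                     paste(missing, collapse = ", ")),
         if (length(extra)) paste0("; extra: ",
                                   paste(extra, collapse = ", ")))
  x <- trait[tree$tip.label]
  if (anyNA(x) || any(!is.finite(x))) stop(what, " has non-finite values")
  x
}
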