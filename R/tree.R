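#' Read a Newick tree with CODEML-style foreground tags
#'
#' Branches can be tagged as foreground by appending `#1` to a tip or
#' internal-node label (e.g. `(kiwi#1,(ostrich,tinamou));`). The tag marks
#' the branch leading to that tip/clade. Untagged branches are background.
#'
#' @param text Newick string, or `file` a path to one.
#' @param file optional path; used when `text` is missing.
#' @return an [ape::phylo] tree with an added logical vector
#'   `foreground` of length `nrow(tree$edge)` (TRUE on tagged branches).
#' @examples
#' tr <- read_tagged_tree("((kiwi#1:0.1,ostrich:0.1):0.05,chicken:0.2);")
#' sum(tr$foreground)
#' @export
read_tagged_tree <- function(text, file = NULL) {
  tr <- if (!is.null(file)) ape::read.tree(file) else ape::read.tree(text = text)
  if (is.null(tr)) stop("could not parse Newick input")
  strip <- function(lab) sub("\\s*#\\d+$", "", lab)
  tagged_tip <- grepl("#\\d+$", tr$tip.label)
  tr$tip.label <- strip(tr$tip.label)
  tagged_node <- rep(FALSE, tr$Nnode)
  if (!is.null(tr$node.label)) {
    tagged_node <- grepl("#\\d+$", tr$node.label)
    tr$node.label <- strip(tr$node.label)
  }
  ntip <- length(tr$tip.label)
  tagged_ids <- c(which(tagged_tip), ntip + which(tagged_node))
  tr$foreground <- tr$edge[, 2] %in% tagged_ids
  tr
}

#' Tag branches leading to given taxa as foreground
#'
#' @param tree an [ape::phylo] tree.
#' @param taxa tip labels whose pendant branches become foreground.
#' @return the tree with a `foreground` logical edge vector.
#' @export
tag_foreground <- function(tree, taxa) {
  missing <- setdiff(taxa, tree$tip.label)
  if (length(missing))
    stop("taxa not in tree: ", paste(missing, collapse = ", "))
  ids <- match(taxa, tree$tip.label)
  tree$foreground <- tree$edge[, 2] %in% ids
  tree
}

# Validate tree/alignment pairing and return the tree in postorder with
# a tip index map aligned to the alignment's taxa.
.check_tree_aln <- function(tree, aln) {
  if (!setequal(tree$tip.label, aln$taxa) ||
      length(tree$tip.label) != length(aln$taxa))
    stop("taxa of alignment and tree must match 1:1")
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch length")
  if (is.null(tree$foreground)) tree$foreground <- rep(FALSE, nrow(tree$edge))
  tree
}
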