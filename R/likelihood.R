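#' Phylogenetic log-likelihood of a codon alignment
#'
#' Felsenstein pruning over the complete codon columns of the alignment
#' (columns containing a gap or ambiguous codon in any taxon are excluded).
#' Foreground branches (see [read_tagged_tree()] / [tag_foreground()]) use
#' `params$omega_foreground`; all others use `params$omega_background`.
#'
#' @param aln a [codon_alignment()].
#' @param tree an [ape::phylo] with branch lengths in expected
#'   substitutions per codon and (optionally) a `foreground` edge vector.
#' @param params a [codon_params()].
#' @return the log-likelihood (scalar). Attribute `n_columns_used` gives
#'   the number of complete codon columns.
#' @examples
#' aln <- codon_alignment(c(a = "ATGAAA", b = "ATGAAG", c = "ATGCAG"))
#' tr <- tag_foreground(ape::read.tree(text = "(a:0.1,b:0.1,c:0.1);"), "a")
#' log_likelihood(aln, tr, codon_params())
#' @export
log_likelihood <- function(aln, tree, params) {
  tree <- .check_tree_aln(tree, aln)
  pat <- alignment_patterns(aln)
  if (pat$n_used == 0L) {
    res <- 0
    attr(res, "n_columns_used") <- 0L
    return(res)
  }
  if (length(aln$taxa) == 1L) {
    # a single pendant branch: reversibility makes lnL independent of t
    res <- sum(pat$weights *
                 log(params$pi[pat$states[1, ]]))
    attr(res, "n_columns_used") <- pat$n_used
    return(res)
  }
  ord <- ape::reorder.phylo(tree, "postorder", index.only = TRUE)
  edge <- tree$edge[ord, , drop = FALSE]
  elen <- tree$edge.length[ord]
  efg <- as.integer(tree$foreground[ord])
  # reorder state rows to ape tip numbering
  st <- pat$states[match(tree$tip.label, rownames(pat$states)), , drop = FALSE]
  pr <- .codon_pairs()
  lnL <- .cpp_codon_lnL(st, pat$weights, edge, elen, efg,
                        params$kappa, params$omega_background,
                        params$omega_foreground, params$pi,
                        pr$i - 1L, pr$j - 1L,
                        as.integer(pr$transition), as.integer(pr$synonymous))
  attr(lnL, "n_columns_used") <- pat$n_used
  lnL
}
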