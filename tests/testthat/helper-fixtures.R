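# Shared fixtures: tiny trees and a brute-force likelihood oracle kept
# independent of the package's pruning path (it only uses the exported
# rate-matrix / transition-probability primitives).

small_star_tree <- function(t = 0.1) {
  ape::read.tree(text = sprintf("(a:%f,b:%f,c:%f);", t, t, t))
}

# Explicit sum over the internal-node state of a 3-taxon star tree:
# lnL = sum_col log sum_i pi_i prod_tip P[i, state_tip]
brute_force_star_lnL <- function(aln, tree, params) {
  Q <- build_rate_matrix(params, "background")
  sts <- lapply(aln$sequences, function(s) {
    cods <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
    match(cods, genetic_code()$sense_codons)
  })
  names(sts) <- aln$taxa
  Ps <- lapply(seq_len(nrow(tree$edge)), function(e)
    transition_probabilities(Q, tree$edge.length[e], params$pi))
  tips <- tree$edge[, 2]
  total <- 0
  for (col in seq_along(sts[[1]])) {
    site <- sum(params$pi * Reduce(`*`, lapply(seq_along(tips), function(k) {
      taxon <- tree$tip.label[tips[k]]
      Ps[[k]][, sts[[taxon]][col]]
    })))
    total <- total + log(site)
  }
  total
}

# Enumeration oracle for the signed-rank test: all 2^n sign patterns.
enumerate_signed_rank_p <- function(d, alternative = "two.sided") {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  W_all <- as.vector(signs %*% r)
  p_ge <- mean(W_all >= W_obs - 1e-12)
  p_le <- mean(W_all <= W_obs + 1e-12)
  switch(alternative,
         greater = p_ge, less = p_le,
         two.sided = min(1, 2 * min(p_le, p_ge)))
}

# Enumeration oracle for the upper-tail hypergeometric: all C(N, n) draws.
enumerate_hypergeom_p <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  in_cat <- draws <= K   # first K universe elements form the category
  mean(colSums(in_cat) >= k)
}
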