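#' Codon substitution model parameters
#'
#' Parameters of a Goldman-Yang style 61-state codon model: transition /
#' transversion rate ratio kappa, nonsynonymous/synonymous rate ratio(s)
#' omega, and equilibrium sense-codon frequencies pi. Under the one-ratio
#' model `omega_foreground` equals `omega_background`; the two-ratio
#' (branch) model gives designated foreground branches their own omega.
#'
#' @param kappa transition/transversion rate ratio (> 0).
#' @param omega_background nonsynonymous/synonymous ratio on background
#'   branches (>= 0).
#' @param omega_foreground ratio on foreground branches; defaults to
#'   `omega_background` (one-ratio model).
#' @param pi equilibrium frequencies over the 61 sense codons in
#'   TCAG-lexicographic order; must be nonnegative and sum to 1.
#'   Default uniform.
#' @return an object of class `codon_params`.
#' @export
codon_params <- function(kappa = 2, omega_background = 0.3,
                         omega_foreground = omega_background,
                         pi = rep(1 / 61, 61)) {
  if (kappa <= 0) stop("kappa must be > 0")
  if (omega_background < 0 || omega_foreground < 0) stop("omega must be >= 0")
  if (length(pi) != 61L) stop("pi must have 61 entries")
  if (any(pi < 0)) stop("pi entries must be >= 0")
  if (abs(sum(pi) - 1) > 1e-8) stop("pi must sum to 1 (got ", sum(pi), ")")
  structure(list(kappa = kappa, omega_background = omega_background,
                 omega_foreground = omega_foreground, pi = as.numeric(pi)),
            class = "codon_params")
}

#' Sense-codon frequencies from an alignment (F3x4 and friends)
#'
#' @param aln a [codon_alignment()].
#' @param method `"F3x4"` (position-specific nucleotide frequencies,
#'   CODEML's default), `"uniform"`, or `"empirical"` (observed codon
#'   frequencies with a pseudocount).
#' @return numeric(61) frequencies over the sense codons, summing to 1.
#' @export
codon_frequencies <- function(aln, method = c("F3x4", "uniform", "empirical")) {
  method <- match.arg(method)
  code <- .code()
  if (method == "uniform") return(rep(1 / 61, 61))
  cods <- unlist(lapply(aln$sequences, codon_split))
  cods <- cods[!grepl("[^ACGT]", cods)]
  if (!length(cods)) return(rep(1 / 61, 61))
  if (method == "empirical") {
    counts <- table(factor(cods, levels = code$sense_codons)) + 0.5
    return(as.numeric(counts / sum(counts)))
  }
  # F3x4: nucleotide frequencies per codon position
  mat <- do.call(rbind, strsplit(cods, ""))
  pos_freq <- lapply(1:3, function(p) {
    f <- table(factor(mat[, p], levels = c("T", "C", "A", "G"))) + 0.5
    f / sum(f)
  })
  cm <- do.call(rbind, strsplit(code$sense_codons, ""))
  pi <- pos_freq[[1]][cm[, 1]] * pos_freq[[2]][cm[, 2]] * pos_freq[[3]][cm[, 3]]
  as.numeric(pi / sum(pi))
}

#' Build the instantaneous codon rate matrix Q
#'
#' Goldman-Yang parameterization: for sense codons i != j differing at a
#' single nucleotide position, `q_ij = pi_j`, multiplied by kappa when the
#' nucleotide change is a transition and by omega when the codon change is
#' nonsynonymous; `q_ij = 0` for multi-step changes. The diagonal makes
#' rows sum to zero, and the matrix is rescaled so that
#' `sum_i pi_i * (-q_ii) = 1`, i.e. branch lengths are expected
#' substitutions per codon.
#'
#' @param params a [codon_params()].
#' @param branch_class `"background"` or `"foreground"`; selects the omega.
#' @return a 61 x 61 rate matrix with codon dimnames.
#' @export
build_rate_matrix <- function(params,
                              branch_class = c("background", "foreground")) {
  branch_class <- match.arg(branch_class)
  stopifnot(inherits(params, "codon_params"))
  omega <- if (branch_class == "foreground") params$omega_foreground
           else params$omega_background
  pr <- .codon_pairs()
  Q <- matrix(0, 61, 61)
  rate <- params$pi[pr$j]
  rate[pr$transition] <- rate[pr$transition] * params$kappa
  rate[!pr$synonymous] <- rate[!pr$synonymous] * omega
  Q[cbind(pr$i, pr$j)] <- rate
  diag(Q) <- -rowSums(Q)
  scale <- -sum(params$pi * diag(Q))
  if (scale > 0) Q <- Q / scale
  dimnames(Q) <- list(.code()$sense_codons, .code()$sense_codons)
  Q
}

#' Transition probability matrix P(t) = exp(Qt)
#'
#' Computed by symmetric eigendecomposition, exploiting the reversibility
#' of the model (`B = D^{1/2} Q D^{-1/2}` is symmetric for `D = diag(pi)`).
#'
#' @param Q rate matrix from [build_rate_matrix()].
#' @param t branch length (expected substitutions per codon, >= 0).
#' @param pi the stationary distribution used to build `Q`.
#' @return a 61 x 61 stochastic matrix; tiny negative entries from
#'   round-off are clamped to 0 and rows renormalized.
#' @export
transition_probabilities <- function(Q, t, pi) {
  if (t < 0) stop("branch length t must be >= 0")
  if (t == 0) return(diag(nrow(Q)))
  d <- sqrt(pi)
  B <- (d %o% (1 / d)) * Q          # symmetric up to round-off
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  P <- ((1 / d) * e$vectors) %*% (exp(e$values * t) * t(e$vectors * d))
  P[P < 0] <- 0
  P / rowSums(P)
}

# Raw (unscaled) synonymous and nonsynonymous flux opportunities under
# kappa/pi, with omega factored out of the nonsynonymous part:
# total rate at omega is omega * nonsyn + syn.
.raw_flux <- function(kappa, pi) {
  pr <- .codon_pairs()
  rate <- pi[pr$j]
  rate[pr$transition] <- rate[pr$transition] * kappa
  flux <- pi[pr$i] * rate
  list(syn = sum(flux[pr$synonymous]), nonsyn = sum(flux[!pr$synonymous]))
}
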