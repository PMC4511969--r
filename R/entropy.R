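#' Shannon entropy of one alignment column
#'
#' `H = -sum_a p_a log2 p_a` over the residues observed in the column.
#' For the 20-letter amino-acid alphabet H ranges from 0 (perfectly
#' conserved position) to `log2(20) = 4.322` bits (all residues equally
#' represented).
#'
#' @param column character vector of one-letter residues (may include `-`).
#' @param gap_policy `"exclude"` drops gaps from the frequencies;
#'   `"symbol"` treats the gap as a 21st symbol.
#' @return entropy in bits; `NA` for an all-gap column under `"exclude"`.
#' @examples
#' column_entropy(rep("A", 10))           # 0
#' round(column_entropy(LETTERS[1:20]), 3)  # 4.322
#' @export
column_entropy <- function(column, gap_policy = c("exclude", "symbol")) {
  gap_policy <- match.arg(gap_policy)
  if (gap_policy == "exclude") column <- column[column != "-"]
  if (!length(column)) return(NA_real_)
  p <- table(column)
  p <- p / sum(p)
  -sum(p * log2(p))
}

#' Per-species repertoire entropy profile
#'
#' Computes per-column Shannon entropy over a within-species protein
#' alignment and summarizes it as mean, SD and SE. Both dispersion
#' measures are reported because a lone "+/-" in a summary can mean
#' either.
#'
#' @param aln named character vector (or `AAStringSet`) of equal-length
#'   aligned protein sequences from one species; >= 2 sequences.
#' @param species optional species label carried into the result.
#' @param gap_policy see [column_entropy()].
#' @return object of class `entropy_profile`: `species`, `H` (per usable
#'   column), `mean_H`, `sd_H`, `se_H`, `n_columns`, `n_skipped`.
#' @export
species_entropy_summary <- function(aln, species = NA_character_,
                                    gap_policy = "exclude") {
  if (methods::is(aln, "XStringSet")) {
    aln <- stats::setNames(as.character(aln), names(aln))
  }
  if (length(aln) < 2L)
    stop("need >= 2 sequences to profile within-species diversity")
  if (length(unique(nchar(aln))) != 1L)
    stop("sequences must be aligned (equal length)")
  mat <- do.call(rbind, strsplit(toupper(aln), ""))
  H <- apply(mat, 2, column_entropy, gap_policy = gap_policy)
  skipped <- sum(is.na(H))
  H <- H[!is.na(H)]
  if (!length(H)) stop("no usable columns after gap policy")
  structure(list(
    species = species, H = H,
    mean_H = mean(H), sd_H = stats::sd(H),
    se_H = stats::sd(H) / sqrt(length(H)),
    n_columns = length(H), n_skipped = skipped
  ), class = "entropy_profile")
}

#' @export
print.entropy_profile <- function(x, ...) {
  cat(sprintf("entropy_profile [%s]: mean H = %.3f (SD %.3f, SE %.3f) over %d columns\n",
              x$species, x$mean_H, x$sd_H, x$se_H, x$n_columns))
  invisible(x)
}

#' Exact Wilcoxon signed-rank test
#'
#' Exact signed-rank test on paired differences. Zero differences are
#' dropped (Wilcoxon's original policy) and ties receive mid-ranks. For
#' `n <= exact_limit` the null distribution of `W+` (sum of ranks of
#' positive differences) is computed exactly over all `2^n` sign
#' assignments via a generating-function convolution, which is exact even
#' with tied ranks; above the limit a normal approximation with tie
#' correction and continuity correction is used.
#'
#' @param differences numeric vector of paired differences.
#' @param alternative `"two.sided"`, `"greater"` (positive shift) or
#'   `"less"`.
#' @param exact_limit maximum n for the exact distribution (default 25).
#' @return list with `statistic` (W+), `n` (non-zero differences),
#'   `pvalue`, `exact` (logical), `alternative`.
#' @examples
#' wilcoxon_signed_rank(c(1, 2, 3, 4, 5, 6, 7, 8, 9))$pvalue  # 2/512
#' @export
wilcoxon_signed_rank <- function(differences,
                                 alternative = c("two.sided", "greater", "less"),
                                 exact_limit = 25L) {
  alternative <- match.arg(alternative)
  d <- differences[differences != 0]
  n <- length(d)
  if (n == 0L) stop("all differences are zero: test undefined")
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= exact_limit) {
    # distribution of W+ over the 2^n equiprobable sign patterns;
    # double the ranks so mid-ranks (.5) become integers
    r2 <- as.integer(round(2 * r))
    M <- sum(r2)
    f <- numeric(M + 1L)   # f[w + 1] = #patterns with 2*W+ == w
    f[1L] <- 1
    for (rv in r2) {
      shifted <- c(numeric(rv), f[seq_len(M + 1L - rv)])
      f <- f + shifted
    }
    probs <- f / 2^n
    w2 <- as.integer(round(2 * W))
    p_le <- sum(probs[seq_len(w2 + 1L)])
    p_ge <- sum(probs[(w2 + 1L):(M + 1L)])
    pvalue <- switch(alternative,
      greater = p_ge,
      less = p_le,
      two.sided = min(1, 2 * min(p_le, p_ge)))
    exact <- TRUE
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sigma2)
    pvalue <- switch(alternative,
      greater = stats::pnorm(z, lower.tail = FALSE),
      less = stats::pnorm(z),
      two.sided = 2 * stats::pnorm(-abs(z)))
    pvalue <- min(1, pvalue)
    exact <- FALSE
  }
  list(statistic = W, n = n, pvalue = pvalue, exact = exact,
       alternative = alternative)
}
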