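#' The universal genetic code over the PAML codon ordering
#'
#' Codons are enumerated lexicographically over the base order T, C, A, G
#' (the ordering used by CODEML output, which eases cross-checking fitted
#' rate matrices against that program). The universal code has 61 sense
#' codons; TAA, TAG and TGA are stops.
#'
#' @return A list with components:
#'   \item{codons}{character(64), all codons in TCAG-lexicographic order.}
#'   \item{aa}{character(64), one-letter amino acid per codon, `"*"` for stops.}
#'   \item{sense_codons}{character(61), codons excluding stops, same order.}
#'   \item{sense_aa}{character(61), amino acids of the sense codons.}
#' @examples
#' gc <- genetic_code()
#' length(gc$sense_codons)  # 61
#' @export
genetic_code <- function() {
  bases <- c("T", "C", "A", "G")
  codons <- as.vector(vapply(bases, function(b1)
    vapply(bases, function(b2)
      paste0(b1, b2, bases), character(4)), character(16)))
  aa <- vapply(codons, function(cd) {
    as.character(Biostrings::translate(
      Biostrings::DNAString(cd), no.init.codon = TRUE))
  }, character(1))
  stopifnot(length(codons) == 64L, sum(aa == "*") == 3L)
  sense <- aa != "*"
  list(codons = codons, aa = unname(aa),
       sense_codons = codons[sense], sense_aa = unname(aa[sense]))
}

# Cache: the code never changes within a session.
the <- new.env(parent = emptyenv())

.code <- function() {
  if (is.null(the$code)) the$code <- genetic_code()
  the$code
}

# Single-nucleotide neighbour structure of the 61 sense codons: for every
# ordered pair (i, j) differing at exactly one position, whether the change
# is a transition (A<->G, C<->T) and whether it is synonymous. This is the
# sparsity pattern of the Goldman-Yang rate matrix.
.codon_pairs <- function() {
  if (!is.null(the$pairs)) return(the$pairs)
  code <- .code()
  n <- length(code$sense_codons)
  mat <- do.call(rbind, strsplit(code$sense_codons, ""))
  ii <- integer(0); jj <- integer(0); ts <- logical(0); syn <- logical(0)
  is_ts <- function(a, b) (a == "A" & b == "G") | (a == "G" & b == "A") |
    (a == "C" & b == "T") | (a == "T" & b == "C")
  for (i in seq_len(n)) {
    diffs <- sweep(mat, 2, mat[i, ], FUN = "!=")
    nd <- rowSums(diffs)
    for (j in which(nd == 1L)) {
      pos <- which(diffs[j, ])
      ii <- c(ii, i); jj <- c(jj, j)
      ts <- c(ts, is_ts(mat[i, pos], mat[j, pos]))
      syn <- c(syn, code$sense_aa[i] == code$sense_aa[j])
    }
  }
  the$pairs <- list(i = ii, j = jj, transition = ts, synonymous = syn)
  the$pairs
}

#' Map codon strings to sense-codon state indices
#'
#' @param codons character vector of 3-base codons (uppercase ACGT).
#' @return integer vector of indices into `genetic_code()$sense_codons`;
#'   `NA` for codons containing gaps/ambiguity, error for stop codons.
#' @keywords internal
codon_states <- function(codons) {
  code <- .code()
  idx <- match(codons, code$sense_codons)
  unknown <- is.na(idx)
  if (any(unknown)) {
    bad <- codons[unknown]
    stops <- bad %in% code$codons
    if (any(stops))
      stop("stop codon(s) in sequence: ", paste(unique(bad[stops]), collapse = ", "))
    # anything else (gap / N / partial) is ambiguity -> NA
  }
  idx
}
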