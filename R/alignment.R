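#' Construct a codon alignment
#'
#' A light container for an in-frame codon alignment: equal-length
#' nucleotide strings whose length is divisible by 3 and whose frame-1
#' codons contain no internal stop. Gaps (`-`) and unresolved bases (`N`)
#' are permitted; columns containing them are excluded from likelihood
#' computations (complete-column analysis).
#'
#' @param sequences named character vector of aligned nucleotide strings.
#' @return An object of class `codon_alignment` with fields `taxa`,
#'   `sequences` and `n_codons`.
#' @examples
#' aln <- codon_alignment(c(a = "ATGAAA", b = "ATGAAG"))
#' aln$n_codons
#' @export
codon_alignment <- function(sequences) {
  if (is.null(names(sequences)) || anyDuplicated(names(sequences)))
    stop("sequences must carry unique taxon names")
  sequences <- toupper(sequences)
  len <- unique(nchar(sequences))
  if (length(len) > 1L) stop("aligned sequences must have equal length")
  if (length(len) == 1L && len %% 3L != 0L)
    stop("alignment length must be divisible by 3 (got ", len, ")")
  stops <- c("TAA", "TAG", "TGA")
  n_codons <- if (length(len)) len %/% 3L else 0L
  for (s in names(sequences)) {
    cods <- codon_split(sequences[[s]])
    internal <- cods[-length(cods)]
    if (n_codons > 1L && any(internal %in% stops))
      stop("internal stop codon in taxon '", s, "'")
  }
  structure(list(taxa = names(sequences),
                 sequences = unname(sequences),
                 n_codons = n_codons),
            class = "codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat("codon_alignment:", length(x$taxa), "taxa x", x$n_codons, "codons\n")
  invisible(x)
}

codon_split <- function(seq) {
  n <- nchar(seq)
  if (n == 0L) return(character(0))
  substring(seq, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
}

#' Read an aligned FASTA file as a codon alignment
#'
#' @param path FASTA file of aligned coding sequences (gaps `-`, ambiguity `N`).
#' @return A [codon_alignment()].
#' @export
read_codon_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  codon_alignment(stats::setNames(as.character(x), names(x)))
}

#' Write a codon alignment to FASTA
#'
#' @param aln a [codon_alignment()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_codon_fasta <- function(aln, path) {
  x <- Biostrings::BStringSet(stats::setNames(aln$sequences, aln$taxa))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

# Codon columns as a taxa x n_codons integer state matrix (NA = gap/ambiguous
# codon in that taxon). Used by the likelihood and the pre-filters.
alignment_states <- function(aln) {
  mat <- t(vapply(aln$sequences, function(s) {
    cods <- codon_split(s)
    idx <- match(cods, .code()$sense_codons)
    # terminal stop codons are tolerated at input but masked here
    idx
  }, integer(aln$n_codons)))
  rownames(mat) <- aln$taxa
  mat
}

# Complete codon columns (no gap/ambiguity in any taxon), with site-pattern
# compression: returns list(states = taxa x npat matrix, weights, n_used,
# n_excluded).
alignment_patterns <- function(aln) {
  st <- alignment_states(aln)
  keep <- colSums(is.na(st)) == 0L
  used <- st[, keep, drop = FALSE]
  if (ncol(used) == 0L)
    return(list(states = used, weights = integer(0),
                n_used = 0L, n_excluded = sum(!keep)))
  key <- apply(used, 2, paste, collapse = ",")
  first <- !duplicated(key)
  w <- as.integer(table(factor(key, levels = key[first])))
  list(states = used[, first, drop = FALSE], weights = w,
       n_used = sum(keep), n_excluded = sum(!keep))
}
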