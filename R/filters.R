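#' Frameshift-free alignment filter
#'
#' The strictest pre-filter for selection analysis: an alignment passes
#' only if every gap run in every sequence has a length divisible by 3
#' (so indels preserve the reading frame) and no sequence contains an
#' internal frame-1 stop codon.
#'
#' @param aln a [codon_alignment()] (gaps allowed).
#' @return TRUE/FALSE.
#' @export
filter_set1 <- function(aln) {
  stops <- c("TAA", "TAG", "TGA")
  for (s in aln$sequences) {
    runs <- gregexpr("-+", s)[[1]]
    if (runs[1] != -1L &&
        any(attr(runs, "match.length") %% 3L != 0L)) return(FALSE)
    cods <- codon_split(s)
    if (length(cods) > 1L &&
        any(cods[-length(cods)] %in% stops)) return(FALSE)
  }
  TRUE
}

#' Longest clean alignment block
#'
#' Finds the maximal run of contiguous alignment columns that contain no
#' gap and no unresolved character in any sequence, trims it to codon
#' boundaries, and returns it only if it spans at least `min_len` bases.
#' Ties are broken towards the leftmost block. This is the fallback
#' filter for alignments that fail [filter_set1()].
#'
#' @param aln a [codon_alignment()].
#' @param min_len minimum block length in aligned bases (default 200).
#' @param unresolved_chars characters treated as unresolved (default `N`).
#' @return `NULL` if no block qualifies, else a list with 1-based
#'   inclusive `start`, `end`, `length` (all in nucleotide columns, codon
#'   aligned) and `alignment`, the extracted sub-alignment.
#' @export
longest_clean_block <- function(aln, min_len = 200L,
                                unresolved_chars = c("N")) {
  if (aln$n_codons == 0L) return(NULL)
  chars <- do.call(rbind, strsplit(aln$sequences, ""))
  bad_char <- chars == "-" | matrix(chars %in% unresolved_chars,
                                    nrow = nrow(chars))
  clean_col <- colSums(bad_char) == 0L
  # runs of clean columns
  r <- rle(clean_col)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  best <- NULL
  for (k in which(r$values)) {
    # trim to codon boundaries
    s <- starts[k]; e <- ends[k]
    s <- s + (3L - (s - 1L) %% 3L) %% 3L   # next column with (col-1)%%3==0
    e <- e - (e %% 3L)                     # last column divisible by 3
    if (e - s + 1L < 3L) next
    len <- e - s + 1L
    if (len >= min_len && (is.null(best) || len > best$length)) {
      best <- list(start = s, end = e, length = len)
    }
  }
  if (is.null(best)) return(NULL)
  sub <- substring(aln$sequences, best$start, best$end)
  best$alignment <- codon_alignment(stats::setNames(sub, aln$taxa))
  best
}
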