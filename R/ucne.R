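#' Validate an ultra-conserved non-coding element catalog
#'
#' UCNEs are defined as non-coding regions of >= 95 % human-chicken
#' identity and strictly longer than 200 bp. Elements violating the
#' length bound or containing non-ACGT symbols are rejected with reasons;
#' rejection is data, not failure.
#'
#' @param records data.frame with columns `id`, `sequence` (and optionally
#'   `gene`).
#' @return list with `accepted` and `rejected` data.frames; `rejected`
#'   gains a `reason` column.
#' @export
validate_catalog <- function(records) {
  len <- nchar(records$sequence)
  bad_sym <- grepl("[^ACGT]", toupper(records$sequence))
  reason <- ifelse(len <= 200L, "length <= 200 bp",
                   ifelse(bad_sym, "non-ACGT symbols", NA))
  rejected <- records[!is.na(reason), , drop = FALSE]
  if (nrow(rejected)) rejected$reason <- reason[!is.na(reason)]
  else rejected$reason <- character(0)
  list(accepted = records[is.na(reason), , drop = FALSE], rejected = rejected)
}

#' Sequence variation of an ortholog against a conserved reference element
#'
#' Globally aligns the ortholog to the reference (affine gap penalties:
#' match +1, mismatch -1, open -5, extend -1) and reports
#' `(mismatches + gap columns) / reference length`. An element is flagged
#' when variation strictly exceeds the threshold (default the 5 %
#' complement of the 95 % identity defining ultra-conservation).
#'
#' @param reference,ortholog non-empty nucleotide strings.
#' @param threshold flagging threshold on the variation fraction.
#' @param count_gaps whether gap columns count as differences (default
#'   TRUE, the conservative reading).
#' @param id optional element id carried through.
#' @return list of class `variation_result`: `id`, `aligned_length`,
#'   `mismatches`, `gap_columns`, `variation`, `flagged`.
#' @export
variation_fraction <- function(reference, ortholog, threshold = 0.05,
                               count_gaps = TRUE, id = NA_character_) {
  if (!nchar(reference) || !nchar(ortholog)) stop("empty sequence")
  reference <- toupper(reference); ortholog <- toupper(ortholog)
  if (identical(reference, ortholog)) {
    mism <- 0L; gaps <- 0L; alen <- nchar(reference)
  } else {
    al <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(ortholog), Biostrings::DNAString(reference),
      type = "global",
      substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
        match = 1, mismatch = -1),
      gapOpening = 5, gapExtension = 1)
    p <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
    s <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
    gaps <- sum(p == "-" | s == "-")
    mism <- sum(p != s & p != "-" & s != "-")
    alen <- length(p)
  }
  diffs <- mism + if (count_gaps) gaps else 0L
  variation <- diffs / nchar(reference)
  structure(list(id = id, aligned_length = alen, mismatches = mism,
                 gap_columns = gaps, variation = variation,
                 flagged = variation > threshold),
            class = "variation_result")
}

#' Screen a UCNE catalog against orthologous sequences
#'
#' @param records validated catalog data.frame (`id`, `sequence`).
#' @param orthologs named character vector (or `DNAStringSet`) keyed by
#'   element id; elements without an ortholog are counted as missing,
#'   never imputed.
#' @param threshold per-screen flagging threshold.
#' @param per_element_threshold optional named vector of per-element
#'   threshold overrides.
#' @return list of class `ucne_screen`: `n_screened`, `n_flagged`,
#'   `n_missing`, `table` (per-element data.frame).
#' @export
screen_catalog <- function(records, orthologs, threshold = 0.05,
                           per_element_threshold = NULL) {
  if (methods::is(orthologs, "XStringSet"))
    orthologs <- stats::setNames(as.character(orthologs), names(orthologs))
  rows <- lapply(seq_len(nrow(records)), function(i) {
    id <- records$id[i]
    if (!id %in% names(orthologs))
      return(data.frame(id = id, variation = NA_real_,
                        mismatches = NA_integer_, gap_columns = NA_integer_,
                        flagged = NA, missing = TRUE))
    thr <- if (!is.null(per_element_threshold) &&
               id %in% names(per_element_threshold))
      per_element_threshold[[id]] else threshold
    v <- variation_fraction(records$sequence[i], orthologs[[id]],
                            threshold = thr, id = id)
    data.frame(id = id, variation = v$variation, mismatches = v$mismatches,
               gap_columns = v$gap_columns, flagged = v$flagged,
               missing = FALSE)
  })
  tab <- do.call(rbind, rows)
  structure(list(
    n_screened = sum(!tab$missing),
    n_flagged = sum(tab$flagged, na.rm = TRUE),
    n_missing = sum(tab$missing),
    table = tab
  ), class = "ucne_screen")
}

#' @export
print.ucne_screen <- function(x, ...) {
  cat(sprintf("ucne_screen: %d screened, %d flagged (>threshold), %d missing\n",
              x$n_screened, x$n_flagged, x$n_missing))
  invisible(x)
}

#' Read a UCNE catalog from FASTA
#'
#' @param path FASTA of reference element sequences; names become ids.
#' @return data.frame `id`, `sequence`.
#' @export
read_ucne_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  data.frame(id = names(x), sequence = as.character(x))
}
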