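#' Canonical k-mer multiplicity histogram from reads
#'
#' Counts canonical k-mers (the lexicographic minimum of a k-mer and its
#' reverse complement) across a read set, skipping k-mers containing `N`,
#' and tabulates how many distinct k-mers occur at each multiplicity
#' (jellyfish-histo style).
#'
#' @param reads character vector of reads (or `DNAStringSet`) over
#'   `A,C,G,T,N`.
#' @param k k-mer length; must not exceed every read length.
#' @return object of class `kmer_histogram`: `k`, `entries` (data.frame
#'   `multiplicity`, `count`), `total_kmers` (instances),
#'   `distinct_kmers`.
#' @export
kmer_histogram <- function(reads, k) {
  if (methods::is(reads, "XStringSet")) reads <- as.character(reads)
  reads <- toupper(reads)
  usable <- nchar(reads) >= k
  if (!any(usable)) stop("k = ", k, " exceeds every read length")
  reads <- reads[usable]
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(reads)))
  kmers <- vector("list", length(reads))
  for (i in seq_along(reads)) {
    L <- nchar(reads[i])
    starts <- seq_len(L - k + 1L)
    fwd <- substring(reads[i], starts, starts + k - 1L)
    # k-mer at forward position p aligns with revcomp position L-k+2-p
    rev <- substring(rc[i], starts, starts + k - 1L)[rev(starts)]
    kmers[[i]] <- pmin(fwd, rev)
  }
  kmers <- unlist(kmers, use.names = FALSE)
  kmers <- kmers[!grepl("N", kmers, fixed = TRUE)]
  if (!length(kmers)) stop("no usable k-mers (all contain N)")
  mult <- tabulate(table(kmers))
  entries <- data.frame(multiplicity = seq_along(mult), count = mult)
  entries <- entries[entries$count > 0L, , drop = FALSE]
  structure(list(k = k, entries = entries,
                 total_kmers = length(kmers),
                 distinct_kmers = sum(entries$count)),
            class = "kmer_histogram")
}

#' Read / write a jellyfish-style histogram TSV
#'
#' @param path 2-column TSV `multiplicity count`.
#' @param k the k-mer length the histogram was built with.
#' @return a `kmer_histogram`.
#' @export
read_kmer_histogram <- function(path, k) {
  e <- utils::read.table(path, header = FALSE,
                         col.names = c("multiplicity", "count"))
  if (any(e$multiplicity < 1) || any(e$count < 0))
    stop("invalid histogram entries")
  structure(list(k = k, entries = e,
                 total_kmers = sum(as.numeric(e$multiplicity) * e$count),
                 distinct_kmers = sum(e$count)),
            class = "kmer_histogram")
}

#' @rdname read_kmer_histogram
#' @param hist a `kmer_histogram` to write.
#' @export
write_kmer_histogram <- function(hist, path) {
  utils::write.table(hist$entries, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Estimate genome size from a k-mer spectrum
#'
#' Standard single-peak spectrum estimator: sequencing errors produce a
#' spike of low-multiplicity k-mers, separated by a local minimum from the
#' main peak at the effective k-mer coverage `c_k`. The error cutoff is
#' the first strict local minimum of the counts; the peak is located as
#' the modal multiplicity above the cutoff (on a 3-point smoothed
#' spectrum) and `c_k` refined as the count-weighted centroid of a +/-2
#' window around it, which removes the +/-1 discretization error of a
#' raw argmax; genome size is the number of k-mer instances above the
#' cutoff divided by `c_k`. When the histogram rises from the first
#' multiplicity (no error spike, e.g. error-free simulated reads) the
#' cutoff is 0 and all k-mers are used.
#'
#' @param hist a `kmer_histogram`.
#' @param read_length optional mean read length `R`; if given, a
#'   read-length-corrected size using base coverage
#'   `c = c_k * R / (R - k + 1)` is also reported.
#' @return object of class `genome_size_estimate`: `error_cutoff`,
#'   `peak_multiplicity` (integer mode), `peak_depth` (refined `c_k`),
#'   `total_kmers_used`, `size` (bp, raw k-mer estimate) and, when
#'   `read_length` is given, `size_read_corrected`.
#' @export
estimate_genome_size <- function(hist, read_length = NULL) {
  e <- hist$entries[order(hist$entries$multiplicity), ]
  # dense counts over 1..max multiplicity (missing multiplicities = 0)
  m_max <- max(e$multiplicity)
  counts <- numeric(m_max)
  counts[e$multiplicity] <- e$count
  cutoff <- 0L
  if (length(counts) >= 2L && counts[1] > counts[2]) {
    # descending error spike: scan to the first strict local minimum
    i <- 2L
    while (i < length(counts) && counts[i] <= counts[i - 1L]) i <- i + 1L
    if (counts[i] <= counts[i - 1L])   # never rose again
      stop("histogram decreases monotonically: no k-mer coverage peak ",
           "separable from the error spike (coverage too low?)")
    cutoff <- i - 1L
  }
  usable <- e$multiplicity > cutoff
  if (!any(usable)) stop("no k-mers above the error cutoff")
  # locate the mode on a lightly smoothed spectrum (3-point moving
  # average), then refine the peak depth as the count-weighted centroid
  # over a +/-2 window: the centroid is exact for symmetric peaks and
  # immune to the +/-1 discretization noise of a raw argmax
  dense <- counts
  if (cutoff > 0L) dense[seq_len(cutoff)] <- 0
  sm <- dense
  if (length(dense) >= 3L)
    sm[2:(length(dense) - 1L)] <-
      (dense[1:(length(dense) - 2L)] + dense[2:(length(dense) - 1L)] +
         dense[3:length(dense)]) / 3
  m_star <- which.max(sm)
  if (m_star <= cutoff) stop("no k-mer coverage peak above the error cutoff")
  win <- max(cutoff + 1L, m_star - 2L):min(length(dense), m_star + 2L)
  peak <- sum(win * dense[win]) / sum(dense[win])
  total <- sum(as.numeric(e$multiplicity[usable]) * e$count[usable])
  out <- list(error_cutoff = cutoff, peak_multiplicity = m_star,
              peak_depth = peak, total_kmers_used = total,
              size = total / peak)
  if (!is.null(read_length)) {
    # base coverage exceeds k-mer coverage because only R-k+1 of R read
    # positions start a k-mer; the corrected size divides by it instead
    c_base <- peak * read_length / (read_length - hist$k + 1)
    out$base_coverage <- c_base
    out$size_read_corrected <- total / c_base
  }
  structure(out, class = "genome_size_estimate")
}

#' @export
print.genome_size_estimate <- function(x, ...) {
  cat(sprintf("genome_size_estimate: %.4g bp (peak %.2f, cutoff %d)\n",
              x$size, x$peak_depth, x$error_cutoff))
  invisible(x)
}

#' N50 of a set of contig/scaffold lengths
#'
#' The smallest length L such that pieces of length >= L together contain
#' at least half of the total assembled bases.
#'
#' @param lengths positive piece lengths.
#' @return the N50 in the same units.
#' @examples
#' n50(c(10, 20, 30, 40))  # 30
#' @export
n50 <- function(lengths) {
  if (!length(lengths)) stop("empty length list")
  if (any(lengths <= 0)) stop("lengths must be > 0")
  s <- sort(lengths, decreasing = TRUE)
  s[which(cumsum(as.numeric(s)) >= sum(as.numeric(s)) / 2)[1]]
}
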