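#' GC-binned genome-wide coverage baseline
#'
#' Stratifies genome-wide read depth by window GC content: for each GC bin
#' the mean depth over all windows whose GC falls in that bin, plus the
#' genome-wide mean. The baseline grounds copy-number correction of
#' collapsed multi-copy regions (a region sequenced at k times the depth
#' expected for its GC content is present in ~k collapsed copies).
#'
#' @param depth data.frame with columns `chrom`, `pos` (1-based), `depth`
#'   (samtools-depth dialect; see [read_depth_tsv()]).
#' @param windows data.frame with columns `chrom`, `start`, `end`
#'   (0-based half-open) and `gc` (fraction in `[0, 1]`).
#' @param bin_width GC bin width (fraction units, default 0.01).
#' @return object of class `coverage_baseline`: `bin_width`, `bins`
#'   (data.frame `gc_lower`, `mean_depth`, `n_windows`; unoccupied bins
#'   have `mean_depth = NA`), `genome_wide_mean`.
#' @export
gc_binned_baseline <- function(depth, windows, bin_width = 0.01) {
  if (nrow(depth) == 0L) stop("empty depth track")
  if (nrow(windows) == 0L) stop("empty GC window track")
  if (any(windows$gc < 0 | windows$gc > 1)) stop("gc must lie in [0, 1]")
  win_mean <- vapply(seq_len(nrow(windows)), function(i) {
    w <- windows[i, ]
    d <- depth$depth[depth$chrom == w$chrom &
                       depth$pos > w$start & depth$pos <= w$end]
    if (!length(d)) NA_real_ else mean(d)
  }, numeric(1))
  keep <- !is.na(win_mean)
  bins_idx <- .gc_bin_index(windows$gc[keep], bin_width)
  n_bins <- ceiling(1 / bin_width)
  means <- rep(NA_real_, n_bins)
  counts <- integer(n_bins)
  agg <- tapply(win_mean[keep], bins_idx, mean)
  means[as.integer(names(agg))] <- as.numeric(agg)
  cnt <- table(bins_idx)
  counts[as.integer(names(cnt))] <- as.integer(cnt)
  structure(list(
    bin_width = bin_width,
    bins = data.frame(gc_lower = (seq_len(n_bins) - 1L) * bin_width,
                      mean_depth = means, n_windows = counts),
    genome_wide_mean = mean(depth$depth)
  ), class = "coverage_baseline")
}

# windows with gc == 1 fall in the last bin
.gc_bin_index <- function(gc, bin_width) {
  n_bins <- ceiling(1 / bin_width)
  pmin(floor(gc / bin_width) + 1L, n_bins)
}

#' Build a coverage baseline directly from bin means
#'
#' Convenience constructor when the per-bin means are already known, e.g.
#' for worked examples and tests.
#'
#' @param gc_lower,mean_depth parallel vectors of bin lower edges and mean
#'   depths.
#' @param bin_width GC bin width.
#' @param genome_wide_mean optional overall mean depth.
#' @return a `coverage_baseline`.
#' @export
coverage_baseline <- function(gc_lower, mean_depth, bin_width = 0.01,
                              genome_wide_mean = mean(mean_depth)) {
  n_bins <- ceiling(1 / bin_width)
  means <- rep(NA_real_, n_bins)
  counts <- integer(n_bins)
  idx <- .gc_bin_index(gc_lower + bin_width / 2, bin_width)
  means[idx] <- mean_depth
  counts[idx] <- 1L
  structure(list(
    bin_width = bin_width,
    bins = data.frame(gc_lower = (seq_len(n_bins) - 1L) * bin_width,
                      mean_depth = means, n_windows = counts),
    genome_wide_mean = genome_wide_mean
  ), class = "coverage_baseline")
}

#' GC-corrected copy-number correction factor
#'
#' Divides a region's mean read depth by the genome-wide mean depth of its
#' GC bin. E.g. a region at 105-fold depth whose GC bin averages 35-fold
#' yields a factor of 3: the region is likely three collapsed copies.
#'
#' @param region list/row with `mean_depth` and `gc`.
#' @param baseline a `coverage_baseline`.
#' @param fallback `"none"` (error on an empty bin) or `"nearest"` (use the
#'   nearest occupied bin; opt-in).
#' @return the correction factor (fold ratio).
#' @export
correction_factor <- function(region, baseline, fallback = c("none", "nearest")) {
  fallback <- match.arg(fallback)
  stopifnot(inherits(baseline, "coverage_baseline"))
  idx <- .gc_bin_index(region$gc, baseline$bin_width)
  ref <- baseline$bins$mean_depth[idx]
  if (is.na(ref)) {
    if (fallback == "none")
      stop(sprintf("GC bin [%.2f, %.2f) has no genome-wide coverage data",
                   baseline$bins$gc_lower[idx],
                   baseline$bins$gc_lower[idx] + baseline$bin_width))
    occ <- which(!is.na(baseline$bins$mean_depth))
    idx <- occ[which.min(abs(occ - idx))]
    ref <- baseline$bins$mean_depth[idx]
  }
  if (ref <= 0) stop("baseline bin mean depth is zero")
  region$mean_depth / ref
}

#' Estimate gene-family copy number from coverage correction factors
#'
#' Multiplies the annotated gene count up by per-gene correction factors:
#' each annotated gene contributes `max(round(c_f), 1)` estimated copies
#' (round half up; a factor below 1 still represents at least the one
#' annotated copy). The unrounded sum is also reported, matching the
#' reading of coverage-based totals as an upper bound.
#'
#' @param regions data.frame of annotated gene regions with columns
#'   `id`, `mean_depth`, `gc` (and optionally `length`).
#' @param baseline a `coverage_baseline`.
#' @param fallback empty-bin policy passed to [correction_factor()].
#' @return object of class `repertoire_estimate`: `annotated_count`,
#'   `per_gene` (data.frame id, factor, copies), `estimated_total`,
#'   `estimated_total_unrounded`.
#' @export
estimate_copy_number <- function(regions, baseline, fallback = "none") {
  cf <- vapply(seq_len(nrow(regions)), function(i)
    correction_factor(regions[i, ], baseline, fallback), numeric(1))
  copies <- pmax(floor(cf + 0.5), 1)       # round half up, floor 1
  structure(list(
    annotated_count = nrow(regions),
    per_gene = data.frame(id = regions$id, factor = cf, copies = copies),
    estimated_total = as.integer(sum(copies)),
    estimated_total_unrounded = sum(pmax(cf, 1))
  ), class = "repertoire_estimate")
}

#' @export
print.repertoire_estimate <- function(x, ...) {
  cat(sprintf("repertoire_estimate: %d annotated -> %d estimated copies (unrounded %.1f)\n",
              x$annotated_count, x$estimated_total,
              x$estimated_total_unrounded))
  invisible(x)
}

#' Classify an open reading frame as intact or pseudogene
#'
#' A gene copy is called a pseudogene if its sequence length is not a
#' multiple of 3 (frameshift proxy), if a premature stop codon occurs
#' before the final codon, or if its translated length falls below
#' `truncation_threshold` of the family reference length.
#'
#' @param orf nucleotide sequence over `A,C,G,T,N`.
#' @param family_reference_length reference protein length of the family
#'   (amino acids).
#' @param truncation_threshold fraction of the reference length below
#'   which the copy is a truncation (default 0.8).
#' @return list with `status` (`"intact"` or `"pseudogene"`) and `reason`
#'   (`NA`, `"frameshift"`, `"premature_stop"` or `"truncation"`).
#' @export
classify_gene <- function(orf, family_reference_length,
                          truncation_threshold = 0.8) {
  orf <- toupper(orf)
  if (!nchar(orf)) stop("empty sequence")
  if (grepl("[^ACGTN]", orf)) stop("sequence must be over A,C,G,T,N")
  if (nchar(orf) %% 3L != 0L)
    return(list(status = "pseudogene", reason = "frameshift"))
  cods <- codon_split(orf)
  stops <- c("TAA", "TAG", "TGA")
  internal <- cods[-length(cods)]
  if (any(internal %in% stops))
    return(list(status = "pseudogene", reason = "premature_stop"))
  aa_len <- length(cods) - (cods[length(cods)] %in% stops)
  if (aa_len < truncation_threshold * family_reference_length)
    return(list(status = "pseudogene", reason = "truncation"))
  list(status = "intact", reason = NA_character_)
}

#' Intact fraction of an estimated repertoire
#'
#' @param intact_count number of intact genes.
#' @param estimated_total estimated total gene count (> 0).
#' @return list with `percent` (full precision) and `percent_integer`.
#' @examples
#' intact_fraction(86, 141)  # 61 %
#' @export
intact_fraction <- function(intact_count, estimated_total) {
  if (estimated_total <= 0) stop("estimated_total must be > 0")
  if (intact_count < 0 || intact_count > estimated_total)
    stop("intact_count must lie in [0, estimated_total]")
  pct <- 100 * intact_count / estimated_total
  list(percent = pct, percent_integer = as.integer(round(pct)))
}

#' Read a samtools-depth style TSV
#'
#' @param path TSV with columns `chrom`, `pos` (1-based), `depth`.
#' @return data.frame.
#' @export
read_depth_tsv <- function(path) {
  d <- utils::read.table(path, header = FALSE, sep = "\t",
                         col.names = c("chrom", "pos", "depth"),
                         colClasses = c("character", "integer", "numeric"))
  d
}
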