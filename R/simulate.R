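#' Simulate a codon alignment under the branch model
#'
#' Evolves codon states down the tree: the root is drawn from `pi` and
#' each branch applies the transition matrix of its branch class. An
#' optional constraint-to-neutral `shift` splits one branch into a
#' constrained segment (its class omega) followed by a neutral segment
#' (omega = 1) covering the most recent `fraction` of the branch - the
#' generative model behind dating a loss of function.
#'
#' @param tree [ape::phylo] with branch lengths (substitutions/codon) and
#'   optionally a `foreground` edge vector.
#' @param params a [codon_params()].
#' @param n_codons number of codon columns (0 gives an empty alignment).
#' @param seed integer seed; identical inputs give identical output.
#' @param shift optional `list(taxon = <tip label>, fraction = f)`:
#'   the branch leading to `taxon` spends its final fraction `f` at
#'   omega = 1.
#' @return a [codon_alignment()] with attribute `truth` (list of all
#'   generating parameters).
#' @export
simulate_codon_alignment <- function(tree, params, n_codons, seed,
                                     shift = NULL) {
  set.seed(seed)
  if (is.null(tree$foreground)) tree$foreground <- rep(FALSE, nrow(tree$edge))
  code <- .code()
  ntip <- length(tree$tip.label)
  shift_edge <- NA_integer_
  if (!is.null(shift)) {
    if (!shift$taxon %in% tree$tip.label)
      stop("shift taxon '", shift$taxon, "' not in tree")
    if (shift$fraction < 0 || shift$fraction > 1)
      stop("shift fraction must lie in [0, 1]")
    shift_edge <- which(tree$edge[, 2] == match(shift$taxon, tree$tip.label))
  }
  if (n_codons == 0L) {
    aln <- codon_alignment(stats::setNames(rep("", ntip), tree$tip.label))
    attr(aln, "truth") <- list(params = params, tree = tree, seed = seed,
                               shift = shift)
    return(aln)
  }
  Q_bg <- build_rate_matrix(params, "background")
  Q_fg <- build_rate_matrix(params, "foreground")
  neutral <- codon_params(params$kappa, 1, 1, params$pi)
  Q_neutral <- build_rate_matrix(neutral, "background")

  ord <- rev(ape::reorder.phylo(tree, "postorder", index.only = TRUE))
  root <- tree$edge[ord[1], 1]
  states <- matrix(NA_integer_, nrow = ntip + tree$Nnode, ncol = n_codons)
  states[root, ] <- sample.int(61L, n_codons, replace = TRUE,
                               prob = params$pi)
  for (e in ord) {
    parent <- tree$edge[e, 1]; child <- tree$edge[e, 2]
    t <- tree$edge.length[e]
    Q <- if (tree$foreground[e]) Q_fg else Q_bg
    if (!is.na(shift_edge) && e == shift_edge && shift$fraction > 0) {
      # the shift fraction is a fraction of clock TIME on the branch; the
      # two eras share the synonymous-rate clock, so the neutral era's
      # length in its own scaled units is inflated by the ratio of total
      # substitution rates R(1)/R(omega_class)
      w_class <- if (tree$foreground[e]) params$omega_foreground
                 else params$omega_background
      fl <- .raw_flux(params$kappa, params$pi)
      rate_ratio <- (fl$nonsyn + fl$syn) / (w_class * fl$nonsyn + fl$syn)
      P <- transition_probabilities(Q, t * (1 - shift$fraction), params$pi) %*%
        transition_probabilities(Q_neutral, t * shift$fraction * rate_ratio,
                                 params$pi)
    } else {
      P <- transition_probabilities(Q, t, params$pi)
    }
    cum <- t(apply(P, 1, cumsum))
    u <- stats::runif(n_codons)
    ps <- states[parent, ]
    states[child, ] <- vapply(seq_len(n_codons), function(i)
      sum(cum[ps[i], ] < u[i]) + 1L, integer(1))
  }
  seqs <- vapply(seq_len(ntip), function(i)
    paste(code$sense_codons[states[i, ]], collapse = ""), character(1))
  aln <- codon_alignment(stats::setNames(seqs, tree$tip.label))
  attr(aln, "truth") <- list(params = params, tree = tree, seed = seed,
                             shift = shift)
  aln
}

#' Simulate a windowed coverage track with GC bias and collapsed copies
#'
#' Per-window depth is drawn as
#' `Poisson(mean_depth * gc_bias(gc) * copy_number)` (or exactly that
#' product with `noise = "none"`), emulating read pile-up over a genome in
#' which multi-copy regions have been collapsed into single assembly
#' loci.
#'
#' @param n_windows number of windows.
#' @param window_size window size in bp.
#' @param gc per-window GC fractions (recycled); default drawn uniformly
#'   from 0.3-0.6.
#' @param mean_depth genome-wide mean depth at the bias curve's reference.
#' @param gc_bias function gc -> relative depth multiplier (default flat 1).
#' @param copy_map integer copy number per window (recycled, >= 1).
#' @param noise `"poisson"` or `"none"`.
#' @param seed integer seed.
#' @return list with `windows` (data.frame `chrom,start,end,gc,depth,copy`)
#'   and `truth`.
#' @export
simulate_coverage_track <- function(n_windows, window_size = 500L,
                                    gc = NULL, mean_depth = 35,
                                    gc_bias = function(g) rep(1, length(g)),
                                    copy_map = 1L,
                                    noise = c("poisson", "none"), seed = 1L) {
  noise <- match.arg(noise)
  set.seed(seed)
  if (is.null(gc)) gc <- stats::runif(n_windows, 0.3, 0.6)
  gc <- rep_len(gc, n_windows)
  copy <- rep_len(as.integer(copy_map), n_windows)
  if (any(copy < 1L)) stop("copy numbers must be integers >= 1")
  lambda <- mean_depth * gc_bias(gc) * copy
  depth <- if (noise == "poisson") stats::rpois(n_windows, lambda) else lambda
  win <- data.frame(
    chrom = "sim", start = (seq_len(n_windows) - 1L) * window_size,
    end = seq_len(n_windows) * window_size, gc = gc,
    depth = as.numeric(depth), copy = copy)
  list(windows = win,
       truth = list(mean_depth = mean_depth, copy_map = copy, seed = seed,
                    noise = noise))
}

#' Simulate within-species receptor-family protein alignments
#'
#' Each species' gene family is derived from one shared consensus protein:
#' every site of every gene mutates to a uniformly chosen different
#' residue with the species' divergence probability. Higher divergence
#' yields higher expected per-column Shannon entropy.
#'
#' @param n_species number of species (names `sp1..spN` unless
#'   `divergence` is named).
#' @param genes_per_species sequences per species.
#' @param consensus_length protein length.
#' @param divergence per-species per-site substitution probabilities
#'   (recycled).
#' @param seed integer seed.
#' @return named list of per-species named character vectors of aligned
#'   proteins, with attribute `truth`.
#' @export
simulate_or_family <- function(n_species, genes_per_species = 10L,
                               consensus_length = 300L, divergence = 0.05,
                               seed = 1L) {
  set.seed(seed)
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  sp_names <- names(divergence) %||% paste0("sp", seq_len(n_species))
  divergence <- rep_len(divergence, n_species)   # rep_len drops names
  sp_names <- rep_len(sp_names, n_species)
  consensus <- sample(aa, consensus_length, replace = TRUE)
  out <- lapply(seq_len(n_species), function(s) {
    seqs <- vapply(seq_len(genes_per_species), function(g) {
      x <- consensus
      hit <- stats::runif(consensus_length) < divergence[s]
      if (any(hit))
        x[hit] <- vapply(x[hit], function(orig)
          sample(setdiff(aa, orig), 1L), character(1))
      paste(x, collapse = "")
    }, character(1))
    stats::setNames(seqs, paste0(sp_names[s], "_gene", seq_len(genes_per_species)))
  })
  names(out) <- sp_names
  attr(out, "truth") <- list(divergence = stats::setNames(divergence, sp_names),
                             consensus = paste(consensus, collapse = ""),
                             seed = seed)
  out
}

#' Simulate shotgun reads from a random genome
#'
#' Draws a uniform-ACGT genome, samples read start positions uniformly,
#' and applies independent substitution errors.
#'
#' @param genome_length genome size in bp.
#' @param coverage mean fold coverage (0 gives an empty read set).
#' @param read_length read length (<= genome_length).
#' @param error_rate per-base substitution error probability.
#' @param seed integer seed.
#' @return list with `reads` (character vector), `genome` (string),
#'   `truth`.
#' @export
simulate_reads <- function(genome_length, coverage = 30, read_length = 100L,
                           error_rate = 0, seed = 1L) {
  set.seed(seed)
  if (read_length > genome_length)
    stop("read_length exceeds genome_length")
  bases <- c("A", "C", "G", "T")
  genome <- paste(sample(bases, genome_length, replace = TRUE), collapse = "")
  n_reads <- round(coverage * genome_length / read_length)
  if (n_reads == 0L)
    return(list(reads = character(0), genome = genome,
                truth = list(genome_length = genome_length, seed = seed)))
  starts <- sample.int(genome_length - read_length + 1L, n_reads,
                       replace = TRUE)
  reads <- substring(genome, starts, starts + read_length - 1L)
  if (error_rate > 0) {
    reads <- vapply(reads, function(r) {
      x <- strsplit(r, "")[[1]]
      hit <- stats::runif(length(x)) < error_rate
      if (any(hit))
        x[hit] <- vapply(x[hit], function(b) sample(setdiff(bases, b), 1L),
                         character(1))
      paste(x, collapse = "")
    }, character(1), USE.NAMES = FALSE)
  }
  list(reads = reads, genome = genome,
       truth = list(genome_length = genome_length, coverage = coverage,
                    read_length = read_length, error_rate = error_rate,
                    seed = seed))
}

#' Simulate a gene-category table with planted enrichment
#'
#' Genes are assigned to categories at random (each gene to one category)
#' and flagged significant with probability `sig_fraction`, except in
#' planted categories where the odds of significance are multiplied.
#'
#' @param n_genes number of genes.
#' @param n_categories number of categories.
#' @param sig_fraction baseline probability a gene is significant.
#' @param planted optional `list(category = <index or name>, odds = o)`.
#' @param seed integer seed.
#' @return list with `annotation` (data.frame gene, category),
#'   `significant` (character vector), `truth`.
#' @export
simulate_category_data <- function(n_genes, n_categories = 20L,
                                   sig_fraction = 0.05, planted = NULL,
                                   seed = 1L) {
  set.seed(seed)
  genes <- sprintf("g%04d", seq_len(n_genes))
  cats <- sprintf("cat%02d", seq_len(n_categories))
  assign <- sample(cats, n_genes, replace = TRUE)
  base_odds <- sig_fraction / (1 - sig_fraction)
  odds <- rep(base_odds, n_genes)
  planted_cat <- NULL
  if (!is.null(planted)) {
    planted_cat <- if (is.numeric(planted$category)) cats[planted$category]
                   else planted$category
    odds[assign == planted_cat] <- base_odds * planted$odds
  }
  p_sig <- odds / (1 + odds)
  sig <- genes[stats::runif(n_genes) < p_sig]
  list(annotation = data.frame(gene = genes, category = assign),
       significant = sig,
       truth = list(sig_fraction = sig_fraction, planted = planted,
                    planted_category = planted_cat, seed = seed))
}

#' Simulate orthologs of conserved elements at planted divergence levels
#'
#' Each element receives exactly `round(divergence * length)` substitutions
#' at distinct positions (each to a different base), so the realized
#' divergence equals the planted level up to rounding - the screen's
#' recovery can then be scored exactly.
#'
#' @param catalog data.frame `id`, `sequence`.
#' @param divergence_map named numeric vector id -> divergence in `[0, 1]`
#'   (or a single value recycled).
#' @param seed integer seed.
#' @return named character vector of ortholog sequences with attribute
#'   `truth` (per-element planted substitution counts).
#' @export
simulate_ucne_orthologs <- function(catalog, divergence_map, seed = 1L) {
  set.seed(seed)
  if (is.null(names(divergence_map)))
    divergence_map <- stats::setNames(rep_len(divergence_map, nrow(catalog)),
                                      catalog$id)
  if (any(divergence_map > 1)) stop("divergence must be <= 1")
  if (any(divergence_map < 0)) stop("divergence must be >= 0")
  bases <- c("A", "C", "G", "T")
  n_sub <- integer(nrow(catalog))
  orth <- vapply(seq_len(nrow(catalog)), function(i) {
    s <- strsplit(toupper(catalog$sequence[i]), "")[[1]]
    d <- divergence_map[[catalog$id[i]]]
    k <- round(d * length(s))
    n_sub[i] <<- k
    if (k > 0) {
      pos <- sample.int(length(s), k)
      s[pos] <- vapply(s[pos], function(b) sample(setdiff(bases, b), 1L),
                       character(1))
    }
    paste(s, collapse = "")
  }, character(1))
  names(orth) <- catalog$id
  attr(orth, "truth") <- list(divergence = divergence_map,
                              n_substitutions = stats::setNames(n_sub, catalog$id),
                              seed = seed)
  orth
}
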