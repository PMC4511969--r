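#' Run the gene-level selection screen with category enrichment
#'
#' For each ortholog alignment: apply the frameshift-free filter (or fall
#' back to the longest clean block), fit the one-ratio and foreground /
#' background branch models, and test the contrast by LRT. Genes
#' significant at `alpha` (uncorrected, per the two-stage design: the
#' multiplicity burden lives at the category level) are split into faster
#' (omega_fg > omega_bg) and slower sets and fed to the hypergeometric
#' enrichment screen with FWER correction and the relaxed
#' three-criterion filter. A failing gene is logged and skipped, never
#' fatal unless every gene fails.
#'
#' @param alignments named list of [codon_alignment()]s (or a directory of
#'   FASTA files, read via [read_codon_fasta()]).
#' @param tree [ape::phylo] covering the alignments' taxa.
#' @param foreground tip label(s) to tag as foreground.
#' @param annotation optional gene-category data.frame for enrichment.
#' @param alpha per-gene significance level.
#' @param min_block_len minimum clean-block length for the fallback filter.
#' @return list of class `selection_screen`: `gene_table` (per-gene fits
#'   and LRT), `faster`, `slower` (gene id vectors), `enrichment_faster`,
#'   `enrichment_slower` (or NULL without annotation), `skipped`
#'   (data.frame id, reason), `filter_log`.
#' @export
run_selection_screen <- function(alignments, tree, foreground,
                                 annotation = NULL, alpha = 0.05,
                                 min_block_len = 200L) {
  if (is.character(alignments) && length(alignments) == 1L) {
    files <- list.files(alignments, pattern = "\\.(fa|fasta|fna)$",
                        full.names = TRUE)
    if (!length(files)) stop("no FASTA files in '", alignments, "'")
    alignments <- stats::setNames(
      lapply(files, function(f)
        tryCatch(read_codon_fasta(f), error = function(e) e$message)),
      sub("\\.[^.]*$", "", basename(files)))
  }
  if (!length(alignments)) stop("empty ortholog set")
  tree <- tag_foreground(tree, foreground)
  skipped <- list(); rows <- list()
  n_set1 <- 0L; n_block <- 0L
  for (id in names(alignments)) {
    aln <- alignments[[id]]
    if (is.character(aln)) {
      skipped[[id]] <- aln; next
    }
    used <- "set1"
    if (!filter_set1(aln)) {
      blk <- longest_clean_block(aln, min_len = min_block_len)
      if (is.null(blk)) {
        skipped[[id]] <- sprintf(
          "fails frameshift filter and has no clean block >= %d bp",
          min_block_len)
        next
      }
      aln <- blk$alignment
      used <- "clean_block"
      n_block <- n_block + 1L
    } else n_set1 <- n_set1 + 1L
    res <- tryCatch({
      fit0 <- fit_model(aln, tree, "one-ratio")
      fit1 <- fit_model(aln, tree, "two-ratio",
                        init = list(kappa = fit0$params$kappa,
                                    omega = fit0$params$omega_background,
                                    omega_fg = fit0$params$omega_background,
                                    branch_lengths = fit0$tree$edge.length))
      lrt <- branch_lrt(fit0, fit1, alpha)
      data.frame(gene = id, filter = used, n_codons = aln$n_codons,
                 lnL0 = fit0$lnL, lnL1 = fit1$lnL,
                 omega_one = fit0$params$omega_background,
                 omega_background = lrt$omega_background,
                 omega_foreground = lrt$omega_foreground,
                 lrt = lrt$statistic, pvalue = lrt$pvalue,
                 significant = lrt$significant,
                 converged = fit0$converged && fit1$converged)
    }, error = function(e) e$message)
    if (is.character(res)) skipped[[id]] <- res else rows[[id]] <- res
  }
  if (!length(rows))
    stop("all genes failed: ", paste(unlist(skipped), collapse = "; "))
  gene_table <- do.call(rbind, rows)
  rownames(gene_table) <- NULL
  faster <- gene_table$gene[gene_table$significant &
                              gene_table$omega_foreground >
                                gene_table$omega_background]
  slower <- gene_table$gene[gene_table$significant &
                              gene_table$omega_foreground <
                                gene_table$omega_background]
  enr <- function(sig) {
    if (is.null(annotation) || !length(sig)) return(NULL)
    sig <- intersect(sig, annotation$gene)
    if (!length(sig)) return(NULL)
    relaxed_filter(fwer_correct(
      hypergeometric_enrichment(annotation, sig)))
  }
  structure(list(
    gene_table = gene_table, faster = faster, slower = slower,
    enrichment_faster = enr(faster), enrichment_slower = enr(slower),
    skipped = data.frame(gene = names(skipped),
                         reason = unlist(skipped, use.names = FALSE)),
    filter_log = list(set1_passed = n_set1, clean_block_used = n_block,
                      skipped = length(skipped))
  ), class = "selection_screen")
}

#' @export
print.selection_screen <- function(x, ...) {
  cat(sprintf("selection_screen: %d genes fitted (%d faster, %d slower at alpha), %d skipped\n",
              nrow(x$gene_table), length(x$faster), length(x$slower),
              nrow(x$skipped)))
  invisible(x)
}

#' All-synthetic nocturnality report
#'
#' Runs a compact, fully synthetic instance of every analysis stage -
#' selection screen, loss-of-function dating, GC-corrected repertoire
#' estimate, entropy comparison, k-mer genome size, UCNE screen - and
#' collates the results into one JSON-serializable list. A stage that
#' fails is marked absent; the run continues.
#'
#' @param config list of per-stage settings; see Details. Only `seed` is
#'   required; every stage has defaults sized for a quick demonstration.
#' @param stages character vector naming stages to run (default all).
#' @details Config entries (all optional): `seed`; `selection` (list:
#'   `n_genes`, `n_codons`, `omega_fg_planted`); `dating` (list:
#'   `omega_constrained`, `duration_my`, `shift_fraction`); `repertoire`
#'   (list: `n_genes`, `copy_numbers`); `entropy` (list: `divergence`);
#'   `genome` (list: `genome_length`, `coverage`); `ucne` (list:
#'   `n_elements`, `n_diverged`).
#' @return list of class `nocturnality_report` with one entry per stage
#'   plus `manifest` (config snapshot and seeds).
#' @export
run_nocturnality_report <- function(config = list(seed = 1L),
                                    stages = c("selection", "dating",
                                               "repertoire", "entropy",
                                               "genome", "ucne")) {
  seed <- config$seed %||% 1L
  report <- list()
  run_stage <- function(name, fun) {
    if (!name %in% stages) return(NULL)
    tryCatch(fun(), error = function(e)
      list(status = "absent", error = conditionMessage(e)))
  }

  report$selection <- run_stage("selection", function() {
    cfg <- config$selection %||% list()
    n_genes <- cfg$n_genes %||% 6L
    n_codons <- cfg$n_codons %||% 150L
    tr <- demo_bird_tree()
    alns <- lapply(seq_len(n_genes), function(g) {
      w_fg <- if (g == 1L) cfg$omega_fg_planted %||% 2 else 0.3
      simulate_codon_alignment(
        tr, codon_params(2, 0.3, w_fg), n_codons, seed = seed + 100L + g)
    })
    names(alns) <- sprintf("gene%02d", seq_len(n_genes))
    scr <- run_selection_screen(alns, tr, foreground = "kiwi")
    list(status = "ok",
         table = scr$gene_table[, c("gene", "omega_background",
                                    "omega_foreground", "lrt", "pvalue",
                                    "significant")],
         faster = scr$faster, slower = scr$slower)
  })

  report$dating <- run_stage("dating", function() {
    cfg <- config$dating %||% list()
    wc <- cfg$omega_constrained %||% 0.021
    T_my <- cfg$duration_my %||% 50
    f <- cfg$shift_fraction %||% 0.4
    w_obs <- wc * (1 - f) + f      # branch-average omega under the mixture
    list(status = "ok", omega_obs = w_obs, omega_constrained = wc,
         duration_my = T_my,
         t_loss_my = date_loss_of_function(w_obs, wc, T_my))
  })

  report$repertoire <- run_stage("repertoire", function() {
    cfg <- config$repertoire %||% list()
    n_genes <- cfg$n_genes %||% 20L
    copies <- rep_len(cfg$copy_numbers %||% c(1L, 1L, 1L, 2L, 3L), n_genes)
    sim <- simulate_coverage_track(2000L, mean_depth = 35, seed = seed)
    base <- gc_windows_baseline(sim$windows)
    genes <- simulate_coverage_track(n_genes, mean_depth = 35,
                                     copy_map = copies, seed = seed + 1L)
    regions <- data.frame(id = sprintf("or%02d", seq_len(n_genes)),
                          mean_depth = genes$windows$depth,
                          gc = genes$windows$gc)
    est <- estimate_copy_number(regions, base)
    list(status = "ok", annotated = est$annotated_count,
         estimated_total = est$estimated_total,
         true_total = sum(copies))
  })

  report$entropy <- run_stage("entropy", function() {
    cfg <- config$entropy %||% list()
    div <- cfg$divergence %||% c(kiwi = 0.12, chicken = 0.08,
                                 zebra_finch = 0.03)
    fam <- simulate_or_family(length(div), divergence = div, seed = seed)
    prof <- lapply(names(fam), function(s)
      species_entropy_summary(fam[[s]], species = s))
    names(prof) <- names(fam)
    means <- vapply(prof, `[[`, numeric(1), "mean_H")
    list(status = "ok",
         mean_H = means,
         sd_H = vapply(prof, `[[`, numeric(1), "sd_H"))
  })

  report$genome <- run_stage("genome", function() {
    cfg <- config$genome %||% list()
    gl <- cfg$genome_length %||% 20000L
    sim <- simulate_reads(gl, coverage = cfg$coverage %||% 30,
                          read_length = 100L, seed = seed)
    est <- estimate_genome_size(kmer_histogram(sim$reads, 19L),
                                read_length = 100L)
    list(status = "ok", true_size = gl, estimated_size = est$size,
         peak_depth = est$peak_depth)
  })

  report$ucne <- run_stage("ucne", function() {
    cfg <- config$ucne %||% list()
    n <- cfg$n_elements %||% 40L
    n_div <- cfg$n_diverged %||% 4L
    catalog <- synthetic_ucne_catalog(n, seed = seed)
    dmap <- stats::setNames(c(rep(0.08, n_div), rep(0.01, n - n_div)),
                            catalog$id)
    orth <- simulate_ucne_orthologs(catalog, dmap, seed = seed + 1L)
    scr <- screen_catalog(catalog, orth)
    list(status = "ok", n_screened = scr$n_screened,
         n_flagged = scr$n_flagged, planted = n_div)
  })

  report$manifest <- list(seed = seed, config = config, stages = stages,
                          package_version =
                            as.character(utils::packageVersion("aptevo")))
  structure(report, class = "nocturnality_report")
}

#' A small eight-taxon bird tree for demonstrations and simulations
#'
#' Ratites and night birds around a kiwi foreground branch, with branch
#' lengths in expected substitutions per codon.
#'
#' @param foreground tip to tag (default `"kiwi"`).
#' @return a tagged [ape::phylo].
#' @export
demo_bird_tree <- function(foreground = "kiwi") {
  txt <- paste0(
    "(((kiwi:0.15,ostrich:0.12):0.05,tinamou:0.14):0.04,",
    "((owl:0.10,nightjar:0.11):0.05,",
    "(chicken:0.08,(zebrafinch:0.09,turkey:0.07):0.03):0.04):0.03);")
  tag_foreground(ape::read.tree(text = txt), foreground)
}

#' Coverage baseline from a simulated window table
#'
#' Bins the per-window depths of [simulate_coverage_track()] output by GC
#' content (the per-window analogue of [gc_binned_baseline()], which
#' works from a per-base depth track).
#'
#' @param windows data.frame with `gc` and `depth` columns.
#' @param bin_width GC bin width.
#' @return a `coverage_baseline`.
#' @export
gc_windows_baseline <- function(windows, bin_width = 0.01) {
  if (!nrow(windows)) stop("empty window table")
  idx <- .gc_bin_index(windows$gc, bin_width)
  n_bins <- ceiling(1 / bin_width)
  means <- rep(NA_real_, n_bins)
  agg <- tapply(windows$depth, idx, mean)
  means[as.integer(names(agg))] <- as.numeric(agg)
  counts <- integer(n_bins)
  cnt <- table(idx)
  counts[as.integer(names(cnt))] <- as.integer(cnt)
  structure(list(
    bin_width = bin_width,
    bins = data.frame(gc_lower = (seq_len(n_bins) - 1L) * bin_width,
                      mean_depth = means, n_windows = counts),
    genome_wide_mean = mean(windows$depth)
  ), class = "coverage_baseline")
}

#' Synthetic conserved-element catalog
#'
#' Random-sequence stand-ins for a conserved-element database, used by
#' simulations and examples (synthetic: these are not real UCNEs).
#'
#' @param n_elements number of elements.
#' @param length_range inclusive bp range to draw lengths from (> 200).
#' @param seed integer seed.
#' @return data.frame `id`, `sequence`, `gene`.
#' @export
synthetic_ucne_catalog <- function(n_elements, length_range = c(250L, 500L),
                                   seed = 1L) {
  set.seed(seed)
  lens <- sample(seq(length_range[1], length_range[2]), n_elements,
                 replace = TRUE)
  data.frame(
    id = sprintf("uce%03d", seq_len(n_elements)),
    sequence = vapply(lens, function(L)
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
      character(1)),
    gene = sprintf("gene%03d", seq_len(n_elements)))
}
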