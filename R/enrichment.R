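#' Hypergeometric category enrichment
#'
#' For each category, the upper-tail hypergeometric probability of drawing
#' at least the observed number of significant genes: with `N` genes in
#' the universe, `K` of them in the category, and `n` significant genes
#' overall, `p = P(X >= k)` for the observed overlap `k`.
#'
#' @param annotation data.frame with columns `gene` and `category`
#'   (one pair per row, pre-propagated if ancestral terms are wanted);
#'   the universe is the set of annotated genes.
#' @param significant_genes character vector of significant genes; must
#'   all be in the universe.
#' @param universe optional explicit universe; defaults to all genes seen
#'   in `annotation`.
#' @return data.frame of enrichment rows: `category`, `n_universe`,
#'   `n_category`, `n_significant_total`, `n_significant_in_category`,
#'   `pvalue`.
#' @export
hypergeometric_enrichment <- function(annotation, significant_genes,
                                      universe = NULL) {
  if (is.null(universe)) universe <- unique(annotation$gene)
  outside <- setdiff(significant_genes, universe)
  if (length(outside))
    stop("significant genes outside the annotation universe: ",
         paste(outside, collapse = ", "))
  N <- length(universe)
  n <- length(unique(significant_genes))
  cats <- split(annotation$gene, annotation$category)
  rows <- lapply(names(cats), function(cat) {
    members <- unique(cats[[cat]])
    K <- length(members)
    k <- length(intersect(members, significant_genes))
    data.frame(category = cat, n_universe = N, n_category = K,
               n_significant_total = n, n_significant_in_category = k,
               pvalue = stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE))
  })
  do.call(rbind, rows)
}

#' Family-wise error rate correction
#'
#' @param rows enrichment data.frame from [hypergeometric_enrichment()].
#' @param method `"bonferroni"` (default) or `"holm"`.
#' @return `rows` with an added `fwer_adjusted` column (capped at 1).
#' @export
fwer_correct <- function(rows, method = c("bonferroni", "holm")) {
  method <- match.arg(method)
  rows$fwer_adjusted <- stats::p.adjust(rows$pvalue, method = method)
  rows
}

#' The relaxed three-criterion enrichment filter
#'
#' After family-wise correction leaves nothing significant, categories are
#' retained for interpretation if all of: (1) raw `p < 0.05`; (2) at least
#' 3 significant genes in the category; (3) the significant genes make up
#' at least 5 % of the genes annotated to the category.
#'
#' @param rows enrichment data.frame.
#' @param p_threshold raw p-value threshold (default 0.05, strict `<`).
#' @param min_genes minimum significant genes in the category (default 3).
#' @param min_fraction minimum significant fraction of the category
#'   (default 0.05, `>=`).
#' @return `rows` with an added logical `passes_relaxed` column.
#' @export
relaxed_filter <- function(rows, p_threshold = 0.05, min_genes = 3L,
                           min_fraction = 0.05) {
  rows$passes_relaxed <- rows$pvalue < p_threshold &
    rows$n_significant_in_category >= min_genes &
    rows$n_significant_in_category >= min_fraction * rows$n_category
  rows
}

#' Species-specific vs shared enriched categories
#'
#' Given the per-species sets of categories passing the screen, labels the
#' focal species' categories as species-specific (absent from every other
#' species) or shared (annotated with the co-occurring species).
#'
#' @param per_species named list: species -> character vector of passing
#'   categories.
#' @param focal name of the focal species (must be in the list).
#' @return list with `specific` (character vector) and `shared`
#'   (data.frame `category`, `shared_with` comma-separated).
#' @export
species_specific_categories <- function(per_species, focal) {
  if (!focal %in% names(per_species))
    stop("focal species '", focal, "' not in the per-species map")
  focal_set <- per_species[[focal]]
  others <- per_species[setdiff(names(per_species), focal)]
  shared_rows <- lapply(focal_set, function(cat) {
    with_sp <- names(others)[vapply(others, function(s) cat %in% s, logical(1))]
    if (length(with_sp))
      data.frame(category = cat, shared_with = paste(with_sp, collapse = ","))
    else NULL
  })
  shared <- do.call(rbind, shared_rows)
  if (is.null(shared))
    shared <- data.frame(category = character(0), shared_with = character(0))
  list(specific = setdiff(focal_set, shared$category), shared = shared)
}

#' Read a gene-category annotation TSV
#'
#' @param path TSV with two columns `gene`, `category`.
#' @return data.frame.
#' @export
read_annotation_tsv <- function(path) {
  utils::read.table(path, header = FALSE, sep = "\t",
                    col.names = c("gene", "category"),
                    colClasses = "character")
}
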