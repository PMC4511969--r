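test_that("hypergeometric p matches exact enumeration", {
  # N=10, K=5, n=4, k=3: C(5,3)C(5,1) + C(5,4)C(5,0) over C(10,4) = 55/210
  ann <- data.frame(gene = sprintf("g%02d", 1:10),
                    category = rep(c("inCat", "other"), each = 5))
  sig <- c("g01", "g02", "g03", "g06")
  rows <- hypergeometric_enrichment(ann, sig)
  expect_equal(rows$pvalue[rows$category == "inCat"], 55 / 210,
               tolerance = 1e-12)
  expect_equal(rows$pvalue[rows$category == "inCat"],
               enumerate_hypergeom_p(10, 5, 4, 3), tolerance = 1e-12)
})

test_that("hypergeometric p matches enumeration across small configurations", {
  for (cfg in list(c(N = 8, K = 3, n = 4, k = 2),
                   c(N = 12, K = 6, n = 5, k = 4),
                   c(N = 11, K = 4, n = 6, k = 1),
                   c(N = 12, K = 12, n = 5, k = 5))) {
    genes <- sprintf("g%02d", seq_len(cfg["N"]))
    ann <- data.frame(
      gene = genes,
      category = c(rep("A", cfg["K"]), rep("B", cfg["N"] - cfg["K"])))
    if (cfg["K"] == cfg["N"]) ann$category <- "A"
    sig <- c(genes[seq_len(cfg["k"])],
             genes[cfg["K"] + seq_len(cfg["n"] - cfg["k"])])
    p_pkg <- hypergeometric_enrichment(ann, sig)
    p_pkg <- p_pkg$pvalue[p_pkg$category == "A"]
    expect_equal(p_pkg,
                 enumerate_hypergeom_p(cfg["N"], cfg["K"], cfg["n"], cfg["k"]),
                 tolerance = 1e-10,
                 label = paste(cfg, collapse = ","))
  }
})

test_that("degenerate cases give p = 1", {
  ann <- data.frame(gene = c("a", "b", "c"), category = "all")
  expect_equal(hypergeometric_enrichment(ann, character(0))$pvalue, 1)
  expect_equal(hypergeometric_enrichment(ann, c("a", "b"))$pvalue, 1)
})

test_that("genes outside the universe are reported by name", {
  ann <- data.frame(gene = c("a", "b"), category = "x")
  expect_error(hypergeometric_enrichment(ann, c("a", "zz")), "zz")
})

test_that("FWER correction: Bonferroni multiplies, Holm dominates", {
  rows <- data.frame(category = sprintf("c%02d", 1:20), pvalue = 0.01)
  bonf <- fwer_correct(rows, "bonferroni")
  expect_equal(bonf$fwer_adjusted, rep(0.20, 20))
  single <- fwer_correct(data.frame(category = "c", pvalue = 0.03))
  expect_equal(single$fwer_adjusted, 0.03)
  set.seed(1)
  rnd <- data.frame(category = sprintf("c%02d", 1:15),
                    pvalue = runif(15, 0, 0.2))
  holm <- fwer_correct(rnd, "holm")$fwer_adjusted
  bonf2 <- fwer_correct(rnd, "bonferroni")$fwer_adjusted
  expect_true(all(holm <= bonf2 + 1e-15))
  expect_true(all(holm >= rnd$pvalue))
  expect_true(all(bonf2 <= 1))
})

test_that("relaxed filter applies its three criteria with exact boundaries", {
  mk <- function(p, k, K) data.frame(category = "c", pvalue = p,
                                     n_significant_in_category = k,
                                     n_category = K)
  expect_true(relaxed_filter(mk(0.04, 3, 60))$passes_relaxed)    # 5 % exactly
  expect_false(relaxed_filter(mk(0.04, 2, 10))$passes_relaxed)   # k = 2 fails
  expect_false(relaxed_filter(mk(0.04, 3, 100))$passes_relaxed)  # 3 % < 5 %
  expect_false(relaxed_filter(mk(0.05, 3, 10))$passes_relaxed)   # p not < .05
  expect_true(relaxed_filter(mk(0.049, 3, 10))$passes_relaxed)
})

test_that("relaxed filter is monotone in p and k", {
  base <- data.frame(category = "c", pvalue = 0.03,
                     n_significant_in_category = 4, n_category = 40)
  expect_true(relaxed_filter(base)$passes_relaxed)
  better_p <- base; better_p$pvalue <- 0.001
  more_k <- base; more_k$n_significant_in_category <- 10
  expect_true(relaxed_filter(better_p)$passes_relaxed)
  expect_true(relaxed_filter(more_k)$passes_relaxed)
})

test_that("species-specific assignment separates shared categories", {
  per_species <- list(kiwi = c("vision", "mito", "feeding"),
                      ostrich = c("vision"),
                      owl = c("anion_channel"))
  res <- species_specific_categories(per_species, "kiwi")
  expect_setequal(res$specific, c("mito", "feeding"))
  expect_equal(res$shared$category, "vision")
  expect_equal(res$shared$shared_with, "ostrich")
  empty <- species_specific_categories(list(kiwi = character(0),
                                            owl = "x"), "kiwi")
  expect_length(empty$specific, 0)
  expect_equal(nrow(empty$shared), 0L)
  expect_error(species_specific_categories(per_species, "moa"), "focal")
})

test_that("planted 10-fold enrichment passes the relaxed filter", {
  hits <- vapply(1:10, function(s) {
    sim <- simulate_category_data(1000L, n_categories = 10L,
                                  sig_fraction = 0.05,
                                  planted = list(category = 1L, odds = 10),
                                  seed = 600 + s)
    rows <- relaxed_filter(fwer_correct(
      hypergeometric_enrichment(sim$annotation, sim$significant)))
    rows$passes_relaxed[rows$category == sim$truth$planted_category]
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
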