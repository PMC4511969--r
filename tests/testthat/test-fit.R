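test_that("one-ratio omega is recovered from simulated data", {
  tr <- demo_bird_tree()
  truth <- codon_params(2, 0.3)
  aln <- simulate_codon_alignment(tr, truth, 500, seed = 21)
  fit <- fit_model(aln, tr, "one-ratio")
  expect_true(fit$converged)
  expect_lt(abs(fit$params$omega_background - 0.3), 0.05)
  expect_lt(abs(fit$params$kappa - 2) / 2, 0.25)
})

test_that("identical sequences drive branch lengths to the lower bound", {
  tr <- small_star_tree(0.1)
  aln <- codon_alignment(c(a = strrep("ATGAAACCC", 20),
                           b = strrep("ATGAAACCC", 20),
                           c = strrep("ATGAAACCC", 20)))
  fit <- fit_model(aln, tr, "one-ratio")
  expect_lt(max(fit$tree$edge.length), 1e-4)
})

test_that("two-ratio lnL dominates one-ratio lnL on the same data (nesting)", {
  tr <- demo_bird_tree()
  aln <- simulate_codon_alignment(tr, codon_params(2, 0.3), 200, seed = 9)
  f0 <- fit_model(aln, tr, "one-ratio")
  f1 <- fit_model(aln, tr, "two-ratio",
                  init = list(kappa = f0$params$kappa,
                              omega = f0$params$omega_background,
                              omega_fg = f0$params$omega_background,
                              branch_lengths = f0$tree$edge.length))
  expect_gte(f1$lnL, f0$lnL - 1e-6)
})

test_that("two-ratio fit recovers a planted foreground shift", {
  tr <- demo_bird_tree()
  truth <- codon_params(2, 0.2, omega_foreground = 1.2)
  aln <- simulate_codon_alignment(tr, truth, 600, seed = 33)
  f1 <- fit_model(aln, tr, "two-ratio")
  expect_lt(abs(f1$params$omega_background - 0.2), 0.06)
  expect_gt(f1$params$omega_foreground, 0.7)
})

test_that("LRT requires matching models and alignments", {
  tr <- demo_bird_tree()
  aln1 <- simulate_codon_alignment(tr, codon_params(), 60, seed = 1)
  aln2 <- simulate_codon_alignment(tr, codon_params(), 60, seed = 2)
  f0 <- fit_model(aln1, tr, "one-ratio")
  f1_other <- fit_model(aln2, tr, "two-ratio")
  expect_error(branch_lrt(f0, f0), "one-ratio")
  expect_error(branch_lrt(f0, f1_other), "different alignments")
})

test_that("equal likelihoods give statistic 0, p 1, not significant", {
  f0 <- structure(list(model_id = "one-ratio", lnL = -100,
                       alignment_id = "x",
                       params = codon_params(2, 0.3)),
                  class = "branch_model_fit")
  f1 <- structure(list(model_id = "two-ratio", lnL = -100,
                       alignment_id = "x",
                       params = codon_params(2, 0.3, 0.3)),
                  class = "branch_model_fit")
  lrt <- branch_lrt(f0, f1)
  expect_equal(lrt$statistic, 0)
  expect_equal(lrt$pvalue, 1)
  expect_false(lrt$significant)
})

test_that("omega error shrinks with alignment length (in expectation)", {
  tr <- ape::read.tree(text = "((a:0.2,b:0.2):0.1,(c:0.2,d:0.2):0.1);")
  truth <- codon_params(2, 0.3)
  err <- function(n_codons, reps) {
    mean(vapply(seq_len(reps), function(r) {
      aln <- simulate_codon_alignment(tr, truth, n_codons,
                                      seed = 7000 + 17 * r + n_codons)
      abs(fit_model(aln, tr, "one-ratio")$params$omega_background - 0.3)
    }, numeric(1)))
  }
  expect_gt(err(80L, 6L), err(400L, 6L))
})

test_that("pairwise Ka/Ks handles identical and diverged pairs", {
  same <- strrep("ATGGCTAAATGC", 25)
  res <- pairwise_kaks(same, same)
  expect_equal(res$Ka, 0)
  expect_equal(res$Ks, 0)
  expect_true(res$undefined)

  # 1500 codons: at total divergence 0.4 the standard error of omega-hat
  # is ~0.04, so the 0.1 recovery band is ~2.5 SE
  tr2 <- ape::read.tree(text = "(A:0.2,B:0.2);")
  truth <- codon_params(2, 0.5)
  aln <- simulate_codon_alignment(tr2, truth, 1500, seed = 77)
  res2 <- pairwise_kaks(aln$sequences[1], aln$sequences[2])
  expect_false(res2$undefined)
  expect_lt(abs(res2$omega - 0.5), 0.1)
  expect_lt(abs(res2$t - 0.4) / 0.4, 0.25)
})

test_that("pairwise Ka/Ks is internally consistent with fit_model", {
  tr2 <- ape::read.tree(text = "(A:0.15,B:0.15);")
  aln <- simulate_codon_alignment(tr2, codon_params(2, 0.4), 300, seed = 13)
  res <- pairwise_kaks(aln$sequences[1], aln$sequences[2])
  fit <- fit_model(codon_alignment(c(A = aln$sequences[1],
                                     B = aln$sequences[2])),
                   tr2, "one-ratio")
  expect_equal(res$omega, fit$params$omega_background, tolerance = 1e-6)
  expect_equal(res$lnL, fit$lnL, tolerance = 1e-6)
})

test_that("frame violations are rejected", {
  expect_error(pairwise_kaks("ATGA", "ATGA"))
  expect_error(codon_alignment(c(a = "ATGA", b = "ATGA")), "divisible by 3")
})
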