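test_that("every generator is deterministic in its seed", {
  tr <- demo_bird_tree()
  p <- codon_params(2, 0.3)
  a1 <- simulate_codon_alignment(tr, p, 30, seed = 5)
  a2 <- simulate_codon_alignment(tr, p, 30, seed = 5)
  expect_identical(a1$sequences, a2$sequences)
  expect_false(identical(
    simulate_codon_alignment(tr, p, 30, seed = 6)$sequences, a1$sequences))

  c1 <- simulate_coverage_track(100, seed = 2)
  c2 <- simulate_coverage_track(100, seed = 2)
  expect_identical(c1$windows, c2$windows)

  f1 <- simulate_or_family(2, seed = 3)
  f2 <- simulate_or_family(2, seed = 3)
  expect_identical(f1, f2)

  r1 <- simulate_reads(2000, coverage = 5, seed = 4)
  r2 <- simulate_reads(2000, coverage = 5, seed = 4)
  expect_identical(r1$reads, r2$reads)

  g1 <- simulate_category_data(100, seed = 8)
  g2 <- simulate_category_data(100, seed = 8)
  expect_identical(g1$annotation, g2$annotation)
  expect_identical(g1$significant, g2$significant)

  cat5 <- synthetic_ucne_catalog(5, seed = 9)
  u1 <- simulate_ucne_orthologs(cat5, 0.05, seed = 10)
  u2 <- simulate_ucne_orthologs(cat5, 0.05, seed = 10)
  expect_identical(as.character(u1), as.character(u2))
})

test_that("zero-codon simulation yields a valid empty alignment", {
  aln <- simulate_codon_alignment(demo_bird_tree(), codon_params(), 0,
                                  seed = 1)
  expect_s3_class(aln, "codon_alignment")
  expect_equal(aln$n_codons, 0L)
  expect_length(aln$taxa, 8L)
})

test_that("coverage generator matches its Poisson mean and copy map", {
  sim <- simulate_coverage_track(4000, mean_depth = 35, seed = 11)
  se <- sqrt(35 / 4000)          # Poisson mean SE
  expect_lt(abs(mean(sim$windows$depth) - 35), 4 * se)
  det <- simulate_coverage_track(10, mean_depth = 35, copy_map = 3L,
                                 noise = "none", seed = 1)
  expect_true(all(det$windows$depth == 105))
  expect_error(simulate_coverage_track(10, copy_map = 0L), "integers >= 1")
})

test_that("zero-divergence families are identical; zero-error reads faithful", {
  fam <- simulate_or_family(1, divergence = 0, seed = 2)
  expect_length(unique(fam[[1]]), 1L)
  expect_equal(species_entropy_summary(fam[[1]])$mean_H, 0)

  rd <- simulate_reads(500, coverage = 3, read_length = 50, seed = 6)
  expect_true(all(vapply(rd$reads, function(r)
    grepl(r, rd$genome, fixed = TRUE), logical(1))))
  expect_length(simulate_reads(500, coverage = 0, seed = 1)$reads, 0L)
  expect_error(simulate_reads(100, read_length = 200), "exceeds")
})

test_that("ucne ortholog generator plants exact substitution counts", {
  catalog <- synthetic_ucne_catalog(10, seed = 21)
  orth <- simulate_ucne_orthologs(catalog, 0.08, seed = 22)
  truth <- attr(orth, "truth")
  for (i in seq_len(nrow(catalog))) {
    ref <- strsplit(catalog$sequence[i], "")[[1]]
    obs <- strsplit(orth[[catalog$id[i]]], "")[[1]]
    expect_equal(sum(ref != obs),
                 unname(truth$n_substitutions[catalog$id[i]]))
    expect_equal(sum(ref != obs), round(0.08 * length(ref)))
  }
  expect_error(simulate_ucne_orthologs(catalog, 1.5), "<= 1")
  same <- simulate_ucne_orthologs(catalog, 0, seed = 1)
  expect_identical(unname(as.character(same)), catalog$sequence)
})

test_that("null category data passes the relaxed filter only rarely", {
  rates <- vapply(1:5, function(s) {
    sim <- simulate_category_data(800L, n_categories = 20L,
                                  sig_fraction = 0.05, seed = 700 + s)
    rows <- relaxed_filter(hypergeometric_enrichment(sim$annotation,
                                                     sim$significant))
    mean(rows$passes_relaxed)
  }, numeric(1))
  expect_lt(mean(rates), 0.10)
})

test_that("constraint shift raises the foreground branch's apparent omega", {
  tr <- demo_bird_tree()
  p <- codon_params(2, 0.05)
  plain <- simulate_codon_alignment(tr, p, 400, seed = 31)
  shifted <- simulate_codon_alignment(tr, p, 400, seed = 31,
                                      shift = list(taxon = "kiwi",
                                                   fraction = 0.8))
  w_plain <- fit_model(plain, tr, "two-ratio")$params$omega_foreground
  w_shift <- fit_model(shifted, tr, "two-ratio")$params$omega_foreground
  expect_gt(w_shift, w_plain)
  expect_error(
    simulate_codon_alignment(tr, p, 10, seed = 1,
                             shift = list(taxon = "dodo", fraction = 0.5)),
    "not in tree")
})
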