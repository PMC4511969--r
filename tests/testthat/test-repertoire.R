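.gc_bin <- function(gc, bw = 0.01) floor(gc / bw) + 1L

test_that("GC-binned baseline averages depth per bin and genome-wide", {
  depth <- data.frame(chrom = "c1", pos = 1:400,
                      depth = rep(c(10, 30), each = 200))
  windows <- data.frame(chrom = "c1", start = c(0, 200),
                        end = c(200, 400), gc = c(0.305, 0.505))
  base <- gc_binned_baseline(depth, windows, bin_width = 0.01)
  expect_equal(base$bins$mean_depth[.gc_bin(0.305)], 10)
  expect_equal(base$bins$mean_depth[.gc_bin(0.505)], 30)
  expect_equal(base$genome_wide_mean, 20)
  expect_true(is.na(base$bins$mean_depth[.gc_bin(0.755)]))
})

test_that("uniform depth gives every occupied bin the same mean", {
  depth <- data.frame(chrom = "c1", pos = 1:300, depth = 35)
  windows <- data.frame(chrom = "c1", start = c(0, 100, 200),
                        end = c(100, 200, 300), gc = c(0.35, 0.45, 0.55))
  base <- gc_binned_baseline(depth, windows)
  occ <- !is.na(base$bins$mean_depth)
  expect_true(all(base$bins$mean_depth[occ] == 35))
})

test_that("correction factor divides region depth by its GC-bin mean", {
  base <- coverage_baseline(gc_lower = 0.50, mean_depth = 35)
  expect_equal(correction_factor(list(mean_depth = 105, gc = 0.50), base), 3)
  expect_equal(correction_factor(list(mean_depth = 35, gc = 0.505), base), 1)
  expect_equal(correction_factor(list(mean_depth = 70, gc = 0.509), base), 2)
})

test_that("correction factor is scale invariant", {
  for (scale in c(0.5, 1, 7)) {
    base <- coverage_baseline(gc_lower = c(0.40, 0.50),
                              mean_depth = scale * c(20, 35))
    cf <- correction_factor(list(mean_depth = scale * 105, gc = 0.50), base)
    expect_equal(cf, 3)
  }
})

test_that("empty GC bins error by name unless nearest-bin fallback is chosen", {
  base <- coverage_baseline(gc_lower = 0.50, mean_depth = 35)
  expect_error(correction_factor(list(mean_depth = 40, gc = 0.70), base),
               "\\[0\\.70")
  cf <- correction_factor(list(mean_depth = 70, gc = 0.70), base,
                          fallback = "nearest")
  expect_equal(cf, 2)
})

test_that("copy-number totals sum rounded per-gene factors with floor 1", {
  base <- coverage_baseline(gc_lower = 0.50, mean_depth = 35)
  regions <- data.frame(id = c("g1", "g2", "g3"),
                        mean_depth = c(35, 70, 105), gc = 0.50)
  est <- estimate_copy_number(regions, base)
  expect_equal(est$estimated_total, 6L)
  expect_equal(est$per_gene$copies, c(1, 2, 3))
  # all-unity factors leave the annotated count unchanged
  flat <- data.frame(id = "g", mean_depth = 35, gc = 0.50)
  expect_equal(estimate_copy_number(flat, base)$estimated_total, 1L)
  # sub-unity factors never shrink the annotated count
  low <- data.frame(id = "g", mean_depth = 10, gc = 0.50)
  expect_equal(estimate_copy_number(low, base)$estimated_total, 1L)
})

test_that("collapsed-duplication simulation recovers the true copy total", {
  set.seed(NULL)
  errs <- vapply(1:10, function(s) {
    copies <- rep(c(1L, 1L, 1L, 2L, 3L), length.out = 82L)
    genome <- simulate_coverage_track(3000L, mean_depth = 35, seed = 400 + s)
    base <- gc_windows_baseline(genome$windows)
    fam <- simulate_coverage_track(82L, mean_depth = 35, copy_map = copies,
                                   seed = 500 + s)
    regions <- data.frame(id = sprintf("or%02d", 1:82),
                          mean_depth = fam$windows$depth,
                          gc = fam$windows$gc)
    est <- estimate_copy_number(regions, base, fallback = "nearest")
    abs(est$estimated_total - sum(copies)) / sum(copies)
  }, numeric(1))
  expect_true(all(errs <= 0.10))
})

test_that("pseudogene classification flags stops, frameshifts, truncations", {
  clean <- paste0("ATG", strrep("GCT", 298), "TAA")   # 300 codons, intact
  expect_equal(classify_gene(clean, 299)$status, "intact")
  premature <- paste0("ATG", strrep("GCT", 48), "TAA",
                      strrep("GCT", 249), "TAA")
  res <- classify_gene(premature, 299)
  expect_equal(res$status, "pseudogene")
  expect_equal(res$reason, "premature_stop")
  shifted <- paste0("ATG", strrep("GCT", 100), "G")
  expect_equal(classify_gene(shifted, 299)$reason, "frameshift")
  truncated <- paste0("ATG", strrep("GCT", 208), "TAA")  # 70 % of reference
  res_t <- classify_gene(truncated, 299, truncation_threshold = 0.8)
  expect_equal(res_t$reason, "truncation")
  expect_error(classify_gene("", 100), "empty")
})

test_that("intact fraction reports integer percent", {
  res <- intact_fraction(86, 141)
  expect_equal(res$percent_integer, 61L)
  expect_equal(res$percent, 100 * 86 / 141)
  expect_equal(intact_fraction(0, 10)$percent, 0)
  expect_equal(intact_fraction(10, 10)$percent, 100)
  expect_error(intact_fraction(1, 0), "> 0")
})
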