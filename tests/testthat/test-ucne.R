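test_that("catalog validation enforces strict length and alphabet rules", {
  recs <- data.frame(
    id = c("ok", "short", "exact200", "hasN"),
    sequence = c(strrep("ACGT", 63),          # 252 bp, clean
                 strrep("ACGT", 10),          # 40 bp
                 strrep("ACGT", 50),          # exactly 200 bp: rejected
                 paste0(strrep("ACGT", 63), "N")))
  v <- validate_catalog(recs)
  expect_equal(v$accepted$id, "ok")
  expect_setequal(v$rejected$id, c("short", "exact200", "hasN"))
  expect_match(v$rejected$reason[v$rejected$id == "exact200"], "200")
  expect_match(v$rejected$reason[v$rejected$id == "hasN"], "ACGT")
})

test_that("identical ortholog has zero variation and no flag", {
  s <- strrep("ACGTTGCA", 40)
  v <- variation_fraction(s, s)
  expect_equal(v$variation, 0)
  expect_false(v$flagged)
})

test_that("variation counts substitutions against reference length", {
  set.seed(10)
  mutate_n <- function(s, n) {
    x <- strsplit(s, "")[[1]]
    pos <- sample(seq_along(x), n)
    x[pos] <- vapply(x[pos], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
    paste(x, collapse = "")
  }
  ref250 <- paste(sample(c("A", "C", "G", "T"), 250, replace = TRUE),
                  collapse = "")
  v <- variation_fraction(ref250, mutate_n(ref250, 15))
  expect_equal(v$variation, 15 / 250)   # 0.06 > 0.05
  expect_true(v$flagged)
  ref300 <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
                  collapse = "")
  v2 <- variation_fraction(ref300, mutate_n(ref300, 15))
  expect_equal(v2$variation, 0.05)
  expect_false(v2$flagged)             # strictly > 5 % flags
  expect_error(variation_fraction("", "ACGT"), "empty")
})

test_that("gap columns count toward variation when asked", {
  ref <- strrep("ACGTACGTGGCCAATT", 20)   # 320 bp
  deleted <- paste0(substr(ref, 1, 100), substr(ref, 111, 320))
  v <- variation_fraction(ref, deleted, count_gaps = TRUE)
  expect_gte(v$gap_columns, 10)
  expect_gt(v$variation, 0)
  v_ng <- variation_fraction(ref, deleted, count_gaps = FALSE)
  expect_lt(v_ng$variation, v$variation)
})

test_that("screen flags the planted diverged set and counts missing ids", {
  flag_sets_ok <- vapply(1:10, function(s) {
    catalog <- synthetic_ucne_catalog(100, seed = 200 + s)
    dmap <- stats::setNames(c(rep(0.08, 10), rep(0.01, 90)), catalog$id)
    orth <- simulate_ucne_orthologs(catalog, dmap, seed = 300 + s)
    scr <- screen_catalog(catalog, orth)
    flagged <- scr$table$id[which(scr$table$flagged)]
    setequal(flagged, catalog$id[1:10])
  }, logical(1))
  expect_gte(sum(flag_sets_ok), 9)

  catalog <- synthetic_ucne_catalog(5, seed = 1)
  scr_missing <- screen_catalog(catalog, character(0))
  expect_equal(scr_missing$n_missing, 5L)
  expect_equal(scr_missing$n_flagged, 0L)
})

test_that("per-element threshold overrides the flat screen threshold", {
  catalog <- synthetic_ucne_catalog(2, seed = 4)
  orth <- simulate_ucne_orthologs(
    catalog, stats::setNames(c(0.04, 0.04), catalog$id), seed = 5)
  flat <- screen_catalog(catalog, orth, threshold = 0.05)
  expect_equal(flat$n_flagged, 0L)
  strict <- screen_catalog(
    catalog, orth, threshold = 0.05,
    per_element_threshold = stats::setNames(0.02, catalog$id[1]))
  expect_equal(strict$n_flagged, 1L)
})
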