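test_that("fixture generation is deterministic in the seed", {
  a <- make_repeat_transcript(seed = 42)
  b <- make_repeat_transcript(seed = 42)
  expect_identical(a$transcript$cds, b$transcript$cds)
  expect_identical(a$transcript$context, b$transcript$context)
  c <- make_repeat_transcript(seed = 43)
  expect_false(identical(a$transcript$cds, c$transcript$cds))

  e1 <- make_expression_fixture(seed = 9)
  e2 <- make_expression_fixture(seed = 9)
  expect_identical(e1$folds, e2$folds)

  p1 <- make_peak_fixture(seed = 9, n_peaks = 100)
  p2 <- make_peak_fixture(seed = 9, n_peaks = 100)
  expect_identical(GenomicRanges::start(p1$peaks),
                   GenomicRanges::start(p2$peaks))

  q1 <- make_ct_fixture(seed = 9, noise_sd = 0.3)
  q2 <- make_ct_fixture(seed = 9, noise_sd = 0.3)
  expect_identical(q1$ct$ct, q2$ct$ct)
})

test_that("the default transcript fixture honours its stated geometry", {
  fx <- make_repeat_transcript(seed = 1)
  tr <- fx$truth
  cds <- fx$transcript$cds
  expect_equal(nchar(cds), 4503L)
  expect_equal(tr$run_start_c, 4459L)
  expect_equal(tr$mutation, "c.4467delA")
  expect_equal(substr(cds, 1, 3), "ATG")
  expect_equal(substr(cds, 4459, 4467), strrep("A", 9))
  # no A-run of length >= 2 anywhere outside the planted run
  outside <- paste0(substr(cds, 1, 4458), "|",
                    substr(cds, 4468, nchar(cds)))
  expect_false(grepl("AA", outside, fixed = TRUE))
  # context embeds the CDS at the recorded offset
  expect_equal(substr(fx$transcript$context, 2001, 2000 + 4503), cds)
})

test_that("a minimal single-codon run fixture can be requested", {
  fx <- make_repeat_transcript(codons = 10, run_length = 3,
                               run_end_c = 15, flank = 50, seed = 2)
  reps <- find_coding_repeats(fx$transcript, min_len = 3)
  expect_equal(reps$start_c, 13L)
  expect_equal(reps$length, 3L)
})

test_that("invalid run placements are rejected", {
  expect_error(make_repeat_transcript(run_end_c = 9, run_length = 9),
               "start codon")
  expect_error(make_repeat_transcript(codons = 10, run_end_c = 33),
               "stop codon")
})

test_that("expression fixtures are recovered exactly by the intersection", {
  fx <- make_expression_fixture(n_up = 20, n_down = 30, n_discordant = 50,
                                n_null = 900, seed = 7)
  ci <- clone_intersection(fx$comparison)
  expect_identical(ci$up, fx$truth$up)
  expect_identical(ci$down, fx$truth$down)

  empty <- make_expression_fixture(n_up = 0, n_down = 0, seed = 8)
  ci0 <- clone_intersection(empty$comparison)
  expect_length(ci0$up, 0L)
  expect_length(ci0$down, 0L)
})

test_that("threshold semantics are inclusive at the boundary", {
  folds <- data.frame(gene = c("edge", "near"),
                      c1 = c(1.5, 1.5), c2 = c(1.5, 1.5),
                      c3 = c(1.5, 1.49))
  ci <- clone_intersection(expression_comparison(folds))
  expect_equal(ci$up, "edge")   # 1.5 in all clones: included
  expect_length(ci$down, 0L)    # 1.49 in one clone: excluded
  expect_error(clone_intersection(expression_comparison(folds,
                                                        threshold = 1.0)),
               "greater than 1")
})

test_that("intersection lists shrink monotonically with the threshold", {
  fx <- make_expression_fixture(seed = 10)
  sizes <- vapply(c(1.5, 1.8, 2.2, 3), function(t) {
    ci <- clone_intersection(fx$comparison, threshold = t)
    length(ci$up) + length(ci$down)
  }, numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("fold-change tables round-trip through delimited text", {
  fx <- make_expression_fixture(n_up = 5, n_down = 5, n_discordant = 5,
                                n_null = 20, seed = 11)
  path <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(fx$folds, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  fc <- read_fold_changes(path)
  ci <- clone_intersection(fc)
  expect_identical(ci$up, fx$truth$up)
  expect_identical(ci$down, fx$truth$down)
})

test_that("Ct fixtures honour planted folds, including the null fold", {
  fx <- make_ct_fixture(folds = c(flat = 1.0), seed = 12)
  rq <- relative_quantity(fx$ct, "PRDM2", c("PGK", "TBP", "ACTB"),
                          "parental")
  expect_equal(rq$rq[rq$sample == "flat"], 1)
})
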