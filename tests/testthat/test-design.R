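fixture_design <- function(seed = 1, ...) {
  fx <- make_repeat_transcript(seed = seed, ...)
  t <- fx$transcript
  reps <- find_coding_repeats(t, min_len = 8)
  m <- parse_hgvs_c(fx$truth$mutation)
  list(fx = fx, t = t, r = reps[1L, , drop = FALSE], m = m)
}

test_that("the (A)9/delA case yields exactly the three G insertions", {
  d <- fixture_design()
  edits <- enumerate_stabilizing_edits(d$t, d$r, d$m)
  expect_equal(nrow(edits), 3L)
  expect_equal(edits$position_c, c(4461L, 4464L, 4467L))
  expect_equal(edits$bases, rep("G", 3))
  expect_equal(edits$five_run, c(2L, 5L, 8L))
  expect_equal(edits$three_run, c(6L, 3L, 0L))
  expect_true(all(edits$protein_identical))
  expect_true(all(edits$split))
  # the pure-A re-insertion is excluded by the split requirement, but
  # is visible with include_nonsplit
  all_e <- enumerate_stabilizing_edits(d$t, d$r, d$m,
                                       include_nonsplit = TRUE)
  expect_equal(nrow(all_e), 4L)
  nonsplit <- all_e[!all_e$split, ]
  expect_equal(nonsplit$bases, "A")
  expect_equal(nonsplit$five_run + nonsplit$three_run, 9L)
})

test_that("a single lysine codon admits one splitting correction", {
  cds <- paste0("ATG", "CGC", "AAA", "CGC", "TGA")
  reps <- find_coding_repeats(cds, min_len = 3)
  expect_equal(reps$start_c, 7L)
  m <- frameshift_variant("del", 9, "A")
  edits <- enumerate_stabilizing_edits(cds, reps[1L, ], m)
  expect_equal(nrow(edits), 1L)
  expect_equal(edits$position_c, 9L)  # third codon position -> AAG
  expect_equal(edits$bases, "G")
  expect_equal(c(edits$five_run, edits$three_run), c(2L, 0L))
  st <- stability_report(reps[1L, ], edits[1L, ])
  expect_equal(st$reduction, 1L)
})

test_that("preconditions are enforced as domain errors", {
  d <- fixture_design()
  expect_error(
    enumerate_stabilizing_edits(d$t, d$r, parse_hgvs_c("c.4464insG")),
    "must be a deletion")
  expect_error(
    enumerate_stabilizing_edits(d$t, d$r, parse_hgvs_c("c.100delT")),
    "reference mismatch|does not lie")
  # a deletion elsewhere in the CDS is outside the repeat
  pos <- 300L
  b <- substr(d$t$cds, pos, pos)
  expect_error(
    enumerate_stabilizing_edits(d$t, d$r,
                                frameshift_variant("del", pos, b)),
    "does not lie within")
})

test_that("ambiguous bases in the repeat window abort enumeration", {
  d <- fixture_design()
  cds_n <- paste0(substr(d$t$cds, 1, 4457), "N",
                  substr(d$t$cds, 4459, nchar(d$t$cds)))
  tn <- transcript(cds_n, id = "with_n")
  expect_error(enumerate_stabilizing_edits(tn, d$r, d$m),
               class = "repeatlock_ambiguous")
  verdict <- assess_amenability(tn, d$r, d$m)
  expect_false(verdict$amenable)
  expect_true("AMBIGUOUS_SEQUENCE" %in% verdict$reasons)
})

test_that("ranking reproduces the published pick and is a total order", {
  d <- fixture_design()
  ranked <- rank_edits(enumerate_stabilizing_edits(d$t, d$r, d$m))
  expect_equal(ranked$position_c, c(4464L, 4461L, 4467L))
  expect_equal(ranked$hgvs[1L], "c.4464insG")
  expect_equal(ranked$longest_residual, c(5L, 6L, 8L))

  # comparator-oracle property on random candidate tables
  set.seed(31)
  for (i in 1:50) {
    n <- sample(2:8, 1L)
    fake <- data.frame(
      hgvs = paste0("e", 1:n), anchor = "", position_c = sample(100L, n),
      bases = "G", five_run = sample(0:9, n, replace = TRUE),
      three_run = sample(0:9, n, replace = TRUE),
      stringsAsFactors = FALSE)
    fake$longest_residual <- pmax(fake$five_run, fake$three_run)
    fake$balance <- abs(fake$five_run - fake$three_run)
    fake$protein_identical <- TRUE
    fake$split <- TRUE
    got <- rank_edits(fake)
    key <- order(fake$longest_residual, fake$balance, fake$position_c)
    expect_equal(got$hgvs, fake$hgvs[key])
    # total: re-ranking a shuffled copy gives the same order
    shuf <- fake[sample(n), ]
    expect_equal(rank_edits(shuf)$hgvs, got$hgvs)
  }
})

test_that("emitted edits conserve the protein, split the run and restore frame", {
  n_cases <- 150
  for (i in seq_len(n_cases)) {
    fx <- random_repeat_fixture(seed = 20000 + i)
    tr <- fx$truth
    d <- if (i %% 5 == 0 && tr$run_length >= 8) 2L else 1L
    m <- frameshift_variant("del", tr$run_end_c - (d - 1L),
                            strrep(tr$run_base, d))
    cds <- fx$transcript$cds
    edits <- enumerate_stabilizing_edits(fx$transcript,
                                         data.frame(base = tr$run_base,
                                                    start_c = tr$run_start_c,
                                                    end_c = tr$run_end_c,
                                                    length = tr$run_length),
                                         m)
    if (!nrow(edits)) next
    mutant <- apply_variant(cds, normalize_3prime(m, cds))
    for (j in seq_len(nrow(edits))) {
      edited <- apply_variant(mutant,
                              frameshift_variant("ins",
                                                 edits$position_c[j],
                                                 edits$bases[j]))
      expect_identical(nchar(edited), nchar(cds))
      expect_identical(oracle_translate(edited), oracle_translate(cds))
      expect_lt(edits$longest_residual[j], tr$run_length)
      # for insertions of non-run bases the residual runs partition
      # the mutant tract exactly (re-inserted run bases may instead
      # rejoin it, which the longest-residual bound already covers)
      if (!grepl(tr$run_base, edits$bases[j], fixed = TRUE))
        expect_equal(edits$five_run[j] + edits$three_run[j],
                     tr$run_length - d)
    }
  }
})

test_that("enumeration matches the exhaustive brute-force oracle", {
  n_cases <- 150
  for (i in seq_len(n_cases)) {
    fx <- random_repeat_fixture(seed = 50000 + i)
    tr <- fx$truth
    cds <- fx$transcript$cds
    m <- frameshift_variant("del", tr$run_end_c, tr$run_base)
    r <- data.frame(base = tr$run_base, start_c = tr$run_start_c,
                    end_c = tr$run_end_c, length = tr$run_length)
    edits <- enumerate_stabilizing_edits(fx$transcript, r, m)
    mutant <- apply_variant(cds, m)
    want <- oracle_edit_sequences(
      cds, mutant, max(1L, tr$run_start_c - 3L),
      min(nchar(cds), tr$run_end_c + 3L), 1L,
      run = list(base = tr$run_base, start_c = tr$run_start_c,
                 end_c = tr$run_end_c, length = tr$run_length))
    expect_identical(edit_sequences_of(edits), want)
  }
})

test_that("any equivalent placement of the run deletion gives the same designs", {
  fx <- make_repeat_transcript(seed = 4)
  tr <- fx$truth
  r <- find_coding_repeats(fx$transcript, min_len = 8)[1L, ]
  seqs <- NULL
  for (p in tr$run_start_c:tr$run_end_c) {
    m <- frameshift_variant("del", p, tr$run_base)
    e <- enumerate_stabilizing_edits(fx$transcript, r, m)
    s <- edit_sequences_of(e)
    if (is.null(seqs)) seqs <- s else expect_identical(s, seqs)
  }
})

test_that("amenability verdicts separate sequence- and construct-level failures", {
  d <- fixture_design()
  v <- assess_amenability(d$t, d$r, d$m)
  expect_true(v$amenable)
  expect_equal(v$reasons, "OK")
  expect_equal(v$best_edit$position_c, 4464L)

  # context shorter than the minimum arm length
  short <- make_repeat_transcript(seed = 1, flank = 300)
  reps_s <- find_coding_repeats(short$transcript, min_len = 8)
  v2 <- assess_amenability(short$transcript, reps_s[1L, ],
                           parse_hgvs_c(short$truth$mutation))
  expect_false(v2$amenable)
  expect_true("ARM_DESIGN_FAIL" %in% v2$reasons)
  expect_null(v2$best_edit)
})

test_that("the stability report quantifies the run reduction", {
  d <- fixture_design()
  ranked <- rank_edits(enumerate_stabilizing_edits(d$t, d$r, d$m))
  st <- stability_report(d$r, ranked[1L, ])
  expect_equal(st$wt_run_length, 9L)
  expect_equal(st$mutant_run_length, 8L)
  expect_equal(unname(st$residual_runs), c(5L, 3L))
  expect_equal(st$reduction, 4L)
})
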