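# Shared design pipeline for the construct tests
design_for <- function(seed = 1, ...) {
  fx <- make_repeat_transcript(seed = seed, ...)
  t <- fx$transcript
  reps <- find_coding_repeats(t, min_len = 8)
  m <- parse_hgvs_c(fx$truth$mutation)
  ranked <- rank_edits(enumerate_stabilizing_edits(t, reps[1L, ], m))
  best <- ranked[1L, , drop = FALSE]
  for (a in c("repeat", "mutation", "wt_cds"))
    attr(best, a) <- attr(ranked, a)
  list(fx = fx, t = t, r = reps[1L, ], m = m, best = best)
}

test_that("homology arms carry the split-repeat allele at the junction", {
  d <- design_for()
  arms <- extract_homology_arms(d$t, d$best)
  expect_equal(nchar(arms$ha1), 1000L)
  expect_equal(nchar(arms$ha2), 1000L)
  # HA1 contains the corrected allele: ...AAAAAG followed by AAA...
  expect_match(arms$ha1, "AAAAAGAAA")
  expect_false(grepl(strrep("A", 9), arms$ha1, fixed = TRUE))
  # HA1 ends exactly at the insertion point; HA2 continues from it
  ctx <- arms$corrected_context
  expect_identical(substr(ctx, arms$junction - 999L, arms$junction),
                   arms$ha1)
  expect_identical(substr(ctx, arms$junction + 1L, arms$junction + 1000L),
                   arms$ha2)
  # HA2 is wild-type downstream sequence
  expect_identical(arms$ha2,
                   substr(d$t$context, arms$junction + 1L,
                          arms$junction + 1000L))
})

test_that("insufficient context fails arm extraction with a clear account", {
  short <- make_repeat_transcript(seed = 1, flank = 300)
  t <- short$transcript
  reps <- find_coding_repeats(t, min_len = 8)
  m <- parse_hgvs_c(short$truth$mutation)
  ranked <- rank_edits(enumerate_stabilizing_edits(t, reps[1L, ], m))
  best <- ranked[1L, , drop = FALSE]
  for (a in c("repeat", "mutation", "wt_cds"))
    attr(best, a) <- attr(ranked, a)
  # HA1 fits (CDS upstream) but HA2 runs off the 300-nt flank
  err <- tryCatch(extract_homology_arms(t, best), condition = identity)
  expect_s3_class(err, "repeatlock_arm_fail")
  expect_match(conditionMessage(err), "available")
})

test_that("payload bookkeeping respects the rAAV capacity across arm lengths", {
  d <- design_for()
  cfg <- construct_config()
  for (arm in c(800L, 1000L, 1150L, 1300L)) {
    arms <- extract_homology_arms(d$t, d$best, arm_len = arm)
    con <- targeting_construct(arms, cfg)
    expect_equal(con$payload, 2L * arm + cfg$cassette_len)
    expect_equal(con$payload <= cfg$capacity,
                 2L * arm + cfg$cassette_len <= cfg$capacity)
  }
  expect_error(extract_homology_arms(d$t, d$best, arm_len = 700),
               "outside the configured range")
})

test_that("Gateway arm primers anchor at the termini with the canonical tails", {
  d <- design_for()
  dd <- design_construct_arms(d$t, d$best)
  arm1 <- dd$arms$ha1
  arm2 <- dd$arms$ha2
  p1 <- dd$ha1_primers
  p2 <- dd$ha2_primers
  # cores are exact prefixes / suffix reverse-complements of the arm
  expect_identical(substr(arm1, 1, nchar(p1$fwd$core)), p1$fwd$core)
  expect_identical(
    p1$rev$core,
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(
      substr(arm1, nchar(arm1) - nchar(p1$rev$core) + 1L, nchar(arm1))))))
  # tails: attB1/attB2 vs attB3/attB4, distinct, and absent from the arm
  expect_match(p1$fwd$name, "attB1")
  expect_match(p2$fwd$name, "attB3")
  tails <- c(p1$fwd$tail, p1$rev$tail, p2$fwd$tail, p2$rev$tail)
  expect_equal(length(unique(tails)), 4L)
  for (tl in tails[1:2]) expect_false(grepl(tl, arm1, fixed = TRUE))
  for (tl in tails[3:4]) expect_false(grepl(tl, arm2, fixed = TRUE))
  # full primer sequence is tail + core, Tm within the window
  cfg <- construct_config()
  for (p in list(p1$fwd, p1$rev, p2$fwd, p2$rev)) {
    expect_identical(p$sequence, paste0(p$tail, p$core))
    expect_gte(p$tm, cfg$tm_range[1])
    expect_lte(p$tm, cfg$tm_range[2])
  }
  expect_error(make_gateway_arm_primers(random_dna(50)), "at least 100")
})

test_that("construct layout is HA1 < loxP < cassette < loxP < HA2", {
  d <- design_for()
  dd <- design_construct_arms(d$t, d$best)
  con <- targeting_construct(dd$arms)
  f <- con$features
  lab <- function(l) f[f$label == l, , drop = FALSE]
  lox <- f[f$label == "loxP", ]
  expect_equal(nrow(lox), 2L)
  expect_true(lab("HA1")$end < lox$start[1])
  expect_true(all(lox$end[1] < c(lab("SA")$start, lab("IRES")$start)))
  expect_true(lab("polyA")$end < lox$start[2])
  expect_true(lox$end[2] < lab("HA2")$start)
  # loxP sites flank the cassette and nothing else
  expect_equal(lox$start[1], lab("HA1")$end + 1L)
  expect_equal(lab("HA2")$start, lox$end[2] + 1L)
  # payload conservation
  expect_equal(con$payload,
               nchar(con$ha1) + nchar(con$cassette) + nchar(con$ha2))
  expect_equal(nchar(con$sequence), con$payload)
  # the variant feature sits inside HA1 and marks the inserted base
  v <- f[f$key == "variation", ]
  expect_equal(v$start, v$end)
  expect_lte(v$end, lab("HA1")$end)
  expect_identical(substr(con$sequence, v$start, v$start), d$best$bases)
})

test_that("construct GenBank output round-trips all feature coordinates", {
  d <- design_for()
  dd <- design_construct_arms(d$t, d$best)
  con <- targeting_construct(dd$arms)
  gb <- withr::local_tempfile(fileext = ".gb")
  emit_construct_genbank(con, gb)
  back <- read_genbank(gb)
  expect_identical(back$sequence, con$sequence)
  expect_equal(nchar(back$sequence), con$payload)
  expect_equal(back$features$start, con$features$start)
  expect_equal(back$features$end, con$features$end)
  expect_equal(back$features$label, con$features$label)
})
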