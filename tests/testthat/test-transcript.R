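test_that("translation follows the standard nuclear code", {
  expect_equal(translate_cds("ATG"), "M")
  expect_equal(translate_cds("AAAAAAAAA"), "KKK")
  # synonymy of AAA and AAG is the design principle behind codon-split
  # corrections
  expect_equal(translate_cds("AAG"), translate_cds("AAA"))
  expect_equal(translate_cds("ATGAAATAA"), "MK*")
  expect_equal(translate_cds("ATGANA"), "MX")
  expect_error(translate_cds("ATGA"), "multiple of 3")
  expect_equal(translate_cds("ATGA", partial = TRUE), "M")
})

test_that("translation agrees with the Biostrings reference on random CDS", {
  set.seed(11)
  for (i in 1:25) {
    cds <- random_dna(3L * sample(5:60, 1L))
    expect_equal(translate_cds(cds), oracle_translate(cds))
  }
})

test_that("fixture codons 1487-1489 read as the lysine tract", {
  fx <- make_repeat_transcript(seed = 1)
  cds <- fx$transcript$cds
  expect_equal(substr(cds, 4459, 4467), strrep("A", 9))
  prot <- translate_cds(cds)
  expect_equal(substr(prot, 1487, 1489), "KKK")
})

test_that("transcript constructor validates the context/CDS relationship", {
  expect_error(transcript("ATGAAA", context = "TTTTTT", cds_offset = 0),
               "does not contain")
  expect_error(transcript("ATGAAA", context = "GATGAAAG"),
               "cds_offset is required")
  t <- transcript("ATGAAA", context = "GATGAAAG", cds_offset = 1L)
  expect_equal(t$cds_offset, 1L)
})

test_that("FASTA and GenBank transcript I/O round-trips", {
  fx <- make_repeat_transcript(seed = 2)
  t <- fx$transcript

  fa <- withr::local_tempfile(fileext = ".fasta")
  write_transcript(t, fa, format = "fasta")
  t_fa <- read_transcript(fa, format = "fasta")
  expect_identical(t_fa$cds, t$cds)
  expect_null(t_fa$context)

  gb <- withr::local_tempfile(fileext = ".gb")
  write_transcript(t, gb, format = "genbank")
  t_gb <- read_transcript(gb, format = "genbank")
  expect_identical(t_gb$cds, t$cds)
  expect_identical(t_gb$context, t$context)
  expect_equal(t_gb$cds_offset, t$cds_offset)
  expect_equal(nchar(t_gb$cds), 4503L)
})

test_that("GenBank reading rejects missing or ambiguous CDS features", {
  gb <- withr::local_tempfile(fileext = ".gb")

  write_genbank(list(name = "noCDS", sequence = "ACGTACGTACGT",
                     features = NULL), gb)
  expect_error(read_transcript(gb, format = "genbank"), "no CDS feature")

  feats <- data.frame(key = c("CDS", "CDS"), start = c(1L, 7L),
                      end = c(6L, 12L), strand = "+",
                      label = c("a", "b"), stringsAsFactors = FALSE)
  write_genbank(list(name = "twoCDS", sequence = "ATGAAAATGCCC",
                     features = feats), gb)
  expect_error(read_transcript(gb, format = "genbank"), "1..6.*7..12")
})

test_that("GenBank record round-trip preserves features and strand", {
  feats <- data.frame(key = c("CDS", "misc_feature"),
                      start = c(3L, 10L), end = c(8L, 15L),
                      strand = c("+", "-"),
                      label = c("cds1", "mark"), stringsAsFactors = FALSE)
  rec <- list(name = "toy", sequence = random_dna(100), features = feats)
  gb <- withr::local_tempfile(fileext = ".gb")
  write_genbank(rec, gb)
  back <- read_genbank(gb)
  expect_equal(back$name, "toy")
  expect_identical(back$sequence, rec$sequence)
  expect_equal(back$features$key, feats$key)
  expect_equal(back$features$start, feats$start)
  expect_equal(back$features$end, feats$end)
  expect_equal(back$features$strand, feats$strand)
  expect_equal(back$features$label, feats$label)
  expect_error(read_genbank(withr::local_tempfile(fileext = ".txt",
                                                  lines = "hello")),
               "LOCUS")
})

test_that("a run deletion frameshifts translation at and after its codon", {
  set.seed(5)
  for (i in 1:20) {
    fx <- random_repeat_fixture(seed = 1000 + i)
    cds <- fx$transcript$cds
    tr <- fx$truth
    m <- frameshift_variant("del", tr$run_end_c, tr$run_base)
    mut <- apply_variant(cds, m)
    wt_p <- translate_cds(cds, partial = TRUE)
    mut_p <- translate_cds(mut, partial = TRUE)
    first_codon <- (tr$run_start_c - 1L) %/% 3L + 1L
    # identical before the run's codon
    if (first_codon > 1L)
      expect_equal(substr(mut_p, 1L, first_codon - 1L),
                   substr(wt_p, 1L, first_codon - 1L))
    # and different somewhere at/after it
    expect_false(identical(mut_p, wt_p))
  }
})
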