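# Deterministic synthetic-data generators.
#
# These emulate the inputs the validation statistics and the designer
# need — a repeat-bearing transcript, per-clone fold-change tables,
# peak/gene-model pairs and qPCR Ct tables — with every planted truth
# returned alongside the data, so recovery can be scored exactly.
# All randomness flows from one seed per generator (withr::with_seed),
# making identical specs byte-identical.

# Codons containing no adenine: usable as filler that can never create
# or extend an A-run (and can never spell a stop codon, since all three
# stops contain A).
A_FREE_CODONS <- {
  b <- c("C", "G", "T")
  apply(expand.grid(b, b, b), 1L, paste0, collapse = "")
}

#' Generate a repeat-bearing transcript fixture
#'
#' Builds a CDS of `codons` coding codons plus a stop: ATG start,
#' A-free filler codons, and a mononucleotide run planted so that its
#' 3'-most base falls at `run_end_c` (default (A)9 ending at c.4467,
#' i.e. run c.4459-c.4467 with codons 1487-1489 reading AAA AAA AAA).
#' The genomic context is the CDS flanked by `flank` nt of
#' non-repetitive random sequence on each side. Filler codons are
#' drawn randomly from the A-free codon set so the sequence has
#' realistic complexity for primer design while guaranteeing that the
#' planted run is the only A-run in the CDS; `filler = "GGC"` gives
#' the fully deterministic single-codon alternative.
#'
#' @param codons Number of coding codons before the stop (default
#'   1500, CDS length 4503 nt).
#' @param run_base Run base (default `"A"`).
#' @param run_length Run length (default 9).
#' @param run_end_c c. coordinate of the run's 3'-most base (default
#'   4467).
#' @param flank Genomic flank length per side (default 2000 nt).
#' @param filler `"random"` (A-free codons, seeded) or a single A-free
#'   codon such as `"GGC"`.
#' @param seed Integer seed.
#' @return A list: `transcript` (a [transcript()]), `truth`
#'   (run coordinates, planted mutation `"c.<run_end_c>del<base>"`,
#'   seed and sizes).
#' @export
make_repeat_transcript <- function(codons = 1500L, run_base = "A",
                                   run_length = 9L, run_end_c = 4467L,
                                   flank = 2000L,
                                   filler = c("random", "GGC"),
                                   seed = 1L) {
  if (is.character(filler) && length(filler) > 1L) filler <- filler[1L]
  run_base <- match.arg(run_base, DNA_BASES)
  run_start_c <- run_end_c - run_length + 1L
  n_cds <- 3L * (codons + 1L)
  if (run_start_c <= 3L)
    stop("run overlaps the start codon", call. = FALSE)
  if (run_end_c > 3L * codons)
    stop("run overlaps the stop codon (CDS has ", codons,
         " coding codons)", call. = FALSE)

  withr::with_seed(as.integer(seed), {
    if (identical(filler, "random")) {
      pool <- A_FREE_CODONS
      if (run_base != "A")
        pool <- pool[!grepl(run_base, pool, fixed = TRUE)]
      # T-weighted base composition (P(T) = 0.5, P(C) = P(G) = 0.25)
      # keeps the A-free CDS near 50% GC, within primer-design bounds
      base_p <- c(C = 0.25, G = 0.25, T = 0.5)
      w <- vapply(strsplit(pool, ""),
                  function(ch) prod(base_p[ch]), numeric(1L))
      body <- sample(pool, codons - 1L, replace = TRUE, prob = w)
    } else {
      check_dna(filler, "filler codon", allow_n = FALSE)
      stopifnot(nchar(filler) == 3L)
      body <- rep(filler, codons - 1L)
    }
    # TGA stop: the only stop codon without an AA dinucleotide, so the
    # planted run stays the only A-run of length >= 2 in the CDS
    cds <- paste0("ATG", paste0(body, collapse = ""), "TGA")
    # keep the planted run the only repeat tract: break any filler
    # homopolymer of >= 5 nt (substitutions never introduce an A)
    cds <- cap_runs(cds, max_run = 5L, avoid = "A")
    stopifnot(nchar(cds) == n_cds)
    # plant the run
    cds <- paste0(substr(cds, 1L, run_start_c - 1L),
                  strrep(run_base, run_length),
                  substr(cds, run_end_c + 1L, n_cds))
    # guard: keep the planted run maximal and unique at its length
    cds <- enforce_run_uniqueness(cds, run_base, run_start_c, run_end_c)

    left <- cap_runs(rand_dna_lcg(flank, seed = sample.int(2^30, 1L)),
                     max_run = 4L)
    right <- cap_runs(rand_dna_lcg(flank, seed = sample.int(2^30, 1L)),
                      max_run = 4L)
    # flanks must not extend the planted run across the CDS boundary
    context <- paste0(left, cds, right)
  })

  tr <- transcript(cds, id = "repeat_fixture", context = context,
                   cds_offset = flank)
  list(transcript = tr,
       truth = list(run_base = run_base, run_start_c = run_start_c,
                    run_end_c = run_end_c, run_length = run_length,
                    mutation = sprintf("c.%ddel%s", run_end_c, run_base),
                    cds_length = n_cds, flank = flank, seed = seed))
}

# Replace filler bases adjacent to the planted run if they happen to
# equal the run base (possible only for non-A run bases drawn from the
# filler alphabet), keeping the run maximal at exactly its length.
enforce_run_uniqueness <- function(cds, base, start_c, end_c) {
  ch <- seq_chars(cds)
  alt <- setdiff(c("C", "G", "T"), base)[1L]
  if (start_c > 1L && ch[start_c - 1L] == base) ch[start_c - 1L] <- alt
  if (end_c < length(ch) && ch[end_c + 1L] == base) ch[end_c + 1L] <- alt
  paste0(ch, collapse = "")
}

#' Generate a three-clone fold-change fixture
#'
#' Plants `n_up` genes concordantly up (fold drawn log-uniform in
#' `fold_range` independently per clone), `n_down` concordantly down
#' (reciprocal folds), `n_discordant` genes strongly changed in one
#' clone only, and `n_null` genes with multiplicative noise bounded
#' strictly inside the threshold, so [clone_intersection()] recovers
#' the planted sets exactly.
#'
#' @param n_up,n_down,n_discordant,n_null Gene counts per category.
#' @param clones Clone names (default three clones).
#' @param threshold Concordance threshold (default 1.5).
#' @param fold_range Planted fold range for concordant genes (both
#'   ends must be >= `threshold`).
#' @param seed Integer seed.
#' @return A list: `comparison` (an [expression_comparison()]),
#'   `folds` (the underlying data.frame), `truth` (`up`, `down` gene
#'   ids).
#' @export
make_expression_fixture <- function(n_up = 20L, n_down = 30L,
                                    n_discordant = 50L, n_null = 900L,
                                    clones = paste0("clone", 1:3),
                                    threshold = 1.5,
                                    fold_range = c(1.6, 4),
                                    seed = 1L) {
  stopifnot(fold_range[1L] >= threshold, length(clones) >= 1L)
  n_total <- n_up + n_down + n_discordant + n_null
  genes <- sprintf("G%04d", seq_len(n_total))
  nc <- length(clones)
  lu <- function(n, lo, hi) exp(runif(n, log(lo), log(hi)))

  withr::with_seed(as.integer(seed), {
    m <- matrix(1, nrow = n_total, ncol = nc,
                dimnames = list(genes, clones))
    idx <- 0L
    up_ids <- genes[seq_len(n_up)]
    for (i in seq_len(n_up))
      m[idx + i, ] <- lu(nc, fold_range[1L], fold_range[2L])
    idx <- idx + n_up
    down_ids <- genes[idx + seq_len(n_down)]
    for (i in seq_len(n_down))
      m[idx + i, ] <- 1 / lu(nc, fold_range[1L], fold_range[2L])
    idx <- idx + n_down
    for (i in seq_len(n_discordant)) {
      hot <- sample.int(nc, 1L)
      row <- lu(nc, 1 / (threshold - 0.05), threshold - 0.05)
      row[hot] <- if (runif(1) < 0.5) lu(1L, fold_range[1L], fold_range[2L])
                  else 1 / lu(1L, fold_range[1L], fold_range[2L])
      m[idx + i, ] <- row
    }
    idx <- idx + n_discordant
    for (i in seq_len(n_null))
      m[idx + i, ] <- lu(nc, 1 / (threshold - 0.05), threshold - 0.05)
  })

  folds <- data.frame(gene = genes, m, stringsAsFactors = FALSE,
                      row.names = NULL)
  names(folds) <- c("gene", clones)
  list(comparison = expression_comparison(folds, threshold = threshold),
       folds = folds,
       truth = list(up = sort(up_ids), down = sort(down_ids),
                    threshold = threshold, seed = seed))
}

#' Generate a peak/gene-model fixture with a planted genic enrichment
#'
#' Lays out `n_genes` non-overlapping genes (2-3 kb, random strand,
#' two exons each) on a single synthetic chromosome, places a
#' reference peak set uniformly, then places a test peak set whose
#' genic placement probability is the reference set's *empirical*
#' genic fraction scaled by `factor`. [peak_feature_summary()] on the
#' result recovers `factor` up to binomial sampling error. A fraction
#' `tss_frac` of the genic test peaks is centered at the TSS (with
#' small jitter), creating the TSS metaprofile spike.
#'
#' @param n_genes Number of genes (default 100).
#' @param genome_len Chromosome length (default 1e6 bp).
#' @param n_peaks,n_ref_peaks Test/reference peak counts (default
#'   2000 each).
#' @param factor Planted genic enrichment factor (default 3).
#' @param peak_width Peak width in bp (default 400).
#' @param tss_frac Fraction of genic test peaks centered at a TSS.
#' @param seed Integer seed.
#' @return A list: `peaks`, `reference_peaks` (GRanges), `models`
#'   (a [gene_models()]), `truth` (planted factor, reference genic
#'   fraction, seed).
#' @export
make_peak_fixture <- function(n_genes = 100L, genome_len = 1e6,
                              n_peaks = 2000L, n_ref_peaks = 2000L,
                              factor = 3, peak_width = 400L,
                              tss_frac = 0.3, seed = 1L) {
  withr::with_seed(as.integer(seed), {
    slot <- floor(genome_len / n_genes)
    margin <- peak_width + 10L
    gene_len <- sample(2000:3000, n_genes, replace = TRUE)
    gene_start <- (seq_len(n_genes) - 1L) * slot +
      sample(margin:(slot - max(gene_len) - margin), n_genes,
             replace = TRUE)
    strand <- sample(c("+", "-"), n_genes, replace = TRUE)
    genes <- GenomicRanges::GRanges(
      "chrS", IRanges::IRanges(gene_start, width = gene_len),
      strand = strand, type = "gene",
      ID = sprintf("gene%03d", seq_len(n_genes)))
    # two exons per gene: first and last 30% of the body
    ex1 <- GenomicRanges::GRanges(
      "chrS", IRanges::IRanges(gene_start, width = floor(gene_len * 0.3)),
      strand = strand, type = "exon",
      ID = sprintf("gene%03d.e1", seq_len(n_genes)))
    ex2_w <- floor(gene_len * 0.3)
    ex2 <- GenomicRanges::GRanges(
      "chrS", IRanges::IRanges(gene_start + gene_len - ex2_w,
                               width = ex2_w),
      strand = strand, type = "exon",
      ID = sprintf("gene%03d.e2", seq_len(n_genes)))
    models <- gene_models(genes = genes,
                          exons = c(ex1, ex2))

    place_uniform <- function(n) {
      mid <- sample.int(genome_len - peak_width, n) + peak_width %/% 2L
      GenomicRanges::GRanges("chrS", IRanges::IRanges(
        mid - peak_width %/% 2L, width = peak_width))
    }
    reference <- place_uniform(n_ref_peaks)
    ref_frac <- mean(classify_peaks(reference, models) != "intergenic")

    p_genic <- min(1, factor * ref_frac)
    genic_flag <- rbinom(n_peaks, 1L, p_genic) == 1L
    tss_flag <- genic_flag & (runif(n_peaks) < tss_frac)

    mids <- integer(n_peaks)
    gene_pick <- sample.int(n_genes, n_peaks, replace = TRUE)
    for (i in seq_len(n_peaks)) {
      gi <- gene_pick[i]
      if (tss_flag[i]) {
        tss <- if (strand[gi] == "+") gene_start[gi]
               else gene_start[gi] + gene_len[gi] - 1L
        mids[i] <- tss + sample(-150:150, 1L)
      } else if (genic_flag[i]) {
        mids[i] <- gene_start[gi] +
          sample.int(gene_len[gi] - 2L, 1L)
      } else {
        # fully intergenic: inside the slot gap, clear of the gene
        repeat {
          cand <- sample.int(genome_len - peak_width, 1L) +
            peak_width %/% 2L
          lo <- cand - peak_width %/% 2L
          hi <- lo + peak_width - 1L
          clear <- !any(hi >= gene_start - 1L &
                          lo <= gene_start + gene_len - 1L + 1L)
          if (clear) { mids[i] <- cand; break }
        }
      }
    }
    peaks <- GenomicRanges::GRanges("chrS", IRanges::IRanges(
      mids - peak_width %/% 2L, width = peak_width))
  })
  list(peaks = peaks, reference_peaks = reference, models = models,
       truth = list(factor = factor, ref_genic_fraction = ref_frac,
                    p_genic = p_genic, tss_frac = tss_frac, seed = seed))
}

#' Generate a qPCR Ct-table fixture with planted fold changes
#'
#' Ct values follow `Ct = baseline - log2(quantity) + noise`; reference
#' genes are flat across samples by construction, so
#' [relative_quantity()] recovers the planted folds exactly at zero
#' noise.
#'
#' @param folds Named vector of planted linear fold changes per clone
#'   relative to the calibrator (defaults spanning the 1.7-5-fold
#'   range typical of restored-allele re-expression).
#' @param target Target gene id.
#' @param references Reference gene ids (default PGK/TBP/ACTB).
#' @param calibrator Calibrator sample name.
#' @param replicates Technical replicates per (sample, gene).
#' @param baseline_ct Target Ct in the calibrator.
#' @param noise_sd Gaussian Ct noise (cycles; default 0).
#' @param seed Integer seed.
#' @return A list: `ct` (a [ct_table()]), `truth` (planted folds and
#'   parameters).
#' @export
make_ct_fixture <- function(folds = c(clone1 = 1.7, clone2 = 2.9,
                                      clone3 = 5.0),
                            target = "PRDM2",
                            references = c("PGK", "TBP", "ACTB"),
                            calibrator = "parental",
                            replicates = 3L, baseline_ct = 26,
                            noise_sd = 0, seed = 1L) {
  stopifnot(all(folds > 0), replicates >= 1L)
  samples <- c(calibrator, names(folds))
  quantity <- c(1, unname(folds))
  ref_base <- stats::setNames(
    seq(18, by = 1.5, length.out = length(references)), references)

  rows <- list()
  withr::with_seed(as.integer(seed), {
    for (i in seq_along(samples)) {
      for (rep_i in seq_len(replicates)) {
        rows[[length(rows) + 1L]] <- data.frame(
          sample = samples[i], gene = target, replicate = rep_i,
          ct = baseline_ct - log2(quantity[i]) + rnorm(1L, 0, noise_sd),
          stringsAsFactors = FALSE)
        for (g in references)
          rows[[length(rows) + 1L]] <- data.frame(
            sample = samples[i], gene = g, replicate = rep_i,
            ct = ref_base[[g]] + rnorm(1L, 0, noise_sd),
            stringsAsFactors = FALSE)
      }
    }
  })
  ct <- ct_table(do.call(rbind, rows))
  list(ct = ct,
       truth = list(folds = folds, target = target,
                    references = references, calibrator = calibrator,
                    baseline_ct = baseline_ct, noise_sd = noise_sd,
                    seed = seed))
}
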