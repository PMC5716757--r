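# Independent oracles used across the test files. These deliberately
# avoid the package's own code paths: translation goes through
# Biostrings, repeat scanning is a quadratic loop, edit enumeration is
# a direct brute-force search over edited sequences.

oracle_translate <- function(cds) {
  suppressWarnings(as.character(
    Biostrings::translate(Biostrings::DNAString(cds),
                          no.init.codon = TRUE)))
}

# Quadratic maximal-run scanner
oracle_repeats <- function(cds, min_len) {
  ch <- strsplit(cds, "")[[1L]]
  n <- length(ch)
  out <- NULL
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && ch[j + 1L] == ch[i]) j <- j + 1L
    if (j - i + 1L >= min_len && ch[i] %in% c("A", "C", "G", "T"))
      out <- rbind(out, data.frame(base = ch[i], start_c = i, end_c = j,
                                   length = j - i + 1L,
                                   stringsAsFactors = FALSE))
    i <- j + 1L
  }
  if (is.null(out))
    data.frame(base = character(), start_c = integer(), end_c = integer(),
               length = integer(), stringsAsFactors = FALSE)
  else out
}

# Brute-force enumeration: all distinct edited sequences obtainable by
# inserting d bases at any gap of the mutant inside the window, that
# restore the wild-type protein; optionally only those splitting the
# run (longest residual run of `base` touching the run region < wt run
# length).
oracle_edit_sequences <- function(cds, mutant, win_lo, win_hi, d,
                                  run = NULL) {
  wt_prot <- oracle_translate(cds)
  combos <- do.call(expand.grid, c(rep(list(c("A", "C", "G", "T")), d),
                                   stringsAsFactors = FALSE))
  bases <- apply(combos, 1L, paste0, collapse = "")
  out <- character()
  for (g in win_lo:min(nchar(cds) - d + 1L, win_hi)) {
    for (b in bases) {
      edited <- paste0(substr(mutant, 1L, g - 1L), b,
                       substr(mutant, g, nchar(mutant)))
      if (nchar(edited) %% 3L != 0L) next
      if (oracle_translate(edited) != wt_prot) next
      if (!is.null(run)) {
        # longest run of run$base intersecting the wild-type run window
        r <- rle(strsplit(edited, "")[[1L]])
        ends <- cumsum(r$lengths)
        starts <- ends - r$lengths + 1L
        touch <- r$values == run$base & starts <= run$end_c + 1L &
          ends >= run$start_c - 1L
        longest <- if (any(touch)) max(r$lengths[touch]) else 0L
        if (longest >= run$length) next
      }
      out <- c(out, edited)
    }
  }
  sort(unique(out))
}

# Edited sequences implied by an enumerate_stabilizing_edits() result
edit_sequences_of <- function(edits) {
  m <- attr(edits, "mutation")
  cds <- attr(edits, "wt_cds")
  mutant <- apply_variant(cds, m)
  if (!nrow(edits)) return(character())
  sort(unique(vapply(seq_len(nrow(edits)), function(i)
    apply_variant(mutant, frameshift_variant("ins", edits$position_c[i],
                                             edits$bases[i])),
    character(1L))))
}

# Independent nearest-neighbor Tm summation (unified parameter set),
# coded directly from the published table rather than via the package
# constants.
oracle_tm <- function(seq, Na = 0.05, ct = 5e-7) {
  pair_h <- list(AA = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, GT = -8.4,
                 CT = -7.8, GA = -8.2, CG = -10.6, GC = -9.8, GG = -8.0)
  pair_s <- list(AA = -22.2, AT = -20.4, TA = -21.3, CA = -22.7,
                 GT = -22.4, CT = -21.0, GA = -22.2, CG = -27.2,
                 GC = -24.4, GG = -19.9)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  ch <- strsplit(seq, "")[[1L]]
  n <- length(ch)
  H <- 0; S <- 0
  for (i in seq_len(n - 1L)) {
    key <- paste0(ch[i], ch[i + 1L])
    if (is.null(pair_h[[key]]))  # look up the complementary stack
      key <- paste0(comp[ch[i + 1L]], comp[ch[i]])
    H <- H + pair_h[[key]]
    S <- S + pair_s[[key]]
  }
  for (end in ch[c(1L, n)]) {
    if (end %in% c("G", "C")) { H <- H + 0.1; S <- S - 2.8 }
    else { H <- H + 2.3; S <- S + 4.1 }
  }
  rc <- paste0(rev(comp[ch]), collapse = "")
  self_comp <- identical(seq, rc)
  if (self_comp) S <- S - 1.4
  S <- S + 0.368 * (n - 1L) * log(Na)
  H * 1000 / (S + 1.9872 * log(ct / if (self_comp) 1 else 4)) - 273.15
}

# Step-up BH over a truncated family, straight from the definition
oracle_bh <- function(p, m) {
  mp <- length(p)
  q <- numeric(mp)
  for (i in seq_len(mp))
    q[i] <- min(1, min(p[i:mp] * m / (i:mp)))
  q
}

# Exhaustive hypergeometric upper tail by enumerating all draws
oracle_hyper_tail <- function(k, K, N, n) {
  draws <- utils::combn(N, n)
  inset <- seq_len(K)  # WLOG the set is elements 1..K
  hits <- apply(draws, 2L, function(d) sum(d %in% inset))
  mean(hits >= k)
}

random_dna <- function(n) {
  paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# A small randomized repeat fixture for property sweeps: run of
# `run_length` bases of `run_base`, random placement, compact CDS.
random_repeat_fixture <- function(seed, codons = NULL, run_base = NULL,
                                  run_length = NULL) {
  set.seed(seed)
  if (is.null(codons)) codons <- sample(20:40, 1L)
  if (is.null(run_base)) run_base <- sample(c("A", "C", "G", "T"), 1L)
  if (is.null(run_length)) run_length <- sample(6:10, 1L)
  run_end_c <- sample(seq(run_length + 3L, 3L * codons), 1L)
  fx <- make_repeat_transcript(codons = codons, run_base = run_base,
                               run_length = run_length,
                               run_end_c = run_end_c, flank = 0L,
                               seed = seed)
  fx
}
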