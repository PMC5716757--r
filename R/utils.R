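# Internal helpers shared across modules. Sequences are plain uppercase
# character scalars over A/C/G/T/N; Biostrings objects are used at the
# I/O and translation boundaries only.

DNA_BASES <- c("A", "C", "G", "T")

assert_scalar_string <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || is.na(x))
    stop(what, " must be a single character string", call. = FALSE)
}

check_dna <- function(seq, what = "sequence", allow_n = TRUE) {
  assert_scalar_string(seq, what)
  alphabet <- if (allow_n) "ACGTN" else "ACGT"
  bad <- gsub(sprintf("[%s]", alphabet), "", seq)
  if (nzchar(bad))
    stop(what, " contains characters outside [", alphabet, "]: '",
         substr(bad, 1L, 10L), "'", call. = FALSE)
  invisible(seq)
}

seq_chars <- function(seq) strsplit(seq, "", fixed = TRUE)[[1L]]

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

gc_fraction <- function(seq) {
  ch <- seq_chars(seq)
  sum(ch %in% c("G", "C")) / length(ch)
}

#' @noRd
#' Deterministic DNA generator on a private xorshift stream, so that
#' construct assembly never touches the user's RNG state.
rand_dna_lcg <- function(n, seed) {
  # Park-Miller minimal-standard generator; 16807 * (2^31 - 2) < 2^53,
  # so the recurrence is exact in double arithmetic.
  state <- (abs(as.numeric(seed)) %% 2147483646) + 1
  out <- integer(n)
  for (i in seq_len(n)) {
    state <- (16807 * state) %% 2147483647
    out[i] <- floor(state / 2048) %% 4
  }
  paste0(DNA_BASES[out + 1L], collapse = "")
}

# Maximal homopolymer runs of `seq` as a data.frame(base, start, end, length)
homopolymer_runs <- function(seq) {
  ch <- seq_chars(seq)
  r <- rle(ch)
  end <- cumsum(r$lengths)
  data.frame(base = r$values,
             start = end - r$lengths + 1L,
             end = end,
             length = r$lengths,
             stringsAsFactors = FALSE)
}

# Break any homopolymer run of length >= max_run by substituting bases;
# used by fixture generators to keep filler free of spurious repeats.
cap_runs <- function(seq, max_run = 4L, avoid = character()) {
  ch <- seq_chars(seq)
  repeat {
    r <- rle(ch)
    long <- which(r$lengths >= max_run)
    if (!length(long)) break
    end <- cumsum(r$lengths)
    for (i in long) {
      pos <- end[i] - r$lengths[i] + max_run - 1L  # break inside the run
      alt <- setdiff(DNA_BASES, c(r$values[i], avoid))
      ch[pos] <- alt[1L + (pos %% length(alt))]
    }
  }
  paste0(ch, collapse = "")
}
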