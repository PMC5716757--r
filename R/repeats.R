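# Coding mononucleotide repeat discovery.

#' Find coding mononucleotide repeats
#'
#' Scans the CDS for maximal single-base runs of at least `min_len`
#' bases. These are the slippage-prone tracts that accumulate
#' frameshifts under mismatch-repair deficiency and are the targets of
#' repeat-stabilizing correction.
#'
#' @param t A [transcript()] or plain CDS string.
#' @param min_len Minimum run length to report (default 6; the
#'   clinically prominent tracts are (A)8/(A)9 but shorter runs occur
#'   in tumor-mutated repeat lists).
#' @return A data.frame with one row per repeat, sorted by `start_c`:
#'   `base`, `start_c`, `end_c`, `length`, `frame_offset` (0-2,
#'   position of the run's first base within its codon), `codon_start`,
#'   `codon_end` (1-based codon indices spanned).
#' @export
#' @examples
#' cds <- paste0("ATG", strrep("GGC", 3), strrep("A", 9), "TAA")
#' find_coding_repeats(cds, min_len = 8)
find_coding_repeats <- function(t, min_len = 6L) {
  cds <- if (inherits(t, "transcript")) t$cds else check_dna(t, "cds")
  if (min_len < 2L) stop("min_len must be at least 2", call. = FALSE)
  runs <- homopolymer_runs(cds)
  runs <- runs[runs$length >= min_len & runs$base %in% DNA_BASES, ,
               drop = FALSE]
  out <- data.frame(
    base = runs$base,
    start_c = runs$start,
    end_c = runs$end,
    length = runs$length,
    frame_offset = (runs$start - 1L) %% 3L,
    codon_start = (runs$start - 1L) %/% 3L + 1L,
    codon_end = (runs$end - 1L) %/% 3L + 1L,
    stringsAsFactors = FALSE
  )
  out[order(out$start_c), , drop = FALSE]
}
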