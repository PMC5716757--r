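# Stabilizing-edit enumeration, ranking and amenability assessment.
#
# The design problem: a deletion of d bases inside a long mononucleotide
# run has shifted the reading frame. Any insertion of d bases restores
# the frame, but re-inserting the run base recreates the original
# slippage-prone tract. A *stabilizing* edit instead inserts a different
# base that (a) leaves the translated protein exactly wild-type — the
# run codons switch to synonymous codons — and (b) splits the run into
# two shorter runs, each less prone to slippage.

condition_error <- function(class, msg) {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = NULL)))
}

#' Enumerate synonymous frame-restoring insertions that split a repeat
#'
#' Exhaustively tests every insertion of `d` bases (where `d` is the
#' size of the deletion `m`) at every position in a window extending 3
#' nt beyond the repeat on each side, against the full re-translation
#' criterion: the edited CDS must translate to exactly the wild-type
#' protein. Candidates producing identical edited sequences are
#' deduplicated; insertions that merely restore the original run
#' (no split) are excluded unless `include_nonsplit = TRUE`.
#'
#' Insertion coordinates are reported in the occupied-position dialect:
#' the position the inserted base occupies in the *corrected* sequence,
#' which has wild-type length. Among equivalent placements the position
#' inside the repeat is preferred (3'-most within the run).
#'
#' @param t Wild-type [transcript()] (or plain CDS string).
#' @param r One repeat: a single row of [find_coding_repeats()] output.
#' @param m The frameshift deletion, a [frameshift_variant()] of 1-2
#'   bases lying within `r` (normalized internally).
#' @param include_nonsplit Keep frame-restoring insertions that do not
#'   split the run (reported with `split = FALSE`) for comparison.
#' @param window_pad Window extension beyond the run (default 3 nt).
#' @return A data.frame of class `stabilizing_edits`, one row per
#'   distinct edited sequence: `hgvs`, `anchor`, `position_c`, `bases`,
#'   `five_run`, `three_run`, `longest_residual`, `balance`,
#'   `protein_identical`, `split`. Attributes `repeat`, `mutation` and
#'   `wt_cds` carry the design context.
#' @export
enumerate_stabilizing_edits <- function(t, r, m, include_nonsplit = FALSE,
                                        window_pad = 3L) {
  cds <- if (inherits(t, "transcript")) t$cds else check_dna(t, "cds")
  r <- as.list(r[1L, , drop = FALSE])
  stopifnot(inherits(m, "frameshift_variant"))
  if (m$kind != "del")
    condition_error("repeatlock_domain",
                    "m must be a deletion (the frameshift to correct)")
  d <- nchar(m$bases)
  if (d > 2L)
    condition_error("repeatlock_domain", paste0(
      "deletions of more than 2 bases are not supported (got ", d, ")"))
  m <- normalize_3prime(m, cds)
  if (m$position < r$start_c || m$position > r$end_c ||
      any(seq_chars(m$bases) != r$base))
    condition_error("repeatlock_domain", paste0(
      "deletion ", format_hgvs_c(m), " does not lie within the ", r$base,
      "-run c.", r$start_c, "-", r$end_c))

  n <- nchar(cds)
  win_lo <- max(1L, r$start_c - window_pad)
  win_hi <- min(n, r$end_c + window_pad)
  if (grepl("N", substr(cds, win_lo, win_hi), fixed = TRUE))
    condition_error("repeatlock_ambiguous", paste0(
      "ambiguous base (N) within the repeat window c.", win_lo, "-",
      win_hi))

  wt_protein <- translate_cds(cds, partial = TRUE)
  mutant <- apply_variant(cds, m)

  # candidate gap positions on the corrected (wild-type length) axis
  gaps <- seq.int(win_lo, min(n - d + 1L, win_hi))
  combos <- do.call(expand.grid,
                    c(rep(list(DNA_BASES), d), stringsAsFactors = FALSE))
  ins_bases <- apply(combos, 1L, paste0, collapse = "")

  hits <- list()  # edited sequence -> list(gs = positions, bases = by g)
  for (g in gaps) {
    for (b in ins_bases) {
      edited <- apply_variant(mutant, frameshift_variant("ins", g, b))
      if (translate_cds(edited, partial = TRUE) != wt_protein) next
      key <- edited
      if (is.null(hits[[key]]))
        hits[[key]] <- list(gs = integer(), bases = character())
      hits[[key]]$gs <- c(hits[[key]]$gs, g)
      hits[[key]]$bases <- c(hits[[key]]$bases, b)
    }
  }
  if (!length(hits)) {
    out <- empty_edits_frame()
  } else {
    rows <- lapply(names(hits), function(edited) {
      h <- hits[[edited]]
      in_run <- h$gs <= r$end_c
      idx <- if (any(in_run)) which.max(h$gs * in_run) else which.min(h$gs)
      g <- h$gs[idx]
      b <- h$bases[idx]
      res <- residual_runs(edited, r$base, r$start_c, r$end_c)
      v <- frameshift_variant("ins", g, b)
      lab <- format_hgvs_c(v)
      data.frame(hgvs = as.character(lab), anchor = attr(lab, "anchor"),
                 position_c = g, bases = b,
                 five_run = res[1L], three_run = res[2L],
                 longest_residual = max(res),
                 balance = abs(res[1L] - res[2L]),
                 protein_identical = TRUE,
                 split = max(res) < r$length,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (!include_nonsplit) out <- out[out$split, , drop = FALSE]
    out <- out[order(out$position_c), , drop = FALSE]
    rownames(out) <- NULL
  }
  structure(out, "repeat" = r, mutation = m, wt_cds = cds,
            class = c("stabilizing_edits", "data.frame"))
}

empty_edits_frame <- function() {
  data.frame(hgvs = character(), anchor = character(),
             position_c = integer(), bases = character(),
             five_run = integer(), three_run = integer(),
             longest_residual = integer(), balance = integer(),
             protein_identical = logical(), split = logical(),
             stringsAsFactors = FALSE)
}

# Residual run lengths of the repeat tract after correction, measured
# at the repeat region of the edited (wild-type-length) sequence: the
# maximal runs of the run base intersecting the original run interval
# [start_c, end_c]. An in-run insertion of a different base yields two
# runs (5', 3'); an insertion elsewhere — including the pure
# re-insertion of the run base — leaves one residual run, reported as
# (length, 0).
residual_runs <- function(edited, base, start_c, end_c) {
  r <- rle(seq_chars(edited))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hit <- r$values == base & starts <= end_c & ends >= start_c
  lens <- r$lengths[hit]
  if (length(lens) == 0L) return(c(0L, 0L))
  if (length(lens) == 1L) return(c(lens, 0L))
  c(lens[1L], lens[2L])
}

#' Rank stabilizing edits by residual-run stability
#'
#' Orders candidates ascending by the longest residual run (shorter
#' runs are more stable), then by run balance (a 5+3 split beats 2+6),
#' then by 5'-most coordinate. The key is a deterministic total order;
#' all candidates remain in the output so alternative policies stay
#' auditable.
#'
#' @param edits Output of [enumerate_stabilizing_edits()].
#' @return The same data.frame, reordered.
#' @export
rank_edits <- function(edits) {
  if (!nrow(edits)) return(edits)
  o <- order(edits$longest_residual, edits$balance, edits$position_c)
  out <- edits[o, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Stability report for one emitted edit
#'
#' A qualitative slippage-stability summary: wild-type and mutant run
#' lengths, the residual run pair after correction, and the reduction
#' of the longest run relative to the wild-type tract.
#'
#' @param r The repeat row the edit was designed for.
#' @param e One row of (ranked) [enumerate_stabilizing_edits()] output.
#' @return `list(wt_run_length, mutant_run_length, residual_runs,
#'   reduction)`.
#' @export
stability_report <- function(r, e) {
  r <- as.list(r[1L, , drop = FALSE])
  e <- as.list(e[1L, , drop = FALSE])
  list(wt_run_length = r$length,
       mutant_run_length = e$five_run + e$three_run,
       residual_runs = c(five = e$five_run, three = e$three_run),
       reduction = r$length - e$longest_residual)
}

#' Assess whether a mutated repeat is amenable to knock-in correction
#'
#' A repeat/mutation pair is amenable when (a) at least one synonymous
#' splitting insertion exists and (b) a targeting construct can be
#' built around the top-ranked edit: homology arms of the configured
#' length fit inside the available genomic context and the payload
#' respects the rAAV capacity. Failures accumulate as verdict codes
#' rather than errors, keeping sequence-level and construct-level
#' failure modes separable.
#'
#' @param t Wild-type [transcript()] (context required for the
#'   construct-level checks).
#' @param r One repeat row from [find_coding_repeats()].
#' @param m The frameshift deletion ([frameshift_variant()]).
#' @param arm_spec Construct configuration from [construct_config()].
#' @param min_len Minimum run length considered a design target.
#' @return `list(amenable, reasons, best_edit)`; `reasons` is `"OK"`
#'   when amenable, otherwise one or more of `NO_SYNONYMOUS_SPLIT`,
#'   `RUN_BELOW_THRESHOLD`, `AMBIGUOUS_SEQUENCE`, `ARM_DESIGN_FAIL`.
#' @export
assess_amenability <- function(t, r, m, arm_spec = construct_config(),
                               min_len = 6L) {
  reasons <- character()
  r1 <- as.list(r[1L, , drop = FALSE])
  if (r1$length < min_len) reasons <- c(reasons, "RUN_BELOW_THRESHOLD")

  edits <- tryCatch(
    enumerate_stabilizing_edits(t, r, m),
    repeatlock_ambiguous = function(e) {
      reasons <<- c(reasons, "AMBIGUOUS_SEQUENCE")
      NULL
    })
  best <- NULL
  if (!is.null(edits)) {
    if (!nrow(edits)) {
      reasons <- c(reasons, "NO_SYNONYMOUS_SPLIT")
    } else {
      ranked <- rank_edits(edits)
      best <- ranked[1L, , drop = FALSE]
      for (a in c("repeat", "mutation", "wt_cds"))
        attr(best, a) <- attr(edits, a)
      arm_ok <- tryCatch({
        arms <- extract_homology_arms(t, best, config = arm_spec)
        payload <- 2L * arms$arm_len + arm_spec$cassette_len
        if (payload > arm_spec$capacity)
          condition_error("repeatlock_arm_fail", paste0(
            "payload ", payload, " nt exceeds rAAV capacity ",
            arm_spec$capacity, " nt"))
        TRUE
      }, repeatlock_arm_fail = function(e) FALSE,
         error = function(e) FALSE)
      if (!arm_ok) reasons <- c(reasons, "ARM_DESIGN_FAIL")
    }
  }
  amenable <- length(reasons) == 0L
  list(amenable = amenable,
       reasons = if (amenable) "OK" else unique(reasons),
       best_edit = if (amenable) best else NULL)
}

#' Corrected CDS for a designed edit
#'
#' Applies the frameshift deletion and then the stabilizing insertion,
#' yielding the corrected coding sequence (wild-type length, wild-type
#' protein, split repeat).
#'
#' @param t Wild-type [transcript()] or CDS string.
#' @param m The frameshift deletion.
#' @param e One edit row.
#' @return The corrected CDS string.
#' @export
corrected_cds <- function(t, m, e) {
  cds <- if (inherits(t, "transcript")) t$cds else check_dna(t, "cds")
  e <- as.list(e[1L, , drop = FALSE])
  mutant <- apply_variant(cds, normalize_3prime(m, cds))
  apply_variant(mutant, frameshift_variant("ins", e$position_c, e$bases))
}
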