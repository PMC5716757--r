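# rAAV Gateway targeting-construct assembly.

LOXP <- "ATAACTTCGTATAATGTATGCTATACGAAGTTAT"  # canonical 34-nt loxP site

#' Targeting-construct configuration
#'
#' Tunable layout and primer parameters. Defaults: 1,000-nt homology
#' arms (accepted range 800-1,300), a 2.4-kb selection cassette, a
#' 4.7-kb rAAV payload capacity, a 57-63 C primer Tm window and 35-65%
#' GC bounds. The cassette is modeled as an opaque named sequence —
#' only its layout (loxP sites flanking a splice-acceptor/IRES/Neo/
#' polyA block) matters to the design logic.
#'
#' @param arm_len Homology-arm length in nt.
#' @param arm_range Acceptable arm-length range.
#' @param cassette_len Total cassette length including both loxP sites.
#' @param capacity rAAV payload capacity in nt.
#' @param tm_range Primer-core melting temperature window (Celsius).
#' @param gc_range Primer-core GC-fraction bounds.
#' @param primer_len Primer-core length bounds.
#' @param tm_conditions Hybridization conditions, see [tm_conditions()].
#' @return A named list of class `construct_config`.
#' @export
construct_config <- function(arm_len = 1000L, arm_range = c(800L, 1300L),
                             cassette_len = 2400L, capacity = 4700L,
                             tm_range = c(57, 63), gc_range = c(0.35, 0.65),
                             primer_len = c(15L, 35L),
                             tm_conditions = repeatlock::tm_conditions()) {
  if (cassette_len < 2L * nchar(LOXP) + 40L)
    stop("cassette_len too small to hold two loxP sites and a marker",
         call. = FALSE)
  structure(list(arm_len = as.integer(arm_len),
                 arm_range = as.integer(arm_range),
                 cassette_len = as.integer(cassette_len),
                 capacity = as.integer(capacity),
                 tm_range = tm_range, gc_range = gc_range,
                 primer_len = as.integer(primer_len),
                 tm_conditions = tm_conditions),
            class = "construct_config")
}

#' Extract homology arms around a stabilizing edit
#'
#' HA1 ends at the cassette insertion point and carries the corrected
#' (split-repeat) allele; HA2 begins at the insertion point and is
#' wild-type downstream sequence. The insertion point is placed
#' `junction_offset` nt 3' of the repeat's last base (default 30 nt —
#' just past the edited exon segment, far enough that the HA1-terminal
#' primer does not have to bind inside the homopolymer tract), so the
#' edit sits near the 3' end of HA1.
#'
#' @param t Wild-type [transcript()] with genomic context.
#' @param e One edit row from [enumerate_stabilizing_edits()] /
#'   [rank_edits()] (attributes `repeat` and `mutation` required, as
#'   produced by those functions).
#' @param arm_len Arm length; defaults to `config$arm_len` and must lie
#'   within `config$arm_range`.
#' @param junction_offset Distance (nt) from the repeat's 3'-most base
#'   to the cassette insertion point.
#' @param config [construct_config()].
#' @return `list(ha1, ha2, junction, arm_len, ...)` of class
#'   `homology_arms`; `junction` is the 0-based context coordinate at
#'   which the cassette is inserted. Errors with condition class
#'   `repeatlock_arm_fail` (reporting required vs available context)
#'   when the context cannot accommodate the arms.
#' @export
extract_homology_arms <- function(t, e, arm_len = NULL,
                                  junction_offset = 30L,
                                  config = construct_config()) {
  stopifnot(inherits(t, "transcript"))
  if (is.null(t$context))
    condition_error("repeatlock_arm_fail",
                    "transcript has no genomic context; arms require one")
  r <- attr(e, "repeat")
  m <- attr(e, "mutation")
  if (is.null(r) || is.null(m))
    stop("edit must carry 'repeat' and 'mutation' attributes ",
         "(use enumerate_stabilizing_edits/rank_edits output)",
         call. = FALSE)
  if (is.null(arm_len)) arm_len <- config$arm_len
  arm_len <- as.integer(arm_len)
  if (arm_len < config$arm_range[1L] || arm_len > config$arm_range[2L])
    stop("arm_len ", arm_len, " outside the configured range ",
         config$arm_range[1L], "-", config$arm_range[2L], call. = FALSE)

  cds_corr <- corrected_cds(t, m, e)
  ctx <- t$context
  corrected_context <- paste0(
    substr(ctx, 1L, t$cds_offset),
    cds_corr,
    substr(ctx, t$cds_offset + nchar(t$cds) + 1L, nchar(ctx)))

  junction <- t$cds_offset + r$end_c +
    as.integer(junction_offset)  # 0-based: HA1 is [jn-arm, jn)
  avail_left <- junction
  avail_right <- nchar(ctx) - junction
  if (avail_left < arm_len || avail_right < arm_len)
    condition_error("repeatlock_arm_fail", sprintf(
      "context too short for %d-nt arms: %d nt available 5' and %d nt 3' of the junction",
      arm_len, avail_left, avail_right))

  structure(list(
    ha1 = substr(corrected_context, junction - arm_len + 1L, junction),
    ha2 = substr(corrected_context, junction + 1L, junction + arm_len),
    junction = junction,
    arm_len = arm_len,
    corrected_context = corrected_context,
    corrected_cds = cds_corr,
    cds_offset = t$cds_offset,
    edit = e[1L, , drop = FALSE],
    "repeat" = r,
    mutation = m
  ), class = "homology_arms")
}

#' Assemble a targeting construct
#'
#' Layout: `HA1 - loxP - SA - IRES - Neo - polyA - loxP - HA2`. The
#' cassette interior is an opaque deterministic placeholder sequence
#' (its exact content is irrelevant to the design logic); loxP sites
#' flank the selection block and nothing else, so Cre excision leaves
#' a single loxP scar between the arms.
#'
#' @param arms A `homology_arms` object from [extract_homology_arms()].
#' @param config [construct_config()].
#' @return A `targeting_construct`: `sequence`, a `features`
#'   data.frame (1-based inclusive coordinates), `payload`, plus the
#'   design context carried over from `arms`.
#' @export
targeting_construct <- function(arms, config = construct_config()) {
  stopifnot(inherits(arms, "homology_arms"))
  inner_len <- config$cassette_len - 2L * nchar(LOXP)
  inner <- rand_dna_lcg(inner_len, seed = 20011L)
  # Avoid accidental primer-confounding homopolymers in the placeholder
  inner <- cap_runs(inner, max_run = 5L)
  cassette <- paste0(LOXP, inner, LOXP)
  sequence <- paste0(arms$ha1, cassette, arms$ha2)

  a1 <- nchar(arms$ha1)
  lox <- nchar(LOXP)
  # opaque marker block partitioned into named segments
  seg <- round(inner_len * c(SA = 0.10, IRES = 0.25, Neo = 0.45))
  seg <- c(seg, polyA = inner_len - sum(seg))
  seg_start <- a1 + lox + cumsum(c(0L, unname(seg)[-4L])) + 1L
  seg_end <- a1 + lox + cumsum(unname(seg))

  edit_pos_in_ha1 <- a1 - (arms$junction - arms$cds_offset -
                             arms$edit$position_c)
  features <- data.frame(
    key = c("misc_feature", "protein_bind", "misc_feature", "misc_feature",
            "misc_feature", "misc_feature", "protein_bind", "misc_feature",
            "variation"),
    start = c(1L, a1 + 1L, seg_start, a1 + lox + inner_len + 1L,
              a1 + nchar(cassette) + 1L, edit_pos_in_ha1),
    end = c(a1, a1 + lox, seg_end, a1 + lox + inner_len + lox,
            nchar(sequence), edit_pos_in_ha1),
    strand = "+",
    label = c("HA1", "loxP", "SA", "IRES", "Neo", "polyA", "loxP", "HA2",
              paste0("stabilizing_insertion_", arms$edit$hgvs)),
    stringsAsFactors = FALSE)

  structure(list(sequence = sequence, features = features,
                 ha1 = arms$ha1, ha2 = arms$ha2, cassette = cassette,
                 payload = nchar(sequence), junction = arms$junction,
                 arms = arms, config = config),
            class = "targeting_construct")
}

#' @export
print.targeting_construct <- function(x, ...) {
  cat("<targeting_construct> payload ", x$payload, " nt (HA1 ",
      nchar(x$ha1), " + cassette ", nchar(x$cassette), " + HA2 ",
      nchar(x$ha2), ")\n", sep = "")
  invisible(x)
}

#' Write a targeting construct as an annotated GenBank record
#'
#' Emits the construct sequence with HA1/HA2, both loxP sites, the
#' cassette segments and a `variation` feature at the stabilizing
#' insertion; the file round-trips through [read_genbank()].
#'
#' @param construct A [targeting_construct()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
emit_construct_genbank <- function(construct, path) {
  stopifnot(inherits(construct, "targeting_construct"))
  write_genbank(list(name = "targeting_construct",
                     sequence = construct$sequence,
                     features = construct$features), path)
}
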