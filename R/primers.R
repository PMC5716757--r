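# Primer objects and Gateway attB-tailed homology-arm primers.

# Canonical Gateway attB tail sequences (standard MultiSite Gateway
# definitions, Invitrogen manuals; not transcribed from any study).
# HA1 recombines into pDONR P1-P2 via attB1/attB2, HA2 into pDONR
# P3-P4 via attB3/attB4. Override via make_gateway_arm_primers(tails=).
ATTB_TAILS <- list(
  "P1-P2" = c(fwd = "GGGGACAAGTTTGTACAAAAAAGCAGGCT",
              rev = "GGGGACCACTTTGTACAAGAAAGCTGGGT"),
  "P3-P4" = c(fwd = "GGGGACAACTTTGTATAATAAAGTTG",
              rev = "GGGGACAACTTTGTATAGAAAAGTTG")
)

#' Primer constructor
#'
#' @param name Primer name.
#' @param core Template-binding core sequence (15-35 nt).
#' @param tail Optional 5' tail (attB site or empty).
#' @param start,end 0-based half-open binding coordinates of the core
#'   on its template.
#' @param strand `"+"` (binds as given) or `"-"` (core is the reverse
#'   complement of the template's plus strand).
#' @param conditions [tm_conditions()] used for the core Tm.
#' @return An object of class `primer` with fields `tm` (core only),
#'   `gc` and `sequence` (tail + core).
#' @export
primer <- function(name, core, tail = "", start = NA_integer_,
                   end = NA_integer_, strand = "+",
                   conditions = tm_conditions()) {
  check_dna(core, "primer core", allow_n = FALSE)
  if (nchar(core) < 15L || nchar(core) > 35L)
    stop("primer core must be 15-35 nt, got ", nchar(core), call. = FALSE)
  if (nzchar(tail)) check_dna(tail, "primer tail", allow_n = FALSE)
  structure(list(name = name, core = core, tail = tail,
                 sequence = paste0(tail, core),
                 tm = as.numeric(melting_temperature(core, conditions)),
                 gc = gc_fraction(core),
                 start = as.integer(start), end = as.integer(end),
                 strand = strand),
            class = "primer")
}

#' @export
print.primer <- function(x, ...) {
  cat(sprintf("<primer> %s  5'-%s%s-3'  core %d nt, Tm %.1f C, GC %.0f%%\n",
              x$name, if (nzchar(x$tail)) paste0("[", x$tail, "]") else "",
              x$core, nchar(x$core), x$tm, 100 * x$gc))
  invisible(x)
}

# Extend a core from a fixed terminus until Tm and GC constraints are
# met. `template` is read so that the core is template[1..len] (callers
# pass reverse-complemented sequence for minus-strand primers).
choose_core <- function(template, config) {
  lens <- seq.int(config$primer_len[1L],
                  min(config$primer_len[2L], nchar(template)))
  if (!length(lens) || nchar(template) < config$primer_len[1L])
    stop("template too short for a primer core (", nchar(template),
         " nt available)", call. = FALSE)
  tried <- character()
  for (len in lens) {
    core <- substr(template, 1L, len)
    if (grepl("N", core, fixed = TRUE)) break
    tm <- as.numeric(melting_temperature(core, config$tm_conditions))
    gc <- gc_fraction(core)
    tm_ok <- tm >= config$tm_range[1L] && tm <= config$tm_range[2L]
    gc_ok <- gc >= config$gc_range[1L] && gc <= config$gc_range[2L]
    if (tm_ok && gc_ok) return(core)
    tried <- c(tried, sprintf("len %d: Tm %.1f [%s], GC %.2f [%s]", len, tm,
                              if (tm_ok) "ok" else "violated", gc,
                              if (gc_ok) "ok" else "violated"))
    if (tm > config$tm_range[2L] && gc_ok) break  # Tm only grows
  }
  stop("no primer core satisfies the constraints (Tm ",
       config$tm_range[1L], "-", config$tm_range[2L], " C, GC ",
       config$gc_range[1L], "-", config$gc_range[2L], "); tried: ",
       paste(utils::head(tried, 3L), collapse = "; "), call. = FALSE)
}

#' Gateway attB-tailed primers for one homology arm
#'
#' Designs the forward/reverse amplification primers for a homology
#' arm: cores anchored at the arm termini (extended inward until the
#' Tm window and GC bounds are satisfied) with the canonical attB
#' tails of the requested donor-vector pair prepended.
#'
#' @param arm Homology-arm sequence (>= 100 nt).
#' @param site_pair `"P1-P2"` (attB1/attB2 tails; used for HA1) or
#'   `"P3-P4"` (attB3/attB4; used for HA2).
#' @param config [construct_config()].
#' @param name_prefix Prefix for the primer names.
#' @param tails Optional override of the tail pair
#'   (`c(fwd = ..., rev = ...)`).
#' @return `list(fwd, rev)` of [primer()] objects with binding
#'   coordinates on the arm.
#' @export
make_gateway_arm_primers <- function(arm, site_pair = c("P1-P2", "P3-P4"),
                                     config = construct_config(),
                                     name_prefix = "HA",
                                     tails = NULL) {
  check_dna(arm, "arm")
  site_pair <- match.arg(site_pair)
  if (nchar(arm) < 100L)
    stop("homology arm must be at least 100 nt, got ", nchar(arm),
         call. = FALSE)
  if (is.null(tails)) tails <- ATTB_TAILS[[site_pair]]
  fwd_core <- choose_core(arm, config)
  rev_core <- choose_core(revcomp(arm), config)
  att_names <- if (site_pair == "P1-P2") c("attB1", "attB2")
               else c("attB3", "attB4")
  list(
    fwd = primer(paste0(name_prefix, "_F_", att_names[1L]), fwd_core,
                 tail = unname(tails["fwd"]), start = 0L,
                 end = nchar(fwd_core), strand = "+",
                 conditions = config$tm_conditions),
    rev = primer(paste0(name_prefix, "_R_", att_names[2L]), rev_core,
                 tail = unname(tails["rev"]),
                 start = nchar(arm) - nchar(rev_core), end = nchar(arm),
                 strand = "-", conditions = config$tm_conditions)
  )
}

#' Select an arm length whose terminal primers are designable
#'
#' Homology-arm amplification primers are anchored at the arm termini,
#' so a locally GC-skewed terminus can make the configured Tm/GC
#' windows unsatisfiable at the default arm length. This sweep tries
#' arm lengths within `config$arm_range` (starting from
#' `config$arm_len`, stepping outward) until both arms admit Gateway
#' primer pairs, mirroring how arm boundaries are chosen in practice.
#'
#' @param t Wild-type [transcript()] with context.
#' @param e Edit row carrying `repeat`/`mutation` attributes.
#' @param config [construct_config()].
#' @param step Sweep step in nt (default 10).
#' @param junction_offsets Candidate distances from the repeat's
#'   3'-most base to the cassette junction (swept in order).
#' @return `list(arms, ha1_primers, ha2_primers)`.
#' @export
design_construct_arms <- function(t, e, config = construct_config(),
                                  step = 10L,
                                  junction_offsets = seq.int(30L, 120L,
                                                             by = 15L)) {
  offsets <- c(0L, as.vector(rbind(seq.int(step, 500L, by = step),
                                   -seq.int(step, 500L, by = step))))
  lens <- unique(config$arm_len + offsets)
  lens <- lens[lens >= config$arm_range[1L] & lens <= config$arm_range[2L]]
  combos <- expand.grid(len = lens, jn_off = junction_offsets,
                        KEEP.OUT.ATTRS = FALSE)
  last_err <- NULL
  for (ci in seq_len(nrow(combos))) {
    len <- combos$len[ci]
    res <- tryCatch({
      arms <- extract_homology_arms(t, e, arm_len = len,
                                    junction_offset = combos$jn_off[ci],
                                    config = config)
      list(arms = arms,
           ha1_primers = make_gateway_arm_primers(
             arms$ha1, "P1-P2", config = config, name_prefix = "HA1"),
           ha2_primers = make_gateway_arm_primers(
             arms$ha2, "P3-P4", config = config, name_prefix = "HA2"))
    }, error = function(err) err)
    if (!inherits(res, "error")) return(res)
    last_err <- res
  }
  stop("no arm length in ", config$arm_range[1L], "-",
       config$arm_range[2L], " nt admits Gateway terminal primers; last ",
       "failure: ", conditionMessage(last_err), call. = FALSE)
}

# Design a primer whose core starts near `anchor` (1-based position on
# `template`) in the given direction; slides the anchor by up to
# `slide` nt to find a constraint-satisfying core.
design_primer_at <- function(template, anchor, direction = c("fwd", "rev"),
                             config = construct_config(), name = "primer",
                             slide = 60L) {
  direction <- match.arg(direction)
  n <- nchar(template)
  for (off in c(0L, seq_len(slide))) {
    for (sgn in if (off == 0L) 1L else c(1L, -1L)) {
      a <- anchor + sgn * off
      if (a < 1L || a > n) next
      core <- tryCatch(
        if (direction == "fwd")
          choose_core(substr(template, a, min(n, a + 60L)), config)
        else
          choose_core(revcomp(substr(template, max(1L, a - 60L), a)), config),
        error = function(e) NULL)
      if (!is.null(core)) {
        if (direction == "fwd")
          return(primer(name, core, start = a - 1L,
                        end = a - 1L + nchar(core), strand = "+",
                        conditions = config$tm_conditions))
        return(primer(name, core, start = a - nchar(core), end = a,
                      strand = "-", conditions = config$tm_conditions))
      }
    }
  }
  stop("could not design primer '", name, "' near position ", anchor,
       call. = FALSE)
}
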