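# In-silico PCR and screening-assay design.

#' In-silico PCR
#'
#' Exact-match PCR simulation: the forward core must occur on the plus
#' strand, the reverse core's reverse complement downstream of it.
#' Returns every product size up to `max_product` (tail lengths
#' included, since tails are incorporated into the amplicon after the
#' first cycles).
#'
#' @param template Template sequence.
#' @param fwd,rev [primer()] objects (or plain core strings).
#' @param max_product Longest product reported (default 10 kb).
#' @return Sorted integer vector of product sizes; empty when the pair
#'   does not amplify.
#' @export
in_silico_pcr <- function(template, fwd, rev, max_product = 10000L) {
  check_dna(template, "template")
  fwd_core <- if (inherits(fwd, "primer")) fwd$core else fwd
  rev_core <- if (inherits(rev, "primer")) rev$core else rev
  tail_len <- (if (inherits(fwd, "primer")) nchar(fwd$tail) else 0L) +
              (if (inherits(rev, "primer")) nchar(rev$tail) else 0L)
  f_pos <- find_all(template, fwd_core)
  r_pos <- find_all(template, revcomp(rev_core))
  if (!length(f_pos) || !length(r_pos)) return(integer())
  sizes <- integer()
  for (f in f_pos) {
    ends <- r_pos[r_pos >= f] + nchar(rev_core) - 1L
    sizes <- c(sizes, ends - f + 1L + tail_len)
  }
  sort(unique(sizes[sizes <= max_product]))
}

find_all <- function(template, pattern) {
  hits <- gregexpr(pattern, template, fixed = TRUE)[[1L]]
  if (hits[1L] == -1L) integer() else as.integer(hits)
}

#' Design the clone-screening assay panel
#'
#' Five assays covering the genotyping logic of an rAAV knock-in
#' experiment, with expected amplicon sizes computed by in-silico PCR
#' on each relevant template:
#'
#' * `WT_ALLELE` — both primers inside the homology region, spanning
#'   the cassette junction: a short product on the parental
#'   (untargeted) allele.
#' * `HA1_JUNCTION` / `HA2_JUNCTION` — one primer *outside* the
#'   homology arm, the other inside the cassette: products appear only
#'   on correctly targeted templates.
#' * `POST_CRE` — primers flanking the junction: after Cre excision the
#'   product shrinks by exactly the cassette length minus the single
#'   remaining loxP scar.
#' * `RT_ACROSS_EDIT` — cDNA primers spanning the inserted base, for
#'   sequencing the expressed allele.
#'
#' @param construct A [targeting_construct()].
#' @param t The wild-type [transcript()] the design came from.
#' @param config [construct_config()].
#' @return A list of class `screening_panel`: per assay either
#'   `list(name, fwd, rev, products)` (products keyed by template) or
#'   `list(name, failed = TRUE, reason)` when that assay could not be
#'   designed. Attribute `templates` carries the template sequences.
#' @export
design_screening_assays <- function(construct, t,
                                    config = construct_config()) {
  stopifnot(inherits(construct, "targeting_construct"),
            inherits(t, "transcript"))
  arms <- construct$arms
  m <- arms$mutation
  jn <- construct$junction
  arm_len <- arms$arm_len

  # genomic templates
  ctx_corr <- arms$corrected_context
  parental <- apply_variant(t$context, frameshift_variant(
    m$kind, t$cds_offset + m$position, m$bases))
  targeted <- paste0(substr(ctx_corr, 1L, jn), construct$cassette,
                     substr(ctx_corr, jn + 1L, nchar(ctx_corr)))
  post_cre <- paste0(substr(ctx_corr, 1L, jn), LOXP,
                     substr(ctx_corr, jn + 1L, nchar(ctx_corr)))
  genomic <- list(parental = parental, targeted = targeted,
                  post_cre = post_cre)
  # cDNA templates; the intronless model extends the mature transcript
  # past the stop codon with up to 300 nt of context (a 3' UTR stand-in)
  # so primers downstream of a near-C-terminal edit have room to bind
  utr3 <- ""
  if (!is.null(t$context)) {
    utr_start <- t$cds_offset + nchar(t$cds) + 1L
    utr3 <- substr(t$context, utr_start,
                   min(nchar(t$context), utr_start + 299L))
  }
  cdna <- list(cdna_parental = paste0(apply_variant(t$cds, m), utr3),
               cdna_corrected = paste0(arms$corrected_cds, utr3))

  edit_ctx <- arms$cds_offset + arms$edit$position_c  # 1-based context pos

  assay <- function(name, templates, fwd_spec, rev_spec) {
    tryCatch({
      fwd <- do.call(design_primer_at, fwd_spec)
      rev <- do.call(design_primer_at, rev_spec)
      products <- lapply(templates, in_silico_pcr, fwd = fwd, rev = rev)
      list(name = name, fwd = fwd, rev = rev, products = products)
    }, error = function(e)
      list(name = name, failed = TRUE, reason = conditionMessage(e)))
  }

  panel <- list(
    WT_ALLELE = assay("WT_ALLELE", genomic,
      list(parental, anchor = jn - 280L, direction = "fwd", config = config,
           name = "WT_F"),
      list(parental, anchor = jn + 280L, direction = "rev", config = config,
           name = "WT_R")),
    HA1_JUNCTION = assay("HA1_JUNCTION", genomic,
      list(parental, anchor = jn - arm_len - 180L, direction = "fwd",
           config = config, name = "HA1_out_F"),
      list(construct$cassette, anchor = 260L, direction = "rev",
           config = config, name = "cassette_5p_R")),
    HA2_JUNCTION = assay("HA2_JUNCTION", genomic,
      list(construct$cassette, anchor = nchar(construct$cassette) - 260L,
           direction = "fwd", config = config, name = "cassette_3p_F"),
      list(parental, anchor = jn + arm_len + 180L, direction = "rev",
           config = config, name = "HA2_out_R")),
    POST_CRE = assay("POST_CRE", genomic,
      list(parental, anchor = jn - 150L, direction = "fwd", config = config,
           name = "CRE_F"),
      list(parental, anchor = jn + 150L, direction = "rev", config = config,
           name = "CRE_R")),
    RT_ACROSS_EDIT = assay("RT_ACROSS_EDIT", cdna,
      list(cdna$cdna_corrected, anchor = arms$edit$position_c - 150L,
           direction = "fwd", config = config, name = "RT_F"),
      list(cdna$cdna_corrected, anchor = arms$edit$position_c + 150L,
           direction = "rev", config = config, name = "RT_R"))
  )
  structure(panel, class = "screening_panel",
            templates = c(genomic, cdna), edit_context_pos = edit_ctx)
}

#' Presence/absence matrix of a screening panel
#'
#' Condenses per-template product lists into a logical matrix (assay x
#' template): `TRUE` when at least one product of a conventional
#' screening size (<= `max_band`) is expected.
#'
#' @param panel A `screening_panel` from [design_screening_assays()].
#' @param max_band Largest band treated as amplifiable (default 5 kb).
#' @return Logical matrix; failed assays give `NA` rows.
#' @export
assay_presence_matrix <- function(panel, max_band = 5000L) {
  templates <- names(attr(panel, "templates"))
  mat <- matrix(NA, nrow = length(panel), ncol = length(templates),
                dimnames = list(names(panel), templates))
  for (a in names(panel)) {
    if (isTRUE(panel[[a]]$failed)) next
    for (tm in names(panel[[a]]$products))
      mat[a, tm] <- any(panel[[a]]$products[[tm]] <= max_band)
  }
  mat
}
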