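# ChIP peak annotation: genic/exonic/intergenic classification, TSS
# metaprofile and genic-enrichment factor versus a reference peak set.

#' Read peak intervals from BED
#'
#' @param path BED file (0-based half-open on disk; returned as a
#'   `GRanges`, i.e. 1-based inclusive — rtracklayer converts).
#' @return A `GRanges` of peaks.
#' @export
read_peaks <- function(path) {
  rtracklayer::import(path, format = "BED")
}

#' Read gene models from GFF3
#'
#' @param path GFF3 file with `gene` (and optionally `exon`) features.
#' @return A list of class `gene_models`: `genes` (GRanges), `exons`
#'   (GRanges, possibly empty), `tss` (width-1 GRanges at each gene's
#'   strand-aware start).
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "GFF3")
  gene_models(genes = gr[gr$type == "gene"],
              exons = gr[gr$type == "exon"])
}

#' Gene-model container
#'
#' @param genes `GRanges` of gene bodies (strand required for TSS
#'   orientation).
#' @param exons Optional `GRanges` of exons.
#' @return A list of class `gene_models` with `genes`, `exons`, `tss`.
#' @export
gene_models <- function(genes, exons = GenomicRanges::GRanges()) {
  stopifnot(methods::is(genes, "GRanges"))
  structure(list(genes = genes, exons = exons,
                 tss = GenomicRanges::resize(genes, width = 1L,
                                             fix = "start")),
            class = "gene_models")
}

#' Classify peaks and summarize genic/TSS enrichment
#'
#' Each peak is classified by any-base-pair overlap with priority
#' exon > genic > intergenic. The TSS metaprofile counts peak midpoints
#' in strand-oriented bins of width `binwidth` within
#' `tss_halfwidth` of every TSS (upstream bins negative). The
#' enrichment factor compares the genic fraction (exonic + intronic
#' gene-body overlap) of `peaks` against that of `reference_peaks`.
#'
#' @param peaks `GRanges` of test peaks (e.g. an edited clone).
#' @param genes A [gene_models()] object (or a `GRanges` of gene
#'   bodies).
#' @param tss_halfwidth Metaprofile half-width in bp (default 2000).
#' @param reference_peaks Optional `GRanges` of reference peaks (e.g.
#'   the parental line) for the enrichment factor.
#' @param binwidth Metaprofile bin width in bp (default 100).
#' @return A list of class `peak_summary`: `counts` (named vector
#'   genic/exonic/intergenic), `total`, `genic_fraction`,
#'   `tss_profile` (counts per bin, `2 * tss_halfwidth / binwidth`
#'   bins), `tss_breaks`, `enrichment` (factor vs reference, `NA` with
#'   `enrichment_defined = FALSE` when undefined).
#' @export
peak_feature_summary <- function(peaks, genes, tss_halfwidth = 2000L,
                                 reference_peaks = NULL, binwidth = 100L) {
  if (!inherits(genes, "gene_models")) genes <- gene_models(genes)
  stopifnot(methods::is(peaks, "GRanges"))
  check_seqspace(peaks, genes$genes)

  cls <- classify_peaks(peaks, genes)
  counts <- c(genic = sum(cls == "genic"),
              exonic = sum(cls == "exonic"),
              intergenic = sum(cls == "intergenic"))
  genic_fraction <- if (length(peaks))
    (counts[["genic"]] + counts[["exonic"]]) / length(peaks) else NA_real_

  # strand-oriented midpoint offsets relative to every nearby TSS
  nbin <- as.integer(2L * tss_halfwidth / binwidth)
  breaks <- seq(-tss_halfwidth, tss_halfwidth, by = binwidth)
  profile <- integer(nbin)
  if (length(peaks) && length(genes$tss)) {
    mids <- GenomicRanges::resize(peaks, width = 1L, fix = "center")
    win <- suppressWarnings(GenomicRanges::resize(
      genes$tss, width = 2L * tss_halfwidth, fix = "center"))
    hits <- GenomicRanges::findOverlaps(mids, win, ignore.strand = TRUE)
    if (length(hits)) {
      mpos <- GenomicRanges::start(mids)[S4Vectors::queryHits(hits)]
      tpos <- GenomicRanges::start(genes$tss)[S4Vectors::subjectHits(hits)]
      sgn <- ifelse(as.character(
        GenomicRanges::strand(genes$tss))[S4Vectors::subjectHits(hits)] ==
          "-", -1L, 1L)
      off <- (mpos - tpos) * sgn
      keep <- off >= -tss_halfwidth & off < tss_halfwidth
      bin <- floor((off[keep] + tss_halfwidth) / binwidth) + 1L
      tab <- tabulate(bin, nbins = nbin)
      profile <- profile + tab
    }
  }

  enrichment <- NA_real_
  enrichment_defined <- FALSE
  if (!is.null(reference_peaks)) {
    check_seqspace(reference_peaks, genes$genes)
    rcls <- classify_peaks(reference_peaks, genes)
    ref_frac <- if (length(reference_peaks))
      mean(rcls != "intergenic") else NA_real_
    if (!length(peaks) || !length(reference_peaks) ||
        is.na(ref_frac) || ref_frac == 0) {
      enrichment_defined <- FALSE
    } else {
      enrichment <- genic_fraction / ref_frac
      enrichment_defined <- TRUE
    }
  }

  structure(list(counts = counts, total = length(peaks),
                 genic_fraction = genic_fraction,
                 tss_profile = profile, tss_breaks = breaks,
                 enrichment = enrichment,
                 enrichment_defined = enrichment_defined),
            class = "peak_summary")
}

classify_peaks <- function(peaks, models) {
  cls <- rep("intergenic", length(peaks))
  if (length(models$genes)) {
    hit_gene <- IRanges::overlapsAny(peaks, models$genes,
                                     ignore.strand = TRUE)
    cls[hit_gene] <- "genic"
  }
  if (length(models$exons)) {
    hit_exon <- IRanges::overlapsAny(peaks, models$exons,
                                     ignore.strand = TRUE)
    cls[hit_exon] <- "exonic"
  }
  cls
}

check_seqspace <- function(x, ref) {
  unknown <- setdiff(as.character(GenomeInfoDb::seqnames(x)),
                     GenomeInfoDb::seqlevels(ref))
  if (length(unknown))
    stop("peaks use sequence name(s) absent from the gene models: ",
         paste(unique(unknown), collapse = ", "), call. = FALSE)
}
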