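# Gene-set overlap statistics: hypergeometric tail + Benjamini-Hochberg
# over an explicit family size.

#' Read gene sets from a GMT file
#'
#' Thin wrapper around `fgsea::gmtPathways()`.
#'
#' @param path Path to a `.gmt` file.
#' @return Named list of character vectors (one per gene set).
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Hypergeometric gene-set overlap
#'
#' Upper-tail probability of observing at least `k` query genes inside
#' a gene set of size `K`, drawing `n = |query|` genes from a universe
#' of `N`: `p = P(X >= k)` with `X ~ Hypergeometric(N, K, n)`. The
#' displayed ratio `k/K` is rounded to 2 decimals; full precision is
#' retained in `ratio`.
#'
#' @param query Character vector of query gene ids (e.g. the
#'   concordantly deregulated genes).
#' @param gene_set Character vector of gene ids in the set.
#' @param universe_n Universe size `N` (total genes assayed). Required:
#'   overlap p-values are meaningless without an explicit universe.
#' @param name Optional gene-set name carried into the result.
#' @return A list of class `geneset_overlap`: `set`, `K`, `k`, `n`,
#'   `N`, `ratio`, `ratio_display`, `p`.
#' @export
#' @examples
#' hypergeometric_overlap(paste0("g", 1:10), paste0("g", 6:40), 1000)
hypergeometric_overlap <- function(query, gene_set, universe_n,
                                   name = NA_character_) {
  query <- unique(as.character(query))
  gene_set <- unique(as.character(gene_set))
  n <- length(query)
  K <- length(gene_set)
  N <- as.integer(universe_n)
  if (length(N) != 1L || is.na(N) || N < 1L)
    stop("universe_n must be a single positive integer", call. = FALSE)
  if (N < n || N < K)
    stop("universe size N = ", N, " smaller than query (", n,
         ") or gene set (", K, ")", call. = FALSE)
  k <- length(intersect(query, gene_set))
  p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  structure(list(set = name, K = K, k = k, n = n, N = N,
                 ratio = if (K > 0L) k / K else NA_real_,
                 ratio_display = if (K > 0L) round(k / K, 2L) else NA_real_,
                 p = p),
            class = "geneset_overlap")
}

#' Benjamini-Hochberg adjustment over an explicit family size
#'
#' Step-up adjustment `q_i = min_{i <= j <= m'} (p_j * m / j)` (clipped
#' to 1) applied to the `m'` smallest p-values of a family of `m`
#' tests. Supplying `family_size` separately from the list length
#' matters when only the top of a collection is tabulated (e.g. the
#' five best of 50 hallmark sets): the adjustment is exact whenever the
#' unobserved p-values are large enough not to enter any minimum,
#' which holds when `p[m'] * m / m'` does not exceed any unobserved
#' `p_j * m / j`.
#'
#' The computation is delegated to `stats::p.adjust(..., n = m)`;
#' input must already be sorted ascending — no silent sorting.
#'
#' @param p_sorted Ascending p-values (the `m'` smallest of the family).
#' @param family_size Total number of tests `m` (`>= length(p_sorted)`).
#' @return Numeric vector of q-values, same length as `p_sorted`,
#'   non-decreasing.
#' @export
#' @examples
#' bh_adjust(c(2.30e-5, 2.30e-5, 2.30e-5, 5.67e-5, 5.86e-5), 50)
bh_adjust <- function(p_sorted, family_size) {
  if (!is.numeric(p_sorted) || any(p_sorted < 0) || any(p_sorted > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  if (is.unsorted(p_sorted))
    stop("p_sorted must be in ascending order (no silent sorting)",
         call. = FALSE)
  m <- as.integer(family_size)
  if (m < length(p_sorted))
    stop("family_size (", m, ") must be at least the number of supplied ",
         "p-values (", length(p_sorted), ")", call. = FALSE)
  stats::p.adjust(p_sorted, method = "BH", n = m)
}

#' Overlap table for a query against a gene-set collection
#'
#' Runs [hypergeometric_overlap()] for every set, sorts by p, adjusts
#' with [bh_adjust()] over the collection size (the full family, even
#' if only the top rows are later displayed).
#'
#' @param query Character vector of query gene ids.
#' @param gene_sets Named list of gene sets (see [read_gmt()]).
#' @param universe_n Universe size `N`.
#' @param family_size BH family size `m`; defaults to
#'   `length(gene_sets)`.
#' @return A data.frame sorted by `p`: `set`, `K`, `k`, `ratio`,
#'   `ratio_display`, `p`, `q`.
#' @export
geneset_overlap_table <- function(query, gene_sets, universe_n,
                                  family_size = length(gene_sets)) {
  stopifnot(is.list(gene_sets), !is.null(names(gene_sets)))
  rows <- lapply(names(gene_sets), function(nm) {
    o <- hypergeometric_overlap(query, gene_sets[[nm]], universe_n,
                                name = nm)
    data.frame(set = nm, K = o$K, k = o$k, ratio = o$ratio,
               ratio_display = o$ratio_display, p = o$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$p, out$set), , drop = FALSE]
  out$q <- bh_adjust(out$p, family_size)
  rownames(out) <- NULL
  out
}

#' Published hallmark-overlap statistics for PRDM2-regulated genes
#'
#' The five top-scoring MSigDB hallmark gene sets (of the 50-set
#' collection) enriched among genes concordantly deregulated after
#' repeat-stabilizing correction of PRDM2 in HCT116 clones, under
#' normal and serum-starved culture. Columns: condition, set, `K`
#' (set size), `k` (overlap), and the reported hypergeometric `p`.
#' The tabulated q-values accompanying these statistics are reproduced
#' by `bh_adjust(p, family_size = 50)` within each condition.
#'
#' @return A data.frame with columns `condition`, `set`, `K`, `k`, `p`.
#' @export
prdm2_hallmark_overlaps <- function() {
  data.frame(
    condition = rep(c("normal", "serum_starved"), each = 5L),
    set = c("EPITHELIAL_MESENCHYMAL_TRANSITION", "KRAS_SIGNALING_UP",
            "TNFA_SIGNALING_VIA_NFKB", "UV_RESPONSE_DN",
            "CHOLESTEROL_HOMEOSTASIS",
            "EPITHELIAL_MESENCHYMAL_TRANSITION", "TNFA_SIGNALING_VIA_NFKB",
            "UV_RESPONSE_DN", "TGF_BETA_SIGNALING", "KRAS_SIGNALING_UP"),
    K = c(200L, 200L, 200L, 144L, 74L, 200L, 200L, 144L, 54L, 200L),
    k = c(6L, 6L, 6L, 5L, 4L, 10L, 9L, 8L, 4L, 6L),
    p = c(2.30e-5, 2.30e-5, 2.30e-5, 5.67e-5, 5.86e-5,
          2.36e-9, 3.79e-8, 4.34e-8, 3.81e-5, 7.40e-5),
    stringsAsFactors = FALSE)
}
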