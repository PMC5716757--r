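# Cross-clone fold-change intersection.

#' Expression comparison constructor
#'
#' Per-gene linear fold changes of each edited clone versus the
#' parental line.
#'
#' @param folds A data.frame with a `gene` column and one numeric
#'   column per clone (fold changes, all positive), or a numeric
#'   matrix with gene rownames.
#' @param threshold Fold-change threshold (> 1; default 1.5).
#' @return A list of class `expression_comparison` with elements
#'   `folds` (matrix, genes x clones), `clones`, `threshold`.
#' @export
expression_comparison <- function(folds, threshold = 1.5) {
  if (threshold <= 1)
    stop("threshold must be greater than 1 (got ", threshold, ")",
         call. = FALSE)
  if (is.data.frame(folds)) {
    if (!"gene" %in% names(folds))
      stop("folds data.frame needs a 'gene' column", call. = FALSE)
    m <- as.matrix(folds[setdiff(names(folds), "gene")])
    rownames(m) <- folds$gene
  } else {
    m <- as.matrix(folds)
    if (is.null(rownames(m)))
      stop("fold matrix needs gene rownames", call. = FALSE)
  }
  if (!is.numeric(m) || ncol(m) < 1L)
    stop("at least one clone column of numeric fold changes is required",
         call. = FALSE)
  if (any(!is.finite(m)) || any(m <= 0))
    stop("fold changes must be finite and positive", call. = FALSE)
  structure(list(folds = m, clones = colnames(m), threshold = threshold),
            class = "expression_comparison")
}

#' Genes concordantly changed in all clones
#'
#' A gene is called "up" when its fold change is at or above the
#' threshold in *every* clone, and "down" when at or below the
#' reciprocal threshold in every clone (inclusive comparisons; a gene
#' at 1.49-fold in a single clone is excluded). This strict
#' all-clone intersection filters clone-private noise and leaves the
#' expression changes attributable to the engineered correction.
#'
#' @param fc An [expression_comparison()] (or a data.frame/matrix
#'   accepted by it).
#' @param threshold Overrides the comparison's threshold if given.
#' @return `list(up, down)`: character vectors of gene ids, sorted.
#' @export
clone_intersection <- function(fc, threshold = NULL) {
  if (!inherits(fc, "expression_comparison"))
    fc <- expression_comparison(fc)
  if (!is.null(threshold)) {
    if (threshold <= 1)
      stop("threshold must be greater than 1 (got ", threshold, ")",
           call. = FALSE)
    fc$threshold <- threshold
  }
  t <- fc$threshold
  up <- rownames(fc$folds)[apply(fc$folds >= t, 1L, all)]
  down <- rownames(fc$folds)[apply(fc$folds <= 1 / t, 1L, all)]
  list(up = sort(up), down = sort(down))
}

#' Read a delimited per-clone fold-change table
#'
#' @param path Delimited text with a header: a `gene` column plus one
#'   numeric fold-change column per clone.
#' @param sep Field separator (default tab).
#' @param threshold Passed to [expression_comparison()].
#' @return An [expression_comparison()].
#' @export
read_fold_changes <- function(path, sep = "\t", threshold = 1.5) {
  expression_comparison(
    utils::read.table(path, header = TRUE, sep = sep,
                      stringsAsFactors = FALSE),
    threshold = threshold)
}
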