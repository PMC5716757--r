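# Relative qPCR quantification (delta-delta-Ct).

#' Ct table constructor/validator
#'
#' @param x A data.frame with columns `sample`, `gene`, `replicate`,
#'   `ct` (threshold cycles; finite and positive).
#' @return The validated data.frame with class `ct_table`.
#' @export
ct_table <- function(x) {
  need <- c("sample", "gene", "replicate", "ct")
  if (!all(need %in% names(x)))
    stop("Ct table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (!all(is.finite(x$ct)) || any(x$ct <= 0))
    stop("Ct values must be finite and positive", call. = FALSE)
  class(x) <- unique(c("ct_table", class(x)))
  x
}

#' Read a delimited Ct table
#'
#' @param path Tab- or comma-delimited file with header columns
#'   `sample`, `gene`, `replicate`, `ct`.
#' @param sep Field separator (default tab).
#' @return A [ct_table()].
#' @export
read_ct_table <- function(path, sep = "\t") {
  ct_table(utils::read.table(path, header = TRUE, sep = sep,
                             stringsAsFactors = FALSE))
}

#' Relative expression by the delta-delta-Ct method
#'
#' For each sample, `dCt = mean Ct(target) - mean over reference genes
#' of mean Ct(ref)` (multiple references are combined by the
#' arithmetic mean of their mean Cts, i.e. the geometric mean of their
#' linear quantities), and `RQ = 2^-(dCt_sample - dCt_calibrator)`, so
#' the calibrator sample has RQ = 1. Replicate spread is propagated to
#' RQ bounds: `rq_min/rq_max = 2^-(ddCt +/- s)` with `s` the combined
#' standard error of the sample's target and reference mean Cts; with
#' single replicates the bounds equal the point estimate.
#'
#' @param ct A [ct_table()] (or plain data.frame with its columns).
#' @param target Target gene id.
#' @param references Character vector of reference gene ids.
#' @param calibrator Sample id used as the RQ = 1 baseline.
#' @return A data.frame with one row per sample: `sample`, `dct`,
#'   `ddct`, `rq`, `rq_min`, `rq_max`.
#' @export
relative_quantity <- function(ct, target, references, calibrator) {
  ct <- ct_table(as.data.frame(ct))
  samples <- unique(ct$sample)
  if (!calibrator %in% samples)
    stop("calibrator sample '", calibrator, "' not present", call. = FALSE)
  for (g in c(target, references)) {
    have <- unique(ct$sample[ct$gene == g])
    missing <- setdiff(samples, have)
    if (length(missing))
      stop("gene '", g, "' missing in sample(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
  }

  per_sample <- lapply(samples, function(s) {
    tgt <- ct$ct[ct$sample == s & ct$gene == target]
    ref_means <- vapply(references, function(g)
      mean(ct$ct[ct$sample == s & ct$gene == g]), numeric(1L))
    sem <- function(x) if (length(x) > 1L) stats::sd(x) / sqrt(length(x)) else 0
    ref_sems <- vapply(references, function(g)
      sem(ct$ct[ct$sample == s & ct$gene == g]), numeric(1L))
    list(dct = mean(tgt) - mean(ref_means),
         s = sqrt(sem(tgt)^2 + sum(ref_sems^2) / length(references)^2))
  })
  names(per_sample) <- samples
  dct_cal <- per_sample[[calibrator]]$dct

  out <- do.call(rbind, lapply(samples, function(s) {
    p <- per_sample[[s]]
    ddct <- p$dct - dct_cal
    data.frame(sample = s, dct = p$dct, ddct = ddct,
               rq = 2^(-ddct),
               rq_min = 2^(-(ddct + p$s)),
               rq_max = 2^(-(ddct - p$s)),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
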