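# Transcript/CDS data model and translation.

# Standard nuclear genetic code, captured at build time so translation
# needs no lazy-binding resolution on first use.
GENETIC_CODE_TABLE <- Biostrings::GENETIC_CODE

#' Transcript constructor
#'
#' A transcript is a CDS on the HGVS c. axis (c.1 = first base of the
#' start codon), optionally embedded in a genomic context window that
#' contains the CDS as an exact substring at a recorded offset. The
#' model is intentionally intronless: multi-exon transcripts are
#' represented as the spliced CDS plus one contiguous genomic window
#' around the region of interest.
#'
#' @param cds CDS sequence (A/C/G/T/N character scalar).
#' @param id Transcript identifier.
#' @param context Optional genomic context sequence containing `cds`.
#' @param cds_offset 0-based offset of the CDS within `context`
#'   (required when `context` is given).
#' @return An object of class `transcript`.
#' @export
#' @examples
#' transcript("ATGAAATGA", id = "toy")
transcript <- function(cds, id = "transcript", context = NULL,
                       cds_offset = NULL) {
  check_dna(cds, "cds")
  assert_scalar_string(id, "id")
  if (!is.null(context)) {
    check_dna(context, "context")
    if (is.null(cds_offset))
      stop("cds_offset is required when a genomic context is supplied",
           call. = FALSE)
    cds_offset <- as.integer(cds_offset)
    if (cds_offset < 0L || cds_offset + nchar(cds) > nchar(context))
      stop("cds_offset places the CDS outside the context", call. = FALSE)
    if (substr(context, cds_offset + 1L, cds_offset + nchar(cds)) != cds)
      stop("context does not contain the CDS at the recorded offset",
           call. = FALSE)
  } else {
    cds_offset <- NA_integer_
  }
  structure(list(id = id, cds = cds, context = context,
                 cds_offset = cds_offset),
            class = "transcript")
}

#' @export
print.transcript <- function(x, ...) {
  cat("<transcript> ", x$id, ": CDS ", nchar(x$cds), " nt", sep = "")
  if (!is.null(x$context))
    cat(", context ", nchar(x$context), " nt (CDS at offset ",
        x$cds_offset, ")", sep = "")
  cat("\n")
  invisible(x)
}

# Map a c. coordinate to a 1-based position on the context
c_to_context <- function(t, pos_c) {
  if (is.null(t$context))
    stop("transcript '", t$id, "' has no genomic context", call. = FALSE)
  t$cds_offset + as.integer(pos_c)
}

#' Translate a CDS under the standard nuclear genetic code
#'
#' Codon-by-codon translation using the standard code table
#' (`Biostrings::GENETIC_CODE`). Stop codons are rendered as `"*"`;
#' any codon containing `N` becomes the unknown residue `"X"`.
#'
#' @param cds CDS sequence; length must be a multiple of 3 unless
#'   `partial = TRUE`, in which case a trailing partial codon is
#'   dropped (useful for inspecting frameshifted sequences).
#' @param partial Drop a trailing partial codon instead of erroring.
#' @return Amino-acid string (one letter per codon, including the
#'   terminal `"*"` if present).
#' @export
#' @examples
#' translate_cds("ATGAAAAAGTAA")  # "MKK*" ; AAA and AAG both encode Lys
translate_cds <- function(cds, partial = FALSE) {
  check_dna(cds, "cds")
  n <- nchar(cds)
  if (n %% 3L != 0L) {
    if (!partial)
      stop("CDS length ", n, " is not a multiple of 3", call. = FALSE)
    n <- n - n %% 3L
    if (n == 0L) return("")
  }
  starts <- seq.int(1L, n - 2L, by = 3L)
  codons <- substring(cds, starts, starts + 2L)
  aa <- unname(GENETIC_CODE_TABLE[codons])
  aa[is.na(aa)] <- "X"
  paste0(aa, collapse = "")
}

#' Read a transcript from FASTA or GenBank
#'
#' FASTA input treats the (single) record as the CDS with no genomic
#' context. GenBank input requires exactly one `CDS` feature: the
#' feature's span becomes the CDS and the full record becomes the
#' genomic context.
#'
#' @param path Input file.
#' @param format `"fasta"` or `"genbank"` (default guessed from the
#'   file extension).
#' @return A [transcript()].
#' @export
read_transcript <- function(path, format = c("auto", "fasta", "genbank")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(gb|gbk|genbank)$", path, ignore.case = TRUE))
      "genbank" else "fasta"
  }
  if (format == "fasta") {
    ss <- Biostrings::readDNAStringSet(path)
    if (length(ss) != 1L)
      stop("expected exactly one FASTA record, found ", length(ss),
           call. = FALSE)
    return(transcript(toupper(as.character(ss[[1L]])),
                      id = sub("\\s.*$", "", names(ss)[1L])))
  }
  rec <- read_genbank(path)
  cds_feats <- rec$features[rec$features$key == "CDS", , drop = FALSE]
  if (nrow(cds_feats) == 0L)
    stop("GenBank record '", rec$name, "' has no CDS feature", call. = FALSE)
  if (nrow(cds_feats) > 1L)
    stop("GenBank record '", rec$name, "' has ", nrow(cds_feats),
         " CDS features (", paste(sprintf("%d..%d", cds_feats$start,
                                          cds_feats$end), collapse = ", "),
         "); exactly one is required", call. = FALSE)
  start <- cds_feats$start[1L]
  end <- cds_feats$end[1L]
  transcript(substr(rec$sequence, start, end), id = rec$name,
             context = rec$sequence, cds_offset = start - 1L)
}

#' Write a transcript to FASTA or GenBank
#'
#' The GenBank writer emits the context (or the bare CDS when no
#' context is recorded) with a single `CDS` feature; [read_transcript()]
#' round-trips it byte-exactly at the sequence level.
#'
#' @param t A [transcript()].
#' @param path Output file.
#' @param format `"fasta"` (CDS only) or `"genbank"`.
#' @return `path`, invisibly.
#' @export
write_transcript <- function(t, path, format = c("genbank", "fasta")) {
  stopifnot(inherits(t, "transcript"))
  format <- match.arg(format)
  if (format == "fasta") {
    ss <- Biostrings::DNAStringSet(t$cds)
    names(ss) <- t$id
    Biostrings::writeXStringSet(ss, path)
    return(invisible(path))
  }
  seq <- if (is.null(t$context)) t$cds else t$context
  off <- if (is.null(t$context)) 0L else t$cds_offset
  feats <- data.frame(key = "CDS", start = off + 1L,
                      end = off + nchar(t$cds), strand = "+",
                      label = t$id, stringsAsFactors = FALSE)
  write_genbank(list(name = t$id, sequence = seq, features = feats), path)
}
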