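# Minimal GenBank flat-file reader/writer.
#
# None of the installed sequence packages parse GenBank feature tables,
# so a small reader/writer is provided covering the subset this package
# emits: single-record files, simple `start..end` or
# `complement(start..end)` locations, and `/label=` qualifiers. Records
# are plain lists: list(name, sequence, features), where features is a
# data.frame(key, start, end, strand, label) with 1-based inclusive
# coordinates, matching GenBank convention.

#' Read a GenBank flat file
#'
#' @param path Path to a single-record GenBank file.
#' @return `list(name, sequence, features)`; `features` is a
#'   data.frame with columns `key`, `start`, `end`, `strand`, `label`
#'   (1-based inclusive coordinates).
#' @export
read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !grepl("^LOCUS", lines[1L]))
    stop("not a GenBank flat file (missing LOCUS line): ", path,
         call. = FALSE)
  name <- strsplit(trimws(sub("^LOCUS\\s+", "", lines[1L])), "\\s+")[[1L]][1L]

  feat_start <- grep("^FEATURES", lines)
  origin <- grep("^ORIGIN", lines)
  if (!length(origin)) stop("GenBank file has no ORIGIN section", call. = FALSE)

  features <- data.frame(key = character(), start = integer(),
                         end = integer(), strand = character(),
                         label = character(), stringsAsFactors = FALSE)
  if (length(feat_start)) {
    fl <- lines[(feat_start[1L] + 1L):(origin[1L] - 1L)]
    key_idx <- grep("^ {5}\\S", fl)
    for (i in seq_along(key_idx)) {
      block_end <- if (i < length(key_idx)) key_idx[i + 1L] - 1L
                   else length(fl)
      block <- fl[key_idx[i]:block_end]
      header <- strsplit(trimws(block[1L]), "\\s+")[[1L]]
      key <- header[1L]
      loc <- header[2L]
      strand <- "+"
      if (grepl("^complement\\(", loc)) {
        strand <- "-"
        loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
      }
      if (!grepl("^[0-9]+\\.\\.[0-9]+$", loc) && !grepl("^[0-9]+$", loc))
        stop("unsupported GenBank location '", loc, "' for feature ", key,
             call. = FALSE)
      bounds <- as.integer(strsplit(loc, "..", fixed = TRUE)[[1L]])
      if (length(bounds) == 1L) bounds <- c(bounds, bounds)
      label <- NA_character_
      lab_line <- grep("^\\s+/label=", block, value = TRUE)
      if (length(lab_line))
        label <- gsub("\"", "", sub("^\\s+/label=", "", lab_line[1L]))
      features <- rbind(features, data.frame(
        key = key, start = bounds[1L], end = bounds[2L], strand = strand,
        label = label, stringsAsFactors = FALSE))
    }
  }

  seq_lines <- lines[(origin[1L] + 1L):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste0(seq_lines, collapse = "")))
  check_dna(sequence, paste0("sequence of ", name))

  list(name = name, sequence = sequence, features = features)
}

#' Write a GenBank flat file
#'
#' @param record `list(name, sequence, features)` as returned by
#'   [read_genbank()]; `features` may be `NULL`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(record, path) {
  seq <- record$sequence
  check_dna(seq, "sequence")
  n <- nchar(seq)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("LOCUS       %s %d bp    DNA     linear   UNA",
                     record$name, n), con)
  writeLines(sprintf("DEFINITION  %s.", record$name), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  feats <- record$features
  if (!is.null(feats) && nrow(feats)) {
    for (i in seq_len(nrow(feats))) {
      loc <- sprintf("%d..%d", feats$start[i], feats$end[i])
      if (!is.null(feats$strand) && identical(feats$strand[i], "-"))
        loc <- sprintf("complement(%s)", loc)
      writeLines(sprintf("     %-16s%s", feats$key[i], loc), con)
      if (!is.null(feats$label) && !is.na(feats$label[i]))
        writeLines(sprintf("                     /label=\"%s\"",
                           feats$label[i]), con)
    }
  }
  writeLines("ORIGIN", con)
  starts <- seq.int(1L, n, by = 60L)
  for (s in starts) {
    chunk <- substr(seq, s, min(s + 59L, n))
    # ten-base blocks, lower case, 9-wide position column
    blocks <- substring(chunk, seq(1L, nchar(chunk), 10L),
                        pmin(seq(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
    writeLines(sprintf("%9d %s", s, tolower(paste(blocks, collapse = " "))),
               con)
  }
  writeLines("//", con)
  invisible(path)
}
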