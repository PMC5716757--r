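# HGVS c.-style variant parsing, normalization and application.
#
# Coordinates: HGVS c. positions are 1-based on the coding sequence
# (c.1 = first base of the start codon). Insertions are carried in the
# "occupied position" dialect: "c.NinsB" means the inserted base B
# occupies position N of the *edited* sequence (equivalently the anchor
# form c.(N-1)_NinsB). All internal string surgery converts to 0-based
# half-open offsets at the function boundary.

#' Frameshift variant constructor
#'
#' Builds a small-indel variant record on CDS (HGVS c.) coordinates.
#' Only deletions and insertions of up to 3 bases are supported; these
#' are the events relevant to mononucleotide-repeat slippage and its
#' correction.
#'
#' @param kind `"del"` or `"ins"`.
#' @param position 1-based c. coordinate. For deletions, the first
#'   deleted base; for insertions, the position the inserted bases
#'   occupy in the edited sequence.
#' @param bases Deleted or inserted bases (1-3 nt, A/C/G/T).
#' @param normalized Logical flag set by [normalize_3prime()].
#' @return An object of class `frameshift_variant`.
#' @seealso [parse_hgvs_c()], [apply_variant()], [normalize_3prime()]
#' @export
#' @examples
#' frameshift_variant("del", 4467, "A")
frameshift_variant <- function(kind, position, bases, normalized = FALSE) {
  kind <- match.arg(kind, c("del", "ins"))
  if (!is.numeric(position) || length(position) != 1L || position < 1 ||
      position != as.integer(position))
    stop("position must be a single positive integer (c. coordinate)",
         call. = FALSE)
  check_dna(bases, "bases", allow_n = FALSE)
  if (nchar(bases) < 1L || nchar(bases) > 3L)
    stop("unsupported variant: only del/ins of 1-3 bases are handled (got ",
         nchar(bases), " bases)", call. = FALSE)
  structure(
    list(kind = kind, position = as.integer(position), bases = bases,
         normalized = isTRUE(normalized)),
    class = "frameshift_variant"
  )
}

#' Parse an HGVS c.-style small indel
#'
#' Supported grammar: `c.<pos>del<base(s)>`, `c.<pos>ins<base(s)>`
#' (occupied-position insertion dialect, e.g. `"c.4464insG"`), and the
#' anchor form `c.<pos>_<pos+1>ins<base(s)>`. Anything else — including
#' `dup`, substitutions and ranged deletions — is rejected with an
#' error naming the offending token.
#'
#' @param text A single variant string such as `"c.4467delA"`.
#' @return A [frameshift_variant()].
#' @export
#' @examples
#' parse_hgvs_c("c.4467delA")
#' parse_hgvs_c("c.4464insG")
#' parse_hgvs_c("c.4463_4464insG")
parse_hgvs_c <- function(text) {
  assert_scalar_string(text, "variant text")
  m <- regmatches(text, regexec("^c\\.([0-9]+)del([ACGT]+)$", text))[[1L]]
  if (length(m)) {
    return(frameshift_variant("del", as.integer(m[2L]), m[3L]))
  }
  m <- regmatches(text, regexec("^c\\.([0-9]+)ins([ACGT]+)$", text))[[1L]]
  if (length(m)) {
    return(frameshift_variant("ins", as.integer(m[2L]), m[3L]))
  }
  m <- regmatches(text,
                  regexec("^c\\.([0-9]+)_([0-9]+)ins([ACGT]+)$", text))[[1L]]
  if (length(m)) {
    p1 <- as.integer(m[2L]); p2 <- as.integer(m[3L])
    if (p2 != p1 + 1L)
      stop("anchor insertion must use adjacent positions, got c.", p1, "_",
           p2, call. = FALSE)
    # inserted bases occupy positions starting at p1 + 1 after editing
    return(frameshift_variant("ins", p1 + 1L, m[4L]))
  }
  token <- sub("^c\\.[0-9_]+", "", text)
  if (!nzchar(token)) token <- text
  stop("cannot parse variant '", text, "': unsupported token '", token, "'",
       call. = FALSE)
}

#' Format a variant in HGVS c. style
#'
#' Insertions are rendered in both supported dialects: the
#' occupied-position form (`"c.4464insG"`) as the primary label and the
#' anchor form (`"c.4463_4464insG"`) as an attribute.
#'
#' @param v A [frameshift_variant()].
#' @return A character scalar; for insertions, with attribute `anchor`.
#' @export
format_hgvs_c <- function(v) {
  stopifnot(inherits(v, "frameshift_variant"))
  if (v$kind == "del") {
    sprintf("c.%ddel%s", v$position, v$bases)
  } else {
    out <- sprintf("c.%dins%s", v$position, v$bases)
    attr(out, "anchor") <- sprintf("c.%d_%dins%s", v$position - 1L,
                                   v$position, v$bases)
    out
  }
}

#' @export
print.frameshift_variant <- function(x, ...) {
  lab <- format_hgvs_c(x)
  cat("<frameshift_variant> ", lab,
      if (x$normalized) " (3'-normalized)" else "", "\n", sep = "")
  if (!is.null(attr(lab, "anchor")))
    cat("  anchor form: ", attr(lab, "anchor"), "\n", sep = "")
  invisible(x)
}

#' Apply a variant to a CDS sequence
#'
#' Pure string surgery: a deletion removes `bases` starting at
#' `position` (after checking they match the reference — this guards
#' against coordinate bugs); an insertion places `bases` so that they
#' occupy `position` onward in the returned sequence.
#'
#' @param cds CDS sequence (character scalar, A/C/G/T/N).
#' @param v A [frameshift_variant()], or a list of them applied left to
#'   right; an empty list returns `cds` unchanged.
#' @return The edited sequence.
#' @export
#' @examples
#' apply_variant("ATGAAAAAATGA", frameshift_variant("del", 8, "A"))
apply_variant <- function(cds, v) {
  check_dna(cds, "cds")
  if (is.list(v) && !inherits(v, "frameshift_variant")) {
    for (vi in v) cds <- apply_variant(cds, vi)
    return(cds)
  }
  stopifnot(inherits(v, "frameshift_variant"))
  n <- nchar(cds)
  w <- nchar(v$bases)
  if (v$kind == "del") {
    if (v$position + w - 1L > n)
      stop("deletion c.", v$position, " extends beyond the CDS (length ", n,
           ")", call. = FALSE)
    ref <- substr(cds, v$position, v$position + w - 1L)
    if (ref != v$bases)
      stop("reference mismatch at c.", v$position, ": expected '", v$bases,
           "' but CDS has '", ref, "'", call. = FALSE)
    paste0(substr(cds, 1L, v$position - 1L),
           substr(cds, v$position + w, n))
  } else {
    if (v$position > n + 1L)
      stop("insertion c.", v$position, " lies beyond the CDS (length ", n,
           ")", call. = FALSE)
    paste0(substr(cds, 1L, v$position - 1L), v$bases,
           substr(cds, v$position, n))
  }
}

#' Invert a variant
#'
#' Returns the variant that undoes `v` on the edited sequence, so that
#' `apply_variant(apply_variant(s, v), invert_variant(v))` is `s`.
#'
#' @param v A [frameshift_variant()].
#' @return A [frameshift_variant()] of the opposite kind.
#' @export
invert_variant <- function(v) {
  stopifnot(inherits(v, "frameshift_variant"))
  frameshift_variant(if (v$kind == "del") "ins" else "del",
                     v$position, v$bases)
}

#' Shift a variant to its 3'-most equivalent position
#'
#' HGVS convention: an indel sliding inside a repeated tract is
#' reported at the 3'-most position that yields the same edited
#' sequence. A single-base deletion inside an (A)9 run therefore
#' anchors at the run's last base. The operation is idempotent and
#' never changes the edited sequence.
#'
#' @param v A [frameshift_variant()].
#' @param t A [transcript()] or a plain CDS string giving the reference
#'   the variant applies to.
#' @return The normalized variant (`normalized = TRUE`).
#' @export
#' @examples
#' cds <- paste0("ATG", strrep("A", 9), "TGA")
#' normalize_3prime(frameshift_variant("del", 4, "A"), cds)  # -> c.12delA
normalize_3prime <- function(v, t) {
  stopifnot(inherits(v, "frameshift_variant"))
  cds <- if (inherits(t, "transcript")) t$cds else check_dna(t, "cds")
  n <- nchar(cds)
  pos <- v$position
  bases <- seq_chars(v$bases)
  w <- length(bases)
  if (v$kind == "del") {
    if (pos < 1L || pos + w - 1L > n)
      stop("deletion position c.", pos, " outside CDS of length ", n,
           call. = FALSE)
    ref <- substr(cds, pos, pos + w - 1L)
    if (ref != v$bases)
      stop("reference mismatch at c.", pos, ": expected '", v$bases,
           "' but CDS has '", ref, "'", call. = FALSE)
    # slide right while the base following the deleted window equals the
    # first deleted base (rotation leaves the edited sequence unchanged)
    while (pos + w <= n && substr(cds, pos + w, pos + w) == bases[1L]) {
      bases <- c(bases[-1L], substr(cds, pos + w, pos + w))
      pos <- pos + 1L
    }
  } else {
    if (pos < 1L || pos > n + 1L)
      stop("insertion position c.", pos, " outside CDS of length ", n,
           call. = FALSE)
    # inserting at occupied position pos equals pos + 1 iff the reference
    # base at pos matches the first inserted base
    while (pos <= n && substr(cds, pos, pos) == bases[1L]) {
      bases <- c(bases[-1L], bases[1L])
      pos <- pos + 1L
    }
  }
  frameshift_variant(v$kind, pos, paste0(bases, collapse = ""),
                     normalized = TRUE)
}
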