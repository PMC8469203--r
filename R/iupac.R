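## IUPAC ambiguity-code algebra for degenerate oligonucleotides.
##
## Degenerate sequences are handled throughout as plain uppercase IUPAC
## strings; internally every symbol maps to a 4-bit mask over {A,C,G,T}
## (A=1, C=2, G=4, T=8) so that set union is bitwOr() and set
## intersection is bitwAnd().  Biostrings supplies the authoritative
## symbol <-> base-set table and the reverse complement.

# bitmask per IUPAC symbol, derived from Biostrings::IUPAC_CODE_MAP at
# build time would need a .onLoad; the table is fixed, so it is spelled
# out (and cross-checked against Biostrings in the test suite).
.IUPAC_MASK <- c(
  A = 1L, C = 2L, G = 4L, T = 8L,
  M = 3L, R = 5L, W = 9L, S = 6L, Y = 10L, K = 12L,
  V = 7L, H = 11L, D = 13L, B = 14L, N = 15L
)

# symbol indexed by mask value 1..15
.MASK_SYMBOL <- character(15L)
.MASK_SYMBOL[.IUPAC_MASK] <- names(.IUPAC_MASK)

# number of concrete bases per mask 0..15
.MASK_SIZE <- vapply(0:15, function(m) {
  sum(bitwAnd(m, c(1L, 2L, 4L, 8L)) > 0L)
}, integer(1))

# concrete bases per mask value
.MASK_BASES <- lapply(0:15, function(m) {
  c("A", "C", "G", "T")[bitwAnd(m, c(1L, 2L, 4L, 8L)) > 0L]
})

# complement mask: swap the A<->T and C<->G bits
.MASK_COMP <- vapply(0:15, function(m) {
  bitwOr(bitwOr(bitwAnd(m, 1L) * 8L, bitwAnd(m, 2L) * 2L),
         bitwOr(bitwAnd(m, 4L) %/% 2L, bitwAnd(m, 8L) %/% 8L))
}, integer(1))

#' Convert an IUPAC string to per-position base-set masks
#'
#' Workhorse for the degenerate-sequence operations. Unknown characters
#' are rejected unless `template = TRUE`, in which case any character
#' outside the IUPAC alphabet (including `N` and gaps) is given the
#' empty mask 0 and therefore never matches a primer position --
#' templates with masked or ambiguous stretches cannot produce phantom
#' amplicons.
#'
#' @param x single character string (IUPAC alphabet).
#' @param template logical; template-mode masking as described above.
#' @return integer vector of 4-bit masks, one per position.
#' @keywords internal
iupacMask <- function(x, template = FALSE) {
  stopifnot(is.character(x), length(x) == 1L, !is.na(x))
  chars <- strsplit(toupper(x), "", fixed = TRUE)[[1]]
  m <- .IUPAC_MASK[chars]
  if (template) {
    m[is.na(m) | chars == "N"] <- 0L
  } else if (anyNA(m)) {
    bad <- unique(chars[is.na(m)])
    stop("invalid IUPAC symbol(s): ", paste(bad, collapse = ", "))
  }
  unname(m)
}

.maskToString <- function(mask) {
  if (any(mask < 1L | mask > 15L)) stop("empty base set has no IUPAC symbol")
  paste(.MASK_SYMBOL[mask], collapse = "")
}

#' Degeneracy of a degenerate sequence
#'
#' The degeneracy number of an IUPAC-coded oligonucleotide: the number
#' of concrete A/C/G/T sequences it represents, i.e. the product over
#' positions of the ambiguity-set sizes. A concrete primer has
#' degeneracy 1.
#'
#' @param x IUPAC string (or a [PrimerPair] slot value).
#' @return a positive number (double, to allow > 2^31 for long patterns).
#' @examples
#' degeneracy("ACGT")                 # 1
#' degeneracy("MCTGGGYATYCACACCGAG")  # 8
#' @export
degeneracy <- function(x) {
  prod(.MASK_SIZE[iupacMask(x) + 1L])
}

#' Expand a degenerate sequence into its concrete variants
#'
#' Enumerates every concrete sequence matched by the pattern, i.e. the
#' primer-batch mixture a degenerate oligo synthesis produces. Refuses
#' patterns whose degeneracy exceeds `cap` (default 4096) so that a
#' pathological pattern cannot exhaust memory.
#'
#' @param x IUPAC string.
#' @param cap maximum degeneracy that will be expanded.
#' @return character vector of `degeneracy(x)` concrete sequences.
#' @examples
#' expandDegenerate("AR")  # "AA" "AG"
#' @export
expandDegenerate <- function(x, cap = 4096) {
  d <- degeneracy(x)
  if (d > cap) {
    stop("degeneracy ", d, " exceeds expansion cap ", cap)
  }
  sets <- .MASK_BASES[iupacMask(x) + 1L]
  do.call(paste0, expand.grid(sets, stringsAsFactors = FALSE))
}

#' Match a degenerate pattern against an equal-length concrete window
#'
#' A position matches iff the window base is a member of the pattern's
#' ambiguity set at that position; a template `N` (or gap) matches
#' nothing. Used by the in-silico PCR scan.
#'
#' @param pattern IUPAC string.
#' @param window concrete sequence of the same length.
#' @param maxMismatch non-negative mismatch allowance.
#' @return list with `match` (logical) and `mismatches` (count).
#' @examples
#' matchesDegenerate("R", "A")  # match, 0 mismatches
#' @export
matchesDegenerate <- function(pattern, window, maxMismatch = 0L) {
  p <- iupacMask(pattern)
  w <- iupacMask(window, template = TRUE)
  if (length(p) != length(w)) {
    stop("pattern and window lengths differ (", length(p), " vs ",
         length(w), ")")
  }
  mm <- sum(bitwAnd(p, w) == 0L)
  list(match = mm <= maxMismatch, mismatches = mm)
}

#' Reverse complement of a degenerate sequence
#'
#' Complements each ambiguity set (the IUPAC alphabet is closed under
#' complementation, e.g. M = \{A,C\} maps to K = \{T,G\}) and reverses
#' the order.
#'
#' @param x IUPAC string.
#' @return IUPAC string.
#' @examples
#' revcompDegenerate("MCT")  # "AGK"
#' @export
revcompDegenerate <- function(x) {
  .maskToString(rev(.MASK_COMP[iupacMask(x) + 1L]))
}

#' Minimal IUPAC symbol for a set of bases
#'
#' Returns the unique IUPAC ambiguity code whose base set equals the
#' input set; the column-wise primitive behind degenerate consensus
#' primers.
#'
#' @param bases character vector, nonempty subset of A, C, G, T.
#' @return single IUPAC character.
#' @examples
#' consensusSymbol(c("A", "C"))  # "M"
#' @export
consensusSymbol <- function(bases) {
  if (length(bases) == 0L) stop("empty base set")
  bases <- toupper(bases)
  if (!all(bases %in% c("A", "C", "G", "T"))) {
    stop("bases must be concrete A/C/G/T")
  }
  m <- Reduce(bitwOr, .IUPAC_MASK[unique(bases)])
  .MASK_SYMBOL[m]
}

#' Read a FASTA file of nucleotide records
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()] that uppercases,
#' maps U to T with a warning, and (outside of MSA use) treats `-` as
#' illegal. Records containing `N` are flagged via the `"hasN"`
#' attribute rather than rejected.
#'
#' @param path FASTA file.
#' @param msa logical; when TRUE gap characters `-` are legal (aligned
#'   input).
#' @return named character vector of sequences; attribute `hasN` marks
#'   records containing N.
#' @export
readFastaRecords <- function(path, msa = FALSE) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  ss <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(ss))
  if (any(grepl("U", seqs, fixed = TRUE))) {
    warning("U bases mapped to T")
    seqs <- gsub("U", "T", seqs, fixed = TRUE)
  }
  ok <- paste0("ACGTRYSWKMBDHVN", if (msa) "-")
  bad <- grepl(sprintf("[^%s]", ok), seqs)
  if (any(bad)) {
    stop("illegal characters in record(s): ",
         paste(names(seqs)[bad], collapse = ", "))
  }
  ids <- sub("\\s.*$", "", names(seqs))
  if (any(!nzchar(ids))) stop("empty record id")
  names(seqs) <- ids
  attr(seqs, "hasN") <- grepl("N", seqs, fixed = TRUE)
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector (IUPAC strings, gaps allowed).
#' @param path output file.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
writeFastaRecords <- function(seqs, path, width = 70L) {
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path,
                              width = width)
  invisible(path)
}
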