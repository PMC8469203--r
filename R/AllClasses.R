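## S4 classes for the primer panel and design results.

#' PrimerPair: one degenerate qPCR primer pair
#'
#' A forward/reverse pair of IUPAC-coded oligonucleotides targeting one
#' phylogenetic cluster of but-gene sequences, together with the
#' expected amplicon length. Pair degeneracy (the product of the two
#' primers' degeneracies) and the recommended working concentration are
#' derived, not stored.
#'
#' @slot cluster single-character cluster label (A-F for the packaged
#'   panel; free-form for de-novo designs).
#' @slot fwd,rev IUPAC strings, written 5' to 3'.
#' @slot expectedLen expected product length in nt (5' end of the
#'   forward site to the 5' end of the reverse site, inclusive).
#' @export
setClass("PrimerPair",
  representation(cluster = "character", fwd = "character",
                 rev = "character", expectedLen = "integer"),
  validity = function(object) {
    msg <- character()
    if (length(object@cluster) != 1L || !nzchar(object@cluster))
      msg <- c(msg, "cluster must be a single nonempty label")
    for (side in c("fwd", "rev")) {
      p <- slot(object, side)
      ok <- tryCatch({ iupacMask(p); TRUE }, error = function(e) FALSE)
      if (length(p) != 1L || !ok)
        msg <- c(msg, paste(side, "is not a valid IUPAC string"))
    }
    if (length(object@expectedLen) != 1L || is.na(object@expectedLen) ||
        object@expectedLen <= nchar(object@fwd) + nchar(object@rev))
      msg <- c(msg, "expectedLen must exceed the summed primer lengths")
    if (length(msg)) msg else TRUE
  })

#' Construct a PrimerPair
#'
#' @param cluster cluster label.
#' @param fwd,rev IUPAC primer strings (5' to 3').
#' @param expectedLen expected product length (nt).
#' @return a [PrimerPair-class] object.
#' @examples
#' PrimerPair("A", "MCTGGGYATYCACACCGAG", "GGTGGGCGATGGAGATAA", 574)
#' @export
PrimerPair <- function(cluster, fwd, rev, expectedLen) {
  new("PrimerPair", cluster = as.character(cluster),
      fwd = toupper(fwd), rev = toupper(rev),
      expectedLen = as.integer(expectedLen))
}

#' PrimerPanel: an ordered collection of PrimerPair objects
#'
#' @slot entries list of [PrimerPair-class] objects with unique cluster
#'   labels.
#' @export
setClass("PrimerPanel",
  representation(entries = "list"),
  validity = function(object) {
    if (!all(vapply(object@entries, is, logical(1), "PrimerPair")))
      return("all entries must be PrimerPair objects")
    cl <- vapply(object@entries, function(e) e@cluster, character(1))
    if (anyDuplicated(cl)) return("duplicate cluster labels")
    TRUE
  })

#' Construct a PrimerPanel
#'
#' @param ... [PrimerPair-class] objects, or a single list of them.
#' @return a [PrimerPanel-class] object, entries named by cluster.
#' @export
PrimerPanel <- function(...) {
  entries <- list(...)
  if (length(entries) == 1L && is.list(entries[[1]]) &&
      !is(entries[[1]], "PrimerPair")) {
    entries <- entries[[1]]
  }
  names(entries) <- vapply(entries, function(e) e@cluster, character(1))
  new("PrimerPanel", entries = entries)
}

#' DesignResult: outcome of a primer-design attempt on one clade
#'
#' @slot leaves character vector of clade member ids.
#' @slot status `"success"` or `"failure"`.
#' @slot pair the designed [PrimerPair-class] (empty list slot on
#'   failure).
#' @slot diagnostics named numeric vector of per-constraint failure
#'   counts recorded during the scan.
#' @export
setClass("DesignResult",
  representation(leaves = "character", status = "character",
                 pair = "list", diagnostics = "numeric"),
  validity = function(object) {
    if (!object@status %in% c("success", "failure"))
      return("status must be success or failure")
    if (object@status == "success" &&
        (length(object@pair) != 1L || !is(object@pair[[1]], "PrimerPair")))
      return("successful result must carry a PrimerPair")
    if (object@status == "failure" && length(object@pair) != 0L)
      return("failed result must not carry a pair")
    TRUE
  })
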