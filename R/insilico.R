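## Degenerate in-silico PCR: binding-site search, amplicon prediction
## and a local off-target screen. Matching is bitmask-based and
## vectorized over window starts; a template N (or any non-IUPAC
## character) never matches a primer position, so masked regions cannot
## produce phantom amplicons.

# mismatch count of `pattern` at every start on the plus strand of
# `tmpl` (template mask vector); returns integer vector length
# length(tmpl) - length(pattern) + 1 (empty if pattern longer)
.slideMismatches <- function(pmask, tmask) {
  L <- length(pmask)
  n <- length(tmask) - L + 1L
  if (n < 1L) return(integer(0))
  mm <- integer(n)
  for (j in seq_len(L)) {
    mm <- mm + (bitwAnd(pmask[j], tmask[j:(j + n - 1L)]) == 0L)
  }
  mm
}

# clamp violation indicator: TRUE where any of the pattern positions in
# `pos` (indices into the pattern) mismatches
.clampViolated <- function(pmask, tmask, pos) {
  L <- length(pmask)
  n <- length(tmask) - L + 1L
  bad <- rep(FALSE, n)
  for (j in pos) {
    bad <- bad | (bitwAnd(pmask[j], tmask[j:(j + n - 1L)]) == 0L)
  }
  bad
}

#' Find degenerate-primer binding sites on a template
#'
#' Scans both strands for windows the primer matches with at most
#' `maxMismatch` mismatches, requiring the `clampExact` 3'-terminal
#' primer positions to match exactly (qPCR extension starts there).
#' Coordinates are 1-based inclusive on the plus strand.
#'
#' @param primer IUPAC string (5' to 3').
#' @param template concrete sequence (N tolerated, never matches).
#' @param maxMismatch mismatch allowance outside the clamp (default 0).
#' @param clampExact number of 3'-terminal primer positions that must
#'   match exactly (default 2).
#' @return data.frame with columns start, end, strand (`+`/`-`),
#'   mismatches; zero rows when the primer finds no site.
#' @export
findBindingSites <- function(primer, template, maxMismatch = 0L,
                             clampExact = 2L) {
  pmask <- iupacMask(primer)
  tmask <- iupacMask(template, template = TRUE)
  if (length(pmask) > length(tmask)) {
    stop("primer longer than template")
  }
  L <- length(pmask)
  res <- list()
  scan <- function(pm, clampPos, strand) {
    mm <- .slideMismatches(pm, tmask)
    ok <- mm <= maxMismatch
    if (clampExact > 0L && any(ok)) {
      ok <- ok & !.clampViolated(pm, tmask, clampPos)
    }
    if (any(ok)) {
      s <- which(ok)
      data.frame(start = s, end = s + L - 1L, strand = strand,
                 mismatches = mm[s], stringsAsFactors = FALSE)
    } else NULL
  }
  clamp <- min(clampExact, L)
  # plus strand: primer 3' end = last positions of the pattern
  res[[1]] <- scan(pmask, if (clamp) (L - clamp + 1L):L else integer(0), "+")
  # minus strand: match revcomp(primer) on the plus strand; its
  # 3'-terminal positions are the first pattern positions
  res[[2]] <- scan(iupacMask(revcompDegenerate(primer)),
                   if (clamp) 1:clamp else integer(0), "-")
  out <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(start = integer(), end = integer(),
                      strand = character(), mismatches = integer(),
                      stringsAsFactors = FALSE)
  }
  out[order(out$start, out$strand), , drop = FALSE]
}

# amplicons in the (+) orientation only: fwd on plus strand, rev
# binding as its reverse complement downstream
.ampliconsPlus <- function(pair, template, maxMismatch, clampExact,
                           productRange) {
  fsites <- findBindingSites(pair@fwd, template, maxMismatch, clampExact)
  fsites <- fsites[fsites$strand == "+", , drop = FALSE]
  rsites <- findBindingSites(pair@rev, template, maxMismatch, clampExact)
  rsites <- rsites[rsites$strand == "-", , drop = FALSE]
  if (!nrow(fsites) || !nrow(rsites)) return(NULL)
  out <- list()
  for (i in seq_len(nrow(fsites))) {
    for (j in seq_len(nrow(rsites))) {
      if (rsites$start[j] <= fsites$end[i]) next
      len <- rsites$end[j] - fsites$start[i] + 1L
      if (len < productRange[1] || len > productRange[2]) next
      out[[length(out) + 1L]] <- data.frame(
        fwd_start = fsites$start[i], fwd_end = fsites$end[i],
        rev_start = rsites$start[j], rev_end = rsites$end[j],
        product_len = len, fwd_mismatches = fsites$mismatches[i],
        rev_mismatches = rsites$mismatches[j],
        stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, out) else NULL
}

#' Predict amplicons of a primer pair on a template
#'
#' Degenerate in-silico PCR. Reports every (forward site, downstream
#' reverse site) combination with product length in range, on both
#' template orientations. Product length is measured from the 5' end of
#' the forward binding site to the 5' end of the reverse binding site
#' on the opposite strand, inclusive -- the convention under which the
#' packaged panel's expected lengths (558--726 nt) are stated.
#' Coordinates are reported 1-based inclusive on the input (plus)
#' strand; `strand == "-"` marks amplicons where the forward primer
#' binds the minus strand.
#'
#' @param pair a [PrimerPair-class].
#' @param template concrete template sequence, or a named character
#'   vector of templates.
#' @param maxMismatch per-primer mismatch allowance (default 0).
#' @param clampExact exact-match 3' clamp length (default 2).
#' @param productRange admissible product lengths (default 40--3000).
#' @return data.frame: template, strand, fwd_start, fwd_end, rev_start,
#'   rev_end, product_len, fwd_mismatches, rev_mismatches; sorted by
#'   (template, fwd_start).
#' @export
predictAmplicons <- function(pair, template, maxMismatch = 0L,
                             clampExact = 2L,
                             productRange = c(40L, 3000L)) {
  stopifnot(is(pair, "PrimerPair"))
  if (length(template) > 1L || !is.null(names(template))) {
    ids <- names(template)
    if (is.null(ids)) ids <- paste0("template", seq_along(template))
    out <- do.call(rbind, lapply(seq_along(template), function(k) {
      h <- predictAmplicons(pair, unname(template[[k]]), maxMismatch,
                            clampExact, productRange)
      if (nrow(h)) h$template <- ids[k]
      h
    }))
    out <- out[order(out$template, out$fwd_start), , drop = FALSE]
    rownames(out) <- NULL
    return(out)
  }
  n <- nchar(template)
  plus <- .ampliconsPlus(pair, template, maxMismatch, clampExact,
                         productRange)
  if (!is.null(plus)) plus$strand <- "+"
  rcTemplate <- revcompDegenerate(template)
  minus <- .ampliconsPlus(pair, rcTemplate, maxMismatch, clampExact,
                          productRange)
  if (!is.null(minus)) {
    # mirror coordinates back onto the plus strand
    minus <- data.frame(
      fwd_start = n - minus$fwd_end + 1L, fwd_end = n - minus$fwd_start + 1L,
      rev_start = n - minus$rev_end + 1L, rev_end = n - minus$rev_start + 1L,
      product_len = minus$product_len,
      fwd_mismatches = minus$fwd_mismatches,
      rev_mismatches = minus$rev_mismatches,
      stringsAsFactors = FALSE)
    minus$strand <- "-"
  }
  out <- rbind(plus, minus)
  if (is.null(out)) {
    out <- data.frame(fwd_start = integer(), fwd_end = integer(),
                      rev_start = integer(), rev_end = integer(),
                      product_len = integer(), fwd_mismatches = integer(),
                      rev_mismatches = integer(), strand = character(),
                      stringsAsFactors = FALSE)
  }
  out$template <- rep("template1", nrow(out))
  out <- out[, c("template", "strand", "fwd_start", "fwd_end",
                 "rev_start", "rev_end", "product_len",
                 "fwd_mismatches", "rev_mismatches")]
  out <- out[order(out$template, out$fwd_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Local off-target screen of a primer panel
#'
#' Runs every panel entry against every template at a permissive
#' mismatch setting and flags entries that amplify a template outside
#' their own cluster. A computational stand-in for a cross-reactivity
#' screen against a sequence database: the template set is supplied by
#' the user.
#'
#' @param panel a [PrimerPanel-class].
#' @param templates named character vector of templates.
#' @param templateClusters optional character vector (parallel to
#'   `templates`) giving each template's true cluster; when absent, no
#'   hit can be declared off-target and all hits are reported
#'   unflagged.
#' @param maxMismatch permissive mismatch allowance (default 2).
#' @param clampExact exact 3' clamp (default 2).
#' @param productRange admissible product lengths.
#' @return data.frame: cluster, template, product_len, fwd_mismatches,
#'   rev_mismatches, offtarget (logical); zero rows for an empty
#'   template set.
#' @export
offtargetScreen <- function(panel, templates, templateClusters = NULL,
                            maxMismatch = 2L, clampExact = 2L,
                            productRange = c(40L, 3000L)) {
  stopifnot(is(panel, "PrimerPanel"))
  empty <- data.frame(cluster = character(), template = character(),
                      product_len = integer(),
                      fwd_mismatches = integer(),
                      rev_mismatches = integer(), offtarget = logical(),
                      stringsAsFactors = FALSE)
  if (length(templates) == 0L) return(empty)
  if (is.null(names(templates))) {
    names(templates) <- paste0("template", seq_along(templates))
  }
  if (!is.null(templateClusters)) {
    stopifnot(length(templateClusters) == length(templates))
    names(templateClusters) <- names(templates)
  }
  rows <- list()
  for (cl in names(panel)) {
    hits <- predictAmplicons(panel[[cl]], templates, maxMismatch,
                             clampExact, productRange)
    if (!nrow(hits)) next
    off <- if (is.null(templateClusters)) {
      rep(FALSE, nrow(hits))
    } else {
      templateClusters[hits$template] != cl
    }
    rows[[length(rows) + 1L]] <- data.frame(
      cluster = cl, template = hits$template,
      product_len = hits$product_len,
      fwd_mismatches = hits$fwd_mismatches,
      rev_mismatches = hits$rev_mismatches,
      offtarget = unname(off), stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$cluster, out$template), , drop = FALSE]
  rownames(out) <- NULL
  out
}
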