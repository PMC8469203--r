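## Degenerate primer-pair design per clade, and the recursive
## tree-descent driver that turns a phylogeny plus MSA into a covering
## primer panel: try to design one degenerate pair for the whole clade;
## if the within-clade variability is too high (no window satisfies the
## constraints), step down to the child clades and try again.

# per-mask screening tables: Wallace Tm contribution (2*(A+T)+4*(G+C))
# and mean GC fraction of the ambiguity set
.MASK_TM <- lapply(0:15, function(m) {
  b <- .MASK_BASES[[m + 1L]]
  tm <- ifelse(b %in% c("G", "C"), 4, 2)
  if (!length(tm)) c(NA_real_, NA_real_) else c(min(tm), max(tm))
})
.MASK_TMMIN <- vapply(.MASK_TM, `[`, numeric(1), 1L)
.MASK_TMMAX <- vapply(.MASK_TM, `[`, numeric(1), 2L)
.MASK_GC <- vapply(0:15, function(m) {
  b <- .MASK_BASES[[m + 1L]]
  if (!length(b)) NA_real_ else mean(b %in% c("G", "C"))
}, numeric(1))

#' Design constraints for degenerate primer scanning
#'
#' Bundles the thresholds that operationalize "a degenerate pair can be
#' designed for this clade". Defaults are calibrated so that all six
#' primer pairs of the packaged panel pass (see the methods vignette
#' for the calibration rationale).
#'
#' @param primer_len allowed primer lengths, nt (default 18--23).
#' @param max_primer_degeneracy per-primer degeneracy cap (default 256).
#' @param max_pair_degeneracy product-of-pair degeneracy cap
#'   (default 2048).
#' @param product_len allowed amplicon length range, nt
#'   (default 400--800).
#' @param tm_range allowed Wallace-rule Tm midpoint range, degrees C
#'   (default 50--65).
#' @param max_tm_diff maximum |forward - reverse| Tm midpoint
#'   difference (default 8).
#' @param gc_range allowed mean-expansion GC fraction (default
#'   0.30--0.70).
#' @param three_prime_clamp number of 3'-terminal positions required
#'   non-degenerate (default 1).
#' @param min_coverage fraction of clade members each primer must match
#'   with 0 mismatches (default 1; only template Ns can break coverage
#'   of a window consensus).
#' @return classed list of constraints.
#' @export
designConstraints <- function(primer_len = c(18L, 23L),
                              max_primer_degeneracy = 256,
                              max_pair_degeneracy = 2048,
                              product_len = c(400L, 800L),
                              tm_range = c(50, 65),
                              max_tm_diff = 8,
                              gc_range = c(0.30, 0.70),
                              three_prime_clamp = 1L,
                              min_coverage = 1) {
  stopifnot(length(primer_len) == 2L, primer_len[1] <= primer_len[2],
            primer_len[1] >= 1L,
            length(product_len) == 2L, product_len[1] <= product_len[2],
            length(tm_range) == 2L, tm_range[1] <= tm_range[2],
            length(gc_range) == 2L, gc_range[1] <= gc_range[2],
            max_primer_degeneracy >= 1, max_pair_degeneracy >= 1,
            three_prime_clamp >= 0L,
            min_coverage > 0, min_coverage <= 1)
  structure(list(primer_len = as.integer(primer_len),
                 max_primer_degeneracy = max_primer_degeneracy,
                 max_pair_degeneracy = max_pair_degeneracy,
                 product_len = as.integer(product_len),
                 tm_range = tm_range, max_tm_diff = max_tm_diff,
                 gc_range = gc_range,
                 three_prime_clamp = as.integer(three_prime_clamp),
                 min_coverage = min_coverage),
            class = "DesignConstraints")
}

# members x columns mask matrix; NA marks gaps
.msaMasks <- function(msa) {
  if (length(unique(nchar(msa))) != 1L) {
    stop("aligned sequences must have equal length")
  }
  m <- do.call(rbind, lapply(unname(msa), function(s) {
    chars <- strsplit(toupper(s), "", fixed = TRUE)[[1]]
    v <- .IUPAC_MASK[chars]
    v[chars == "-"] <- NA_integer_
    if (anyNA(v[chars != "-"])) stop("illegal character in alignment")
    unname(v)
  }))
  rownames(m) <- names(msa)
  m
}

#' Column-wise degenerate consensus over an alignment window
#'
#' The minimal IUPAC symbol per column over the bases observed in the
#' clade members; the enabling primitive of degenerate primer design.
#' A window overlapping a gap in any member is unusable and yields
#' `NA`.
#'
#' @param msa named character vector of aligned sequences.
#' @param start 1-based alignment column of the window start.
#' @param length window length.
#' @return IUPAC string, or `NA_character_` if any member has a gap in
#'   the window.
#' @export
windowConsensus <- function(msa, start, length) {
  masks <- .msaMasks(msa)
  if (start < 1L || start + length - 1L > ncol(masks)) {
    stop("window out of alignment range")
  }
  win <- masks[, start:(start + length - 1L), drop = FALSE]
  if (anyNA(win)) return(NA_character_)
  .maskToString(apply(win, 2L, function(col) Reduce(bitwOr, col)))
}

#' Wallace-rule melting-temperature range of a degenerate primer
#'
#' Min and max Tm = 2(A+T) + 4(G+C) over the concrete expansions,
#' computed per position without enumerating the expansion.
#'
#' @param p IUPAC string.
#' @return numeric `c(min, max)` in degrees C.
#' @examples
#' primerTmRange("RT")  # 4 6
#' @export
primerTmRange <- function(p) {
  m <- iupacMask(p)
  c(min = sum(.MASK_TMMIN[m + 1L]), max = sum(.MASK_TMMAX[m + 1L]))
}

# windowed sums via cumulative sums; x length C, window length L
.winSum <- function(x, L) {
  cs <- c(0, cumsum(x))
  cs[(L + 1L):length(cs)] - cs[1:(length(cs) - L)]
}

#' Scan an alignment for degenerate primer candidates
#'
#' Slides windows of every allowed length across the clade alignment,
#' takes the degenerate column consensus, and keeps windows passing the
#' gap, degeneracy, Tm, GC, 3'-clamp and coverage screens. Candidates
#' are ranked by (degeneracy ascending, |Tm midpoint - 60|, position).
#' Reverse-orientation candidates are the reverse complements of window
#' consensi, with the clamp applied to their 3' end (the left edge of
#' the window on the plus strand).
#'
#' @param msa named character vector of aligned clade members.
#' @param constraints a [designConstraints()] object.
#' @param orientation `"forward"` or `"reverse"`.
#' @return data.frame of candidates (start, len, seq, degeneracy,
#'   tm_min, tm_max, tm_mid, gc), ranked; attribute `"rejected"` holds
#'   per-constraint rejection counts.
#' @export
scanCandidates <- function(msa, constraints = designConstraints(),
                           orientation = c("forward", "reverse")) {
  orientation <- match.arg(orientation)
  if (length(msa) == 0L) stop("empty alignment")
  masks <- .msaMasks(msa)
  C <- ncol(masks)
  gapCol <- apply(masks, 2L, anyNA)
  colMask <- apply(masks, 2L, function(col) {
    if (anyNA(col)) 0L else Reduce(bitwOr, col)
  })
  nCol <- colMask == 15L &
    apply(masks, 2L, function(col) any(!is.na(col) & col == 15L))
  # members carrying N cannot be matched at those columns
  memberN <- masks == 15L
  memberN[is.na(memberN)] <- FALSE

  colLog2 <- ifelse(gapCol, 0, log2(.MASK_SIZE[colMask + 1L]))
  colTmMin <- ifelse(gapCol, 0, .MASK_TMMIN[colMask + 1L])
  colTmMax <- ifelse(gapCol, 0, .MASK_TMMAX[colMask + 1L])
  colGc <- ifelse(gapCol, 0, .MASK_GC[colMask + 1L])
  conc <- .MASK_SIZE[colMask + 1L] == 1L & !gapCol  # concrete column

  rejected <- c(gap = 0, degeneracy = 0, tm = 0, gc = 0, clamp = 0,
                coverage = 0)
  out <- list()
  for (L in constraints$primer_len[1]:constraints$primer_len[2]) {
    if (L > C) next
    n <- C - L + 1L
    hasGap <- .winSum(as.numeric(gapCol), L) > 0
    deg <- round(2^.winSum(colLog2, L))
    tmMin <- .winSum(colTmMin, L)
    tmMax <- .winSum(colTmMax, L)
    tmMid <- (tmMin + tmMax) / 2
    gc <- .winSum(colGc, L) / L
    clamp <- constraints$three_prime_clamp
    if (clamp > 0L) {
      concW <- .winSum(as.numeric(conc), clamp)  # runs of length clamp
      if (orientation == "forward") {
        # last `clamp` columns of the window: run starting at s + L - clamp
        clampOk <- concW[(1:n) + L - clamp] == clamp
      } else {
        clampOk <- concW[1:n] == clamp
      }
    } else {
      clampOk <- rep(TRUE, n)
    }
    # coverage: members with an N inside the window are not matched
    if (any(memberN)) {
      covered <- rep(nrow(masks), n)
      for (i in seq_len(nrow(masks))) {
        covered <- covered - (.winSum(as.numeric(memberN[i, ]), L) > 0)
      }
      covOk <- covered / nrow(masks) >= constraints$min_coverage
    } else {
      covOk <- rep(TRUE, n)
    }

    degOk <- deg <= constraints$max_primer_degeneracy
    tmOk <- tmMid >= constraints$tm_range[1] & tmMid <= constraints$tm_range[2]
    gcOk <- gc >= constraints$gc_range[1] & gc <= constraints$gc_range[2]
    keep <- !hasGap & degOk & tmOk & gcOk & clampOk & covOk
    rejected["gap"] <- rejected["gap"] + sum(hasGap)
    rejected["degeneracy"] <- rejected["degeneracy"] + sum(!hasGap & !degOk)
    rejected["tm"] <- rejected["tm"] + sum(!hasGap & degOk & !tmOk)
    rejected["gc"] <- rejected["gc"] + sum(!hasGap & degOk & tmOk & !gcOk)
    rejected["clamp"] <- rejected["clamp"] +
      sum(!hasGap & degOk & tmOk & gcOk & !clampOk)
    rejected["coverage"] <- rejected["coverage"] +
      sum(!hasGap & degOk & tmOk & gcOk & clampOk & !covOk)
    if (!any(keep)) next
    idx <- which(keep)
    seqs <- vapply(idx, function(s) {
      .maskToString(colMask[s:(s + L - 1L)])
    }, character(1))
    if (orientation == "reverse") {
      seqs <- vapply(seqs, revcompDegenerate, character(1),
                     USE.NAMES = FALSE)
    }
    out[[length(out) + 1L]] <- data.frame(
      start = idx, len = L, seq = seqs, degeneracy = deg[idx],
      tm_min = tmMin[idx], tm_max = tmMax[idx], tm_mid = tmMid[idx],
      gc = gc[idx], stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else {
    data.frame(start = integer(), len = integer(), seq = character(),
               degeneracy = numeric(), tm_min = numeric(),
               tm_max = numeric(), tm_mid = numeric(), gc = numeric(),
               stringsAsFactors = FALSE)
  }
  res <- res[order(res$degeneracy, abs(res$tm_mid - 60), res$start,
                   res$len), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "rejected") <- rejected
  res
}

#' Design a degenerate primer pair for one clade
#'
#' Scans both orientations, then pairs candidates in rank order and
#' returns the first pair whose implied product length (5' end of the
#' forward window to the 3'-most column of the reverse window,
#' inclusive, measured on the ungapped reference member) falls in
#' range, whose pair degeneracy is below the cap and whose Tm midpoints
#' differ by at most `max_tm_diff`. Failure is a value (a
#' [DesignResult-class] with diagnostics), not an error.
#'
#' @param msa named character vector of aligned clade members (>= 1).
#' @param constraints a [designConstraints()] object.
#' @param label cluster label for the designed pair.
#' @param refIndex member on whose ungapped coordinates product length
#'   is measured (default the first).
#' @param maxCandidates per-orientation cap on candidates entering the
#'   pair search, keeping the scan near-linear.
#' @return a [DesignResult-class].
#' @export
designForCluster <- function(msa, constraints = designConstraints(),
                             label = "clade", refIndex = 1L,
                             maxCandidates = 400L) {
  if (length(msa) < 1L) stop("clade must have at least one member")
  fwd <- scanCandidates(msa, constraints, "forward")
  rev <- scanCandidates(msa, constraints, "reverse")
  diag <- attr(fwd, "rejected") + attr(rev, "rejected")
  diag <- c(diag, pair_product_len = 0, pair_degeneracy = 0,
            pair_tm_diff = 0)

  # alignment column -> ungapped position on the reference member
  refChars <- strsplit(toupper(msa[[refIndex]]), "", fixed = TRUE)[[1]]
  refMap <- cumsum(refChars != "-")

  fail <- function() {
    new("DesignResult", leaves = names(msa), status = "failure",
        pair = list(), diagnostics = diag)
  }
  if (nrow(fwd) == 0L || nrow(rev) == 0L) return(fail())
  fwd <- utils::head(fwd, maxCandidates)
  rev <- utils::head(rev, maxCandidates)

  for (i in seq_len(nrow(fwd))) {
    fs <- fwd$start[i]; fl <- fwd$len[i]
    for (j in seq_len(nrow(rev))) {
      rs <- rev$start[j]; rl <- rev$len[j]
      if (rs < fs + fl) next  # reverse site must lie downstream
      prodLen <- refMap[rs + rl - 1L] - refMap[fs] + 1L
      if (prodLen < constraints$product_len[1] ||
          prodLen > constraints$product_len[2]) {
        diag["pair_product_len"] <- diag["pair_product_len"] + 1
        next
      }
      if (fwd$degeneracy[i] * rev$degeneracy[j] >
          constraints$max_pair_degeneracy) {
        diag["pair_degeneracy"] <- diag["pair_degeneracy"] + 1
        next
      }
      if (abs(fwd$tm_mid[i] - rev$tm_mid[j]) > constraints$max_tm_diff) {
        diag["pair_tm_diff"] <- diag["pair_tm_diff"] + 1
        next
      }
      pair <- PrimerPair(label, fwd$seq[i], rev$seq[j], prodLen)
      return(new("DesignResult", leaves = names(msa),
                 status = "success", pair = list(pair),
                 diagnostics = diag))
    }
  }
  fail()
}

#' Recursive tree-descent primer design
#'
#' Depth-first from the root: attempt a degenerate pair for the current
#' clade; on success emit it and do not descend further; on failure
#' step down to the child clades and retry. Leaves where even a
#' single-sequence design fails are reported as undesignable. The
#' emitted clades partition the designable leaf set.
#'
#' @param tree rooted [ape::phylo] tree whose tip labels equal
#'   `names(msa)`.
#' @param msa named character vector: global alignment of all leaves.
#'   Clade members are re-sliced from this alignment on descent (no
#'   re-alignment).
#' @param constraints a [designConstraints()] object.
#' @return list of [DesignResult-class]; successful results carry
#'   cluster labels A, B, ... in emission order.
#' @export
recursiveDesign <- function(tree, msa, constraints = designConstraints()) {
  stopifnot(inherits(tree, "phylo"))
  if (!setequal(tree$tip.label, names(msa)) ||
      length(tree$tip.label) != length(msa)) {
    stop("tree leaves and alignment ids do not match")
  }
  ntip <- length(tree$tip.label)
  results <- list()
  nextLabel <- function() {
    k <- sum(vapply(results, function(r) r@status == "success", logical(1)))
    if (k < 26L) LETTERS[k + 1L] else paste0("C", k + 1L)
  }
  visit <- function(node) {
    leaves <- .leavesUnder(tree, node)
    res <- designForCluster(msa[leaves], constraints,
                            label = nextLabel())
    if (res@status == "success" || node <= ntip) {
      results[[length(results) + 1L]] <<- res
    } else {
      for (child in .treeChildren(tree, node)) visit(child)
    }
    invisible(NULL)
  }
  root <- if (ntip == 1L) 1L else ntip + 1L
  visit(root)
  results
}

#' Simple progressive aligner for small families
#'
#' Convenience only: aligns each sequence globally against the first
#' (reference) sequence with [Biostrings::pairwiseAlignment()] and
#' threads the pairwise alignments into one reference-anchored MSA.
#' Insertions relative to the reference from different members are not
#' aligned to each other. Intended for families of up to 50 sequences;
#' use a dedicated multiple aligner for anything serious.
#'
#' @param seqs named character vector of unaligned A/C/G/T sequences.
#' @return named character vector of equal-length aligned sequences.
#' @export
alignFamily <- function(seqs) {
  if (length(seqs) > 50L) {
    stop("built-in aligner is limited to 50 sequences; supply an MSA")
  }
  if (is.null(names(seqs))) stop("sequences must be named")
  if (length(seqs) == 1L) return(seqs)
  ref <- seqs[[1]]
  # per member: chars at each ref position ("-" for deletion) and
  # insertion strings keyed by the ref position they follow (0 = lead)
  profiles <- lapply(seqs[-1], function(s) {
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(s), Biostrings::DNAString(ref),
      type = "global")
    p <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
    q <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
    atRef <- character(nchar(ref))
    ins <- vector("list", nchar(ref) + 1L)
    rp <- 0L
    for (k in seq_along(q)) {
      if (q[k] != "-") {
        rp <- rp + 1L
        atRef[rp] <- p[k]
      } else {
        ins[[rp + 1L]] <- c(ins[[rp + 1L]], p[k])
      }
    }
    list(atRef = atRef, ins = ins)
  })
  insLen <- vapply(seq_len(nchar(ref) + 1L), function(k) {
    max(c(0L, vapply(profiles, function(pr) length(pr$ins[[k]]),
                     integer(1))))
  }, integer(1))
  pad <- function(chars, n) {
    c(chars, rep("-", n - length(chars)))
  }
  refChars <- strsplit(ref, "")[[1]]
  buildRow <- function(atRef, ins) {
    parts <- character(0)
    for (k in 0:nchar(ref)) {
      if (insLen[k + 1L] > 0L) {
        parts <- c(parts, pad(ins[[k + 1L]], insLen[k + 1L]))
      }
      if (k < nchar(ref)) parts <- c(parts, atRef[k + 1L])
    }
    paste(parts, collapse = "")
  }
  refRow <- buildRow(refChars, vector("list", nchar(ref) + 1L))
  rows <- c(list(refRow),
            lapply(profiles, function(pr) buildRow(pr$atRef, pr$ins)))
  out <- unlist(rows)
  names(out) <- names(seqs)
  out
}
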