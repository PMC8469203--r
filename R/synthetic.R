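## Synthetic-data generators with known ground truth for every
## pipeline stage: homolog families with clade-conserved primer
## islands, qPCR Ct tables with known group effects, and compositional
## count tables. All generators are pure functions of their arguments
## plus a mandatory seed; the caller's RNG state is left untouched.

.withSeed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Simulate a divergent gene family with clade-conserved islands
#'
#' Evolves a random ancestor sequence down a rooted tree by i.i.d.
#' substitutions (uniform choice among the three alternative bases, no
#' indels), except inside "conserved islands": alignment windows that
#' are immune to substitution on every branch inside their designated
#' clade. The result emulates a variable functional gene whose
#' clade-conserved stretches are the only viable degenerate-primer
#' sites.
#'
#' @param tree rooted [ape::phylo] tree; or `NULL` to sample a random
#'   topology with `nLeaves` leaves.
#' @param nLeaves number of leaves when `tree` is NULL.
#' @param ancestorLength ancestor sequence length, nt.
#' @param subProb per-branch, per-site substitution probability in
#'   `[0, 1)`.
#' @param islands list of `list(clade = <tip labels or "root">,
#'   start =, length =)`; windows must fit in the ancestor.
#' @param seed RNG seed (mandatory).
#' @return list with `sequences` (named character vector, ungapped and
#'   positionally aligned), `tree`, and `islands` (the input, as a
#'   data.frame with a clade id).
#' @export
simulateFamily <- function(tree = NULL, nLeaves = 8L,
                           ancestorLength = 1200L, subProb = 0.25,
                           islands = list(), seed) {
  stopifnot(subProb >= 0, subProb < 1, ancestorLength >= 1L)
  for (isl in islands) {
    stopifnot(isl$start >= 1L,
              isl$start + isl$length - 1L <= ancestorLength)
  }
  .withSeed(seed, {
    if (is.null(tree)) tree <- ape::rtree(nLeaves)
    tree <- stats::reorder(tree, "cladewise")  # parents before children
    ntip <- length(tree$tip.label)
    nnode <- ntip + tree$Nnode
    # per-island: nodes of the protected subtree (edges whose parent is
    # inside never mutate island positions)
    protected <- matrix(FALSE, nnode, ancestorLength)
    for (isl in islands) {
      pos <- isl$start:(isl$start + isl$length - 1L)
      if (identical(isl$clade, "root")) {
        protected[, pos] <- TRUE
      } else {
        tips <- match(isl$clade, tree$tip.label)
        if (anyNA(tips)) stop("island clade names not in tree")
        sub <- if (length(tips) == 1L) tips else {
          mrca <- ape::getMRCA(tree, tips)
          nodes <- mrca
          i <- 1L
          while (i <= length(nodes)) {
            nodes <- c(nodes, .treeChildren(tree, nodes[i]))
            i <- i + 1L
          }
          nodes
        }
        protected[sub, pos] <- TRUE
      }
    }
    bases <- c("A", "C", "G", "T")
    anc <- sample(bases, ancestorLength, replace = TRUE)
    seqs <- vector("list", nnode)
    root <- if (ntip == 1L) 1L else ntip + 1L
    seqs[[root]] <- anc
    # edges in cladewise order guarantee parents before children
    for (e in seq_len(nrow(tree$edge))) {
      parent <- tree$edge[e, 1]; child <- tree$edge[e, 2]
      s <- seqs[[parent]]
      mut <- stats::runif(ancestorLength) < subProb & !protected[parent, ]
      if (any(mut)) {
        idx <- which(mut)
        shift <- sample.int(3L, length(idx), replace = TRUE)
        s[idx] <- bases[(match(s[idx], bases) - 1L + shift) %% 4L + 1L]
      }
      seqs[[child]] <- s
    }
    out <- vapply(seq_len(ntip), function(i) paste(seqs[[i]], collapse = ""),
                  character(1))
    names(out) <- tree$tip.label
    isl <- if (length(islands)) {
      data.frame(
        clade = vapply(islands, function(i)
          paste(i$clade, collapse = ","), character(1)),
        start = vapply(islands, function(i) as.integer(i$start), integer(1)),
        length = vapply(islands, function(i) as.integer(i$length),
                        integer(1)))
    } else data.frame(clade = character(), start = integer(),
                      length = integer())
    list(sequences = out, tree = tree, islands = isl)
  })
}

#' Planted-island family with k designable clades
#'
#' Convenience wrapper around [simulateFamily()] that builds a balanced
#' tree of `k` clades with `perClade` leaves each and plants one
#' conserved island per clade at non-overlapping positions, so that the
#' recursive design descent should recover exactly `k` clusters.
#'
#' @param k number of clades (>= 1).
#' @param perClade leaves per clade.
#' @param islandLength island length, nt (default 650, sized so one
#'   island hosts a forward and a reverse primer at an amplicon
#'   spacing of 400--800 nt).
#' @param gap spacing between islands, nt.
#' @param subProb per-branch substitution probability.
#' @param seed RNG seed.
#' @return as [simulateFamily()], plus `clades`: list of tip-label
#'   vectors, one per planted clade.
#' @export
plantedIslandFamily <- function(k, perClade = 3L, islandLength = 650L,
                                gap = 50L, subProb = 0.25, seed) {
  stopifnot(k >= 1L, perClade >= 1L)
  cladeTips <- lapply(seq_len(k), function(i) {
    paste0("c", i, "_", seq_len(perClade))
  })
  subNewick <- function(tips) {
    if (length(tips) == 1L) return(tips)
    s <- tips[1]
    for (t in tips[-1]) s <- paste0("(", s, ",", t, ")")
    s
  }
  clades <- vapply(cladeTips, subNewick, character(1))
  nwk <- if (k == 1L) {
    if (perClade == 1L) paste0("(", clades[1], ");")
    else paste0(clades[1], ";")
  } else {
    s <- clades[1]
    for (i in 2:k) s <- paste0("(", s, ",", clades[i], ")")
    paste0(s, ";")
  }
  tree <- parseNewick(nwk)
  islands <- lapply(seq_len(k), function(i) {
    list(clade = if (k == 1L) "root" else cladeTips[[i]],
         start = 51L + (i - 1L) * (islandLength + gap),
         length = islandLength)
  })
  len <- 100L + k * (islandLength + gap)
  fam <- simulateFamily(tree = tree, ancestorLength = len,
                        subProb = subProb, islands = islands,
                        seed = seed)
  fam$clades <- cladeTips
  fam
}

#' Simulate a long-format qPCR Ct table
#'
#' Reference (spike-in UNC-6) Ct values are drawn per sample from a
#' normal distribution; each target assay's Ct is offset by
#' `-log_E(true ratio)` for the sample's group plus measurement noise,
#' and a 16S reference assay sits `s16Offset` cycles below the spike
#' (the 16S gene being far more abundant than the target). Default
#' group sizes and per-cluster ratios emulate the vegan (VG, n = 63)
#' versus obese-omnivore (OB, n = 62) study design with the observed
#' per-cluster median abundances.
#'
#' @param groupSizes named integer vector of samples per group.
#' @param trueRatios groups x clusters matrix of true target/reference
#'   copy ratios (rownames = groups, colnames = cluster assays).
#' @param refCtMean,refCtSd mean and biological sd of the reference Ct.
#' @param noiseSd per-measurement Ct noise sd (cycles).
#' @param efficiency amplification efficiency.
#' @param s16Offset cycles by which the 16S reference precedes the
#'   spike-in (default 10).
#' @param replicates technical replicates per assay (default 2).
#' @param seed RNG seed.
#' @return long data.frame: sample, group, assay, replicate, Ct.
#' @export
simulateQpcr <- function(groupSizes = c(VG = 63L, OB = 62L),
                         trueRatios = rbind(
                           VG = c(A = 3.5, B = 0.45, C = 211, D = 63,
                                  E = 0.28, F = 12.5),
                           OB = c(A = 4.8, B = 0.28, C = 86, D = 34,
                                  E = 0.32, F = 17.6)),
                         refCtMean = 25, refCtSd = 1, noiseSd = 0.5,
                         efficiency = 2, s16Offset = 10,
                         replicates = 2L, seed) {
  stopifnot(all(groupSizes >= 1L), all(trueRatios > 0),
            refCtSd >= 0, noiseSd >= 0, efficiency > 1,
            setequal(rownames(trueRatios), names(groupSizes)))
  .withSeed(seed, {
    rows <- list()
    sampleId <- 0L
    for (g in names(groupSizes)) {
      for (s in seq_len(groupSizes[[g]])) {
        sampleId <- sampleId + 1L
        id <- sprintf("S%03d", sampleId)
        ctRef <- stats::rnorm(1, refCtMean, refCtSd)
        assays <- c(UNC6 = 0, S16 = s16Offset,
                    log(trueRatios[g, ]) / log(efficiency))
        names(assays) <- c("UNC6", "S16", colnames(trueRatios))
        for (a in names(assays)) {
          ct <- ctRef - assays[[a]] +
            stats::rnorm(replicates, 0, noiseSd)
          rows[[length(rows) + 1L]] <- data.frame(
            sample = id, group = g, assay = a,
            replicate = seq_len(replicates), Ct = ct,
            stringsAsFactors = FALSE)
        }
      }
    }
    do.call(rbind, rows)
  })
}

#' Simulate a compositional count matrix
#'
#' Multinomial read counts at a fixed depth per sample.
#'
#' @param props samples x taxa matrix of true proportions (rows sum to
#'   1).
#' @param depth reads per sample.
#' @param seed RNG seed.
#' @return samples x taxa integer matrix of counts.
#' @export
simulateCounts <- function(props, depth, seed) {
  props <- as.matrix(props)
  if (any(props < 0) || any(abs(rowSums(props) - 1) > 1e-8)) {
    stop("proportions must be non-negative and sum to 1 per sample")
  }
  .withSeed(seed, {
    out <- t(apply(props, 1L, function(p) {
      stats::rmultinom(1L, size = depth, prob = p)[, 1]
    }))
    dimnames(out) <- dimnames(props)
    out
  })
}
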