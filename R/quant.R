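## Delta-Ct relative quantification of but-gene abundance against a
## spike-in (C. elegans UNC-6) or 16S rRNA gene reference, plus the
## degeneracy-based primer concentration rule.
##
## Ct tables are long-format data.frames with columns
## sample, group, assay, replicate, Ct; assay ids are the cluster
## labels plus "UNC6" and "S16".

.REF_ASSAYS <- c(UNC6 = "UNC6", S16 = "S16")

#' Validate a long-format Ct table
#'
#' @param q data.frame with columns sample, group, assay, Ct and
#'   optionally replicate.
#' @return the table, with a replicate column added if missing.
#' @export
validateQpcrTable <- function(q) {
  need <- c("sample", "group", "assay", "Ct")
  missing <- setdiff(need, names(q))
  if (length(missing)) {
    stop("Ct table lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (!"replicate" %in% names(q)) q$replicate <- 1L
  if (any(is.finite(q$Ct) & q$Ct <= 0)) stop("Ct values must be positive")
  q
}

#' Single delta-Ct copy ratio
#'
#' Target copies per reference copy: `efficiency^(ctRef - ctTarget)`,
#' the uncorrected delta-Ct estimator with perfect doubling
#' (efficiency 2) by default. Vectorized; non-finite Ct values yield
#' `NA` (flagged missing, never zero).
#'
#' @param ctTarget,ctRef cycle-threshold values.
#' @param efficiency amplification efficiency per cycle (default 2.0;
#'   configurable input, never estimated here).
#' @return positive numeric (or NA).
#' @examples
#' copyRatio(23, 25)  # 4
#' @export
copyRatio <- function(ctTarget, ctRef, efficiency = 2.0) {
  stopifnot(efficiency > 1)
  out <- efficiency^(ctRef - ctTarget)
  out[!is.finite(ctTarget) | !is.finite(ctRef)] <- NA_real_
  out
}

#' Aggregate technical replicates of a Ct table
#'
#' Arithmetic mean of replicate Ct values per (sample, assay) --
#' equivalently the geometric mean of copy ratios -- after dropping
#' replicates more than `outlierCycles` cycles from the replicate
#' median. With fewer than three replicates the outlier is not
#' identifiable (each of a discordant duplicate is equally far from
#' their median), so the rule is only applied to triplicates and up.
#'
#' @param q long Ct table (see [validateQpcrTable()]).
#' @param outlierCycles outlier rule threshold in cycles (default 0.5;
#'   set `Inf` to keep everything).
#' @return data.frame sample, group, assay, Ct (one row per
#'   sample/assay).
#' @export
aggregateReplicates <- function(q, outlierCycles = 0.5) {
  q <- validateQpcrTable(q)
  key <- interaction(q$sample, q$assay, drop = TRUE)
  keep <- unlist(lapply(split(seq_len(nrow(q)), key), function(idx) {
    ct <- q$Ct[idx]
    if (length(idx) < 3L) return(idx)
    med <- stats::median(ct, na.rm = TRUE)
    idx[is.na(ct) | abs(ct - med) <= outlierCycles]
  }), use.names = FALSE)
  q <- q[sort(keep), , drop = FALSE]
  agg <- stats::aggregate(Ct ~ sample + group + assay, data = q,
                          FUN = mean, na.action = stats::na.pass)
  agg[order(agg$sample, agg$assay), , drop = FALSE]
}

#' Normalize a Ct table to a reference assay
#'
#' Delta-Ct normalization of every target (cluster) assay against the
#' chosen reference: the spike-in (`"UNC6"`) or the 16S rRNA gene
#' (`"S16"`). Replicates are aggregated first; samples missing the
#' reference assay are reported with `NA` ratios (and a warning), never
#' silently dropped. With `reference = "S16"` a per-genome 16S copy
#' correction can be applied (see [sixteenSCopyCorrection()]).
#'
#' @param q long Ct table.
#' @param reference `"UNC6"` or `"S16"`.
#' @param efficiency amplification efficiency (default 2.0).
#' @param copiesPerGenome optional 16S copies per genome; when given
#'   (and `reference = "S16"`) a `genome_equivalents` column is added.
#' @param outlierCycles replicate outlier rule (default 0.5 cycles).
#' @return data.frame sample, group, cluster, reference, copy_ratio
#'   (+ genome_equivalents).
#' @export
normalizeTable <- function(q, reference = c("UNC6", "S16"),
                           efficiency = 2.0, copiesPerGenome = NULL,
                           outlierCycles = 0.5) {
  reference <- match.arg(reference)
  agg <- aggregateReplicates(q, outlierCycles)
  targets <- setdiff(unique(agg$assay), .REF_ASSAYS)
  if (!length(targets)) stop("no target assays in Ct table")
  refCt <- agg[agg$assay == reference, c("sample", "Ct")]
  samples <- unique(agg[, c("sample", "group")])
  noRef <- setdiff(samples$sample, refCt$sample)
  if (length(noRef)) {
    warning("sample(s) missing reference assay ", reference, ": ",
            paste(noRef, collapse = ", "))
  }
  tgt <- agg[agg$assay %in% targets, , drop = FALSE]
  ref <- refCt$Ct[match(tgt$sample, refCt$sample)]
  out <- data.frame(sample = tgt$sample, group = tgt$group,
                    cluster = tgt$assay, reference = reference,
                    copy_ratio = copyRatio(tgt$Ct, ref, efficiency),
                    stringsAsFactors = FALSE)
  if (reference == "S16" && !is.null(copiesPerGenome)) {
    out$genome_equivalents <-
      sixteenSCopyCorrection(out$copy_ratio, copiesPerGenome)
  }
  out <- out[order(out$sample, out$cluster), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Correct a 16S-normalized ratio to genome equivalents
#'
#' Bacteria carry a variable number of 16S rRNA gene copies; across
#' sequenced genomes the average is about 4.2 copies per genome.
#' Multiplying a target-per-16S-copy ratio by that factor expresses
#' abundance per genome equivalent of the 16S pool.
#'
#' @param copy_ratio target copies per 16S copy.
#' @param copiesPerGenome average 16S copies per genome (default 4.2).
#' @return genome-equivalent abundance.
#' @export
sixteenSCopyCorrection <- function(copy_ratio, copiesPerGenome = 4.2) {
  if (!is.numeric(copiesPerGenome) || copiesPerGenome <= 0) {
    stop("copiesPerGenome must be positive")
  }
  copy_ratio * copiesPerGenome
}

#' Recommended working concentration for a degenerate pair
#'
#' A degenerate primer is a mixture, so the per-variant concentration
#' drops with degeneracy; in practice working concentrations rise from
#' the conventional 200 nM for a concrete pair up to 1 uM for highly
#' degenerate pairs. This rule interpolates log-linearly between those
#' endpoints, saturating at degeneracy 256:
#' `200 + 800 * min(1, log2(d)/8)` nM, rounded to 10 nM.
#'
#' @param pair_degeneracy degeneracy number of the pair (>= 1).
#' @return concentration in nM.
#' @examples
#' recommendConcentration(1)    # 200
#' recommendConcentration(16)   # 600
#' recommendConcentration(256)  # 1000
#' @export
recommendConcentration <- function(pair_degeneracy) {
  if (any(pair_degeneracy < 1)) stop("degeneracy must be >= 1")
  round((200 + 800 * pmin(1, log2(pair_degeneracy) / 8)) / 10) * 10
}
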