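## Statistical toolkit: nonparametric group comparison, rank
## correlation, Bland-Altman method agreement, and compositional (CLR)
## treatment of NGS count tables with multiplicative zero replacement.
## No multiple-testing correction is applied by default (per-test
## alpha = 0.05); a Benjamini-Hochberg option exists but is off.

#' Mann-Whitney U test
#'
#' Two-sided Mann-Whitney-Wilcoxon test via [stats::wilcox.test()]:
#' exact when the pooled size is at most 16 and the data are tie-free,
#' otherwise the normal approximation with tie and continuity
#' correction. Returns the U statistic for the first sample.
#'
#' @param x,y numeric vectors (each nonempty).
#' @return list with `U`, `p` and `method` (`"exact"` or
#'   `"approximate"`).
#' @export
mannWhitney <- function(x, y) {
  if (!length(x) || !length(y)) stop("empty group")
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- (length(x) + length(y) <= 16L) && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                       correct = TRUE))
  list(U = unname(wt$statistic), p = wt$p.value,
       method = if (exact) "exact" else "approximate")
}

#' Spearman rank correlation
#'
#' Midrank-based Spearman rho via [stats::cor.test()]; exact p for
#' small tie-free samples, t-approximation otherwise. A constant input
#' leaves rho undefined and is flagged rather than erroring.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return list with `rho`, `p`, `defined` (FALSE when an input is
#'   constant, in which case rho and p are NA).
#' @export
spearmanCor <- function(x, y) {
  if (length(x) != length(y)) stop("inputs must have equal length")
  if (length(x) < 3L) stop("need at least 3 pairs")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(rho = NA_real_, p = NA_real_, defined = FALSE))
  }
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = NULL))
  list(rho = unname(ct$estimate), p = ct$p.value, defined = TRUE)
}

#' Bland-Altman agreement analysis
#'
#' Bias and 95% limits of agreement between two paired measurement
#' series, with 95% confidence intervals: the bias CI uses the t
#' distribution on the mean difference; each limit's CI uses the
#' standard approximation se(LoA) = sd * sqrt(3/n). Inputs are expected
#' on the scale the comparison is meant on (log-transform upstream for
#' ratio-scale quantities).
#'
#' @param a,b paired numeric vectors, length >= 3.
#' @return object of class `"blandAltman"`: list with `bias`,
#'   `sd_diff`, `loa_low`, `loa_high`, `bias_ci`, `loa_low_ci`,
#'   `loa_high_ci`, `n`.
#' @export
blandAltman <- function(a, b) {
  if (length(a) != length(b)) stop("inputs must have equal length")
  ok <- is.finite(a) & is.finite(b)
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  if (n < 3L) stop("need at least 3 complete pairs")
  d <- a - b
  bias <- mean(d)
  s <- stats::sd(d)
  tq <- stats::qt(0.975, n - 1L)
  seBias <- s / sqrt(n)
  seLoa <- s * sqrt(3 / n)
  loa <- bias + c(-1, 1) * 1.96 * s
  structure(list(
    bias = bias, sd_diff = s, loa_low = loa[1], loa_high = loa[2],
    bias_ci = bias + c(-1, 1) * tq * seBias,
    loa_low_ci = loa[1] + c(-1, 1) * tq * seLoa,
    loa_high_ci = loa[2] + c(-1, 1) * tq * seLoa,
    n = n), class = "blandAltman")
}

#' @export
print.blandAltman <- function(x, ...) {
  cat(sprintf(
    "Bland-Altman (n = %d)\n  bias %.4g [%.4g, %.4g]\n  LoA   [%.4g, %.4g]\n",
    x$n, x$bias, x$bias_ci[1], x$bias_ci[2], x$loa_low, x$loa_high))
  invisible(x)
}

#' Centred log-ratio transform with multiplicative zero replacement
#'
#' Treats each sample (row) of a count matrix as compositional: zeros
#' are replaced by the count-zero-multiplicative rule -- each zero
#' becomes the pseudo-proportion `delta = zeroFrac / total(sample)` and
#' the non-zero proportions are rescaled multiplicatively so the row
#' still sums to one -- then each proportion is log-ratioed against the
#' row's geometric mean. CLR rows sum to zero.
#'
#' @param counts samples x taxa matrix (or data.frame) of non-negative
#'   counts, with row and column names.
#' @param zeroFrac fraction of the per-sample detection limit used for
#'   the replacement (default 0.65, the conventional choice).
#' @return numeric matrix of CLR values with attribute
#'   `state = "clr"`.
#' @examples
#' clrTransform(rbind(s1 = c(a = 2, b = 8)))  # -0.693, 0.693
#' @export
clrTransform <- function(counts, zeroFrac = 0.65) {
  m <- as.matrix(counts)
  if (any(m < 0)) stop("counts must be non-negative")
  if (is.null(rownames(m))) rownames(m) <- paste0("sample", seq_len(nrow(m)))
  tot <- rowSums(m)
  if (any(tot == 0)) {
    stop("all-zero sample(s): ",
         paste(rownames(m)[tot == 0], collapse = ", "))
  }
  out <- t(apply(m, 1L, function(row) {
    total <- sum(row)
    p <- row / total
    z <- row == 0
    if (any(z)) {
      delta <- zeroFrac * (1 / total)
      p[z] <- delta
      p[!z] <- p[!z] * (1 - sum(z) * delta)
    }
    log(p) - mean(log(p))
  }))
  dimnames(out) <- dimnames(m)
  attr(out, "state") <- "clr"
  out
}

#' Spearman correlation matrix between cluster assays and taxa
#'
#' Correlates (log-transformed) normalized but-gene copy ratios per
#' cluster assay with CLR-transformed taxon abundances across the
#' shared samples; per-cell significance at `alpha` with no
#' multiplicity correction (matching a fixed per-test alpha design),
#' optionally Benjamini-Hochberg adjusted.
#'
#' @param norm normalized abundance table from [normalizeTable()].
#' @param taxaClr samples x taxa CLR matrix ([clrTransform()]).
#' @param alpha per-cell significance level (default 0.05).
#' @param logRatios log-transform the copy ratios first (default TRUE;
#'   natural log, ratios are strictly positive by construction).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return list of matrices `rho`, `p`, `significant` with clusters as
#'   rows and taxa as columns (zero columns for an empty taxa set).
#' @export
correlationMatrix <- function(norm, taxaClr, alpha = 0.05,
                              logRatios = TRUE,
                              adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  clusters <- sort(unique(norm$cluster))
  taxa <- colnames(taxaClr)
  wide <- stats::reshape(
    norm[, c("sample", "cluster", "copy_ratio")],
    idvar = "sample", timevar = "cluster", direction = "wide")
  rownames(wide) <- wide$sample
  shared <- intersect(rownames(wide), rownames(taxaClr))
  if (length(taxa) && length(shared) < 3L) {
    stop("fewer than 3 shared samples")
  }
  rho <- p <- matrix(NA_real_, length(clusters), length(taxa),
                     dimnames = list(clusters, taxa))
  for (cl in clusters) {
    v <- wide[shared, paste0("copy_ratio.", cl)]
    if (logRatios) v <- log(v)
    for (tx in taxa) {
      sc <- spearmanCor(v, taxaClr[shared, tx])
      rho[cl, tx] <- sc$rho
      p[cl, tx] <- sc$p
    }
  }
  padj <- if (adjust == "BH") {
    matrix(stats::p.adjust(p, method = "BH"), nrow(p), ncol(p),
           dimnames = dimnames(p))
  } else p
  list(rho = rho, p = p, significant = padj < alpha)
}

#' Per-cluster group comparison report
#'
#' For each cluster assay: median and interquartile range per group
#' plus the two-sided Mann-Whitney p value, shaped like a
#' median-(IQR) summary table. A Shapiro-Wilk normality p value per
#' group is reported for information only (the nonparametric test is
#' used regardless).
#'
#' @param norm normalized abundance table ([normalizeTable()]).
#' @param groups length-2 character vector naming the groups to
#'   compare (default: the two groups present).
#' @param adjust `"none"` (default) or `"BH"` for the p values.
#' @return data.frame, one row per cluster: median/IQR per group,
#'   `p_value`, Shapiro p per group.
#' @export
groupCompareReport <- function(norm, groups = NULL,
                               adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (is.null(groups)) groups <- sort(unique(norm$group))
  if (length(groups) != 2L) stop("exactly 2 groups required")
  rows <- lapply(sort(unique(norm$cluster)), function(cl) {
    sub <- norm[norm$cluster == cl & is.finite(norm$copy_ratio), ]
    g1 <- sub$copy_ratio[sub$group == groups[1]]
    g2 <- sub$copy_ratio[sub$group == groups[2]]
    if (length(g1) < 2L || length(g2) < 2L) {
      stop("group with fewer than 2 samples in cluster ", cl)
    }
    sw <- function(v) {
      if (length(v) >= 3L && length(v) <= 5000L && stats::sd(v) > 0) {
        stats::shapiro.test(v)$p.value
      } else NA_real_
    }
    mw <- mannWhitney(g1, g2)
    df <- data.frame(
      cluster = cl,
      median_1 = stats::median(g1), iqr_1 = stats::IQR(g1),
      median_2 = stats::median(g2), iqr_2 = stats::IQR(g2),
      p_value = mw$p, shapiro_p_1 = sw(g1), shapiro_p_2 = sw(g2),
      stringsAsFactors = FALSE)
    names(df) <- sub("_1$", paste0("_", groups[1]), names(df))
    names(df) <- sub("_2$", paste0("_", groups[2]), names(df))
    df
  })
  out <- do.call(rbind, rows)
  if (adjust == "BH") out$p_value <- stats::p.adjust(out$p_value, "BH")
  rownames(out) <- NULL
  out
}
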