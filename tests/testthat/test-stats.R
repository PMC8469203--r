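# Group comparison, correlation, agreement, compositional transform.

test_that("Mann-Whitney exact branch matches full enumeration", {
  mw <- mannWhitney(c(1, 2), c(3, 4))
  expect_equal(mw$U, 0)
  expect_equal(mw$p, 1 / 3, tolerance = 1e-9)
  expect_identical(mw$method, "exact")
  set.seed(51)
  for (sizes in list(c(2, 3), c(4, 4), c(3, 6))) {
    x <- rnorm(sizes[1]); y <- rnorm(sizes[2])
    expect_equal(mannWhitney(x, y)$p, oracleMannWhitneyP(x, y),
                 tolerance = 1e-9)
  }
  # identical tiny groups: p at the boundary
  expect_gte(mannWhitney(c(5, 6), c(5, 6))$p, 0.9)
  expect_error(mannWhitney(numeric(0), 1), "empty")
})

test_that("exact and approximate branches agree on tie-free 8+8", {
  # the continuity-corrected normal approximation sits within ~0.01 of
  # the exact distribution at this size (worst case just above it)
  set.seed(52)
  diffs <- vapply(1:50, function(i) {
    x <- rnorm(8); y <- rnorm(8, 0.5)
    pExact <- mannWhitney(x, y)$p
    wApprox <- suppressWarnings(
      stats::wilcox.test(x, y, exact = FALSE, correct = TRUE))$p.value
    abs(pExact - wApprox)
  }, numeric(1))
  expect_lt(max(diffs), 0.02)
  expect_lt(median(diffs), 0.01)
})

test_that("Spearman rho follows the rank formula and its invariances", {
  expect_equal(spearmanCor(1:10, (1:10)^3)$rho, 1)
  expect_equal(spearmanCor(1:10, -(1:10))$rho, -1)
  expect_equal(spearmanCor(c(1, 2, 3, 4), c(1, 3, 2, 4))$rho, 0.8)
  cst <- spearmanCor(rep(1, 5), 1:5)
  expect_false(cst$defined)
  expect_true(is.na(cst$rho))
  set.seed(53)
  x <- rnorm(20); y <- rnorm(20)
  base <- spearmanCor(x, y)
  expect_equal(spearmanCor(exp(x), y)$rho, base$rho)
  expect_equal(spearmanCor(x, 2 * y + 7)$rho, base$rho)
  expect_error(spearmanCor(1:3, 1:4), "equal length")
})

test_that("Bland-Altman identities and antisymmetry hold", {
  a <- c(1.2, 3.4, 2.2, 5.1, 4.4)
  ba0 <- blandAltman(a, a)
  expect_equal(ba0$bias, 0)
  expect_equal(ba0$sd_diff, 0)
  expect_equal(c(ba0$loa_low, ba0$loa_high), c(0, 0))
  baC <- blandAltman(a, a - 0.7)
  expect_equal(baC$bias, 0.7)
  expect_equal(baC$sd_diff, 0)
  expect_equal(blandAltman(a, rev(a))$bias,
               -blandAltman(rev(a), a)$bias)
  expect_true(ba0$loa_low <= ba0$bias && ba0$bias <= ba0$loa_high)
  expect_error(blandAltman(1:4, 1:5), "equal length")
})

test_that("Bland-Altman recovers a known bias and LoA width", {
  set.seed(54)
  b <- rnorm(1000)
  a <- b + rnorm(1000, mean = 0.5, sd = 1)
  ba <- blandAltman(a, b)
  expect_true(ba$bias > 0.4 && ba$bias < 0.6)
  width <- ba$loa_high - ba$loa_low
  expect_lt(abs(width - 3.92) / 3.92, 0.1)
  expect_true(ba$bias_ci[1] < ba$bias && ba$bias < ba$bias_ci[2])
})

test_that("CLR rows are centred and scale-invariant", {
  expect_equal(unname(clrTransform(rbind(s = c(1, 1, 1, 1)))[1, ]),
               c(0, 0, 0, 0))
  expect_equal(unname(clrTransform(rbind(s = c(2, 8)))[1, ]),
               c(-log(2), log(2)), tolerance = 1e-6)
  set.seed(55)
  m <- matrix(rpois(60, 40) + 1, 6, 10,
              dimnames = list(paste0("s", 1:6), paste0("t", 1:10)))
  clr <- clrTransform(m)
  expect_true(all(abs(rowSums(clr)) < 1e-9))
  clr2 <- clrTransform(m * 17)
  expect_equal(unclass(clr2), unclass(clr), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("zeros get the multiplicative replacement, all-zero rows error", {
  m <- rbind(s1 = c(a = 0, b = 10, c = 30))
  clr <- clrTransform(m)
  expect_true(all(is.finite(clr)))
  expect_lt(abs(sum(clr[1, ])), 1e-9)
  # replaced proportion is 0.65/total and the rest is rescaled
  delta <- 0.65 / 40
  p <- c(delta, (10 / 40) * (1 - delta), (30 / 40) * (1 - delta))
  expect_equal(unname(clr[1, ]), log(p) - mean(log(p)), tolerance = 1e-9)
  expect_error(clrTransform(rbind(good = c(1, 2), dead = c(0, 0))),
               "dead")
})

test_that("assay-taxon correlation flags planted monotone links", {
  q <- simulateQpcr(groupSizes = c(VG = 15, OB = 15), seed = 6)
  norm <- normalizeTable(q, "UNC6")
  cVals <- norm$copy_ratio[norm$cluster == "C"]
  names(cVals) <- norm$sample[norm$cluster == "C"]
  samples <- names(cVals)
  # second taxon constant so the CLR keeps the first monotone
  taxa <- cbind(linked = rank(cVals) * 10 + 5,
                flat = rep(50, length(cVals)))
  rownames(taxa) <- samples
  cm <- correlationMatrix(norm, clrTransform(taxa))
  expect_equal(unname(cm$rho["C", "linked"]), 1)
  expect_true(cm$significant["C", "linked"])
  empty <- correlationMatrix(norm, clrTransform(taxa)[, 0, drop = FALSE])
  expect_equal(dim(empty$rho), c(6, 0))
  expect_error(correlationMatrix(norm[norm$sample %in% samples[1:2], ],
                                 clrTransform(taxa)), "3 shared")
})

test_that("group report gives medians, IQRs, and the Mann-Whitney p", {
  norm <- data.frame(sample = rep(sprintf("s%02d", 1:10), 2),
                     group = rep(rep(c("VG", "OB"), each = 5), 2),
                     cluster = rep(c("A", "B"), each = 10),
                     copy_ratio = c(1:5, 1:5, 2 * (1:5), 2 * (1:5)))
  rep <- groupCompareReport(norm, groups = c("VG", "OB"))
  expect_equal(rep$cluster, c("A", "B"))
  expect_equal(rep$median_VG, rep$median_OB)
  expect_true(all(rep$p_value > 0.9))
  # two samples per group still runs (exact branch)
  tiny <- norm[norm$sample %in% c("s01", "s02", "s06", "s07"), ]
  expect_s3_class(groupCompareReport(tiny, c("VG", "OB")), "data.frame")
  one <- norm[norm$sample %in% c("s01", "s06", "s07"), ]
  expect_error(groupCompareReport(one, c("VG", "OB")), "fewer than 2")
})
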