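# Degenerate in-silico PCR: binding sites, amplicon prediction,
# off-target screen.

test_that("planted binding sites are found at the planted positions", {
  set.seed(41)
  primer <- "GGKCCBATHGARRTTGCAGA"
  variant <- sample(oracleExpand(primer), 1)
  tmpl <- paste0(randSeq(100), variant, randSeq(150))
  hits <- findBindingSites(primer, tmpl)
  plus <- hits[hits$strand == "+", ]
  expect_true(any(plus$start == 101 & plus$mismatches == 0))
  # minus strand: plant the reverse complement of a variant
  tmpl2 <- paste0(randSeq(80), oracleRevcomp(variant), randSeq(60))
  hits2 <- findBindingSites(primer, tmpl2)
  minus <- hits2[hits2$strand == "-", ]
  expect_true(any(minus$start == 81 & minus$mismatches == 0))
})

test_that("mismatch allowance and 3' clamp gate the scan", {
  set.seed(42)
  primer <- "ACGTACGTACGTACGTAC"
  tmpl0 <- paste0(randSeq(50), primer, randSeq(50))
  # one internal mismatch: found at 1, absent at 0
  mut <- tmpl0
  substr(mut, 58, 58) <- if (substr(mut, 58, 58) == "A") "C" else "A"
  h0 <- findBindingSites(primer, mut, maxMismatch = 0)
  h1 <- findBindingSites(primer, mut, maxMismatch = 1)
  expect_false(any(h0$start == 51 & h0$strand == "+"))
  expect_true(any(h1$start == 51 & h1$strand == "+"))
  # a mismatch in the clamp positions is never tolerated
  mutClamp <- tmpl0
  substr(mutClamp, 68, 68) <- if (substr(mutClamp, 68, 68) == "A") "G" else "A"
  h2 <- findBindingSites(primer, mutClamp, maxMismatch = 2, clampExact = 2)
  expect_false(any(h2$start == 51 & h2$strand == "+"))
  h3 <- findBindingSites(primer, mutClamp, maxMismatch = 2, clampExact = 0)
  expect_true(any(h3$start == 51 & h3$strand == "+"))
  expect_error(findBindingSites(strrep("A", 30), "ACGT"), "longer")
})

test_that("amplicon length follows the 5'-to-5' inclusive convention", {
  pair <- PrimerPair("T", "GGKCCBATHGARRTTGCAGA", "TKTCGTCMASCCABTCATAC",
                     679)
  set.seed(43)
  fwdV <- sample(oracleExpand(fwdPrimer(pair)), 1)   # 20 nt
  revV <- sample(oracleExpand(revPrimer(pair)), 1)   # 20 nt
  tmpl <- paste0(fwdV, strrep("A", 500), oracleRevcomp(revV))
  hits <- predictAmplicons(pair, tmpl)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$product_len, 20 + 500 + 20)
  expect_equal(hits$fwd_start, 1)
  expect_equal(hits$rev_end, nchar(tmpl))
  # no reverse site: nothing predicted
  expect_equal(nrow(predictAmplicons(pair, paste0(fwdV, strrep("A", 500)))),
               0)
})

test_that("prediction matches an exhaustive quadratic oracle", {
  set.seed(44)
  pair <- PrimerPair("T", "ACGTMCGTACGTACGTAR", "TGCATGCAYGCATGCATG", 100)
  for (i in 1:5) {
    fwdV <- sample(oracleExpand(fwdPrimer(pair)), 1)
    revV <- sample(oracleExpand(revPrimer(pair)), 1)
    tmpl <- paste0(randSeq(40), fwdV, randSeq(sample(50:200, 1)),
                   oracleRevcomp(revV), randSeq(40),
                   fwdV, randSeq(30))  # extra orphan forward site
    got <- predictAmplicons(pair, tmpl, productRange = c(40, 1000))
    got <- got[got$strand == "+", ]
    want <- oracleAmplicons(fwdPrimer(pair), revPrimer(pair), tmpl,
                            c(40, 1000))
    expect_equal(nrow(got), nrow(want))
    expect_equal(got$product_len, unname(want[, "product_len"]))
    expect_equal(got$fwd_start, unname(want[, "fwd_start"]))
  }
})

test_that("reverse-complementing the template mirrors hits", {
  set.seed(45)
  pair <- PrimerPair("T", "ACGTMCGTACGTACGTAR", "TGCATGCAYGCATGCATG", 100)
  fwdV <- sample(oracleExpand(fwdPrimer(pair)), 1)
  revV <- sample(oracleExpand(revPrimer(pair)), 1)
  tmpl <- paste0(randSeq(30), fwdV, randSeq(100), oracleRevcomp(revV),
                 randSeq(50))
  n <- nchar(tmpl)
  h <- predictAmplicons(pair, tmpl, productRange = c(40, 500))
  hrc <- predictAmplicons(pair, revcompDegenerate(tmpl),
                          productRange = c(40, 500))
  expect_equal(nrow(h), nrow(hrc))
  expect_setequal(hrc$strand, setdiff(c("+", "-"), h$strand))
  expect_equal(sort(hrc$product_len), sort(h$product_len))
  # forward site coordinates mirror: start' = n - end + 1
  expect_equal(sort(n - hrc$fwd_end + 1L), sort(h$fwd_start))
})

test_that("deterministic ordering by template then position", {
  pair <- PrimerPair("T", "ACGTACGTACGTACGTAC", "TGCATGCATGCATGCATG", 60)
  core <- paste0("ACGTACGTACGTACGTAC", strrep("G", 30),
                 oracleRevcomp("TGCATGCATGCATGCATG"))
  tmpls <- c(z = core, a = core)
  got <- predictAmplicons(pair, tmpls, productRange = c(40, 100))
  expect_equal(got$template, c("a", "z"))
})

test_that("off-target screen flags only cross-cluster amplification", {
  fam <- plantedIslandFamily(2, seed = 404)
  res <- recursiveDesign(fam$tree, fam$sequences)
  ok <- Filter(function(r) r@status == "success", res)
  panel <- PrimerPanel(lapply(ok, function(r) r@pair[[1]]))
  cladeOf <- setNames(
    rep(vapply(ok, function(r) clusterLabel(r@pair[[1]]), character(1)),
        vapply(ok, function(r) length(r@leaves), integer(1))),
    unlist(lapply(ok, function(r) r@leaves)))
  rep <- offtargetScreen(panel, fam$sequences,
                         cladeOf[names(fam$sequences)],
                         maxMismatch = 0)
  expect_true(all(!rep$offtarget))
  # every pair hits every member of its own clade
  for (r in ok) {
    cl <- clusterLabel(r@pair[[1]])
    expect_setequal(rep$template[rep$cluster == cl], r@leaves)
  }
  # random templates: silence
  set.seed(46)
  rnd <- c(r1 = randSeq(900), r2 = randSeq(900))
  expect_equal(nrow(offtargetScreen(panel, rnd, c("A", "A"),
                                    maxMismatch = 0)), 0)
  expect_equal(nrow(offtargetScreen(panel, character(0))), 0)
})
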