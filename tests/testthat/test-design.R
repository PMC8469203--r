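# Window consensus, candidate scanning, per-clade design, recursive
# descent.

relaxed <- designConstraints(product_len = c(40L, 3000L),
                             tm_range = c(0, 200), gc_range = c(0, 1),
                             max_tm_diff = 1000)

test_that("window consensus is the column-wise minimal cover", {
  msa <- c(s1 = "ACGTACGTACGTACGTACGTAC",
           s2 = "ACGTACGTACGTACGTACGTAC",
           s3 = "ACGTACGTACGTACGTACGTAC")
  expect_identical(windowConsensus(msa, 1, 10), "ACGTACGTAC")
  msa2 <- c(s1 = "ACGTACGTAC", s2 = "CCGTACGTAC")
  expect_identical(windowConsensus(msa2, 1, 4), "MCGT")
  msa3 <- c(s1 = "ACGTACGTAC", s2 = "AC-TACGTAC")
  expect_true(is.na(windowConsensus(msa3, 1, 5)))
  expect_identical(windowConsensus(msa3, 4, 5), "TACGT")
  expect_error(windowConsensus(msa2, 8, 5), "range")
})

test_that("Wallace Tm bounds are per-position extrema over expansions", {
  expect_equal(unname(primerTmRange("ACGT")), c(12, 12))
  expect_equal(unname(primerTmRange("RT")), c(4, 6))
  set.seed(31)
  for (i in 1:20) {
    p <- randPattern(sample(5:10, 1))
    r <- primerTmRange(p)
    # oracle: Wallace Tm over the explicit expansion
    tms <- vapply(expandDegenerate(p), function(s) {
      ch <- strsplit(s, "")[[1]]
      2 * sum(ch %in% c("A", "T")) + 4 * sum(ch %in% c("G", "C"))
    }, numeric(1))
    expect_equal(unname(r), unname(range(tms)))
  }
})

test_that("candidate scan keeps exactly the admissible windows", {
  # identical members, generous constraints: every window of legal length
  msa <- c(a = randSeqFixed(60, 41), b = randSeqFixed(60, 41))
  got <- scanCandidates(msa, relaxed, "forward")
  nExpected <- sum(vapply(18:23, function(L) 60 - L + 1, numeric(1)))
  expect_equal(nrow(got), nExpected)
  # a polymorphic column kills windows covering it under degeneracy cap 1
  msa2 <- msa
  substr(msa2["b"], 30, 30) <- "A"
  substr(msa2["a"], 30, 30) <- "C"
  strict <- designConstraints(max_primer_degeneracy = 1,
                              product_len = c(40L, 3000L),
                              tm_range = c(0, 200), gc_range = c(0, 1))
  got2 <- scanCandidates(msa2, strict, "forward")
  expect_false(any(got2$start <= 30 & got2$start + got2$len - 1 >= 30))
  # reverse orientation: sequences are reverse complements of consensi
  gotR <- scanCandidates(msa, relaxed, "reverse")
  w <- gotR[1, ]
  expect_identical(w$seq,
                   revcompDegenerate(substr(msa[["a"]], w$start,
                                            w$start + w$len - 1)))
})

test_that("a conserved island in divergent sequences is the only site", {
  set.seed(32)
  island <- randSeq(30)
  mk <- function() paste0(randSeq(100), island, randSeq(100))
  msa <- c(a = mk(), b = mk())
  cons <- designConstraints(max_primer_degeneracy = 1,
                            product_len = c(40L, 3000L),
                            tm_range = c(0, 200), gc_range = c(0, 1),
                            three_prime_clamp = 0)
  got <- scanCandidates(msa, cons, "forward")
  # brute-force: windows whose consensus is concrete
  expected <- 0L
  for (L in 18:23) {
    for (s in seq_len(230 - L + 1)) {
      wc <- windowConsensus(msa, s, L)
      if (degeneracy(wc) == 1) expected <- expected + 1L
    }
  }
  expect_equal(nrow(got), expected)
  expect_true(all(got$start >= 101 - 5 & got$start <= 130))
})

test_that("single-sequence design succeeds with a concrete pair", {
  seqs <- c(only = randSeqFixed(800, 42))
  res <- designForCluster(seqs, designConstraints(), label = "X")
  expect_s4_class(res, "DesignResult")
  expect_identical(res@status, "success")
  pair <- res@pair[[1]]
  expect_equal(pairDegeneracy(pair), 1)
  expect_identical(clusterLabel(pair), "X")
  expect_true(expectedLength(pair) >= 400 && expectedLength(pair) <= 800)
  # and the pair amplifies its own template at the expected length
  hit <- predictAmplicons(pair, seqs[["only"]],
                          productRange = c(400, 800))
  expect_true(expectedLength(pair) %in% hit$product_len)
})

test_that("design failure is a value with actionable diagnostics", {
  # infeasible product range
  seqs <- c(only = randSeqFixed(800, 43))
  res <- designForCluster(seqs, designConstraints(product_len = c(10L, 20L)))
  expect_identical(res@status, "failure")
  expect_gt(res@diagnostics[["pair_product_len"]], 0)
  # two unrelated random sequences: no covering window
  set.seed(33)
  msa <- c(a = randSeq(500), b = randSeq(500))
  res2 <- designForCluster(msa, designConstraints())
  expect_identical(res2@status, "failure")
})

test_that("descent stops at the shallowest designable clade", {
  # all leaves identical: one result at the root
  s <- randSeqFixed(800, 44)
  msa <- c(A = s, B = s, C = s, D = s)
  tree <- parseNewick("((A,B),(C,D));")
  res <- recursiveDesign(tree, msa)
  expect_length(res, 1)
  expect_identical(res[[1]]@status, "success")
  expect_setequal(res[[1]]@leaves, c("A", "B", "C", "D"))

  # two conserved families sharing nothing across families
  set.seed(34)
  fam1 <- randSeq(800); fam2 <- randSeq(800)
  msa2 <- c(A = fam1, B = fam1, C = fam2, D = fam2)
  res2 <- recursiveDesign(tree, msa2)
  expect_length(res2, 2)
  expect_setequal(lapply(res2, function(r) sort(r@leaves)),
                  list(c("A", "B"), c("C", "D")))
  # cross-check: of the 7 clades, exactly {A,B},{C,D} and the
  # singletons admit a pair; the root does not
  root <- designForCluster(msa2, designConstraints())
  expect_identical(root@status, "failure")
})

test_that("emitted clades partition the leaf set (planted families)", {
  for (seed in c(101, 202)) {
    fam <- plantedIslandFamily(3, seed = seed)
    res <- recursiveDesign(fam$tree, fam$sequences)
    ok <- Filter(function(r) r@status == "success", res)
    bad <- Filter(function(r) r@status == "failure", res)
    emitted <- unlist(lapply(ok, function(r) r@leaves))
    expect_false(anyDuplicated(emitted) > 0)
    expect_setequal(c(emitted, unlist(lapply(bad, function(r) r@leaves))),
                    names(fam$sequences))
  }
})

test_that("relaxing the degeneracy cap never fragments the panel more", {
  fam <- plantedIslandFamily(2, subProb = 0.15, seed = 303)
  nClusters <- function(cap) {
    res <- recursiveDesign(fam$tree, fam$sequences,
                           designConstraints(max_primer_degeneracy = cap))
    length(Filter(function(r) r@status == "success", res))
  }
  n64 <- nClusters(64); n256 <- nClusters(256); n1024 <- nClusters(1024)
  expect_true(n256 <= n64)
  expect_true(n1024 <= n256)
})

test_that("the packaged primers satisfy the primer-level defaults", {
  p <- loadPrimerPanel()
  cons <- designConstraints()
  for (cl in names(p)) {
    for (side in c(fwdPrimer(p[[cl]]), revPrimer(p[[cl]]))) {
      L <- nchar(side)
      expect_true(L >= cons$primer_len[1] && L <= cons$primer_len[2])
      expect_lte(degeneracy(side), cons$max_primer_degeneracy)
      # 3' clamp: terminal positions concrete
      tail <- substr(side, L - cons$three_prime_clamp + 1L, L)
      expect_equal(degeneracy(tail), 1)
    }
    expect_lte(pairDegeneracy(p[[cl]]), cons$max_pair_degeneracy)
  }
})

test_that("the progressive aligner threads indels consistently", {
  ref <- "ACGTACGTACGTACGTACGT"
  del <- "ACGTACGTCGTACGT"    # 5 nt missing
  ins <- "ACGTACGTTTTACGTACGTACGT"  # 3 nt inserted
  out <- alignFamily(c(r = ref, d = del, i = ins))
  expect_length(unique(nchar(out)), 1)
  expect_identical(gsub("-", "", out[["r"]]), ref)
  expect_identical(gsub("-", "", out[["d"]]), del)
  expect_identical(gsub("-", "", out[["i"]]), ins)
  expect_error(alignFamily(setNames(as.character(1:51), 1:51)), "50")
})
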