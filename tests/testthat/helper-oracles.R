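# Independent oracles built on Biostrings' IUPAC table and brute-force
# enumeration; they deliberately avoid the package's bitmask machinery.

.iupacSets <- strsplit(Biostrings::IUPAC_CODE_MAP, "")

# full expansion by recursive cartesian product over per-position sets
oracleExpand <- function(pattern) {
  sets <- .iupacSets[strsplit(pattern, "")[[1]]]
  out <- ""
  for (s in sets) out <- as.vector(outer(out, s, paste0))
  out
}

# mismatch count by set membership per position (concrete window)
oracleMismatches <- function(pattern, window) {
  ps <- .iupacSets[strsplit(pattern, "")[[1]]]
  wc <- strsplit(window, "")[[1]]
  sum(!mapply(function(set, ch) ch %in% set, ps, wc))
}

oracleRevcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# random degenerate pattern with degeneracy <= cap
randPattern <- function(len, cap = 4096, pAmbig = 0.25) {
  syms <- names(Biostrings::IUPAC_CODE_MAP)
  conc <- c("A", "C", "G", "T")
  amb <- setdiff(syms, conc)
  repeat {
    p <- ifelse(runif(len) < pAmbig, sample(amb, len, TRUE),
                sample(conc, len, TRUE))
    p <- paste(p, collapse = "")
    if (degeneracy(p) <= cap) return(p)
  }
}

randSeq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, TRUE), collapse = "")
}

# deterministic random sequence, independent of the caller's RNG state
randSeqFixed <- function(len, seed) {
  withr::with_seed(seed, randSeq(len))
}

# quadratic-scan amplicon oracle (plus orientation only): every
# (fwd site, downstream revcomp-rev site) pair, product length 5'->5'
oracleAmplicons <- function(fwd, rev, template, productRange) {
  n <- nchar(template)
  lf <- nchar(fwd); lr <- nchar(rev)
  rcRev <- oracleRevcomp(rev)
  fs <- Filter(function(s) {
    oracleMismatches(fwd, substr(template, s, s + lf - 1L)) == 0L
  }, seq_len(n - lf + 1L))
  rs <- Filter(function(s) {
    oracleMismatches(rcRev, substr(template, s, s + lr - 1L)) == 0L
  }, seq_len(n - lr + 1L))
  hits <- list()
  for (i in fs) for (j in rs) {
    if (j <= i + lf - 1L) next
    len <- j + lr - 1L - i + 1L
    if (len >= productRange[1] && len <= productRange[2]) {
      hits[[length(hits) + 1L]] <- c(fwd_start = i, rev_end = j + lr - 1L,
                                     product_len = len)
    }
  }
  if (length(hits)) do.call(rbind, hits) else
    matrix(integer(0), 0, 3,
           dimnames = list(NULL, c("fwd_start", "rev_end", "product_len")))
}

# exact two-sided Mann-Whitney p by full enumeration of labelings
oracleMannWhitneyP <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled); nx <- length(x)
  uStat <- function(a, b) {
    sum(vapply(a, function(v) sum(v > b) + 0.5 * sum(v == b), numeric(1)))
  }
  uObs <- uStat(x, y)
  combs <- utils::combn(n, nx)
  us <- apply(combs, 2L, function(idx) uStat(pooled[idx], pooled[-idx]))
  muU <- nx * (n - nx) / 2
  mean(abs(us - muU) >= abs(uObs - muU) - 1e-9)
}
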