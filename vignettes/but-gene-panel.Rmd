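---
title: "Degenerate primer panels for the but gene: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Degenerate primer panels for the but gene: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(butqPCR)
```

## The problem

Colonic butyrate is mostly produced through the butyryl-CoA:acetate
CoA-transferase route, so the abundance of the encoding gene (*but*)
in fecal DNA is a direct, sequencing-free proxy for a microbiome's
butyrate synthesis capacity. The catch is that *but* is highly
variable across the gut taxa that carry it: no single primer pair —
not even a degenerate one — covers all of them. The method this
package implements resolves that by **phylogeny-guided clustering**:
taxa are grouped by phylogenetic distance, one degenerate primer pair
is attempted per group, and whenever a group's variability defeats the
design constraints the procedure steps down the tree to the group's
children and tries again. For the packaged curation of 36 gut
butyrate-producer genomes this descent ends in six clusters (A–F),
each with one degenerate pair and an expected amplicon of 558–726 nt.

A degenerate primer written in IUPAC ambiguity codes stands for a
mixture of concrete oligonucleotides; its **degeneracy number** is the
size of that mixture, the product of the per-position ambiguity-set
sizes (`degeneracy("MCTGGGYATYCACACCGAG")` is 8: M·Y·Y = 2·2·2).
Degeneracy drives two operational rules implemented here: only a
fraction of the mixture matches any one template, so working
concentration grows with degeneracy; and synthesis batches differ in
variant composition, which is why the concentration rule is stated per
pair rather than per batch.

## The design procedure

`recursiveDesign(tree, msa, constraints)` walks the rooted clade tree
depth-first from the root. At each clade it calls
`designForCluster()`, which:

1. scans every alignment window of an allowed length in both
   orientations (`scanCandidates()`), taking the **column-wise minimal
   IUPAC consensus** over the clade members (`consensusSymbol()`);
   a window touching an alignment gap in any member is discarded;
2. screens each candidate for degeneracy, Wallace-rule melting
   temperature, mean GC fraction, and a non-degenerate 3′ clamp;
3. pairs forward and reverse candidates in rank order and accepts the
   first pair whose implied product length — measured 5′ end of the
   forward site to the 5′ end of the reverse site on the opposite
   strand, inclusive, on the ungapped reference member — falls in
   range, subject to a pair-degeneracy cap and a maximum Tm mismatch.

Success stops the descent for that subtree; failure recurses into the
children; a leaf that fails even alone is reported undesignable. The
emitted clades therefore partition the designable leaf set, and
because the consensus covers every observed base, each emitted primer
matches every clade member with zero mismatches (only members with
ambiguous N bases can escape coverage; such columns make the consensus
N and in practice fail the degeneracy cap instead).

"Success" has no canonical definition in this procedure — it is
operationalized entirely by `designConstraints()`, and every threshold
is a tunable:

| parameter | default | units | rationale |
|---|---|---|---|
| `primer_len` | 18–23 | nt | the span of the packaged panel's primers |
| `max_primer_degeneracy` | 256 | variants | keeps per-variant concentration workable; admits the most degenerate packaged primer (216) |
| `max_pair_degeneracy` | 2048 | variants | must admit the packaged cluster-B pair (72 × 24 = 1728) |
| `product_len` | 400–800 | nt | brackets the panel's 558–726 nt amplicons; qPCR-friendly |
| `tm_range` | 50–65 | °C | Wallace-scale window compatible with 60 °C annealing |
| `max_tm_diff` | 8 | °C | forward/reverse midpoint mismatch tolerance |
| `gc_range` | 0.30–0.70 | fraction | conventional primer QC band |
| `three_prime_clamp` | 1 | positions | see below |
| `min_coverage` | 1.0 | fraction | every clade member must be matched exactly |

Three of these deserve a note, because the design space was genuinely
open:

* **3′ clamp = 1, not 2.** Extension starts at the 3′ end, so
  degenerate 3′-terminal positions are the riskiest. A two-position
  clamp is common advice, but the packaged cluster-C forward
  (…TA**Y**G) and cluster-F forward (…Y T**W**G) primers are
  degenerate at the penultimate position; a calibration that rejects
  the panel it ships would be incoherent, so the default requires only
  the terminal base to be concrete. The in-silico matcher
  (`findBindingSites()`) keeps a separate, stricter default —
  `clampExact = 2` template positions must match exactly — because
  there the clamp models extension failure, not design caution.
* **Tm screen on the midpoint.** A degenerate primer has a Tm *range*
  over its expansion (`primerTmRange()`, computed per position without
  enumerating). Requiring the whole range inside `tm_range` would
  reject the packaged cluster-F reverse primer (Wallace maximum
  68 °C), so a candidate passes when its midpoint does, and pair
  balance is compared on midpoints.
* **Coverage = 1.0.** Whether a cluster primer must match every member
  or merely most is not dictated by the procedure; the default demands
  all, which is also what the consensus construction delivers for
  N-free inputs.

Ranking is deterministic: degeneracy ascending, then Tm-midpoint
proximity to 60 °C, then leftmost window; the pair search prefers the
best-ranked forward candidate. Ties never depend on hash order or
RNG. Coordinates are 0-based half-open internally and 1-based
inclusive in every report.

The descent re-slices clade members from the one global MSA rather
than re-aligning each clade — determinism and speed over marginal
alignment quality. A convenience reference-anchored progressive
aligner (`alignFamily()`, pairwise global alignments threaded into one
MSA) is provided for ≤ 50 sequences; it does not align insertions from
different members against each other and is no substitute for a real
multiple aligner. Neighbor joining (`njTree()`, via ape) with midpoint
rooting covers users who arrive with sequences but no tree; midpoint
was chosen because the descent needs *some* root and branch lengths
are otherwise unused.

## In-silico PCR

`predictAmplicons()` reports every (forward site, downstream reverse
site) combination on both template orientations, with product length
under the 5′→5′ inclusive convention — the convention matters, since
the packaged expected lengths are only reproducible under it. A
template `N` (or any non-IUPAC character) matches nothing, so masked
template stretches cannot seed phantom amplicons. Multiple amplicons
per template are all reported; deciding what a multi-product qPCR
means is deliberately left to the reader of the report. The off-target
screen defaults to a permissive `maxMismatch = 2` so that near-misses
surface; the on-target default is 0 mismatches, which is the regime
qPCR specificity actually requires.

## Quantification

`copyRatio()` is the uncorrected ΔCt estimator
`E^(Ct_ref − Ct_target)` with efficiency fixed at 2.0 (perfect
doubling). Per-assay efficiencies can be supplied but are never
estimated here — estimating them needs dilution series this package
does not model. Replicates are averaged on the Ct scale (equivalently,
geometric mean of ratios); a replicate more than 0.5 cycles from the
replicate median is dropped, but only for triplicates and larger,
because with two replicates the outlier is unidentifiable (each of a
discordant duplicate is equally far from their median).

Two references are supported: an exogenous spike (the *C. elegans*
UNC-6 netrin gene fragment, added before DNA isolation) and the 16S
rRNA gene. Their ratio within a sample is a cluster-independent
constant `E^(Ct_UNC6 − Ct_S16)` — an exact identity the tests verify
to machine precision, and the reason the two normalizations agree up
to a per-sample offset on the log scale. Because bacteria carry
variable 16S copy numbers, 16S-normalized values can optionally be
rescaled by an average 4.2 copies per genome
(`sixteenSCopyCorrection()`); the factor is an across-genome average
and is configurable.

The concentration rule `recommendConcentration()` interpolates
`200 + 800·min(1, log2(d)/8)` nM (rounded to 10 nM) between the
conventional 200 nM for a concrete pair and 1 µM at degeneracy 256 and
beyond. The endpoints and the degeneracy dependence are operational
facts; the log-linear interpolation between them is this package's
choice and should be treated as a starting point for titration, not a
law.

## Statistics

Group comparison uses the two-sided Mann–Whitney test
(`mannWhitney()`, delegating to `stats::wilcox.test`): exact when the
pooled sample is ≤ 16 and tie-free, otherwise the tie- and
continuity-corrected normal approximation. The exact branch is checked
against full enumeration of labelings in the test suite; the
approximate branch deviates from the exact distribution by up to about
0.011 at 8+8, which is why the branch-agreement property is asserted
at 0.02. Shapiro–Wilk normality p values are reported for information
only — the nonparametric test is used regardless, so normality gates
nothing. No multiple-testing correction is applied by default (the
per-test α = 0.05 convention); a Benjamini–Hochberg option exists on
the reporting functions but defaults off.

NGS count tables are treated as compositional: `clrTransform()`
replaces zeros by the count-zero-multiplicative rule — each zero
becomes δ = 0.65·(1/rowTotal) of the composition, the conventional
0.65 fraction of the detection limit, with the non-zero parts rescaled
multiplicatively — then centers log proportions on their geometric
mean. CLR rows sum to zero within 1e-9, and the transform is invariant
to row scaling for zero-free rows. An all-zero sample has no
composition and errors out by name. Correlations between cluster
assays and taxa (`correlationMatrix()`) use Spearman's rho on
naturally log-transformed copy ratios (strictly positive by
construction, so no offset is added).

`blandAltman()` follows the standard formulas: bias = mean difference,
limits of agreement = bias ± 1.96·sd, bias CI from the t distribution,
and LoA CIs using se(LoA) = sd·√(3/n) — the common approximation; the
exact variant differs negligibly at the sample sizes involved.

## What the synthetic generators emulate — and what they do not

`plantedIslandFamily()` evolves a random ancestor down a fixed clade
tree by i.i.d. substitutions (uniform replacement among the three
alternative bases, no indels by default) while "islands" — windows
designated per clade — are immune to substitution inside their clade.
One 650-nt island per clade makes exactly that clade designable (a
650-nt conserved stretch hosts a forward and reverse primer at an
amplicon spacing inside 400–800 nt) while the same region diverges
freely elsewhere. The defaults (3 leaves per clade, per-branch
substitution probability 0.25) are set so that multi-clade consensus
windows reliably blow past the degeneracy caps — which is the regime
the real *but* family occupies. Ground truth is exact: the descent
should emit one cluster per island clade, and each emitted pair should
amplify all and only its clade members, which the acceptance suite
verifies over 20 seeds for k ∈ {1, 2, 6}.

`simulateQpcr()` draws a biological reference Ct per sample
(normal, default mean 25, sd 1), offsets each target assay by
−log₂(true ratio), and adds per-measurement noise (default sd 0.5
cycles); a 16S reference runs a constant 10 cycles below the spike.
Default group sizes (63 vs 62) and per-cluster true ratios mirror the
two-cohort study design this method was developed on, with cluster C
dominant (ratios 211 vs 86) and cluster B rare.

Passing tests on these generators demonstrate that the *pipeline* is
correct — they do not demonstrate field performance. In particular:

* substitution is i.i.d. and indel-free; real *but* sequences have
  rate heterogeneity, codon structure and indels, so real alignments
  are harder and real clusters fuzzier;
* `simulateQpcr()` models **measurement noise only**. Real cohorts add
  large between-subject biological spread (observed interquartile
  ranges are of the same order as the medians), so simulated p values
  are far sharper than real ones: under the defaults every cluster
  with unequal ratios separates, whereas in a real cohort only the
  strong effects do. Power statements from this generator are
  best-case;
* the off-target screen sees only the templates it is given; it is a
  local check, not a database-wide specificity guarantee;
* amplification efficiency is ideal (2.0) and common to all assays.

## Problem sizes and numerical conventions

The test and acceptance suites run at desk scale, chosen to keep the
whole suite in a few minutes while leaving the conclusions stable
across seeds: design-recovery at k ∈ {1, 2, 6} × 20 seeds,
fold-change recovery over 100 simulated studies of 60 + 60 samples,
power over 200 seeds, type-I error over 2000 null draws, exact-test
enumeration up to 8+8 (12 870 labelings). Degenerate expansion is
capped at 4096 variants by default (`expandDegenerate()` refuses
beyond the cap by name); degeneracy itself is computed positionally
and never requires expansion. Window statistics in the scan are
windowed cumulative sums, so a full scan is linear in alignment length
per primer length; degeneracy per window is reconstituted from log2
column sizes and rounded, exact for products of sizes 1–4 at any
realistic primer length. Ct values must be positive and finite;
non-finite Ct propagates as "flagged missing", never as zero or a
silent drop.

## Known limitations

The cluster membership shipped with the target table is complete only
where the source curation states it unambiguously; taxa whose cluster
cannot be pinned down are left unassigned rather than guessed. The
packaged expected product lengths are validated in-silico against
synthetic templates constructed to carry the binding sites (the
package performs no network access); validation against the actual
accession sequences is a one-liner for users with network access via
`accessionManifest()` plus `predictAmplicons()`. The built-in aligner
and NJ tree are conveniences for small families, not replacements for
MUSCLE/PhyML-class tools; and nothing here models amplification
kinetics, melt curves, or absolute quantification against standard
curves.
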