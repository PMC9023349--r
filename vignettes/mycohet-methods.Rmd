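---
title: "Methods behind mycohet: loss indices, Ks modes and LTR clocks"
author: "mycohet authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind mycohet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mycohet)
```

This vignette documents the statistical models, the defaults and the design
choices in `mycohet`, in the spirit of a methods section: what each
estimator assumes, where its tunable parameters matter, and what the
synthetic-data generators do and do not emulate.

## 1. Gene-family loss and the F index

### Model

Given an orthogroup-by-species count matrix, the F index compares a
species' gene count in a family against the family's average per-species
share:

$$F = \frac{\log_2\!\big(a\,c_{ij}/N_j + \tfrac12\big) + 1}
           {\log_2\!\big(a + \tfrac12\big) + 1},
\qquad a = \frac{S^2 - 2S}{2},$$

with $c_{ij}$ the count of species $i$ in family $j$, $N_j$ the family's
total gene count and $S$ the number of species represented in the family.
The normalisation is chosen so that $F = 0$ iff $c_{ij} = 0$, $F = 1$ iff
the species holds the whole family, and $F = 1/2$ exactly at the average
share $c_{ij}/N_j = 1/S$: substituting gives numerator
$\log_2\!\big((S-1)/2\big) + 1 = \log_2(S-1)$ and denominator
$\log_2\!\big((S-1)^2/2\big) + 1 = 2\log_2(S-1)$. The property-based tests
verify this identity at machine precision over random $(S, N_j)$.

Interpretation of the symbols deserves one note: we read $N_j$ as the
*total number of genes in family $j$* — the only reading under which
$c_{ij}/N_j$ is a proportion and the 0.5-at-average identity holds — and
$S$ as the number of species with a nonzero count in the family (not the
panel size). For a species with $c_{ij} = 0$ the family's $S$ from the
nonzero species is used; $F = 0$ regardless, so the choice only affects
reported metadata.

### Choices and degenerate cases

* **Conservation filter first.** Families are filtered to those present in
  at least `minSpecies` of the panel (16 of 19 in the motivating use case)
  *and* with a homolog in a designated early-diverging outgroup, before any
  F computation. This restricts the classification to families one can
  defend as anciently conserved, so that absence is interpretable as loss.
* **$S < 3$.** At $S = 2$, $a = 0$ and the formula degenerates. Such
  families are reported as not evaluable (`evaluable = FALSE`, NA index)
  rather than silently dropped; the conservation filter makes them rare in
  practice.
* **Category boundaries** (0 / 0.45 / 0.5 / 0.55, upper-inclusive) are
  compared at full floating-point precision; F is never rounded before
  classification. "Missing" is the category name used in output.
* The per-cell table, per-species category percentages (rows sum to 100)
  and pairwise shared-missing counts are what the bar-plot style summaries
  of loss studies are built from.

## 2. Ortholog identification and NG86 Ks

### Reciprocal best hits

Hits from 12-column tabular BLAST/DIAMOND output are filtered at
`evalue < 1e-5`, then each query's best hit is chosen by bit score, ties
broken by e-value, then by lexicographically smallest subject id (a
deterministic total order). A pair is an ortholog candidate iff it is
mutual. The procedure is symmetric: swapping the two tables mirrors the
pair set, which the suite asserts on random tables.

### Alignment and back-translation

Ortholog proteins are aligned globally (Needleman–Wunsch with affine gaps,
BLOSUM62, gap of length $L$ costing $10 + 0.5L$), then back-translated to
codons with every gap column removed. Back-translation refuses CDS/protein
pairs that do not translate exactly (reporting the first offending codon),
and strips a terminal stop codon if present. The aligner is
`Biostrings::pairwiseAlignment` behind a stable package interface; a
brute-force Gotoh dynamic program in the test suite pins down the exact
scoring convention.

ML codon models (Goldman–Yang) are deliberately out of scope: the built-in
estimator is NG86, which is fully specifiable and oracle-testable, and an
import path (`importKsTable`) accepts externally computed Ks (e.g. CODEML)
whenever those are preferred.

### NG86 conventions

Per codon, the synonymous site count is the synonymous fraction of the
nine single-nucleotide mutations, summed over positions; mutations creating
stop codons count as nonsynonymous. Differences between a codon pair are
averaged over all substitution orderings, excluding orderings that pass
through a stop; a pair whose *every* ordering crosses a stop is excluded
from counting with a warning, as are codons containing N. Sites are
averaged over the two sequences; $p_S = S_d/\bar S$ is Jukes–Cantor
corrected, $K_s = -\tfrac34\ln(1 - \tfrac43 p_S)$, undefined (flagged
`saturated_Ks`) at $p_S \ge 3/4$. The implementation precomputes 61×61
difference tables once per session; the acceptance suite checks *every*
sense-codon pair against an independent exhaustive path-enumeration oracle.

## 3. Ks modes, bootstrap and relative rates

### KDE mode

A Ks distribution is filtered to bounds (default $(0.01, 5)$ — the lower
bound removes near-zero alignment artefacts, the upper removes saturated
estimates; neither is sharp and both are configurable and logged). The mode
is the argmax of a Gaussian KDE with Silverman's reference bandwidth
(`bw.nrd0`) on a 512-point uniform grid over the bounds, ties broken toward
smaller Ks (the younger divergence). Estimation requires $n \ge 30$; the
KDE is computed on the raw Ks scale. Raw-scale KDE with a global bandwidth
slightly oversmooths strongly skewed distributions — for a lognormal with
sdlog 0.5 and 5,000 points the mode bias is of order 0.05–0.1 — which is
why downstream comparisons rest on bootstrap intervals rather than the
point mode alone.

### Bootstrap

`bootstrapMode` resamples the values with replacement (default 200
resamples), recomputes the KDE mode per resample, and reports the median of
the bootstrap modes (robust against the grid discretisation) with the
2.5/97.5 percentile interval; percentile intervals are used throughout.
Box statistics of the bootstrap modes use quartiles with 1.5×IQR whiskers.
All resampling is driven by an explicit seed and restores the caller's RNG
state.

### Relative-rate decomposition

For outgroup $O$ and ingroup species $A, B$, the three pairwise mode
distances decompose as

$$d_A = \tfrac12(d_{AB} + d_{OA} - d_{OB}),\quad
  d_B = \tfrac12(d_{AB} + d_{OB} - d_{OA}),\quad
  d_{\text{shared}} = \tfrac12(d_{OA} + d_{OB} - d_{AB}),$$

so $d_A + d_B = d_{AB}$ and companions hold identically. Noise can produce
negative branch distances (triangle violations); these are flagged, never
clipped. The joint bootstrap resamples all three distributions per
replicate and reports percentile intervals per branch; the point estimate
decomposes the per-distribution bootstrap-median modes so the linear
identities hold exactly for the reported values too.

## 4. LTR insertion dating

The two LTRs of a retrotransposon are identical at insertion; their
divergence clocks the element. We compute the mismatch proportion $p$ over
columns where both sequences have an unambiguous base (gap and N columns
are excluded from numerator *and* denominator), correct for multiple hits
with Jukes–Cantor, and convert via $T = K/(2r)$. The calibration rate
$r = d/(2t)$ comes from a collinear-block divergence $d$ and a dated split
$t$; with $d = 0.38379$ and $t = 11.63$ Ma this yields
$1.65\times10^{-8}$ substitutions/site/year. Rates are treated as
per-*year* throughout (a per-Ma reading of a rate of this magnitude would
be dimensionally inconsistent with $d = 2rt$ at $t \approx 11.63$ Ma), and
outputs carry explicit unit labels. "Insertions before $x$ Ma" is read as
$T < x$ (more recent than $x$ Ma), noted in output headers. At $p \ge 3/4$
the JC correction is undefined and the element is flagged saturated.

## 5. Enrichment

The over-representation test is the one-sided hypergeometric upper tail
$P[X \ge k]$ — inclusive of the observed $k$, the conservative standard —
computed exactly in log space (`phyper`), with Bonferroni correction over
the number of terms actually tested (those with $k \ge 1$; terms with no
study-set overlap are skipped, and the denominator is logged). No GO-graph
propagation or other FDR procedures are attempted. Exactness is asserted
against a brute-force combinatorial sum over every configuration with
universe size up to 12, and the type-I error of the whole chain is checked
under the null annotation simulator.

## 6. k-mer genome profiling

Reads are decomposed into canonical k-mers (lexicographic minimum of the
window and its reverse complement; windows containing N are skipped),
2-bit-encoded into doubles — exact up to $k = 26$, default $k = 17$ — and
tallied into a multiplicity histogram. Genome size is the Lander–Waterman
quotient: total counted k-mers divided by the peak depth. Multiplicities
below `minMult = 3` are excluded from both the total and the peak search,
to keep the sequencing-error peak out; real heterozygous genomes show a
first major peak at half the homozygous depth, so the estimator reports all
local maxima and accepts an explicit `peak` override rather than guessing.
Heterozygosity-rate mixture modelling is out of scope. Strand symmetry and
coverage equivariance (duplicating reads doubles the peak, not the size)
are property-tested.

## 7. The synthetic-data generators

Each generator emits data plus ground truth, under a mandatory seed
(default 1729, always recorded in run manifests), and is bit-reproducible.

* **Count matrices**: per-species Bernoulli retention; an optional joint
  loss component for a designated species pair (union with independent
  losses, mimicking correlated loss in two mycoheterotrophs); present
  families draw sizes from a *positive-truncated* Poisson whose truncated
  mean equals `meanFamilySize` (so "present" always means at least one
  gene; the underlying rate is solved numerically, requiring mean > 1).
* **Codon quartets**: a root sequence of uniform sense codons evolves down
  the fixed (outgroup, (reference, (spA, spB))) topology. Substitutions are
  proposed as random single-nucleotide changes and accepted only if
  synonymous and stop-free, with Poisson(branch dS × synonymous sites)
  accepted events per branch. Keeping the process synonymous-only leaves
  the true branch dS directly comparable with NG86 output, without a dN
  confound — at the cost of not emulating nonsynonymous divergence,
  alignment uncertainty, or among-site rate variation. Because the protein
  never changes, alignments of simulated orthologs are trivially gapless;
  the aligner is exercised separately on its own tests.
* **LTR pairs**: both LTRs of an element accumulate
  Poisson(rate × age × length) substitutions from a shared ancestor
  (multiple hits at a site allowed, hence genuine JC-style saturation at
  old ages), pairwise expectation $2rt$ per site.
* **Reads**: uniform sampling (random strand) from a uniform-random
  genome, optional per-base substitution errors. Real genomes' repeats and
  coverage biases are *not* emulated, so passing recovery tests shows
  estimator correctness under the model, not robustness to repeat-rich
  genomes.
* **Annotations**: one designated term draws its genes from a target set
  with a given probability; all other terms draw uniformly — a minimal
  enrichment/null pair for calibration studies.

## 8. Problem sizes and numerical tolerances in the test suite

The deep end-to-end checks run at deliberately chosen scales: loss-rate
recovery at 10,000 families (binomial 3-SE tolerance); branch-rate ratio
recovery (true ratio 2.0, ±20%) from a 300-gene, 300-codon quartet; LTR
age recovery on 200 elements of 2 kb (bias within 2 standard errors of the
mean error); genome size within 10% from a 1 Mb genome at 30× coverage;
and bootstrap-mode coverage on 200 outer replicates of a lognormal with
density mode 0.8 (sdlog 0.5, n = 5,000 per replicate — scaled down from
the ~10⁴ ortholog pairs of a typical species comparison), asserted at
95% ± 4 points. Decomposition identities are checked to $10^{-12}$ on
10,000 random triples; exact quantities (F-index identities, NG86 tables,
hypergeometric tails) to $10^{-12}$ or better.

## 9. Known limitations

* NG86 underestimates Ks relative to ML codon models at high divergence
  and ignores transition/transversion bias; use `importKsTable` for
  published-grade Ks when an external CODEML run is available.
* The KDE mode on the raw scale carries smoothing bias for very skewed
  distributions (see §3); log-scale density estimation is a reasonable
  sensitivity check.
* The k-mer estimator deliberately implements only the peak-quotient
  formula; heterozygous genomes need manual peak selection via `peak`.
* Percentage reporting uses round-half-up to two decimals; note that
  printed summaries elsewhere are not always consistent with any single
  rounding rule at the last digit.
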