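# mycohet

Comparative-genomic signatures of mycoheterotrophy — gene-family loss,
synonymous-rate acceleration, LTR insertion dating, enrichment, and
genome-size profiling — as a tested, reusable R package.

## The problem

Mycoheterotrophic plants (plants that draw carbon from fungi rather than
photosynthesis, as many orchids do partially or fully) show two recurrent
genomic signatures relative to their autotrophic relatives: **massive
gene-family loss** (photosynthesis, photoreceptor and transporter genes) and
**elevated synonymous substitution rates**. Quantifying either requires a
chain of small, bespoke computations that are usually re-implemented ad hoc
per study. `mycohet` packages that chain for R users working on plant
comparative genomics:

* **F-index loss classification.** For species *i* and gene family *j* with
  count *c\_ij*, family total *N\_j* and *S* species represented,

      F = (log2(a · c_ij / N_j + 1/2) + 1) / (log2(a + 1/2) + 1),
      a = (S² − 2S) / 2

  so that F = 0 iff the family is missing, F = 1 iff the species holds the
  entire family, and F = 1/2 exactly when *c\_ij/N\_j = 1/S* (an exactly
  average share). Families are classified into five categories (Missing /
  Less than average / Around average (less) / Around average (greater) /
  Greater than average) with boundaries at 0, 0.45, 0.5 and 0.55, after a
  conservation filter (present in ≥ *m* of the panel species and in a
  designated early-diverging outgroup).
* **Ortholog Ks.** Reciprocal-best-hit orthologs from 12-column BLAST
  tables (bit score, then e-value, then subject id), global protein
  alignment (BLOSUM62, affine gaps), codon back-translation with gap-column
  removal, and NG86 counting with Jukes–Cantor correction:
  Ks = −(3/4)·ln(1 − 4·pS/3).
* **Rate comparison.** Gaussian-KDE modes of ortholog Ks distributions
  (Silverman bandwidth, 512-point grid), 200-fold bootstrap percentile
  intervals and box statistics, and the outgroup relative-rate
  decomposition d\_A = (d\_AB + d\_OA − d\_OB)/2 (and companions), which
  splits pairwise distances into branch-specific Ks since the A/B split.
* **LTR dating.** Jukes–Cantor divergence K of a retrotransposon's 5′/3′
  LTR pair, rate calibration r = d/(2t), insertion time T = K/(2r), and era
  summaries (fraction of insertions younger than a threshold).
* **Enrichment.** One-sided hypergeometric over-representation with
  Bonferroni correction.
* **Genome size.** Canonical k-mer histograms from reads and the
  Lander–Waterman estimate size = total k-mers / peak depth.
* **Synthetic data.** Generators for every input above with known ground
  truth (loss probabilities, branch-specific dS on a fixed 4-taxon tree,
  LTR ages, genome size/coverage, enriched annotation terms), so the whole
  pipeline is testable without external data.

## Worked example

Simulate a 6-species orthogroup matrix in which two "mycoheterotroph"
species lose families independently (8–12%) and jointly (3%), filter to
conserved families, and summarise losses:

```r
library(mycohet)
sc <- lossScenario(2000, c("auto1","auto2","auto3","mycoA","mycoB","Atr"),
                   retentionProb = c(auto1=0.98, auto2=0.98, auto3=0.97,
                                     mycoA=0.90, mycoB=0.88, Atr=0.99),
                   sharedPair = c("mycoA","mycoB"), sharedLossProb = 0.03,
                   seed = 1)
x  <- filterConserved(simulateCountMatrix(sc), minSpecies = 4, outgroup = "Atr")
ms <- missingSummary(x)
ms$perSpeciesMissing
#> auto1 auto2 auto3 mycoA mycoB   Atr
#>    37    39    54   245   290     0
ms$sharedMissing["mycoA","mycoB"]
#> [1] 85
summarizePercent(85, 245)
#> [1] 34.69
fIndex(2, 32, 16)
#> [1] 0.5
```

The two mycoheterotroph-like species are missing 245 and 290 of the 1,979
conserved families (the autotrophs 37–54), 85 families are missing in both
(34.69% of mycoA's losses), and an exactly average family share scores
F = 0.5. `ms$categoryPercent` holds the five-category percentages per
species (rows sum to 100), e.g. 12.38% Missing for mycoA versus 1.87% for
auto1 under this scenario.

Rate analysis on a synthetic quartet (outgroup, (reference, (spA, spB)))
with spB evolving twice as fast as spA (branch dS 0.2 vs 0.1):

```r
qs  <- quartetScenario(c(outgroup=0.15, reference=0.1, internal=0.05,
                         spA=0.1, spB=0.2),
                       nGenes = 120, codonsPerGene = 200, seed = 2)
sim <- simulateCodonQuartet(qs)
ksOf <- function(t1, t2) vapply(names(sim$sequences[[t1]]), function(g)
  ng86Ks(CodonAlignment(sim$sequences[[t1]][[g]],
                        sim$sequences[[t2]][[g]]))$Ks, numeric(1))
dec <- relativeRateBootstrap(
  KsDistribution(ksOf("reference","spA"), c("ref","spA")),
  KsDistribution(ksOf("reference","spB"), c("ref","spB")),
  KsDistribution(ksOf("spA","spB"),       c("spA","spB")),
  nBoot = 200, seed = 7, taxa = c("reference","spA","spB"))
dec
#> RateDecomposition: outgroup reference ; ingroup spA / spB
#>   dA = 0.07336  dB = 0.2101  dShared = 0.171
#>   dA 95% CI [0.05383, 0.1173]
#>   dB 95% CI [0.1661, 0.2296]
#>   dShared 95% CI [0.1269, 0.1857]
```

The decomposition recovers the rate asymmetry (dB ≈ 0.21 vs its true 0.2;
dA's true value 0.1 sits inside its interval; at 120 genes the point
estimates are still noisy — the package's acceptance suite uses 300 genes,
where the dB/dA ratio lands within ±20% of 2). `runPipeline()` drives the
same computations from files and writes TSV outputs plus a `manifest.json`
recording every parameter and seed.

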