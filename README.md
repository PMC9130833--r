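# adipospec

Tissue-specificity screening and adipose expression genetics for
multi-tissue transcriptomes.

## What this is for

Adipose depots (visceral, subcutaneous, intramuscular) drive feed
efficiency and meat quality in cattle, yet which genes are expressed
*specifically* in fat — and which sequence variants in those genes matter —
is hard to pin down from any single experiment. `adipospec` implements the
full analysis chain such a screen needs, as a tested R package:

* **Tissue-specific gene calling** from a genes × samples FPKM matrix over
  a 14-tissue panel, using the tau specificity index

  τ = Σᵢ (1 − xᵢ / maxⱼ xⱼ) / (N − 1)

  on replicate-averaged tissue means, followed by a three-rule caller:
  drop genes under 1 FPKM in every tissue, take the top 20% of genes by τ
  as candidates, and call a candidate specific to a tissue where its mean
  FPKM exceeds 1 and ranks in the profile's top three.
* **Adipose vs non-adipose differential expression** on read counts:
  median-of-ratios size factors, a gene-wise method-of-moments
  negative-binomial dispersion, a Wald test on the log-mean difference and
  Benjamini–Hochberg correction.
* **Tissue profiling**: Pearson correlations of log2(FPKM+1) profiles with
  exact t-transform p-values, a PCA + median/MAD replicate outlier screen,
  and average-linkage clustering on the 1 − r distance.
* **qPCR quantification** by the 2^−ΔΔCt method with replicate averaging
  on the Ct scale.
* **Indel population genetics**: genotype-count reconstruction from printed
  frequency tables, allele frequencies, homozygosity / expected
  heterozygosity / effective allele number / polymorphism information
  content, Hardy–Weinberg χ² tests, and genotype–trait association with
  Levene-gated pooled/Welch t-tests (groups under n = 3 excluded).
* **Seeded synthetic-data generators** that emulate the whole study design
  (tissue panel, replicate ranges, planted specific genes including a
  23-gene shared adipose program, biotype mix, NB counts with planted fold
  changes, indel genotypes with genotype-dependent traits), so every stage
  is verifiable against planted truth.

The package is Bioconductor-shaped: the expression containers extend
`SummarizedExperiment`, readers/writers cover TSV matrices, GFF3
annotation, and long-format genotype/trait/Ct tables, and `runPipeline()`
(or the `inst/cli/adipospec.R` script) orchestrates
simulate → tsg → de → profiles → qpcr → popgen with a checksummed manifest.

## Worked example

Simulate a study-scale dataset, call tissue-specific genes, and score the
caller against the planted truth:

```r
library(adipospec)

cfg <- simConfig(nGenes = 2000L, seed = 7)
sim <- simulateExpression(cfg)
tp  <- filterLowExpression(tissueMeans(sim$expr))          # FPKM >= 1 somewhere
calls <- callTissueSpecific(tp, candidatesByTau(tp, 0.20),  # top 20% by tau
                            fpkmMin = 1, rankK = 3)
tsgRecovery(calls, sim$truth)
#> $precision
#> [1] 0.9883041
#> $recall
#> [1] 1
#> $nPlantedPairs
#> [1] 169
#> $nCallsPlanted
#> [1] 171
#> $nCallsOther
#> [1] 517
```

All 169 planted (gene → home tissue) assignments are recovered, and 98.8%
of the tissue calls made for planted genes are true homes. The per-tissue
adipose sets and their overlap:

```r
sets <- tsgSets(calls)
lengths(sets[adiposeTissues()])
#>      visceral_adipose  subcutaneous_adipose intramuscular_adipose
#>                    59                    75                    59
sr <- intersectSets(sets[adiposeTissues()])
intersectionCount(sr)   # genes specific to all three adipose tissues
#> [1] 24
```

The triple overlap contains the entire 23-gene planted shared adipose
program plus one background gene that genuinely satisfies the calling rules.

Population genetics from a printed genotype table (frequencies 0.407 /
0.492 / 0.102 at n = 59):

```r
gt <- countsFromFrequencies(c(0.407, 0.492, 0.102), 59, "Luxi")
round(diversityStats(gt)[, c("pD", "pI", "hom", "het", "ne", "pic", "hweP")], 3)
#>      pD    pI   hom   het   ne   pic  hweP
#> 1 0.653 0.347 0.547 0.453 1.83 0.351 0.519
```

`hom` is the sum of squared allele frequencies, `ne` the effective allele
number and `pic` the biallelic Botstein information content. And a
two-sample association test reconstructed from printed summary statistics
(mean ± SE, n):

```r
tt <- ttestFromSummary(11.66, 0.94, 25, 14.6, 0.57, 4, "welch")
sprintf("t = %.3f, df = %.1f, p = %.4f", tt$t, tt$df, tt$p)
#> [1] "t = -2.674, df = 21.6, p = 0.0140"
```

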