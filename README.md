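# pedDNM

Pedigree-based de novo mutation discovery and rate estimation.

Multigenerational families are the cleanest setting for measuring how many
new mutations each generation adds to a human genome: with four genotyped
generations, every child allele can be traced to one of the four founder
haplotypes (A, B on the paternal side, C, D on the maternal side), so
genotyping errors, meiotic crossovers and genuine de novo events each leave
a distinct signature. pedDNM packages that machinery for statistical
geneticists and methods developers:

- **Inheritance vectors** — per-meiosis two-state hidden Markov model,
  decoded with the Viterbi algorithm; transitions are crossovers, and a
  founder-haplotype concordance test splits variants into
  pedigree-consistent (phased), violating, and untestable sites.
- **Recombination maps** — haplotype-match vectors segmented by recursive
  binary segmentation (mean ≤ 0.25 → H1, ≥ 0.75 → H2, < 500 kb dropped),
  merging of maps from independent callers with `best.range`/`min.range`,
  breakpoint refinement against aligned parental sequences,
  gene-conversion-like switch detection, telomeric-enrichment permutation
  tests, and a Poisson GLM of crossover counts on parental age and sex.
- **Small de novo variants** — trio candidates validated across sequencing
  platforms by base-quality-stratified read counts, phased to a parental
  haplotype by read-level voting over informative SNVs, classified germline
  versus postzygotic (haplotype-fraction rule, or χ²-homogeneity plus
  one-sided exact binomial balance test when unphased), and traced through
  transmissions.
- **Tandem repeats** — Manhattan-distance Mendelian concordance over all
  eight allele assignments, de novo allele scoring and filtering
  (trio depth ≥ 10, denovo coverage ≥ 2, child ratio ≥ 0.2, parental
  support < 5%, uniqueness, expansion/contraction), minimum-diff event
  sizing, phase-block parent-of-origin, net-CIGAR short-read validation
  (±1 bp), and recurrence labelling.
- **Rates** — callable-site masks, exact Poisson confidence intervals via
  χ² quantiles (`lo = χ²(α/2, 2k)/2`, `hi = χ²(1−α/2, 2k+2)/2`), rates per
  bp per generation (diploid or haploid exposure), feature-stratified
  enrichment with paired t-tests, paternal:maternal bias with a Wilcoxon
  signed-rank test, and linear parental-age effects.
- **Synthetic pedigree generator** — a 28-member, four-generation family
  with configurable crossover, germline, postzygotic and tandem-repeat
  mutation processes and per-platform read evidence, with complete ground
  truth, so the whole pipeline is testable without any sequencing data.

## Worked example

```r
library(pedDNM)

cfg <- simConfig(seed = 1L, nChromosomes = 2L, chromLengthBp = 1e7,
                 germlineSnvRate = 5e-8, trCatalogSize = 500L,
                 trMutationRate = 1e-3)
sim <- simulatePedigree(cfg)
sim
#> Synthetic pedigree simulation (seed 1)
#> Pedigree with 28 members across 4 generations
#>   G1: 4, G2: 2, G3: 10, G4: 12
#>   2077 marker sites; 114 crossovers; 38 germline DNMs; 2 PZMs; 25 TR DNMs

iv <- inheritanceVectors(sim, children = "C3_01")
head(iv$vectors, 4)
#>   child homologue chrom   start     end label
#> 1 C3_01  paternal  chr1   32294 9983545     A
#> 2 C3_01  paternal  chr2    9510 9994231     A
#> 3 C3_01  maternal  chr1   22533 6040872     C
#> 4 C3_01  maternal  chr1 6040872 9967146     D
nrow(iv$breakpoints)   # 4 recovered = 4 true crossovers for this child
```

The maternal homologue of child `C3_01` switches from grandmaternal
haplotype C to D near 6.04 Mb on chr1 — a decoded crossover. Calling and
validating de novo variants in four G3 children, then estimating the rate:

```r
calls <- do.call(rbind, lapply(paste0("C3_0", 1:4), function(ch)
  callDnmsForChild(sim, ch, seed = 2L)))
snvRate(sum(calls$pass & calls$class == "germline"), 4 * 2e7)
#>     stratum count exposure rate         ciLo         ciHi
#> 1 autosomal     8  1.6e+08 5e-08 2.158645e-08 9.851993e-08
```

Eight validated germline mutations over 4 children × 2 × 20 Mb callable
give 5e-08 per bp per generation — the configured rate — with its exact
95% Poisson interval. The classic tandem-repeat concordance check:

```r
manhattanConcordance(c(100, 50), c(100, 100), c(50, 150))
#> $minDistance
#> [1] 0
#> $concordant
#> [1] TRUE
```

A full pipeline run (`simulate → inherit → recomb → dnm → tr → rates`) is
one call — `runPipeline(list(seed = 8), "outdir")` — or, from a shell,
`inst/scripts/pedDNM all --seed 8 --out outdir`.

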