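---
title: "Models and methods behind pedDNM"
author: "pedDNM authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pedDNM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pedDNM)
```

# Scope

pedDNM implements the computational core of a multigenerational de novo
mutation (DNM) study: given a four-generation pedigree with two founder
couples, a G2 couple, a G3 sibship with two marrying-in spouses and two G4
sibships, it infers which founder haplotype each child segment derives from,
filters variants to a pedigree-consistent set, maps meiotic crossovers,
calls and classifies small de novo variants, analyses tandem-repeat (TR)
expansions and contractions, and turns counts into per-generation mutation
rates. Because the sequencing data of such a family cannot ship with a
package, a synthetic-data generator reproduces the *structure* of the
problem with complete ground truth, and every stage is tested against it.

# The synthetic pedigree generator

`simulatePedigree()` draws founder haplotypes as abstract biallelic markers
(allele identity is all the downstream logic needs; nucleotide sequence is
emitted only where the breakpoint-refinement path wants columns). Each
meiosis receives a Poisson number of crossovers with sex-specific means
(defaults 1.4 maternal, 1.0 paternal per chromosome), placed uniformly
except that a configurable fraction of paternal crossovers (default 0.5) is
forced into the terminal 5% windows, emulating the male telomeric bias.
The bias is modelled this way because the phenomenon is reported as a
count enrichment in terminal windows without a published generative model.

Germline DNMs arise per meiosis at 1.17e-8 per bp (so 2 x rate x genome
per child), paternal with probability 0.814; postzygotic mutations (PZMs)
at 2.04e-9 per bp with a variant allele fraction (VAF) drawn from a
two-component Beta mixture scaled to (0, 0.5]: a dominant low-balance bulk
(mean below 0.25) plus a small high-balance tail. The mixture is a
declared stand-in — summary statistics of mosaic balance are published but
a full distribution is not — and its parameters are exposed in
`simConfig()`. Indel DNMs share the SNV machinery under a class tag,
mirroring how their validation mirrors SNV validation.

Read evidence is drawn per platform (two long-read, two short-read
profiles) as Poisson depth, binomial allele counts at balance 0.5 for
heterozygotes and at the VAF for mosaics, with base-calling errors
concentrated in the low-quality base class (90% by default). That
concentration is the empirical rationale for stratifying evidence into
high and low base-quality counts in the first place; it also means a
perfectly clean simulation is obtained by zeroing the error rates rather
than by a special code path. Haplotype tags on long reads are error-free
conditional on the read: tagging mistakes are dominated by the
informative-site error model exercised in the phasing stage.

TR loci carry one or two motifs (1-2000 bp); 30% of loci are polymorphic
among founders, the rest sit at the reference length, roughly the
proportion seen when a large catalog is genotyped in a single family.
Mutations are stepwise (default steps of 1-3 motif units, symmetric) at
4.74e-6 per locus per haplotype per generation. A mutant allele that would
coincide with a parental allele length is redrawn: such an event is
undetectable by construction under the de novo filters (it is not an
expansion or contraction relative to the parental alleles), so the
generator produces only assayable events and rate recovery is interpretable.
Short TR reads span a locus only if the allele plus flanks fits in the read
and mis-report the length by one motif unit at the stutter rate; long reads
report the true length. Emitted CIGAR strings place the net indel inside
the locus so read-level re-sizing can be round-tripped.

What the generator does *not* model: sequence-level errors (no FASTQ),
instrument-specific error spectra, reference bias, segmental-duplication
mismapping, or cell-line artefacts. Tests passing on this generator
demonstrate the correctness of the *logic* — thresholds, bookkeeping,
estimators — not robustness to those real-data pathologies.

# Inheritance vectors

Each meiosis is a two-state hidden Markov chain over the transmitting
parent's homologues. Between adjacent informative sites at distance $d$
the switch probability is $1 - e^{-dr}$ with $r$ = 1.2e-8 per bp (the
order of the human recombination rate); observations contradict the state
with probability 0.002. Exact published values for these matrices are not
available, so they are declared defaults, not inferred quantities; the
decoding is insensitive to them over a wide range because informative
sites are dense relative to crossovers. Viterbi backtrace ties break
toward the previous state, which favours paths with fewer crossovers
(parsimony). Segment boundaries are placed midway between flanking
informative sites, matching interval-style breakpoint reporting. The
greedy `sketchInheritance()` (blocks of at least 10 agreeing sites) is
retained as the quick first-pass view.

The chain is decomposed per meiosis rather than decoding a joint
inheritance vector across the sibship; with meiosis-specific observations
the decomposition is exact, and it makes the decoder testable against an
exhaustive path enumeration at small $n$.

`concordanceSite()` asks whether any assignment of alleles to the four
founder haplotypes A, B (paternal side) and C, D (maternal side)
reproduces the parents' and every child's genotype given the segment
labels; for biallelic sites that is 16 assignments. Passing sites are
phased by the witness assignment; failing sites report the children that
the best assignment cannot explain — a single-child violation is exactly
how a de novo candidate surfaces. Sites over a segment boundary are
"untestable" rather than pass/fail.

# Crossover mapping

A child homologue is encoded 0/1 by which parental haplotype it matches at
sites where the parent is heterozygous. Segmentation is recursive binary
segmentation maximizing a two-sample z statistic with a significance stop
(z >= 3) and a minimum segment size (20 sites for sparse input; dense
callsets conventionally use 400-500). Bit-compatibility with any
particular changepoint library is not a goal — recovery of the injected
breakpoints is, and the tests enforce it. Segments with mean code at most
0.25 are labelled H1, at least 0.75 H2; anything between is ambiguous and
dropped, as are segments shorter than 500 kb (how the published 0.8/0.2
segment-median gates interact with these mean thresholds is not fully
specified anywhere we could verify, so only the 0.25/0.75 rule is
applied). Adjacent same-label segments merge; each H1/H2 adjacency is a
crossover interval; a single-label chromosome is non-recombinant.

Maps from independent callers merge under a 1 Mb support window per child
and homologue; `best.range` is the narrowest directly overlapping call and
`min.range` the sub-interval of maximal coverage (computed with IRanges).
Refinement against aligned parental sequences minimizes, over all split
points of the discriminating columns, the child's mismatches to a
prefix/suffix concatenation of the parents — checked against a brute-force
split search — and skips children more than 99% identical to a single
parent. Gene-conversion-like switches are runs of at least two opposing-
haplotype variants, merged within 5 kb, suppressed within 100 kb of a
crossover or inside exclusion masks. Telomeric clustering is tested by
circular per-chromosome permutation (1,000 shuffles preserving
per-chromosome counts), with empirical p = (1 + #null >= obs)/(n + 1).
Crossover counts regress on parental age and sex in a log-link Poisson
GLM via `stats::glm`.

# Small de novo variants

Candidates are child-only alternate alleles with homozygous-reference
parents. Clusters of three or more candidate SNVs within 1 kb are removed.
Validation requires alternate support in at least two platforms in the
child, zero high-quality parental alternate bases, at most two low-quality
parental alternate bases, mapping-quality-failing reads excluded
throughout, and (for SNVs) high-quality absence from every non-descendant
pedigree member, screened in the most accurate long-read platform.

Phasing assigns each long read to a parent by majority vote over the
informative flanking SNVs it covers (ties leave the read unassigned); a
variant is phased when all alternate-carrying assigned reads agree, and
excluded when they conflict. A phased variant is germline only if every
read of the mutant parental haplotype carries the alternate; otherwise it
is postzygotic with the haplotype fraction recorded; fewer than five
assigned reads is indeterminate and excluded from rates. Unphased
variants are postzygotic when their balance is homogeneous across
platforms — a chi-squared test at alpha = 0.05, replaced by Fisher's exact
test when expected counts drop below five — and the pooled balance is
below 0.5 by a one-sided exact binomial test, also at 0.05. The binomial
operationalization is a design choice: "significantly less than 0.5" does
not by itself name a test, and the one-sided exact binomial is the natural
reading for a balance bounded above by one half.

Transmission tracing marks a call transmitted when an offspring inherited
the mutant haplotype segment and carries the allele; a segment-inheriting
offspring *without* the allele contradicts a germline classification and
is surfaced as a haplotype-based validation failure — the signature of an
undetected mosaic.

# Tandem repeats

Mendelian concordance is the minimum Manhattan distance over the eight
assignments of the child's two allele lengths (ALs) to one paternal and
one maternal allele; zero is concordant. Loci with missing genotypes
leave the concordance denominator but complete trios remain eligible for
de novo calling. De novo scoring partitions child spanning reads to
alleles by nearest AL (ties split evenly — a deliberate desk-scale
surrogate for alignment-score realignment, whose internals are not
reproducible from published material; the acceptance surface here is
filter behaviour, not score values). Filters: trio spanning depth >= 10;
allele uniqueness (de novo AL matching one parent while the other child
allele matches the other parent is rejected); a genuine expansion or
contraction; denovo coverage >= 2 with child ratio >= 0.2; parental
support < 5%. Event size is the minimum |de novo AL - parental AL| within
the phased parent (or over all four unphased), signed by direction; the
minimum-diff convention means the reported size is a lower bound on the
true event size whenever the mutated allele was not the parent's nearest.

Parent of origin uses phased flanking SNVs within 500 kb sharing the de
novo allele's phase block, subject to depth >= 10, GQ >= 20, child
heterozygous, parents not identical-by-state; the N = 3 closest mutually
consistent sites vote (the default of 3 balances robustness against
phase-block truncation against the risk of leaving the phase block). Orthogonal short-read
validation compares read-level net-CIGAR lengths to the de novo relative
AL with a symmetric +/-1 bp tolerance: validated iff at least one child
read and zero parental reads support it. Recurrence requires two or more
carriers with all pedigree members genotyped at depth >= 10, labelled
intragenerational when all events share a generation.

# Rates

A site is callable when both parents are homozygous reference and each
trio member has at least one mapping-quality-passing, high-base-quality
read; male sex chromosomes compare only the relevant parent and drop the
genotype requirement. Autosomal rates divide counts by twice the callable
base pairs; female X exposure is twice callable X, male exposure is
callable X plus callable Y; TR rates divide de novo allele counts by
callable loci and then by two for a per-haplotype rate. All intervals are
exact Poisson: lower bound qchisq(alpha/2, 2k)/2 (zero at k = 0), upper
qchisq(1-alpha/2, 2k+2)/2, over the exposure. Feature strata use pooled
counts for the headline rate but per-sample rates for the paired
two-sided t-test against the autosomal rate (degenerate all-zero
differences return p = 1). Parental bias uses a paired Wilcoxon
signed-rank test; age effects use ordinary least squares on counts.

# Problem sizes and determinism

The shipped tests and the acceptance script run entirely on generated
data: pedigrees of 2-14 chromosomes of 2-50 Mb, marker densities of one
site per 2-10 kb, a 100,000-locus TR catalog, 5,000 phased mutations for
the parental-fraction study and 400 children for the age-effect study —
sizes chosen so each study carries enough events for its interval to be
informative while the whole suite stays comfortably interactive. Every
stochastic stage takes an explicit seed; a configuration with the same
seed reproduces its outputs byte for byte, and sub-stages draw from child
streams of the root seed so they are reproducible in isolation.

# Known limitations

The generator's idealizations listed above mean recovery results here do
not certify performance on real alignments. The segmentation stop rule is
a z-threshold, not a permutation p-value, which can over-segment extremely
long noisy vectors (the 500 kb and ambiguity filters absorb this in
practice). The concordance search enumerates founder-allele assignments
and is exponential in allele count — fine for biallelic and triallelic
sites, not meant for dense multiallelics. Manual review steps ("noisy"
call removal, visual inspection of recurrent loci) are represented by
quantitative rules plus a review flag, not replaced.
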