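Package: pedDNM
Title: Pedigree-Based De Novo Mutation Discovery and Rate Estimation
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Computational machinery for multigenerational pedigree studies of
    de novo mutation: inheritance-vector inference by hidden Markov model and
    Viterbi decoding against founder haplotypes, pedigree-concordance filtering
    of variant calls, meiotic crossover mapping by binary segmentation of
    haplotype-match vectors, small-variant de novo calling with multiplatform
    read validation, parent-of-origin phasing and postzygotic classification,
    tandem-repeat de novo expansion/contraction analysis, and mutation-rate
    estimation with exact Poisson confidence intervals. A synthetic
    four-generation pedigree generator with complete ground truth (haplotypes,
    crossovers, germline and postzygotic mutations, tandem-repeat mutations,
    per-platform read evidence) makes every stage testable without access to
    sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
biocViews: Genetics, VariantDetection, Sequencing, Software
RoxygenNote: 7.3.3
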