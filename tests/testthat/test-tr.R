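# Tandem repeats: Manhattan concordance, de novo scoring and filtering,
# event sizing, parent-of-origin, CIGAR-based sizing, orthogonal validation,
# recurrence and locus classification.

test_that("Manhattan concordance equals the eight-combination brute force", {
  # worked trio: an inherited pair is concordant at distance zero
  r <- manhattanConcordance(c(100, 50), c(100, 100), c(50, 150))
  expect_equal(r$minDistance, 0)
  expect_true(r$concordant)
  # de novo child allele: minimum distance 50, discordant
  r2 <- manhattanConcordance(c(200, 100), c(100, 100), c(50, 150))
  expect_equal(r2$minDistance, 50)
  expect_false(r2$concordant)
  # brute-force oracle on random trios
  brute <- function(c2, f2, m2) {
    best <- Inf
    for (perm in list(1:2, 2:1)) for (i in 1:2) for (j in 1:2)
      best <- min(best, abs(c2[perm[1]] - f2[i]) + abs(c2[perm[2]] - m2[j]))
    best
  }
  set.seed(77)
  for (rep in 1:800) {
    c2 <- sample.int(300, 2, replace = TRUE)
    f2 <- sample.int(300, 2, replace = TRUE)
    m2 <- sample.int(300, 2, replace = TRUE)
    expect_equal(manhattanConcordance(c2, f2, m2)$minDistance,
                 brute(c2, f2, m2))
  }
  # missing genotypes mark the locus missing
  expect_true(manhattanConcordance(c(NA, 50), c(1, 2), c(3, 4))$missing)
})

test_that("de novo scores count child-unique read support", {
  # child allele present in the father's reads: zero de novo coverage
  sc <- denovoScore(c(100, 120), childReads = rep(c(100, 120), each = 10),
                    parentReads = c(rep(100, 10), rep(120, 10)))
  expect_equal(sc$denovoCoverage, c(0L, 0L))
  # injected expansion with clean reads: de novo coverage equals the reads
  # on that haplotype
  sc2 <- denovoScore(c(100, 126), childReads = rep(c(100, 126), c(12, 9)),
                     parentReads = rep(c(100, 104), each = 15))
  k <- which(sc2$allele == 126)
  expect_equal(sc2$denovoCoverage[k], 9L)
  expect_equal(sc2$childRatio[k], 9 / 21)
  expect_equal(sc2$parentalFraction[k], 0)
  # no spanning reads: undefined
  expect_null(denovoScore(c(1, 2), numeric(), numeric()))
})

test_that("the de novo filter enforces each rule at its boundary", {
  base <- list(denovoAl = 126, otherAl = 100, fatherAl = c(100, 104),
               motherAl = c(96, 100), depthChild = 20L, depthFather = 20L,
               depthMother = 20L, denovoCoverage = 9L, childRatio = 9 / 21,
               parentalFraction = 0)
  expect_true(do.call(filterDeNovo, base)$pass)
  # mother at depth 9 fails the trio-depth rule
  d9 <- base; d9$depthMother <- 9L
  expect_true("depth_lt_10" %in% do.call(filterDeNovo, d9)$reasons)
  # uniqueness: de novo allele from the father, other allele from the mother
  uq <- base; uq$denovoAl <- 104; uq$otherAl <- 96
  expect_true("not_unique" %in% do.call(filterDeNovo, uq)$reasons)
  # a de novo allele equal to a parental allele is not an expansion or
  # contraction
  eq <- base; eq$denovoAl <- 100
  expect_true("no_expansion_or_contraction" %in%
                do.call(filterDeNovo, eq)$reasons)
  # coverage and ratio boundaries
  cv <- base; cv$denovoCoverage <- 1L
  expect_true("denovo_coverage_lt_2" %in% do.call(filterDeNovo, cv)$reasons)
  cr <- base; cr$childRatio <- 0.19
  expect_true("child_ratio_lt_0.2" %in% do.call(filterDeNovo, cr)$reasons)
  pf <- base; pf$parentalFraction <- 0.05
  expect_true("parental_support_ge_5pct" %in%
                do.call(filterDeNovo, pf)$reasons)
  pf2 <- base; pf2$parentalFraction <- 0.049
  expect_true(do.call(filterDeNovo, pf2)$pass)
  # minimal passing candidate
  mini <- base; mini$denovoCoverage <- 2L; mini$childRatio <- 0.25
  expect_true(do.call(filterDeNovo, mini)$pass)
})

test_that("event sizing reproduces the worked diff example and its "
          %&&% "symmetries", {
  # father 100,100; mother 50,150; de novo allele 200
  sz <- deNovoSize(200, c(100, 100), c(50, 150))
  expect_equal(sz$diffsFather, c(100, 100))
  expect_equal(sz$diffsMother, c(150, 50))
  # phased maternal: minimum maternal diff 50, an expansion
  expect_equal(deNovoSize(200, c(100, 100), c(50, 150),
                          phase = "maternal")$size, 50)
  # unphased: the smallest diff over all four alleles
  expect_equal(sz$size, 50)
  # contraction carries a negative sign
  expect_equal(deNovoSize(40, c(100, 100), c(50, 150),
                          phase = "maternal")$size, -10)
  # unphased sizing is symmetric under parental relabelling, with magnitude
  # bounded by the largest parental diff
  set.seed(8)
  for (rep in 1:200) {
    f <- sample.int(200, 2, TRUE); m <- sample.int(200, 2, TRUE)
    dn <- sample.int(250, 1)
    a <- deNovoSize(dn, f, m); b <- deNovoSize(dn, m, f)
    expect_equal(a$size, b$size)
    expect_lte(abs(a$size), max(abs(dn - c(f, m))))
  }
})

test_that("parent-of-origin phasing follows phase blocks and informative "
          %&&% "sites", {
  snvs <- data.frame(pos = c(-2000, 1500, 3000),
                     fatherGt = c("0/1", "0/1", "0/1"),
                     motherGt = c("0/0", "0/0", "0/0"),
                     childGt = "0/1",
                     childPhasedGt = c("1|0", "1|0", "1|0"),
                     phaseSet = c(1L, 1L, 1L), depth = 30L, gq = 50L)
  # child haplotype 1 carries the paternal allele; de novo on haplotype 1
  r <- phaseTrPoo(snvs, dnmPos = 0, dnmHaplotype = 1L, dnmPhaseSet = 1L)
  expect_equal(r$origin, "paternal")
  expect_equal(r$nUsed, 3L)
  expect_equal(r$contradictions, 0L)
  # de novo on haplotype 2: maternal
  expect_equal(phaseTrPoo(snvs, 0, 2L, 1L)$origin, "maternal")
  # sites in a different phase block: unknown
  expect_equal(phaseTrPoo(snvs, 0, 1L, 2L)$origin, "unknown")
  # low genotype quality disqualifies sites
  lowq <- transform(snvs, gq = 10L)
  expect_equal(phaseTrPoo(lowq, 0, 1L, 1L)$origin, "unknown")
  # parents identical by state are uninformative
  ibs <- transform(snvs, motherGt = "0/1")
  expect_equal(phaseTrPoo(ibs, 0, 1L, 1L)$origin, "unknown")
  # contradictory votes return unknown rather than a guess
  mixed <- snvs
  mixed$childPhasedGt <- c("1|0", "0|1", "1|0")
  expect_equal(phaseTrPoo(mixed, 0, 1L, 1L)$origin, "unknown")
  expect_gt(phaseTrPoo(mixed, 0, 1L, 1L)$contradictions, 0L)
})

test_that("simulated known-origin events phase correctly through flanking "
          %&&% "sites", {
  set.seed(19)
  correct <- 0L; known <- 0L
  for (i in 1:100) {
    truthPat <- i %% 2 == 0
    npos <- 12L
    pos <- sort(runif(npos, -4e5, 4e5))
    fhet <- runif(npos) < 0.5
    snvs <- data.frame(
      pos = pos,
      fatherGt = ifelse(fhet, "0/1", "0/0"),
      motherGt = ifelse(fhet, "0/0", "0/1"),
      childGt = "0/1",
      childPhasedGt = NA_character_,
      phaseSet = 1L, depth = 30L, gq = 60L)
    # haplotype 1 paternal: phased genotype consistent with the rule table
    patAl <- ifelse(fhet, 1L, 0L)
    snvs$childPhasedGt <- paste0(patAl, "|", 1L - patAl)
    hapOfDnm <- if (truthPat) 1L else 2L
    r <- phaseTrPoo(snvs, 0, hapOfDnm, 1L)
    if (r$origin != "unknown") {
      known <- known + 1L
      if ((r$origin == "paternal") == truthPat) correct <- correct + 1L
      expect_equal(r$contradictions, 0L)
    }
  }
  expect_gte(known, 95L)
  expect_gte(correct / known, 0.98)
})

test_that("net CIGAR length reproduces the hand-expanded example", {
  # read spanning a locus with a 2 bp deletion and 6 bp insertion: net +4
  expect_equal(netCigarAlleleLength("100M2D10M6I32M", 90, 140, 0), 4L)
  # pure matches contribute nothing
  expect_equal(netCigarAlleleLength("150M", 50, 100, 0), 0L)
  # indels outside the locus are ignored
  expect_equal(netCigarAlleleLength("10M5I90M", 50, 100, 0), 0L)
  expect_equal(netCigarAlleleLength("10M5D135M", 50, 100, 0), 0L)
  expect_error(netCigarAlleleLength("12Q", 0, 10, 0), "malformed")
})

test_that("orthogonal validation requires child support and parental "
          %&&% "absence", {
  expect_equal(orthogonalValidate(26, childRelAls = c(26, 25, 26),
                                  parentRelAls = c(0, 2)), "validated")
  # one parental read within one bp refutes
  expect_equal(orthogonalValidate(26, childRelAls = 26,
                                  parentRelAls = 25), "refuted")
  # no spanning child reads: unassessable
  expect_equal(orthogonalValidate(26, numeric(), c(0)), "unassessable")
  # child support within the one-bp tolerance counts
  expect_equal(orthogonalValidate(26, childRelAls = 27,
                                  parentRelAls = 0), "validated")
})

test_that("recurrence labelling distinguishes generations and requires "
          %&&% "complete genotyping", {
  gens <- c(A3 = 3L, B3 = 3L, C4 = 4L)
  allS <- c("A3", "B3", "C4")
  geno <- expand.grid(locus = c("L1", "L2", "L3"), sample = allS,
                      stringsAsFactors = FALSE)
  geno$depth <- 30L
  calls <- data.frame(child = c("A3", "B3", "A3", "C4", "A3", "B3"),
                      locus = c("L1", "L1", "L2", "L2", "L3", "L3"))
  r <- findRecurrent(calls, gens, geno, allS)
  expect_equal(r$label[r$locus == "L1"], "intragenerational")
  expect_equal(r$label[r$locus == "L2"], "intergenerational")
  # dropping one member's genotype removes the locus
  geno2 <- geno[!(geno$locus == "L3" & geno$sample == "C4"), ]
  r2 <- findRecurrent(calls, gens, geno2, allS)
  expect_false("L3" %in% r2$locus)
  # low depth removes the locus too
  geno3 <- geno; geno3$depth[geno3$locus == "L1"][1] <- 9L
  expect_false("L1" %in% findRecurrent(calls, gens, geno3, allS)$locus)
})

test_that("locus classification follows the motif-size rules", {
  expect_equal(classifyLocus("A"), list(class = "STR", minMotif = 1L))
  expect_equal(classifyLocus(c("AT", "AGA", "T"))$class, "STR")
  # a 21 bp motif beside a 5 bp motif mixes both classes
  fig <- classifyLocus(c("GAGGCGCCAGGAGAGAGCGCT", "ACGGG"))
  expect_equal(fig$class, "complex")
  expect_equal(fig$minMotif, 5L)
  expect_equal(classifyLocus(c("GAGGCGCCAGG", "AGAGAGCGCTACGGG"))$class,
               "VNTR")
  expect_error(classifyLocus(character()), "empty")
})

test_that("error-free simulation recovers every injected mutation with no "
          %&&% "false positives", {
  sim <- smallSim()
  calls <- callTrDnms(sim, seed = 3L)
  truthKeys <- paste(sim$trTruth$child, sim$trTruth$locus)
  expect_setequal(paste(calls$child, calls$locus), truthKeys)
  expect_true(all(calls$pass))
  # the minimum-diff size estimate never exceeds the injected event size in
  # magnitude, and matches it exactly whenever the mutated parental allele
  # is that parent's nearest allele
  mrg <- merge(calls, sim$trTruth, by = c("child", "locus"))
  expect_true(all(abs(mrg$size) <= abs(mrg$sizeBp)))
  expect_gte(mean(mrg$size == mrg$sizeBp), 0.5)
})

test_that("restricting to polymorphic loci raises the per-locus rate", {
  sim <- smallSim()
  gt <- sim$trGenotypes
  nUnique <- tapply(c(gt$al1, gt$al2), rep(gt$locus, 2),
                    function(x) length(unique(x)))
  poly <- names(nUnique)[nUnique >= 2L]
  expect_lt(length(poly), sim$config@trCatalogSize)
  calls <- callTrDnms(sim, seed = 3L)
  rateAll <- sum(calls$pass) / (2 * sim$config@trCatalogSize)
  ratePoly <- sum(calls$pass & calls$locus %in% poly) / (2 * length(poly))
  expect_gt(ratePoly, rateAll)
})
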