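# Small de novo variant calling: candidates, cluster filter, multiplatform
# validation, informative-site enumeration, read-based phasing, postzygotic
# classification and transmission.

test_that("candidates are child-unique alternate alleles", {
  gt <- rbind(s1 = c(C = 1L, F = 0L, M = 0L),   # de novo
              s2 = c(C = 1L, F = 1L, M = 0L),   # inherited het
              s3 = c(C = 2L, F = 0L, M = 0L),   # de novo hom (error-like)
              s4 = c(C = 0L, F = 0L, M = 0L))
  expect_setequal(candidateDnms(gt, "C", "F", "M"), c("s1", "s3"))
})

test_that("the cluster filter matches a sliding-window brute force", {
  expect_equal(clusterFilter(c(100, 200, 5e4)), rep(TRUE, 3))   # 2 kept
  expect_equal(clusterFilter(c(100, 500, 900)), rep(FALSE, 3))  # 3 in 1 kb
  bruteForce <- function(pos, w = 1000, k = 3L) {
    drop <- rep(FALSE, length(pos))
    for (i in seq_along(pos)) for (j in seq_along(pos)) {
      if (j >= i + k - 1L && pos[j] - pos[i] <= w) drop[i:j] <- TRUE
    }
    !drop
  }
  set.seed(12)
  for (rep in 1:20) {
    pos <- sort(sample.int(2e4, 40))
    expect_identical(clusterFilter(pos), bruteForce(pos))
  }
})

test_that("multiplatform validation enforces the parental evidence "
          %&&% "boundaries", {
  mkEv <- function(childAltPlatforms = c("HiFi", "ONT"),
                   parentAltHq = 0L, parentAltLq = 0L,
                   cohortAltHq = 0L) {
    plats <- c("HiFi", "ONT", "SRS-A")
    rows <- list()
    for (p in plats) {
      rows[[length(rows) + 1L]] <- data.frame(
        sample = "child", platform = p, refHq = 15L,
        altHq = if (p %in% childAltPlatforms) 14L else 0L,
        refLq = 1L, altLq = 0L)
      for (par in c("fa", "mo"))
        rows[[length(rows) + 1L]] <- data.frame(
          sample = par, platform = p, refHq = 30L,
          altHq = if (p == "HiFi" && par == "fa") parentAltHq else 0L,
          refLq = 2L,
          altLq = if (p == "HiFi" && par == "fa") parentAltLq else 0L)
      rows[[length(rows) + 1L]] <- data.frame(
        sample = "uncle", platform = p, refHq = 30L, altHq = cohortAltHq,
        refLq = 0L, altLq = 0L)
    }
    do.call(rbind, rows)
  }
  ok <- validateMultiplatform(mkEv(), "child", "fa", "mo", "uncle")
  expect_true(ok$pass)
  # child support on a single platform only
  one <- validateMultiplatform(mkEv(childAltPlatforms = "HiFi"),
                               "child", "fa", "mo", "uncle")
  expect_false(one$pass)
  expect_true("child_support_lt_2_platforms" %in% one$reasons)
  # one high-quality parental alternate read kills the candidate
  hq <- validateMultiplatform(mkEv(parentAltHq = 1L), "child", "fa", "mo")
  expect_false(hq$pass)
  expect_true("parental_high_bq_alt" %in% hq$reasons)
  # more than two low-quality parental reads fail, exactly two pass
  lq3 <- validateMultiplatform(mkEv(parentAltLq = 3L), "child", "fa", "mo")
  expect_false(lq3$pass)
  lq2 <- validateMultiplatform(mkEv(parentAltLq = 2L), "child", "fa", "mo")
  expect_true(lq2$pass)
  # cohort screen applies to SNVs only
  coh <- validateMultiplatform(mkEv(cohortAltHq = 2L), "child", "fa", "mo",
                               "uncle", isSnv = TRUE)
  expect_false(coh$pass)
  indel <- validateMultiplatform(mkEv(cohortAltHq = 2L), "child", "fa", "mo",
                                 "uncle", isSnv = FALSE)
  expect_true(indel$pass)
  # missing parental evidence is untestable
  miss <- validateMultiplatform(mkEv()[mkEv()$sample != "mo", ],
                                "child", "fa", "mo")
  expect_false(miss$pass)
  expect_equal(miss$reasons, "untestable_missing_parental_evidence")
})

test_that("informative-site selection matches the genotype rule table", {
  gts <- c("0/0", "0/1", "1/1")
  # enumerate all parental genotype pairs with a heterozygous child
  for (f in gts) for (m in gts) {
    cand <- data.frame(pos = 0, fatherGt = f, motherGt = m, childGt = "0/1")
    res <- findInformativeSites(cand, 0)
    bothHet <- f == "0/1" && m == "0/1"
    same <- f == m
    mendelBroken <- (f == "0/0" && m == "0/0") || (f == "1/1" && m == "1/1")
    expectInformative <- !bothHet && !same && !mendelBroken
    expect_equal(nrow(res) == 1L, expectInformative,
                 info = paste(f, m))
    if (nrow(res) == 1L) {
      # the paternal allele is the one only the father can have donated
      fDose <- sum(as.integer(strsplit(f, "/")[[1]]))
      mDose <- sum(as.integer(strsplit(m, "/")[[1]]))
      pat <- if (fDose == 0L) 0L else if (fDose == 2L) 1L else
        if (mDose == 0L) 1L else 0L
      expect_equal(res$patAllele, pat, info = paste(f, m))
      expect_equal(res$matAllele, 1L - pat)
    }
  }
  # sites outside the window are excluded
  far <- data.frame(pos = 1e5, fatherGt = "0/1", motherGt = "0/0",
                    childGt = "0/1")
  expect_equal(nrow(findInformativeSites(far, 0, windowBp = 8e4)), 0L)
})

test_that("read phasing assigns unanimous alternate reads and excludes "
          %&&% "conflicts", {
  info <- data.frame(pos = c(-100, 100), patAllele = c(1L, 0L),
                     matAllele = c(0L, 1L))
  # 8/8 alternate reads on the paternal haplotype
  reads <- data.frame(readId = sprintf("r%d", 1:16),
                      dnmAllele = rep(c(1L, 0L), each = 8))
  am <- rbind(matrix(rep(c(1L, 0L), each = 8), nrow = 8),   # paternal reads
              matrix(rep(c(0L, 1L), each = 8), nrow = 8))   # maternal reads
  ph <- phaseDnm(reads, am, info)
  expect_equal(ph$origin, "paternal")
  expect_equal(unname(ph$hapCounts), c(8L, 8L))
  # alternate reads split between haplotypes: conflicting, excluded
  reads2 <- data.frame(readId = sprintf("r%d", 1:8), dnmAllele = 1L)
  am2 <- rbind(matrix(rep(c(1L, 0L), each = 4), nrow = 4),
               matrix(rep(c(0L, 1L), each = 4), nrow = 4))
  expect_equal(phaseDnm(reads2, am2, info)$origin, "conflicting")
  # no informative coverage: unphased
  am3 <- matrix(NA_integer_, nrow = 8, ncol = 2)
  expect_equal(phaseDnm(reads2, am3, info)$origin, "unphased")
})

test_that("simulated mutations phase to the correct parent at depth 20", {
  correct <- 0L; total <- 0L
  for (i in 1:200) {
    origin <- if (i %% 2 == 0) "paternal" else "maternal"
    rs <- simulateDnmReadSet(origin, depth = 20L, errorRate = 0.002,
                             seed = 1000L + i)
    info <- findInformativeSites(rs$candidates, 0)
    keep <- rs$candidates$pos %in% info$pos
    ph <- phaseDnm(rs$reads, rs$alleleMat[, keep, drop = FALSE], info)
    if (ph$origin %in% c("paternal", "maternal")) {
      total <- total + 1L
      if (ph$origin == origin) correct <- correct + 1L
    }
  }
  expect_gte(total, 180L)
  expect_gte(correct / total, 0.99)
})

test_that("postzygotic classification follows the haplotype-fraction and "
          %&&% "balance rules", {
  # every haplotype read carries the alternate: germline
  expect_equal(classifyPzm(hapCounts = c(alt = 10L, total = 10L))$class,
               "germline")
  # a fraction of haplotype reads: postzygotic
  pz <- classifyPzm(hapCounts = c(alt = 4L, total = 12L))
  expect_equal(pz$class, "postzygotic")
  expect_equal(pz$hapFraction, 1 / 3)
  # too few assigned reads: indeterminate
  expect_equal(classifyPzm(hapCounts = c(alt = 3L, total = 4L))$class,
               "indeterminate")
  # unphased: homogeneous platforms with pooled balance below half
  pc <- data.frame(platform = c("HiFi", "ONT", "SRS-A"),
                   alt = c(10L, 10L, 10L), total = c(40L, 40L, 40L))
  un <- classifyPzm(platformCounts = pc)
  expect_equal(un$class, "postzygotic")
  # the binomial p-value matches the closed form
  expect_equal(un$pBalance, pbinom(30, 120, 0.5))
  # balanced alleles stay germline
  bal <- data.frame(platform = c("HiFi", "ONT"), alt = c(20L, 21L),
                    total = c(40L, 41L))
  expect_equal(classifyPzm(platformCounts = bal)$class, "germline")
})

test_that("a balanced germline simulation is misclassified at most at the "
          %&&% "test level", {
  set.seed(33)
  wrong <- 0L
  n <- 400L
  for (i in seq_len(n)) {
    tot <- c(40L, 40L, 40L)
    alt <- rbinom(3, tot, 0.5)
    pc <- data.frame(platform = c("a", "b", "c"), alt = alt, total = tot)
    if (classifyPzm(platformCounts = pc)$class == "postzygotic")
      wrong <- wrong + 1L
  }
  expect_lte(wrong / n, 0.05)
})

test_that("phasing is invariant to read order", {
  rs <- simulateDnmReadSet("paternal", depth = 24L, seed = 5L)
  info <- findInformativeSites(rs$candidates, 0)
  keep <- rs$candidates$pos %in% info$pos
  perm <- sample(nrow(rs$reads))
  a <- phaseDnm(rs$reads, rs$alleleMat[, keep, drop = FALSE], info)
  b <- phaseDnm(rs$reads[perm, ], rs$alleleMat[perm, keep, drop = FALSE],
                info)
  expect_equal(a$origin, b$origin)
  expect_equal(a$hapCounts, b$hapCounts)
})

test_that("transmission checking distinguishes transmitted, untransmitted "
          %&&% "and contradictory calls", {
  off <- data.frame(id = c("k1", "k2"),
                    inheritedMutantSegment = c(TRUE, FALSE),
                    carriesAlt = c(TRUE, FALSE))
  tr <- checkTransmission(off, "germline")
  expect_equal(tr$transmitted, "transmitted")
  expect_false(tr$validationFailure)
  # segment without the allele under a germline call: validation failure
  bad <- data.frame(id = "k1", inheritedMutantSegment = TRUE,
                    carriesAlt = FALSE)
  expect_true(checkTransmission(bad, "germline")$validationFailure)
  expect_false(checkTransmission(bad, "postzygotic")$validationFailure)
  expect_equal(checkTransmission(NULL)$transmitted, "unassayable")
})

test_that("germline mutations transmit to about half of offspring", {
  sim <- simulatePedigree(simConfig(seed = 31L, nChromosomes = 4L,
                                    chromLengthBp = 1e7, snvDensity = 1e-5,
                                    germlineSnvRate = 4e-7, pzmRate = 0,
                                    trCatalogSize = 0L, nG4a = 7L,
                                    nG4b = 5L))
  dn <- sim$dnmTruth
  m <- members(sim$pedigree)
  parents <- c("C3_01", "C3_02")
  events <- 0L; transmitted <- 0L
  for (p in parents) {
    kids <- m$id[!is.na(m$father) & (m$father == p | m$mother == p)]
    dd <- dn[dn$sample == p & dn$class == "germline", ]
    for (i in seq_len(nrow(dd))) for (k in kids) {
      events <- events + 1L
      if (any(sim$dnmCarriers$site == dd$site[i] &
                sim$dnmCarriers$sample == k))
        transmitted <- transmitted + 1L
    }
  }
  expect_gte(events, 200L)
  se <- sqrt(0.25 / events)
  expect_lt(abs(transmitted / events - 0.5), 3 * se)
})

test_that("error-free simulation gives perfect precision and recall for "
          %&&% "validated germline calls", {
  sim <- simulatePedigree(simConfig(seed = 61L, nChromosomes = 2L,
                                    chromLengthBp = 5e6, snvDensity = 1e-5,
                                    germlineSnvRate = 2e-6, pzmRate = 0,
                                    trCatalogSize = 0L))
  pr <- cleanProfiles(30)
  calls <- callDnmsForChild(sim, "C3_01", profiles = pr, seed = 2L)
  expect_gt(nrow(calls), 5L)
  expect_true(all(calls$pass))
  truthSites <- sim$dnmTruth$site[sim$dnmTruth$sample == "C3_01"]
  expect_setequal(calls$site, truthSites)
})
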