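# Small de novo variant calling, multiplatform validation, parent-of-origin
# phasing, postzygotic classification, and transmission checking.
#
# Candidates are child-unique alternate alleles in a trio. Validation uses
# read evidence stratified by base-quality class across platforms: a true de
# novo allele is supported in at least two platforms in the child, is absent
# from high-quality parental bases, and tolerates at most two low-quality
# parental alternate bases. Phasing assigns alternate-carrying long reads to
# a parental haplotype via flanking informative sites; incomplete haplotype
# linkage, or a sub-0.5 allele balance consistent across platforms,
# classifies a mutation as postzygotic.

#' Candidate de novo variants from trio genotypes
#'
#' @param gtMat integer dosage matrix (sites x samples).
#' @param child,father,mother column names.
#' @return character vector of candidate site ids: child carries at least
#'   one alternate allele while both parents are homozygous reference.
#' @export
candidateDnms <- function(gtMat, child, father, mother) {
  rn <- rownames(gtMat)
  rn[gtMat[, child] > 0L & gtMat[, father] == 0L & gtMat[, mother] == 0L]
}

#' Remove clustered candidate SNVs
#'
#' Drops every candidate that belongs to a window of `k` or more candidates
#' within `windowBp`.
#'
#' @param pos sorted numeric positions of candidate SNVs (one chromosome).
#' @param windowBp window size (default 1 kb).
#' @param k cluster size threshold (default 3).
#' @return logical vector: TRUE for candidates kept.
#' @examples
#' clusterFilter(c(100, 200, 300, 5e4))
#' @export
clusterFilter <- function(pos, windowBp = 1000, k = 3L) {
  stopifnot(!is.unsorted(pos))
  n <- length(pos)
  drop <- rep(FALSE, n)
  if (n >= k) {
    for (i in seq_len(n - k + 1L)) {
      j <- i + k - 1L
      if (pos[j] - pos[i] <= windowBp) drop[i:j] <- TRUE
    }
  }
  !drop
}

#' Multiplatform read validation of a candidate de novo variant
#'
#' Applies the evidence rules for a true de novo allele: (a) child alternate
#' support in at least two platforms, (b) zero high-quality parental
#' alternate bases, (c) at most two low-quality parental alternate bases,
#' with (d) mapping-quality-failing reads excluded from all counts (the
#' evidence tables carry MQ-passing counts only). SNVs additionally require
#' high-quality absence from every pedigree member that is not a descendant
#' of the child, screened in the most accurate long-read platform only.
#'
#' @param evidence data.frame of read evidence rows (as from
#'   [simulateReads()]) for one site: columns sample, platform, refHq,
#'   altHq, refLq, altLq.
#' @param child,father,mother sample ids.
#' @param cohortSamples ids of non-descendant pedigree members to screen for
#'   SNVs (may be empty); descendants must already be excluded by the
#'   caller.
#' @param isSnv logical: apply the cohort screen.
#' @param maxParentalLowBq maximum tolerated low-quality parental alternate
#'   reads (default 2).
#' @param cohortPlatforms platforms examined for the cohort screen (default
#'   "HiFi").
#' @return list(pass = logical, reasons = character vector of failure codes).
#' @export
validateMultiplatform <- function(evidence, child, father, mother,
                                  cohortSamples = character(),
                                  isSnv = TRUE, maxParentalLowBq = 2L,
                                  cohortPlatforms = "HiFi") {
  reasons <- character()
  ev <- evidence
  che <- ev[ev$sample == child, , drop = FALSE]
  pae <- ev[ev$sample %in% c(father, mother), , drop = FALSE]
  if (!nrow(pae) || !all(c(father, mother) %in% ev$sample)) {
    return(list(pass = FALSE, reasons = "untestable_missing_parental_evidence"))
  }
  platformsWithAlt <- unique(che$platform[che$altHq + che$altLq > 0L])
  if (length(platformsWithAlt) < 2L)
    reasons <- c(reasons, "child_support_lt_2_platforms")
  if (sum(pae$altHq) > 0L)
    reasons <- c(reasons, "parental_high_bq_alt")
  if (sum(pae$altLq) > maxParentalLowBq)
    reasons <- c(reasons, "parental_low_bq_alt_gt_2")
  if (isSnv && length(cohortSamples)) {
    coh <- ev[ev$sample %in% cohortSamples &
                ev$platform %in% cohortPlatforms, , drop = FALSE]
    if (sum(coh$altHq) > 0L)
      reasons <- c(reasons, "cohort_high_bq_alt")
  }
  list(pass = length(reasons) == 0L, reasons = reasons)
}

#' Informative sites for read-based parent-of-origin phasing
#'
#' A flanking SNP is informative when an allele of a heterozygous child can
#' be uniquely attributed to one parent: the parental genotypes differ and
#' they are not both heterozygous. The returned table gives, for each
#' informative site, the allele on the child's paternally and maternally
#' inherited haplotypes.
#'
#' @param candidates data.frame(pos, fatherGt, motherGt, childGt) of
#'   biallelic SNVs near the de novo site (genotypes as "0/0", "0/1", "1/1").
#' @param dnmPos position of the de novo variant.
#' @param windowBp total window size centred on the variant (default 80 kb).
#' @return subset of `candidates` with added integer columns patAllele and
#'   matAllele.
#' @examples
#' findInformativeSites(data.frame(pos = 10, fatherGt = "0/1",
#'                                 motherGt = "0/0", childGt = "0/1"), 0)
#' @export
findInformativeSites <- function(candidates, dnmPos, windowBp = 80000) {
  dose <- function(g) vapply(strsplit(g, "[/|]"), function(x)
    sum(as.integer(x)), 1L)
  w <- candidates[abs(candidates$pos - dnmPos) <= windowBp / 2, , drop = FALSE]
  if (!nrow(w)) { w$patAllele <- integer(); w$matAllele <- integer(); return(w) }
  fd <- dose(w$fatherGt); md <- dose(w$motherGt); cd <- dose(w$childGt)
  childHet <- cd == 1L
  bothHet <- fd == 1L & md == 1L
  mendelOk <- cd >= (fd > 1L) + (md > 1L) & cd <= (fd > 0L) + (md > 0L)
  informative <- childHet & !bothHet & fd != md & mendelOk
  w <- w[informative, , drop = FALSE]
  fd <- fd[informative]; md <- md[informative]
  # child is 0/1; the parent that can only donate one allele fixes the phase
  pat <- ifelse(fd == 0L, 0L, ifelse(fd == 2L, 1L,
           ifelse(md == 0L, 1L, 0L)))   # father het, mother homozygous
  w$patAllele <- as.integer(pat)
  w$matAllele <- 1L - w$patAllele
  w
}

#' Assign a de novo variant to a parental haplotype from read evidence
#'
#' Each read is assigned to a parent by majority vote of its informative
#' alleles (ties leave the read unassigned). The variant is phased when
#' every alternate-carrying assigned read points to the same parent;
#' disagreement among alternate reads excludes the variant from the
#' callset, and absence of informative coverage leaves it unphased.
#'
#' @param reads data.frame(readId, dnmAllele) with dnmAllele 0/1.
#' @param alleleMat reads x informative-sites matrix of observed alleles
#'   (NA = site not covered by the read).
#' @param info informative-site table from [findInformativeSites()]
#'   (columns patAllele, matAllele).
#' @return list with `origin` ("paternal", "maternal", "unphased" or
#'   "conflicting"), `readParent` (per-read assignment), and per-haplotype
#'   alternate/total counts used by [classifyPzm()].
#' @export
phaseDnm <- function(reads, alleleMat, info) {
  n <- nrow(reads)
  if (n == 0L || nrow(info) == 0L)
    return(list(origin = "unphased", readParent = character(0),
                hapCounts = NULL))
  patVotes <- matVotes <- integer(n)
  for (r in seq_len(n)) {
    a <- alleleMat[r, ]
    cov <- !is.na(a)
    patVotes[r] <- sum(a[cov] == info$patAllele[cov])
    matVotes[r] <- sum(a[cov] == info$matAllele[cov])
  }
  readParent <- ifelse(patVotes > matVotes, "paternal",
                ifelse(matVotes > patVotes, "maternal", "unassigned"))
  altIdx <- reads$dnmAllele == 1L
  altAssigned <- readParent[altIdx & readParent != "unassigned"]
  origin <- if (!length(altAssigned)) "unphased"
    else if (all(altAssigned == "paternal")) "paternal"
    else if (all(altAssigned == "maternal")) "maternal"
    else "conflicting"
  hapCounts <- NULL
  if (origin %in% c("paternal", "maternal")) {
    onHap <- readParent == origin
    hapCounts <- c(alt = sum(onHap & altIdx), total = sum(onHap))
  }
  list(origin = origin, readParent = readParent, hapCounts = hapCounts)
}

#' Classify a de novo variant as germline or postzygotic
#'
#' Phased variants are germline when every read assigned to the mutant
#' parental haplotype carries the alternate allele; a variant present on
#' only a fraction of those reads is postzygotic, with the haplotype read
#' fraction recorded. Fewer than `minHapReads` assigned reads is
#' indeterminate. Unphased variants are postzygotic when their allele
#' balance is homogeneous across platforms (chi-squared test not rejected at
#' `alpha`; an exact test is used when expected counts are small) and the
#' pooled balance is significantly below 0.5 by a one-sided exact binomial
#' test.
#'
#' @param hapCounts named vector c(alt, total) of mutant-haplotype reads
#'   (phased variants), or NULL for unphased.
#' @param platformCounts data.frame(platform, alt, total) for unphased
#'   variants.
#' @param alpha test level (default 0.05).
#' @param minHapReads minimum haplotype-assigned reads (default 5).
#' @return list with `class` ("germline", "postzygotic" or "indeterminate"),
#'   `hapFraction`, and for unphased variants `pHomogeneity` and
#'   `pBalance`.
#' @export
classifyPzm <- function(hapCounts = NULL, platformCounts = NULL,
                        alpha = 0.05, minHapReads = 5L) {
  if (!is.null(hapCounts)) {
    if (hapCounts[["total"]] < minHapReads)
      return(list(class = "indeterminate",
                  hapFraction = hapCounts[["alt"]] / hapCounts[["total"]]))
    frac <- hapCounts[["alt"]] / hapCounts[["total"]]
    return(list(class = if (hapCounts[["alt"]] == hapCounts[["total"]])
      "germline" else "postzygotic", hapFraction = frac))
  }
  stopifnot(!is.null(platformCounts))
  tab <- rbind(alt = platformCounts$alt,
               ref = platformCounts$total - platformCounts$alt)
  pHom <- if (ncol(tab) < 2L) 1 else {
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(expected < 5))
      stats::fisher.test(tab, simulate.p.value = ncol(tab) > 2L,
                         B = 10000)$p.value
    else suppressWarnings(stats::chisq.test(tab)$p.value)
  }
  pooledAlt <- sum(platformCounts$alt)
  pooledTot <- sum(platformCounts$total)
  pBal <- stats::binom.test(pooledAlt, pooledTot, p = 0.5,
                            alternative = "less")$p.value
  isPzm <- (pHom >= alpha) && (pBal < alpha)
  list(class = if (isPzm) "postzygotic" else "germline",
       hapFraction = pooledAlt / pooledTot,
       pHomogeneity = pHom, pBalance = pBal)
}

#' Check transmission of a de novo allele to the next generation
#'
#' A call is transmitted when at least one offspring inherited the mutant
#' haplotype segment and carries the alternate allele. An offspring that
#' inherited the segment without the allele contradicts a germline
#' classification (a haplotype-based validation failure, the signature of an
#' undetected postzygotic event); these events are reported separately.
#'
#' @param offspring data.frame(id, inheritedMutantSegment, carriesAlt)
#'   with one row per sequenced offspring of the calling individual.
#' @param callClass "germline" or "postzygotic" classification of the call.
#' @return list with `transmitted` ("transmitted", "not_transmitted" or
#'   "unassayable") and `validationFailure` (TRUE when a germline call has a
#'   segment-inheriting offspring without the allele).
#' @export
checkTransmission <- function(offspring, callClass = "germline") {
  if (is.null(offspring) || nrow(offspring) == 0L)
    return(list(transmitted = "unassayable", validationFailure = FALSE))
  hit <- offspring$inheritedMutantSegment & offspring$carriesAlt
  miss <- offspring$inheritedMutantSegment & !offspring$carriesAlt
  list(transmitted = if (any(hit)) "transmitted" else "not_transmitted",
       validationFailure = callClass == "germline" && any(miss))
}

#' End-to-end small de novo calling on a simulated trio
#'
#' Convenience driver used by the pipeline and the rate-recovery studies:
#' builds candidates from the simulated truth (child-unique alleles),
#' simulates cohort read evidence at candidate sites, validates each
#' candidate across platforms, and returns the surviving callset.
#'
#' @param sim a `pedSim` object.
#' @param child child id.
#' @param profiles platform profiles.
#' @param seed integer seed.
#' @return data.frame(site, chrom, pos, class, vclass, pass, reasons) for
#'   every true de novo site of the child, plus validation outcomes.
#' @export
callDnmsForChild <- function(sim, child,
                             profiles = sim$config@platformProfiles,
                             seed = 1L) {
  m <- members(sim$pedigree)
  r <- m[m$id == child, ]
  dn <- sim$dnmTruth[sim$dnmTruth$sample == child, , drop = FALSE]
  if (!nrow(dn))
    return(data.frame(site = character(), chrom = character(),
                      pos = numeric(), class = character(),
                      vclass = character(), pass = logical(),
                      reasons = character()))
  desc <- descendantsOf(sim$pedigree, child)
  cohort <- setdiff(m$id, c(child, desc))
  rows <- lapply(seq_len(nrow(dn)), function(i) {
    d <- dn[i, ]
    samples <- unique(c(child, r$father, r$mother, cohort))
    st <- data.frame(site = d$site, sample = samples,
                     gt = ifelse(samples == child, 1L, 0L),
                     vaf = ifelse(samples == child & d$class == "postzygotic",
                                  d$vaf, NA_real_),
                     homologue = d$homologue, stringsAsFactors = FALSE)
    ev <- simulateReads(st, profiles, seed = childSeed(seed, 31L + i))
    val <- validateMultiplatform(ev, child, r$father, r$mother,
                                 cohortSamples = cohort,
                                 isSnv = d$vclass == "SNV")
    data.frame(site = d$site, chrom = d$chrom, pos = d$pos, class = d$class,
               vclass = d$vclass, pass = val$pass,
               reasons = paste(val$reasons, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' All descendants of an individual
#' @param ped a [Pedigree-class].
#' @param id individual id.
#' @return character vector of descendant ids (excluding `id`).
#' @export
descendantsOf <- function(ped, id) {
  m <- members(ped)
  out <- character()
  frontier <- id
  while (length(frontier)) {
    kids <- m$id[!is.na(m$father) &
                   (m$father %in% frontier | m$mother %in% frontier)]
    kids <- setdiff(kids, out)
    out <- c(out, kids)
    frontier <- kids
  }
  out
}
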