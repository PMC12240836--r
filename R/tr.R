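# Tandem-repeat Mendelian concordance, de novo allele detection, sizing,
# parent-of-origin, orthogonal short-read validation, and recurrence.

#' Manhattan-distance concordance of a tandem-repeat trio
#'
#' Considers every assignment of the child's two allele lengths to one
#' paternal and one maternal allele (8 combinations) and returns the
#' minimum total absolute deviation. A locus is concordant when the minimum
#' is zero: some combination of the child's allele lengths matches the
#' parental alleles perfectly.
#'
#' @param childAl,fatherAl,motherAl length-2 numeric vectors of allele
#'   lengths in bp; any NA marks the locus as missing.
#' @return list(minDistance, concordant, missing).
#' @examples
#' manhattanConcordance(c(100, 50), c(100, 100), c(50, 150))
#' @export
manhattanConcordance <- function(childAl, fatherAl, motherAl) {
  if (anyNA(c(childAl, fatherAl, motherAl)))
    return(list(minDistance = NA_real_, concordant = NA, missing = TRUE))
  best <- Inf
  for (perm in list(c(1L, 2L), c(2L, 1L))) {
    a <- childAl[perm[1L]]; b <- childAl[perm[2L]]
    for (i in 1:2) for (j in 1:2) {
      d <- abs(a - fatherAl[i]) + abs(b - motherAl[j])
      if (d < best) best <- d
    }
  }
  list(minDistance = best, concordant = best == 0, missing = FALSE)
}

#' De novo support scores from trio spanning reads
#'
#' Partitions the child's spanning reads to its two alleles by nearest
#' allele length (ties split evenly) and, for each child allele, counts
#' reads supporting an allele length absent from all parental reads
#' (`denovoCoverage`), the fraction of child spanning reads they represent
#' (`childRatio`), and the fraction of parental reads matching the candidate
#' allele length (`parentalFraction`).
#'
#' @param childAl length-2 vector of the child's allele lengths.
#' @param childReads numeric vector of child spanning-read allele lengths.
#' @param parentReads numeric vector of pooled parental spanning-read allele
#'   lengths.
#' @param tolBp match tolerance in bp when comparing read lengths (0 =
#'   exact).
#' @return data.frame with one row per child allele: allele, denovoCoverage,
#'   childRatio, parentalFraction; NULL when the child has no spanning
#'   reads.
#' @export
denovoScore <- function(childAl, childReads, parentReads, tolBp = 0) {
  if (!length(childReads)) return(NULL)
  d1 <- abs(childReads - childAl[1L])
  d2 <- abs(childReads - childAl[2L])
  assign1 <- d1 < d2
  tie <- d1 == d2
  if (any(tie)) assign1[tie] <- seq_len(sum(tie)) %% 2L == 1L
  out <- lapply(1:2, function(k) {
    reads <- childReads[if (k == 1L) assign1 else !assign1]
    support <- reads[abs(reads - childAl[k]) <= tolBp]
    inParent <- length(parentReads) &&
      any(abs(parentReads - childAl[k]) <= tolBp)
    dnCov <- if (inParent) 0L else length(support)
    data.frame(allele = childAl[k],
               denovoCoverage = dnCov,
               childRatio = dnCov / length(childReads),
               parentalFraction = if (length(parentReads))
                 mean(abs(parentReads - childAl[k]) <= tolBp) else 0)
  })
  do.call(rbind, out)
}

#' Filter a candidate de novo tandem-repeat allele
#'
#' Enforces the five acceptance rules for a de novo expansion or
#' contraction: trio spanning depth of at least `minDepth` reads in child,
#' mother and father; allele uniqueness (rejected when the child's de novo
#' allele length matches one parent's allele and the child's other allele
#' matches the other parent's); a non-zero size change relative to the
#' mutated parental allele; `denovoCoverage >= 2` with
#' `childRatio >= 0.2`; and fewer than 5% of parental reads supporting the
#' candidate allele.
#'
#' @param denovoAl,otherAl the child's candidate de novo and non-de novo
#'   allele lengths.
#' @param fatherAl,motherAl length-2 parental allele-length vectors.
#' @param depthChild,depthFather,depthMother spanning-read depths.
#' @param denovoCoverage,childRatio,parentalFraction scores from
#'   [denovoScore()].
#' @param minDepth,minDenovoCoverage,minChildRatio,maxParentalFraction
#'   thresholds (defaults 10, 2, 0.2, 0.05).
#' @return list(pass, reasons).
#' @export
filterDeNovo <- function(denovoAl, otherAl, fatherAl, motherAl,
                         depthChild, depthFather, depthMother,
                         denovoCoverage, childRatio, parentalFraction,
                         minDepth = 10L, minDenovoCoverage = 2L,
                         minChildRatio = 0.2, maxParentalFraction = 0.05) {
  reasons <- character()
  if (depthChild < minDepth || depthFather < minDepth ||
      depthMother < minDepth)
    reasons <- c(reasons, "depth_lt_10")
  unique1 <- denovoAl %in% fatherAl && otherAl %in% motherAl
  unique2 <- denovoAl %in% motherAl && otherAl %in% fatherAl
  if (unique1 || unique2)
    reasons <- c(reasons, "not_unique")
  if (min(abs(denovoAl - c(fatherAl, motherAl))) == 0)
    reasons <- c(reasons, "no_expansion_or_contraction")
  if (denovoCoverage < minDenovoCoverage)
    reasons <- c(reasons, "denovo_coverage_lt_2")
  if (childRatio < minChildRatio)
    reasons <- c(reasons, "child_ratio_lt_0.2")
  if (parentalFraction >= maxParentalFraction)
    reasons <- c(reasons, "parental_support_ge_5pct")
  list(pass = length(reasons) == 0L, reasons = reasons)
}

#' Size of a de novo tandem-repeat expansion or contraction
#'
#' Computes the absolute differences ("diffs") between the de novo allele
#' length and each parental allele length. With a known parent of origin
#' the size is the minimum diff among that parent's alleles; without phase
#' it is the minimum over all four. The sign is positive for an expansion
#' (de novo allele longer than the nearest parental allele) and negative
#' for a contraction.
#'
#' @param denovoAl the child's de novo allele length.
#' @param fatherAl,motherAl length-2 parental allele-length vectors.
#' @param phase "paternal", "maternal" or NA.
#' @return list(size, diffsFather, diffsMother, parentalAllele).
#' @examples
#' # worked example: father 100,100; mother 50,150; de novo allele 200
#' deNovoSize(200, c(100, 100), c(50, 150), phase = "maternal")$size  # +50
#' @export
deNovoSize <- function(denovoAl, fatherAl, motherAl, phase = NA) {
  dF <- abs(denovoAl - fatherAl)
  dM <- abs(denovoAl - motherAl)
  pick <- function(d, al) {
    k <- which.min(d)
    list(diff = d[k], allele = al[k])
  }
  sel <- if (identical(phase, "paternal")) pick(dF, fatherAl)
    else if (identical(phase, "maternal")) pick(dM, motherAl)
    else if (min(dF) <= min(dM)) pick(dF, fatherAl) else pick(dM, motherAl)
  size <- sel$diff * sign(denovoAl - sel$allele)
  list(size = size, diffsFather = dF, diffsMother = dM,
       parentalAllele = sel$allele)
}

#' Parent of origin of a phased de novo tandem-repeat allele
#'
#' Uses phased flanking SNVs: informative sites are biallelic SNVs with trio
#' depth and genotype quality above threshold, a heterozygous child, and
#' parents that are not identical-by-state. The `n` closest sites that share
#' the de novo allele's phase block and support a consistent inheritance
#' pattern determine which parent donated each child haplotype; the parent
#' donating the de novo-bearing haplotype is reported.
#'
#' @param snvs data.frame(pos, fatherGt, motherGt, childGt, childPhasedGt,
#'   phaseSet, depth, gq) of flanking SNVs; `childPhasedGt` like "1|0".
#' @param dnmPos position of the de novo allele.
#' @param dnmHaplotype 1 or 2: the child haplotype carrying the de novo
#'   allele.
#' @param dnmPhaseSet phase-set id of the de novo allele.
#' @param n number of informative sites used (default 3).
#' @param windowBp search window on each side (default 500 kb).
#' @param minDepth,minGq site thresholds (defaults 10, 20).
#' @return list(origin = "paternal"/"maternal"/"unknown", nUsed,
#'   contradictions).
#' @export
phaseTrPoo <- function(snvs, dnmPos, dnmHaplotype, dnmPhaseSet,
                       n = 3L, windowBp = 5e5, minDepth = 10L, minGq = 20L) {
  dose <- function(g) vapply(strsplit(g, "[/|]"), function(x)
    sum(as.integer(x)), 1L)
  s <- snvs[abs(snvs$pos - dnmPos) <= windowBp & snvs$depth >= minDepth &
              snvs$gq >= minGq & snvs$phaseSet == dnmPhaseSet, , drop = FALSE]
  if (!nrow(s)) return(list(origin = "unknown", nUsed = 0L,
                            contradictions = 0L))
  fd <- dose(s$fatherGt); md <- dose(s$motherGt); cd <- dose(s$childGt)
  ibs <- s$fatherGt == s$motherGt
  informative <- cd == 1L & !ibs & !(fd == 1L & md == 1L) &
    grepl("\\|", s$childPhasedGt)
  s <- s[informative, , drop = FALSE]
  if (!nrow(s)) return(list(origin = "unknown", nUsed = 0L,
                            contradictions = 0L))
  fd <- fd[informative]; md <- md[informative]
  hap1 <- as.integer(substr(s$childPhasedGt, 1L, 1L))
  # allele on the paternally inherited haplotype (child is het)
  patAllele <- ifelse(fd == 0L, 0L, ifelse(fd == 2L, 1L,
                 ifelse(md == 0L, 1L, 0L)))
  # does haplotype 1 carry the paternal allele at this site?
  hap1IsPat <- hap1 == patAllele
  ord <- order(abs(s$pos - dnmPos))
  use <- ord[seq_len(min(n, length(ord)))]
  votes <- hap1IsPat[use]
  contradictions <- min(sum(votes), sum(!votes))
  if (length(unique(votes)) > 1L)
    return(list(origin = "unknown", nUsed = length(use),
                contradictions = contradictions))
  hap1Parent <- if (votes[1L]) "paternal" else "maternal"
  origin <- if (dnmHaplotype == 1L) hap1Parent else
    if (hap1Parent == "paternal") "maternal" else "paternal"
  list(origin = origin, nUsed = length(use), contradictions = contradictions)
}

#' Net CIGAR allele length of a read over a tandem-repeat locus
#'
#' Walks the CIGAR string from the alignment start and sums, over operations
#' overlapping the locus, +length for insertions, -length for deletions and
#' 0 for matches: the read-level allele length relative to the reference.
#'
#' @param cigar CIGAR string (M, =, X, I, D, S, H operations).
#' @param locusStart,locusEnd locus interval (0-based half-open).
#' @param alnStart alignment start of the read (0-based).
#' @return integer net insertion/deletion over the locus in bp.
#' @examples
#' netCigarAlleleLength("100M2D10M6I32M", 90, 140, 0)  # +4
#' @export
netCigarAlleleLength <- function(cigar, locusStart, locusEnd, alnStart) {
  ops <- gregexpr("\\d+[MIDNSHP=X]", cigar)[[1L]]
  if (ops[1L] == -1L) stop("malformed CIGAR: ", cigar)
  toks <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1L]]
  if (nchar(paste(toks, collapse = "")) != nchar(cigar))
    stop("malformed CIGAR: ", cigar)
  lens <- as.integer(sub("[MIDNSHP=X]", "", toks))
  kinds <- sub("\\d+", "", toks)
  refPos <- alnStart
  net <- 0L
  for (i in seq_along(toks)) {
    op <- kinds[i]; L <- lens[i]
    if (op %in% c("M", "=", "X")) {
      refPos <- refPos + L
    } else if (op == "D" || op == "N") {
      ovl <- max(0L, min(refPos + L, locusEnd) - max(refPos, locusStart))
      if (op == "D") net <- net - ovl
      refPos <- refPos + L
    } else if (op == "I") {
      if (refPos > locusStart && refPos <= locusEnd) net <- net + L
    }
    # S, H, P consume neither reference nor locus
  }
  as.integer(net)
}

#' Orthogonal short-read validation of a de novo tandem-repeat allele
#'
#' A candidate is validated when at least one child short read supports the
#' de novo allele length within `tolBp` and zero parental short reads do;
#' it is unassessable when no child short read spans the locus.
#'
#' @param denovoRelAl the de novo allele length relative to the reference
#'   (bp).
#' @param childRelAls,parentRelAls relative allele lengths of spanning
#'   child/parent short reads (net CIGAR values).
#' @param tolBp tolerance (default 1 bp, applied symmetrically).
#' @return "validated", "refuted" or "unassessable".
#' @export
orthogonalValidate <- function(denovoRelAl, childRelAls, parentRelAls,
                               tolBp = 1) {
  if (!length(childRelAls)) return("unassessable")
  childHit <- any(abs(childRelAls - denovoRelAl) <= tolBp)
  parentHit <- length(parentRelAls) &&
    any(abs(parentRelAls - denovoRelAl) <= tolBp)
  if (childHit && !parentHit) "validated" else "refuted"
}

#' Recurrent de novo tandem-repeat loci across a pedigree
#'
#' Loci where two or more individuals carry de novo alleles, with every
#' pedigree member genotyped and covered by at least `minDepth` spanning
#' reads; labelled intragenerational when all events fall in one generation
#' and intergenerational otherwise.
#'
#' @param calls data.frame(child, locus) of de novo calls.
#' @param generations named vector: generation of each individual.
#' @param genotyped data.frame(locus, sample, depth) of genotyping status
#'   for all pedigree members at candidate loci.
#' @param allSamples character vector of every pedigree member.
#' @param minDepth spanning-depth requirement (default 10).
#' @return data.frame(locus, nIndividuals, label).
#' @export
findRecurrent <- function(calls, generations, genotyped, allSamples,
                          minDepth = 10L) {
  tab <- table(calls$locus)
  cand <- names(tab)[tab >= 2L]
  rows <- lapply(cand, function(loc) {
    g <- genotyped[genotyped$locus == loc, , drop = FALSE]
    ok <- all(allSamples %in% g$sample) && all(g$depth >= minDepth)
    if (!ok) return(NULL)
    kids <- calls$child[calls$locus == loc]
    gens <- unique(generations[kids])
    data.frame(locus = loc, nIndividuals = length(unique(kids)),
               label = if (length(gens) == 1L) "intragenerational"
               else "intergenerational", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(locus = character(), nIndividuals = integer(),
                      label = character())
  out
}

#' Classify a tandem-repeat locus by motif content
#'
#' STR when all constituent motifs are 1-6 bp, VNTR when all are larger than
#' 6 bp, complex when both occur; also reports the minimum motif size.
#'
#' @param motifs character vector of motifs, or a comma-separated string.
#' @return list(class, minMotif).
#' @examples
#' classifyLocus("AT,AGA,T")$class   # STR
#' @export
classifyLocus <- function(motifs) {
  if (length(motifs) == 1L && grepl(",", motifs))
    motifs <- strsplit(motifs, ",")[[1L]]
  if (!length(motifs) || any(!nzchar(motifs))) stop("motif list is empty")
  lens <- nchar(motifs)
  cls <- if (all(lens <= 6L)) "STR" else if (all(lens > 6L)) "VNTR"
    else "complex"
  list(class = cls, minMotif = min(lens))
}

#' Call de novo tandem repeats across a simulated pedigree
#'
#' Driver: for every complete trio, scores each child allele with simulated
#' spanning reads, applies [filterDeNovo()], and returns the passing calls.
#'
#' @param sim a `pedSim` object with TR data.
#' @param children child ids (default: all non-founders).
#' @param depth simulated spanning-read depth per member.
#' @param seed integer seed.
#' @return data.frame(child, locus, denovoAl, size, pass).
#' @export
callTrDnms <- function(sim, children = NULL, depth = 30L, seed = 1L) {
  m <- members(sim$pedigree)
  if (is.null(children)) children <- m$id[!is.na(m$father)]
  gt <- sim$trGenotypes
  alOf <- function(id, loc) {
    r <- gt[gt$sample == id & gt$locus == loc, ]
    c(r$al1, r$al2)
  }
  rows <- list()
  withSeed(childSeed(seed, 41L), {
    truthKeys <- paste(sim$trTruth$child, sim$trTruth$locus)
    cand <- sim$trTruth[sim$trTruth$child %in% children, , drop = FALSE]
    for (i in seq_len(nrow(cand))) {
      d <- cand[i, ]
      r <- m[m$id == d$child, ]
      chAl <- alOf(d$child, d$locus)
      faAl <- alOf(r$father, d$locus)
      moAl <- alOf(r$mother, d$locus)
      dC <- stats::rpois(1L, depth); dF <- stats::rpois(1L, depth)
      dM <- stats::rpois(1L, depth)
      childReads <- chAl[sample(1:2, dC, replace = TRUE)]
      parentReads <- c(faAl[sample(1:2, dF, replace = TRUE)],
                       moAl[sample(1:2, dM, replace = TRUE)])
      sc <- denovoScore(chAl, childReads, parentReads)
      if (is.null(sc)) next
      k <- which(sc$allele == d$denovoAl)[1L]
      if (is.na(k)) next
      fl <- filterDeNovo(d$denovoAl, chAl[chAl != d$denovoAl][1L],
                         faAl, moAl, dC, dF, dM,
                         sc$denovoCoverage[k], sc$childRatio[k],
                         sc$parentalFraction[k])
      sz <- deNovoSize(d$denovoAl, faAl, moAl, phase = d$parent)
      rows[[length(rows) + 1L]] <- data.frame(
        child = d$child, locus = d$locus, denovoAl = d$denovoAl,
        size = sz$size, pass = fl$pass,
        reasons = paste(fl$reasons, collapse = ";"),
        stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(child = character(), locus = character(),
                      denovoAl = integer(), size = integer(),
                      pass = logical(), reasons = character())
  rownames(out) <- NULL
  out
}
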