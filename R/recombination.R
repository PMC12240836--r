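# Meiotic crossover detection, merging, refinement and characterization.
#
# A child homologue is compared with the two haplotypes of its transmitting
# parent; informative sites are encoded 0/1 by which parental haplotype they
# match, the 0/1 sequence is segmented by recursive binary segmentation, and
# label switches between adjacent segments are reported as crossover
# intervals. Additional operations merge maps from independent callers,
# refine breakpoints against aligned parental sequences, call short
# gene-conversion-like switches, test telomeric clustering by permutation,
# and model crossover counts on parental age and sex.

#' Encode a child homologue against the two parental haplotypes
#'
#' @param childAlleles allele vector of the child homologue.
#' @param parentH1,parentH2 parental haplotype allele vectors.
#' @param pos site positions.
#' @return list with `pos`, `code` (0 = matches H1, 1 = matches H2) at sites
#'   where the parent is informative (H1 != H2) and the child matches one of
#'   them, and `nSkipped` (informative sites matching neither allele).
#' @examples
#' encodeMatchVector(c(0, 1, 1), c(0, 0, 1), c(1, 1, 0), c(10, 20, 30))
#' @export
encodeMatchVector <- function(childAlleles, parentH1, parentH2, pos) {
  informative <- parentH1 != parentH2
  m1 <- childAlleles == parentH1
  m2 <- childAlleles == parentH2
  use <- informative & (m1 | m2)
  list(pos = pos[use], code = as.integer(m2[use]),
       nSkipped = sum(informative & !m1 & !m2))
}

# maximal two-sample t-like statistic over all single split points of x;
# returns list(index of last element of left part, z value)
bestSplit <- function(x) {
  n <- length(x)
  cs <- cumsum(x)
  tot <- cs[n]
  i <- seq_len(n - 1L)
  mL <- cs[i] / i
  mR <- (tot - cs[i]) / (n - i)
  p <- tot / n
  v <- p * (1 - p)
  z <- abs(mL - mR) / sqrt(pmax(v, 1e-12) * (1 / i + 1 / (n - i)))
  k <- which.max(z)
  list(index = k, z = z[k])
}

#' Segment a 0/1 haplotype-match vector by recursive binary segmentation
#'
#' Recursively splits the sequence at the position maximizing a two-sample
#' z statistic, stopping when the statistic falls below `zStop` or a side
#' would drop below `minSeg` sites. Segments are labelled H1 when their mean
#' code is at most 0.25 and H2 when at least 0.75; segments in between are
#' ambiguous and dropped, as are segments shorter than `minLengthBp`.
#' Adjacent same-label segments are merged.
#'
#' @param code 0/1 integer vector.
#' @param pos site positions (same length, increasing).
#' @param minSeg minimum sites per segment (default 20, the sparse-input
#'   setting; dense callsets typically use 400-500).
#' @param zStop significance stop for further splitting.
#' @param minLengthBp minimum segment span retained (default 500 kb).
#' @param meanLow,meanHigh labelling thresholds.
#' @return data.frame(start, end, label, nSites, firstIdx, lastIdx); a
#'   single unlabelled row with label NA when fewer than `minSeg` sites.
#' @examples
#' segmentCBS(rep(c(0L, 1L), each = 50), seq(1e5, 1e7, length.out = 100),
#'            minSeg = 10)
#' @export
segmentCBS <- function(code, pos, minSeg = 20L, zStop = 3,
                       minLengthBp = 5e5, meanLow = 0.25, meanHigh = 0.75) {
  stopifnot(minSeg >= 2L, length(code) == length(pos))
  n <- length(code)
  if (n < minSeg)
    return(data.frame(start = if (n) pos[1L] else numeric(),
                      end = if (n) pos[n] else numeric(),
                      label = if (n) NA_character_ else character(),
                      nSites = if (n) n else integer(),
                      firstIdx = if (n) 1L else integer(),
                      lastIdx = if (n) n else integer()))
  cuts <- integer()        # last index of each left part
  recurse <- function(lo, hi) {
    if (hi - lo + 1L < 2L * minSeg) return()
    seg <- code[lo:hi]
    sp <- bestSplit(seg)
    k <- sp$index
    if (sp$z < zStop) return()
    if (k < minSeg || (length(seg) - k) < minSeg) {
      # best split too close to an edge: try the best admissible split
      n2 <- length(seg)
      cs <- cumsum(seg)
      i <- seq(minSeg, n2 - minSeg)
      mL <- cs[i] / i
      mR <- (cs[n2] - cs[i]) / (n2 - i)
      p <- cs[n2] / n2
      z <- abs(mL - mR) / sqrt(pmax(p * (1 - p), 1e-12) * (1 / i + 1 / (n2 - i)))
      k <- i[which.max(z)]
      if (max(z) < zStop) return()
    }
    cuts <<- c(cuts, lo + k - 1L)
    recurse(lo, lo + k - 1L)
    recurse(lo + k, hi)
  }
  recurse(1L, n)
  bnd <- sort(unique(c(0L, cuts, n)))
  segs <- data.frame(firstIdx = bnd[-length(bnd)] + 1L, lastIdx = bnd[-1L])
  segs$nSites <- segs$lastIdx - segs$firstIdx + 1L
  segs$mean <- vapply(seq_len(nrow(segs)), function(i)
    mean(code[segs$firstIdx[i]:segs$lastIdx[i]]), 1)
  segs$start <- pos[segs$firstIdx]
  segs$end <- pos[segs$lastIdx]
  segs$label <- ifelse(segs$mean <= meanLow, "H1",
                ifelse(segs$mean >= meanHigh, "H2", NA_character_))
  segs <- segs[!is.na(segs$label) & (segs$end - segs$start) >= minLengthBp, ,
               drop = FALSE]
  if (!nrow(segs))
    return(data.frame(start = numeric(), end = numeric(), label = character(),
                      nSites = integer(), firstIdx = integer(),
                      lastIdx = integer()))
  # merge adjacent same-label segments
  keep <- c(TRUE, segs$label[-1L] != segs$label[-nrow(segs)])
  grp <- cumsum(keep)
  out <- do.call(rbind, lapply(split(segs, grp), function(g)
    data.frame(start = g$start[1L], end = g$end[nrow(g)],
               label = g$label[1L], nSites = sum(g$nSites),
               firstIdx = g$firstIdx[1L], lastIdx = g$lastIdx[nrow(g)],
               stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}

#' Call crossover intervals from labelled segments
#'
#' One call per adjacent H1/H2 segment pair; the interval runs from the last
#' site of the left segment to the first site of the right segment. A
#' single-label chromosome yields no call (a non-recombinant homologue).
#'
#' @param segments data.frame as returned by [segmentCBS()].
#' @return data.frame(start, end) of breakpoint intervals.
#' @export
callBreakpoints <- function(segments) {
  if (nrow(segments) < 2L)
    return(data.frame(start = numeric(), end = numeric()))
  i <- seq_len(nrow(segments) - 1L)
  sw <- segments$label[i] != segments$label[i + 1L]
  data.frame(start = segments$end[i][sw], end = segments$start[i + 1L][sw])
}

#' Crossover map of a child homologue from a simulated pedigree
#'
#' Convenience wrapper: encodes the match vector against the transmitting
#' parent, segments it, and calls breakpoints per chromosome.
#'
#' @param sim a `pedSim` object.
#' @param child child id.
#' @param role "paternal" or "maternal" homologue.
#' @param minSeg,zStop,minLengthBp passed to [segmentCBS()].
#' @param flipCode optional fraction of codes flipped (noise injection).
#' @param seed seed for noise injection.
#' @return data.frame(child, homologue, chrom, start, end).
#' @export
crossoverMap <- function(sim, child, role = "paternal", minSeg = 20L,
                         zStop = 3, minLengthBp = 5e5, flipCode = 0,
                         seed = 1L) {
  m <- members(sim$pedigree)
  r <- m[m$id == child, ]
  parent <- if (role == "paternal") r$father else r$mother
  hrow <- if (role == "paternal") 1L else 2L
  ph <- sim$hap[[parent]]
  rows <- list()
  for (cn in unique(sim$sites$chrom)) {
    idx <- which(sim$sites$chrom == cn)
    mv <- encodeMatchVector(sim$hap[[child]][hrow, idx], ph[1L, idx],
                            ph[2L, idx], sim$sites$pos[idx])
    code <- mv$code
    if (flipCode > 0 && length(code)) {
      code <- withSeed(childSeed(seed, 21L), {
        fl <- stats::runif(length(code)) < flipCode
        ifelse(fl, 1L - code, code)
      })
    }
    segs <- segmentCBS(code, mv$pos, minSeg = minSeg, zStop = zStop,
                       minLengthBp = minLengthBp)
    bp <- callBreakpoints(segs)
    if (nrow(bp))
      rows[[length(rows) + 1L]] <- data.frame(
        child = child, homologue = role, chrom = cn,
        start = bp$start, end = bp$end, stringsAsFactors = FALSE)
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(child = character(), homologue = character(),
               chrom = character(), start = numeric(), end = numeric())
}

#' Merge crossover maps from independent callers
#'
#' Each reference call is "supported" by an alternate map when that map has a
#' call for the same child and homologue within `windowBp`. `best.range` is
#' the narrowest directly overlapping interval across maps; `min.range` is
#' the sub-interval covered by the largest number of maps. Alternate calls
#' supporting no reference call are returned as unique to their map.
#'
#' @param reference data.frame(child, homologue, chrom, start, end).
#' @param alternates named list of data.frames with the same columns.
#' @param windowBp support window (default 1 Mb).
#' @return list with `merged` (reference calls plus support, best.range and
#'   min.range columns) and `unique` (unsupported alternate calls with a
#'   `map` column).
#' @export
mergeBreakpointMaps <- function(reference, alternates, windowBp = 1e6) {
  ref <- reference
  ref$support <- "reference"
  ref$best.start <- ref$start; ref$best.end <- ref$end
  ref$min.start <- ref$start; ref$min.end <- ref$end
  usedAlt <- lapply(alternates, function(a) rep(FALSE, nrow(a)))
  for (i in seq_len(nrow(ref))) {
    ivs <- data.frame(start = ref$start[i], end = ref$end[i])
    supp <- character()
    for (nm in names(alternates)) {
      a <- alternates[[nm]]
      cand <- which(a$child == ref$child[i] &
                      a$homologue == ref$homologue[i] &
                      a$chrom == ref$chrom[i] &
                      a$start <= ref$end[i] + windowBp &
                      a$end >= ref$start[i] - windowBp)
      if (length(cand)) {
        supp <- c(supp, nm)
        usedAlt[[nm]][cand] <- TRUE
        ov <- which(a$start[cand] <= ref$end[i] & a$end[cand] >= ref$start[i])
        if (length(ov))
          ivs <- rbind(ivs, data.frame(start = a$start[cand][ov],
                                       end = a$end[cand][ov]))
      }
    }
    ref$support[i] <- paste(c("reference", supp), collapse = ",")
    w <- ivs$end - ivs$start
    ref$best.start[i] <- ivs$start[which.min(w)]
    ref$best.end[i] <- ivs$end[which.min(w)]
    # sub-interval of maximal coverage
    ir <- IRanges::IRanges(start = round(ivs$start), end = round(ivs$end))
    cov <- IRanges::coverage(ir)
    mx <- max(S4Vectors::runValue(cov))
    top <- IRanges::reduce(IRanges::IRanges(cov >= mx))
    ref$min.start[i] <- IRanges::start(top)[1L]
    ref$min.end[i] <- IRanges::end(top)[1L]
  }
  uniq <- do.call(rbind, lapply(names(alternates), function(nm) {
    a <- alternates[[nm]][!usedAlt[[nm]], , drop = FALSE]
    if (!nrow(a)) return(NULL)
    a$map <- nm
    a
  }))
  if (is.null(uniq))
    uniq <- data.frame(child = character(), homologue = character(),
                       chrom = character(), start = numeric(),
                       end = numeric(), map = character())
  list(merged = ref, unique = uniq)
}

#' Refine a crossover against aligned parental sequences
#'
#' Works on pre-aligned columns of a child homologue and the two parental
#' haplotypes over the lookup window. Among discriminating columns (where
#' the parental haplotypes differ), the split index minimizing the child's
#' total mismatches to a parental prefix/suffix concatenation localizes the
#' crossover; the refined interval spans the two discriminating columns
#' flanking the optimal split. Children more than 99% identical to a single
#' parental haplotype across discriminating columns are skipped.
#'
#' @param child,parentH1,parentH2 equal-length aligned sequences (character
#'   vectors of single characters, or strings split internally).
#' @param colPos optional positions of the alignment columns (defaults to
#'   1..n).
#' @param identitySkip skip threshold (default 0.99).
#' @return list with `interval` (c(start, end) positions flanking the
#'   refined breakpoint) and `orientation` ("H1H2" or "H2H1"), or NULL when
#'   skipped or fewer than two discriminating columns exist.
#' @export
refineBreakpoint <- function(child, parentH1, parentH2, colPos = NULL,
                             identitySkip = 0.99) {
  toVec <- function(x) if (length(x) == 1L && nchar(x) > 1L)
    strsplit(x, "")[[1L]] else as.character(x)
  ch <- toVec(child); h1 <- toVec(parentH1); h2 <- toVec(parentH2)
  stopifnot(length(ch) == length(h1), length(h1) == length(h2))
  if (is.null(colPos)) colPos <- seq_along(ch)
  disc <- which(h1 != h2)
  if (length(disc) < 2L) return(NULL)
  m1 <- ch[disc] == h1[disc]
  m2 <- ch[disc] == h2[disc]
  if (mean(m1) > identitySkip || mean(m2) > identitySkip) return(NULL)
  n <- length(disc)
  # mismatches of H1-prefix/H2-suffix with split after column k (k = 0..n)
  mis12 <- cumsum(c(0L, !m1)) + rev(cumsum(rev(c(!m2, 0L))))
  mis21 <- cumsum(c(0L, !m2)) + rev(cumsum(rev(c(!m1, 0L))))
  if (min(mis12) <= min(mis21)) {
    k <- which.min(mis12) - 1L; orient <- "H1H2"
  } else {
    k <- which.min(mis21) - 1L; orient <- "H2H1"
  }
  k <- min(max(k, 1L), n - 1L)   # breakpoint between two discriminating cols
  list(interval = c(colPos[disc[k]], colPos[disc[k + 1L]]),
       orientation = orient, mismatches = min(min(mis12), min(mis21)))
}

#' Brute-force split search (oracle for breakpoint refinement)
#'
#' Evaluates every split of the discriminating columns directly; intended as
#' an independent cross-check of [refineBreakpoint()] on small inputs.
#'
#' @inheritParams refineBreakpoint
#' @return same structure as [refineBreakpoint()].
#' @export
refineBreakpointBrute <- function(child, parentH1, parentH2, colPos = NULL,
                                  identitySkip = 0.99) {
  toVec <- function(x) if (length(x) == 1L && nchar(x) > 1L)
    strsplit(x, "")[[1L]] else as.character(x)
  ch <- toVec(child); h1 <- toVec(parentH1); h2 <- toVec(parentH2)
  if (is.null(colPos)) colPos <- seq_along(ch)
  disc <- which(h1 != h2)
  if (length(disc) < 2L) return(NULL)
  m1 <- ch[disc] == h1[disc]; m2 <- ch[disc] == h2[disc]
  if (mean(m1) > identitySkip || mean(m2) > identitySkip) return(NULL)
  n <- length(disc)
  best <- NULL
  for (orient in c("H1H2", "H2H1")) for (k in 0:n) {
    pre <- if (orient == "H1H2") m1 else m2
    suf <- if (orient == "H1H2") m2 else m1
    mis <- sum(!pre[seq_len(k)]) + sum(!suf[seq_len(n - k) + k])
    if (is.null(best) || mis < best$mismatches)
      best <- list(k = k, orientation = orient, mismatches = mis)
  }
  k <- min(max(best$k, 1L), n - 1L)
  list(interval = c(colPos[disc[k]], colPos[disc[k + 1L]]),
       orientation = best$orientation, mismatches = best$mismatches)
}

#' Detect short opposing-haplotype switches (gene-conversion candidates)
#'
#' Within a haplotype segment whose expected parental homologue is known,
#' finds maximal runs of at least two consecutive variants matching the
#' opposing parental haplotype, merges runs separated by at most
#' `mergeGapBp`, and removes regions within `crossoverExclusionBp` of a
#' known crossover or overlapping any supplied exclusion mask.
#'
#' @param pos positions of filtered informative variants.
#' @param matchesExpected logical: does the child allele match the expected
#'   parental homologue at each variant.
#' @param crossovers numeric positions of crossovers on the chromosome.
#' @param masks optional data.frame(start, end) of excluded intervals.
#' @param minRun minimum opposing variants per run.
#' @param mergeGapBp merge distance (default 5 kb).
#' @param crossoverExclusionBp exclusion distance from crossovers (100 kb).
#' @return data.frame(start, end, nVariants) of retained switch regions.
#' @export
detectGeneConversion <- function(pos, matchesExpected, crossovers = numeric(),
                                 masks = NULL, minRun = 2L, mergeGapBp = 5e3,
                                 crossoverExclusionBp = 1e5) {
  runs <- indexRuns(!matchesExpected)
  runs <- runs[runs$value & (runs$end - runs$start + 1L) >= minRun, ,
               drop = FALSE]
  if (!nrow(runs))
    return(data.frame(start = numeric(), end = numeric(),
                      nVariants = integer()))
  reg <- data.frame(start = pos[runs$start], end = pos[runs$end],
                    nVariants = runs$end - runs$start + 1L)
  # merge close regions
  if (nrow(reg) > 1L) {
    grp <- cumsum(c(TRUE, reg$start[-1L] - reg$end[-nrow(reg)] > mergeGapBp))
    reg <- do.call(rbind, lapply(split(reg, grp), function(g)
      data.frame(start = g$start[1L], end = g$end[nrow(g)],
                 nVariants = sum(g$nVariants))))
  }
  if (length(crossovers)) {
    near <- vapply(seq_len(nrow(reg)), function(i)
      any(crossovers >= reg$start[i] - crossoverExclusionBp &
            crossovers <= reg$end[i] + crossoverExclusionBp), TRUE)
    reg <- reg[!near, , drop = FALSE]
  }
  if (!is.null(masks) && nrow(masks) && nrow(reg)) {
    hit <- vapply(seq_len(nrow(reg)), function(i)
      any(masks$start <= reg$end[i] & masks$end >= reg$start[i]), TRUE)
    reg <- reg[!hit, , drop = FALSE]
  }
  rownames(reg) <- NULL
  reg
}

#' Permutation test for telomeric clustering of crossovers
#'
#' Counts crossovers falling in the terminal 5% windows at both ends of each
#' chromosome, separately per parental origin, and compares against a null
#' built from circular per-chromosome shuffles that preserve per-chromosome
#' counts. The empirical p-value is `(1 + #null >= observed) / (nPerm + 1)`.
#'
#' @param breakpoints data.frame(chrom, pos, origin) with origin "paternal"
#'   or "maternal" (midpoints of crossover intervals).
#' @param chromLengths named numeric vector of chromosome lengths.
#' @param nPerm number of shuffles (default 1000).
#' @param terminalFraction window size at each end (default 0.05).
#' @param seed integer seed.
#' @return data.frame(origin, observed, expected, p).
#' @export
telomereEnrichment <- function(breakpoints, chromLengths, nPerm = 1000L,
                               terminalFraction = 0.05, seed = 1L) {
  inTerminal <- function(pos, L)
    pos <= terminalFraction * L | pos >= (1 - terminalFraction) * L
  origins <- c("paternal", "maternal")
  withSeed(seed, {
    out <- lapply(origins, function(org) {
      b <- breakpoints[breakpoints$origin == org, , drop = FALSE]
      if (!nrow(b)) return(data.frame(origin = org, observed = 0L,
                                      expected = NA_real_, p = 1))
      L <- chromLengths[b$chrom]
      obs <- sum(inTerminal(b$pos, L))
      nullCounts <- integer(nPerm)
      for (k in seq_len(nPerm)) {
        shift <- stats::runif(length(unique(b$chrom)))
        names(shift) <- unique(b$chrom)
        newPos <- (b$pos + shift[b$chrom] * L) %% L
        nullCounts[k] <- sum(inTerminal(newPos, L))
      }
      data.frame(origin = org, observed = obs,
                 expected = mean(nullCounts),
                 p = (1 + sum(nullCounts >= obs)) / (nPerm + 1))
    })
    do.call(rbind, out)
  })
}

#' Poisson regression of crossover counts on parental age and sex
#'
#' Fits a log-link Poisson generalized linear model
#' `count ~ age + sex` and reports coefficients, standard errors, Wald
#' p-values and the AIC.
#'
#' @param counts integer crossover counts per meiosis.
#' @param age transmitting parent's age at conception.
#' @param sex transmitting parent's sex ("M"/"F" or factor).
#' @return list with `coefficients` (matrix from `summary.glm`), `aic`, and
#'   the fitted `model`.
#' @export
ageSexGlm <- function(counts, age, sex) {
  if (any(counts != round(counts))) stop("counts must be integers")
  sex <- factor(sex)
  if (any(table(sex) < 3L)) stop("need at least 3 observations per sex")
  fit <- stats::glm(counts ~ age + sex, family = stats::poisson())
  sm <- summary(fit)
  list(coefficients = sm$coefficients, aic = stats::AIC(fit), model = fit)
}
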