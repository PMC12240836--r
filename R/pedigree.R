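# Inheritance-vector inference and pedigree-concordance filtering.
#
# Each meiosis is modelled as a two-state hidden Markov chain over the
# transmitting parent's homologues; the most probable state path (Viterbi)
# segments the transmitted gamete into founder-haplotype blocks, and the
# transitions of that path are the inferred meiotic crossovers. A site-level
# concordance test against the four founder haplotypes (A, B on the paternal
# side, C, D on the maternal side) then separates pedigree-consistent
# variation from genotyping errors and candidate de novo events.

#' Hidden Markov model parameters for inheritance-vector decoding
#'
#' @param transitionRatePerBp per-bp prior probability density of a
#'   recombination between adjacent sites; the transition probability over a
#'   gap of d bp is `1 - exp(-d * rate)`.
#' @param emissionError probability an informative-site observation
#'   contradicts the true inheritance state (genotyping error).
#' @param minSupport minimum consecutive supporting sites used by the greedy
#'   sketch.
#' @return list of validated parameters.
#' @export
hmmParams <- function(transitionRatePerBp = 1.2e-8, emissionError = 0.002,
                      minSupport = 10L) {
  stopifnot(transitionRatePerBp > 0, transitionRatePerBp < 1,
            emissionError > 0, emissionError < 1, minSupport >= 1)
  list(transitionRatePerBp = transitionRatePerBp,
       emissionError = emissionError, minSupport = as.integer(minSupport))
}

#' Remove sites outside the expected per-sample coverage distribution
#'
#' @param genotypes data.frame of per-site records with a depth column per
#'   sample, or a single numeric depth matrix (sites x samples).
#' @param depths numeric matrix (sites x samples) of read depths; if missing,
#'   `genotypes` itself is taken as the depth matrix.
#' @param bounds optional 2 x samples matrix of (lo, hi) per sample; defaults
#'   to mean +/- 3 sd computed per sample.
#' @return logical vector: TRUE for sites whose depth is inside the bounds in
#'   every sample.
#' @examples
#' d <- matrix(30, nrow = 5, ncol = 2); d[3, 1] <- 0
#' filterDepth(d)
#' @export
filterDepth <- function(genotypes, depths = NULL, bounds = NULL) {
  d <- if (is.null(depths)) as.matrix(genotypes) else as.matrix(depths)
  if (is.null(bounds)) {
    mu <- colMeans(d)
    sdv <- apply(d, 2, stats::sd)
    bounds <- rbind(lo = mu - 3 * sdv, hi = mu + 3 * sdv)
  }
  keep <- rep(TRUE, nrow(d))
  for (j in seq_len(ncol(d)))
    keep <- keep & d[, j] >= bounds[1, j] & d[, j] <= bounds[2, j]
  keep
}

#' Greedy sketch of inheritance blocks
#'
#' Emits a block wherever at least `minSupport` consecutive informative sites
#' agree on the same founder-haplotype label; disagreeing or short runs leave
#' unassigned gaps.
#'
#' @param obs vector of per-site labels (any atomic type; NA = uninformative).
#' @param pos numeric positions of the sites (same length).
#' @param minSupport minimum run length (default 10 supporting sites).
#' @return data.frame(start, end, label, nSites) of blocks in position space;
#'   zero rows when no run reaches the threshold.
#' @examples
#' sketchInheritance(rep(c("A", "B"), each = 10), 1:20)
#' @export
sketchInheritance <- function(obs, pos, minSupport = 10L) {
  keep <- !is.na(obs)
  obs <- obs[keep]; pos <- pos[keep]
  empty <- data.frame(start = numeric(), end = numeric(),
                      label = character(), nSites = integer())
  if (!length(obs)) return(empty)
  runs <- indexRuns(obs)
  runs <- runs[runs$end - runs$start + 1L >= minSupport, , drop = FALSE]
  if (!nrow(runs)) return(empty)
  data.frame(start = pos[runs$start], end = pos[runs$end],
             label = as.character(runs$value),
             nSites = runs$end - runs$start + 1L,
             stringsAsFactors = FALSE)
}

#' Viterbi decoding of a two-state inheritance chain
#'
#' Finds the maximum a posteriori sequence of transmitting-parent homologues
#' given per-site observations. Transition probability between adjacent
#' sites is `1 - exp(-d * r)` for inter-site distance d; observations
#' contradict the true state with the emission error probability. Ties in
#' the backtrace are broken toward the previous state, which favours paths
#' with fewer crossovers.
#'
#' @param obs integer vector in \{1, 2, NA\}: per-site evidence for homologue
#'   1 or 2 (NA = missing).
#' @param pos numeric site positions, strictly increasing.
#' @param params [hmmParams()] list.
#' @return list with `path` (decoded state per site), `segments`
#'   (data.frame(start, end, state) with boundaries midway between flanking
#'   informative sites), `breakpoints` (data.frame(start, end) intervals
#'   between the sites flanking each transition), and `logLik` of the path.
#' @examples
#' v <- viterbiInheritance(c(1, 1, 1, 2, 2, 2), c(1, 2, 3, 10, 11, 12) * 1e5)
#' v$breakpoints
#' @export
viterbiInheritance <- function(obs, pos, params = hmmParams()) {
  n <- length(obs)
  if (n == 0L)
    return(list(path = integer(),
                segments = data.frame(start = numeric(), end = numeric(),
                                      state = integer()),
                breakpoints = data.frame(start = numeric(), end = numeric()),
                logLik = 0))
  stopifnot(length(pos) == n, !is.unsorted(pos, strictly = TRUE))
  e <- params$emissionError
  lEmit <- function(o, s) {
    if (is.na(o)) 0 else if (o == s) log1p(-e) else log(e)
  }
  delta <- matrix(-Inf, nrow = n, ncol = 2L)
  psi <- matrix(1L, nrow = n, ncol = 2L)
  delta[1L, ] <- log(0.5) + c(lEmit(obs[1L], 1L), lEmit(obs[1L], 2L))
  for (i in seq_len(n)[-1L]) {
    d <- pos[i] - pos[i - 1L]
    pSwitch <- -expm1(-d * params$transitionRatePerBp)
    lStay <- log1p(-pSwitch); lSw <- log(pSwitch)
    for (s in 1:2) {
      stay <- delta[i - 1L, s] + lStay
      sw <- delta[i - 1L, 3L - s] + lSw
      if (sw > stay) {          # strict: ties stay on the previous state
        delta[i, s] <- sw + lEmit(obs[i], s)
        psi[i, s] <- 3L - s
      } else {
        delta[i, s] <- stay + lEmit(obs[i], s)
        psi[i, s] <- s
      }
    }
  }
  path <- integer(n)
  path[n] <- if (delta[n, 2L] > delta[n, 1L]) 2L else 1L
  if (n > 1L) for (i in (n - 1L):1L) path[i] <- psi[i + 1L, path[i + 1L]]
  runs <- indexRuns(path)
  mid <- function(i, j) (pos[i] + pos[j]) / 2
  segStart <- c(pos[1L], vapply(runs$start[-1L], function(i)
    mid(i - 1L, i), 1))
  segEnd <- c(vapply(runs$end[-nrow(runs)], function(i) mid(i, i + 1L), 1),
              pos[n])
  segments <- data.frame(start = segStart, end = segEnd,
                         state = as.integer(runs$value))
  bps <- if (nrow(runs) > 1L)
    data.frame(start = pos[runs$end[-nrow(runs)]],
               end = pos[runs$start[-1L]])
  else data.frame(start = numeric(), end = numeric())
  list(path = path, segments = segments, breakpoints = bps,
       logLik = max(delta[n, ]))
}

#' Log-likelihood of an explicit state path (for exhaustive cross-checks)
#'
#' Scores a full state sequence under the same model as
#' [viterbiInheritance()].
#'
#' @param states integer vector of states in \{1, 2\}.
#' @param obs,pos,params as in [viterbiInheritance()].
#' @return log-likelihood of the path.
#' @export
pathLogLik <- function(states, obs, pos, params = hmmParams()) {
  e <- params$emissionError
  ll <- log(0.5)
  for (i in seq_along(states)) {
    if (i > 1L) {
      pSwitch <- -expm1(-(pos[i] - pos[i - 1L]) * params$transitionRatePerBp)
      ll <- ll + if (states[i] == states[i - 1L]) log1p(-pSwitch) else log(pSwitch)
    }
    if (!is.na(obs[i]))
      ll <- ll + if (obs[i] == states[i]) log1p(-e) else log(e)
  }
  ll
}

#' Observations for one meiosis from phased parent and child homologue
#'
#' At sites where the transmitting parent is heterozygous, the child's
#' transmitted allele identifies the parental homologue it was copied from.
#'
#' @param childAlleles 0/1 vector: the child homologue transmitted by this
#'   parent.
#' @param parentHap 2 x n matrix of the parent's phased haplotypes.
#' @return integer vector in \{1, 2, NA\}: matching homologue per site (NA
#'   where the parent is homozygous, hence uninformative).
#' @export
meiosisObservations <- function(childAlleles, parentHap) {
  het <- parentHap[1L, ] != parentHap[2L, ]
  obs <- rep(NA_integer_, length(childAlleles))
  obs[het] <- ifelse(childAlleles[het] == parentHap[1L, het], 1L, 2L)
  obs
}

#' Decode inheritance vectors for every G3 meiosis of a simulated pedigree
#'
#' Runs [viterbiInheritance()] per child, homologue and chromosome and
#' returns founder-labelled segments (paternal homologue A/B, maternal C/D).
#'
#' @param sim a `pedSim` object.
#' @param children child ids (default: all children of the G2 couple).
#' @param params [hmmParams()].
#' @param flipNoise optional fraction of informative observations flipped
#'   (injected genotyping error, for robustness studies).
#' @param seed seed used when `flipNoise > 0`.
#' @return list with `vectors` (data.frame child, homologue, chrom, start,
#'   end, label) and `breakpoints` (data.frame child, homologue, chrom,
#'   start, end).
#' @export
inheritanceVectors <- function(sim, children = NULL, params = hmmParams(),
                               flipNoise = 0, seed = 1L) {
  m <- members(sim$pedigree)
  if (is.null(children))
    children <- m$id[!is.na(m$father) & m$father == "F1" & m$mother == "M1"]
  segRows <- list(); bpRows <- list()
  noiseSeed <- childSeed(seed, 11L)
  for (child in children) {
    r <- m[m$id == child, ]
    for (role in c("paternal", "maternal")) {
      parent <- if (role == "paternal") r$father else r$mother
      hrow <- if (role == "paternal") 1L else 2L
      labels <- if (role == "paternal") c("A", "B") else c("C", "D")
      obsAll <- meiosisObservations(sim$hap[[child]][hrow, ], sim$hap[[parent]])
      if (flipNoise > 0) {
        obsAll <- withSeed(noiseSeed, {
          inf <- which(!is.na(obsAll))
          fl <- inf[stats::runif(length(inf)) < flipNoise]
          obsAll[fl] <- 3L - obsAll[fl]
          obsAll
        })
        noiseSeed <- noiseSeed + 1L
      }
      for (cn in unique(sim$sites$chrom)) {
        idx <- which(sim$sites$chrom == cn)
        keep <- idx[!is.na(obsAll[idx])]
        if (!length(keep)) next
        v <- viterbiInheritance(obsAll[keep], sim$sites$pos[keep], params)
        sg <- v$segments
        segRows[[length(segRows) + 1L]] <- data.frame(
          child = child, homologue = role, chrom = cn,
          start = sg$start, end = sg$end, label = labels[sg$state],
          stringsAsFactors = FALSE)
        if (nrow(v$breakpoints))
          bpRows[[length(bpRows) + 1L]] <- data.frame(
            child = child, homologue = role, chrom = cn,
            start = v$breakpoints$start, end = v$breakpoints$end,
            stringsAsFactors = FALSE)
      }
    }
  }
  list(vectors = do.call(rbind, c(segRows, list(NULL))),
       breakpoints = if (length(bpRows)) do.call(rbind, bpRows) else
         data.frame(child = character(), homologue = character(),
                    chrom = character(), start = numeric(), end = numeric()))
}

# label of an inheritance vector at (chrom, pos) for one child/homologue;
# NA when the position is uncovered or falls between segments
ivLabelAt <- function(vectors, child, homologue, chrom, pos) {
  v <- vectors[vectors$child == child & vectors$homologue == homologue &
                 vectors$chrom == chrom, , drop = FALSE]
  hit <- which(v$start <= pos & pos <= v$end)
  if (length(hit) == 1L) v$label[hit] else NA_character_
}

#' Pedigree-concordance filter against founder haplotypes
#'
#' For each site, searches for an assignment of alleles to the four founder
#' haplotypes A, B (father) and C, D (mother) that reproduces the father's,
#' mother's and every child's genotype given the children's inheritance-
#' vector labels at that position. Sites with a consistent assignment pass
#' and are phased by it; sites without one are violations, reported with the
#' set of children whose genotype cannot be explained under the
#' best-fitting assignment (de novo mutations surface this way, as a
#' single-child violation). Sites where any child's label is ambiguous
#' (segment boundary or gap) are routed to "untestable".
#'
#' @param gt named integer vector or 1-row slice: alternate-allele dosage
#'   (0/1/2) for "father", "mother" and each child id.
#' @param labels data.frame(child, paternal, maternal): founder labels at the
#'   site (paternal in A/B, maternal in C/D; NA = ambiguous).
#' @param nAlleles number of distinct alleles at the site (2 = biallelic).
#' @return list with `status` ("pass", "violation" or "untestable"),
#'   `assignment` (named vector of founder-haplotype alleles for passing
#'   sites), `phased` (data.frame sample, hap1, hap2) and `violators`
#'   (character vector of inconsistent samples for failing sites).
#' @examples
#' labels <- data.frame(child = "C1", paternal = "A", maternal = "C")
#' concordanceSite(c(father = 1, mother = 0, C1 = 1), labels)$status
#' @export
concordanceSite <- function(gt, labels, nAlleles = 2L) {
  if (anyNA(labels$paternal) || anyNA(labels$maternal))
    return(list(status = "untestable", assignment = NULL, phased = NULL,
                violators = character()))
  alleles <- seq_len(nAlleles) - 1L
  combos <- as.matrix(expand.grid(A = alleles, B = alleles,
                                  C = alleles, D = alleles))
  samples <- c("father", "mother", labels$child)
  best <- NULL; bestOk <- -1L
  for (k in seq_len(nrow(combos))) {
    a <- combos[k, ]
    expFather <- a[["A"]] + a[["B"]]
    expMother <- a[["C"]] + a[["D"]]
    expKids <- a[labels$paternal] + a[labels$maternal]
    ok <- c(gt[["father"]] == expFather, gt[["mother"]] == expMother,
            gt[labels$child] == expKids)
    nOk <- sum(ok)
    if (nOk > bestOk) { bestOk <- nOk; best <- list(a = a, ok = ok) }
    if (nOk == length(samples)) {
      phased <- data.frame(
        sample = samples,
        hap1 = c(a[["A"]], a[["C"]], unname(a[labels$paternal])),
        hap2 = c(a[["B"]], a[["D"]], unname(a[labels$maternal])),
        stringsAsFactors = FALSE)
      return(list(status = "pass", assignment = a, phased = phased,
                  violators = character()))
    }
  }
  list(status = "violation", assignment = best$a, phased = NULL,
       violators = samples[!best$ok])
}

#' Apply the concordance filter across a genotype matrix
#'
#' @param gtMat integer matrix (sites x samples) of dosages; columns must
#'   include "father"/"mother" aliases via `father`/`mother` arguments.
#' @param ivs inheritance vectors as returned by [inheritanceVectors()].
#' @param sites data.frame(site, chrom, pos) matching `gtMat` rows.
#' @param father,mother column names of the G2 parents.
#' @param children child ids (columns of `gtMat`).
#' @return data.frame(site, status, violators) plus a `phased` attribute:
#'   a list of per-site phased assignments for passing sites.
#' @export
concordanceFilter <- function(gtMat, ivs, sites, father = "F1", mother = "M1",
                              children = NULL) {
  if (is.null(children))
    children <- setdiff(colnames(gtMat), c(father, mother))
  status <- character(nrow(sites))
  violators <- character(nrow(sites))
  phased <- vector("list", nrow(sites))
  v <- ivs$vectors
  for (i in seq_len(nrow(sites))) {
    lab <- data.frame(
      child = children,
      paternal = vapply(children, function(ch)
        ivLabelAt(v, ch, "paternal", sites$chrom[i], sites$pos[i]), ""),
      maternal = vapply(children, function(ch)
        ivLabelAt(v, ch, "maternal", sites$chrom[i], sites$pos[i]), ""),
      stringsAsFactors = FALSE)
    gt <- c(father = unname(gtMat[i, father]),
            mother = unname(gtMat[i, mother]))
    gt <- c(gt, stats::setNames(gtMat[i, children], children))
    res <- concordanceSite(gt, lab)
    status[i] <- res$status
    violators[i] <- paste(res$violators, collapse = ",")
    phased[[i]] <- res$phased
  }
  out <- data.frame(site = sites$site, status = status,
                    violators = violators, stringsAsFactors = FALSE)
  attr(out, "phased") <- phased
  out
}
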