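# Synthetic four-generation pedigree generator with complete ground truth.
#
# The generator emulates the structure of a deeply sequenced four-generation
# family: two founder couples, one G2 couple, a G3 sibship plus two
# marrying-in spouses, and two G4 sibships. Founder haplotypes are abstract
# biallelic markers; meioses carry sex-specific crossover counts with a
# paternal telomeric bias; germline and postzygotic mutations, tandem-repeat
# stepwise mutations and per-platform read evidence are all drawn from the
# configured rates and recorded as truth.

#' Simulate a four-generation pedigree with full ground truth
#'
#' Generates the family graph, founder marker haplotypes, all gametes
#' (recording every crossover), germline and postzygotic de novo mutations,
#' tandem-repeat genotypes and mutations, and returns them together with the
#' truth tables needed to score every downstream inference stage.
#'
#' @param config a [SimConfig-class] object.
#' @return A list of class `"pedSim"` with elements:
#' \describe{
#'   \item{pedigree}{[Pedigree-class] of all members.}
#'   \item{sites}{data.frame of marker sites (site, chrom, pos).}
#'   \item{hap}{named list; per sample a 2 x nSites 0/1 matrix (row 1 =
#'     paternal homologue, row 2 = maternal homologue).}
#'   \item{meioses}{named list keyed "child|role" describing each gamete:
#'     start homologue and crossover positions per chromosome.}
#'   \item{crossoverTruth}{data.frame(meiosis, child, parent, role, chrom, pos).}
#'   \item{dnmTruth}{data.frame of germline and postzygotic mutations with
#'     parent-of-origin, homologue, VAF (PZMs) and variant class.}
#'   \item{dnmCarriers}{data.frame(site, sample, dosage) listing every carrier
#'     of every de novo allele, including transmissions to descendants.}
#'   \item{trCatalog, trGenotypes, trTruth}{tandem-repeat catalog, per-sample
#'     allele lengths, and injected TR mutations.}
#'   \item{config}{the input configuration.}
#' }
#' @examples
#' sim <- simulatePedigree(simConfig(seed = 7L, nChromosomes = 2L,
#'                                   chromLengthBp = 2e6, trCatalogSize = 50L))
#' sim$pedigree
#' head(sim$crossoverTruth)
#' @export
simulatePedigree <- function(config = simConfig()) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  if (any(config@chromLengthBp <= 0)) stop("non-positive chromosome length")
  seed <- config@seed

  ped <- buildFamily(config)
  m <- members(ped)

  sites <- withSeed(childSeed(seed, 1L), drawMarkerSites(config))
  S <- nrow(sites)

  fnd <- founders(ped)
  hap <- vector("list", nrow(m)); names(hap) <- m$id
  withSeed(childSeed(seed, 2L), {
    for (id in fnd)
      hap[[id]] <- matrix(stats::rbinom(2L * S, 1L, 0.5), nrow = 2L)
  })

  # meioses in generation order; record start homologue + crossovers per chrom
  meioses <- list()
  coRows <- list()
  withSeed(childSeed(seed, 3L), {
    ord <- m$id[order(m$generation)]
    for (id in ord) {
      r <- m[m$id == id, ]
      if (is.na(r$father)) next
      gp <- drawGamete(hap[[r$father]], "M", config, sites)
      gm <- drawGamete(hap[[r$mother]], "F", config, sites)
      hap[[id]] <- rbind(gp$alleles, gm$alleles)
      meioses[[paste0(id, "|paternal")]] <-
        list(child = id, parent = r$father, role = "paternal",
             h0 = gp$h0, crossovers = gp$crossovers)
      meioses[[paste0(id, "|maternal")]] <-
        list(child = id, parent = r$mother, role = "maternal",
             h0 = gm$h0, crossovers = gm$crossovers)
      for (role in c("paternal", "maternal")) {
        g <- if (role == "paternal") gp else gm
        if (nrow(g$crossovers))
          coRows[[length(coRows) + 1L]] <- data.frame(
            meiosis = paste0(id, "|", role), child = id,
            parent = if (role == "paternal") r$father else r$mother,
            role = role, chrom = g$crossovers$chrom, pos = g$crossovers$pos,
            stringsAsFactors = FALSE)
      }
    }
  })
  crossoverTruth <- if (length(coRows)) do.call(rbind, coRows) else
    data.frame(meiosis = character(), child = character(), parent = character(),
               role = character(), chrom = character(), pos = numeric())
  rownames(crossoverTruth) <- NULL

  sim <- list(pedigree = ped, sites = sites, hap = hap, meioses = meioses,
              crossoverTruth = crossoverTruth, config = config)
  class(sim) <- "pedSim"

  sim$dnmTruth <- withSeed(childSeed(seed, 4L), drawDnms(sim))
  sim$dnmCarriers <- propagateDnms(sim)

  if (config@trCatalogSize > 0L) {
    tr <- withSeed(childSeed(seed, 5L), drawTrData(sim))
    sim$trCatalog <- tr$catalog
    sim$trGenotypes <- tr$genotypes
    sim$trTruth <- tr$truth
  } else {
    sim$trCatalog <- NULL
  }
  sim
}

#' @export
print.pedSim <- function(x, ...) {
  cat("Synthetic pedigree simulation (seed ", x$config@seed, ")\n", sep = "")
  show(x$pedigree)
  cat("  ", nrow(x$sites), " marker sites; ",
      nrow(x$crossoverTruth), " crossovers; ",
      sum(x$dnmTruth$class == "germline"), " germline DNMs; ",
      sum(x$dnmTruth$class == "postzygotic"), " PZMs",
      if (!is.null(x$trCatalog)) paste0("; ", nrow(x$trTruth), " TR DNMs"),
      "\n", sep = "")
  invisible(x)
}

# --- family graph ------------------------------------------------------------

buildFamily <- function(config) {
  sexes <- function(n, start = "M") {
    rep_len(if (start == "M") c("M", "F") else c("F", "M"), n)
  }
  g1 <- data.frame(
    id = c("GF1", "GM1", "GF2", "GM2"), sex = c("M", "F", "M", "F"),
    generation = 1L, father = NA_character_, mother = NA_character_)
  g2 <- data.frame(
    id = c("F1", "M1"), sex = c("M", "F"), generation = 2L,
    father = c("GF1", "GF2"), mother = c("GM1", "GM2"))
  nG3 <- config@nG3
  g3 <- data.frame(
    id = sprintf("C3_%02d", seq_len(nG3)), sex = sexes(nG3, "M"),
    generation = 3L, father = "F1", mother = "M1")
  sp <- data.frame(
    id = c("SP1", "SP2"),
    sex = ifelse(g3$sex[seq_len(min(2L, nG3))] == "M", "F", "M"),
    generation = 3L, father = NA_character_, mother = NA_character_)
  mk4 <- function(idx, g3row, spid, n) {
    if (n < 1L) return(NULL)
    fa <- if (g3row$sex == "M") g3row$id else spid
    mo <- if (g3row$sex == "M") spid else g3row$id
    data.frame(id = sprintf("C4%s_%02d", idx, seq_len(n)),
               sex = sexes(n, "F"), generation = 4L, father = fa, mother = mo)
  }
  g4 <- rbind(mk4("a", g3[1, ], "SP1", config@nG4a),
              mk4("b", g3[2, ], "SP2", config@nG4b))
  Pedigree(rbind(g1, g2, g3, sp, g4))
}

# --- markers and gametes -----------------------------------------------------

chromNames <- function(config) sprintf("chr%d", seq_len(config@nChromosomes))

drawMarkerSites <- function(config) {
  out <- lapply(seq_len(config@nChromosomes), function(i) {
    L <- config@chromLengthBp[i]
    n <- stats::rpois(1L, config@snvDensity * L)
    pos <- sort(sample.int(as.integer(L), min(n, as.integer(L))))
    data.frame(chrom = sprintf("chr%d", i), pos = pos, stringsAsFactors = FALSE)
  })
  sites <- do.call(rbind, out)
  sites$site <- paste0(sites$chrom, "_", sites$pos)
  sites[, c("site", "chrom", "pos")]
}

# Crossover positions for one meiosis on one chromosome. A configurable
# fraction of paternal crossovers is forced into the terminal 5% windows,
# emulating the male telomeric bias; placement is otherwise uniform.
drawCrossoverPositions <- function(n, L, sexOfParent, config) {
  if (n == 0L) return(numeric())
  pos <- stats::runif(n, 1, L)
  if (sexOfParent == "M" && config@telomereBiasPaternal > 0) {
    biased <- stats::runif(n) < config@telomereBiasPaternal
    nb <- sum(biased)
    if (nb) {
      w <- 0.05 * L
      u <- stats::runif(nb, 0, 2 * w)
      pos[biased] <- ifelse(u < w, u + 1, L - (u - w))
    }
  }
  sort(pmin(pmax(pos, 1), L - 1))
}

drawGamete <- function(parentHap, sexOfParent, config, sites) {
  rate <- if (sexOfParent == "M") config@crossoverRatePaternal else
    config@crossoverRateMaternal
  S <- nrow(sites)
  alleles <- integer(S)
  origin <- integer(S)
  h0 <- integer(config@nChromosomes)
  co <- list()
  for (i in seq_len(config@nChromosomes)) {
    L <- config@chromLengthBp[i]
    cn <- sprintf("chr%d", i)
    idx <- which(sites$chrom == cn)
    n <- stats::rpois(1L, rate)
    pos <- drawCrossoverPositions(n, L, sexOfParent, config)
    h0[i] <- sample(1:2, 1L)
    if (length(idx)) {
      nBefore <- findInterval(sites$pos[idx], pos)
      org <- ifelse(nBefore %% 2L == 0L, h0[i], 3L - h0[i])
      origin[idx] <- org
      alleles[idx] <- parentHap[cbind(org, idx)]
    }
    if (length(pos))
      co[[length(co) + 1L]] <- data.frame(chrom = cn, pos = pos,
                                          stringsAsFactors = FALSE)
  }
  list(alleles = alleles, origin = origin, h0 = h0,
       crossovers = if (length(co)) do.call(rbind, co) else
         data.frame(chrom = character(), pos = numeric()))
}

#' Which parental homologue a gamete carries at an arbitrary position
#'
#' @param meiosis one element of `sim$meioses`.
#' @param chrom chromosome name.
#' @param pos position (bp).
#' @return 1 or 2: the transmitting parent's homologue present at `pos`.
#' @export
gameteOriginAt <- function(meiosis, chrom, pos) {
  i <- as.integer(sub("chr", "", chrom))
  cps <- meiosis$crossovers$pos[meiosis$crossovers$chrom == chrom]
  nBefore <- findInterval(pos, sort(cps))
  ifelse(nBefore %% 2L == 0L, meiosis$h0[i], 3L - meiosis$h0[i])
}

# vectorized gamete origin over mixed chromosomes
gameteOriginVec <- function(meiosis, chrom, pos) {
  out <- integer(length(pos))
  for (cn in unique(chrom)) {
    idx <- chrom == cn
    out[idx] <- gameteOriginAt(meiosis, cn, pos[idx])
  }
  out
}

#' Founder-label inheritance vector truth for a child at marker sites
#'
#' Labels the child's paternal homologue A/B (father's homologue 1/2) and
#' maternal homologue C/D (mother's homologue 1/2) at every marker site.
#'
#' @param sim a `pedSim` object.
#' @param child child id (must have both parents in the pedigree).
#' @return data.frame(site, chrom, pos, paternal, maternal) with labels.
#' @export
trueInheritance <- function(sim, child) {
  mp <- sim$meioses[[paste0(child, "|paternal")]]
  mm <- sim$meioses[[paste0(child, "|maternal")]]
  if (is.null(mp)) stop("child has no recorded meioses: ", child)
  s <- sim$sites
  pat <- mat <- integer(nrow(s))
  for (cn in unique(s$chrom)) {
    idx <- which(s$chrom == cn)
    pat[idx] <- gameteOriginAt(mp, cn, s$pos[idx])
    mat[idx] <- gameteOriginAt(mm, cn, s$pos[idx])
  }
  data.frame(site = s$site, chrom = s$chrom, pos = s$pos,
             paternal = c("A", "B")[pat], maternal = c("C", "D")[mat],
             stringsAsFactors = FALSE)
}

# --- de novo mutations -------------------------------------------------------

#' Draw postzygotic variant allele fractions
#'
#' Two-component Beta mixture scaled to (0, 0.5]: a dominant low-balance
#' component and a minority high-balance tail, reflecting mosaic mutations
#' that arise across a range of embryonic cell generations.
#'
#' @param n number of draws.
#' @param config a [SimConfig-class].
#' @return numeric vector in (0, 0.5].
#' @export
rPzmVaf <- function(n, config = simConfig()) {
  pick <- stats::runif(n) < config@pzmVafMixWeight
  v <- numeric(n)
  v[pick] <- stats::rbeta(sum(pick), config@pzmVafShape1, config@pzmVafShape2)
  v[!pick] <- stats::rbeta(sum(!pick), config@pzmVafShape1b, config@pzmVafShape2b)
  pmin(pmax(v * 0.5, 1e-4), 0.5)
}

drawDnms <- function(sim) {
  config <- sim$config
  m <- members(sim$pedigree)
  kids <- m$id[!is.na(m$father)]
  G <- sum(config@chromLengthBp)
  rows <- list()
  used <- new.env(hash = TRUE)
  for (s in sim$sites$site) assign(s, TRUE, envir = used)
  lens <- config@chromLengthBp
  drawPos <- function() {
    repeat {
      ci <- sample.int(config@nChromosomes, 1L, prob = lens)
      p <- sample.int(as.integer(lens[ci]), 1L)
      key <- sprintf("chr%d_%d", ci, p)
      if (!exists(key, envir = used)) {
        assign(key, TRUE, envir = used)
        return(list(chrom = sprintf("chr%d", ci), pos = p, site = key))
      }
    }
  }
  for (id in kids) {
    nG <- stats::rpois(1L, config@germlineSnvRate * 2 * G)
    nP <- stats::rpois(1L, config@pzmRate * 2 * G)
    if (nG) for (k in seq_len(nG)) {
      loc <- drawPos()
      pat <- stats::runif(1) < config@paternalFraction
      rows[[length(rows) + 1L]] <- data.frame(
        sample = id, site = loc$site, chrom = loc$chrom, pos = loc$pos,
        class = "germline",
        vclass = if (stats::runif(1) < config@indelFraction) "indel" else "SNV",
        parent = if (pat) "paternal" else "maternal",
        homologue = if (pat) 1L else 2L, vaf = NA_real_,
        stringsAsFactors = FALSE)
    }
    if (nP) for (k in seq_len(nP)) {
      loc <- drawPos()
      pat <- stats::runif(1) < 0.5
      rows[[length(rows) + 1L]] <- data.frame(
        sample = id, site = loc$site, chrom = loc$chrom, pos = loc$pos,
        class = "postzygotic",
        vclass = if (stats::runif(1) < config@indelFraction) "indel" else "SNV",
        parent = if (pat) "paternal" else "maternal",
        homologue = if (pat) 1L else 2L,
        vaf = rPzmVaf(1L, config),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(sample = character(), site = character(),
                      chrom = character(), pos = numeric(), class = character(),
                      vclass = character(), parent = character(),
                      homologue = integer(), vaf = numeric()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Propagate each de novo allele to descendants that inherited the mutant
# haplotype segment. Germline alleles transmit deterministically with the
# segment; postzygotic alleles transmit with probability min(1, 2*VAF) given
# the segment (the mosaic fraction of the contributing germ line).
propagateDnms <- function(sim) {
  m <- members(sim$pedigree)
  dn <- sim$dnmTruth
  if (!nrow(dn))
    return(data.frame(site = character(), sample = character(),
                      dosage = integer()))
  rows <- list()
  addCarrier <- function(site, sample)
    rows[[length(rows) + 1L]] <<- data.frame(site = site, sample = sample,
                                             dosage = 1L)
  for (i in seq_len(nrow(dn))) {
    d <- dn[i, ]
    addCarrier(d$site, d$sample)
    # walk descendants: carrier passes the allele iff the transmitted gamete
    # carries the mutant homologue at the site
    frontier <- list(list(id = d$sample, hom = d$homologue,
                          pzm = d$class == "postzygotic", vaf = d$vaf))
    while (length(frontier)) {
      cur <- frontier[[1L]]; frontier <- frontier[-1L]
      kids <- m$id[!is.na(m$father) &
                     (m$father == cur$id | m$mother == cur$id)]
      for (kid in kids) {
        role <- if (m$father[m$id == kid] == cur$id) "paternal" else "maternal"
        mei <- sim$meioses[[paste0(kid, "|", role)]]
        inherited <- gameteOriginAt(mei, d$chrom, d$pos) == cur$hom
        if (!inherited) next
        if (cur$pzm && stats::runif(1) > min(1, 2 * cur$vaf)) next
        addCarrier(d$site, kid)
        frontier[[length(frontier) + 1L]] <-
          list(id = kid, hom = if (role == "paternal") 1L else 2L,
               pzm = FALSE, vaf = NA_real_)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# --- read evidence -----------------------------------------------------------

#' Simulate per-platform read evidence at variant sites
#'
#' For each (site, sample) row, draws platform read counts stratified by
#' allele and base-quality class, with mapping-quality pass flags and, for
#' long-read platforms, per-haplotype tagged counts. Heterozygous germline
#' sites have expected allele balance 0.5; postzygotic sites have expected
#' balance equal to their VAF. Base-calling errors are predominantly assigned
#' to the low-quality class, which is the empirical rationale for counting
#' high- and low-quality bases separately when validating candidate de novo
#' mutations.
#'
#' @param siteTable data.frame with columns site, sample, gt (0, 1 or 2 copies
#'   of the alternate allele), and optionally vaf (postzygotic fraction,
#'   overrides gt = 1 balance) and homologue (1/2, mutant homologue for
#'   haplotype tagging).
#' @param profiles platform profile data.frame (see
#'   [defaultPlatformProfiles()]).
#' @param seed integer seed.
#' @param errLowBqFraction fraction of error reads assigned low base quality.
#' @return data.frame with one row per site/sample/platform: depth, refHq,
#'   altHq, refLq, altLq, mqFail, hap1Alt, hap1Tot, hap2Alt, hap2Tot.
#' @examples
#' ev <- simulateReads(data.frame(site = "chr1_100", sample = "C3_01",
#'                                gt = 1, vaf = NA, homologue = 1), seed = 1)
#' ev[, c("platform", "depth", "altHq", "altLq")]
#' @export
simulateReads <- function(siteTable, profiles = defaultPlatformProfiles(),
                          seed = 1L, errLowBqFraction = 0.9) {
  stopifnot(all(c("site", "sample", "gt") %in% names(siteTable)))
  if (!"vaf" %in% names(siteTable)) siteTable$vaf <- NA_real_
  if (!"homologue" %in% names(siteTable)) siteTable$homologue <- NA_integer_
  withSeed(seed, {
    out <- list()
    for (p in seq_len(nrow(profiles))) {
      pr <- profiles[p, ]
      n <- nrow(siteTable)
      depth <- stats::rpois(n, pr$depth)
      mqPass <- stats::rbinom(n, depth, pr$mqPassRate)
      mqFail <- depth - mqPass
      # haplotype split among MQ-passing reads
      hap1 <- stats::rbinom(n, mqPass, 0.5)
      hap2 <- mqPass - hap1
      # alt probability on the mutant homologue
      mutHom <- ifelse(is.na(siteTable$homologue), 1L, siteTable$homologue)
      pAltMut <- ifelse(siteTable$gt == 2, 1,
                 ifelse(siteTable$gt == 0, 0,
                 ifelse(is.na(siteTable$vaf), 1,
                        pmin(1, 2 * siteTable$vaf))))
      pAltOther <- ifelse(siteTable$gt == 2, 1, 0)
      altMutHap <- stats::rbinom(n, ifelse(mutHom == 1L, hap1, hap2), pAltMut)
      altOthHap <- stats::rbinom(n, ifelse(mutHom == 1L, hap2, hap1), pAltOther)
      hap1Alt <- ifelse(mutHom == 1L, altMutHap, altOthHap)
      hap2Alt <- ifelse(mutHom == 1L, altOthHap, altMutHap)
      alt <- hap1Alt + hap2Alt
      ref <- mqPass - alt
      # sequencing errors flip observed alleles; errors concentrate at
      # low-quality bases
      refToAlt <- stats::rbinom(n, ref, pr$baseError / 3)
      altToRef <- stats::rbinom(n, alt, pr$baseError)
      altObs <- alt - altToRef + refToAlt
      refObs <- ref - refToAlt + altToRef
      trueAlt <- pmax(altObs - refToAlt, 0L)
      altLqTrue <- stats::rbinom(n, trueAlt, pr$lowBqFraction)
      altLqErr <- stats::rbinom(n, refToAlt, errLowBqFraction)
      altLq <- altLqTrue + altLqErr
      altHq <- altObs - altLq
      refLq <- stats::rbinom(n, refObs, pr$lowBqFraction)
      refHq <- refObs - refLq
      long <- isTRUE(pr$longRead)
      out[[p]] <- data.frame(
        site = siteTable$site, sample = siteTable$sample,
        platform = pr$platform, depth = depth, mqFail = mqFail,
        refHq = refHq, altHq = altHq, refLq = refLq, altLq = altLq,
        hap1Alt = if (long) hap1Alt else NA_integer_,
        hap1Tot = if (long) hap1 else NA_integer_,
        hap2Alt = if (long) hap2Alt else NA_integer_,
        hap2Tot = if (long) hap2 else NA_integer_,
        stringsAsFactors = FALSE)
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
  })
}

#' Simulate read-level phasing evidence around a de novo mutation
#'
#' Emulates the read data used to assign a de novo allele to a parental
#' haplotype: long reads covering the mutation also cover flanking
#' informative sites, whose alleles reveal which parental haplotype each
#' read derives from.
#'
#' @param origin "paternal" or "maternal": the true mutant haplotype.
#' @param depth number of reads covering the mutation.
#' @param windowBp size of the informative-site lookup window (total).
#' @param infoSpacingBp mean spacing between candidate flanking SNVs.
#' @param readLengthBp read length.
#' @param errorRate per-base observation error.
#' @param seed integer seed.
#' @return list with `candidates` (data.frame pos, fatherGt, motherGt,
#'   childGt of flanking SNVs), `reads` (data.frame readId, dnmAllele),
#'   and `alleleMat` (reads x candidate-site matrix of observed alleles,
#'   NA where a read does not cover a site).
#' @export
simulateDnmReadSet <- function(origin = "paternal", depth = 20L,
                               windowBp = 80000L, infoSpacingBp = 5000L,
                               readLengthBp = 18000L, errorRate = 0.002,
                               seed = 1L) {
  withSeed(seed, {
    half <- windowBp / 2
    pos <- sort(round(stats::runif(max(2L, stats::rpois(1L, windowBp / infoSpacingBp)),
                                   -half, half)))
    pos <- pos[pos != 0]
    # trio genotypes at flanking SNVs: mixture of informative and
    # uninformative configurations
    cfg <- sample(1:4, length(pos), replace = TRUE)
    fatherGt <- c("0/1", "0/0", "0/1", "1/1")[cfg]
    motherGt <- c("0/0", "0/1", "0/1", "0/0")[cfg]
    childGt <- rep("0/1", length(pos))
    # child's haplotype alleles at each flanking site (paternal, maternal)
    patAl <- c(1L, 0L, NA, 1L)[cfg]
    matAl <- c(0L, 1L, NA, 0L)[cfg]
    amb <- is.na(patAl)  # both parents het: allele origin ambiguous
    patAl[amb] <- sample(0:1, sum(amb), replace = TRUE)
    matAl[amb] <- 1L - patAl[amb]
    starts <- round(stats::runif(depth, -readLengthBp + 1, 0))
    hapIsPat <- stats::runif(depth) < 0.5
    mutHapPat <- origin == "paternal"
    dnmAllele <- as.integer(hapIsPat == mutHapPat)
    flip <- stats::runif(depth) < errorRate
    dnmAllele[flip] <- 1L - dnmAllele[flip]
    alleleMat <- matrix(NA_integer_, nrow = depth, ncol = length(pos))
    for (r in seq_len(depth)) {
      cov <- pos >= starts[r] & pos < starts[r] + readLengthBp
      truth <- ifelse(hapIsPat[r], patAl[cov], matAl[cov])
      err <- stats::runif(sum(cov)) < errorRate
      truth[err] <- 1L - truth[err]
      alleleMat[r, cov] <- truth
    }
    list(
      candidates = data.frame(pos = pos, fatherGt = fatherGt,
                              motherGt = motherGt, childGt = childGt,
                              stringsAsFactors = FALSE),
      reads = data.frame(readId = sprintf("r%03d", seq_len(depth)),
                         dnmAllele = dnmAllele, stringsAsFactors = FALSE),
      alleleMat = alleleMat,
      truthHapIsPat = hapIsPat)
  })
}

# --- tandem repeats ----------------------------------------------------------

drawTrData <- function(sim) {
  config <- sim$config
  nL <- config@trCatalogSize
  if (nL < 1L) stop("empty TR catalog")
  m <- members(sim$pedigree)
  lens <- config@chromLengthBp
  ci <- sample.int(config@nChromosomes, nL, replace = TRUE, prob = lens)
  start <- vapply(ci, function(i) sample.int(as.integer(lens[i] - 2e4), 1L), 1L)
  nMotif <- sample(1:2, nL, replace = TRUE, prob = c(0.8, 0.2))
  motifs <- vapply(seq_len(nL), function(i) {
    ml <- sample(config@trMotifLengths, nMotif[i], replace = TRUE,
                 prob = config@trMotifWeights)
    paste(vapply(ml, randomMotif, ""), collapse = ",")
  }, "")
  minMotif <- vapply(strsplit(motifs, ","), function(x) min(nchar(x)), 1L)
  units <- pmax(ceiling(10 / minMotif), 3L) + stats::rpois(nL, 8)
  refLen <- pmin(minMotif * units, 10000L)
  catalog <- data.frame(
    locus = sprintf("TR%05d", seq_len(nL)),
    chrom = sprintf("chr%d", ci), start = start, end = start + refLen,
    motifs = motifs, refLen = refLen, minMotif = minMotif,
    stringsAsFactors = FALSE)

  # founder allele lengths: most loci are monomorphic at the reference
  # length; a minority are polymorphic, with founder alleles a few motif
  # units either side of the reference
  isPoly <- stats::runif(nL) < 0.3
  als <- list()
  fnd <- m$id[is.na(m$father)]
  for (id in fnd) {
    devs <- matrix(sample(-2:6, 2L * nL, replace = TRUE,
                          prob = c(2, 4, 10, 6, 4, 3, 2, 1, 1)), nrow = 2L)
    devs[, !isPoly] <- 0L
    al <- pmax(rep(refLen, each = 2L) + as.vector(devs) * rep(minMotif, each = 2L), 0L)
    als[[id]] <- matrix(al, nrow = 2L)
  }

  truthRows <- list()
  ord <- m$id[order(m$generation)]
  for (id in ord) {
    r <- m[m$id == id, ]
    if (is.na(r$father)) next
    # transmitted alleles for both gametes first, then mutations: a mutant
    # allele colliding with a parental allele length is undetectable by
    # construction (the de novo filters require an expansion or contraction
    # relative to the parental alleles), so steps are redrawn on collision
    al <- matrix(0L, nrow = 2L, ncol = nL)
    for (role in c("paternal", "maternal")) {
      parent <- if (role == "paternal") r$father else r$mother
      mei <- sim$meioses[[paste0(id, "|", role)]]
      homs <- gameteOriginVec(mei, catalog$chrom, catalog$start)
      al[if (role == "paternal") 1L else 2L, ] <-
        als[[parent]][cbind(homs, seq_len(nL))]
    }
    parentAls <- rbind(als[[r$father]], als[[r$mother]])
    for (role in c("paternal", "maternal")) {
      hrow <- if (role == "paternal") 1L else 2L
      mut <- which(stats::runif(nL) < config@trMutationRate)
      for (j in mut) {
        trans <- al[hrow, j]
        newAl <- NA_integer_
        for (try in 1:20) {
          step <- sample(config@trStepSizes, 1L, prob = config@trStepWeights)
          cand <- trans + step * catalog$minMotif[j]
          if (cand >= 0L && !cand %in% parentAls[, j]) { newAl <- cand; break }
        }
        if (is.na(newAl)) next
        truthRows[[length(truthRows) + 1L]] <- data.frame(
          child = id, locus = catalog$locus[j], denovoAl = newAl,
          parent = role, parentalAl = trans, sizeBp = newAl - trans,
          homologue = hrow, stringsAsFactors = FALSE)
        al[hrow, j] <- newAl
      }
    }
    als[[id]] <- al
  }
  genotypes <- do.call(rbind, lapply(names(als), function(id)
    data.frame(sample = id, locus = catalog$locus,
               al1 = als[[id]][1L, ], al2 = als[[id]][2L, ],
               stringsAsFactors = FALSE)))
  truth <- if (length(truthRows)) do.call(rbind, truthRows) else
    data.frame(child = character(), locus = character(), denovoAl = integer(),
               parent = character(), parentalAl = integer(), sizeBp = integer(),
               homologue = integer())
  rownames(truth) <- NULL
  list(catalog = catalog, genotypes = genotypes, truth = truth)
}

randomMotif <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

#' Simulate read-level allele-length observations at a tandem-repeat locus
#'
#' Long reads report the true allele length exactly; short reads span the
#' locus only when the allele plus flanks fits within the read length, and
#' mis-report the length by one motif unit with the configured stutter rate.
#' Each read carries a CIGAR string whose net insertion/deletion over the
#' locus reconstructs the simulated length difference from the reference.
#'
#' @param locus one row of a TR catalog (needs refLen, minMotif).
#' @param als length-2 integer vector of the individual's allele lengths (bp).
#' @param platform one row of a platform profile data.frame.
#' @param stutterRate probability a short read mis-reports by one motif.
#' @param flankBp flanking bases a short read needs on each side to span.
#' @param seed integer seed.
#' @return data.frame(readId, haplotype, al, cigar, alnStart, mq, spanning).
#'   `al` is the observed allele length; non-spanning short reads are
#'   reported with `spanning = FALSE` and NA length.
#' @export
simulateTrReads <- function(locus, als, platform, stutterRate = 0.05,
                            flankBp = 20L, seed = 1L) {
  if (locus$minMotif < 1L) stop("motif length 0")
  if (any(als < 0)) stop("allele lengths must be >= 0")
  withSeed(seed, {
    depth <- stats::rpois(1L, platform$depth)
    if (depth == 0L)
      return(data.frame(readId = character(), haplotype = integer(),
                        al = integer(), cigar = character(),
                        alnStart = numeric(), mq = integer(),
                        spanning = logical()))
    hapl <- sample(1:2, depth, replace = TRUE)
    trueAl <- als[hapl]
    long <- isTRUE(platform$longRead)
    obs <- trueAl
    if (!long) {
      st <- stats::runif(depth) < stutterRate
      obs[st] <- pmax(obs[st] +
        sample(c(-1L, 1L), sum(st), replace = TRUE) * locus$minMotif, 0L)
    }
    spanning <- if (long) rep(TRUE, depth) else
      (obs + 2L * flankBp) <= platform$readLength
    net <- obs - locus$refLen
    alnStart <- locus$start - flankBp
    cigar <- vapply(seq_len(depth), function(r) {
      if (!spanning[r]) return(NA_character_)
      d <- net[r]
      if (d == 0) sprintf("%dM", locus$refLen + 2L * flankBp)
      else if (d > 0)
        sprintf("%dM%dI%dM", flankBp + ceiling(locus$refLen / 2), d,
                locus$refLen - ceiling(locus$refLen / 2) + flankBp)
      else
        sprintf("%dM%dD%dM", flankBp + ceiling((locus$refLen + d) / 2), -d,
                locus$refLen - ceiling((locus$refLen + d) / 2) + flankBp)
    }, "")
    data.frame(readId = sprintf("t%03d", seq_len(depth)), haplotype = hapl,
               al = ifelse(spanning, obs, NA_integer_), cigar = cigar,
               alnStart = alnStart, mq = 60L, spanning = spanning,
               stringsAsFactors = FALSE)
  })
}

#' Simulate haploid transmissions of a male-specific region
#'
#' Draws per-transmission de novo counts for a haploid region passed father
#' to son (for example the male-specific Y), for rate-recovery studies.
#'
#' @param n number of transmissions.
#' @param lengthBp accessible haploid length per transmission.
#' @param rate mutations per bp per generation.
#' @param seed integer seed.
#' @return data.frame(transmission, count, exposureBp).
#' @export
simulateHaploidTransmissions <- function(n = 5L, lengthBp = 48.8e6,
                                         rate = 1.99e-7, seed = 1L) {
  withSeed(seed, data.frame(
    transmission = sprintf("Y%02d", seq_len(n)),
    count = stats::rpois(n, rate * lengthBp),
    exposureBp = lengthBp))
}

#' Marker genotype dosage matrix
#'
#' @param sim a `pedSim` object.
#' @return integer matrix (marker sites x samples) of alternate-allele counts.
#' @export
genotypeMatrix <- function(sim) {
  ids <- members(sim$pedigree)$id
  g <- vapply(ids, function(id) sim$hap[[id]][1L, ] + sim$hap[[id]][2L, ],
              integer(nrow(sim$sites)))
  rownames(g) <- sim$sites$site
  g
}
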