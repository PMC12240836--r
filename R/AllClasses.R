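#' @import methods
NULL

#' Simulation configuration for the synthetic four-generation pedigree
#'
#' A validated container for every tunable of the synthetic-data generator.
#' Defaults reproduce the study conditions of a deeply sequenced
#' four-generation family: a germline single-nucleotide de novo mutation
#' (DNM) rate of 1.17e-8 per bp per generation with 81.4% of mutations
#' arising on the paternal gamete, a postzygotic mutation (PZM) rate of
#' 2.04e-9 per bp per generation with variant allele fraction below 0.5,
#' sex-specific crossover counts with a paternal telomeric bias, and a
#' tandem-repeat (TR) stepwise mutation rate of 4.74e-6 per locus per
#' haplotype per generation.
#'
#' @slot seed integer root seed; all child streams derive from it.
#' @slot nChromosomes number of autosomes simulated.
#' @slot chromLengthBp length of each chromosome in bp.
#' @slot snvDensity heterozygous marker density in founders (sites per bp).
#' @slot germlineSnvRate germline DNMs per bp per generation.
#' @slot indelFraction fraction of germline DNMs tagged as indels.
#' @slot paternalFraction probability a germline DNM arises on the paternal
#'   gamete.
#' @slot pzmRate postzygotic mutations per bp per generation.
#' @slot pzmVafShape1,pzmVafShape2,pzmVafShape1b,pzmVafShape2b,pzmVafMixWeight
#'   parameters of the two-component Beta mixture (scaled to (0, 0.5])
#'   for PZM variant allele fraction.
#' @slot crossoverRateMaternal,crossoverRatePaternal expected crossovers per
#'   chromosome per meiosis.
#' @slot telomereBiasPaternal fraction of paternal crossovers forced into the
#'   terminal 5% windows of the chromosome.
#' @slot platformProfiles data.frame with columns platform, depth, baseError,
#'   lowBqFraction, mqPassRate.
#' @slot trCatalogSize number of TR loci in the synthetic catalog.
#' @slot trMotifLengths,trMotifWeights motif-length distribution (bp, 1-2000).
#' @slot trMutationRate TR mutations per locus per haplotype per generation.
#' @slot trStepSizes,trStepWeights distribution of expansion/contraction step
#'   sizes in motif units (signed).
#' @slot stutterRateShortRead probability a short read mis-reports an allele
#'   length by one motif unit.
#' @slot nG3,nG4a,nG4b family sizes: G3 sibship and the two G4 sibships.
#'
#' @export
setClass("SimConfig", representation(
  seed = "integer",
  nChromosomes = "integer",
  chromLengthBp = "numeric",
  snvDensity = "numeric",
  germlineSnvRate = "numeric",
  indelFraction = "numeric",
  paternalFraction = "numeric",
  pzmRate = "numeric",
  pzmVafShape1 = "numeric",
  pzmVafShape2 = "numeric",
  pzmVafShape1b = "numeric",
  pzmVafShape2b = "numeric",
  pzmVafMixWeight = "numeric",
  crossoverRateMaternal = "numeric",
  crossoverRatePaternal = "numeric",
  telomereBiasPaternal = "numeric",
  platformProfiles = "data.frame",
  trCatalogSize = "integer",
  trMotifLengths = "integer",
  trMotifWeights = "numeric",
  trMutationRate = "numeric",
  trStepSizes = "integer",
  trStepWeights = "numeric",
  stutterRateShortRead = "numeric",
  nG3 = "integer",
  nG4a = "integer",
  nG4b = "integer"
))

setValidity("SimConfig", function(object) {
  msg <- character()
  rates <- c(
    snvDensity = object@snvDensity,
    germlineSnvRate = object@germlineSnvRate,
    pzmRate = object@pzmRate,
    trMutationRate = object@trMutationRate,
    crossoverRateMaternal = object@crossoverRateMaternal,
    crossoverRatePaternal = object@crossoverRatePaternal
  )
  if (any(rates < 0))
    msg <- c(msg, paste("negative rate:", paste(names(rates)[rates < 0], collapse = ", ")))
  if (object@paternalFraction < 0 || object@paternalFraction > 1)
    msg <- c(msg, "paternalFraction must lie in [0, 1]")
  if (object@indelFraction < 0 || object@indelFraction > 1)
    msg <- c(msg, "indelFraction must lie in [0, 1]")
  if (object@telomereBiasPaternal < 0 || object@telomereBiasPaternal > 1)
    msg <- c(msg, "telomereBiasPaternal must lie in [0, 1]")
  if (any(object@chromLengthBp <= 0))
    msg <- c(msg, "chromosome lengths must be positive")
  if (object@nChromosomes < 1L)
    msg <- c(msg, "need at least one chromosome")
  need <- c("platform", "depth", "baseError", "lowBqFraction", "mqPassRate", "readLength")
  if (!all(need %in% names(object@platformProfiles)))
    msg <- c(msg, paste("platformProfiles must have columns:", paste(need, collapse = ", ")))
  if (any(object@trMotifLengths < 1L) || any(object@trMotifLengths > 2000L))
    msg <- c(msg, "TR motif lengths must lie in [1, 2000]")
  if (any(object@trStepSizes == 0L))
    msg <- c(msg, "TR step sizes must be non-zero (an event is an expansion or contraction)")
  if (object@stutterRateShortRead < 0 || object@stutterRateShortRead > 1)
    msg <- c(msg, "stutterRateShortRead must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Construct a simulation configuration
#'
#' See [SimConfig-class] for the meaning of every field. Defaults are the
#' study conditions; pass overrides by name.
#'
#' @param seed integer root seed.
#' @param nChromosomes,chromLengthBp genome layout.
#' @param snvDensity founder heterozygous-marker density per bp.
#' @param germlineSnvRate,indelFraction,paternalFraction germline DNM model.
#' @param pzmRate postzygotic mutation rate per bp per generation.
#' @param pzmVafShape1,pzmVafShape2,pzmVafShape1b,pzmVafShape2b,pzmVafMixWeight
#'   Beta-mixture VAF model on (0, 0.5].
#' @param crossoverRateMaternal,crossoverRatePaternal expected crossovers per
#'   chromosome.
#' @param telomereBiasPaternal fraction of paternal crossovers placed in the
#'   terminal 5% windows.
#' @param platformProfiles per-platform depth/error profile data.frame.
#' @param trCatalogSize,trMotifLengths,trMotifWeights,trMutationRate,trStepSizes,trStepWeights,stutterRateShortRead
#'   tandem-repeat model.
#' @param nG3,nG4a,nG4b sibship sizes (defaults give the canonical 28-member
#'   pedigree: 4 founders, 2 G2, 8 G3 + 2 spouses, 12 G4).
#' @return A validated [SimConfig-class] object.
#' @examples
#' cfg <- simConfig(seed = 1L, nChromosomes = 2L, chromLengthBp = 5e6)
#' cfg
#' @export
simConfig <- function(seed = 1L,
                      nChromosomes = 4L,
                      chromLengthBp = 1e7,
                      snvDensity = 1e-4,
                      germlineSnvRate = 1.17e-8,
                      indelFraction = 0.088,
                      paternalFraction = 0.814,
                      pzmRate = 2.04e-9,
                      pzmVafShape1 = 2, pzmVafShape2 = 6,
                      pzmVafShape1b = 8, pzmVafShape2b = 2,
                      pzmVafMixWeight = 0.85,
                      crossoverRateMaternal = 1.4,
                      crossoverRatePaternal = 1.0,
                      telomereBiasPaternal = 0.5,
                      platformProfiles = defaultPlatformProfiles(),
                      trCatalogSize = 2000L,
                      trMotifLengths = c(1L, 2L, 3L, 4L, 5L, 6L, 10L, 21L, 50L),
                      trMotifWeights = c(30, 25, 12, 10, 6, 5, 6, 4, 2),
                      trMutationRate = 4.74e-6,
                      trStepSizes = c(-3L, -2L, -1L, 1L, 2L, 3L),
                      trStepWeights = c(1, 3, 10, 10, 3, 1),
                      stutterRateShortRead = 0.05,
                      nG3 = 8L, nG4a = 7L, nG4b = 5L) {
  chromLengthBp <- rep_len(as.numeric(chromLengthBp), nChromosomes)
  new("SimConfig",
    seed = as.integer(seed), nChromosomes = as.integer(nChromosomes),
    chromLengthBp = chromLengthBp, snvDensity = snvDensity,
    germlineSnvRate = germlineSnvRate, indelFraction = indelFraction,
    paternalFraction = paternalFraction, pzmRate = pzmRate,
    pzmVafShape1 = pzmVafShape1, pzmVafShape2 = pzmVafShape2,
    pzmVafShape1b = pzmVafShape1b, pzmVafShape2b = pzmVafShape2b,
    pzmVafMixWeight = pzmVafMixWeight,
    crossoverRateMaternal = crossoverRateMaternal,
    crossoverRatePaternal = crossoverRatePaternal,
    telomereBiasPaternal = telomereBiasPaternal,
    platformProfiles = platformProfiles,
    trCatalogSize = as.integer(trCatalogSize),
    trMotifLengths = as.integer(trMotifLengths),
    trMotifWeights = as.numeric(trMotifWeights),
    trMutationRate = trMutationRate,
    trStepSizes = as.integer(trStepSizes),
    trStepWeights = as.numeric(trStepWeights),
    stutterRateShortRead = stutterRateShortRead,
    nG3 = as.integer(nG3), nG4a = as.integer(nG4a), nG4b = as.integer(nG4b))
}

#' Default per-platform sequencing profiles
#'
#' One long-read platform pair (HiFi, ONT) and two short-read platforms
#' (SRS-A, SRS-B), with mean depth, base-error rate, fraction of bases below
#' base quality 20, mapping-quality pass rate, and read length.
#'
#' @return data.frame with one row per platform.
#' @export
defaultPlatformProfiles <- function() {
  data.frame(
    platform = c("HiFi", "ONT", "SRS-A", "SRS-B"),
    depth = c(30, 30, 35, 35),
    baseError = c(0.002, 0.005, 0.002, 0.002),
    lowBqFraction = c(0.02, 0.10, 0.05, 0.05),
    mqPassRate = c(0.98, 0.97, 0.95, 0.95),
    readLength = c(18000L, 30000L, 150L, 150L),
    longRead = c(TRUE, TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
}

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig (seed ", object@seed, ")\n", sep = "")
  cat("  genome: ", object@nChromosomes, " chromosomes, ",
      format(sum(object@chromLengthBp), big.mark = ","), " bp\n", sep = "")
  cat("  germline SNV rate ", format(object@germlineSnvRate),
      " /bp/gen (paternal fraction ", object@paternalFraction, ")\n", sep = "")
  cat("  PZM rate ", format(object@pzmRate), " /bp/gen\n", sep = "")
  cat("  crossovers/chrom: maternal ", object@crossoverRateMaternal,
      ", paternal ", object@crossoverRatePaternal,
      " (telomere bias ", object@telomereBiasPaternal, ")\n", sep = "")
  cat("  TR catalog: ", object@trCatalogSize, " loci, mutation rate ",
      format(object@trMutationRate), " /locus/haplotype/gen\n", sep = "")
  cat("  platforms: ", paste(object@platformProfiles$platform, collapse = ", "),
      "\n", sep = "")
})

#' Four-generation pedigree structure
#'
#' Directed family graph. One row per individual with sex, generation, and
#' parental identifiers (NA for founders and marrying-in spouses).
#'
#' @slot members data.frame with columns id, sex ("M"/"F"), generation
#'   (integer), father, mother (character or NA).
#' @export
setClass("Pedigree", representation(members = "data.frame"))

setValidity("Pedigree", function(object) {
  m <- object@members
  msg <- character()
  need <- c("id", "sex", "generation", "father", "mother")
  if (!all(need %in% names(m)))
    return(paste("members needs columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(m$id)) msg <- c(msg, "duplicate individual ids")
  if (!all(m$sex %in% c("M", "F"))) msg <- c(msg, "sex must be 'M' or 'F'")
  half <- xor(is.na(m$father), is.na(m$mother))
  if (any(half)) msg <- c(msg, "individuals must have both parents or neither")
  known <- !is.na(m$father)
  if (any(known & !(m$father %in% m$id & m$mother %in% m$id)))
    msg <- c(msg, "parent ids must be present in the pedigree")
  # acyclicity: generation must strictly increase parent -> child
  if (any(known)) {
    gf <- m$generation[match(m$father[known], m$id)]
    gm <- m$generation[match(m$mother[known], m$id)]
    if (any(gf >= m$generation[known] | gm >= m$generation[known]))
      msg <- c(msg, "parents must belong to an earlier generation (acyclic)")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a Pedigree from a member table
#' @param members data.frame with columns id, sex, generation, father, mother.
#' @return A [Pedigree-class] object.
#' @export
Pedigree <- function(members) {
  members$id <- as.character(members$id)
  members$father <- as.character(members$father)
  members$mother <- as.character(members$mother)
  new("Pedigree", members = members)
}

setMethod("show", "Pedigree", function(object) {
  m <- object@members
  cat("Pedigree with ", nrow(m), " members across ",
      length(unique(m$generation)), " generations\n", sep = "")
  tab <- table(m$generation)
  cat("  ", paste(sprintf("G%s: %d", names(tab), as.integer(tab)),
                  collapse = ", "), "\n", sep = "")
})

#' @describeIn Pedigree member table accessor
#' @param x a Pedigree
#' @return `members()` returns the member data.frame.
#' @export
members <- function(x) x@members

#' Founders of a pedigree
#' @param x a Pedigree
#' @return character vector of ids with no recorded parents.
#' @export
founders <- function(x) {
  m <- members(x)
  m$id[is.na(m$father)]
}

#' Children of a given couple
#' @param x a Pedigree
#' @param father,mother parental ids
#' @return character vector of offspring ids.
#' @export
offspringOf <- function(x, father, mother) {
  m <- members(x)
  m$id[!is.na(m$father) & m$father == father & m$mother == mother]
}
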