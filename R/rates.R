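# Callable-genome determination and mutation-rate estimation.
#
# Rates are counts over haploid-adjusted exposure: autosomal germline rates
# divide de novo counts by twice the callable base pairs; tandem-repeat
# rates divide de novo allele counts by callable loci and then by two for a
# per-haplotype rate. Confidence intervals are exact Poisson intervals from
# chi-squared quantiles.

#' Callable-site mask from trio genotypes and read classes
#'
#' A site is callable when both parents are homozygous reference and every
#' trio member has at least one mapping-quality-passing read with a
#' high-quality base call. On male sex chromosomes only the relevant parent
#' is compared and the homozygous-reference requirement on parents is
#' dropped.
#'
#' @param fatherGt,motherGt per-site parental dosages (0/1/2).
#' @param hqReadsChild,hqReadsFather,hqReadsMother per-site counts of
#'   MQ-passing, high-base-quality reads.
#' @param mode "autosome" (default), "maleX" (compare mother only) or
#'   "maleY" (compare father only).
#' @return logical vector: callable per site.
#' @export
callableSites <- function(fatherGt, motherGt, hqReadsChild, hqReadsFather,
                          hqReadsMother, mode = c("autosome", "maleX",
                                                  "maleY")) {
  mode <- match.arg(mode)
  covered <- switch(mode,
    autosome = hqReadsChild >= 1L & hqReadsFather >= 1L & hqReadsMother >= 1L,
    maleX = hqReadsChild >= 1L & hqReadsMother >= 1L,
    maleY = hqReadsChild >= 1L & hqReadsFather >= 1L)
  gtOk <- switch(mode,
    autosome = fatherGt == 0L & motherGt == 0L,
    maleX = TRUE, maleY = TRUE)
  covered & gtOk
}

#' Exact Poisson confidence interval for a rate
#'
#' Chi-squared formulation: the lower bound is `qchisq(alpha/2, 2k) / 2`
#' (zero when k = 0) and the upper bound `qchisq(1 - alpha/2, 2k + 2) / 2`,
#' both divided by the exposure.
#'
#' @param k observed count (non-negative integer).
#' @param exposure exposure (bp, loci, ...); must be positive.
#' @param alpha 1 - confidence level (default 0.05).
#' @return named numeric c(lo, hi).
#' @examples
#' poissonCI(4, 1)   # (1.0899, 10.2416)
#' @export
poissonCI <- function(k, exposure, alpha = 0.05) {
  stopifnot(k >= 0, k == round(k))
  if (exposure <= 0) stop("exposure must be positive")
  lo <- if (k == 0) 0 else stats::qchisq(alpha / 2, 2 * k) / 2
  hi <- stats::qchisq(1 - alpha / 2, 2 * k + 2) / 2
  c(lo = lo / exposure, hi = hi / exposure)
}

#' Mutation-rate estimate with exact Poisson confidence interval
#'
#' @param count de novo count.
#' @param exposureBp callable base pairs (per-site exposure before ploidy
#'   adjustment).
#' @param ploidy haploid copies per callable site (2 for autosomes, 1 for
#'   haploid transmissions).
#' @param alpha CI level complement (default 0.05).
#' @param stratum label carried through to reports.
#' @return data.frame(stratum, count, exposure, rate, ciLo, ciHi).
#' @examples
#' snvRate(62, 2.66e9)   # about 1.17e-8
#' @export
snvRate <- function(count, exposureBp, ploidy = 2, alpha = 0.05,
                    stratum = "autosomal") {
  exposure <- ploidy * exposureBp
  if (exposure <= 0) stop("zero exposure")
  ci <- poissonCI(count, exposure, alpha)
  data.frame(stratum = stratum, count = count, exposure = exposure,
             rate = count / exposure, ciLo = ci[["lo"]], ciHi = ci[["hi"]],
             stringsAsFactors = FALSE)
}

#' Sex-chromosome exposure for rate estimation
#'
#' Female X exposure is twice the callable X base pairs; male exposure is
#' the sum of callable X and callable Y base pairs.
#'
#' @param sex "M" or "F".
#' @param callableX,callableY callable base pairs.
#' @return exposure in haploid base pairs.
#' @export
sexChromosomeExposure <- function(sex, callableX, callableY = 0) {
  if (sex == "F") 2 * callableX else callableX + callableY
}

#' Feature-stratified rates and per-sample tests against the autosomal rate
#'
#' Computes, per sample, the rate inside the feature (count in feature over
#' twice the callable base pairs in the feature) and compares the per-sample
#' feature rates with the per-sample autosomal rates by a paired two-sided
#' t-test.
#'
#' @param featureCounts,featureExposureBp per-sample counts and callable bp
#'   within the feature.
#' @param autosomalCounts,autosomalExposureBp per-sample genome-wide counts
#'   and callable bp.
#' @param ploidy haploid copies (default 2).
#' @param stratum label.
#' @return list with `pooled` (pooled rate estimate with CI), `enrichment`
#'   (pooled feature rate over pooled autosomal rate), and `pValue` from the
#'   paired t-test.
#' @export
featureRate <- function(featureCounts, featureExposureBp,
                        autosomalCounts, autosomalExposureBp,
                        ploidy = 2, stratum = "feature") {
  stopifnot(length(featureCounts) == length(autosomalCounts),
            length(featureCounts) >= 2L)
  if (all(featureExposureBp <= 0)) stop("empty feature overlap")
  fr <- featureCounts / (ploidy * featureExposureBp)
  ar <- autosomalCounts / (ploidy * autosomalExposureBp)
  pooled <- snvRate(sum(featureCounts), sum(featureExposureBp),
                    ploidy = ploidy, stratum = stratum)
  d <- fr - ar
  p <- if (stats::sd(d) == 0) 1 else stats::t.test(fr, ar, paired = TRUE)$p.value
  list(pooled = pooled,
       enrichment = pooled$rate /
         (sum(autosomalCounts) / (ploidy * sum(autosomalExposureBp))),
       perSampleFeature = fr, perSampleAutosomal = ar, pValue = p)
}

#' Tandem-repeat de novo mutation rate per locus per haplotype
#'
#' Divides the de novo allele count by the number of callable loci (trio
#' spanning depth at least 10 at the locus) and by two to express the rate
#' per locus per haplotype per generation, with an exact Poisson CI.
#'
#' @param count de novo TR allele count.
#' @param callableLoci number of callable loci.
#' @param stratum label.
#' @param alpha CI level complement.
#' @return data.frame(stratum, count, exposure, rate, ciLo, ciHi); exposure
#'   is `2 * callableLoci` (locus-haplotypes).
#' @examples
#' trRate(65, 6.88e6)   # about 4.72e-6
#' @export
trRate <- function(count, callableLoci, stratum = "all", alpha = 0.05) {
  if (callableLoci <= 0) stop("zero callable loci")
  exposure <- 2 * callableLoci
  ci <- poissonCI(count, exposure, alpha)
  data.frame(stratum = stratum, count = count, exposure = exposure,
             rate = count / exposure, ciLo = ci[["lo"]], ciHi = ci[["hi"]],
             stringsAsFactors = FALSE)
}

#' Parental-origin bias of phased de novo calls
#'
#' Reports the paternal fraction and ratio, and a paired Wilcoxon
#' signed-rank test across samples of paternal versus maternal counts.
#'
#' @param paternal,maternal per-sample phased call counts.
#' @return list(fractionPaternal, ratio, pValue, statistic).
#' @export
parentalBias <- function(paternal, maternal) {
  stopifnot(length(paternal) == length(maternal), length(paternal) >= 1L)
  tot <- sum(paternal) + sum(maternal)
  if (tot == 0) stop("no phased calls")
  w <- if (length(paternal) >= 2L && any(paternal != maternal))
    suppressWarnings(stats::wilcox.test(paternal, maternal, paired = TRUE))
  else list(p.value = NA_real_, statistic = NA_real_)
  list(fractionPaternal = sum(paternal) / tot,
       ratio = if (sum(maternal) > 0) sum(paternal) / sum(maternal) else Inf,
       pValue = w$p.value, statistic = unname(w$statistic))
}

#' Linear parental-age effect on de novo counts
#'
#' Ordinary least squares of count on paternal age and, separately, on
#' maternal age; slopes with standard errors and two-sided t-test p-values.
#'
#' @param counts per-child de novo counts.
#' @param paternalAge,maternalAge parental ages at conception; either may be
#'   NULL.
#' @return data.frame(parent, slope, se, p, intercept).
#' @export
ageEffectLinear <- function(counts, paternalAge = NULL, maternalAge = NULL) {
  stopifnot(length(counts) >= 3L)
  one <- function(age, label) {
    if (is.null(age)) return(NULL)
    if (length(unique(age)) < 2L) stop("constant ages for ", label)
    fit <- stats::lm(counts ~ age)
    sm <- suppressWarnings(summary(fit))$coefficients
    data.frame(parent = label, slope = sm["age", "Estimate"],
               se = sm["age", "Std. Error"], p = sm["age", "Pr(>|t|)"],
               intercept = sm["(Intercept)", "Estimate"],
               stringsAsFactors = FALSE)
  }
  out <- rbind(one(paternalAge, "paternal"), one(maternalAge, "maternal"))
  rownames(out) <- NULL
  out
}

#' Pooled rate from externally derived call tables
#'
#' Combines (count, exposure) rows, for example assembly-derived call sets
#' over different accessible regions, into a single pooled rate with CI.
#'
#' @param counts,exposures parallel vectors.
#' @param stratum label.
#' @return data.frame as in [snvRate()] with ploidy already folded into the
#'   exposures.
#' @export
pooledRate <- function(counts, exposures, stratum = "combined") {
  k <- sum(counts); ex <- sum(exposures)
  if (ex <= 0) stop("zero exposure")
  ci <- poissonCI(k, ex)
  data.frame(stratum = stratum, count = k, exposure = ex, rate = k / ex,
             ciLo = ci[["lo"]], ciHi = ci[["hi"]], stringsAsFactors = FALSE)
}
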