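## Synthetic methylation cohorts with known informative loci, used to make
## every downstream stage testable without external data.

#' Specification of a synthetic methylation cohort
#'
#' Describes a cohort whose informative loci follow class-conditional
#' bimodal beta-like distributions (hypo- and hyper-methylated modes at
#' `0.5 - separation/2` and `0.5 + separation/2`) while noise loci are
#' drawn identically for every class. This mirrors the bimodality of real
#' Illumina beta values without attempting to model probe chemistry, batch
#' effects or chromosomal structure.
#'
#' @param classLabels data.frame with columns `cancer_type` and
#'   `malignant`, one row per class.
#' @param nSamplesPerClass Samples generated per class (>= 2).
#' @param nInformative Number of label-informative loci.
#' @param nNoise Number of uninformative loci;
#'   `nInformative + nNoise` must equal the platform locus count.
#' @param separation Distance in `(0, 1]` between the class-specific beta
#'   modes of an informative locus.
#' @param concentration Positive concentration of the beta-like draws
#'   around their mode (larger = tighter).
#' @param missingRate Probability in `[0, 1)` that a cell is masked as
#'   missing.
#' @param platform A [methylPlatform()] descriptor (default
#'   `custom(nInformative + nNoise)`).
#' @param seed Integer seed; generation is fully reproducible.
#' @return A list of class `CohortSpec`.
#' @export
cohortSpec <- function(classLabels = data.frame(
                         cancer_type = c("TypeA", "TypeB", "TypeC"),
                         malignant = c(TRUE, TRUE, TRUE)),
                       nSamplesPerClass = 20L, nInformative = 50L,
                       nNoise = 450L, separation = 0.6,
                       concentration = 30, missingRate = 0,
                       platform = NULL, seed = 1L) {
  if (is.null(platform))
    platform <- methylPlatform("custom", nInformative + nNoise)
  spec <- list(classLabels = classLabels,
               nSamplesPerClass = as.integer(nSamplesPerClass),
               nInformative = as.integer(nInformative),
               nNoise = as.integer(nNoise), separation = separation,
               concentration = concentration, missingRate = missingRate,
               platform = platform, seed = as.integer(seed))
  class(spec) <- "CohortSpec"
  validateCohortSpec(spec)
  spec
}

validateCohortSpec <- function(spec) {
  if (spec$nSamplesPerClass < 2L)
    stop("nSamplesPerClass must be at least 2")
  if (spec$nInformative + spec$nNoise != spec$platform$nLoci)
    stop("locus budget mismatch: nInformative + nNoise = ",
         spec$nInformative + spec$nNoise, " but the platform has ",
         spec$platform$nLoci, " loci")
  if (spec$separation < 0 || spec$separation > 1)
    stop("separation must be in [0, 1]")
  if (spec$concentration <= 0)
    stop("concentration must be positive")
  if (spec$missingRate < 0 || spec$missingRate >= 1)
    stop("missingRate must be in [0, 1)")
  invisible(spec)
}

## Beta-like draw with mode mu and given concentration; clamped away from
## a degenerate mean of exactly 0/1.
rBetaMode <- function(n, mu, concentration) {
  mu <- pmin(pmax(mu, 0.02), 0.98)
  stats::rbeta(n, mu * concentration, (1 - mu) * concentration)
}

#' Generate a synthetic methylation cohort
#'
#' Draws a [BetaSet-class] under a [cohortSpec()]: each informative locus
#' receives a class-to-mode assignment (hypo vs hyper, never identical
#' across all classes) and samples are drawn from beta-like distributions
#' around their class mode; noise loci share one mode across classes.
#' Missing cells are then injected at `missingRate`.
#'
#' @param spec A [cohortSpec()].
#' @return A list with elements `betaSet` (a [BetaSet-class]) and `truth`
#'   (list with `informativeLoci`, character ids, and `classOfSample`,
#'   named character vector).
#' @export
generateCohort <- function(spec) {
  validateCohortSpec(spec)
  withSeed(spec$seed, {
    nc <- nrow(spec$classLabels)
    n <- nc * spec$nSamplesPerClass
    p <- spec$platform$nLoci
    classIdx <- rep(seq_len(nc), each = spec$nSamplesPerClass)
    lociIds <- sprintf("cg%08d", seq_len(p))
    informative <- sort(sample.int(p, spec$nInformative))
    lo <- 0.5 - spec$separation / 2
    hi <- 0.5 + spec$separation / 2

    m <- matrix(NA_real_, n, p)
    ## class-to-mode map for informative loci: nc x nInformative in {lo,hi},
    ## redrawn when a column is constant so every truth locus separates
    ## at least two classes
    modes <- matrix(sample(c(lo, hi), nc * spec$nInformative, replace = TRUE),
                    nc, spec$nInformative)
    flat <- which(apply(modes, 2L, function(col) length(unique(col)) == 1L))
    for (j in flat) {
      flip <- sample.int(nc, 1L)
      modes[flip, j] <- if (modes[flip, j] == lo) hi else lo
    }
    for (j in seq_along(informative)) {
      mu <- modes[classIdx, j]
      m[, informative[j]] <- rBetaMode(n, mu, spec$concentration)
    }
    noise <- setdiff(seq_len(p), informative)
    noiseModes <- sample(c(0.25, 0.75), length(noise), replace = TRUE)
    for (j in seq_along(noise)) {
      m[, noise[j]] <- rBetaMode(n, noiseModes[j], spec$concentration)
    }

    sampleIds <- sprintf("S%04d", seq_len(n))
    dimnames(m) <- list(sampleIds, lociIds)
    bs <- BetaSet(m,
                  cancerType = spec$classLabels$cancer_type[classIdx],
                  malignant = spec$classLabels$malignant[classIdx],
                  platform = spec$platform)
    if (spec$missingRate > 0)
      bs <- injectMissing(bs, spec$missingRate,
                          seed = deriveSeed(spec$seed, 104729L))
    truthClass <- spec$classLabels$cancer_type[classIdx]
    names(truthClass) <- sampleIds
    list(betaSet = bs,
         truth = list(informativeLoci = lociIds[informative],
                      classOfSample = truthClass))
  })
}

#' Mask cells as missing at a fixed rate
#'
#' Each cell of the beta matrix is set missing independently with
#' probability `rate`, reproducibly under `seed`.
#'
#' @param x A [BetaSet-class].
#' @param rate Missing probability in `[0, 1)`.
#' @param seed Integer seed.
#' @return A [BetaSet-class] with injected missing values.
#' @export
injectMissing <- function(x, rate, seed = 1L) {
  if (rate < 0 || rate >= 1)
    stop("rate must be in [0, 1)")
  if (rate == 0) return(x)
  withSeed(seed, {
    b <- assay(x, "beta")
    mask <- stats::runif(length(b)) < rate
    b[mask] <- NA_real_
    assay(x, "beta") <- b
    x
  })
}

#' Write the truth set of a synthetic cohort
#'
#' @param truth The `truth` element returned by [generateCohort()].
#' @param file Path; one informative locus id per line.
#' @export
writeTruthLoci <- function(truth, file) {
  writeLines(truth$informativeLoci, file)
  invisible(file)
}
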