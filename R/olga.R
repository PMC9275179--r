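## Outer-layer genetic algorithm (OLGA): a binary GA over CpG loci whose
## fitness is not computed independently but retrieved from the inner
## grouping GA after convergence on the masked feature space — the nested
## feedback that couples cluster separability to feature selectivity.

#' Single-point crossover of two feature masks
#'
#' Picks one uniform cut point and swaps the tails of the two parents,
#' preserving length and the per-position bit multiset.
#'
#' @param p1,p2 [FeatureMask-class] parents of equal length.
#' @return List of the two offspring masks. Uses the current RNG stream.
#' @export
singlePointCrossover <- function(p1, p2) {
  L <- length(p1@bits)
  if (L != length(p2@bits)) stop("parent masks differ in length")
  cut <- sample.int(L - 1L, 1L)
  tail <- seq.int(cut + 1L, L)
  c1 <- p1@bits; c2 <- p2@bits
  c1[tail] <- p2@bits[tail]; c2[tail] <- p1@bits[tail]
  list(featureMask(c1, p1@platform, p1@lociIds),
       featureMask(c2, p2@platform, p2@lociIds))
}

#' Adaptive bit-flip mutation
#'
#' Non-uniform mutation whose per-bit flip probability is driven by the
#' convergence of the latest generation:
#' `p = pMax * fAvg / fBest` (clamped to `[0, pMax]`, 0 when `fBest` is 0),
#' computed on min-shifted fitnesses so `0 <= fAvg <= fBest`. As the
#' population converges (`fAvg -> fBest`) the rate approaches its cap,
#' injecting diversity; each bit then flips independently.
#'
#' @param mask A [FeatureMask-class].
#' @param fBest,fAvg Best and average shifted fitness of the latest
#'   generation (`fBest >= fAvg >= 0`).
#' @param pMax Flip-probability cap (default 0.05).
#' @return The mutated [FeatureMask-class]. Uses the current RNG stream.
#' @export
adaptiveBitflipMutation <- function(mask, fBest, fAvg, pMax = 0.05) {
  if (fBest < fAvg || fAvg < 0)
    stop("shifted fitnesses must satisfy fBest >= fAvg >= 0")
  p <- if (fBest <= 0) 0 else min(pMax * (fAvg / fBest), pMax)
  if (p <= 0) return(mask)
  flip <- stats::runif(length(mask@bits)) < p
  featureMask(xor(mask@bits, flip), mask@platform, mask@lociIds)
}

#' Score a feature mask with the inner grouping GA
#'
#' Restricts the data columns to the selected loci (equivalently,
#' multiplies the feature vectors by the binary mask), runs the inner GA
#' to convergence, and returns the converged best cluster-validity record
#' as the mask's fitness.
#'
#' @param mask A [FeatureMask-class] with at least 2 selected loci.
#' @param data A fully observed [BetaSet-class] or samples-by-loci matrix.
#' @param ilga An [ilgaConfig()]; its seed controls the inner run.
#' @return The best [FitnessRecord-class] of the inner run.
#' @export
evaluateMask <- function(mask, data, ilga = ilgaConfig()) {
  if (sum(mask@bits) < 2L)
    stop("an evaluable mask needs at least 2 selected loci")
  runIlga(data, ilga, mask = mask)$fitness
}

## Ensure a mask stays evaluable: repair to >= 2 set bits (seeded caller RNG).
repairMask <- function(mask) {
  if (sum(mask@bits) >= 2L) return(mask)
  bits <- mask@bits
  bits[sample.int(length(bits), 2L)] <- TRUE
  featureMask(bits, mask@platform, mask@lociIds)
}

#' Run the outer-layer feature-selection GA
#'
#' Evolves binary CpG-selection masks: roulette-wheel selection,
#' single-point crossover, adaptive bit-flip mutation capped at its
#' configured maximum, and elitism. Every non-elite chromosome is scored
#' each generation by a fresh inner-GA run ([evaluateMask()]) under a seed
#' derived from the master seed, the generation and the chromosome index,
#' so evaluations are independent and may run concurrently
#' (`config@threads > 1`) with results identical to the sequential order;
#' elites carry their already-computed record.
#'
#' @param data A fully observed [BetaSet-class] of a single cohort
#'   (patients with an established cancer history) with >= 4 samples, or a
#'   samples-by-loci matrix.
#' @param config An [olgaConfig()].
#' @return A list: `mask` (best [FeatureMask-class]), `fitness` (its
#'   [FitnessRecord-class]), and `history` (data.frame of generation,
#'   best fitness, selected-locus count of the best mask).
#' @export
runOlga <- function(data, config = olgaConfig()) {
  X <- asSampleMatrix(data)
  if (nrow(X) < 4L) stop("cohort too small: at least 4 samples are required")
  platform <- if (is(data, "BetaSet")) platformOf(data)
              else methylPlatform("custom", ncol(X))
  ids <- if (is(data, "BetaSet")) lociIds(data) else character()
  L <- ncol(X)

  evalPop <- function(masks, need, gen) {
    records <- vector("list", length(masks))
    idx <- which(need)
    one <- function(i) {
      cfg <- config@ilga
      cfg@seed <- deriveSeed(config@seed, gen, i)
      runIlga(X[, masks[[i]]@bits, drop = FALSE], cfg)$fitness
    }
    res <- if (config@threads > 1L)
      parallel::mclapply(idx, one, mc.cores = config@threads)
    else lapply(idx, one)
    records[idx] <- res
    records
  }

  withSeed(deriveSeed(config@seed, 7L), {
    pop <- replicate(config@populationSize, {
      repairMask(featureMask(stats::runif(L) < 0.5, platform, ids))
    }, simplify = FALSE)
    rec <- evalPop(pop, rep(TRUE, config@populationSize), 0L)
    fit <- effectiveFitness(rec)
    G <- config@generations
    hist <- data.frame(generation = seq_len(G), best = NA_real_,
                       n_selected = NA_integer_)
    for (g in seq_len(G)) {
      ord <- order(fit, decreasing = TRUE)
      elite <- ord[seq_len(config@eliteCount)]
      ## adaptive mutation rate from the latest generation's fitnesses
      finite <- is.finite(fit)
      if (any(finite)) {
        fs <- fit - min(fit[finite]); fs[!finite] <- 0
        fBest <- max(fs); fAvg <- mean(fs)
      } else { fBest <- 0; fAvg <- 0 }

      newPop <- pop[elite]
      newRec <- rec[elite]
      while (length(newPop) < config@populationSize) {
        if (stats::runif(1L) < config@crossoverProbability) {
          i <- rouletteIdx(fit); j <- rouletteIdx(fit)
          kids <- singlePointCrossover(pop[[i]], pop[[j]])
        } else {
          kids <- list(pop[[rouletteIdx(fit)]])
        }
        for (kid in kids) {
          if (length(newPop) >= config@populationSize) break
          kid <- adaptiveBitflipMutation(kid, fBest, fAvg,
                                         config@mutationProbabilityMax)
          newPop[[length(newPop) + 1L]] <- repairMask(kid)
          newRec[length(newRec) + 1L] <- list(NULL)
        }
      }
      need <- seq_along(newPop) > config@eliteCount
      fresh <- evalPop(newPop, need, g)
      rec <- newRec
      rec[need] <- fresh[need]
      pop <- newPop
      fit <- effectiveFitness(rec)
      b <- which.max(fit)
      hist$best[g] <- fit[b]
      hist$n_selected[g] <- sum(pop[[b]]@bits)
    }
    best <- which.max(fit)
    list(mask = pop[[best]], fitness = rec[[best]], history = hist)
  })
}

#' Dimensionality-reduction summary of a mask
#'
#' @param mask A [FeatureMask-class].
#' @return List with `nSelected` and `percentReduction`
#'   (`100 * (1 - nSelected/total)`).
#' @examples
#' pf <- methylPlatform("custom", 27578)
#' m <- featureMask(seq_len(27578) <= 18904, pf)
#' reductionReport(m)$percentReduction  # ~31.5
#' @export
reductionReport <- function(mask) {
  n <- sum(mask@bits)
  list(nSelected = n,
       percentReduction = 100 * (1 - n / length(mask@bits)))
}

#' Intersect feature masks across cohorts
#'
#' Bitwise AND of the masks selected for the individual cancer types,
#' yielding the common CpG loci used by the classification stage.
#'
#' @param masks List of [FeatureMask-class] on the same platform.
#' @return The intersection [FeatureMask-class]; a warning is raised when
#'   it is empty.
#' @export
commonFeatures <- function(masks) {
  if (length(masks) == 0L) stop("no masks supplied")
  pf <- masks[[1L]]@platform
  bits <- masks[[1L]]@bits
  for (m in masks[-1L]) {
    if (!samePlatform(m@platform, pf))
      stop("masks come from different platforms")
    bits <- bits & m@bits
  }
  if (!any(bits)) warning("the mask intersection is empty")
  featureMask(bits, pf, masks[[1L]]@lociIds)
}

#' Write / read a feature mask
#'
#' Two plain-text forms: one selected locus id per line (`writeMaskLoci`),
#' and a two-column CSV of locus id and 0/1 bit (`writeMaskBits`,
#' `readMaskBits`).
#'
#' @param mask A [FeatureMask-class] carrying locus ids.
#' @param file Path.
#' @export
writeMaskLoci <- function(mask, file) {
  writeLines(as.character(selectedLoci(mask)), file)
  invisible(file)
}

#' @rdname writeMaskLoci
#' @export
writeMaskBits <- function(mask, file) {
  ids <- if (length(mask@lociIds)) mask@lociIds
         else as.character(seq_along(mask@bits))
  utils::write.csv(data.frame(locus_id = ids,
                              selected = as.integer(mask@bits)),
                   file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname writeMaskLoci
#' @param platform Platform for the mask being read; defaults to
#'   `custom(n rows)`.
#' @return `readMaskBits()`: a [FeatureMask-class].
#' @export
readMaskBits <- function(file, platform = NULL) {
  df <- utils::read.csv(file)
  if (is.null(platform)) platform <- methylPlatform("custom", nrow(df))
  featureMask(df$selected == 1, platform, df$locus_id)
}
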