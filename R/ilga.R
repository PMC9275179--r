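## Inner-layer genetic algorithm (ILGA): evolves contiguous-cluster
## partitions of the samples on a masked feature space and scores them with
## the Calinski-Harabasz cluster-validity index. The objective follows
## Ward's variance view of clustering: maximise the between-cluster
## dispersion alpha while minimising the within-cluster dispersion gamma.

## ---------------------------------------------------------------------------
## Data plumbing
## ---------------------------------------------------------------------------

## samples x selected-features numeric matrix from a BetaSet or matrix,
## optionally restricted by a FeatureMask.
asSampleMatrix <- function(data, mask = NULL) {
  X <- if (is(data, "BetaSet")) betaValues(data) else as.matrix(data)
  if (!is.null(mask)) {
    if (is(mask, "FeatureMask")) {
      if (ncol(X) != length(mask@bits))
        stop("mask length does not match the number of loci")
      X <- X[, mask@bits, drop = FALSE]
    } else X <- X[, as.logical(mask), drop = FALSE]
  }
  if (ncol(X) < 1L) stop("at least one selected feature is required")
  if (anyNA(X)) stop("data must be fully observed on the selected features")
  X
}

## Sufficient statistics reused across every partition evaluation of one
## masked dataset: row squared norms, global centroid term, total SSD.
fitnessContext <- function(X) {
  n <- nrow(X)
  sq <- rowSums(X * X)
  ctr <- colSums(X) / n
  centerSS <- n * sum(ctr * ctr)
  list(X = X, n = n, sq = sq, sumSq = sum(sq),
       centerSS = centerSS, totalSS = sum(sq) - centerSS)
}

## alpha, gamma and F_CH for one partition from the sufficient statistics:
## with cluster sums CS_k and sizes n_k,
##   alpha = sum_k ||CS_k||^2 / n_k - n ||c||^2
##   gamma = sum_i ||x_i||^2 - sum_k ||CS_k||^2 / n_k
## which are the size-weighted centroid dispersion and the within-cluster
## SSD (equal to the pairwise half-sum form).
evalPartition <- function(part, ctx) {
  k <- length(part@sizes)
  g <- clusterAssignments(part)
  cs <- rowsum(ctx$X, g)                 # k x F cluster sums, ordered 1..k
  csn <- sum(rowSums(cs * cs) / part@sizes)
  alpha <- max(csn - ctx$centerSS, 0)
  gamma <- max(ctx$sumSq - csn, 0)
  degenerate <- gamma <= ctx$totalSS * 1e-12
  fch <- if (k < 2L) 0
         else if (degenerate) Inf
         else (alpha / gamma) * (ctx$n - k) / (k - 1)
  new("FitnessRecord", alpha = alpha, gamma = gamma, fCh = fch,
      nClusters = k, nSamples = ctx$n, degenerate = degenerate)
}

## Fitness used for ranking/selection: degenerate partitions get no
## advantage and are never elites.
effectiveFitness <- function(records) {
  vapply(records, function(r) if (r@degenerate) -Inf else r@fCh, numeric(1))
}

## ---------------------------------------------------------------------------
## Exported cluster-validity operations
## ---------------------------------------------------------------------------

#' Between-cluster dispersion of a partition
#'
#' Size-weighted sum over clusters of the squared Euclidean distance
#' between the cluster feature-mean and the overall centroid,
#' \eqn{\alpha = \sum_k S_k \, D(\bar F_k, \hat F)^2}, computed on the
#' currently selected features.
#'
#' @param partition A [ClusterPartition-class].
#' @param data A fully observed [BetaSet-class] or samples-by-features
#'   matrix.
#' @param mask Optional [FeatureMask-class] restricting the features.
#' @return Non-negative scalar.
#' @export
computeAlpha <- function(partition, data, mask = NULL) {
  X <- asSampleMatrix(data, mask)
  validObject(partition)
  g <- clusterAssignments(partition)
  ctr <- colMeans(X)
  a <- 0
  for (k in seq_along(partition@sizes)) {
    mu <- colMeans(X[g == k, , drop = FALSE])
    a <- a + partition@sizes[k] * sum((mu - ctr)^2)
  }
  a
}

#' Within-cluster dispersion of a partition (pairwise form)
#'
#' For each cluster, half the mean pairwise squared Euclidean distance
#' accumulated over all ordered member pairs,
#' \eqn{\gamma = \sum_h \frac{1}{2 S_h} \sum_{n \in C_h} \sum_{m \in C_h}
#' D(F_n, F_m)^2}; this equals the sum of squared distances of members to
#' their cluster centroid.
#'
#' @inheritParams computeAlpha
#' @return Non-negative scalar.
#' @export
computeGamma <- function(partition, data, mask = NULL) {
  X <- asSampleMatrix(data, mask)
  validObject(partition)
  g <- clusterAssignments(partition)
  tot <- 0
  for (k in seq_along(partition@sizes)) {
    M <- X[g == k, , drop = FALSE]
    s <- nrow(M)
    if (s > 1L) {
      d2 <- as.matrix(stats::dist(M))^2
      tot <- tot + sum(d2) / (2 * s)
    }
  }
  tot
}

#' Calinski-Harabasz fitness of a partition
#'
#' Evaluates the grouping-GA objective
#' \eqn{F_{CH} = \frac{\alpha}{\gamma} \times \frac{n - k}{k - 1}} for `n`
#' samples in `k` clusters — the Calinski-Harabasz cluster-validity index,
#' where higher values mean better-separated clusters and hence better
#' feature selection. Single-cluster partitions score 0; partitions with
#' zero within-cluster dispersion are returned flagged `degenerate` with an
#' infinite sentinel and are never given a selection advantage by the GA.
#'
#' @inheritParams computeAlpha
#' @return A [FitnessRecord-class].
#' @export
chFitness <- function(partition, data, mask = NULL) {
  X <- asSampleMatrix(data, mask)
  validObject(partition)
  if (nrow(X) != length(partition@arrangement))
    stop("partition and data disagree on the number of samples")
  evalPartition(partition, fitnessContext(X))
}

## ---------------------------------------------------------------------------
## Operators
## ---------------------------------------------------------------------------

#' Random initial partition
#'
#' Draws a uniform random arrangement of the samples and cuts it into a
#' cluster count drawn uniformly from `2..ceiling(sqrt(n))`, with uniformly
#' placed boundaries (all clusters non-empty).
#'
#' @param nSamples Number of samples (>= 2).
#' @return A valid [ClusterPartition-class]. Uses the current RNG stream.
#' @export
initPartition <- function(nSamples) {
  if (nSamples < 2L) stop("at least 2 samples are required")
  kmax <- max(2L, as.integer(ceiling(sqrt(nSamples))))
  k <- if (kmax == 2L) 2L else sample(2:kmax, 1L)
  arrangement <- sample.int(nSamples)
  cuts <- sort(sample.int(nSamples - 1L, k - 1L))
  clusterPartition(arrangement, diff(c(0L, cuts, nSamples)))
}

## Deterministic core of the modified MPX crossover: remove the substring
## of p1's target cluster starting at within-cluster position `start` with
## length `size` (truncated at the cluster end), drop those items from p1,
## then append p2's surviving items in p2's relative order, one new cluster
## per contiguous run of p2 donor clusters.
mpxRecombine <- function(p1, p2, clusterIdx, start, size) {
  ends <- cumsum(p1@sizes)
  begins <- ends - p1@sizes + 1L
  cfrom <- begins[clusterIdx]; cto <- ends[clusterIdx]
  s0 <- cfrom + start - 1L
  s1 <- min(s0 + size - 1L, cto)
  subPos <- seq.int(s0, s1)
  sub <- p1@arrangement[subPos]

  keep <- setdiff(seq_along(p1@arrangement), subPos)
  remainder <- p1@arrangement[keep]
  newSizes <- p1@sizes
  newSizes[clusterIdx] <- newSizes[clusterIdx] - length(subPos)
  newSizes <- newSizes[newSizes > 0L]

  ## p2's surviving items = exactly the removed substring, in p2 order
  g2 <- clusterAssignments(p2)
  inSub <- p2@arrangement %in% sub
  inserted <- p2@arrangement[inSub]
  donor <- g2[inserted]
  runLens <- rle(donor)$lengths

  clusterPartition(c(remainder, inserted), c(newSizes, runLens))
}

#' Modified MPX (maximal-preservation) crossover
#'
#' Recombines two partitions of the same sample set. In each parent the
#' target is the cluster whose centroid lies nearest the overall centroid;
#' a random within-cluster cut-off and random size select a substring that
#' is removed from that parent, the parent's remaining items are removed
#' from the other parent, and the other parent's surviving items are
#' appended sequentially (grouped by their donor clusters). The operation
#' is performed symmetrically for both parents and the fitter offspring is
#' returned, the other discarded.
#'
#' @param parent1,parent2 [ClusterPartition-class] objects over the same
#'   samples.
#' @inheritParams computeAlpha
#' @return The fitter offspring [ClusterPartition-class]. Uses the current
#'   RNG stream.
#' @export
mpxCrossover <- function(parent1, parent2, data, mask = NULL) {
  X <- asSampleMatrix(data, mask)
  if (length(parent1@arrangement) != length(parent2@arrangement) ||
      length(parent1@arrangement) != nrow(X))
    stop("parents must partition the same sample set as the data")
  mpxCrossoverImpl(parent1, parent2, fitnessContext(X))$partition
}

nearestCentroidCluster <- function(p, ctx) {
  g <- clusterAssignments(p)
  cs <- rowsum(ctx$X, g)
  mu <- cs / p@sizes
  ctr <- colSums(ctx$X) / ctx$n
  d2 <- rowSums((mu - rep(ctr, each = nrow(mu)))^2)
  which.min(d2)
}

mpxCrossoverImpl <- function(p1, p2, ctx) {
  makeChild <- function(a, b) {
    tgt <- nearestCentroidCluster(a, ctx)
    sz <- a@sizes[tgt]
    start <- sample.int(sz, 1L)
    size <- sample.int(sz, 1L)
    mpxRecombine(a, b, tgt, start, size)
  }
  c1 <- makeChild(p1, p2)
  c2 <- makeChild(p2, p1)
  r1 <- evalPartition(c1, ctx)
  r2 <- evalPartition(c2, ctx)
  if (effectiveFitness(list(r2)) > effectiveFitness(list(r1)))
    list(partition = c2, record = r2)
  else list(partition = c1, record = r1)
}

#' Split/merge mutation of a partition
#'
#' Non-uniform mutation in the same gene-level style as the outer layer's
#' per-bit flips: every cluster is independently eligible for one mutation
#' event at the given rate, and each event either splits one cluster (of
#' size >= 2) or merges two neighbouring clusters, the move class chosen
#' uniformly among the feasible ones. The sample multiset is conserved and
#' the cluster count changes by one per fired move. The merge move
#' counteracts the fragmentation tendency of variance-minimising
#' clustering: with `data` supplied, "neighbouring" is Ward's notion — a
#' random cluster is fused with the cluster whose centroid is nearest —
#' and splits cut the cluster after canonically ordering its members along
#' their elongation (distance from the member farthest from the cluster
#' centroid), so a random interior cut bisects the cluster in data space.
#' Without `data` the moves fall back to the encoding order: split at a
#' random interior point, merge a random adjacent pair.
#'
#' @param partition A [ClusterPartition-class].
#' @param probability Per-cluster mutation-event probability in `[0, 1]`.
#' @param data Optional fully observed samples-by-features matrix or
#'   [BetaSet-class] guiding the data-space moves.
#' @param mask Optional [FeatureMask-class] restricting the features.
#' @return A [ClusterPartition-class]. Uses the current RNG stream.
#' @export
splitMergeMutation <- function(partition, probability, data = NULL,
                               mask = NULL) {
  if (probability < 0 || probability > 1)
    stop("probability must be in [0, 1]")
  if (probability == 0) return(partition)
  X <- if (!is.null(data)) asSampleMatrix(data, mask)
  events <- sum(stats::runif(length(partition@sizes)) < probability)
  for (e in seq_len(events))
    partition <- splitMergeMove(partition, X)
  partition
}

## one split-or-merge move; X = NULL means encoding-order fallback
splitMergeMove <- function(partition, X = NULL) {
  sizes <- partition@sizes
  arr <- partition@arrangement
  canSplit <- any(sizes >= 2L)
  canMerge <- length(sizes) >= 2L
  if (!canSplit && !canMerge) return(partition)
  doSplit <- if (canSplit && canMerge) stats::runif(1L) < 0.5 else canSplit
  ends <- cumsum(sizes)
  begins <- ends - sizes + 1L
  if (doSplit) {
    eligible <- which(sizes >= 2L)
    k <- if (length(eligible) == 1L) eligible else sample(eligible, 1L)
    if (!is.null(X)) {
      idx <- arr[begins[k]:ends[k]]
      M <- X[idx, , drop = FALSE]
      cen <- colMeans(M)
      far <- which.max(rowSums(sweep(M, 2L, cen)^2))
      key <- rowSums(sweep(M, 2L, M[far, ])^2)
      arr[begins[k]:ends[k]] <- idx[order(key)]
    }
    cut <- sample.int(sizes[k] - 1L, 1L)
    sizes <- append(sizes[-k], c(cut, sizes[k] - cut), after = k - 1L)
  } else {
    if (!is.null(X) && length(sizes) > 2L) {
      cen <- t(vapply(seq_along(sizes), function(k) {
        colMeans(X[arr[begins[k]:ends[k]], , drop = FALSE])
      }, numeric(ncol(X))))
      a <- sample.int(length(sizes), 1L)
      d <- rowSums(sweep(cen, 2L, cen[a, ])^2)
      d[a] <- Inf
      b <- which.min(d)
      i <- min(a, b); j <- max(a, b)
    } else {
      i <- if (length(sizes) == 2L) 1L else sample.int(length(sizes) - 1L, 1L)
      j <- i + 1L
    }
    blockJ <- arr[begins[j]:ends[j]]
    arr <- append(arr[-(begins[j]:ends[j])], blockJ, after = ends[i])
    sizes[i] <- sizes[i] + sizes[j]
    sizes <- sizes[-j]
  }
  clusterPartition(arr, sizes)
}

#' Roulette-wheel selection
#'
#' Samples one individual with probability proportional to its fitness
#' shifted so the minimum maps to zero; when all shifted weights are zero
#' (all fitnesses equal) selection is uniform.
#'
#' @param population List of individuals.
#' @param fitnesses Numeric fitness per individual (finite).
#' @return One element of `population`. Uses the current RNG stream.
#' @export
rouletteSelect <- function(population, fitnesses) {
  if (length(population) == 0L) stop("empty population")
  population[[rouletteIdx(fitnesses)]]
}

rouletteIdx <- function(fitnesses) {
  finite <- is.finite(fitnesses)
  if (!any(finite)) return(sample.int(length(fitnesses), 1L))
  w <- fitnesses - min(fitnesses[finite])
  w[!finite] <- 0                       # degenerate/-Inf: no advantage
  if (sum(w) <= 0) {
    idx <- which(finite)
    return(if (length(idx) == 1L) idx else sample(idx, 1L))
  }
  sample.int(length(w), 1L, prob = w / sum(w))
}

## ---------------------------------------------------------------------------
## ILGA driver
## ---------------------------------------------------------------------------

#' Run the inner-layer grouping GA
#'
#' Evolves sample partitions on the (masked) feature space: roulette
#' selection, modified MPX crossover at the configured probability,
#' split/merge mutation whose rate adapts to the population's convergence
#' (average over best shifted fitness, like the outer layer's operator) up
#' to its cap, and elitism (the fittest individuals are carried unchanged,
#' so the elite fitness trajectory is non-decreasing). Deterministic under
#' the configured seed.
#'
#' @param data A fully observed [BetaSet-class] or samples-by-features
#'   matrix.
#' @param config An [ilgaConfig()].
#' @param mask Optional [FeatureMask-class] restricting the features.
#' @return A list: `partition` (best [ClusterPartition-class]), `fitness`
#'   (its [FitnessRecord-class]), `history` (data.frame of generation,
#'   best, mean fitness), and `degenerateData` (TRUE when all samples are
#'   identical so no partition can separate them).
#' @export
runIlga <- function(data, config, mask = NULL) {
  X <- asSampleMatrix(data, mask)
  n <- nrow(X)
  if (n < 2L) stop("at least 2 samples are required")
  ctx <- fitnessContext(X)
  if (ctx$totalSS <= 0) {
    part <- clusterPartition(seq_len(n), n)
    return(list(partition = part, fitness = evalPartition(part, ctx),
                history = data.frame(generation = integer(), best = numeric(),
                                     mean = numeric()),
                degenerateData = TRUE))
  }
  withSeed(config@seed, {
    res <- .cppRunIlga(X, config@populationSize, config@generations,
                       config@crossoverProbability,
                       config@mutationProbabilityMax, config@eliteCount)
    part <- clusterPartition(res$arrangement, res$sizes)
    fitness <- new("FitnessRecord", alpha = res$alpha, gamma = res$gamma,
                   fCh = res$fch, nClusters = as.integer(res$nClusters),
                   nSamples = n, degenerate = res$degenerate)
    list(partition = part, fitness = fitness,
         history = data.frame(generation = seq_len(config@generations),
                              best = res$history[, 1L],
                              mean = res$history[, 2L]),
         degenerateData = FALSE)
  })
}

#' Write a partition as one tab-separated line of sample ids per cluster
#'
#' @param partition A [ClusterPartition-class].
#' @param file Output path.
#' @param sampleIds Optional ids; defaults to the integer indices.
#' @export
writePartition <- function(partition, file, sampleIds = NULL) {
  if (is.null(sampleIds)) sampleIds <- as.character(seq_along(partition@arrangement))
  ends <- cumsum(partition@sizes)
  begins <- ends - partition@sizes + 1L
  lines <- vapply(seq_along(ends), function(k) {
    paste(sampleIds[partition@arrangement[begins[k]:ends[k]]],
          collapse = "\t")
  }, character(1))
  writeLines(lines, file)
  invisible(file)
}
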