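#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assay<- colData colData<-
NULL

## ---------------------------------------------------------------------------
## Platform descriptors
## ---------------------------------------------------------------------------

#' Methylation platform descriptor
#'
#' Describes the CpG locus universe of an Illumina-style methylation array.
#' The two real platforms carry their canonical locus counts and the
#' missing-value rejection thresholds used during preprocessing (strictly
#' more than 10% missing rejects a 27k sample, strictly more than 20% a
#' 450k sample). `custom` platforms are used for desk-scale synthetic
#' cohorts and take an explicit locus count; they have no default rejection
#' threshold, so [filterSamples()] requires one.
#'
#' @param name One of `"27k"`, `"450k"`, `"custom"`.
#' @param nLoci Locus count; required for `"custom"`, fixed otherwise.
#' @return A list with elements `name`, `nLoci` and `missingThreshold`
#'   (`NA` for custom platforms).
#' @examples
#' methylPlatform("27k")$nLoci      # 27578
#' methylPlatform("custom", 500)
#' @export
methylPlatform <- function(name = c("27k", "450k", "custom"), nLoci = NULL) {
  name <- match.arg(name)
  if (name == "27k") {
    list(name = "27k", nLoci = 27578L, missingThreshold = 0.10)
  } else if (name == "450k") {
    list(name = "450k", nLoci = 485764L, missingThreshold = 0.20)
  } else {
    if (is.null(nLoci) || length(nLoci) != 1L || is.na(nLoci) || nLoci < 1)
      stop("a custom platform requires a positive 'nLoci'")
    list(name = "custom", nLoci = as.integer(nLoci), missingThreshold = NA_real_)
  }
}

samePlatform <- function(a, b) {
  identical(a$name, b$name) && identical(a$nLoci, b$nLoci)
}

## ---------------------------------------------------------------------------
## BetaSet: beta-value matrix container
## ---------------------------------------------------------------------------

#' BetaSet: a cohort of beta-value methylation profiles
#'
#' S4 container for a samples-by-loci matrix of DNA methylation beta values,
#' built on [SummarizedExperiment::SummarizedExperiment]. Following
#' Bioconductor convention the assay is stored loci-by-samples (features in
#' rows); [betaValues()] returns the samples-by-loci orientation used by the
#' selection and classification stages. Missing measurements are `NA`; all
#' observed values lie in `[0, 1]`. Per-sample labels (`cancer_type`,
#' `malignant`) live in `colData`, the platform descriptor in `metadata`.
#'
#' @slot assays,colData,... inherited from `SummarizedExperiment`.
#' @seealso [BetaSet()] constructor, [betaValues()], [filterSamples()],
#'   [imputeMissing()]
#' @export
setClass("BetaSet", contains = "SummarizedExperiment")

setValidity("BetaSet", function(object) {
  msg <- character()
  if (!"beta" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'beta' is required")
  else {
    b <- assay(object, "beta")
    if (any(b < 0 | b > 1, na.rm = TRUE))
      msg <- c(msg, "beta values must lie in [0, 1] or be NA")
  }
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "locus ids (rownames) must be present and unique")
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msg <- c(msg, "sample ids (colnames) must be present and unique")
  if (!all(c("cancer_type", "malignant") %in% names(colData(object))))
    msg <- c(msg, "colData must contain 'cancer_type' and 'malignant'")
  pf <- metadata(object)$platform
  if (is.null(pf) || !all(c("name", "nLoci") %in% names(pf)))
    msg <- c(msg, "metadata must carry a platform descriptor")
  if (length(msg)) msg else TRUE
})

#' Construct a BetaSet
#'
#' @param values Numeric samples-by-loci matrix in `[0, 1]`, `NA` for
#'   missing. Row names are sample ids, column names locus ids (both
#'   required unless `sampleIds`/`lociIds` are given).
#' @param cancerType Character vector of per-sample cancer types.
#' @param malignant Logical vector of per-sample malignancy.
#' @param platform A [methylPlatform()] descriptor; its locus count must
#'   match `ncol(values)`.
#' @param sampleIds,lociIds Optional explicit identifiers.
#' @return A [BetaSet-class] object.
#' @examples
#' m <- matrix(runif(6), 2, 3,
#'             dimnames = list(c("s1", "s2"), c("cg01", "cg02", "cg03")))
#' bs <- BetaSet(m, cancerType = c("Breast", "Breast"),
#'               malignant = c(TRUE, FALSE),
#'               platform = methylPlatform("custom", 3))
#' @export
BetaSet <- function(values, cancerType, malignant, platform,
                    sampleIds = rownames(values), lociIds = colnames(values)) {
  values <- as.matrix(values)
  if (is.null(sampleIds) || is.null(lociIds))
    stop("sample and locus identifiers are required")
  if (ncol(values) != platform$nLoci)
    stop("locus count (", ncol(values), ") does not match platform (",
         platform$nLoci, ")")
  if (length(cancerType) != nrow(values) || length(malignant) != nrow(values))
    stop("labels must have one entry per sample")
  a <- t(values)
  dimnames(a) <- list(lociIds, sampleIds)
  se <- SummarizedExperiment(
    assays = list(beta = a),
    colData = DataFrame(cancer_type = as.character(cancerType),
                        malignant = as.logical(malignant),
                        row.names = sampleIds))
  metadata(se)$platform <- platform
  new("BetaSet", se)
}

## ---------------------------------------------------------------------------
## ClusterPartition: inner-layer GA chromosome
## ---------------------------------------------------------------------------

#' ClusterPartition: a grouping-GA chromosome
#'
#' An ordered arrangement of sample indices cut into contiguous logical
#' clusters. `arrangement` is a permutation of `1..n`; `sizes` are the
#' cluster sizes in arrangement order (all positive, summing to `n`).
#'
#' @slot arrangement integer permutation of the sample indices.
#' @slot sizes integer cluster sizes.
#' @seealso [clusterPartition()], [initPartition()], [chFitness()]
#' @export
setClass("ClusterPartition",
         representation(arrangement = "integer", sizes = "integer"))

setValidity("ClusterPartition", function(object) {
  n <- length(object@arrangement)
  msg <- character()
  if (!identical(sort(object@arrangement), seq_len(n)))
    msg <- c(msg, "arrangement must be a permutation of 1..n")
  if (length(object@sizes) < 1L || any(object@sizes < 1L))
    msg <- c(msg, "every cluster must be non-empty")
  if (sum(object@sizes) != n)
    msg <- c(msg, "cluster sizes must sum to the number of samples")
  if (length(msg)) msg else TRUE
})

#' @rdname ClusterPartition-class
#' @param arrangement Integer permutation of `1..n`.
#' @param sizes Positive integer cluster sizes summing to `n`.
#' @export
clusterPartition <- function(arrangement, sizes) {
  new("ClusterPartition", arrangement = as.integer(arrangement),
      sizes = as.integer(sizes))
}

#' @rdname ClusterPartition-class
#' @param x A `ClusterPartition`.
#' @return `nClusters()`: the number of logical clusters.
#' @export
nClusters <- function(x) length(x@sizes)

#' Cluster membership vector
#'
#' @param x A [ClusterPartition-class].
#' @return Integer vector `g` with `g[i]` the cluster index of sample `i`.
#' @export
clusterAssignments <- function(x) {
  g <- integer(length(x@arrangement))
  g[x@arrangement] <- rep.int(seq_along(x@sizes), x@sizes)
  g
}

## ---------------------------------------------------------------------------
## FitnessRecord
## ---------------------------------------------------------------------------

#' FitnessRecord: cluster-validity evaluation of one partition
#'
#' Holds the between-cluster dispersion `alpha` (size-weighted squared
#' distances of cluster centroids to the overall centroid), the
#' within-cluster dispersion `gamma` (pairwise form of the within-cluster
#' sum of squares), and the Calinski-Harabasz fitness
#' `fCh = (alpha/gamma) * (n - k) / (k - 1)` for `n` samples in `k`
#' clusters. Partitions with `gamma == 0` are flagged `degenerate`; they
#' receive a sentinel fitness but no selection advantage and are never
#' propagated as elites.
#'
#' @slot alpha,gamma,fCh numeric scalars.
#' @slot nClusters,nSamples integer scalars.
#' @slot degenerate logical flag.
#' @export
setClass("FitnessRecord",
         representation(alpha = "numeric", gamma = "numeric", fCh = "numeric",
                        nClusters = "integer", nSamples = "integer",
                        degenerate = "logical"))

setValidity("FitnessRecord", function(object) {
  msg <- character()
  if (object@alpha < -1e-12) msg <- c(msg, "alpha must be non-negative")
  if (object@gamma < -1e-12) msg <- c(msg, "gamma must be non-negative")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## FeatureMask: outer-layer GA chromosome
## ---------------------------------------------------------------------------

#' FeatureMask: a binary feature-selection chromosome
#'
#' A logical vector over the platform's CpG loci: `TRUE` marks a selected
#' locus passed to the clustering layer, `FALSE` an unselected one.
#'
#' @slot bits logical vector, one per platform locus.
#' @slot lociIds character locus identifiers (may be empty).
#' @slot platform platform descriptor list.
#' @seealso [featureMask()], [runOlga()], [commonFeatures()]
#' @export
setClass("FeatureMask",
         representation(bits = "logical", lociIds = "character",
                        platform = "list"))

setValidity("FeatureMask", function(object) {
  msg <- character()
  if (anyNA(object@bits)) msg <- c(msg, "bits must not contain NA")
  if (length(object@bits) != object@platform$nLoci)
    msg <- c(msg, "mask length must equal the platform locus count")
  if (length(object@lociIds) &&
      length(object@lociIds) != length(object@bits))
    msg <- c(msg, "lociIds, when given, must match the mask length")
  if (length(msg)) msg else TRUE
})

#' @rdname FeatureMask-class
#' @param bits Logical (or 0/1) vector over loci.
#' @param platform A [methylPlatform()] descriptor.
#' @param lociIds Optional locus identifiers.
#' @export
featureMask <- function(bits, platform, lociIds = character()) {
  new("FeatureMask", bits = as.logical(bits), lociIds = as.character(lociIds),
      platform = platform)
}

#' @rdname FeatureMask-class
#' @param x A `FeatureMask`.
#' @return `nSelected()`: number of selected loci.
#' @export
nSelected <- function(x) sum(x@bits)

#' Selected locus identifiers of a mask
#' @param x A [FeatureMask-class].
#' @return Character ids when the mask carries ids, else integer positions.
#' @export
selectedLoci <- function(x) {
  if (length(x@lociIds)) x@lociIds[x@bits] else which(x@bits)
}

## ---------------------------------------------------------------------------
## GA configurations
## ---------------------------------------------------------------------------

#' Inner-layer (grouping) GA configuration
#'
#' Defaults follow the published setup: 200 generations, 30% crossover
#' probability for the modified MPX operator, split/merge mutation whose
#' rate rises with population convergence up to a 10% cap, and elitism.
#' Population size is not stated in the source method; 30 is the package
#' default.
#'
#' @param populationSize Number of partitions per generation.
#' @param generations Number of generations.
#' @param crossoverProbability Probability an offspring is produced by MPX
#'   crossover rather than copied.
#' @param mutationProbabilityMax Cap of the adaptive per-cluster
#'   split/merge mutation rate.
#' @param eliteCount Individuals copied unchanged each generation.
#' @param seed Integer seed for this run.
#' @return An object of class `IlgaConfig`.
#' @export
ilgaConfig <- function(populationSize = 30L, generations = 200L,
                       crossoverProbability = 0.30,
                       mutationProbabilityMax = 0.10,
                       eliteCount = 1L, seed = 1L) {
  new("IlgaConfig", populationSize = as.integer(populationSize),
      generations = as.integer(generations),
      crossoverProbability = crossoverProbability,
      mutationProbabilityMax = mutationProbabilityMax,
      eliteCount = as.integer(eliteCount), seed = as.integer(seed))
}

#' @rdname ilgaConfig
#' @export
setClass("IlgaConfig",
         representation(populationSize = "integer", generations = "integer",
                        crossoverProbability = "numeric",
                        mutationProbabilityMax = "numeric",
                        eliteCount = "integer", seed = "integer"))

setValidity("IlgaConfig", function(object) {
  msg <- character()
  if (object@crossoverProbability < 0 || object@crossoverProbability > 1)
    msg <- c(msg, "crossoverProbability must be in [0, 1]")
  if (object@mutationProbabilityMax < 0 || object@mutationProbabilityMax > 1)
    msg <- c(msg, "mutationProbabilityMax must be in [0, 1]")
  if (object@eliteCount < 1L || object@eliteCount >= object@populationSize)
    msg <- c(msg, "eliteCount must be in [1, populationSize)")
  if (object@populationSize < 2L)
    msg <- c(msg, "populationSize must be at least 2")
  if (length(msg)) msg else TRUE
})

#' Outer-layer (feature-selection) GA configuration
#'
#' Defaults follow the published setup: 100 generations, single-point
#' crossover, adaptive bit-flip mutation capped at 5%, elitism,
#' roulette-wheel selection. Each outer chromosome is scored by a fresh
#' inner-GA run configured by `ilga`.
#'
#' @param populationSize Number of masks per generation.
#' @param generations Number of outer generations.
#' @param mutationProbabilityMax Per-bit flip probability cap.
#' @param eliteCount Masks copied unchanged each generation.
#' @param crossoverProbability Probability a non-elite slot is filled by
#'   crossover offspring rather than a copied parent.
#' @param ilga An [ilgaConfig()] for the inner layer.
#' @param seed Integer master seed; per-chromosome seeds are derived from
#'   it so concurrent evaluation is reproducible.
#' @param threads Number of worker processes for mask evaluation (1 =
#'   sequential; results are identical either way).
#' @return An object of class `OlgaConfig`.
#' @export
olgaConfig <- function(populationSize = 20L, generations = 100L,
                       mutationProbabilityMax = 0.05, eliteCount = 1L,
                       crossoverProbability = 0.9,
                       ilga = ilgaConfig(), seed = 1L, threads = 1L) {
  new("OlgaConfig", populationSize = as.integer(populationSize),
      generations = as.integer(generations),
      mutationProbabilityMax = mutationProbabilityMax,
      eliteCount = as.integer(eliteCount),
      crossoverProbability = crossoverProbability,
      ilga = ilga, seed = as.integer(seed), threads = as.integer(threads))
}

#' @rdname olgaConfig
#' @export
setClass("OlgaConfig",
         representation(populationSize = "integer", generations = "integer",
                        mutationProbabilityMax = "numeric",
                        eliteCount = "integer",
                        crossoverProbability = "numeric",
                        ilga = "IlgaConfig", seed = "integer",
                        threads = "integer"))

setValidity("OlgaConfig", function(object) {
  msg <- character()
  if (object@mutationProbabilityMax < 0 || object@mutationProbabilityMax > 1)
    msg <- c(msg, "mutationProbabilityMax must be in [0, 1]")
  if (object@eliteCount < 1L || object@eliteCount >= object@populationSize)
    msg <- c(msg, "eliteCount must be in [1, populationSize)")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## ClassificationReport
## ---------------------------------------------------------------------------

#' ClassificationReport: full evaluation of a classifier
#'
#' @slot classes ordered class labels.
#' @slot confusion square count matrix (rows = truth, columns = predicted).
#' @slot perClass data.frame of one-vs-rest accuracy, precision, recall,
#'   F1 per class (precision is 0 with `precision_defined = FALSE` when no
#'   positive prediction was made).
#' @slot overallAccuracy trace/total.
#' @slot mcc Matthews correlation coefficient (binary form for two
#'   classes, generalized multi-class coefficient otherwise).
#' @slot heatmap row-normalized confusion proportions.
#' @slot roc list of per-class ROC curves (data.frames with fpr, tpr,
#'   threshold) or `NULL` when no scores were supplied.
#' @slot microAuc,macroAuc micro- and macro-averaged one-vs-rest AUC
#'   (`NA` without scores).
#' @export
setClass("ClassificationReport",
         representation(classes = "character", confusion = "matrix",
                        perClass = "data.frame", overallAccuracy = "numeric",
                        mcc = "numeric", heatmap = "matrix", roc = "list",
                        microAuc = "numeric", macroAuc = "numeric"))

## ---------------------------------------------------------------------------
## show methods
## ---------------------------------------------------------------------------

setMethod("show", "BetaSet", function(object) {
  pf <- metadata(object)$platform
  b <- assay(object, "beta")
  cat("BetaSet with", ncol(object), "samples and", nrow(object),
      "CpG loci\n")
  cat("platform:", pf$name, sprintf("(%d loci)", pf$nLoci), "\n")
  cat(sprintf("missing: %.2f%% of entries\n", 100 * mean(is.na(b))))
  ct <- table(colData(object)$cancer_type)
  cat("cancer types:", paste(sprintf("%s(%d)", names(ct), ct),
                             collapse = ", "), "\n")
})

setMethod("show", "ClusterPartition", function(object) {
  cat("ClusterPartition:", length(object@arrangement), "samples in",
      length(object@sizes), "clusters (sizes:",
      paste(object@sizes, collapse = ", "), ")\n")
})

setMethod("show", "FitnessRecord", function(object) {
  cat(sprintf(
    "FitnessRecord: F_CH = %.4f (alpha = %.4f, gamma = %.4f, %d clusters, %d samples%s)\n",
    object@fCh, object@alpha, object@gamma, object@nClusters,
    object@nSamples, if (object@degenerate) ", DEGENERATE" else ""))
})

setMethod("show", "FeatureMask", function(object) {
  cat(sprintf("FeatureMask on %s platform: %d of %d loci selected (%.1f%% reduction)\n",
              object@platform$name, sum(object@bits), length(object@bits),
              100 * (1 - mean(object@bits))))
})

setMethod("show", "ClassificationReport", function(object) {
  cat("ClassificationReport over classes:",
      paste(object@classes, collapse = ", "), "\n")
  cat(sprintf("overall accuracy: %.4f   MCC: %.4f\n",
              object@overallAccuracy, object@mcc))
  if (!is.na(object@microAuc))
    cat(sprintf("micro AUC: %.4f   macro AUC: %.4f\n",
                object@microAuc, object@macroAuc))
})
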