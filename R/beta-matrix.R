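## Beta-value preprocessing: Eq-style beta computation, missingness
## filtering, per-sample linear imputation, matrix assembly and CSV IO.

#' Beta value from methylated/unmethylated intensities
#'
#' Computes the methylation beta value
#' \deqn{\beta = \frac{\max(M, 0)}{\max(M, 0) + \max(U, 0) + \alpha}}
#' where `M` and `U` are the methylated and unmethylated fluorescence
#' intensities and `offset` (\eqn{\alpha}, Illumina default 100) calibrates
#' the ratio when both intensities are low. The result lies in `[0, 1)`:
#' 0 means no methylated signal was detected, values near 1 mean nearly
#' complete methylation.
#'
#' @param methylated Numeric vector of methylated intensities (M).
#' @param unmethylated Numeric vector of unmethylated intensities (U).
#' @param offset Positive calibration constant (default 100).
#' @return Numeric vector of beta values in `[0, 1)`.
#' @examples
#' computeBeta(0, 500)    # 0: no methylated molecules detected
#' computeBeta(900, 0)    # 0.9
#' computeBeta(-50, -20)  # 0: negative intensities clamp to zero
#' @export
computeBeta <- function(methylated, unmethylated, offset = 100) {
  if (length(offset) != 1L || is.na(offset) || offset <= 0)
    stop("'offset' must be a single positive number")
  m <- pmax(methylated, 0)
  u <- pmax(unmethylated, 0)
  m / (m + u + offset)
}

## ---------------------------------------------------------------------------
## Accessors
## ---------------------------------------------------------------------------

#' Beta values in samples-by-loci orientation
#'
#' @param x A [BetaSet-class].
#' @return Numeric matrix, rows = samples, columns = CpG loci, `NA` where
#'   missing.
#' @export
betaValues <- function(x) t(assay(x, "beta"))

#' @rdname betaValues
#' @return `sampleIds()`/`lociIds()`: character identifier vectors.
#' @export
sampleIds <- function(x) colnames(x)

#' @rdname betaValues
#' @export
lociIds <- function(x) rownames(x)

#' @rdname betaValues
#' @return `platformOf()`: the [methylPlatform()] descriptor.
#' @export
platformOf <- function(x) metadata(x)$platform

#' @rdname betaValues
#' @return `sampleLabels()`: data.frame with `cancer_type` and `malignant`.
#' @export
sampleLabels <- function(x) as.data.frame(colData(x))

## ---------------------------------------------------------------------------
## Missingness
## ---------------------------------------------------------------------------

#' Fraction of missing loci for one sample
#'
#' @param x A [BetaSet-class].
#' @param sample A sample identifier present in `x`.
#' @return Fraction of the sample's loci with missing beta values.
#' @export
missingFraction <- function(x, sample) {
  if (!sample %in% colnames(x))
    stop("unknown sample: ", sample)
  mean(is.na(assay(x, "beta")[, sample]))
}

#' Reject samples with excessive missingness
#'
#' Drops every sample whose missing fraction is strictly greater than the
#' platform threshold (10% for 27k profiles, 20% for 450k profiles);
#' samples exactly at the threshold are retained. Rejection is computed on
#' the raw matrix before any imputation. The removed samples are recorded
#' in `metadata(result)$rejectionLog` (a data.frame of `sample_id`,
#' `missing_fraction`) and optionally written as tab-separated lines.
#'
#' @param x A [BetaSet-class].
#' @param threshold Missing-fraction threshold; defaults to the platform's
#'   own. Required for custom platforms.
#' @param logFile Optional path for the plain-text rejection log.
#' @return The filtered [BetaSet-class]; `x` is unmodified.
#' @export
filterSamples <- function(x, threshold = NULL, logFile = NULL) {
  pf <- platformOf(x)
  if (is.null(threshold)) threshold <- pf$missingThreshold
  if (is.null(threshold) || is.na(threshold))
    stop("custom platforms require an explicit rejection 'threshold'")
  frac <- colMeans(is.na(assay(x, "beta")))
  keep <- frac <= threshold
  if (!any(keep))
    stop("empty cohort: every sample exceeds ", threshold, " missingness")
  rejected <- data.frame(sample_id = colnames(x)[!keep],
                         missing_fraction = unname(frac[!keep]))
  if (!is.null(logFile))
    writeLines(sprintf("%s\t%.6g", rejected$sample_id,
                       rejected$missing_fraction), logFile)
  out <- x[, keep]
  metadata(out)$rejectionLog <- rejected
  out
}

## ---------------------------------------------------------------------------
## Imputation
## ---------------------------------------------------------------------------

## One sample's profile: interior gaps are linearly interpolated between
## the flanking observed loci; runs at either edge are extrapolated from a
## least-squares line through the k nearest observed loci, clamped to [0,1].
imputeProfile <- function(v, k = 4L) {
  miss <- is.na(v)
  if (!any(miss)) return(v)
  obs <- which(!miss)
  if (length(obs) == 0L)
    stop("cannot impute a sample with no observed loci")
  if (length(obs) == 1L) {
    v[miss] <- v[obs]
    return(v)
  }
  ## interior: linear interpolation between flanking neighbours
  v2 <- stats::approx(obs, v[obs], xout = seq_along(v), method = "linear",
                      rule = 1)$y
  ## edges: regression line through the k nearest observed loci
  lo <- obs[1L]; hi <- obs[length(obs)]
  if (lo > 1L) {
    idx <- obs[seq_len(min(k, length(obs)))]
    fit <- stats::lm.fit(cbind(1, idx), v[idx])
    pos <- seq_len(lo - 1L)
    v2[pos] <- fit$coefficients[1L] + fit$coefficients[2L] * pos
  }
  if (hi < length(v)) {
    idx <- obs[seq.int(length(obs) - min(k, length(obs)) + 1L, length(obs))]
    fit <- stats::lm.fit(cbind(1, idx), v[idx])
    pos <- seq.int(hi + 1L, length(v))
    v2[pos] <- fit$coefficients[1L] + fit$coefficients[2L] * pos
  }
  v[miss] <- pmin(pmax(v2[miss], 0), 1)
  v
}

#' Impute missing beta values
#'
#' Fills every missing entry per sample by linear regression on the locus
#' index: interior gaps become linear interpolation between the flanking
#' observed loci, leading/trailing gaps are extrapolated from the
#' least-squares line through the `k` nearest observed loci of the same
#' sample. Imputed values are clamped to `[0, 1]`; observed values are
#' untouched. Imputation never borrows information across samples.
#'
#' @param x A [BetaSet-class] that already passed [filterSamples()].
#' @param k Number of nearest observed loci used for edge extrapolation.
#' @return A fully observed [BetaSet-class].
#' @export
imputeMissing <- function(x, k = 4L) {
  b <- assay(x, "beta")          # loci x samples: impute per column
  for (j in seq_len(ncol(b)))
    b[, j] <- imputeProfile(b[, j], k = k)
  assay(x, "beta") <- b
  validObject(x)
  x
}

## ---------------------------------------------------------------------------
## Assembly and CSV IO
## ---------------------------------------------------------------------------

#' Assemble a BetaSet from per-sample locus maps
#'
#' Builds the samples-by-loci matrix by transposing each sample's
#' locus-to-beta map into a row. Row order follows the input sample order,
#' column order the platform locus order; loci absent from a sample's map
#' become missing values.
#'
#' @param perSample Named list: one `locus id -> beta` named numeric vector
#'   per sample; names are sample ids.
#' @param labels data.frame with columns `sample_id`, `cancer_type`,
#'   `malignant` covering every sample.
#' @param platform A [methylPlatform()] descriptor.
#' @param lociUniverse Character vector of the platform's locus ids, in
#'   column order.
#' @return A [BetaSet-class].
#' @export
assembleBetaSet <- function(perSample, labels, platform, lociUniverse) {
  ids <- names(perSample)
  if (is.null(ids) || anyDuplicated(ids))
    stop("duplicate or missing sample ids")
  if (length(lociUniverse) != platform$nLoci)
    stop("locus universe does not match the platform locus count")
  m <- matrix(NA_real_, length(ids), length(lociUniverse),
              dimnames = list(ids, lociUniverse))
  for (s in ids) {
    v <- perSample[[s]]
    bad <- setdiff(names(v), lociUniverse)
    if (length(bad))
      stop("sample ", s, " carries loci outside the platform universe: ",
           paste(utils::head(bad, 3), collapse = ", "))
    m[s, names(v)] <- unname(v)
  }
  lab <- labels[match(ids, labels$sample_id), , drop = FALSE]
  if (anyNA(lab$sample_id))
    stop("labels are missing for some samples")
  BetaSet(m, cancerType = lab$cancer_type, malignant = lab$malignant,
          platform = platform)
}

#' Read / write beta-matrix and label CSV files
#'
#' The beta-matrix dialect: first row holds the locus ids, first column the
#' sample id, empty cells are missing values, UTF-8, comma-separated. The
#' labels file has columns `sample_id`, `cancer_type`, `malignant` (0/1).
#'
#' @param x A [BetaSet-class].
#' @param file Path of the matrix CSV.
#' @param labelsFile Path of the labels CSV.
#' @export
writeBetaCsv <- function(x, file, labelsFile = NULL) {
  m <- betaValues(x)
  df <- data.frame(sample_id = rownames(m), m, check.names = FALSE)
  utils::write.csv(df, file, row.names = FALSE, quote = FALSE, na = "")
  if (!is.null(labelsFile)) {
    lab <- sampleLabels(x)
    utils::write.csv(
      data.frame(sample_id = rownames(lab),
                 cancer_type = lab$cancer_type,
                 malignant = as.integer(lab$malignant)),
      labelsFile, row.names = FALSE, quote = FALSE)
  }
  invisible(file)
}

#' @rdname writeBetaCsv
#' @param platform Platform of the stored matrix; defaults to
#'   `custom(n columns)`.
#' @return `readBetaCsv()`: a [BetaSet-class].
#' @export
readBetaCsv <- function(file, labelsFile, platform = NULL) {
  df <- utils::read.csv(file, check.names = FALSE, colClasses = NA)
  if (names(df)[1L] != "sample_id")
    stop("malformed beta matrix: first column must be 'sample_id'")
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df$sample_id
  lab <- readLabelsCsv(labelsFile)
  lab <- lab[match(rownames(m), lab$sample_id), , drop = FALSE]
  if (anyNA(lab$sample_id))
    stop("labels file does not cover every sample in the matrix")
  if (is.null(platform)) platform <- methylPlatform("custom", ncol(m))
  BetaSet(m, cancerType = lab$cancer_type, malignant = lab$malignant,
          platform = platform)
}

#' @rdname writeBetaCsv
#' @return `readLabelsCsv()`: data.frame `sample_id`, `cancer_type`,
#'   `malignant` (logical).
#' @export
readLabelsCsv <- function(labelsFile) {
  lab <- utils::read.csv(labelsFile, check.names = FALSE)
  need <- c("sample_id", "cancer_type", "malignant")
  if (!all(need %in% names(lab))) {
    bad <- setdiff(need, names(lab))
    stop("malformed labels file ", labelsFile, ": missing column(s) ",
         paste(bad, collapse = ", "))
  }
  if (!all(lab$malignant %in% c(0, 1, TRUE, FALSE)))
    stop("malformed labels file ", labelsFile, ": 'malignant' must be 0/1 (first offending line: ",
         which(!lab$malignant %in% c(0, 1, TRUE, FALSE))[1L] + 1L, ")")
  lab$malignant <- as.logical(lab$malignant)
  lab
}
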