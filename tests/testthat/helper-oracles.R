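# Independent oracles and small fixture builders shared across the suite.

# Naive Calinski-Harabasz index computed straight from its definition:
# explicit per-cluster centroid loops, no shared code with the package's
# sufficient-statistics implementation.
naiveCH <- function(assignments, X) {
  X <- as.matrix(X)
  ids <- unique(assignments)
  k <- length(ids)
  n <- nrow(X)
  grand <- colMeans(X)
  between <- 0
  within <- 0
  for (cl in ids) {
    M <- X[assignments == cl, , drop = FALSE]
    mu <- colMeans(M)
    between <- between + nrow(M) * sum((mu - grand)^2)
    for (r in seq_len(nrow(M)))
      within <- within + sum((M[r, ] - mu)^2)
  }
  (between / within) * (n - k) / (k - 1)
}

# Centroid-form within-cluster SSD (oracle for the pairwise gamma).
naiveWithinSSD <- function(assignments, X) {
  X <- as.matrix(X)
  tot <- 0
  for (cl in unique(assignments)) {
    M <- X[assignments == cl, , drop = FALSE]
    mu <- colMeans(M)
    for (r in seq_len(nrow(M)))
      tot <- tot + sum((M[r, ] - mu)^2)
  }
  tot
}

# Rand index between two label vectors (pair-counting agreement).
randIndex <- function(a, b) {
  n <- length(a)
  agree <- 0
  for (i in seq_len(n - 1))
    for (j in seq.int(i + 1, n))
      agree <- agree + ((a[i] == a[j]) == (b[i] == b[j]))
  agree / choose(n, 2)
}

# Random valid partition of n samples.
randomPartition <- function(n, kmax = max(2L, ceiling(sqrt(n)))) {
  k <- if (kmax == 2L) 2L else sample(2:kmax, 1L)
  cuts <- sort(sample.int(n - 1L, k - 1L))
  clusterPartition(sample.int(n), diff(c(0L, cuts, n)))
}

# Tiny two-class cohort with tight, well-separated classes.
tightCohort <- function(nPerClass = 8L, nLoci = 60L, separation = 0.9,
                        seed = 5L, classes = c("TypeA", "TypeB")) {
  generateCohort(cohortSpec(
    classLabels = data.frame(cancer_type = classes,
                             malignant = rep(TRUE, length(classes))),
    nSamplesPerClass = nPerClass,
    nInformative = as.integer(round(nLoci * 0.6)),
    nNoise = nLoci - as.integer(round(nLoci * 0.6)),
    separation = separation, concentration = 60, seed = seed))
}
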