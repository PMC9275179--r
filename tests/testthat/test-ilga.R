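test_that("partition containers enforce their invariants", {
  expect_error(clusterPartition(c(1L, 1L, 3L), c(2L, 1L)), "permutation")
  expect_error(clusterPartition(1:3, c(2L, 0L, 1L)), "non-empty")
  expect_error(clusterPartition(1:3, c(2L, 2L)), "sum")
  p <- clusterPartition(c(2L, 3L, 1L), c(2L, 1L))
  expect_identical(nClusters(p), 2L)
  expect_identical(clusterAssignments(p), c(2L, 1L, 1L))
})

test_that("initial partitions are valid with cluster counts in 2..ceil(sqrt(n))", {
  set.seed(1)
  # n = 2: the only admissible count is 2 singletons
  p2 <- initPartition(2)
  expect_identical(sort(p2@sizes), c(1L, 1L))
  expect_error(initPartition(1), "at least 2")
  # every draw is valid; at n = 16 all counts 2..4 occur
  counts <- integer(0)
  for (i in 1:2000) {
    p <- initPartition(16)
    expect_true(validObject(p, complete = TRUE))
    counts <- c(counts, nClusters(p))
  }
  expect_setequal(unique(counts), 2:4)
})

test_that("alpha matches hand computations and scales with duplication", {
  X <- matrix(c(0, 2), 2, 1)
  # single cluster holding all samples: cluster mean equals the centre
  expect_equal(computeAlpha(clusterPartition(1:2, 2L), X), 0)
  # two singletons at 0 and 2 about centroid 1
  expect_equal(computeAlpha(clusterPartition(1:2, c(1L, 1L)), X), 2)
  # duplicating every sample doubles alpha (brute-force random instance)
  set.seed(7)
  Y <- matrix(runif(18), 6, 3)
  p <- clusterPartition(c(3L, 1L, 6L, 2L, 4L, 5L), c(2L, 3L, 1L))
  Y2 <- rbind(Y, Y)
  p2 <- clusterPartition(c(3L, 9L, 1L, 7L, 12L, 6L, 2L, 8L, 10L, 4L, 5L, 11L),
                         c(4L, 6L, 2L))
  expect_equal(computeAlpha(p2, Y2), 2 * computeAlpha(p, Y), tolerance = 1e-9)
})

test_that("pairwise gamma equals the centroid within-cluster SSD", {
  X <- matrix(c(0, 2), 2, 1)
  expect_equal(computeGamma(clusterPartition(1:2, c(1L, 1L)), X), 0)
  expect_equal(computeGamma(clusterPartition(1:2, 2L), X), 2)
  set.seed(11)
  for (i in 1:100) {
    n <- sample(4:30, 1)
    X <- matrix(runif(n * 3), n, 3)
    p <- randomPartition(n)
    expect_equal(computeGamma(p, X),
                 naiveWithinSSD(clusterAssignments(p), X),
                 tolerance = 1e-9)
  }
})

test_that("the CH fitness agrees with an independent reference", {
  set.seed(13)
  for (i in 1:40) {
    n <- sample(6:30, 1)
    X <- matrix(runif(n * 2), n, 2)
    p <- randomPartition(n)
    r <- chFitness(p, X)
    expect_equal(r@fCh, naiveCH(clusterAssignments(p), X), tolerance = 1e-9)
    expect_gte(r@alpha, 0)
    expect_gte(r@gamma, 0)
  }
  # normalization factor (n - k)/(k - 1) at n = 4, k = 2 is 2
  X <- matrix(c(0, 0, 10, 10, 0, 1, 0, 1), 4, 2)
  r <- chFitness(clusterPartition(1:4, c(2L, 2L)), X)
  expect_equal(r@fCh, (r@alpha / r@gamma) * 2)
  # a true tight partition beats a random equal-size one
  co <- tightCohort()
  cls <- co$truth$classOfSample
  pTrue <- clusterPartition(order(cls), as.integer(table(cls)))
  set.seed(3)
  pRand <- clusterPartition(sample.int(16), c(8L, 8L))
  expect_gt(chFitness(pTrue, co$betaSet)@fCh,
            chFitness(pRand, co$betaSet)@fCh)
})

test_that("alpha and gamma decompose the total SSD about the centre", {
  set.seed(17)
  for (i in 1:25) {
    n <- sample(5:25, 1)
    X <- matrix(runif(n * 4), n, 4)
    p <- randomPartition(n)
    tot <- sum(sweep(X, 2L, colMeans(X))^2)
    expect_equal(computeAlpha(p, X) + computeGamma(p, X), tot,
                 tolerance = 1e-9)
  }
})

test_that("zero within-cluster dispersion is flagged degenerate", {
  X <- matrix(c(0, 0, 1, 1), 4, 1)
  # all singletons: gamma is exactly 0
  r <- chFitness(clusterPartition(1:4, rep(1L, 4)), X)
  expect_true(r@degenerate)
  expect_identical(r@fCh, Inf)
  # degenerate records never win roulette advantage over finite ones
  set.seed(23)
  picks <- replicate(300, rouletteSelect(list("fin", "deg"), c(5, Inf)))
  expect_true(all(picks == "fin"))
})

test_that("the documented MPX walk-through reproduces the expected offspring", {
  # parent 1: clusters [1,10], [9,4,2], [3,5], [7,8,6]; target cluster 2,
  # cut-off 1, size 3 removes the substring [9,4,2]
  p1 <- clusterPartition(c(1L, 10L, 9L, 4L, 2L, 3L, 5L, 7L, 8L, 6L),
                         c(2L, 3L, 2L, 3L))
  p2 <- clusterPartition(c(4L, 7L, 2L, 10L, 9L, 1L, 3L, 6L, 5L, 8L),
                         c(3L, 4L, 3L))
  off <- methylGA:::mpxRecombine(p1, p2, clusterIdx = 2L, start = 1L,
                                 size = 3L)
  # remainder [1,10,3,5,7,8,6] first, then the removed items in parent 2's
  # relative order (4, 2, 9)
  expect_identical(off@arrangement,
                   c(1L, 10L, 3L, 5L, 7L, 8L, 6L, 4L, 2L, 9L))
  expect_identical(off@arrangement[1:7], c(1L, 10L, 3L, 5L, 7L, 8L, 6L))
  expect_true(validObject(off, complete = TRUE))
})

test_that("MPX offspring always conserve the sample permutation", {
  set.seed(29)
  X <- matrix(runif(12 * 3), 12, 3)
  for (i in 1:300) {
    p1 <- randomPartition(12)
    p2 <- randomPartition(12)
    off <- mpxCrossover(p1, p2, X)
    expect_identical(sort(off@arrangement), 1:12)
    expect_true(all(off@sizes >= 1L))
    expect_identical(sum(off@sizes), 12L)
  }
  # identical parents still yield a valid permutation of the same items
  p <- randomPartition(12)
  off <- mpxCrossover(p, p, X)
  expect_identical(sort(off@arrangement), 1:12)
  expect_error(mpxCrossover(randomPartition(5), randomPartition(12), X),
               "same sample set")
})

test_that("split/merge mutation conserves samples and respects feasibility", {
  set.seed(31)
  X <- matrix(runif(20), 10, 2)
  # probability 0 is the identity
  p <- randomPartition(10)
  expect_identical(splitMergeMutation(p, 0), p)
  # single cluster: only a split is feasible
  one <- clusterPartition(sample.int(10), 10L)
  m1 <- splitMergeMutation(one, 1, X)
  expect_identical(nClusters(m1), 2L)
  # all singletons: only merges are feasible
  singl <- clusterPartition(sample.int(10), rep(1L, 10))
  m2 <- splitMergeMutation(singl, 1, X)
  expect_lt(nClusters(m2), 10L)
  # conservation under repeated mutation, with and without data
  for (i in 1:50) {
    q <- splitMergeMutation(randomPartition(10), 0.5,
                            if (i %% 2) X else NULL)
    expect_identical(sort(q@arrangement), 1:10)
    expect_identical(sum(q@sizes), 10L)
  }
})

test_that("roulette selection is fitness-proportional after min-shift", {
  set.seed(37)
  pop <- as.list(letters[1:3])
  # min-shift leaves only the first individual with weight
  expect_true(all(replicate(200, rouletteSelect(pop, c(5, 0, 0))) == "a"))
  # single member: always that member
  expect_identical(rouletteSelect(list("z"), 3.2), "z")
  expect_error(rouletteSelect(list(), numeric()), "empty")
  # equal fitnesses: uniform within a chi-square 99% bound
  draws <- replicate(10000, rouletteSelect(pop, c(2, 2, 2)))
  tab <- table(factor(unlist(draws), levels = letters[1:3]))
  expect_lt(suppressWarnings(chisq.test(tab)$statistic),
            qchisq(0.99, df = 2))
})

test_that("the inner GA recovers a well-separated two-class structure", {
  co <- tightCohort(nPerClass = 8, seed = 5)
  res <- runIlga(co$betaSet, ilgaConfig(populationSize = 20,
                                        generations = 60, seed = 7))
  cls <- co$truth$classOfSample
  ri <- randIndex(clusterAssignments(res$partition), as.integer(factor(cls)))
  expect_gte(ri, 0.9)
  # elite trajectory is non-decreasing and the run is deterministic
  expect_false(is.unsorted(res$history$best))
  res2 <- runIlga(co$betaSet, ilgaConfig(populationSize = 20,
                                         generations = 60, seed = 7))
  expect_identical(res$history, res2$history)
  expect_identical(res$partition@arrangement, res2$partition@arrangement)
  # the reported record matches an R-side re-evaluation of the partition
  re <- chFitness(res$partition, co$betaSet)
  expect_equal(re@fCh, res$fitness@fCh, tolerance = 1e-9)
  expect_equal(re@alpha, res$fitness@alpha, tolerance = 1e-9)
})

test_that("identical samples yield a flagged degenerate inner-GA result", {
  X <- matrix(0.4, 6, 5)
  res <- runIlga(X, ilgaConfig(populationSize = 5, generations = 3, seed = 1))
  expect_true(res$degenerateData)
})

test_that("partition serialization writes one cluster per line", {
  p <- clusterPartition(c(3L, 1L, 2L, 4L), c(2L, 2L))
  f <- tempfile()
  writePartition(p, f, sampleIds = c("a", "b", "c", "d"))
  expect_identical(readLines(f), c("c\ta", "b\td"))
})
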