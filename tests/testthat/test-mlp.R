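test_that("Adam updates match the bias-corrected hand computation", {
  p <- list(matrix(1, 2, 2))
  st <- adamInit(p, learningRate = 0.001)
  # zero gradient from a zero state leaves parameters unchanged
  out <- adamStep(st, p, list(matrix(0, 2, 2)))
  expect_equal(out$params[[1]], p[[1]])
  # one step with constant g = 1: mhat = 1, vhat = 1, so the update is
  # -lr * 1 / (1 + eps) ~ -0.001
  out1 <- adamStep(st, p, list(matrix(1, 2, 2)))
  expect_equal(out1$params[[1]],
               p[[1]] - 0.001 * 1 / (1 + 1e-08),
               tolerance = 1e-12)
  # identical inputs give identical states
  out2 <- adamStep(st, p, list(matrix(1, 2, 2)))
  expect_identical(out1, out2)
  expect_error(adamStep(st, p, list(matrix(1, 3, 2))), "shape mismatch")
  expect_error(adamInit(p, beta1 = 1), "beta1")
})

test_that("Adam descends a convex quadratic after warm-up", {
  # f(x) = 0.5 * ||x - c||^2, gradient x - c
  target <- c(3, -2)
  x <- list(matrix(c(0, 0), 1, 2))
  st <- adamInit(x, learningRate = 0.05)
  loss <- numeric(200)
  for (i in 1:200) {
    g <- list(x[[1]] - matrix(target, 1, 2))
    loss[i] <- 0.5 * sum(g[[1]]^2)
    out <- adamStep(st, x, g)
    st <- out$state; x <- out$params
  }
  # monotone descent after warm-up until the loss hits the noise floor
  expect_true(all(diff(loss[10:100]) <= 1e-8))
  expect_lt(loss[200], 1e-6)
  expect_lt(loss[100], loss[10] / 100)
})

test_that("input masking zeroes exactly the unselected features", {
  pf <- methylPlatform("custom", 2)
  expect_equal(maskInput(c(0.3, 0.9), featureMask(c(1, 0), pf)), c(0.3, 0))
  full <- featureMask(c(1, 1), pf)
  expect_equal(maskInput(c(0.3, 0.9), full), c(0.3, 0.9))
  X <- matrix(runif(10), 5, 2)
  out <- maskInput(X, featureMask(c(0, 1), pf))
  expect_true(all(out[, 1] == 0))
  expect_identical(out[, 2], X[, 2])
  expect_error(maskInput(c(1, 2, 3), full), "width")
})

sepCohort <- function(seed = 61, nPerClass = 15) {
  generateCohort(cohortSpec(classLabels = data.frame(
                              cancer_type = c("A", "B", "C"),
                              malignant = c(TRUE, TRUE, FALSE)),
                            nSamplesPerClass = nPerClass, nInformative = 40,
                            nNoise = 120, separation = 0.9,
                            concentration = 50, seed = seed))
}

test_that("training fits a separable cohort and is seed-deterministic", {
  co <- sepCohort()
  X <- betaValues(co$betaSet)
  y <- co$truth$classOfSample[rownames(X)]
  spec <- mlpSpec(ncol(X), c(32L), classes = c("A", "B", "C"),
                  learningRate = 0.001)
  fit <- trainMlp(X, y, spec, epochs = 50, batch = 16, seed = 2)
  acc <- mean(predict(fit, X)$labels == y)
  expect_gte(acc, 0.95)
  # training loss decreases overall
  expect_lt(tail(fit$history$train_loss, 1), fit$history$train_loss[1])
  # same seed twice: identical final loss
  fit2 <- trainMlp(X, y, spec, epochs = 50, batch = 16, seed = 2)
  expect_identical(tail(fit$history$train_loss, 1),
                   tail(fit2$history$train_loss, 1))
  # a class with < 2 training samples is a stratification error
  expect_error(trainMlp(X[c(1, 16, 17), ], y[c(1, 16, 17)], spec,
                        epochs = 2, seed = 1),
               "stratification")
})

test_that("permuted labels collapse held-out accuracy to chance", {
  co <- sepCohort(seed = 67, nPerClass = 20)
  X <- betaValues(co$betaSet)
  y <- co$truth$classOfSample[rownames(X)]
  sp <- trainTestSplit(y, 0.7, seed = 3)
  set.seed(9)
  yPerm <- sample(y[sp$train])
  spec <- mlpSpec(ncol(X), c(32L), classes = c("A", "B", "C"),
                  learningRate = 0.001)
  fit <- trainMlp(X[sp$train, ], yPerm, spec, epochs = 40, batch = 16,
                  seed = 4)
  accPerm <- mean(predict(fit, X[sp$test, ])$labels == y[sp$test])
  majority <- max(table(y[sp$test])) / length(sp$test)
  # within binomial noise of the majority-class rate
  expect_lt(accPerm, majority + 3 * sqrt(majority * (1 - majority) / length(sp$test)))
})

test_that("predictions are normalized scores with lexicographic tie-breaks", {
  co <- sepCohort(seed = 71)
  X <- betaValues(co$betaSet)
  y <- co$truth$classOfSample[rownames(X)]
  sp <- trainTestSplit(y, 0.7, seed = 5)
  spec <- mlpSpec(ncol(X), c(32L), classes = c("A", "B", "C"),
                  learningRate = 0.001)
  fit <- trainMlp(X[sp$train, ], y[sp$train], spec, epochs = 50, batch = 16,
                  seed = 6)
  pred <- predict(fit, X[sp$test, ])
  expect_equal(unname(rowSums(pred$scores)), rep(1, length(sp$test)),
               tolerance = 1e-6)
  # the reported label always maximizes the reported score
  for (i in seq_along(sp$test))
    expect_equal(pred$scores[i, pred$labels[i]], max(pred$scores[i, ]))
  expect_gte(mean(pred$labels == y[sp$test]), 0.9)
  expect_error(predict(fit, X[, 1:10]), "width")
})

test_that("outputs depend on selected features only", {
  co <- sepCohort(seed = 73)
  X <- betaValues(co$betaSet)
  y <- co$truth$classOfSample[rownames(X)]
  bits <- rep(c(TRUE, FALSE), 80)
  mask <- featureMask(bits, platformOf(co$betaSet))
  spec <- mlpSpec(ncol(X), c(16L), classes = c("A", "B", "C"),
                  learningRate = 0.001, featureMask = mask)
  fit <- trainMlp(X, y, spec, epochs = 10, batch = 16, seed = 7)
  X2 <- X
  X2[, !bits] <- matrix(runif(sum(!bits) * nrow(X)), nrow(X))
  expect_equal(predict(fit, X)$scores, predict(fit, X2)$scores)
})

test_that("the stratified split is disjoint, exhaustive and per-class 70/30", {
  y <- rep(c("A", "B", "C"), times = c(30, 20, 10))
  sp <- trainTestSplit(y, 0.7, seed = 8)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test), seq_along(y))
  expect_identical(sum(y[sp$train] == "A"), 21L)
  expect_identical(sum(y[sp$train] == "B"), 14L)
  expect_identical(sum(y[sp$train] == "C"), 7L)
  expect_error(trainTestSplit(y, 1.2), "fraction")
})

test_that("grid search enumerates the grid and returns the evaluated best", {
  co <- sepCohort(seed = 79)
  X <- betaValues(co$betaSet)
  y <- co$truth$classOfSample[rownames(X)]
  sp <- trainTestSplit(y, 0.7, seed = 9)
  # a 1-combination grid returns exactly that combination
  g1 <- gridSearch(X[sp$train, ], y[sp$train], X[sp$test, ], y[sp$test],
                   classes = c("A", "B", "C"), learningRates = 0.001,
                   hiddenSizes = 16L, layerCounts = 1L, epochs = 10, seed = 10)
  expect_identical(g1$spec$hiddenLayers, 16L)
  expect_identical(g1$spec$learningRate, 0.001)
  # small exhaustive grid: the winner's accuracy matches the table maximum
  # and multi-layer candidates use halving widths
  g <- gridSearch(X[sp$train, ], y[sp$train], X[sp$test, ], y[sp$test],
                  classes = c("A", "B", "C"),
                  learningRates = c(0.01, 0.001),
                  hiddenSizes = c(32L, 16L), layerCounts = c(1L, 2L),
                  epochs = 10, seed = 10)
  expect_identical(nrow(g$results), 8L)
  expect_equal(max(g$results$accuracy),
               g$results$accuracy[which(
                 g$results$lr == g$spec$learningRate &
                 g$results$size == g$spec$hiddenLayers[1] &
                 g$results$layers == length(g$spec$hiddenLayers))][1])
  two <- g$results$layers == 2
  expect_true(all(g$results$size[two] / 2 >= 1))
  g2spec <- mlpSpec(ncol(X), c(32L, 16L), c("A", "B", "C"), 0.001)
  expect_identical(g2spec$hiddenLayers, c(32L, 16L))
  expect_error(gridSearch(X, y, X, y, classes = c("A", "B", "C"),
                          learningRates = numeric()), "empty")
})

test_that("model checkpoints restore byte-identical predictions", {
  co <- sepCohort(seed = 83)
  X <- betaValues(co$betaSet)
  y <- co$truth$classOfSample[rownames(X)]
  mask <- featureMask(rep(c(TRUE, TRUE, TRUE, FALSE), 40),
                      platformOf(co$betaSet))
  spec <- mlpSpec(ncol(X), c(8L), classes = c("A", "B", "C"),
                  learningRate = 0.001, featureMask = mask)
  fit <- trainMlp(X, y, spec, epochs = 5, batch = 16, seed = 11)
  f <- tempfile(fileext = ".json")
  saveMlp(fit, f)
  back <- loadMlp(f)
  expect_equal(predict(back, X)$scores, predict(fit, X)$scores,
               tolerance = 1e-12)
})
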