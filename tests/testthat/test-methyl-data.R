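test_that("beta values follow the intensity ratio with clamping and offset", {
  expect_identical(computeBeta(0, 500), 0)
  expect_equal(computeBeta(900, 0), 0.9)
  expect_identical(computeBeta(-50, -20), 0)
  expect_error(computeBeta(10, 10, offset = 0), "positive")
  expect_error(computeBeta(10, 10, offset = -5), "positive")

  # monotone non-decreasing in M, non-increasing in U, always < 1
  m <- seq(0, 5000, by = 250)
  expect_true(all(diff(computeBeta(m, 300)) >= 0))
  expect_true(all(diff(computeBeta(300, m)) <= 0))
  set.seed(1)
  expect_true(all(computeBeta(runif(500, -100, 1e5),
                              runif(500, -100, 1e5)) < 1))
  # beta is 0 iff the clamped methylated intensity is 0
  expect_true(all(computeBeta(c(0, -3), c(10, 10)) == 0))
  expect_true(all(computeBeta(c(1e-3, 10), c(10, 10)) > 0))
})

makeBetaSet <- function(m, types = NULL) {
  if (is.null(rownames(m))) rownames(m) <- sprintf("s%d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("cg%05d", seq_len(ncol(m)))
  if (is.null(types)) types <- rep("Breast", nrow(m))
  BetaSet(m, cancerType = types, malignant = rep(TRUE, nrow(m)),
          platform = methylPlatform("custom", ncol(m)))
}

test_that("BetaSet validity rejects malformed containers", {
  m <- matrix(runif(6), 2, 3,
              dimnames = list(c("s1", "s2"), c("cg1", "cg2", "cg3")))
  expect_s4_class(makeBetaSet(m), "BetaSet")
  bad <- m; bad[1, 1] <- 1.7
  expect_error(makeBetaSet(bad), "\\[0, 1\\]")
  expect_error(BetaSet(m, cancerType = "x", malignant = TRUE,
                       platform = methylPlatform("custom", 3)),
               "one entry per sample")
  expect_error(BetaSet(m, cancerType = c("x", "x"),
                       malignant = c(TRUE, TRUE),
                       platform = methylPlatform("custom", 99)),
               "does not match")
})

test_that("missing fractions are exact and unknown samples error", {
  m <- matrix(runif(20), 2, 10)
  m[2, c(3, 7)] <- NA
  bs <- makeBetaSet(m)
  expect_identical(missingFraction(bs, "s1"), 0)
  expect_identical(missingFraction(bs, "s2"), 0.2)
  m[1, ] <- NA
  expect_identical(missingFraction(makeBetaSet(m), "s1"), 1)
  expect_error(missingFraction(bs, "nope"), "unknown sample")
})

test_that("sample rejection is strict at the platform threshold", {
  # 100 loci so missing fractions are exact percentages
  set.seed(42)
  m <- matrix(runif(300), 3, 100)
  m[1, 1:11] <- NA   # 11% missing
  m[2, 1:10] <- NA   # exactly 10%
  bs <- makeBetaSet(m)
  kept <- filterSamples(bs, threshold = 0.10)
  expect_setequal(sampleIds(kept), c("s2", "s3"))
  log <- S4Vectors::metadata(kept)$rejectionLog
  expect_equal(log$sample_id, "s1")
  expect_equal(log$missing_fraction, 0.11)
  # 450k-style threshold keeps a 15%-missing sample
  m2 <- matrix(runif(200), 2, 100)
  m2[1, 1:15] <- NA
  expect_setequal(sampleIds(filterSamples(makeBetaSet(m2), threshold = 0.20)),
                  c("s1", "s2"))
  # all samples rejected -> empty-cohort error
  m3 <- matrix(NA_real_, 2, 100)
  m3[, 1:50] <- 0.5
  expect_error(filterSamples(makeBetaSet(m3), threshold = 0.10),
               "empty cohort")
  # the original object is unmodified
  expect_identical(sum(is.na(betaValues(bs))), 21L)
})

test_that("platform descriptors carry canonical locus counts and thresholds", {
  expect_identical(methylPlatform("27k")$nLoci, 27578L)
  expect_identical(methylPlatform("27k")$missingThreshold, 0.10)
  expect_identical(methylPlatform("450k")$nLoci, 485764L)
  expect_identical(methylPlatform("450k")$missingThreshold, 0.20)
  expect_error(methylPlatform("custom"), "nLoci")
})

test_that("imputation interpolates interior gaps and extrapolates edges", {
  # interior gap: midpoint of the line through the flanking neighbours
  m <- matrix(c(0.2, NA, 0.4), 1, 3)
  out <- betaValues(imputeMissing(makeBetaSet(m)))
  expect_equal(unname(out[1, 2]), 0.3)
  expect_equal(unname(out[1, c(1, 3)]), c(0.2, 0.4))

  # no missing entries: identity
  m2 <- matrix(runif(40), 4, 10, dimnames = list(sprintf("s%d", 1:4), NULL))
  bs2 <- makeBetaSet(m2)
  expect_equal(betaValues(imputeMissing(bs2)), betaValues(bs2))

  # leading-edge gap: least-squares line through the k = 4 nearest
  # observed loci, checked against an independent lm() fit
  v <- c(NA, 0.30, 0.35, 0.42, 0.44, 0.50)
  m3 <- matrix(v, 1, 6)
  out3 <- betaValues(imputeMissing(makeBetaSet(m3)))
  fit <- lm(y ~ x, data = data.frame(x = 2:5, y = v[2:5]))
  expect_equal(unname(out3[1, 1]),
               unname(predict(fit, data.frame(x = 1))), tolerance = 1e-10)

  # imputed values are clamped into [0, 1]
  v4 <- c(NA, NA, 0.05, 0.5, 0.95, NA)
  out4 <- betaValues(imputeMissing(makeBetaSet(matrix(v4, 1, 6))))
  expect_true(all(out4 >= 0 & out4 <= 1))

  # a sample with no observed loci cannot be imputed
  m5 <- rbind(rep(NA_real_, 4), runif(4))
  expect_error(imputeMissing(makeBetaSet(m5)), "no observed loci")
})

test_that("filtering then imputing leaves retained samples fully observed", {
  co <- generateCohort(cohortSpec(nSamplesPerClass = 6, nInformative = 20,
                                  nNoise = 80, missingRate = 0.05,
                                  seed = 9))
  out <- imputeMissing(filterSamples(co$betaSet, threshold = 0.10))
  b <- betaValues(out)
  expect_false(anyNA(b))
  expect_true(all(b >= 0 & b <= 1))
})

test_that("matrix assembly transposes per-sample maps with platform order", {
  pf <- methylPlatform("custom", 5)
  uni <- sprintf("cg%02d", 1:5)
  per <- list(
    a = c(cg01 = 0.1, cg02 = 0.2, cg03 = 0.3, cg04 = 0.4, cg05 = 0.5),
    b = c(cg05 = 0.9, cg01 = 0.8),
    c = c(cg02 = 0.6, cg03 = 0.7, cg04 = 0.65, cg05 = 0.55, cg01 = 0.45))
  labels <- data.frame(sample_id = c("a", "b", "c"),
                       cancer_type = "Breast", malignant = c(1, 1, 0))
  bs <- assembleBetaSet(per, labels, pf, uni)
  expect_identical(dim(betaValues(bs)), c(3L, 5L))
  expect_identical(sampleIds(bs), c("a", "b", "c"))
  expect_identical(lociIds(bs), uni)
  # omitted loci are missing; column order follows the platform
  expect_true(all(is.na(betaValues(bs)["b", c("cg02", "cg03", "cg04")])))
  expect_equal(unname(betaValues(bs)["c", "cg01"]), 0.45)

  dup <- per; names(dup) <- c("a", "a", "c")
  expect_error(assembleBetaSet(dup, labels, pf, uni), "duplicate")
  alien <- per; names(alien$a)[1] <- "cgXX"
  expect_error(assembleBetaSet(alien, labels, pf, uni), "outside the platform")
})

test_that("CSV round trip preserves values, missingness and labels", {
  co <- generateCohort(cohortSpec(nSamplesPerClass = 4, nInformative = 10,
                                  nNoise = 30, missingRate = 0.08, seed = 2))
  f <- tempfile(fileext = ".csv"); fl <- tempfile(fileext = ".csv")
  writeBetaCsv(co$betaSet, f, fl)
  back <- readBetaCsv(f, fl)
  expect_equal(betaValues(back), betaValues(co$betaSet))
  expect_identical(sampleLabels(back), sampleLabels(co$betaSet))
  # serialized forms are byte-stable
  f2 <- tempfile(fileext = ".csv")
  writeBetaCsv(back, f2)
  expect_identical(readLines(f), readLines(f2))

  # malformed labels are reported
  bad <- tempfile(fileext = ".csv")
  writeLines(c("sample_id,cancer_type", "s1,Breast"), bad)
  expect_error(readLabelsCsv(bad), "malignant")
})
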