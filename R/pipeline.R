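## End-to-end orchestration: preprocess -> per-cancer feature selection ->
## common-feature intersection -> binary + pan-class training ->
## evaluation, with manifest-tracked artifacts and a seed hash chain.

#' Pipeline run configuration
#'
#' @param betaSet A [BetaSet-class], or `NULL` to read from files.
#' @param matrixFile,labelsFile CSV inputs (used when `betaSet` is NULL).
#' @param platform Platform of the input (default inferred as custom).
#' @param missingThreshold Rejection threshold for custom platforms.
#' @param olga An [olgaConfig()] template; its seed is re-derived per
#'   cohort from the master seed.
#' @param hiddenLayers,learningRate,epochs,batch MLP settings shared by the
#'   binary and pan models.
#' @param splitFraction Train fraction of the stratified split
#'   (default 0.70).
#' @param seed Master seed; every stage derives its own stream from it.
#' @param threads Worker count for outer-GA mask evaluation.
#' @param outDir Artifact directory.
#' @return A `RunConfig` list.
#' @export
runConfig <- function(betaSet = NULL, matrixFile = NULL, labelsFile = NULL,
                      platform = NULL, missingThreshold = 0.10,
                      olga = olgaConfig(), hiddenLayers = 64L,
                      learningRate = 0.001, epochs = 60L, batch = 16L,
                      splitFraction = 0.70, seed = 1L, threads = 1L,
                      outDir = tempfile("methylga_run_")) {
  if (splitFraction <= 0 || splitFraction >= 1)
    stop("splitFraction must be in (0, 1)")
  structure(list(betaSet = betaSet, matrixFile = matrixFile,
                 labelsFile = labelsFile, platform = platform,
                 missingThreshold = missingThreshold, olga = olga,
                 hiddenLayers = as.integer(hiddenLayers),
                 learningRate = learningRate, epochs = as.integer(epochs),
                 batch = as.integer(batch), splitFraction = splitFraction,
                 seed = as.integer(seed), threads = as.integer(threads),
                 outDir = outDir),
            class = "RunConfig")
}

configHash <- function(config) {
  cfg <- config[setdiff(names(config), c("betaSet", "outDir"))]
  hashString(paste(utils::capture.output(utils::str(cfg)), collapse = "\n"))
}

pipeLog <- function(...) {
  message(format(Sys.time(), "%H:%M:%S"), " [methylGA] ", ...)
}

loadCohort <- function(config) {
  if (!is.null(config$betaSet)) return(config$betaSet)
  if (is.null(config$matrixFile) || is.null(config$labelsFile))
    stop("either a BetaSet or matrixFile + labelsFile must be supplied")
  readBetaCsv(config$matrixFile, config$labelsFile, config$platform)
}

#' Run the full pipeline
#'
#' Executes the stages in order: preprocessing (missingness filtering and
#' imputation), per-cancer-type feature selection over the malignant
#' samples of each type, mask intersection, training of the binary
#' malignancy model and the pan-classification model on the common mask
#' (the classifiers consume the intersection mask), and evaluation on the
#' held-out split. Every artifact is written under `config$outDir`
#' together with a manifest recording the config hash and derived seeds;
#' stages can be re-run individually from the cached artifacts. Sequential
#' runs with the same config and master seed are byte-identical.
#'
#' @param config A [runConfig()].
#' @param stages Character subset of
#'   `c("preprocess", "select", "intersect", "train", "evaluate")`, in
#'   pipeline order; earlier artifacts are loaded from `outDir` when a
#'   stage is skipped.
#' @return Invisible list of artifacts: the preprocessed [BetaSet-class],
#'   per-type masks, the common mask, both fitted models and both
#'   [ClassificationReport-class] objects.
#' @export
runPipeline <- function(config,
                        stages = c("preprocess", "select", "intersect",
                                   "train", "evaluate")) {
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$outDir, ...)
  manifest <- list(config_hash = configHash(config),
                   master_seed = config$seed, stages = stages,
                   seeds = list(), files = list())
  art <- list()

  step <- function(name, expr) {
    pipeLog("stage ", name, " started")
    res <- tryCatch(expr, error = function(e) {
      stop("pipeline halted at stage '", name, "': ", conditionMessage(e),
           call. = FALSE)
    })
    pipeLog("stage ", name, " done")
    res
  }

  ## -- preprocess ----------------------------------------------------------
  if ("preprocess" %in% stages) {
    art$betaSet <- step("preprocess", {
      bs <- loadCohort(config)
      bs <- filterSamples(bs, threshold = if (is.na(platformOf(bs)$missingThreshold))
                                            config$missingThreshold else NULL,
                          logFile = out("rejected_samples.tsv"))
      bs <- imputeMissing(bs)
      writeBetaCsv(bs, out("preprocessed_matrix.csv"), out("labels.csv"))
      bs
    })
  } else {
    art$betaSet <- readBetaCsv(out("preprocessed_matrix.csv"),
                               out("labels.csv"), config$platform)
  }
  bs <- art$betaSet
  lab <- sampleLabels(bs)
  types <- sort(unique(lab$cancer_type[lab$malignant]))

  ## -- select --------------------------------------------------------------
  if ("select" %in% stages) {
    art$masks <- step("select", {
      masks <- list()
      for (i in seq_along(types)) {
        ty <- types[i]
        cohort <- bs[, lab$malignant & lab$cancer_type == ty]
        cfg <- config$olga
        cfg@seed <- deriveSeed(config$seed, 1L, i)
        cfg@threads <- config$threads
        manifest$seeds[[paste0("select_", ty)]] <- cfg@seed
        sel <- runOlga(cohort, cfg)
        masks[[ty]] <- sel$mask
        writeMaskBits(sel$mask, out(paste0("mask_", ty, ".csv")))
        utils::write.csv(sel$history, out(paste0("history_", ty, ".csv")),
                         row.names = FALSE)
      }
      masks
    })
  } else {
    art$masks <- lapply(stats::setNames(types, types), function(ty) {
      readMaskBits(out(paste0("mask_", ty, ".csv")), platformOf(bs))
    })
  }

  ## -- intersect -----------------------------------------------------------
  if ("intersect" %in% stages) {
    art$commonMask <- step("intersect", {
      cm <- commonFeatures(unname(art$masks))
      writeMaskBits(cm, out("mask_common.csv"))
      cm
    })
  } else {
    art$commonMask <- readMaskBits(out("mask_common.csv"), platformOf(bs))
  }

  ## -- train ---------------------------------------------------------------
  X <- betaValues(bs)
  binY <- ifelse(lab$malignant, "malignant", "benign")
  panY <- ifelse(lab$malignant, lab$cancer_type, "normal")
  splitSeed <- deriveSeed(config$seed, 2L)
  manifest$seeds$split <- splitSeed
  sp <- trainTestSplit(panY, config$splitFraction, splitSeed)

  if ("train" %in% stages) {
    models <- step("train", {
      trainSeed <- deriveSeed(config$seed, 3L)
      manifest$seeds$train <- trainSeed
      mk <- function(classes) {
        mlpSpec(ncol(X), config$hiddenLayers, classes, config$learningRate,
                featureMask = art$commonMask)
      }
      binM <- trainMlp(X[sp$train, , drop = FALSE], binY[sp$train],
                       mk(c("benign", "malignant")), epochs = config$epochs,
                       batch = config$batch, seed = trainSeed)
      panM <- trainMlp(X[sp$train, , drop = FALSE], panY[sp$train],
                       mk(sort(unique(panY))), epochs = config$epochs,
                       batch = config$batch, seed = deriveSeed(trainSeed, 1L))
      saveMlp(binM, out("model_binary.json"))
      saveMlp(panM, out("model_pan.json"))
      list(binary = binM, pan = panM)
    })
  } else {
    models <- list(binary = loadMlp(out("model_binary.json")),
                   pan = loadMlp(out("model_pan.json")))
  }
  art$models <- models

  ## -- evaluate ------------------------------------------------------------
  if ("evaluate" %in% stages) {
    art$reports <- step("evaluate", {
      evalOne <- function(model, y, tag) {
        pred <- predict(model, X[sp$test, , drop = FALSE])
        rep <- classificationReport(y[sp$test], pred$labels, pred$scores,
                                    classes = model$classes)
        writeReport(rep, out(paste0("report_", tag, ".json")),
                    rocFile = out(paste0("roc_", tag, ".tsv")),
                    heatmapFile = out(paste0("heatmap_", tag, ".csv")))
        utils::write.csv(
          data.frame(sample_id = sampleIds(bs)[sp$test],
                     predicted_class = pred$labels,
                     round(pred$scores, 10), check.names = FALSE),
          out(paste0("predictions_", tag, ".csv")), row.names = FALSE)
        rep
      }
      list(binary = evalOne(models$binary, binY, "binary"),
           pan = evalOne(models$pan, panY, "pan"))
    })
  }

  manifest$files <- sort(list.files(config$outDir))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(art)
}

#' Save / load a fitted MLP as a self-describing JSON checkpoint
#'
#' @param model An `MlpModel`.
#' @param file Path.
#' @export
saveMlp <- function(model, file) {
  doc <- list(input_width = model$spec$inputWidth,
              hidden_layers = model$spec$hiddenLayers,
              classes = model$classes,
              learning_rate = model$spec$learningRate,
              mask_bits = if (!is.null(model$spec$featureMask))
                as.integer(model$spec$featureMask@bits),
              W = lapply(model$W, function(w) unname(as.matrix(w))),
              b = lapply(model$b, as.numeric))
  jsonlite::write_json(doc, file, digits = NA, auto_unbox = TRUE)
  invisible(file)
}

#' @rdname saveMlp
#' @return `loadMlp()`: the restored `MlpModel`.
#' @export
loadMlp <- function(file) {
  doc <- jsonlite::read_json(file, simplifyVector = TRUE)
  mask <- NULL
  if (!is.null(doc$mask_bits))
    mask <- featureMask(doc$mask_bits == 1,
                        methylPlatform("custom", length(doc$mask_bits)))
  spec <- mlpSpec(doc$input_width, doc$hidden_layers, doc$classes,
                  doc$learning_rate, mask)
  W <- lapply(doc$W, function(w) {
    if (is.matrix(w)) w
    else matrix(unlist(w), nrow = length(w), byrow = TRUE)
  })
  structure(list(spec = spec, classes = doc$classes, W = W,
                 b = lapply(doc$b, as.numeric),
                 history = data.frame()),
            class = "MlpModel")
}

#' Replicate the feature selector and summarise its stability
#'
#' Runs [runOlga()] `n` times under seeds derived from the master seed and
#' reports the selected-feature counts, their mean, and the normalized 95%
#' confidence interval half-width `t * sd/sqrt(n) / mean` (Student t with
#' `n - 1` degrees of freedom), the stability statistic used to report
#' selector precision.
#'
#' @param data A fully observed [BetaSet-class] or matrix.
#' @param config An [olgaConfig()] template.
#' @param n Number of replicates (>= 2).
#' @return List with `counts`, `mean`, `ciHalfWidth`, `normalizedCI`
#'   (half-width divided by the mean; multiply by 100 for percent).
#' @export
replicateRuns <- function(data, config, n = 5L) {
  if (n < 2L) stop("at least 2 replicates are required")
  counts <- integer(n)
  for (r in seq_len(n)) {
    cfg <- config
    cfg@seed <- deriveSeed(config@seed, 11L, r)
    counts[r] <- sum(runOlga(data, cfg)$mask@bits)
  }
  m <- mean(counts)
  hw <- if (stats::sd(counts) == 0) 0
        else stats::qt(0.975, n - 1L) * stats::sd(counts) / sqrt(n)
  list(counts = counts, mean = m, ciHalfWidth = hw,
       normalizedCI = if (m > 0) hw / m else 0)
}
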