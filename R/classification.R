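#' Stratified train/test split
#'
#' Splits sample indices into a training and a test set while maintaining
#' class proportions. The total test size is `ceiling(testFraction * N)`;
#' per-class test counts are allocated proportionally by floor, with the
#' remaining seats assigned by largest fractional remainder (ties broken
#' in favour of the larger class, then by class-name order). Within-class
#' membership is drawn uniformly at random under the seed.
#'
#' @param labels character vector of class labels, one per sample.
#' @param testFraction fraction of samples held out (default 0.2).
#' @param seed integer seed.
#' @return list with `train` and `test` (integer index vectors into
#'   `labels`), `perClass` (`data.frame` of per-class train/test counts),
#'   `testFraction`, `seed`.
#' @examples
#' labs <- rep(c("HD", "NLPBL", "DLBCL", "CLL"), c(291, 90, 182, 348))
#' stratifiedSplit(labs, 0.2, seed = 1)$perClass
#' @export
stratifiedSplit <- function(labels, testFraction = 0.2, seed = 1L) {
  if (!length(labels)) .stopf("no samples to split")
  if (testFraction <= 0 || testFraction >= 1)
    .stopf("'testFraction' must lie in (0, 1)")
  classes <- unique(labels)
  sizes <- vapply(classes, function(cl) sum(labels == cl), integer(1L))
  if (any(sizes == 0L)) .stopf("empty class in 'labels'")
  n <- length(labels)
  total <- ceiling(testFraction * n)

  exact <- sizes * total / n
  alloc <- floor(exact)
  seats <- total - sum(alloc)
  if (seats > 0L) {
    remainder <- exact - alloc
    pick <- order(-remainder, -sizes, classes)[seq_len(seats)]
    alloc[pick] <- alloc[pick] + 1L
  }
  if (any(alloc > sizes))
    .stopf("test allocation exceeds a class size; lower 'testFraction'")

  test <- withr::with_seed(.deriveSeed(seed, 1L), {
    unlist(lapply(seq_along(classes), function(i) {
      idx <- which(labels == classes[i])
      if (alloc[i] == 0L) integer() else sort(sample(idx, alloc[i]))
    }))
  })
  test <- sort(test)
  train <- setdiff(seq_len(n), test)
  perClass <- data.frame(class = classes, size = sizes,
                         test = as.integer(alloc),
                         train = as.integer(sizes - alloc),
                         stringsAsFactors = FALSE)
  rownames(perClass) <- NULL
  list(train = train, test = test, perClass = perClass,
       testFraction = testFraction, seed = as.integer(seed))
}

#' Random oversampling of all classes but the majority class
#'
#' Every non-majority class is resampled with replacement up to the
#' majority-class count; the majority class is untouched. Returns an index
#' multiset over the input samples with equal class counts.
#'
#' @param labels character vector of training labels.
#' @param seed integer seed.
#' @return integer index vector (with repeats) into `labels`.
#' @examples
#' table(rep(c("a", "b"), c(5, 2))[randomOversample(
#'   rep(c("a", "b"), c(5, 2)), seed = 1)])
#' @export
randomOversample <- function(labels, seed = 1L) {
  if (!length(labels)) .stopf("no samples to oversample")
  classes <- unique(labels)
  sizes <- vapply(classes, function(cl) sum(labels == cl), integer(1L))
  target <- max(sizes)
  withr::with_seed(.deriveSeed(seed, 2L), {
    unlist(lapply(classes, function(cl) {
      idx <- which(labels == cl)
      extra <- target - length(idx)
      if (extra > 0L) c(idx, sample(idx, extra, replace = TRUE)) else idx
    }))
  })
}

## Stratified k-fold assignment over the original training samples.
.stratifiedFolds <- function(labels, k, seed) {
  fold <- integer(length(labels))
  withr::with_seed(.deriveSeed(seed, 3L), {
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

#' Default hyperparameter grids
#'
#' Logistic family: ridge penalty `lambda` in \{0.01, 0.1, 1, 10, 100\}
#' crossed with feature scaling on/off. Forest family: number of trees in
#' \{100, 300, 500\}, maximum depth in \{unlimited, 10, 30\}, scaling
#' on/off.
#'
#' @param family `"logistic"` or `"forest"`.
#' @return `data.frame`, one row per grid point.
#' @export
defaultGrid <- function(family = c("logistic", "forest")) {
  family <- match.arg(family)
  if (family == "logistic")
    expand.grid(lambda = c(0.01, 0.1, 1, 10, 100),
                scaling = c(TRUE, FALSE))
  else
    expand.grid(num_trees = c(100L, 300L, 500L),
                max_depth = c(0L, 10L, 30L),   # 0 = unlimited
                scaling = c(TRUE, FALSE))
}

.fitModel <- function(x, y, family, params, seed = 1L) {
  y <- factor(y)
  if (family == "logistic") {
    # fit along a short descending path containing the target penalty;
    # glmnet's warm starts are more stable than a single-lambda fit
    path <- sort(unique(c(100, 10, 1, 0.1, 0.01, params$lambda)),
                 decreasing = TRUE)
    fit <- withCallingHandlers(
      glmnet::glmnet(x, y, family = "multinomial", alpha = 0,
                     lambda = path, standardize = FALSE),
      warning = function(w) {
        # routine small-class advisory on tiny validation folds
        if (grepl("fewer than 8", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
    coefs <- stats::coef(fit, s = params$lambda)
    coefMatrix <- do.call(cbind, lapply(coefs, function(cc)
      as.matrix(cc)[-1L, 1L]))  # drop intercept row
    colnames(coefMatrix) <- names(coefs)
    structure(list(fit = fit, lambda = params$lambda,
                   classes = levels(y), coefMatrix = coefMatrix,
                   featureNames = colnames(x), family = "logistic"),
              class = "lymphrepModel")
  } else {
    xd <- as.data.frame(x)
    colnames(xd) <- paste0("f", seq_len(ncol(xd)))
    fit <- ranger::ranger(
      x = xd, y = y,
      num.trees = params$num_trees,
      max.depth = if (params$max_depth == 0L) NULL else params$max_depth,
      importance = "impurity",
      seed = .deriveSeed(seed, 4L),
      num.threads = 1L)
    structure(list(fit = fit, classes = levels(y),
                   featureNames = colnames(x), family = "forest"),
              class = "lymphrepModel")
  }
}

.predictModel <- function(model, x) {
  if (model$family == "logistic") {
    as.character(stats::predict(model$fit, newx = x, type = "class",
                                s = model$lambda)[, 1L])
  } else {
    xd <- as.data.frame(x)
    colnames(xd) <- paste0("f", seq_len(ncol(xd)))
    as.character(stats::predict(model$fit, data = xd)$predictions)
  }
}

## Per-class precision/recall/F1 with the zero-division -> 0 convention.
.classificationMetrics <- function(true, pred, classes) {
  conf <- table(factor(true, levels = classes),
                factor(pred, levels = classes))
  tp <- diag(conf)
  predTotal <- colSums(conf)
  trueTotal <- rowSums(conf)
  precision <- ifelse(predTotal > 0, tp / predTotal, 0)
  recall <- ifelse(trueTotal > 0, tp / trueTotal, 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  zeroDiv <- predTotal == 0 | trueTotal == 0
  support <- as.integer(trueTotal)
  list(
    table = data.frame(class = classes,
                       precision = unname(precision),
                       recall = unname(recall),
                       f1 = unname(f1),
                       support = support,
                       zero_division = unname(zeroDiv),
                       stringsAsFactors = FALSE),
    confusion = unclass(conf),
    accuracy = sum(tp) / length(true),
    weightedF1 = sum(f1 * support) / sum(support))
}

#' Support-weighted F1 of a prediction
#'
#' @param true,pred character vectors of true and predicted labels.
#' @param classes class set (defaults to the classes present in `true`).
#' @return weighted mean of per-class F1 scores (zero-division -> 0).
#' @export
weightedF1Score <- function(true, pred, classes = unique(true)) {
  .classificationMetrics(true, pred, classes)$weightedF1
}

#' Grid-search with stratified k-fold cross-validation
#'
#' Stratified k-fold cross-validation over the original training samples.
#' Within each fold iteration the k-1 training folds are randomly
#' oversampled (majority class untouched) and, for grid points with
#' scaling enabled, standardisation is refit on the oversampled training
#' folds only; the held-out fold is scored untouched by either, so
#' duplicated samples never cross a fold boundary and no scaling
#' statistics leak from validation data. For each grid point the
#' support-weighted F1 on the held-out fold is averaged over folds; the
#' best setting is the highest mean, ties broken by grid order.
#'
#' @param x unscaled feature matrix (rows = training samples, with the
#'   `nSlots` attribute from [assembleFeatureMatrix()]).
#' @param labels training labels (row order of `x`).
#' @param schema the [FeatureSchema-class] used to build `x`.
#' @param family `"logistic"` or `"forest"`.
#' @param k number of folds (default 3); must not exceed the smallest
#'   class count.
#' @param seed integer seed.
#' @param grid hyperparameter grid (default [defaultGrid()]).
#' @return list with `best` (named list of chosen hyperparameters),
#'   `bestScore` (its mean CV weighted F1), `cvTable` (per-grid-point mean
#'   scores), `folds` (fold assignment vector).
#' @export
gridSearchCV <- function(x, labels, schema,
                         family = c("logistic", "forest"),
                         k = 3L, seed = 1L, grid = defaultGrid(family)) {
  family <- match.arg(family)
  if (k < 2L) .stopf("'k' must be >= 2")
  counts <- table(labels)
  if (k > min(counts))
    .stopf("k = %d exceeds the smallest class count (%d)", k, min(counts))
  if (!nrow(grid)) .stopf("empty hyperparameter grid")

  nSlots <- attr(x, "nSlots")
  if (is.null(nSlots)) nSlots <- rep(schema@nClonotypes, nrow(x))
  folds <- .stratifiedFolds(labels, k, seed)

  scores <- matrix(NA_real_, nrow(grid), k)
  for (f in seq_len(k)) {
    trainIdx <- which(folds != f)
    validIdx <- which(folds == f)
    osIdx <- trainIdx[randomOversample(labels[trainIdx],
                                       seed = .deriveSeed(seed, 100L + f))]
    xTrainRaw <- x[osIdx, , drop = FALSE]
    xValidRaw <- x[validIdx, , drop = FALSE]
    schemaFold <- fitScaling(schema, xTrainRaw)
    xTrainScaled <- .applyScaling(xTrainRaw, schemaFold, nSlots[osIdx])
    xValidScaled <- .applyScaling(xValidRaw, schemaFold, nSlots[validIdx])
    for (g in seq_len(nrow(grid))) {
      params <- as.list(grid[g, , drop = FALSE])
      useScaled <- isTRUE(params$scaling)
      xt <- if (useScaled) xTrainScaled else xTrainRaw
      xv <- if (useScaled) xValidScaled else xValidRaw
      model <- .fitModel(xt, labels[osIdx], family, params,
                         seed = .deriveSeed(seed, 200L + f))
      pred <- .predictModel(model, xv)
      scores[g, f] <- weightedF1Score(labels[validIdx], pred,
                                      classes = sort(unique(labels)))
    }
  }
  meanScores <- rowMeans(scores)
  bestIdx <- which.max(meanScores)  # ties -> first occurrence, grid order
  cvTable <- cbind(grid, mean_cv_f1 = meanScores)
  list(best = as.list(grid[bestIdx, , drop = FALSE]),
       bestScore = meanScores[bestIdx],
       cvTable = cvTable,
       folds = folds)
}

#' Fit the final model and evaluate on the test set
#'
#' Refits the chosen hyperparameter setting on the full training set
#' (randomly oversampled; scaling refit on the oversampled training set if
#' the chosen setting enables it) and computes per-class precision,
#' recall, F1 and support, accuracy, the support-weighted F1 and the
#' confusion matrix on the held-out test samples. Undefined precision or
#' recall (zero denominator) is reported as 0 and flagged in the
#' `zero_division` column.
#'
#' @param xTrain,xTest unscaled feature matrices (train / test rows, each
#'   with its `nSlots` attribute).
#' @param yTrain,yTest labels.
#' @param schema the [FeatureSchema-class] used to build the matrices.
#' @param family `"logistic"` or `"forest"`.
#' @param params chosen hyperparameters (named list; see [defaultGrid()]).
#' @param seed integer seed.
#' @param scenario,nClonotypes metadata recorded in the report.
#' @return an [EvaluationReport-class].
#' @export
fitFinalAndEvaluate <- function(xTrain, yTrain, xTest, yTest, schema,
                                family = c("logistic", "forest"),
                                params, seed = 1L,
                                scenario = "", nClonotypes = NA_integer_) {
  family <- match.arg(family)
  if (!nrow(xTest) || !length(yTest)) .stopf("empty test set")
  unseen <- setdiff(unique(yTest), unique(yTrain))
  if (length(unseen))
    .stopf("test class(es) absent from training: %s",
           paste(unseen, collapse = ", "))

  nSlotsTrain <- attr(xTrain, "nSlots")
  if (is.null(nSlotsTrain)) nSlotsTrain <- rep(schema@nClonotypes, nrow(xTrain))
  nSlotsTest <- attr(xTest, "nSlots")
  if (is.null(nSlotsTest)) nSlotsTest <- rep(schema@nClonotypes, nrow(xTest))

  osIdx <- randomOversample(yTrain, seed = .deriveSeed(seed, 300L))
  xt <- xTrain[osIdx, , drop = FALSE]
  yt <- yTrain[osIdx]
  xv <- xTest
  if (isTRUE(params$scaling)) {
    schemaFit <- fitScaling(schema, xt)
    xt <- .applyScaling(xt, schemaFit, nSlotsTrain[osIdx])
    xv <- .applyScaling(xTest, schemaFit, nSlotsTest)
  }
  model <- .fitModel(xt, yt, family, params, seed = .deriveSeed(seed, 301L))
  pred <- .predictModel(model, xv)
  classes <- sort(unique(yTrain))
  met <- .classificationMetrics(yTest, pred, classes)

  report <- new("EvaluationReport",
                classMetrics = met$table,
                accuracy = met$accuracy,
                weightedF1 = met$weightedF1,
                confusion = met$confusion,
                scenario = scenario,
                nClonotypes = as.integer(nClonotypes),
                model = family,
                hyperparameters = params)
  attr(report, "fittedModel") <- model
  report
}

#' Predefined classification scenarios
#'
#' The three class-set scenarios evaluated by the pipeline.
#'
#' @return named list of class-label vectors.
#' @export
lymphomaScenarios <- function() {
  list(
    "HD_DLBCL_CLL" = c("HD", "DLBCL", "CLL"),
    "HD_NLPBL_DLBCL" = c("HD", "NLPBL", "DLBCL"),
    "HD_NLPBL_DLBCL_CLL" = c("HD", "NLPBL", "DLBCL", "CLL"))
}

#' Run a full classification scenario over an n-sweep
#'
#' For each number of top clonotypes n in the sweep and each model family,
#' runs the full pipeline on the scenario's classes: stratified 80/20
#' split, schema construction on the training split, stratified k-fold
#' grid-search cross-validation with per-fold oversampling and scaling,
#' final fit on the oversampled training set, and test-set evaluation.
#'
#' @param repertoires named list of labelled [Repertoire-class] objects.
#' @param scenarioClasses character vector of class labels to include
#'   (>= 2), e.g. an element of [lymphomaScenarios()].
#' @param nSweep clonotype counts to sweep (subset of 1..10, 20, 50, 100).
#' @param families model families to fit.
#' @param testFraction held-out fraction (default 0.2).
#' @param k CV folds (default 3).
#' @param seed integer seed driving split, folds, oversampling and forest
#'   fitting.
#' @param scenarioName name recorded in reports.
#' @return list with `results` (tidy `data.frame`: scenario, model, n,
#'   mean CV weighted F1, test weighted F1, accuracy, chosen
#'   hyperparameters), `reports` (list of [EvaluationReport-class]),
#'   `split` (the split plan), `schemas` (per-n [FeatureSchema-class]).
#' @export
runScenario <- function(repertoires, scenarioClasses,
                        nSweep = c(1L, 3L, 10L),
                        families = c("logistic", "forest"),
                        testFraction = 0.2, k = 3L, seed = 1L,
                        scenarioName = paste(scenarioClasses,
                                             collapse = "_")) {
  if (length(scenarioClasses) < 2L)
    .stopf("a scenario needs >= 2 classes")
  labelsAll <- vapply(repertoires, classLabel, character(1L))
  missing <- setdiff(scenarioClasses, labelsAll)
  if (length(missing))
    .stopf("scenario class(es) absent from the cohort: %s",
           paste(missing, collapse = ", "))
  keep <- labelsAll %in% scenarioClasses
  reps <- repertoires[keep]
  labels <- labelsAll[keep]

  split <- stratifiedSplit(labels, testFraction, seed)
  trainReps <- reps[split$train]
  testReps <- reps[split$test]
  yTrain <- labels[split$train]
  yTest <- labels[split$test]

  rows <- list()
  reports <- list()
  schemas <- list()
  for (n in nSweep) {
    schema <- buildSchema(trainReps, n)
    schemas[[as.character(n)]] <- schema
    train <- assembleFeatureMatrix(trainReps, schema, scale = FALSE)
    test <- assembleFeatureMatrix(testReps, schema, scale = FALSE)
    for (family in families) {
      cv <- gridSearchCV(train$x, yTrain, schema, family, k = k,
                         seed = seed)
      report <- fitFinalAndEvaluate(train$x, yTrain, test$x, yTest,
                                    schema, family, cv$best, seed = seed,
                                    scenario = scenarioName,
                                    nClonotypes = n)
      key <- sprintf("%s_n%d", family, n)
      reports[[key]] <- report
      rows[[key]] <- data.frame(
        scenario = scenarioName, model = family, n = as.integer(n),
        cv_weighted_f1 = cv$bestScore,
        test_weighted_f1 = report@weightedF1,
        accuracy = report@accuracy,
        hyperparameters = paste(names(cv$best),
                                unlist(lapply(cv$best, as.character)),
                                sep = "=", collapse = ";"),
        stringsAsFactors = FALSE)
    }
  }
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  list(results = results, reports = reports, split = split,
       schemas = schemas)
}
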