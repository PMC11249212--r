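test_that("stratified 80/20 split reproduces the cohort allocation table", {
  labs <- rep(c("HD", "NLPBL", "DLBCL", "CLL"), c(291, 90, 182, 348))
  plan <- stratifiedSplit(labs, 0.2, seed = 1)
  pc <- plan$perClass
  expect_equal(pc$test[match(c("HD", "NLPBL", "DLBCL", "CLL"), pc$class)],
               c(58L, 18L, 37L, 70L))
  expect_equal(pc$train[match(c("HD", "NLPBL", "DLBCL", "CLL"), pc$class)],
               c(233L, 72L, 145L, 278L))
  # 125 lymphoma + 58 HD test samples in total
  expect_equal(sum(pc$test), 183L)
  expect_equal(sum(pc$test[pc$class != "HD"]), 125L)
})

test_that("largest-remainder allocation resolves fractional seats", {
  plan <- stratifiedSplit(rep(c("a", "b"), c(6, 4)), 0.25, seed = 3)
  expect_equal(sum(plan$perClass$test), 3L)
  expect_equal(plan$perClass$test[plan$perClass$class == "a"], 2L)
  expect_equal(plan$perClass$test[plan$perClass$class == "b"], 1L)
})

test_that("single-class splits follow the ceiling rule", {
  plan <- stratifiedSplit(rep("x", 10), 0.2, seed = 5)
  expect_length(plan$test, 2L)
  expect_length(plan$train, 8L)
})

test_that("splits partition the cohort with proportional class allocation", {
  withr::with_seed(17, {
    for (i in 1:50) {
      k <- sample(2:5, 1L)
      sizes <- sample(5:60, k)
      labs <- rep(letters[seq_len(k)], sizes)
      tf <- runif(1L, 0.1, 0.4)
      plan <- stratifiedSplit(labs, tf, seed = i)
      expect_length(intersect(plan$train, plan$test), 0L)
      expect_setequal(c(plan$train, plan$test), seq_along(labs))
      expect_equal(length(plan$test), ceiling(tf * length(labs)))
      exact <- sizes * length(plan$test) / length(labs)
      expect_true(all(plan$perClass$test >= floor(exact)))
      expect_true(all(plan$perClass$test <= ceiling(exact)))
    }
  })
  expect_error(stratifiedSplit(character()), "no samples")
})

test_that("oversampling equalises counts and never touches the majority class", {
  labs <- rep(c("HD", "NLPBL", "DLBCL", "CLL"), c(233, 72, 145, 278))
  idx <- randomOversample(labs, seed = 2)
  counts <- table(labs[idx])
  expect_true(all(counts == 278L))
  expect_length(idx, 1112L)
  majority <- which(labs == "CLL")
  expect_identical(sort(idx[labs[idx] == "CLL"]), majority)
  # balanced input returned unchanged up to ordering
  bal <- rep(c("a", "b"), each = 5L)
  expect_setequal(randomOversample(bal, seed = 1), seq_along(bal))
  expect_identical(sort(randomOversample(rep("a", 4L), seed = 1)), 1:4)
})

test_that("hand-computed confusion-matrix metrics are reproduced", {
  met <- lymphrep:::.classificationMetrics(c("A", "A", "B", "B"),
                                           c("A", "B", "B", "B"),
                                           c("A", "B"))
  tbl <- met$table
  expect_equal(tbl$precision[tbl$class == "A"], 1.0)
  expect_equal(tbl$recall[tbl$class == "A"], 0.5)
  expect_equal(tbl$f1[tbl$class == "A"], 2 / 3)
  expect_equal(tbl$precision[tbl$class == "B"], 2 / 3)
  expect_equal(tbl$recall[tbl$class == "B"], 1.0)
  expect_equal(tbl$f1[tbl$class == "B"], 0.8)
  expect_equal(met$accuracy, 0.75)
  expect_equal(met$weightedF1, (2 * 2 / 3 + 2 * 0.8) / 4)
})

test_that("undefined precision or recall reports zero and is flagged", {
  met <- lymphrep:::.classificationMetrics(c("A", "A", "B"),
                                           c("A", "A", "A"),
                                           c("A", "B"))
  tbl <- met$table
  expect_equal(tbl$precision[tbl$class == "B"], 0)
  expect_equal(tbl$f1[tbl$class == "B"], 0)
  expect_true(tbl$zero_division[tbl$class == "B"])
})

test_that("grid-search CV separates well-separated synthetic classes", {
  reps <- fastCohort(12L, seed = 44)
  labels <- vapply(reps, classLabel, character(1L))
  keep <- labels %in% c("HD", "CLL")
  reps <- reps[keep]; labels <- labels[keep]
  schema <- buildSchema(reps, 2)
  fm <- assembleFeatureMatrix(reps, schema, scale = FALSE)
  cv <- gridSearchCV(fm$x, labels, schema, "logistic", k = 3, seed = 9)
  expect_gte(cv$bestScore, 0.95)
  expect_true(all(c("lambda", "scaling") %in% names(cv$best)))
})

test_that("randomly permuted labels score near chance in CV", {
  reps <- fastCohort(12L, seed = 45)
  labels <- withr::with_seed(46, sample(rep(c("w", "x", "y", "z"), 12L)))
  schema <- buildSchema(reps, 2)
  fm <- assembleFeatureMatrix(reps, schema, scale = FALSE)
  cv <- gridSearchCV(fm$x, labels, schema, "logistic", k = 3, seed = 9)
  expect_lt(cv$bestScore, 0.5)
})

test_that("CV rejects folds exceeding the smallest class", {
  reps <- fastCohort(3L, seed = 47)[c(1:3, 4:5)]  # one class of size 2
  labels <- vapply(reps, classLabel, character(1L))
  schema <- buildSchema(reps, 1)
  fm <- assembleFeatureMatrix(reps, schema, scale = FALSE)
  expect_error(gridSearchCV(fm$x, labels, schema, "logistic", k = 3),
               "smallest class")
})

test_that("CV folds partition samples and oversampling stays inside folds", {
  reps <- fastCohort(6L, seed = 48)
  labels <- vapply(reps, classLabel, character(1L))
  schema <- buildSchema(reps, 1)
  fm <- assembleFeatureMatrix(reps, schema, scale = FALSE)
  cv <- gridSearchCV(fm$x, labels, schema, "logistic", k = 3, seed = 7)
  folds <- cv$folds
  expect_setequal(unique(folds), 1:3)
  # stratification: every class appears in every fold
  for (f in 1:3)
    expect_setequal(unique(labels[folds == f]), unique(labels))
  # the oversampled multiset for fold f draws only from the other folds
  for (f in 1:3) {
    trainIdx <- which(folds != f)
    osIdx <- trainIdx[randomOversample(labels[trainIdx],
                                       seed = lymphrep:::.deriveSeed(7, 100L + f))]
    expect_length(intersect(osIdx, which(folds == f)), 0L)
  }
})

test_that("final evaluation validates its inputs", {
  reps <- fastCohort(5L, seed = 50)
  labels <- vapply(reps, classLabel, character(1L))
  schema <- buildSchema(reps, 1)
  fm <- assembleFeatureMatrix(reps, schema, scale = FALSE)
  params <- list(lambda = 1, scaling = FALSE)
  expect_error(
    fitFinalAndEvaluate(fm$x, labels, fm$x[0, , drop = FALSE], character(),
                        schema, "logistic", params),
    "empty test")
  expect_error(
    fitFinalAndEvaluate(fm$x[1:10, ], labels[1:10], fm$x[11:12, ],
                        c("nosuch", "nosuch"), schema, "logistic", params),
    "absent from training")
})

test_that("perfect predictions yield accuracy and weighted F1 of one", {
  reps <- fastCohort(8L, seed = 51)
  labels <- vapply(reps, classLabel, character(1L))
  keep <- labels %in% c("HD", "CLL")
  reps <- reps[keep]; labels <- labels[keep]
  plan <- stratifiedSplit(labels, 0.25, seed = 4)
  schema <- buildSchema(reps[plan$train], 2)
  train <- assembleFeatureMatrix(reps[plan$train], schema, scale = FALSE)
  test <- assembleFeatureMatrix(reps[plan$test], schema, scale = FALSE)
  report <- fitFinalAndEvaluate(train$x, labels[plan$train], test$x,
                                labels[plan$test], schema, "logistic",
                                list(lambda = 0.1, scaling = TRUE),
                                seed = 4, scenario = "sep", nClonotypes = 2)
  # HD vs CLL presets are far apart; expect the clean optimum
  expect_equal(report@accuracy, 1.0)
  expect_equal(weightedF1(report), 1.0)
  expect_equal(sum(classMetrics(report)$support), length(plan$test))
})

test_that("runScenario sweeps n and model families into a tidy table", {
  reps <- fastCohort(6L, seed = 52)
  run <- runScenario(reps, c("HD", "NLPBL", "DLBCL", "CLL"),
                     nSweep = c(1L, 2L), families = c("logistic", "forest"),
                     seed = 6)
  expect_equal(nrow(run$results), 4L)
  expect_setequal(run$results$model, c("logistic", "forest"))
  expect_setequal(run$results$n, c(1L, 2L))
  expect_true(all(run$results$test_weighted_f1 >= 0 &
                    run$results$test_weighted_f1 <= 1))
  expect_error(runScenario(reps, c("HD", "nosuch")), "absent from the cohort")
  expect_error(runScenario(reps, "HD"), ">= 2 classes")
})

test_that("test-only genes never enter the schema vocabulary", {
  trainRep <- collapseToRepertoire(makeRecords(
    c("AAA", "CCC"), read_count = c(6L, 4L),
    v_call = c("IGHV1-2*01", "IGHV3-23*01")), "tr", label = "A")
  testRep <- collapseToRepertoire(makeRecords(
    "GGG", v_call = "IGHV6-1*01"), "te", label = "B")
  schema <- buildSchema(list(trainRep), 2)
  expect_false("IGHV6-1" %in% schema@vVocab)
  v <- vectorizeRepertoire(testRep, schema, scale = FALSE)
  expect_true(all(v[grep("^slot001_V_", names(v))] == 0))
})
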