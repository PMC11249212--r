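#' PCA embedding of a feature matrix
#'
#' Centers the matrix internally and returns the scores on the first
#' `nComponents` principal components together with the explained-variance
#' fractions of all components. Component signs are fixed so the loading
#' with the largest magnitude is positive, making embeddings reproducible
#' across platforms.
#'
#' @param x numeric matrix (samples x features), >= 2 samples and >= 2
#'   features.
#' @param nComponents number of components to return (default 2).
#' @return list with `scores` (n x nComponents), `explainedVariance`
#'   (fractions, non-increasing), `rotation` (feature loadings of the
#'   returned components).
#' @export
pcaEmbed <- function(x, nComponents = 2L) {
  x <- as.matrix(x)
  if (nrow(x) < nComponents)
    .stopf("need at least %d samples for %d components", nComponents,
           nComponents)
  if (ncol(x) < 2L) .stopf("need >= 2 features")
  pr <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  keep <- seq_len(min(nComponents, ncol(pr$x)))
  scores <- pr$x[, keep, drop = FALSE]
  rotation <- pr$rotation[, keep, drop = FALSE]
  for (j in keep) {
    load <- rotation[, j]
    if (load[which.max(abs(load))] < 0) {
      rotation[, j] <- -rotation[, j]
      scores[, j] <- -scores[, j]
    }
  }
  ev <- pr$sdev^2 / sum(pr$sdev^2)
  list(scores = scores, explainedVariance = ev, rotation = rotation)
}

#' MANOVA comparison of group mean vectors
#'
#' Multivariate analysis of variance on a multivariate response (typically
#' the first two principal-component scores), reporting Wilks' lambda with
#' its F approximation and p-value.
#'
#' @param x numeric response matrix (samples x dimensions).
#' @param labels group labels (>= 2 groups, each with more samples than
#'   response dimensions).
#' @return list with `wilks`, `approxF`, `df` (numerator, denominator),
#'   `pValue`, `degenerate` (`TRUE` when the within-group covariance is
#'   singular and the test statistic is unavailable).
#' @export
manovaGroups <- function(x, labels) {
  x <- as.matrix(x)
  groups <- factor(labels)
  if (nlevels(groups) < 2L) .stopf("need >= 2 groups")
  sizes <- table(groups)
  if (any(sizes <= ncol(x)))
    .stopf("every group needs more samples than response dimensions (%d)",
           ncol(x))
  res <- tryCatch({
    fit <- stats::manova(x ~ groups)
    st <- summary(fit, test = "Wilks")$stats
    list(wilks = unname(st[1L, "Wilks"]),
         approxF = unname(st[1L, "approx F"]),
         df = unname(c(st[1L, "num Df"], st[1L, "den Df"])),
         pValue = unname(st[1L, "Pr(>F)"]),
         degenerate = FALSE)
  }, error = function(e)
    list(wilks = NA_real_, approxF = NA_real_, df = c(NA_real_, NA_real_),
         pValue = NA_real_, degenerate = TRUE))
  res
}

#' Rank predictors of a multinomial linear model by coefficient magnitude
#'
#' Scores each feature by the mean absolute coefficient across the
#' per-class coefficient vectors of a fitted multinomial logistic model,
#' returns the top k features (ties broken by feature-name byte order),
#' and tabulates for every unordered class pair the signed per-feature
#' contribution `coefficient(a) - coefficient(b)`. For forest models,
#' impurity importances are reported instead and labelled as such.
#'
#' @param model a fitted model as attached to an
#'   [EvaluationReport-class] by [fitFinalAndEvaluate()] (attribute
#'   `fittedModel`), or a plain features x classes coefficient matrix.
#' @param featureNames feature names (defaults to the model's).
#' @param k ranking length (default 20; clipped with a warning if it
#'   exceeds the feature count).
#' @return list with `ranking` (`data.frame`: feature, score, ordered
#'   non-increasing), `pairwise` (`data.frame`: class_a, class_b, feature,
#'   contribution; `NULL` for forests), `method` (`"coefficient"` or
#'   `"impurity"`), `k`.
#' @export
rankPredictors <- function(model, featureNames = NULL, k = 20L) {
  if (is.matrix(model)) {
    coefMatrix <- model
    method <- "coefficient"
  } else if (inherits(model, "lymphrepModel") && model$family == "logistic") {
    coefMatrix <- model$coefMatrix
    method <- "coefficient"
  } else if (inherits(model, "lymphrepModel") && model$family == "forest") {
    imp <- ranger::importance(model$fit)
    coefMatrix <- matrix(imp, ncol = 1L,
                         dimnames = list(model$featureNames, "importance"))
    method <- "impurity"
  } else {
    .stopf("'model' must be a lymphrep model or a coefficient matrix")
  }
  if (is.null(featureNames))
    featureNames <- rownames(coefMatrix)
  if (is.null(featureNames))
    featureNames <- paste0("feature", seq_len(nrow(coefMatrix)))

  score <- rowMeans(abs(coefMatrix))
  if (k > length(score)) {
    .warnf("k = %d exceeds the feature count (%d); clipping", k,
           length(score))
    k <- length(score)
  }
  ord <- order(-score, featureNames, method = "radix")[seq_len(k)]
  ranking <- data.frame(feature = featureNames[ord],
                        score = unname(score[ord]),
                        stringsAsFactors = FALSE)

  pairwise <- NULL
  if (method == "coefficient" && ncol(coefMatrix) >= 2L) {
    pairs <- utils::combn(colnames(coefMatrix), 2L)
    pairwise <- do.call(rbind, apply(pairs, 2L, function(pr) {
      data.frame(class_a = pr[1L], class_b = pr[2L],
                 feature = featureNames,
                 contribution = unname(coefMatrix[, pr[1L]] -
                                         coefMatrix[, pr[2L]]),
                 stringsAsFactors = FALSE)
    }))
    rownames(pairwise) <- NULL
  }
  list(ranking = ranking, pairwise = pairwise, method = method,
       k = as.integer(k))
}
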