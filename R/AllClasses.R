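#' @import methods
NULL

## Column layout of the clonotype table carried by a Repertoire.
.CLONOTYPE_COLS <- c("cdr3_nt", "cdr3_aa", "v_gene", "d_gene", "j_gene",
                     "read_count", "fraction", "v_identity_pct",
                     "is_hypermutated")

#' ClassPreset: generative parameters for one diagnostic class
#'
#' A `ClassPreset` bundles the statistical parameters from which synthetic
#' IGH repertoires of one diagnostic class (healthy donor or a lymphoma
#' entity) are drawn: how many clonotypes a sample carries (richness), how
#' strongly the top clone dominates (a Beta law on its repertoire fraction),
#' how evenly the remaining "bystander" mass is spread (symmetric Dirichlet
#' concentration), the probability that a clonotype is somatically
#' hypermutated, V/D/J gene-usage weights, and the CDR3 amino-acid length
#' distribution.
#'
#' @slot label class name, one of `"HD"`, `"NLPBL"`, `"DLBCL"`, `"CLL"` (any
#'   non-empty string is accepted so custom classes can be simulated).
#' @slot richnessRange integer vector of length 2, inclusive bounds on the
#'   number of clonotypes S; lower bound >= 1.
#' @slot dominanceAlpha,dominanceBeta shape parameters of the Beta
#'   distribution of the top-clone repertoire fraction.
#' @slot bystanderConcentration positive concentration of the symmetric
#'   Dirichlet splitting the non-dominant mass over the S - 1 bystanders.
#' @slot shmProbability probability in \[0, 1\] that a clonotype is drawn
#'   from the hypermutated germline-identity component.
#' @slot vUsage,dUsage,jUsage named numeric weight vectors over gene
#'   vocabularies; each sums to 1.
#' @slot cdr3LengthMean,cdr3LengthSd mean and standard deviation (amino
#'   acids) of the CDR3 length distribution; sd > 0.
#' @slot totalReads total sequencing reads distributed over the clonotypes
#'   by a multinomial draw.
#'
#' @seealso [defaultPresets()], [sampleRepertoire()]
#' @export
setClass("ClassPreset",
  representation(
    label = "character",
    richnessRange = "integer",
    dominanceAlpha = "numeric",
    dominanceBeta = "numeric",
    bystanderConcentration = "numeric",
    shmProbability = "numeric",
    vUsage = "numeric",
    dUsage = "numeric",
    jUsage = "numeric",
    cdr3LengthMean = "numeric",
    cdr3LengthSd = "numeric",
    totalReads = "integer"
  )
)

setValidity("ClassPreset", function(object) {
  msg <- character()
  if (length(object@label) != 1L || !nzchar(object@label))
    msg <- c(msg, "'label' must be a single non-empty string")
  rr <- object@richnessRange
  if (length(rr) != 2L || anyNA(rr) || rr[1L] < 1L || rr[2L] < rr[1L])
    msg <- c(msg, "'richnessRange' must be c(lower, upper) with 1 <= lower <= upper")
  for (s in c("dominanceAlpha", "dominanceBeta", "bystanderConcentration",
              "cdr3LengthMean", "cdr3LengthSd")) {
    v <- slot(object, s)
    if (length(v) != 1L || is.na(v) || v <= 0)
      msg <- c(msg, sprintf("'%s' must be a single positive number", s))
  }
  p <- object@shmProbability
  if (length(p) != 1L || is.na(p) || p < 0 || p > 1)
    msg <- c(msg, "'shmProbability' must lie in [0, 1]")
  for (s in c("vUsage", "dUsage", "jUsage")) {
    w <- slot(object, s)
    if (length(w) == 0L || is.null(names(w)) || any(!nzchar(names(w))))
      msg <- c(msg, sprintf("'%s' must be a named weight vector", s))
    else if (any(w < 0) || abs(sum(w) - 1) > 1e-8)
      msg <- c(msg, sprintf("'%s' weights must be non-negative and sum to 1", s))
  }
  if (length(object@totalReads) != 1L || is.na(object@totalReads) ||
      object@totalReads < 1L)
    msg <- c(msg, "'totalReads' must be a positive integer")
  if (length(msg)) msg else TRUE
})

#' Repertoire: one filtered, collapsed IGH repertoire sample
#'
#' A `Repertoire` holds the clonotype table of a single sample after the
#' record-level rules have been applied: non-productive records and records
#' with fewer than 2 reads removed, records collapsed by unique CDR3
#' nucleotide sequence, read counts converted to fractions, and somatic
#' hypermutation called at <= 98 percent V-gene germline identity.
#' Clonotypes are ordered by fraction (descending), ties broken by read
#' count then CDR3 sequence.
#'
#' @slot sampleId sample identifier.
#' @slot label diagnostic class label, or `"unknown"`.
#' @slot tissue tissue of origin, possibly empty.
#' @slot clonotypes `data.frame` with columns `cdr3_nt`, `cdr3_aa`,
#'   `v_gene`, `d_gene`, `j_gene`, `read_count`, `fraction`,
#'   `v_identity_pct`, `is_hypermutated`.
#' @slot totalReads total retained read count.
#'
#' @seealso [collapseToRepertoire()], [computeMetrics()]
#' @export
setClass("Repertoire",
  representation(
    sampleId = "character",
    label = "character",
    tissue = "character",
    clonotypes = "data.frame",
    totalReads = "integer"
  )
)

setValidity("Repertoire", function(object) {
  msg <- character()
  cl <- object@clonotypes
  missing <- setdiff(.CLONOTYPE_COLS, names(cl))
  if (length(missing))
    return(sprintf("clonotype table lacks column(s): %s",
                   paste(missing, collapse = ", ")))
  if (nrow(cl) == 0L)
    msg <- c(msg, "a repertoire must contain at least one clonotype")
  else {
    if (abs(sum(cl$fraction) - 1) > 1e-9)
      msg <- c(msg, "clonotype fractions must sum to 1 (within 1e-9)")
    if (is.unsorted(rev(cl$fraction)))
      msg <- c(msg, "clonotypes must be ordered by non-increasing fraction")
    if (any(cl$read_count < 2L))
      msg <- c(msg, "every retained clonotype must have read_count >= 2")
    if (anyDuplicated(cl$cdr3_nt))
      msg <- c(msg, "clonotype keys (cdr3_nt) must be unique")
  }
  if (length(object@totalReads) != 1L || is.na(object@totalReads) ||
      object@totalReads < 1L)
    msg <- c(msg, "'totalReads' must be a positive integer")
  if (length(msg)) msg else TRUE
})

#' FeatureSchema: layout of the fixed-length top-n feature vector
#'
#' A `FeatureSchema` records everything needed to turn a repertoire into a
#' fixed-length numeric vector: the number of clonotype slots n, the V/D/J
#' one-hot vocabularies learned from training repertoires, the ordered
#' feature names, and (optionally) per-column standardisation parameters
#' fitted on training vectors. Each clonotype slot contributes 12 numeric
#' features (fraction, CDR3 amino-acid length, ten Kidera factors) plus the
#' one-hot gene blocks; four repertoire-level features (clonality, Shannon
#' index, richness, SHM fraction) are appended.
#'
#' @slot nClonotypes number of clonotype slots n.
#' @slot vVocab,dVocab,jVocab sorted, duplicate-free gene vocabularies.
#' @slot featureNames full ordered feature-name vector.
#' @slot numericMask logical mask over columns: TRUE for numeric columns
#'   subject to scaling, FALSE for one-hot columns.
#' @slot scalingEnabled whether vectors are standardised by default.
#' @slot scalingCenter,scalingScale per-column mean and standard deviation
#'   fitted on the training vectors (scale 1 for constant columns).
#'
#' @seealso [buildSchema()], [vectorizeRepertoire()]
#' @export
setClass("FeatureSchema",
  representation(
    nClonotypes = "integer",
    vVocab = "character",
    dVocab = "character",
    jVocab = "character",
    featureNames = "character",
    numericMask = "logical",
    scalingEnabled = "logical",
    scalingCenter = "numeric",
    scalingScale = "numeric"
  )
)

setValidity("FeatureSchema", function(object) {
  msg <- character()
  width <- object@nClonotypes *
    (12L + length(object@vVocab) + length(object@dVocab) +
       length(object@jVocab)) + 4L
  if (length(object@featureNames) != width)
    msg <- c(msg, sprintf("feature name count (%d) != schema width (%d)",
                          length(object@featureNames), width))
  if (anyDuplicated(object@featureNames))
    msg <- c(msg, "feature names must be unique")
  for (s in c("vVocab", "dVocab", "jVocab")) {
    v <- slot(object, s)
    if (anyDuplicated(v) || is.unsorted(v))
      msg <- c(msg, sprintf("'%s' must be sorted and duplicate-free", s))
  }
  if (length(object@numericMask) != width)
    msg <- c(msg, "numeric mask length must equal schema width")
  if (length(object@scalingCenter) != width ||
      length(object@scalingScale) != width)
    msg <- c(msg, "scaling parameter length must equal schema width")
  if (length(msg)) msg else TRUE
})

#' EvaluationReport: test-set performance of one fitted model
#'
#' Per-class precision, recall, F1 and support, overall accuracy,
#' support-weighted average F1, and the confusion matrix for one
#' scenario / clonotype-count / model-family combination.
#'
#' @slot classMetrics `data.frame` with columns `class`, `precision`,
#'   `recall`, `f1`, `support` (and `zero_division`, flagging classes whose
#'   precision or recall had a zero denominator and was reported as 0).
#' @slot accuracy overall accuracy on the test set.
#' @slot weightedF1 support-weighted mean of the per-class F1 scores.
#' @slot confusion confusion matrix, rows = truth, columns = prediction.
#' @slot scenario scenario name.
#' @slot nClonotypes number of top clonotypes featurized.
#' @slot model model family (`"logistic"` or `"forest"`).
#' @slot hyperparameters chosen hyperparameter setting (named list).
#'
#' @export
setClass("EvaluationReport",
  representation(
    classMetrics = "data.frame",
    accuracy = "numeric",
    weightedF1 = "numeric",
    confusion = "matrix",
    scenario = "character",
    nClonotypes = "integer",
    model = "character",
    hyperparameters = "list"
  )
)

setValidity("EvaluationReport", function(object) {
  cm <- object@classMetrics
  need <- c("class", "precision", "recall", "f1", "support")
  if (!all(need %in% names(cm)))
    return("classMetrics must have columns class, precision, recall, f1, support")
  scores <- unlist(cm[c("precision", "recall", "f1")])
  if (any(scores < -1e-12 | scores > 1 + 1e-12))
    return("all scores must lie in [0, 1]")
  if (sum(cm$support) != sum(object@confusion))
    return("supports must sum to the test-set size")
  TRUE
})

#' @export
setMethod("show", "ClassPreset", function(object) {
  cat(sprintf("ClassPreset '%s'\n", object@label))
  cat(sprintf("  richness: %d-%d, top-clone Beta(%.3g, %.3g) [mean %.3f]\n",
              object@richnessRange[1L], object@richnessRange[2L],
              object@dominanceAlpha, object@dominanceBeta,
              object@dominanceAlpha /
                (object@dominanceAlpha + object@dominanceBeta)))
  cat(sprintf("  SHM probability: %.3f; bystander concentration: %.3g\n",
              object@shmProbability, object@bystanderConcentration))
  cat(sprintf("  CDR3 length ~ N(%.1f, %.1f) aa; total reads: %d\n",
              object@cdr3LengthMean, object@cdr3LengthSd, object@totalReads))
  cat(sprintf("  vocab sizes: V %d, D %d, J %d\n", length(object@vUsage),
              length(object@dUsage), length(object@jUsage)))
})

#' @export
setMethod("show", "Repertoire", function(object) {
  cl <- object@clonotypes
  cat(sprintf("Repertoire '%s' (label: %s%s)\n", object@sampleId,
              object@label,
              if (nzchar(object@tissue)) paste0(", ", object@tissue) else ""))
  cat(sprintf("  %d clonotypes, %d reads, top-clone fraction %.4f\n",
              nrow(cl), object@totalReads,
              if (nrow(cl)) cl$fraction[1L] else NA_real_))
  cat(sprintf("  hypermutated clonotypes: %d (%.1f%%)\n",
              sum(cl$is_hypermutated),
              100 * mean(cl$is_hypermutated)))
})

#' @export
setMethod("show", "FeatureSchema", function(object) {
  cat(sprintf("FeatureSchema: n = %d clonotype slot(s), width %d\n",
              object@nClonotypes, length(object@featureNames)))
  cat(sprintf("  vocabularies: V %d, D %d, J %d; scaling %s\n",
              length(object@vVocab), length(object@dVocab),
              length(object@jVocab),
              if (object@scalingEnabled) "enabled" else "disabled"))
})

#' @export
setMethod("show", "EvaluationReport", function(object) {
  cat(sprintf("EvaluationReport: scenario '%s', %s model, n = %d\n",
              object@scenario, object@model, object@nClonotypes))
  print(object@classMetrics, row.names = FALSE, digits = 4)
  cat(sprintf("  accuracy %.4f, weighted F1 %.4f (test n = %d)\n",
              object@accuracy, object@weightedF1, sum(object@confusion)))
})

#' @describeIn Repertoire sample identifier
#' @param object a `Repertoire`
#' @export
setGeneric("sampleId", function(object) standardGeneric("sampleId"))
#' @describeIn Repertoire diagnostic class label
#' @export
setGeneric("classLabel", function(object) standardGeneric("classLabel"))
#' @describeIn Repertoire clonotype table (fraction-sorted `data.frame`)
#' @export
setGeneric("clonotypes", function(object) standardGeneric("clonotypes"))
#' @describeIn Repertoire total retained read count
#' @export
setGeneric("totalReads", function(object) standardGeneric("totalReads"))

#' @export
setMethod("sampleId", "Repertoire", function(object) object@sampleId)
#' @export
setMethod("classLabel", "Repertoire", function(object) object@label)
#' @export
setMethod("clonotypes", "Repertoire", function(object) object@clonotypes)
#' @export
setMethod("totalReads", "Repertoire", function(object) object@totalReads)
#' @export
setMethod("classLabel", "ClassPreset", function(object) object@label)

#' @describeIn EvaluationReport support-weighted average F1
#' @param object an `EvaluationReport`
#' @export
setGeneric("weightedF1", function(object) standardGeneric("weightedF1"))
#' @export
setMethod("weightedF1", "EvaluationReport", function(object) object@weightedF1)

#' @describeIn EvaluationReport per-class precision/recall/F1/support table
#' @export
setGeneric("classMetrics", function(object) standardGeneric("classMetrics"))
#' @export
setMethod("classMetrics", "EvaluationReport", function(object) object@classMetrics)
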