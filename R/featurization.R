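.ALLOWED_N <- c(1:10, 20L, 50L, 100L)

.REPERTOIRE_BLOCK <- c("clonality", "shannon", "richness", "shm_fraction")

## Ordered feature names for one clonotype slot.
.slotNames <- function(i, vVocab, dVocab, jVocab) {
  pre <- sprintf("slot%03d_", i)
  c(paste0(pre, c("fraction", "cdr3_length", paste0("KF", 1:10))),
    paste0(pre, "V_", vVocab),
    paste0(pre, "D_", dVocab),
    paste0(pre, "J_", jVocab))
}

#' Build the feature schema from training repertoires
#'
#' Learns, from the training repertoires only, everything needed to map a
#' repertoire to a fixed-length vector: the V/D/J one-hot vocabularies
#' (sorted union of the allele-free genes observed among the top-n
#' clonotypes of the training set) and, when `scalingEnabled`, per-column
#' standardisation parameters (mean and standard deviation over the
#' unscaled training vectors, numeric columns only; constant columns get
#' scale 1, so they map to 0). Genes seen only at prediction time encode
#' as an all-zero one-hot block, which prevents test-set leakage into the
#' schema. The schema is independent of the order in which training
#' repertoires are presented.
#'
#' Each clonotype slot contributes 12 numeric features (fraction, CDR3
#' amino-acid length, KF1..KF10) plus the one-hot blocks, so the total
#' width is `n * (12 + |V| + |D| + |J|) + 4` including the appended
#' repertoire block (clonality, Shannon index, richness, SHM fraction).
#'
#' @param trainRepertoires list of [Repertoire-class] objects (training
#'   split only).
#' @param nClonotypes number of top clonotype slots n; one of 1..10, 20,
#'   50, 100.
#' @param scalingEnabled standardise numeric columns by default.
#' @return a [FeatureSchema-class].
#' @examples
#' reps <- lapply(1:3, function(i)
#'   sampleRepertoire(defaultPresets()[["CLL"]], seed = i))
#' buildSchema(reps, nClonotypes = 2)
#' @export
buildSchema <- function(trainRepertoires, nClonotypes,
                        scalingEnabled = FALSE) {
  if (!length(trainRepertoires))
    .stopf("need at least one training repertoire")
  n <- as.integer(nClonotypes)
  if (!(n %in% .ALLOWED_N))
    .stopf("'nClonotypes' must be one of 1..10, 20, 50, 100 (got %s)",
           as.character(nClonotypes))

  tops <- lapply(trainRepertoires, function(r)
    utils::head(r@clonotypes, n))
  vocab <- function(col) {
    genes <- unique(unlist(lapply(tops, `[[`, col), use.names = FALSE))
    genes[.radixOrder(genes)]
  }
  vVocab <- vocab("v_gene")
  dVocab <- vocab("d_gene")
  jVocab <- vocab("j_gene")

  featureNames <- c(
    unlist(lapply(seq_len(n), .slotNames, vVocab, dVocab, jVocab)),
    .REPERTOIRE_BLOCK)
  width <- length(featureNames)
  numericMask <- !grepl("_(V|D|J)_", featureNames)

  schema <- new("FeatureSchema",
                nClonotypes = n, vVocab = vVocab, dVocab = dVocab,
                jVocab = jVocab, featureNames = featureNames,
                numericMask = numericMask,
                scalingEnabled = isTRUE(scalingEnabled),
                scalingCenter = numeric(width),
                scalingScale = rep(1, width))

  raw <- assembleFeatureMatrix(trainRepertoires, schema, scale = FALSE)
  fitScaling(schema, raw$x)
}

#' Refit a schema's scaling parameters on a training matrix
#'
#' Computes per-column mean and standard deviation over the rows of an
#' unscaled feature matrix, numeric columns only (one-hot columns keep
#' center 0 / scale 1); columns with zero variance get scale 1 so they
#' standardise to 0. Used internally by [buildSchema()] and refit on each
#' cross-validation training fold so scaling never sees validation data.
#'
#' @param schema a [FeatureSchema-class].
#' @param x unscaled feature matrix whose columns follow the schema.
#' @return the schema with updated `scalingCenter` / `scalingScale`.
#' @export
fitScaling <- function(schema, x) {
  stopifnot(is(schema, "FeatureSchema"),
            ncol(x) == length(schema@featureNames))
  center <- rep(0, ncol(x))
  scale <- rep(1, ncol(x))
  m <- schema@numericMask
  center[m] <- colMeans(x[, m, drop = FALSE])
  sds <- apply(x[, m, drop = FALSE], 2L, stats::sd)
  sds[!is.finite(sds) | sds == 0] <- 1
  scale[m] <- sds
  schema@scalingCenter <- center
  schema@scalingScale <- scale
  schema
}

## Raw (unscaled) vector for one repertoire + the number of real slots.
.vectorizeRaw <- function(repertoire, schema) {
  n <- schema@nClonotypes
  cl <- utils::head(repertoire@clonotypes, n)
  s <- nrow(cl)
  slotWidth <- 12L + length(schema@vVocab) + length(schema@dVocab) +
    length(schema@jVocab)
  values <- numeric(n * slotWidth + 4L)
  for (i in seq_len(s)) {
    off <- (i - 1L) * slotWidth
    values[off + 1L] <- cl$fraction[i]
    values[off + 2L] <- nchar(cl$cdr3_aa[i])
    values[off + 2L + 1:10] <- kideraDescriptor(cl$cdr3_aa[i])
    vHit <- match(cl$v_gene[i], schema@vVocab)
    if (!is.na(vHit)) values[off + 12L + vHit] <- 1
    dHit <- match(cl$d_gene[i], schema@dVocab)
    if (!is.na(dHit)) values[off + 12L + length(schema@vVocab) + dHit] <- 1
    jHit <- match(cl$j_gene[i], schema@jVocab)
    if (!is.na(jHit))
      values[off + 12L + length(schema@vVocab) + length(schema@dVocab) +
               jHit] <- 1
  }
  met <- computeMetrics(repertoire)
  values[n * slotWidth + 1:4] <-
    c(met$clonality, met$shannon, met$richness, met$shm_fraction)
  list(values = values, nSlots = s)
}

## Standardise a raw matrix per schema, keeping padded slots exactly zero.
.applyScaling <- function(x, schema, nSlots) {
  slotWidth <- 12L + length(schema@vVocab) + length(schema@dVocab) +
    length(schema@jVocab)
  scaled <- sweep(sweep(x, 2L, schema@scalingCenter, "-"),
                  2L, schema@scalingScale, "/")
  scaled[, !schema@numericMask] <- x[, !schema@numericMask]
  for (r in seq_len(nrow(scaled))) {
    if (nSlots[r] < schema@nClonotypes) {
      padStart <- nSlots[r] * slotWidth + 1L
      scaled[r, padStart:(schema@nClonotypes * slotWidth)] <- 0
    }
  }
  scaled
}

#' Map one repertoire to its fixed-length feature vector
#'
#' Fills the n clonotype slots in fraction-descending order with
#' \[fraction, CDR3 amino-acid length, KF1..KF10, one-hot(V), one-hot(D),
#' one-hot(J)\]; slots beyond the repertoire's clonotype count are
#' zero-padded (and remain exactly zero under scaling); genes absent from
#' the schema vocabulary encode as an all-zero one-hot block. The
#' repertoire block \[clonality, shannon, richness, shm_fraction\] is
#' appended.
#'
#' @param repertoire a [Repertoire-class].
#' @param schema a [FeatureSchema-class].
#' @param scale apply the schema's standardisation (defaults to the
#'   schema's `scalingEnabled`).
#' @return named numeric vector of length `length(schema@featureNames)`.
#' @export
vectorizeRepertoire <- function(repertoire, schema,
                                scale = schema@scalingEnabled) {
  raw <- .vectorizeRaw(repertoire, schema)
  values <- matrix(raw$values, nrow = 1L)
  if (scale) values <- .applyScaling(values, schema, raw$nSlots)
  stats::setNames(values[1L, ], schema@featureNames)
}

#' Assemble the feature matrix of a cohort
#'
#' @param repertoires list of [Repertoire-class] objects (rows follow this
#'   order).
#' @param schema a [FeatureSchema-class].
#' @param scale apply the schema's standardisation.
#' @return list with `x` (numeric matrix, rownames = sample ids, colnames
#'   = feature names, attribute `nSlots` = real slot count per row) and
#'   `labels` (character vector of class labels in row order).
#' @export
assembleFeatureMatrix <- function(repertoires, schema,
                                  scale = schema@scalingEnabled) {
  stopifnot(is(schema, "FeatureSchema"))
  raws <- lapply(repertoires, .vectorizeRaw, schema = schema)
  x <- do.call(rbind, lapply(raws, `[[`, "values"))
  nSlots <- vapply(raws, `[[`, integer(1L), "nSlots")
  if (scale) x <- .applyScaling(x, schema, nSlots)
  dimnames(x) <- list(unname(vapply(repertoires, sampleId, character(1L))),
                      schema@featureNames)
  attr(x, "nSlots") <- unname(nSlots)
  list(x = x,
       labels = vapply(repertoires, classLabel, character(1L)))
}
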