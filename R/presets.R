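## Bundled allele-free IMGT-style human IGH gene vocabularies used by the
## simulator. The /OR (orphon) V segment is kept verbatim: orphon names
## carry no allele suffix structure and do occur in real repertoire calls.
.IGHV_GENES <- c("IGHV1-18", "IGHV1-2", "IGHV1-46", "IGHV1-69", "IGHV2-5",
                 "IGHV3-11", "IGHV3-21", "IGHV3-23", "IGHV3-30", "IGHV3-48",
                 "IGHV3-53", "IGHV3-7", "IGHV4-34", "IGHV4-39", "IGHV4-4",
                 "IGHV4-59", "IGHV4/OR15-8", "IGHV5-51", "IGHV6-1",
                 "IGHV7-4-1")
.IGHD_GENES <- c("IGHD1-1", "IGHD2-15", "IGHD2-2", "IGHD3-10", "IGHD3-22",
                 "IGHD3-3", "IGHD4-17", "IGHD5-12", "IGHD6-13", "IGHD6-19")
.IGHJ_GENES <- c("IGHJ1", "IGHJ2", "IGHJ3", "IGHJ4", "IGHJ5", "IGHJ6")

## Baseline gene-usage weights, loosely shaped after healthy peripheral
## blood IGH repertoires (IGHV3-23/IGHV3-30/IGHV4-34 common, IGHJ4
## dominant); class presets re-scale a handful of genes on top of these.
.baseUsage <- function(genes, favoured = character(), factor = 1) {
  w <- stats::setNames(rep(1, length(genes)), genes)
  w[c("IGHV3-23", "IGHV3-30", "IGHV4-34", "IGHV1-69")] <-
    ifelse(c("IGHV3-23", "IGHV3-30", "IGHV4-34", "IGHV1-69") %in% genes, 2, 1)
  w <- w[genes]
  w[is.na(w)] <- 1
  names(w) <- genes
  w[favoured] <- w[favoured] * factor
  w / sum(w)
}

.baseJUsage <- function(favoured = character(), factor = 1) {
  w <- stats::setNames(c(0.05, 0.08, 0.08, 0.45, 0.12, 0.22), .IGHJ_GENES)
  w[favoured] <- w[favoured] * factor
  w / sum(w)
}

#' Construct a ClassPreset
#'
#' Builds and validates the generative parameter set for one diagnostic
#' class. See [defaultPresets()] for the bundled class presets and the
#' rationale behind their values.
#'
#' @param label class name.
#' @param richnessRange inclusive integer bounds on clonotype count S.
#' @param dominanceAlpha,dominanceBeta Beta shape parameters of the
#'   top-clone repertoire fraction.
#' @param bystanderConcentration symmetric Dirichlet concentration for the
#'   non-dominant clonotypes.
#' @param shmProbability probability that a clonotype is hypermutated.
#' @param vUsage,dUsage,jUsage named gene-usage weight vectors (normalised
#'   internally).
#' @param cdr3LengthMean,cdr3LengthSd CDR3 amino-acid length distribution.
#' @param totalReads total reads per simulated sample.
#' @return a validated [ClassPreset-class] object.
#' @examples
#' classPreset("HD", richnessRange = c(10, 20))
#' @export
classPreset <- function(label,
                        richnessRange = c(100L, 500L),
                        dominanceAlpha = 2, dominanceBeta = 8,
                        bystanderConcentration = 1,
                        shmProbability = 0.2,
                        vUsage = .baseUsage(.IGHV_GENES),
                        dUsage = .baseUsage(.IGHD_GENES),
                        jUsage = .baseJUsage(),
                        cdr3LengthMean = 15, cdr3LengthSd = 3,
                        totalReads = 100000L) {
  new("ClassPreset",
      label = label,
      richnessRange = as.integer(richnessRange),
      dominanceAlpha = as.numeric(dominanceAlpha),
      dominanceBeta = as.numeric(dominanceBeta),
      bystanderConcentration = as.numeric(bystanderConcentration),
      shmProbability = as.numeric(shmProbability),
      vUsage = vUsage / sum(vUsage),
      dUsage = dUsage / sum(dUsage),
      jUsage = jUsage / sum(jUsage),
      cdr3LengthMean = as.numeric(cdr3LengthMean),
      cdr3LengthSd = as.numeric(cdr3LengthSd),
      totalReads = as.integer(totalReads))
}

#' Default class presets for the four-group study design
#'
#' Returns the bundled `ClassPreset` objects for healthy donors (HD) and
#' the three lymphoma entities (NLPBL, DLBCL, CLL). The presets encode the
#' qualitative structure the classifier exploits:
#'
#' * clonal dominance increases HD < NLPBL < DLBCL < CLL (mean top-clone
#'   fraction roughly 0.05, 0.35, 0.75, 0.9), while richness decreases in
#'   the same order (HD 2000-5000, NLPBL 500-2000, DLBCL 50-500,
#'   CLL 10-200 clonotypes), so CLL/DLBCL samples are near-monoclonal,
#'   NLPBL sits in between with its dominant bystander background, and HD
#'   blood is polyclonal;
#' * per-clonotype hypermutation probabilities anchored to the cohort
#'   averages of the somatically hypermutated clonotype percentage:
#'   HD 0.192, NLPBL 0.184, DLBCL 0.449, CLL 0.224;
#' * V-gene biases: IGHV4-34 up-weighted in NLPBL and DLBCL, IGHV1-69
#'   (with IGHJ6) up-weighted in CLL, reflecting well-known usage skews.
#'
#' @return named list of [ClassPreset-class] objects
#'   (`HD`, `NLPBL`, `DLBCL`, `CLL`).
#' @examples
#' defaultPresets()[["CLL"]]
#' @export
defaultPresets <- function() {
  list(
    HD = classPreset("HD",
      richnessRange = c(2000L, 5000L),
      dominanceAlpha = 2, dominanceBeta = 38,        # mean 0.05
      bystanderConcentration = 5,
      shmProbability = 0.192,
      vUsage = .baseUsage(.IGHV_GENES),
      cdr3LengthMean = 15, cdr3LengthSd = 3,
      totalReads = 200000L),
    NLPBL = classPreset("NLPBL",
      richnessRange = c(500L, 2000L),
      dominanceAlpha = 3.5, dominanceBeta = 6.5,     # mean 0.35
      bystanderConcentration = 2,
      shmProbability = 0.184,
      vUsage = .baseUsage(.IGHV_GENES, favoured = "IGHV4-34", factor = 4),
      cdr3LengthMean = 16, cdr3LengthSd = 3,
      totalReads = 100000L),
    DLBCL = classPreset("DLBCL",
      richnessRange = c(50L, 500L),
      dominanceAlpha = 7.5, dominanceBeta = 2.5,     # mean 0.75
      bystanderConcentration = 1,
      shmProbability = 0.449,
      vUsage = .baseUsage(.IGHV_GENES, favoured = "IGHV4-34", factor = 4),
      cdr3LengthMean = 16, cdr3LengthSd = 3.5,
      totalReads = 100000L),
    CLL = classPreset("CLL",
      richnessRange = c(10L, 200L),
      dominanceAlpha = 18, dominanceBeta = 2,        # mean 0.9
      bystanderConcentration = 0.5,
      shmProbability = 0.224,
      vUsage = .baseUsage(.IGHV_GENES, favoured = "IGHV1-69", factor = 4),
      jUsage = .baseJUsage(favoured = "IGHJ6", factor = 3),
      cdr3LengthMean = 17, cdr3LengthSd = 4,
      totalReads = 100000L)
  )
}

#' Cohort configuration for the synthetic generator
#'
#' @param counts named integer vector or list mapping class label to the
#'   number of samples to simulate (counts >= 0).
#' @param seed master cohort seed; per-sample seeds are derived from it by
#'   a stable integer hash of (seed, sample index), so regeneration is
#'   order-independent.
#' @param presets named list of [ClassPreset-class] objects covering every
#'   class in `counts`.
#' @return a validated cohort configuration (list with elements `counts`,
#'   `seed`, `presets`).
#' @examples
#' cohortConfig(c(HD = 3, CLL = 2), seed = 7)
#' @export
cohortConfig <- function(counts, seed = 1L, presets = defaultPresets()) {
  counts <- unlist(counts)
  if (is.null(names(counts)) || any(!nzchar(names(counts))))
    .stopf("'counts' must be a named class -> count map")
  if (any(is.na(counts)) || any(counts < 0))
    .stopf("sample counts must be non-negative")
  missing <- setdiff(names(counts), names(presets))
  if (length(missing))
    .stopf("no preset for class(es): %s", paste(missing, collapse = ", "))
  for (p in presets) validObject(p)
  structure(list(counts = stats::setNames(as.integer(counts), names(counts)),
                 seed = as.integer(seed), presets = presets),
            class = "cohortConfig")
}
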