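.checkFractions <- function(fractions) {
  if (length(fractions) == 0L)
    .stopf("empty fraction vector")
  if (any(is.na(fractions)) || any(fractions < 0))
    .stopf("fractions must be non-negative")
  if (abs(sum(fractions) - 1) > 1e-6)
    .stopf("fractions must sum to 1 (got %.8f)", sum(fractions))
  invisible(fractions)
}

#' Shannon diversity index (bits)
#'
#' H' = -sum(p_i * log2(p_i)) over the strictly positive entries of a
#' clonotype fraction vector, with the 0 * log(0) := 0 convention.
#'
#' @param fractions non-negative vector summing to 1 (within 1e-6).
#' @return Shannon index in bits.
#' @examples
#' shannonIndex(rep(0.25, 4)) # 2 bits
#' @export
shannonIndex <- function(fractions) {
  .checkFractions(fractions)
  p <- fractions[fractions > 0]
  -sum(p * log2(p))
}

#' Clonality: one minus Pielou's evenness
#'
#' Pielou's evenness J = H'/log2(S), with H' the Shannon index in bits and
#' S the number of clonotypes (richness). Clonality = 1 - J: 1 indicates a
#' sample comprising a single clonotype, 0 complete clonal diversity. For
#' S = 1, log2(S) = 0 leaves J undefined; the single-clonotype convention
#' assigns J = 0 and clonality = 1.
#'
#' @inheritParams shannonIndex
#' @return clonality in \[0, 1\].
#' @examples
#' clonality(1)                    # 1: monoclonal
#' clonality(rep(1 / 16, 16))      # 0: perfectly even
#' clonality(c(0.5, 0.25, 0.25))   # 1 - 1.5/log2(3)
#' @export
clonality <- function(fractions) {
  .checkFractions(fractions)
  s <- sum(fractions > 0)
  if (s <= 1L) return(1)
  res <- 1 - shannonIndex(fractions) / log2(s)
  # clamp away floating-point residue at the boundaries
  min(max(res, 0), 1)
}

#' Compute the repertoire metrics of one sample
#'
#' Richness S (clonotype count), Shannon index H' (bits), Pielou's
#' evenness J = H'/log2(S), clonality 1 - J (with the S = 1 convention
#' J = 0, clonality = 1), the fraction of clonotypes called somatically
#' hypermutated (counting clonotypes, not reads), and the same fraction
#' over the min(10, S) most frequent clonotypes.
#'
#' @param repertoire a [Repertoire-class].
#' @param topN number of top clonotypes for the top-n SHM fraction.
#' @return one-row `data.frame` with columns `sample_id`, `label`,
#'   `richness`, `shannon`, `evenness`, `clonality`, `shm_fraction`,
#'   `topn_shm_fraction`, `total_reads`.
#' @examples
#' computeMetrics(sampleRepertoire(defaultPresets()[["DLBCL"]], seed = 3))
#' @export
computeMetrics <- function(repertoire, topN = 10L) {
  stopifnot(is(repertoire, "Repertoire"))
  cl <- repertoire@clonotypes
  s <- nrow(cl)
  h <- shannonIndex(cl$fraction)
  ev <- if (s == 1L) 0 else h / log2(s)
  data.frame(
    sample_id = repertoire@sampleId,
    label = repertoire@label,
    richness = s,
    shannon = h,
    evenness = ev,
    clonality = clonality(cl$fraction),
    shm_fraction = mean(cl$is_hypermutated),
    topn_shm_fraction = mean(cl$is_hypermutated[seq_len(min(topN, s))]),
    total_reads = repertoire@totalReads,
    stringsAsFactors = FALSE)
}

#' Metrics table for a cohort
#'
#' @param repertoires list of [Repertoire-class] objects.
#' @return `data.frame`, one row per sample (see [computeMetrics()]).
#' @export
cohortMetrics <- function(repertoires) {
  do.call(rbind, lapply(repertoires, computeMetrics))
}

#' Pairwise Mann-Whitney comparison of a metric between classes
#'
#' For every unordered pair of classes, a two-sided Mann-Whitney U test
#' (exact for small samples without ties, tie-corrected normal
#' approximation otherwise) at alpha = 0.05, with no multiple-testing
#' correction.
#'
#' @param valuesByClass named list mapping class to a numeric vector of
#'   per-sample metric values (>= 2 classes, none empty).
#' @param alpha significance level.
#' @return `data.frame` with columns `class_a`, `class_b`, `u_statistic`,
#'   `p_value`, `significant`.
#' @examples
#' compareMetricBetweenGroups(list(A = c(1, 2, 3), B = c(4, 5, 6)))
#' @export
compareMetricBetweenGroups <- function(valuesByClass, alpha = 0.05) {
  if (!is.list(valuesByClass) || length(valuesByClass) < 2L ||
      is.null(names(valuesByClass)))
    .stopf("'valuesByClass' must be a named list with >= 2 classes")
  if (any(vapply(valuesByClass, length, integer(1L)) == 0L))
    .stopf("every class must contribute at least one value")
  pairs <- utils::combn(names(valuesByClass), 2L)
  rows <- apply(pairs, 2L, function(pr) {
    wt <- suppressWarnings(
      stats::wilcox.test(valuesByClass[[pr[1L]]], valuesByClass[[pr[2L]]],
                         alternative = "two.sided"))
    data.frame(class_a = pr[1L], class_b = pr[2L],
               u_statistic = unname(wt$statistic),
               p_value = wt$p.value,
               significant = wt$p.value < alpha,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pearson correlation of repertoire metrics with total read count
#'
#' Checks whether richness, clonality and Shannon diversity depend on
#' sequencing depth (they should not, appreciably, if raw counts are used
#' without read normalisation).
#'
#' @param metricsTable cohort metrics `data.frame` (see [cohortMetrics()]),
#'   >= 3 rows.
#' @param metrics metric column names to correlate against `total_reads`.
#' @return `data.frame` with columns `metric`, `r`, `p_value`,
#'   `degenerate` (`TRUE` where a constant metric or constant read count
#'   leaves the correlation undefined; `r` and `p_value` are `NA` there).
#' @export
metricReadCountCorrelation <- function(metricsTable,
                                       metrics = c("richness", "clonality",
                                                   "shannon")) {
  if (nrow(metricsTable) < 3L)
    .stopf("need >= 3 samples to estimate a correlation")
  missing <- setdiff(c(metrics, "total_reads"), names(metricsTable))
  if (length(missing))
    .stopf("metrics table lacks column(s): %s",
           paste(missing, collapse = ", "))
  reads <- metricsTable$total_reads
  rows <- lapply(metrics, function(m) {
    v <- metricsTable[[m]]
    if (stats::sd(v) == 0 || stats::sd(reads) == 0)
      return(data.frame(metric = m, r = NA_real_, p_value = NA_real_,
                        degenerate = TRUE, stringsAsFactors = FALSE))
    ct <- stats::cor.test(v, reads, method = "pearson",
                          alternative = "two.sided")
    data.frame(metric = m, r = unname(ct$estimate), p_value = ct$p.value,
               degenerate = FALSE, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
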