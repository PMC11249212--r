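# Shared fixtures: record tables built in code, tiny fast presets.

# record data.frame mimicking readAirrTable() output
makeRecords <- function(cdr3_nt,
                        read_count = rep(5L, length(cdr3_nt)),
                        productive = rep(TRUE, length(cdr3_nt)),
                        v_call = rep("IGHV3-23*01", length(cdr3_nt)),
                        d_call = rep("IGHD3-3*01", length(cdr3_nt)),
                        j_call = rep("IGHJ4*01", length(cdr3_nt)),
                        v_identity_pct = rep(99.5, length(cdr3_nt)),
                        cdr3_aa = NULL) {
  if (is.null(cdr3_aa))
    cdr3_aa <- vapply(cdr3_nt, function(nt)
      paste(rep("A", max(1L, nchar(nt) %/% 3L)), collapse = ""),
      character(1L), USE.NAMES = FALSE)
  data.frame(
    sequence_id = sprintf("seq-%03d", seq_along(cdr3_nt)),
    cdr3_nt = cdr3_nt, cdr3_aa = cdr3_aa,
    v_call = v_call, d_call = d_call, j_call = j_call,
    read_count = as.integer(read_count), productive = productive,
    v_identity_pct = v_identity_pct, stringsAsFactors = FALSE)
}

# small, fast presets with the same dominance contrast as the defaults
fastPreset <- function(label, alpha, beta, richness = c(10L, 40L),
                       shm = 0.2, conc = 1, reads = 20000L) {
  classPreset(label, richnessRange = richness, dominanceAlpha = alpha,
              dominanceBeta = beta, bystanderConcentration = conc,
              shmProbability = shm, totalReads = reads)
}

fastCohort <- function(countsPerClass = 10L, seed = 1L) {
  presets <- list(
    HD = fastPreset("HD", 2, 38, richness = c(150L, 300L), conc = 5),
    NLPBL = fastPreset("NLPBL", 3.5, 6.5, richness = c(60L, 150L), conc = 2),
    DLBCL = fastPreset("DLBCL", 7.5, 2.5, richness = c(20L, 80L)),
    CLL = fastPreset("CLL", 18, 2, richness = c(5L, 40L), conc = 0.5))
  cfg <- cohortConfig(
    stats::setNames(rep(countsPerClass, 4L), names(presets)),
    seed = seed, presets = presets)
  generateCohort(cfg)$repertoires
}

# random point on the probability simplex
randomSimplex <- function(s) {
  g <- stats::rgamma(s, shape = 1)
  g / sum(g)
}
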