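## Most-common human codon per amino acid; used to back-translate the
## sampled CDR3 amino-acid sequence into a nucleotide clonotype key.
.CODON <- c(A = "GCC", R = "CGG", N = "AAC", D = "GAC", C = "TGC",
            Q = "CAG", E = "GAG", G = "GGC", H = "CAC", I = "ATC",
            L = "CTG", K = "AAG", M = "ATG", F = "TTC", P = "CCC",
            S = "AGC", T = "ACC", W = "TGG", Y = "TAC", V = "GTG")

.AA_ALPHABET <- names(.CODON)

## Vectorised random peptide generation: one big letter draw, split into
## sequences by substring on the concatenated string.
.randomPeptides <- function(lengths) {
  if (!length(lengths)) return(character())
  letters <- sample(.AA_ALPHABET, sum(lengths), replace = TRUE)
  big <- paste(letters, collapse = "")
  ends <- cumsum(lengths)
  substring(big, ends - lengths + 1L, ends)
}

.backTranslate <- function(aa) {
  if (!length(aa)) return(character())
  chars <- strsplit(aa, "", fixed = TRUE)
  vapply(chars, function(x) paste(.CODON[x], collapse = ""), character(1L))
}

#' Simulate one IGH repertoire from a class preset
#'
#' Draws a single labelled repertoire: richness S uniform on the preset's
#' richness range; the top-clone fraction from
#' Beta(dominanceAlpha, dominanceBeta); the remaining mass split over the
#' S - 1 bystander clonotypes by a symmetric Dirichlet; read counts as a
#' multinomial draw of `totalReads` over the fraction vector, after which
#' clonotypes with fewer than 2 reads are dropped (the same record-level
#' rule the ingestion pipeline applies) and fractions renormalised. Each
#' clonotype receives V/D/J calls from the preset's biased vocabularies, a
#' CDR3 amino-acid sequence of Gaussian-sampled length (clamped to 5-32
#' residues) over the 20-letter alphabet with its back-translated
#' nucleotide sequence, and a V-gene germline identity drawn from a
#' two-component mixture: with probability `shmProbability` uniform on
#' \[90, 98\] (hypermutated, boundary inclusive), otherwise uniform on
#' \[98.5, 100\]. The gap (98, 98.5) is deliberately never generated, so
#' the generative hypermutation label coincides exactly with the <= 98
#' percent identity call made by [callShm()]. All records are productive.
#'
#' Identical seeds reproduce identical repertoires bit-for-bit.
#'
#' @param preset a [ClassPreset-class].
#' @param seed integer seed for this sample.
#' @param sampleId sample identifier; defaults to `<label>_s<seed>`.
#' @return a [Repertoire-class], clonotypes sorted by descending fraction.
#' @examples
#' rep <- sampleRepertoire(defaultPresets()[["CLL"]], seed = 42)
#' rep
#' @export
sampleRepertoire <- function(preset, seed,
                             sampleId = sprintf("%s_s%d", preset@label,
                                                as.integer(seed))) {
  validObject(preset)
  if (preset@richnessRange[2L] < preset@richnessRange[1L])
    .stopf("degenerate preset: richness upper bound below lower bound")
  if (preset@cdr3LengthSd <= 0)
    .stopf("degenerate preset: CDR3 length sd must be positive")
  seed <- as.integer(seed)

  withr::with_seed(seed, {
    rr <- preset@richnessRange
    S <- rr[1L] + sample.int(rr[2L] - rr[1L] + 1L, 1L) - 1L

    topFrac <- stats::rbeta(1L, preset@dominanceAlpha, preset@dominanceBeta)
    if (S == 1L) {
      fractions <- 1
    } else {
      bystanders <- stats::rgamma(S - 1L,
                                  shape = preset@bystanderConcentration)
      if (sum(bystanders) == 0) bystanders <- rep(1, S - 1L)
      fractions <- c(topFrac, (1 - topFrac) * bystanders / sum(bystanders))
    }

    counts <- stats::rmultinom(1L, preset@totalReads, fractions)[, 1L]
    keep <- counts >= 2L
    if (!any(keep))
      .stopf("preset yields no clonotype with >= 2 reads; increase totalReads")
    counts <- counts[keep]
    S <- length(counts)
    fractions <- counts / sum(counts)

    vGene <- sample(names(preset@vUsage), S, TRUE, prob = preset@vUsage)
    dGene <- sample(names(preset@dUsage), S, TRUE, prob = preset@dUsage)
    jGene <- sample(names(preset@jUsage), S, TRUE, prob = preset@jUsage)

    lengths <- pmin(pmax(round(stats::rnorm(S, preset@cdr3LengthMean,
                                            preset@cdr3LengthSd)), 5L), 32L)
    cdr3Aa <- .randomPeptides(lengths)
    # clonotype keys must be unique; resample colliding sequences
    while (anyDuplicated(cdr3Aa)) {
      dup <- duplicated(cdr3Aa)
      cdr3Aa[dup] <- .randomPeptides(lengths[dup])
    }
    cdr3Nt <- .backTranslate(cdr3Aa)

    hyper <- stats::runif(S) < preset@shmProbability
    identity <- numeric(S)
    identity[hyper] <- stats::runif(sum(hyper), 90.0, 98.0)
    identity[!hyper] <- stats::runif(sum(!hyper), 98.5, 100.0)

    ord <- order(-counts, cdr3Nt, method = "radix")
    cl <- data.frame(
      cdr3_nt = cdr3Nt[ord],
      cdr3_aa = cdr3Aa[ord],
      v_gene = vGene[ord],
      d_gene = dGene[ord],
      j_gene = jGene[ord],
      read_count = as.integer(counts[ord]),
      fraction = fractions[ord],
      v_identity_pct = identity[ord],
      is_hypermutated = (identity <= 98.0)[ord],
      stringsAsFactors = FALSE)

    new("Repertoire", sampleId = sampleId, label = preset@label,
        tissue = "", clonotypes = cl,
        totalReads = as.integer(sum(counts)))
  })
}

#' Generate a labelled synthetic cohort
#'
#' Simulates the per-class sample counts requested by a [cohortConfig()],
#' deriving one stable seed per sample from the cohort seed and the sample
#' index so regeneration is order-independent. When `outDir` is given,
#' every repertoire is written as an AIRR Rearrangement TSV (see
#' [writeAirrTable()]) along with a manifest TSV
#' (`sample_id`, `label`, `path`, `seed`).
#'
#' @param config a [cohortConfig()].
#' @param outDir output directory, created if missing; `NULL` keeps the
#'   cohort in memory only.
#' @return (invisibly) list with `repertoires` (named list of
#'   [Repertoire-class]) and `manifest` (`data.frame`).
#' @examples
#' cfg <- cohortConfig(c(CLL = 2), seed = 1)
#' cohort <- generateCohort(cfg)
#' length(cohort$repertoires)
#' @export
generateCohort <- function(config, outDir = NULL) {
  if (!inherits(config, "cohortConfig"))
    .stopf("'config' must be created by cohortConfig()")
  write <- !is.null(outDir)
  if (write && !dir.exists(outDir) &&
      !dir.create(outDir, recursive = TRUE, showWarnings = FALSE))
    .stopf("cannot create output directory '%s'", outDir)

  repertoires <- list()
  rows <- list()
  index <- 0L
  for (cls in names(config$counts)) {
    preset <- config$presets[[cls]]
    for (i in seq_len(config$counts[[cls]])) {
      index <- index + 1L
      sampleSeed <- .deriveSeed(config$seed, index)
      id <- sprintf("%s_%03d", cls, i)
      rep <- sampleRepertoire(preset, sampleSeed, sampleId = id)
      repertoires[[id]] <- rep
      path <- if (write) file.path(outDir, paste0(id, ".tsv")) else ""
      if (write) writeAirrTable(rep, path)
      rows[[index]] <- data.frame(sample_id = id, label = cls, path = path,
                                  seed = sampleSeed,
                                  stringsAsFactors = FALSE)
    }
  }
  manifest <- if (length(rows)) do.call(rbind, rows)
              else data.frame(sample_id = character(), label = character(),
                              path = character(), seed = integer(),
                              stringsAsFactors = FALSE)
  if (nrow(manifest) == 0L)
    .warnf("all requested sample counts are zero; empty cohort generated")
  if (write)
    utils::write.table(manifest, file.path(outDir, "manifest.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(repertoires = repertoires, manifest = manifest))
}
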