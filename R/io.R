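.AIRR_REQUIRED <- c("sequence_id", "productive", "v_call", "d_call",
                    "j_call", "junction", "junction_aa", "duplicate_count",
                    "v_identity")

.parseBool <- function(x) {
  up <- toupper(trimws(x))
  out <- rep(NA, length(x))
  out[up %in% c("T", "TRUE")] <- TRUE
  out[up %in% c("F", "FALSE")] <- FALSE
  out
}

## Allele suffix stripped at '*'; '/OR' orphon segment names kept verbatim.
## Ambiguous comma-separated multi-gene calls resolve to the first gene.
.cleanGeneCall <- function(call) {
  first <- sub(",.*$", "", call)
  sub("\\*.*$", "", first)
}

#' Read an AIRR Rearrangement clonotype table
#'
#' Parses a tab-separated clonotype table in the AIRR Rearrangement
#' dialect into a record-level `data.frame`. Required columns:
#' `sequence_id`, `productive`, `v_call`, `d_call`, `j_call`, `junction`
#' (CDR3 nucleotide sequence), `junction_aa`, `duplicate_count` (clonotype
#' read abundance), and `v_identity` (V-segment germline identity as a
#' fraction in \[0, 1\], converted to percent internally). Booleans are
#' accepted as T/F or true/false. Malformed rows (unparseable booleans,
#' counts, or identities; empty junction) are dropped with a warning that
#' names their row numbers.
#'
#' @param path path to the TSV file.
#' @return `data.frame` with columns `sequence_id`, `cdr3_nt`, `cdr3_aa`,
#'   `v_call`, `d_call`, `j_call`, `read_count`, `productive`,
#'   `v_identity_pct` (one row per retained input row).
#' @examples
#' rep <- sampleRepertoire(defaultPresets()[["CLL"]], seed = 1)
#' tf <- tempfile(fileext = ".tsv")
#' writeAirrTable(rep, tf)
#' head(readAirrTable(tf))
#' @export
readAirrTable <- function(path) {
  if (!file.exists(path)) .stopf("file not found: '%s'", path)
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character",
                           check.names = FALSE, quote = "",
                           stringsAsFactors = FALSE)
  if (nrow(raw) == 0L)
    .stopf("empty input: '%s' contains no records", path)
  missing <- setdiff(.AIRR_REQUIRED, names(raw))
  if (length(missing))
    .stopf("schema error in '%s': missing required column(s): %s",
           path, paste(missing, collapse = ", "))

  productive <- .parseBool(raw$productive)
  readCount <- suppressWarnings(as.numeric(raw$duplicate_count))
  vIdentity <- suppressWarnings(as.numeric(raw$v_identity))
  bad <- is.na(productive) | is.na(readCount) | readCount < 0 |
    readCount != floor(readCount) |
    is.na(vIdentity) | vIdentity < 0 | vIdentity > 1 |
    !nzchar(raw$junction)
  if (any(bad))
    .warnf("'%s': dropped %d malformed row(s): %s", path, sum(bad),
           paste(utils::head(which(bad), 10L), collapse = ", "))

  keep <- !bad
  data.frame(
    sequence_id = raw$sequence_id[keep],
    cdr3_nt = raw$junction[keep],
    cdr3_aa = raw$junction_aa[keep],
    v_call = raw$v_call[keep],
    d_call = raw$d_call[keep],
    j_call = raw$j_call[keep],
    read_count = as.integer(readCount[keep]),
    productive = productive[keep],
    v_identity_pct = vIdentity[keep] * 100,
    stringsAsFactors = FALSE)
}

#' Write a repertoire as an AIRR Rearrangement TSV
#'
#' Inverse of the ingestion path: expands the clonotype table back to one
#' row per clonotype with `v_identity` as a fraction and an allele suffix
#' (`*01`) re-attached to V/D/J calls where the gene name admits one, so
#' the reader's allele stripping is exercised on round trips.
#'
#' @param repertoire a [Repertoire-class].
#' @param path output file path.
#' @return (invisibly) the path.
#' @export
writeAirrTable <- function(repertoire, path) {
  stopifnot(is(repertoire, "Repertoire"))
  cl <- repertoire@clonotypes
  withAllele <- function(g)
    ifelse(grepl("/OR", g, fixed = TRUE), g, paste0(g, "*01"))
  df <- data.frame(
    sequence_id = sprintf("%s-%05d", repertoire@sampleId,
                          seq_len(nrow(cl))),
    productive = "T",
    v_call = withAllele(cl$v_gene),
    d_call = withAllele(cl$d_gene),
    j_call = withAllele(cl$j_gene),
    junction = cl$cdr3_nt,
    junction_aa = cl$cdr3_aa,
    duplicate_count = cl$read_count,
    v_identity = sprintf("%.12g", cl$v_identity_pct / 100),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Apply the record-level filtering rules
#'
#' Retains exactly the records that are productive and have at least 2
#' reads; non-productive records and records with fewer than 2 read
#' counts are discarded. Input order is preserved and the operation is
#' idempotent. Discard counts per reason are reported via a message.
#'
#' @param records record `data.frame` as returned by [readAirrTable()].
#' @param quiet suppress the discard-count message.
#' @return the retained records (possibly zero rows).
#' @export
filterRecords <- function(records, quiet = TRUE) {
  nonProductive <- !records$productive
  lowCount <- records$read_count < 2L
  keep <- !(nonProductive | lowCount)
  if (!quiet)
    message(sprintf(
      "filtered %d record(s): %d non-productive, %d with < 2 reads",
      sum(!keep), sum(nonProductive), sum(lowCount & !nonProductive)))
  records[keep, , drop = FALSE]
}

#' Call somatic hypermutation from V-gene germline identity
#'
#' A clonotype is considered somatically hypermutated when its V segment
#' shows at most 98 percent identity to the germline sequence (boundary
#' inclusive).
#'
#' @param vIdentityPct percent identity value(s) in \[0, 100\].
#' @return logical vector, `TRUE` where hypermutated.
#' @examples
#' callShm(c(98.0, 98.01, 100)) # TRUE FALSE FALSE
#' @export
callShm <- function(vIdentityPct) {
  if (any(is.na(vIdentityPct)) || any(vIdentityPct < 0 | vIdentityPct > 100))
    .stopf("germline identity must lie in [0, 100] percent")
  vIdentityPct <= 98.0
}

#' Collapse filtered records into a Repertoire
#'
#' Groups records by unique CDR3 nucleotide sequence (the clonotype
#' definition), sums read counts within each group, takes the V/D/J calls
#' of the highest-count member (allele suffixes stripped at `*`,
#' comma-separated multi-gene calls resolved to the first gene), averages
#' the germline identity weighted by read count, converts counts to
#' repertoire fractions, calls hypermutation via [callShm()], and sorts by
#' descending fraction (ties: read count descending, then CDR3 sequence
#' byte order).
#'
#' @param records filtered record `data.frame` (see [filterRecords()]).
#' @param sampleId sample identifier.
#' @param label class label (default `"unknown"`).
#' @param tissue optional tissue annotation.
#' @return a [Repertoire-class].
#' @export
collapseToRepertoire <- function(records, sampleId, label = "unknown",
                                 tissue = "") {
  if (nrow(records) == 0L)
    .stopf("empty repertoire: no records retained for sample '%s'", sampleId)

  grp <- factor(records$cdr3_nt, levels = unique(records$cdr3_nt))
  counts <- as.integer(tapply(records$read_count, grp, sum))
  identity <- as.numeric(tapply(
    records$read_count * records$v_identity_pct, grp, sum)) / counts
  # representative member = highest read count within the group
  repIdx <- as.integer(tapply(seq_len(nrow(records)), grp, function(i)
    i[which.max(records$read_count[i])]))

  cdr3Nt <- levels(grp)
  total <- sum(counts)
  cl <- data.frame(
    cdr3_nt = cdr3Nt,
    cdr3_aa = records$cdr3_aa[repIdx],
    v_gene = .cleanGeneCall(records$v_call[repIdx]),
    d_gene = .cleanGeneCall(records$d_call[repIdx]),
    j_gene = .cleanGeneCall(records$j_call[repIdx]),
    read_count = counts,
    fraction = counts / total,
    v_identity_pct = identity,
    is_hypermutated = callShm(identity),
    stringsAsFactors = FALSE)
  cl <- cl[order(-cl$read_count, cl$cdr3_nt, method = "radix"), ,
           drop = FALSE]
  rownames(cl) <- NULL

  new("Repertoire", sampleId = sampleId, label = label, tissue = tissue,
      clonotypes = cl, totalReads = total)
}

#' Read one sample file through the full ingestion path
#'
#' Convenience composition: [readAirrTable()] then [filterRecords()] then
#' [collapseToRepertoire()].
#'
#' @inheritParams collapseToRepertoire
#' @param path AIRR TSV path.
#' @return a [Repertoire-class].
#' @export
readRepertoire <- function(path, sampleId, label = "unknown", tissue = "") {
  collapseToRepertoire(filterRecords(readAirrTable(path)),
                       sampleId = sampleId, label = label, tissue = tissue)
}

#' Read a cohort manifest and ingest all listed samples
#'
#' The manifest is a TSV with columns `sample_id`, `label`, `path` and
#' optionally `tissue`; relative paths are resolved against the manifest's
#' directory.
#'
#' @param manifestPath path to the manifest TSV.
#' @return named list of [Repertoire-class] objects, in manifest order.
#' @export
readCohort <- function(manifestPath) {
  if (!file.exists(manifestPath))
    .stopf("manifest not found: '%s'", manifestPath)
  mf <- utils::read.delim(manifestPath, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, comment.char = "#")
  need <- c("sample_id", "label", "path")
  missing <- setdiff(need, names(mf))
  if (length(missing))
    .stopf("manifest lacks column(s): %s", paste(missing, collapse = ", "))
  base <- dirname(manifestPath)
  reps <- vector("list", nrow(mf))
  for (i in seq_len(nrow(mf))) {
    p <- mf$path[i]
    if (!file.exists(p) && file.exists(file.path(base, basename(p))))
      p <- file.path(base, basename(p))
    reps[[i]] <- readRepertoire(
      p, sampleId = mf$sample_id[i], label = mf$label[i],
      tissue = if ("tissue" %in% names(mf)) mf$tissue[i] else "")
  }
  stats::setNames(reps, mf$sample_id)
}
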