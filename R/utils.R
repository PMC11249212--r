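.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

## Stable per-sample seed derivation: two rounds of the MINSTD multiplier
## modulo the Mersenne prime 2^31 - 1, mixing in the sample index. All
## intermediates stay below 2^53 so the arithmetic is exact in doubles,
## and the result is a valid (positive, < 2^31) seed on every platform.
.deriveSeed <- function(seed, index) {
  m <- 2147483647
  x <- (abs(as.numeric(seed)) %% m) + 1
  x <- (x * 48271) %% m
  x <- (x + as.numeric(index) * 69621) %% m
  x <- (x * 48271) %% m
  as.integer(x %% m) + 1L
}

## Byte-wise (C-locale) ordering, used everywhere a lexicographic
## tie-break on sequences or gene names must be platform-independent.
.radixOrder <- function(...) order(..., method = "radix")

## Tiny deterministic content hash for table provenance headers
## (sum/rotate over UTF-8 bytes; no cryptographic intent).
.contentHash <- function(x) {
  bytes <- utf8ToInt(paste(as.character(x), collapse = "\x1f"))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2^31
  sprintf("%08x", as.integer(h))
}

## Write a data.frame as TSV with "# key: value" provenance comment lines.
.writeCommentedTsv <- function(df, path, meta = NULL) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (length(meta))
    writeLines(sprintf("# %s: %s", names(meta),
                       vapply(meta, as.character, character(1L))), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
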