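writeRawAirr <- function(df) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

airrRow <- function(sequence_id = "s1", productive = "T",
                    v_call = "IGHV3-23*01", d_call = "IGHD3-3*01",
                    j_call = "IGHJ4*01", junction = "TGTGCGAGA",
                    junction_aa = "CAR", duplicate_count = 5,
                    v_identity = 0.995) {
  data.frame(sequence_id, productive, v_call, d_call, j_call, junction,
             junction_aa, duplicate_count, v_identity,
             stringsAsFactors = FALSE)
}

test_that("written repertoires read back field-for-field", {
  rep <- sampleRepertoire(fastPreset("X", 3, 3, richness = c(5L, 5L)),
                          seed = 8)
  path <- withr::local_tempfile(fileext = ".tsv")
  writeAirrTable(rep, path)
  records <- readAirrTable(path)
  cl <- clonotypes(rep)
  expect_equal(nrow(records), nrow(cl))
  expect_identical(records$cdr3_nt, cl$cdr3_nt)
  expect_identical(records$cdr3_aa, cl$cdr3_aa)
  expect_identical(records$read_count, cl$read_count)
  expect_true(all(records$productive))
  expect_equal(records$v_identity_pct, cl$v_identity_pct)
})

test_that("missing required columns raise a schema error naming the column", {
  df <- airrRow()
  df$junction <- NULL
  expect_error(readAirrTable(writeRawAirr(df)), "junction")
  df2 <- airrRow()
  df2$duplicate_count <- NULL
  expect_error(readAirrTable(writeRawAirr(df2)), "duplicate_count")
})

test_that("empty files raise a distinct empty-input error", {
  path <- writeRawAirr(airrRow()[0, ])
  expect_error(readAirrTable(path), "empty input")
  expect_error(readAirrTable(tempfile()), "not found")
})

test_that("v_identity fractions convert to percent", {
  rec <- readAirrTable(writeRawAirr(airrRow(v_identity = 0.979)))
  expect_equal(rec$v_identity_pct, 97.9)
})

test_that("malformed rows are dropped with their row numbers reported", {
  df <- rbind(airrRow(sequence_id = "ok"),
              airrRow(sequence_id = "bad", duplicate_count = "many"))
  expect_warning(rec <- readAirrTable(writeRawAirr(df)), "malformed")
  expect_equal(rec$sequence_id, "ok")
})

test_that("boolean productive flags parse as T/F and true/false", {
  df <- rbind(airrRow(sequence_id = "a", productive = "T"),
              airrRow(sequence_id = "b", productive = "false"),
              airrRow(sequence_id = "c", productive = "TRUE"))
  rec <- readAirrTable(writeRawAirr(df))
  expect_identical(rec$productive, c(TRUE, FALSE, TRUE))
})

test_that("filtering retains exactly productive records with >= 2 reads", {
  records <- makeRecords(c("AAA", "CCC", "GGG", "TTT"),
                         read_count = c(1L, 2L, 100L, 50L),
                         productive = c(TRUE, TRUE, FALSE, TRUE))
  kept <- filterRecords(records)
  # read count 1 discarded, boundary count 2 retained, non-productive out
  expect_identical(kept$cdr3_nt, c("CCC", "TTT"))
  expect_identical(filterRecords(kept), kept)  # idempotent
  expect_equal(nrow(filterRecords(records[0, ])), 0L)
})

test_that("somatic hypermutation call is inclusive at the 98% boundary", {
  expect_true(callShm(98.0))
  expect_false(callShm(98.01))
  expect_false(callShm(100.0))
  expect_true(callShm(90.0))
  expect_error(callShm(101), "identity")
  expect_error(callShm(-1), "identity")
})

test_that("collapse merges identical CDR3nt and aggregates counts", {
  records <- makeRecords(c("TGTGCGAGA", "TGTGCGAGA"),
                         read_count = c(3L, 5L),
                         v_identity_pct = c(99.0, 95.0))
  rep <- collapseToRepertoire(records, "s1")
  cl <- clonotypes(rep)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$read_count, 8L)
  expect_equal(cl$fraction, 1.0)
  # count-weighted identity mean: (3*99 + 5*95) / 8
  expect_equal(cl$v_identity_pct, (3 * 99 + 5 * 95) / 8)
})

test_that("collapse normalizes fractions and orders by abundance", {
  records <- makeRecords(c("AAATTT", "CCCGGG"), read_count = c(2L, 6L))
  cl <- clonotypes(collapseToRepertoire(records, "s1"))
  expect_identical(cl$cdr3_nt, c("CCCGGG", "AAATTT"))
  expect_equal(cl$fraction, c(0.75, 0.25))
})

test_that("single records collapse to a fraction-one repertoire", {
  rep <- collapseToRepertoire(makeRecords("AAATTT"), "s1")
  expect_equal(clonotypes(rep)$fraction, 1.0)
  expect_equal(totalReads(rep), 5L)
})

test_that("collapse rejects empty record sets", {
  expect_error(collapseToRepertoire(makeRecords(character()), "s1"),
               "empty repertoire")
})

test_that("gene calls lose allele suffixes but keep orphon names", {
  records <- makeRecords(c("AAA", "CCC"), read_count = c(4L, 4L),
                         v_call = c("IGHV4-34*01", "IGHV4/OR15-8"),
                         d_call = c("IGHD2-2*02,IGHD3-3*01", "IGHD1-1*01"),
                         j_call = c("IGHJ6*02", "IGHJ4*01"))
  cl <- clonotypes(collapseToRepertoire(records, "s1"))
  expect_setequal(cl$v_gene, c("IGHV4-34", "IGHV4/OR15-8"))
  # ambiguous multi-gene call resolves to the first listed gene
  expect_true("IGHD2-2" %in% cl$d_gene)
  expect_setequal(cl$j_gene, c("IGHJ6", "IGHJ4"))
})

test_that("representative calls come from the highest-count member", {
  records <- makeRecords(c("AAA", "AAA"), read_count = c(2L, 9L),
                         v_call = c("IGHV1-2*01", "IGHV3-21*01"))
  cl <- clonotypes(collapseToRepertoire(records, "s1"))
  expect_equal(cl$v_gene, "IGHV3-21")
})

test_that("collapsed fractions sum to one for random record sets", {
  withr::with_seed(404, {
    for (i in 1:20) {
      k <- sample(2:30, 1L)
      nts <- sample(sprintf("SEQ%02d", 1:12), k, replace = TRUE)
      records <- makeRecords(nts, read_count = sample(2:50, k, TRUE))
      # dedupe sequence ids, collapse handles duplicate cdr3
      rep <- collapseToRepertoire(records, "s")
      expect_lt(abs(sum(clonotypes(rep)$fraction) - 1), 1e-9)
      expect_equal(totalReads(rep), sum(records$read_count))
    }
  })
})
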