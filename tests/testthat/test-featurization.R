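# two-repertoire fixture with controlled gene usage for schema tests
schemaFixture <- function() {
  r1 <- collapseToRepertoire(makeRecords(
    c("TGTGCG", "TGTTTT", "TGTCCC"), read_count = c(10L, 6L, 4L),
    v_call = c("IGHV1-2*01", "IGHV3-23*01", "IGHV4-34*01"),
    d_call = c("IGHD3-3*01", "IGHD3-3*01", "IGHD2-2*01"),
    j_call = c("IGHJ4*01", "IGHJ4*01", "IGHJ6*01"),
    cdr3_aa = c("CAK", "CFS", "CPH")), "r1", label = "A")
  r2 <- collapseToRepertoire(makeRecords(
    c("TGTAAA", "TGTGGG"), read_count = c(8L, 2L),
    v_call = c("IGHV1-2*01", "IGHV5-51*01"),
    d_call = c("IGHD1-1*01", "IGHD3-3*01"),
    j_call = c("IGHJ4*01", "IGHJ4*01"),
    cdr3_aa = c("CWY", "CLM")), "r2", label = "B")
  list(r1 = r1, r2 = r2)
}

test_that("Kidera descriptors are residue-table lookups averaged over the peptide", {
  tab <- kideraTable()
  expect_equal(kideraDescriptor("A"), tab["A", ])
  expect_equal(kideraDescriptor("AA"), kideraDescriptor("A"))
  expect_equal(kideraDescriptor("AC"), colMeans(tab[c("A", "C"), ]))
  expect_equal(kideraDescriptor("WYV"), colMeans(tab[c("W", "Y", "V"), ]))
  expect_error(kideraDescriptor("AX"), "position 2")
  expect_error(kideraDescriptor(""), "non-empty")
})

test_that("schema width follows n * (12 + |V| + |D| + |J|) + 4", {
  fx <- schemaFixture()
  # n = 2 takes the top-2 clonotypes: V genes {1-2, 3-23, 5-51},
  # D genes {1-1, 3-3}, J genes {4}
  schema <- buildSchema(list(fx$r1, fx$r2), nClonotypes = 2)
  expect_identical(schema@vVocab, c("IGHV1-2", "IGHV3-23", "IGHV5-51"))
  expect_identical(schema@dVocab, c("IGHD1-1", "IGHD3-3"))
  expect_identical(schema@jVocab, "IGHJ4")
  expect_length(schema@featureNames, 2L * (12L + 3L + 2L + 1L) + 4L)
  expect_error(buildSchema(list(fx$r1), nClonotypes = 11), "1..10")
  expect_error(buildSchema(list(), 1), "at least one")
})

test_that("schemas are invariant to training-repertoire order", {
  fx <- schemaFixture()
  s1 <- buildSchema(list(fx$r1, fx$r2), 2)
  s2 <- buildSchema(list(fx$r2, fx$r1), 2)
  expect_identical(s1@featureNames, s2@featureNames)
  expect_identical(s1@scalingCenter, s2@scalingCenter)
  expect_identical(s1@scalingScale, s2@scalingScale)
})

test_that("repertoires shorter than n are zero-padded, scaled or not", {
  fx <- schemaFixture()
  schema <- buildSchema(list(fx$r1, fx$r2), 4)
  slotWidth <- 12L + length(schema@vVocab) + length(schema@dVocab) +
    length(schema@jVocab)
  v <- vectorizeRepertoire(fx$r2, schema, scale = FALSE)  # S = 2 under n = 4
  pad <- (2L * slotWidth + 1L):(4L * slotWidth)
  expect_true(all(v[pad] == 0))
  schemaScaled <- buildSchema(list(fx$r1, fx$r2), 4, scalingEnabled = TRUE)
  vs <- vectorizeRepertoire(fx$r2, schemaScaled)
  expect_true(all(vs[pad] == 0))
  expect_false(all(vs == v))  # scaling did something elsewhere
})

test_that("hand-built expected vector matches for a single-clonotype repertoire", {
  rep <- collapseToRepertoire(makeRecords("TGTGCG", cdr3_aa = "CAK"), "m",
                              label = "A")
  schema <- buildSchema(list(rep), 1)
  v <- vectorizeRepertoire(rep, schema, scale = FALSE)
  expected <- c(1.0, 3, unname(kideraDescriptor("CAK")), 1, 1, 1,
                1.0, 0.0, 1, 0.0)
  expect_equal(unname(v), expected)
})

test_that("genes unseen in training encode as an all-zero one-hot block", {
  fx <- schemaFixture()
  schema <- buildSchema(list(fx$r1), 2)  # training = r1 only
  v <- vectorizeRepertoire(fx$r2, schema, scale = FALSE)
  # r2's second clonotype uses IGHV5-51, absent from r1's vocabulary
  vBlock <- v[grep("^slot002_V_", names(v))]
  expect_true(all(vBlock == 0))
  expect_false("IGHV5-51" %in% schema@vVocab)
})

test_that("constant columns standardise to zero under scaling", {
  fx <- schemaFixture()
  schema <- buildSchema(list(fx$r1, fx$r1), 1, scalingEnabled = TRUE)
  v <- vectorizeRepertoire(fx$r1, schema)
  numericIdx <- which(schema@numericMask)
  expect_true(all(abs(v[numericIdx]) < 1e-12))
})

test_that("slot fractions are monotone non-increasing by construction", {
  reps <- fastCohort(3L, seed = 5)
  schema <- buildSchema(reps, 5)
  for (r in reps) {
    v <- vectorizeRepertoire(r, schema, scale = FALSE)
    fr <- v[grep("^slot[0-9]+_fraction$", names(v))]
    fr <- fr[fr > 0]
    expect_false(is.unsorted(rev(fr)))
  }
})

test_that("feature matrices assemble with labels in row order and round-trip as TSV", {
  reps <- fastCohort(2L, seed = 9)
  schema <- buildSchema(reps, 3)
  fm <- assembleFeatureMatrix(reps, schema, scale = FALSE)
  expect_equal(dim(fm$x), c(length(reps), length(schema@featureNames)))
  expect_identical(rownames(fm$x),
                   vapply(reps, sampleId, character(1L), USE.NAMES = FALSE))
  expect_identical(unname(fm$labels),
                   vapply(reps, classLabel, character(1L),
                          USE.NAMES = FALSE))
  path <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(fm$x, path, sep = "\t", quote = FALSE)
  back <- as.matrix(utils::read.delim(path, sep = "\t", check.names = FALSE))
  expect_equal(back, fm$x, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("vector width holds across random cohorts and allowed n values", {
  reps <- fastCohort(2L, seed = 31)
  for (n in c(1L, 4L, 10L, 20L)) {
    schema <- buildSchema(reps, n)
    width <- n * (12L + length(schema@vVocab) + length(schema@dVocab) +
                    length(schema@jVocab)) + 4L
    expect_length(schema@featureNames, width)
    expect_length(vectorizeRepertoire(reps[[1L]], schema), width)
  }
})
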