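test_that("feature block construction enforces its invariants", {
  expect_error(feature_block(matrix(c(1, NaN), 1, 2), "B"), "non-finite")
  expect_error(feature_block(matrix(numeric(0), 0, 0), "B"), "at least 1")
  expect_error(feature_block(matrix(1:4, 2, 2), ""), "non-empty string")
  fb <- feature_block(matrix(1:6 / 7, 3, 2), "FV2", "darknet/fc")
  expect_identical(dim(fb), c(3L, 2L))
  expect_equal(fb$source_tag, "darknet/fc")
})

test_that("delimited block I/O round-trips values and names exactly", {
  set.seed(1)
  m <- matrix(rnorm(50), 10, 5,
              dimnames = list(NULL, paste0("col_", 1:5)))
  fb <- feature_block(m, "FV2")
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_block(fb, path)
  back <- read_feature_block(path, name = "FV2")
  expect_identical(back$values, fb$values)   # bit-exact round trip
  expect_identical(colnames(back$values), paste0("col_", 1:5))
  # header row is verbatim first line
  expect_identical(readLines(path, n = 1), paste(colnames(m), collapse = ","))
})

test_that("columnar-binary block I/O round-trips exactly", {
  set.seed(3)
  fb <- feature_block(matrix(rnorm(24), 6, 4), "FV3")
  path <- withr::local_tempfile(fileext = ".feather")
  write_feature_block(fb, path, format = "columnar-binary")
  back <- read_feature_block(path, format = "columnar-binary", name = "FV3")
  expect_identical(back$values, fb$values)
})

test_that("malformed block files raise errors naming the offence", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("a,b", "1,2", "NaN,4"), path)
  expect_error(read_feature_block(path), "row 2")
  expect_error(read_feature_block(file.path(tempdir(), "nope.csv")),
               "not found")
  writeLines(c("a,b", "1,x"), path)
  expect_error(read_feature_block(path), "row 1")
})

test_that("label I/O round-trips and reads the 160/40 two-class layout", {
  y <- rep(c("benign", "melanoma"), c(160, 40))
  path <- withr::local_tempfile(fileext = ".csv")
  write_labels(y, path)
  lv <- read_labels(path)
  expect_length(lv, 200)
  expect_identical(lv$classes, c("benign", "melanoma"))
  expect_identical(lv$labels, y)
  # two-column sample,label form
  writeLines(c("sample,label", paste0("s", 1:4, ",", c("a", "b", "a", "b"))),
             path)
  expect_identical(read_labels(path)$labels, c("a", "b", "a", "b"))
})

test_that("mask serialization is bit-exact with a JSON sidecar", {
  set.seed(5)
  for (i in 1:5) {
    bits <- rbinom(20, 1, 0.4)
    bits[1] <- 1L   # ensure non-empty
    m <- selection_mask(bits)
    path <- withr::local_tempfile(fileext = ".txt")
    write_mask(m, path)
    back <- read_mask(path)
    expect_identical(back$bits, m$bits)
    side <- jsonlite::read_json(paste0(path, ".json"))
    expect_equal(side$selected_count, m$selected_count)
  }
  expect_error(selection_mask(rep(0, 4)), "at least one")
})

test_that("dataset assembly validates and never silently truncates", {
  b1 <- rand_block(10, 4, "FV1", seed = 1)
  b2 <- rand_block(10, 3, "FV2", seed = 2)
  y <- rep(c("a", "b"), 5)
  ds <- assemble_dataset(list(b1, b2), y)
  expect_s3_class(ds, "feature_dataset")
  expect_named(ds$blocks, c("FV1", "FV2"))

  expect_error(assemble_dataset(list(b1, rand_block(9, 3, "FV2")), y),
               "mismatch")
  expect_error(assemble_dataset(list(b1, rand_block(10, 3, "FV1")), y),
               "duplicate")
  expect_error(assemble_dataset(list(b1), rep("a", 10)), "at least 2 classes")
})
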