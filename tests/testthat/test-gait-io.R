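writeTs <- function(rows, name) {
  path <- file.path(withr::local_tempdir(.local_envir = parent.frame()), name)
  writeLines(rows, path)
  path
}

test_that("readGaitndd extracts the requested column and label", {
  rows <- sprintf("%.2f %.2f %.2f", cumsum(rep(1.1, 5)),
                  c(1.07, 1.12, 1.10, 1.09, 1.11), rep(0.3, 5))
  rec <- readGaitndd(writeTs(rows, "als3.ts"))
  expect_s4_class(rec, "GaitRecord")
  expect_equal(strideSeries(rec), c(1.07, 1.12, 1.10, 1.09, 1.11))
  expect_equal(classLabel(rec), "ALS")
  expect_equal(rec@nRaw, 5L)
  # column 1 is elapsed time
  rec1 <- readGaitndd(writeTs(rows, "als3.ts"), columnIndex = 1L)
  expect_equal(strideSeries(rec1), cumsum(rep(1.1, 5)))
})

test_that("filename prefixes map onto the four diagnostic classes", {
  rows <- c("1.0\t1.0", "2.0\t1.1", "3.0\t1.2")
  expect_equal(classLabel(readGaitndd(writeTs(rows, "hunt12.ts"))), "HD")
  expect_equal(classLabel(readGaitndd(writeTs(rows, "park7.ts"))), "PD")
  expect_equal(classLabel(readGaitndd(writeTs(rows, "control1.ts"))), "CO")
  expect_error(readGaitndd(writeTs(rows, "subject9.ts")), "class label")
})

test_that("malformed and empty records fail with informative errors", {
  expect_error(readGaitndd(writeTs(character(0), "als1.ts")), "empty")
  bad <- c("1.0 1.07", "2.0 oops", "3.0 1.10")
  expect_error(readGaitndd(writeTs(bad, "als1.ts")), "line 2")
  short <- c("1.0 1.07", "2.0")
  expect_error(readGaitndd(writeTs(short, "als1.ts")), "line 2")
})

test_that("preprocessStrides drops the start and filters 3-SD outliers", {
  expect_equal(preprocessStrides(rep(1, 25)), rep(1, 5))  # SD 0: keep all
  # median 1.0; SD of the 30 post-drop values ~1.64; only 10.0 exceeds
  series <- c(rep(2, 20), rep(1, 29), 10)
  out <- preprocessStrides(series)
  expect_equal(out, rep(1, 29))
  expect_error(preprocessStrides(rep(1, 20)), "too short")
})

test_that("preprocess output is an ordered subsequence of the tail", {
  set.seed(31)
  for (rep in 1:10) {
    x <- c(rnorm(20, 2), rnorm(60, 1.1, 0.05),
           sample(c(4, -1), 3, replace = TRUE))
    x <- x[sample.int(length(x))]
    x[1:20] <- rnorm(20, 2)
    out <- preprocessStrides(x)
    tail80 <- x[-(1:20)]
    expect_lte(length(out), length(tail80))
    # order-preserving subsequence check
    pos <- 0L
    ok <- TRUE
    for (v in out) {
      nxt <- which(tail80[(pos + 1L):length(tail80)] == v)
      if (length(nxt) == 0L) { ok <- FALSE; break }
      pos <- pos + nxt[[1L]]
    }
    expect_true(ok)
  }
})

test_that("gaitndd writer and reader round-trip a record", {
  rec <- new("GaitRecord", subjectId = "control2", classLabel = "CO",
             series = c(1.1, 1.2, 1.15), nRaw = 3L)
  path <- file.path(withr::local_tempdir(), "control2.ts")
  writeGaitndd(rec, path)
  back <- readGaitndd(path)
  expect_equal(strideSeries(back), strideSeries(rec), tolerance = 1e-4)
  expect_equal(classLabel(back), "CO")
})

test_that("string dataset files round-trip label/string pairs", {
  path <- file.path(withr::local_tempdir(), "strings.txt")
  writeStringDataset(path, c("abc", "ddd"), c("ALS", "CO"))
  back <- readStringDataset(path)
  expect_equal(back$label, c("ALS", "CO"))
  expect_equal(back$string, c("abc", "ddd"))
  writeLines(c("ALS abc", "broken"), path)
  expect_error(readStringDataset(path), "line 2")
})

test_that("gaitToStrings yields one symbol per surviving stride", {
  recs <- generateGaitRecords(defaultGaitTemplates()["CO"],
                              nPerClass = 2, len = 60, seed = 4)
  df <- gaitToStrings(recs)
  expect_equal(nrow(df), 2L)
  expect_equal(df$label, c("CO", "CO"))
  lens <- vapply(recs, function(r)
    length(preprocessStrides(strideSeries(r))), integer(1))
  expect_equal(nchar(df$string), lens)
})
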