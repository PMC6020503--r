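#' Read a stride-interval record in gaitndd format
#'
#' Parses a plain-text record of whitespace-separated numeric columns,
#' one row per stride (column 1 is elapsed time; column 2 is the
#' left-foot stride interval in seconds, the column the classifier
#' uses). The class label is taken from the filename prefix: `als` ->
#' ALS, `hunt` -> HD, `park` -> PD, `control` -> CO.
#'
#' @param path path to a `.ts` record.
#' @param columnIndex 1-based column to extract (default 2).
#' @return a [GaitRecord-class].
#' @export
readGaitndd <- function(path, columnIndex = 2L) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L)
    stop(sprintf("empty gait record: '%s'", path))
  fields <- strsplit(trimws(lines), "[ \t]+")
  series <- vapply(seq_along(fields), function(i) {
    row <- fields[[i]]
    if (columnIndex > length(row))
      stop(sprintf("line %d of '%s': only %d columns, need column %d",
                   i, path, length(row), columnIndex))
    v <- suppressWarnings(as.numeric(row[[columnIndex]]))
    if (is.na(v))
      stop(sprintf("line %d of '%s': malformed numeric field '%s'",
                   i, path, row[[columnIndex]]))
    v
  }, numeric(1))
  id <- sub("\\.[^.]*$", "", basename(path))
  new("GaitRecord", subjectId = id, classLabel = labelFromPrefix(id),
      series = series, nRaw = length(series))
}

labelFromPrefix <- function(id) {
  prefixes <- c(als = "ALS", hunt = "HD", park = "PD", control = "CO")
  hit <- which(startsWith(tolower(id), names(prefixes)))
  if (length(hit) == 0L)
    stop(sprintf("cannot infer class label from '%s' (expected prefix %s)",
                 id, paste(names(prefixes), collapse = "/")))
  unname(prefixes[hit[[1L]]])
}

#' @export
setMethod("show", "GaitRecord", function(object) {
  cat(sprintf("GaitRecord %s [%s]: %d strides (raw %d), mean %.3f s\n",
              object@subjectId, object@classLabel, length(object@series),
              object@nRaw,
              if (length(object@series)) mean(object@series) else NA_real_))
})

#' Stride series of a gait record
#' @param x a [GaitRecord-class].
#' @return numeric vector of stride intervals (s).
#' @export
strideSeries <- function(x) x@series

#' Class label of a gait record
#' @param x a [GaitRecord-class].
#' @return character scalar.
#' @export
classLabel <- function(x) x@classLabel

#' Preprocess a stride-interval series
#'
#' Removes the first `dropFirst` strides (startup effects) and then
#' applies a single-pass 3-SD median filter: the median and sample SD of
#' the remaining series are computed once, and every value farther than
#' `sdMultiple` SDs from the median is discarded. Survivor order is
#' preserved.
#'
#' @param series numeric vector, longer than `dropFirst`.
#' @param dropFirst number of leading strides to drop (default 20).
#' @param sdMultiple filter width in SDs (default 3).
#' @return numeric vector of surviving strides.
#' @export
preprocessStrides <- function(series, dropFirst = 20L, sdMultiple = 3) {
  if (length(series) <= dropFirst)
    stop(sprintf("series too short: %d values, need more than %d",
                 length(series), dropFirst))
  x <- if (dropFirst > 0) series[-seq_len(dropFirst)] else series
  med <- stats::median(x)
  s <- stats::sd(x)
  if (is.na(s) || s == 0) return(x)
  x[abs(x - med) <= sdMultiple * s]
}

#' Preprocess and SAX-transform gait records
#'
#' The full front end of the classification pipeline: each record's
#' series is preprocessed with [preprocessStrides()] and converted to a
#' symbol string with [saxTransform()] at `w` equal to the preprocessed
#' length (one symbol per stride).
#'
#' @param records list of [GaitRecord-class] objects.
#' @param alphabet a [SaxAlphabet-class].
#' @param dropFirst,sdMultiple passed to [preprocessStrides()].
#' @return `data.frame` with columns `subjectId`, `label`, `string`.
#' @export
gaitToStrings <- function(records, alphabet = saxAlphabet(),
                          dropFirst = 20L, sdMultiple = 3) {
  stopifnot(length(records) > 0L)
  rows <- lapply(records, function(r) {
    clean <- preprocessStrides(r@series, dropFirst, sdMultiple)
    data.frame(subjectId = r@subjectId, label = r@classLabel,
               string = saxTransform(clean, alphabet),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write a gait record in gaitndd format
#'
#' Two whitespace-separated columns: elapsed time (cumulative stride
#' time, s) and the stride interval (s) — the layout [readGaitndd()]
#' expects with the default `columnIndex = 2`.
#'
#' @param record a [GaitRecord-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeGaitndd <- function(record, path) {
  elapsed <- cumsum(record@series)
  writeLines(sprintf("%.4f\t%.4f", elapsed, record@series), path)
  invisible(path)
}

#' Read / write a labelled string dataset
#'
#' Plain-text format, one `<label> <string>` pair per line.
#'
#' @param path file path.
#' @return `readStringDataset`: a `data.frame` with columns `label` and
#'   `string`.
#' @export
readStringDataset <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(trimws(lines), "[ \t]+")
  bad <- which(lengths(parts) != 2L)
  if (length(bad))
    stop(sprintf("line %d of '%s': expected '<label> <string>'",
                 bad[[1L]], path))
  data.frame(label = vapply(parts, `[[`, "", 1L),
             string = vapply(parts, `[[`, "", 2L),
             stringsAsFactors = FALSE)
}

#' @rdname readStringDataset
#' @param strings character vector of symbol strings.
#' @param labels character vector of class labels, recycled if scalar.
#' @return `writeStringDataset`: `path`, invisibly.
#' @export
writeStringDataset <- function(path, strings, labels) {
  if (length(labels) == 1L) labels <- rep(labels, length(strings))
  stopifnot(length(labels) == length(strings))
  writeLines(paste(labels, strings), path)
  invisible(path)
}
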