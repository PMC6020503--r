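#' Equiprobable standard-normal breakpoints
#'
#' Breakpoints for an alphabet of size `A`: the A-1 standard-normal
#' quantiles at cumulative probabilities i/A, i = 1..A-1. A z-normalised
#' Gaussian series then falls into each of the A cells with probability
#' 1/A. The list is symmetric about 0.
#'
#' @param A integer alphabet size, at least 2.
#' @return numeric vector of length `A - 1`, strictly ascending.
#' @examples
#' gaussianBreakpoints(2)  # 0
#' gaussianBreakpoints(8)
#' @export
gaussianBreakpoints <- function(A) {
  if (length(A) != 1L || is.na(A) || A < 2 || A != round(A))
    stop("alphabet size A must be an integer >= 2")
  stats::qnorm(seq_len(A - 1) / A)
}

#' Construct a SAX alphabet
#'
#' @param size integer number of symbols (default 8, the size used for
#'   the gait experiments).
#' @param symbols ordered character vector of single characters; default
#'   the first `size` lowercase letters.
#' @param breakpoints cell boundaries; default the equiprobable
#'   standard-normal quantiles from [gaussianBreakpoints()].
#' @return a [SaxAlphabet-class] object.
#' @export
saxAlphabet <- function(size = 8L, symbols = letters[seq_len(size)],
                        breakpoints = gaussianBreakpoints(length(symbols))) {
  new("SaxAlphabet", symbols = symbols, breakpoints = breakpoints)
}

#' @describeIn saxAlphabet number of symbols in the alphabet.
#' @param x a `SaxAlphabet`.
#' @export
setMethod("length", "SaxAlphabet", function(x) length(x@symbols))

#' @export
setMethod("show", "SaxAlphabet", function(object) {
  cat(sprintf("SaxAlphabet of size %d: %s\n", length(object@symbols),
              paste(object@symbols, collapse = "")))
  cat("breakpoints:", paste(signif(object@breakpoints, 4), collapse = " "),
      "\n")
})

#' Alphabet symbols
#' @param x a [SaxAlphabet-class].
#' @return character vector of symbols in cell order.
#' @export
alphabetSymbols <- function(x) x@symbols

#' Alphabet breakpoints
#' @param x a [SaxAlphabet-class].
#' @return numeric vector of cell boundaries.
#' @export
alphabetBreakpoints <- function(x) x@breakpoints

#' Z-normalise a series
#'
#' Centre to mean 0 and scale to unit standard deviation. The SAX
#' convention (population SD, divisor n) is the default; `sdType =
#' "sample"` switches to the n-1 divisor.
#'
#' @param series numeric vector, length at least 2.
#' @param sdType `"population"` (default) or `"sample"`.
#' @return numeric vector of the same length.
#' @export
znormalize <- function(series, sdType = c("population", "sample")) {
  sdType <- match.arg(sdType)
  if (length(series) < 2L) stop("need at least 2 values to z-normalise")
  if (anyNA(series) || any(!is.finite(series)))
    stop("series must be finite and free of NA")
  mu <- mean(series)
  centred <- series - mu
  s <- if (sdType == "population") sqrt(mean(centred^2)) else stats::sd(series)
  if (s == 0)
    stop("zero-variance series cannot be z-normalised (degenerate series)")
  centred / s
}

#' Piecewise aggregate approximation
#'
#' Downsample a series of length n to `w` segment means. Segment i is
#' the mean of the i-th block of `floor(n/w)` consecutive points; when
#' n is not divisible by w the trailing remainder is dropped. With
#' `w = n` (the setting used for gait strings) the series is returned
#' unchanged.
#'
#' @param series numeric vector.
#' @param w integer number of segments, `1 <= w <= length(series)`.
#' @return numeric vector of length `w`.
#' @export
paa <- function(series, w) {
  n <- length(series)
  if (length(w) != 1L || is.na(w) || w < 1 || w > n || w != round(w))
    stop("w must be an integer in [1, length(series)]")
  if (w == n) return(series)
  blockSize <- n %/% w
  idx <- rep(seq_len(w), each = blockSize)
  as.numeric(tapply(series[seq_len(w * blockSize)], idx, mean))
}

#' Map values to alphabet symbols
#'
#' Each value maps to the symbol of the cell it falls in; cells are
#' lower-inclusive, so a value equal to a breakpoint maps to the higher
#' cell. Values below the first breakpoint take the first symbol, values
#' at or above the last take the last.
#'
#' @param values finite numeric vector.
#' @param alphabet a [SaxAlphabet-class].
#' @return character scalar: the concatenated symbol string.
#' @examples
#' symbolize(c(-2, -0.5, 0, 0.5, 2), saxAlphabet(8))  # "acefh"
#' @export
symbolize <- function(values, alphabet = saxAlphabet()) {
  if (anyNA(values) || any(!is.finite(values)))
    stop("values must be finite")
  cell <- findInterval(values, alphabet@breakpoints) + 1L
  paste(alphabet@symbols[cell], collapse = "")
}

#' SAX transform of a stride-interval series
#'
#' Z-normalise, reduce to `w` segment means, and symbolise against the
#' alphabet's Gaussian breakpoints. The gait pipeline uses `w` equal to
#' the series length, i.e. one symbol per stride.
#'
#' @param series numeric vector.
#' @param alphabet a [SaxAlphabet-class] (default 8 symbols, a..h).
#' @param w integer segment count (default `length(series)`).
#' @param sdType SD convention passed to [znormalize()].
#' @return character scalar of length-`w` symbols.
#' @export
saxTransform <- function(series, alphabet = saxAlphabet(),
                         w = length(series),
                         sdType = c("population", "sample")) {
  symbolize(paa(znormalize(series, match.arg(sdType)), w), alphabet)
}
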