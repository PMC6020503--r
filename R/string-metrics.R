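#' Levenshtein distance
#'
#' Minimum number of single-symbol insertions, deletions and
#' substitutions (unit costs) transforming one string into another.
#' Computed with the C-level dynamic program in [utils::adist()].
#' Vectorised: with vector arguments the full distance matrix is
#' returned (rows follow `a`, columns follow `b`); scalar-vs-scalar
#' calls return a single integer.
#'
#' @param a,b character vectors of symbol strings (empty strings
#'   allowed).
#' @return integer scalar, vector or matrix of edit distances.
#' @examples
#' levenshtein("kitten", "sitting")  # 3
#' @export
levenshtein <- function(a, b) {
  d <- utils::adist(a, b)
  storage.mode(d) <- "integer"
  if (length(a) == 1L && length(b) == 1L) d[1L, 1L] else drop(d)
}

checkWeights <- function(weights, n) {
  if (length(weights) != n)
    stop(sprintf("need one weight per string (%d), got %d", n,
                 length(weights)))
  if (anyNA(weights) || any(!is.finite(weights)) || any(weights < 0))
    stop("weights must be finite and non-negative")
  if (all(weights == 0))
    stop("at least one weight must be strictly positive")
  invisible(weights)
}

#' Set median string
#'
#' The dataset member minimising the total Levenshtein distance to all
#' members. Ties are broken by the lowest index.
#'
#' @param strings character vector, at least one string.
#' @return character scalar, the median string.
#' @export
setMedianString <- function(strings) {
  stopifnot(length(strings) >= 1L)
  strings[medianIndex(strings, rep(1, length(strings)))]
}

medianIndex <- function(strings, weights) {
  totals <- as.vector(utils::adist(strings, strings) %*% weights)
  which.min(totals)  # which.min takes the first minimum: lowest index
}

#' Dataset scale beta
#'
#' Mean Levenshtein distance from the set median string to every
#' dataset member — the string analogue of a sample variance, used to
#' calibrate the typicality exponential of the clustering objective.
#' A set of identical strings has scale 0, which the possibilistic
#' update cannot use, so that case is an error.
#'
#' @param strings character vector, at least one string.
#' @return positive numeric scalar.
#' @export
betaScale <- function(strings) {
  med <- setMedianString(strings)
  b <- mean(utils::adist(med, strings))
  if (b == 0)
    stop("degenerate dataset: all strings identical (beta = 0)")
  b
}

#' Weighted (fuzzy) median string over the dataset
#'
#' The dataset member minimising the weighted sum of Levenshtein
#' distances `sum_k w_k * Lev(candidate, s_k)`. With uniform weights
#' this reduces to [setMedianString()]. Ties break to the lowest index.
#'
#' @param strings character vector.
#' @param weights non-negative finite weights, one per string, at least
#'   one strictly positive.
#' @return character scalar.
#' @export
weightedMedianString <- function(strings, weights) {
  stopifnot(length(strings) >= 1L)
  checkWeights(weights, length(strings))
  strings[medianIndex(strings, weights)]
}

weightedCost <- function(candidate, strings, weights) {
  as.vector(utils::adist(candidate, strings) %*% weights)
}

#' Modified fuzzy median string
#'
#' Greedy local search for the weighted median over the free monoid
#' (all strings over the alphabet), not just the dataset: starting from
#' `start`, the full one-edit neighbourhood — every single-symbol
#' substitution, every single-symbol deletion, and every single-symbol
#' insertion (before each position and at the end) — is evaluated, the
#' edit giving the largest decrease in the weighted Levenshtein cost is
#' applied, and the search repeats until no edit improves or
#' `maxPasses` edits have been applied. The returned cost never exceeds
#' the cost of `start`.
#'
#' Tie-breaking is deterministic: substitutions are preferred to
#' deletions to insertions, then earlier positions, then alphabet
#' order.
#'
#' @param strings character vector of dataset strings.
#' @param weights non-negative weights, one per string.
#' @param start non-empty starting string (typically the weighted set
#'   median).
#' @param alphabet a [SaxAlphabet-class] supplying the symbol set.
#' @param maxPasses maximum number of accepted edits (default 10).
#' @return character scalar with attribute `"cost"`, the weighted cost
#'   of the returned string.
#' @export
modifiedFuzzyMedian <- function(strings, weights, start,
                                alphabet = saxAlphabet(), maxPasses = 10L) {
  checkWeights(weights, length(strings))
  if (!nzchar(start)) stop("start string must be non-empty")
  syms <- alphabet@symbols
  current <- start
  cost <- weightedCost(current, strings, weights)
  for (pass in seq_len(maxPasses)) {
    cands <- editNeighbourhood(current, syms)
    costs <- as.vector(utils::adist(cands, strings) %*% weights)
    best <- which.min(costs)  # first minimum respects the build order
    if (costs[[best]] >= cost) break
    current <- cands[[best]]
    cost <- costs[[best]]
  }
  structure(current, cost = cost)
}

# All strings one edit away, in deterministic tie-break order:
# substitutions (position-major, alphabet-minor), deletions (never to
# the empty string), insertions (position-major incl. the end,
# alphabet-minor).
editNeighbourhood <- function(s, syms) {
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  L <- length(chars)
  subs <- unlist(lapply(seq_len(L), function(i) {
    others <- syms[syms != chars[[i]]]
    vapply(others, function(sym) {
      tmp <- chars; tmp[[i]] <- sym; paste(tmp, collapse = "")
    }, "", USE.NAMES = FALSE)
  }))
  dels <- if (L > 1L)
    vapply(seq_len(L), function(i) paste(chars[-i], collapse = ""), "")
  else character(0)
  ins <- unlist(lapply(seq_len(L + 1L), function(i) {
    vapply(syms, function(sym) {
      paste(c(chars[seq_len(i - 1L)], sym,
              if (i <= L) chars[i:L] else character(0)), collapse = "")
    }, "", USE.NAMES = FALSE)
  }))
  c(subs, dels, ins)
}
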