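#' @import methods
NULL

#' SAX symbol alphabet
#'
#' An ordered alphabet of single-character symbols together with the
#' breakpoints that partition the real line into one half-open cell per
#' symbol. For SAX the breakpoints are standard-normal quantiles at
#' cumulative probabilities i/A, so that a z-normalised Gaussian series
#' visits every symbol with equal probability.
#'
#' @slot symbols character vector of distinct single characters, in cell
#'   order (lowest cell first).
#' @slot breakpoints strictly ascending numeric vector of length
#'   `length(symbols) - 1`.
#' @seealso [saxAlphabet()], [gaussianBreakpoints()], [symbolize()]
#' @exportClass SaxAlphabet
setClass("SaxAlphabet",
  representation(symbols = "character", breakpoints = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (length(object@symbols) < 2L)
      msg <- c(msg, "alphabet needs at least 2 symbols")
    if (any(nchar(object@symbols) != 1L))
      msg <- c(msg, "symbols must be single characters")
    if (anyDuplicated(object@symbols))
      msg <- c(msg, "symbols must be distinct")
    if (length(object@breakpoints) != length(object@symbols) - 1L)
      msg <- c(msg, "need exactly |symbols| - 1 breakpoints")
    if (length(object@breakpoints) > 1L && any(diff(object@breakpoints) <= 0))
      msg <- c(msg, "breakpoints must be strictly ascending")
    if (is.null(msg)) TRUE else msg
  })

#' One subject's stride-interval record
#'
#' Holds the raw left-foot stride-to-stride interval series (seconds) for
#' one subject together with the diagnostic class label: ALS (amyotrophic
#' lateral sclerosis), HD (Huntington disease), PD (Parkinson's disease)
#' or CO (healthy control).
#'
#' @slot subjectId character scalar.
#' @slot classLabel one of `"ALS"`, `"HD"`, `"PD"`, `"CO"`.
#' @slot series numeric vector of strictly positive stride intervals, in
#'   recording order.
#' @slot nRaw integer, number of strides before any preprocessing.
#' @seealso [readGaitndd()], [preprocessStrides()], [gaitToStrings()]
#' @exportClass GaitRecord
setClass("GaitRecord",
  representation(subjectId = "character", classLabel = "character",
                 series = "numeric", nRaw = "integer"),
  validity = function(object) {
    msg <- NULL
    if (length(object@classLabel) != 1L ||
        !object@classLabel %in% gaitClasses())
      msg <- c(msg, sprintf("classLabel must be one of %s",
                            paste(gaitClasses(), collapse = "/")))
    if (length(object@series) && any(object@series <= 0))
      msg <- c(msg, "stride intervals must be strictly positive")
    if (is.null(msg)) TRUE else msg
  })

#' Template for synthetic gait-like stride series
#'
#' Class-specific parameters for a stride-interval generator: mean
#' stride and the SD of its stochastic AR(1) fluctuation (seconds),
#' lag-1 autocorrelation, the rate and magnitude of injected outlier
#' strides (magnitude in multiples of `sdStride`), and an optional
#' deterministic rhythmic modulation of the stride time — a shared
#' class waveform emulating pathological stride-time oscillations —
#' given by its depth (multiples of `sdStride`) and period (strides).
#'
#' @slot classLabel one of `"ALS"`, `"HD"`, `"PD"`, `"CO"`.
#' @slot meanStride positive numeric, mean stride interval (s).
#' @slot sdStride positive numeric, SD of the stochastic component (s).
#' @slot ar1 lag-1 autocorrelation in `[0, 1)`.
#' @slot outlierRate outlier probability per stride, in `[0, 1)`.
#' @slot outlierMag outlier offset in multiples of `sdStride`.
#' @slot modDepth modulation amplitude in multiples of `sdStride`
#'   (0 = no modulation).
#' @slot modPeriod modulation period in strides (0 = no modulation).
#' @seealso [gaitTemplate()], [generateGaitRecords()]
#' @exportClass GaitTemplate
setClass("GaitTemplate",
  representation(classLabel = "character", meanStride = "numeric",
                 sdStride = "numeric", ar1 = "numeric",
                 outlierRate = "numeric", outlierMag = "numeric",
                 modDepth = "numeric", modPeriod = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (!object@classLabel %in% gaitClasses())
      msg <- c(msg, "classLabel must be one of ALS/HD/PD/CO")
    if (object@meanStride <= 0 || object@sdStride <= 0)
      msg <- c(msg, "meanStride and sdStride must be positive")
    if (object@ar1 < 0 || object@ar1 >= 1)
      msg <- c(msg, "ar1 must lie in [0, 1)")
    if (object@outlierRate < 0 || object@outlierRate >= 1)
      msg <- c(msg, "outlierRate must lie in [0, 1)")
    if (object@modDepth < 0 || object@modPeriod < 0)
      msg <- c(msg, "modDepth and modPeriod must be non-negative")
    if (object@modDepth > 0 && object@modPeriod < 2)
      msg <- c(msg, "modulation needs a period of at least 2 strides")
    if (is.null(msg)) TRUE else msg
  })

#' Fitted string-grammar possibilistic fuzzy C-medians model
#'
#' Result of [sgupfcmed()]: C string prototypes, the fuzzy membership
#' matrix U (columns sum to 1), the possibilistic typicality matrix T
#' (entries in (0, 1], equal to 1 exactly on zero edit distance), the
#' dataset scale beta (mean Levenshtein distance to the set median), and
#' the objective value after each iteration.
#'
#' @slot prototypes character vector of C prototype strings.
#' @slot membership C x N numeric matrix U.
#' @slot typicality C x N numeric matrix T.
#' @slot beta positive numeric scale.
#' @slot objective numeric vector, objective after each iteration.
#' @slot params named list of the fitting parameters (m, eta, a, b, tol,
#'   maxIter, maxPasses, seed).
#' @slot nIter integer, iterations actually run.
#' @slot reseeds integer, number of coincident-prototype reseed events.
#' @seealso [sgupfcmed()], [prototypes()], [memberships()],
#'   [typicalities()]
#' @exportClass ClusterModel
setClass("ClusterModel",
  representation(prototypes = "character", membership = "matrix",
                 typicality = "matrix", beta = "numeric",
                 objective = "numeric", params = "list",
                 nIter = "integer", reseeds = "integer"),
  validity = function(object) {
    msg <- NULL
    C <- length(object@prototypes)
    if (nrow(object@membership) != C || nrow(object@typicality) != C)
      msg <- c(msg, "U and T must have one row per prototype")
    if (!all(dim(object@membership) == dim(object@typicality)))
      msg <- c(msg, "U and T must have identical dimensions")
    if (ncol(object@membership) > 0) {
      cs <- colSums(object@membership)
      if (max(abs(cs - 1)) > 1e-6)
        msg <- c(msg, "membership columns must sum to 1")
    }
    if (any(object@membership < -1e-12) || any(object@membership > 1 + 1e-12))
      msg <- c(msg, "membership entries must lie in [0, 1]")
    if (any(object@typicality <= 0) || any(object@typicality > 1))
      msg <- c(msg, "typicality entries must lie in (0, 1]")
    if (length(object@beta) != 1L || object@beta <= 0)
      msg <- c(msg, "beta must be a positive scalar")
    if (is.null(msg)) TRUE else msg
  })

#' Class-labelled prototype set for fuzzy k-NN
#'
#' Prototypes pooled across per-class clustering runs. Each prototype
#' carries a membership vector over the classes; with crisp labelling
#' (the default produced by [trainPrototypes()]) that vector is one-hot
#' on the prototype's own class.
#'
#' @slot prototypes character vector of prototype strings.
#' @slot classLabels character vector, class of each prototype.
#' @slot classes character vector, the ordered class set.
#' @slot membership numeric matrix, one row per prototype, one column
#'   per class; rows sum to 1.
#' @seealso [prototypeSet()], [trainPrototypes()], [fknnClassify()]
#' @exportClass PrototypeSet
setClass("PrototypeSet",
  representation(prototypes = "character", classLabels = "character",
                 classes = "character", membership = "matrix"),
  validity = function(object) {
    msg <- NULL
    n <- length(object@prototypes)
    if (length(object@classLabels) != n)
      msg <- c(msg, "one class label per prototype required")
    if (!all(object@classLabels %in% object@classes))
      msg <- c(msg, "classLabels must be drawn from classes")
    if (nrow(object@membership) != n ||
        ncol(object@membership) != length(object@classes))
      msg <- c(msg, "membership must be nPrototypes x nClasses")
    if (n > 0 && max(abs(rowSums(object@membership) - 1)) > 1e-9)
      msg <- c(msg, "membership rows must sum to 1")
    if (is.null(msg)) TRUE else msg
  })

#' Cross-validation report
#'
#' Mean and SD of the per-fold classification accuracy (percent) over a
#' grid of prototype counts p and neighbour counts K, plus sensitivity
#' and specificity of the best grid cell. Cells where K exceeds the
#' pooled prototype count are marked unavailable.
#'
#' @slot accuracyMean,accuracySD numeric p x K matrices (percent).
#' @slot available logical p x K matrix.
#' @slot confusions list indexed `[[p]][[K]]` of per-fold confusion
#'   matrices for available cells.
#' @slot best named list: `p`, `K`, per-fold and summary sensitivity and
#'   specificity (percent).
#' @slot classes character vector of class labels in confusion order.
#' @slot nFolds integer.
#' @slot seed integer seed the fold partition and fits derive from.
#' @seealso [runCV()]
#' @exportClass CVReport
setClass("CVReport",
  representation(accuracyMean = "matrix", accuracySD = "matrix",
                 available = "matrix", confusions = "list",
                 best = "list", classes = "character",
                 nFolds = "integer", seed = "integer"),
  validity = function(object) {
    msg <- NULL
    ok <- object@available & !is.na(object@accuracyMean)
    if (any(object@accuracyMean[ok] < 0 | object@accuracyMean[ok] > 100))
      msg <- c(msg, "accuracies must lie in [0, 100] percent")
    if (is.null(msg)) TRUE else msg
  })

#' The closed set of gait class labels
#'
#' @return `c("ALS", "HD", "PD", "CO")` — the two-letter codes for
#'   amyotrophic lateral sclerosis, Huntington disease, Parkinson's
#'   disease and healthy control.
#' @export
gaitClasses <- function() c("ALS", "HD", "PD", "CO")
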