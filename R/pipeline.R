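#' Stratified cross-validation folds
#'
#' Partitions subjects into `nFolds` folds so that each class is spread
#' as evenly as possible across folds: within each class the subjects
#' are shuffled (under `seed`) and dealt round-robin to folds 1..n.
#'
#' @param labels character vector of class labels, one per subject.
#' @param nFolds number of folds (default 4).
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return integer vector of fold ids (1..nFolds), one per subject.
#' @export
makeFolds <- function(labels, nFolds = 4L, seed = NULL) {
  stopifnot(nFolds >= 2L)
  counts <- table(labels)
  small <- names(counts)[counts < nFolds]
  if (length(small))
    stop(sprintf("class %s has fewer subjects than folds (%d)",
                 paste(small, collapse = ", "), nFolds))
  runWithSeed(seed, function() {
    fold <- integer(length(labels))
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep(seq_len(nFolds), length.out = length(idx))
    }
    fold
  })
}

#' Learn a pooled per-class prototype set
#'
#' Runs [sgupfcmed()] separately on the strings of each class with
#' `C = p` clusters, and pools all class prototypes into a
#' [PrototypeSet-class] with crisp (one-hot) class memberships — the
#' multiprototype reference set for [fknnClassify()].
#'
#' @param strings character vector of training strings.
#' @param labels character vector of class labels, one per string.
#' @param p prototypes per class.
#' @param classes ordered class set (default: order of first
#'   appearance).
#' @param seed integer; the per-class fit for class j uses `seed + j`.
#' @param ... further arguments to [sgupfcmed()] (m, eta, a, b, tol,
#'   maxIter, alphabet, maxPasses).
#' @return a [PrototypeSet-class] with `p * length(classes)` entries.
#' @export
trainPrototypes <- function(strings, labels, p, classes = unique(labels),
                            seed = NULL, ...) {
  protos <- character(0)
  protoLabels <- character(0)
  for (j in seq_along(classes)) {
    cl <- classes[[j]]
    member <- strings[labels == cl]
    fit <- tryCatch(
      sgupfcmed(member, C = p,
                seed = if (is.null(seed)) NULL else seed + j, ...),
      error = function(e)
        stop(sprintf("class %s: %s", cl, conditionMessage(e)), call. = FALSE))
    protos <- c(protos, prototypes(fit))
    protoLabels <- c(protoLabels, rep(cl, p))
  }
  prototypeSet(protos, protoLabels, classes = classes)
}

#' Confusion matrix of fuzzy k-NN predictions
#'
#' Classifies each test string against the prototype set and tabulates
#' true against predicted classes.
#'
#' @param strings character vector of test strings.
#' @param labels true class labels.
#' @param pset a [PrototypeSet-class].
#' @param K neighbours for [fknnClassify()].
#' @param m fuzzifier.
#' @return square integer matrix, rows = true classes, columns =
#'   predicted, in `pset`'s class order.
#' @export
evaluateFknn <- function(strings, labels, pset, K = 1L, m = 2) {
  stopifnot(all(labels %in% pset@classes))
  pred <- fknnClassify(strings, pset, K = K, m = m)$labels
  table(true = factor(labels, levels = pset@classes),
        predicted = factor(pred, levels = pset@classes))
}

confusionAccuracy <- function(cm) 100 * sum(diag(cm)) / sum(cm)

# Recall on the pooled diseased classes (sensitivity) and on the
# healthy controls (specificity), after collapsing predictions to
# diseased-vs-control.
sensSpec <- function(cm, controlClass = "CO") {
  classes <- rownames(cm)
  if (!controlClass %in% classes)
    return(c(sensitivity = NA_real_, specificity = NA_real_))
  diseased <- setdiff(classes, controlClass)
  sens <- 100 * sum(cm[diseased, diseased, drop = FALSE]) /
    sum(cm[diseased, , drop = FALSE])
  spec <- 100 * cm[controlClass, controlClass] /
    sum(cm[controlClass, , drop = FALSE])
  c(sensitivity = sens, specificity = spec)
}

#' Cross-validated gait classification protocol
#'
#' The full experimental protocol: for every prototype count `p` and
#' neighbour count `K` in the grids, and every stratified fold, the
#' classifier is trained on the out-of-fold subjects (per-class
#' clustering with [trainPrototypes()]) and evaluated on the held-out
#' fold with [evaluateFknn()]. Cells where `K` exceeds the pooled
#' prototype count (`p * nClasses`) are marked unavailable. For the
#' best cell (highest mean accuracy; ties to smaller `p`, then smaller
#' `K`) the per-fold sensitivity (recall on the pooled diseased
#' classes) and specificity (recall on healthy controls) are reported.
#'
#' Held-out strings never enter clustering for their own fold.
#'
#' @param strings character vector, one SAX string per subject.
#' @param labels class labels, one per subject.
#' @param pGrid prototype counts per class (default 2:5).
#' @param kGrid neighbour counts (default c(1, 3, 5)).
#' @param nFolds folds (default 4).
#' @param seed integer; drives the fold partition and, via derived
#'   per-fold offsets, the clustering initialisations.
#' @param classes ordered class set.
#' @param controlClass label of the healthy class (default `"CO"`).
#' @param ... further arguments to [sgupfcmed()].
#' @return a [CVReport-class].
#' @export
runCV <- function(strings, labels, pGrid = 2:5, kGrid = c(1L, 3L, 5L),
                  nFolds = 4L, seed = 1L, classes = unique(labels),
                  controlClass = "CO", ...) {
  stopifnot(length(strings) == length(labels),
            length(pGrid) >= 1L, length(kGrid) >= 1L)
  fold <- makeFolds(labels, nFolds, seed = seed)
  dn <- list(p = as.character(pGrid), K = as.character(kGrid))
  accMean <- accSD <- matrix(NA_real_, length(pGrid), length(kGrid),
                             dimnames = dn)
  avail <- matrix(TRUE, length(pGrid), length(kGrid), dimnames = dn)
  confusions <- list()
  for (pi in seq_along(pGrid)) {
    p <- pGrid[[pi]]
    psets <- lapply(seq_len(nFolds), function(f)
      trainPrototypes(strings[fold != f], labels[fold != f], p = p,
                      classes = classes,
                      seed = seed + 1000L * f + 10L * p, ...))
    for (ki in seq_along(kGrid)) {
      K <- kGrid[[ki]]
      if (K > p * length(classes)) {
        avail[pi, ki] <- FALSE
        next
      }
      cms <- lapply(seq_len(nFolds), function(f)
        evaluateFknn(strings[fold == f], labels[fold == f],
                     psets[[f]], K = K))
      accs <- vapply(cms, confusionAccuracy, numeric(1))
      accMean[pi, ki] <- mean(accs)
      accSD[pi, ki] <- stats::sd(accs)
      confusions[[paste(p, K, sep = "x")]] <- cms
    }
  }
  best <- bestCell(accMean, avail, pGrid, kGrid)
  bestInfo <- list(p = NA_integer_, K = NA_integer_)
  if (!is.null(best)) {
    cms <- confusions[[paste(best$p, best$K, sep = "x")]]
    ss <- vapply(cms, sensSpec, numeric(2), controlClass = controlClass)
    bestInfo <- list(p = best$p, K = best$K,
                     accuracy = accMean[as.character(best$p),
                                        as.character(best$K)],
                     accuracySD = accSD[as.character(best$p),
                                        as.character(best$K)],
                     sensitivity = mean(ss["sensitivity", ]),
                     sensitivitySD = stats::sd(ss["sensitivity", ]),
                     specificity = mean(ss["specificity", ]),
                     specificitySD = stats::sd(ss["specificity", ]),
                     foldSensitivity = unname(ss["sensitivity", ]),
                     foldSpecificity = unname(ss["specificity", ]))
  }
  new("CVReport", accuracyMean = accMean, accuracySD = accSD,
      available = avail, confusions = confusions, best = bestInfo,
      classes = classes, nFolds = as.integer(nFolds),
      seed = as.integer(seed))
}

bestCell <- function(accMean, avail, pGrid, kGrid) {
  ok <- which(avail & !is.na(accMean), arr.ind = TRUE)
  if (nrow(ok) == 0L) return(NULL)
  vals <- accMean[ok]
  top <- ok[vals == max(vals), , drop = FALSE]
  # ties: smaller p, then smaller K
  top <- top[order(top[, 1L], top[, 2L]), , drop = FALSE]
  list(p = pGrid[[top[1L, 1L]]], K = kGrid[[top[1L, 2L]]])
}

#' @export
setMethod("show", "CVReport", function(object) {
  cat(sprintf("CVReport: %d-fold CV, classes %s\n", object@nFolds,
              paste(object@classes, collapse = "/")))
  cat("mean +/- SD accuracy (%) by prototypes per class (rows) and K (cols):\n")
  fmt <- matrix("-", nrow(object@accuracyMean), ncol(object@accuracyMean),
                dimnames = dimnames(object@accuracyMean))
  ok <- object@available & !is.na(object@accuracyMean)
  fmt[ok] <- sprintf("%.2f+/-%.2f", object@accuracyMean[ok],
                     object@accuracySD[ok])
  print(as.data.frame(fmt), right = TRUE)
  b <- object@best
  if (!is.na(b$p))
    cat(sprintf(
      "best cell: p = %d, K = %d: accuracy %.2f%%, sensitivity %.2f%%, specificity %.2f%%\n",
      b$p, b$K, b$accuracy, b$sensitivity, b$specificity))
})

#' Accessors for cross-validation reports
#'
#' `cvAccuracy()` returns the p x K matrix of mean fold accuracies
#' (percent, `NA` for unavailable cells), `cvAccuracySD()` the matching
#' SDs, `cvAvailable()` the availability mask, and `cvBest()` the
#' best-cell summary (p, K, accuracy, sensitivity, specificity with
#' SDs and per-fold values).
#'
#' @param object a [CVReport-class].
#' @return see description.
#' @name cv-accessors
NULL

#' @rdname cv-accessors
#' @export
cvAccuracy <- function(object) object@accuracyMean

#' @rdname cv-accessors
#' @export
cvAccuracySD <- function(object) object@accuracySD

#' @rdname cv-accessors
#' @export
cvAvailable <- function(object) object@available

#' @rdname cv-accessors
#' @export
cvBest <- function(object) object@best
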