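#' Construct a class-labelled prototype set
#'
#' Pools prototypes with their class labels into the reference set the
#' fuzzy k-NN classifier uses. By default each prototype gets a crisp
#' (one-hot) membership vector on its own class.
#'
#' @param prototypes character vector of prototype strings.
#' @param classLabels character vector, class of each prototype.
#' @param classes ordered class set; defaults to the order of first
#'   appearance in `classLabels`.
#' @param membership optional nPrototypes x nClasses matrix of class
#'   memberships (rows sum to 1); default one-hot.
#' @return a [PrototypeSet-class].
#' @export
prototypeSet <- function(prototypes, classLabels,
                         classes = unique(classLabels),
                         membership = NULL) {
  if (is.null(membership)) {
    membership <- matrix(0, length(prototypes), length(classes),
                         dimnames = list(NULL, classes))
    membership[cbind(seq_along(prototypes),
                     match(classLabels, classes))] <- 1
  }
  new("PrototypeSet", prototypes = prototypes, classLabels = classLabels,
      classes = classes, membership = membership)
}

#' @export
setMethod("show", "PrototypeSet", function(object) {
  cat(sprintf("PrototypeSet: %d prototypes, %d classes (%s)\n",
              length(object@prototypes), length(object@classes),
              paste(object@classes, collapse = ", ")))
  tab <- table(factor(object@classLabels, levels = object@classes))
  for (cl in object@classes)
    cat(sprintf("  %s: %d\n", cl, tab[[cl]]))
})

#' @rdname model-accessors
#' @export
setMethod("prototypes", "PrototypeSet", function(object) object@prototypes)
#' @rdname model-accessors
#' @export
setMethod("memberships", "PrototypeSet", function(object) object@membership)

#' @describeIn prototypeSet number of prototypes in the set.
#' @param x a `PrototypeSet`.
#' @export
setMethod("length", "PrototypeSet", function(x) length(x@prototypes))

#' Serialise / restore a prototype set
#'
#' @param pset a [PrototypeSet-class].
#' @param path file path.
#' @return `writePrototypeSet`: `path`, invisibly. `readPrototypeSet`:
#'   the restored [PrototypeSet-class].
#' @export
writePrototypeSet <- function(pset, path) {
  jsonlite::write_json(list(prototypes = pset@prototypes,
                            classLabels = pset@classLabels,
                            classes = pset@classes,
                            membership = pset@membership),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writePrototypeSet
#' @export
readPrototypeSet <- function(path) {
  x <- jsonlite::fromJSON(path)
  membership <- as.matrix(x$membership)
  dimnames(membership) <- list(NULL, as.character(x$classes))
  new("PrototypeSet", prototypes = as.character(x$prototypes),
      classLabels = as.character(x$classLabels),
      classes = as.character(x$classes),
      membership = membership)
}

#' Fuzzy k-nearest-neighbour classification of symbol strings
#'
#' For each query string the `K` nearest prototypes by Levenshtein
#' distance are selected (distance ties broken by lowest prototype
#' index); the class membership of the query is the distance-weighted
#' combination of the neighbours' class membership vectors,
#' `u_i(s) = sum_j u_ij (1/d_j)^(1/(m-1)) / sum_j (1/d_j)^(1/(m-1))`,
#' and the predicted class is the one with the largest membership. A
#' query at distance zero from a prototype takes that prototype's class
#' with membership 1 immediately. Membership ties on argmax go to the
#' class owning the nearest neighbour among the tied classes, then to
#' the lowest class index — so predictions do not depend on the order
#' prototypes were pooled in.
#'
#' @param strings character vector of query strings.
#' @param pset a [PrototypeSet-class].
#' @param K odd number of neighbours, at most `length(pset)`.
#' @param m fuzzifier, > 1 (default 2).
#' @return list with `labels` (character vector of predicted classes)
#'   and `membership` (nQueries x nClasses matrix).
#' @export
fknnClassify <- function(strings, pset, K = 1L, m = 2) {
  nP <- length(pset@prototypes)
  if (K > nP)
    stop(sprintf("K = %d exceeds the number of prototypes (%d)", K, nP))
  stopifnot(K >= 1L, m > 1)
  classes <- pset@classes
  D <- utils::adist(strings, pset@prototypes)
  U <- matrix(0, length(strings), length(classes),
              dimnames = list(NULL, classes))
  labels <- character(length(strings))
  tieEps <- 1e-12
  for (q in seq_along(strings)) {
    d <- D[q, ]
    if (any(d == 0L)) {
      hit <- which(d == 0L)[[1L]]
      cls <- pset@classLabels[[hit]]
      U[q, cls] <- 1
      labels[[q]] <- cls
      next
    }
    # ties by distance then class index, so pooling order cannot
    # change the prediction (same-class ties are interchangeable
    # under crisp memberships)
    ord <- order(d, match(pset@classLabels, classes))
    nb <- ord[seq_len(K)]
    wts <- (1 / d[nb])^(1 / (m - 1))
    u <- colSums(pset@membership[nb, , drop = FALSE] * wts) / sum(wts)
    U[q, ] <- u
    tied <- which(u >= max(u) - tieEps)
    if (length(tied) > 1L) {
      nbClasses <- match(pset@classLabels[nb], classes)
      owner <- nbClasses[nbClasses %in% tied]
      pick <- if (length(owner)) owner[[1L]] else tied[[1L]]
    } else {
      pick <- tied[[1L]]
    }
    labels[[q]] <- classes[[pick]]
  }
  list(labels = labels, membership = U)
}
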