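#' Membership update (fuzzy component)
#'
#' The exact minimiser of the clustering objective over the membership
#' matrix for fixed prototypes:
#' `u_ik = 1 / sum_j (Lev(sc_i, s_k) / Lev(sc_j, s_k))^(1/(m-1))`.
#' When a string coincides with one or more prototypes (zero distance)
#' its unit membership is split equally among the zero-distance
#' prototypes. Columns always sum to 1.
#'
#' @param strings character vector of N dataset strings.
#' @param prototypes character vector of C prototype strings.
#' @param m fuzzifier, > 1.
#' @return C x N membership matrix U.
#' @export
updateMemberships <- function(strings, prototypes, m = 2) {
  stopifnot(length(prototypes) >= 1L, m > 1)
  D <- utils::adist(prototypes, strings)
  U <- matrix(0, nrow(D), ncol(D))
  W <- D^(-1 / (m - 1))
  for (k in seq_len(ncol(D))) {
    zero <- D[, k] == 0L
    if (any(zero)) {
      U[zero, k] <- 1 / sum(zero)
    } else {
      U[, k] <- W[, k] / sum(W[, k])
    }
  }
  U
}

#' Typicality update (possibilistic component)
#'
#' The exact minimiser of the objective over the typicality matrix for
#' fixed memberships and prototypes:
#' `t_ik = exp(-(b * eta * C * Lev(sc_i, s_k)) / beta)`.
#' Entries lie in (0, 1], with `t_ik = 1` exactly when the distance is
#' zero. Values that underflow the double exponential are clamped to
#' the smallest positive double so the open lower bound survives
#' floating point.
#'
#' @param strings character vector of N dataset strings.
#' @param prototypes character vector of C prototype strings.
#' @param beta positive dataset scale, see [betaScale()].
#' @param b possibilistic weight, > 0.
#' @param eta typicality fuzzifier, > 1.
#' @return C x N typicality matrix.
#' @export
updateTypicalities <- function(strings, prototypes, beta, b = 6, eta = 2) {
  if (length(beta) != 1L || !is.finite(beta) || beta <= 0)
    stop("beta must be a positive scalar")
  stopifnot(b > 0, eta > 1)
  C <- length(prototypes)
  D <- utils::adist(prototypes, strings)
  Tm <- exp(-(b * eta * C * D) / beta)
  Tm[Tm == 0] <- .Machine$double.xmin
  Tm
}

#' Clustering objective
#'
#' The possibilistic fuzzy C-medians objective on string data:
#' `sum_ik (a u_ik^m + b t_ik^eta) Lev(s_k, sc_i)
#'  + (beta / (eta^2 C)) sum_ik (t_ik^eta log t_ik^eta - t_ik^eta)`.
#' The entropy term uses the continuous extension `0` at `t = 0`, so
#' typicalities that underflow to numerical zero contribute nothing.
#'
#' @param strings character vector of N dataset strings.
#' @param U C x N membership matrix.
#' @param Tm C x N typicality matrix.
#' @param prototypes character vector of C prototypes.
#' @param beta positive dataset scale.
#' @param a,b,m,eta objective parameters (defaults 1, 6, 2, 2).
#' @return numeric scalar.
#' @export
sgObjective <- function(strings, U, Tm, prototypes, beta,
                        a = 1, b = 6, m = 2, eta = 2) {
  D <- utils::adist(prototypes, strings)
  stopifnot(all(dim(U) == dim(D)), all(dim(Tm) == dim(D)))
  Teta <- Tm^eta
  ent <- ifelse(Teta > 0, Teta * log(Teta) - Teta, 0)
  sum((a * U^m + b * Teta) * D) +
    (beta / (eta^2 * length(prototypes))) * sum(ent)
}

#' Prototype update (weighted modified fuzzy medians)
#'
#' For each cluster i the per-string weights are
#' `w_k = a u_ik^m + b t_ik^eta`; the new prototype is the modified
#' fuzzy median reached by greedy edit descent from the better of the
#' weighted set median and the previous prototype, so its weighted cost
#' never exceeds either. If two clusters land on the same string, the
#' duplicate is reseeded with the dataset string carrying the largest
#' weighted-distance contribution to the objective (an anti-collapse
#' restart inherited from the possibilistic C-means lineage).
#'
#' @param strings character vector of N dataset strings.
#' @param U,Tm C x N membership and typicality matrices.
#' @param previous optional character vector of the C current
#'   prototypes, kept as descent candidates.
#' @param a,b,m,eta objective parameters.
#' @param alphabet a [SaxAlphabet-class] for the edit search.
#' @param maxPasses maximum accepted edits per cluster per update.
#' @return character vector of C prototypes, with attribute
#'   `"reseeds"`: how many duplicates were reseeded.
#' @export
updatePrototypes <- function(strings, U, Tm, previous = NULL,
                             a = 1, b = 6, m = 2, eta = 2,
                             alphabet = saxAlphabet(), maxPasses = 10L) {
  C <- nrow(U)
  stopifnot(nrow(Tm) == C, ncol(U) == length(strings))
  protos <- character(C)
  for (i in seq_len(C)) {
    w <- a * U[i, ]^m + b * Tm[i, ]^eta
    start <- weightedMedianString(strings, w)
    if (!is.null(previous) &&
        weightedCost(previous[[i]], strings, w) < weightedCost(start, strings, w))
      start <- previous[[i]]
    protos[[i]] <- as.character(
      modifiedFuzzyMedian(strings, w, start, alphabet, maxPasses))
  }
  reseeds <- 0L
  repeat {
    dup <- which(duplicated(protos))
    if (length(dup) == 0L) break
    i <- dup[[1L]]
    free <- setdiff(unique(strings), protos)
    if (length(free) == 0L) break
    D <- utils::adist(protos, strings)
    contrib <- colSums((a * U^m + b * Tm^eta) * D)
    cand <- free[which.max(contrib[match(free, strings)])]
    protos[[i]] <- cand
    reseeds <- reseeds + 1L
  }
  structure(protos, reseeds = reseeds)
}

# Farthest-first traversal: uniform first pick, then repeatedly the
# string with the largest minimum distance to the picks so far.
initPrototypes <- function(distinct, C) {
  picked <- sample(distinct, 1L)
  while (length(picked) < C) {
    rest <- setdiff(distinct, picked)
    minD <- apply(utils::adist(rest, picked), 1L, min)
    picked <- c(picked, rest[[which.max(minD)]])
  }
  picked
}

runWithSeed <- function(seed, fn) {
  if (is.null(seed)) return(fn())
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  set.seed(seed)
  fn()
}

#' String-grammar unsupervised possibilistic fuzzy C-medians
#'
#' Clusters a set of symbol strings into `C` clusters, each represented
#' by a string prototype, by alternating three updates until the
#' membership matrix stabilises: the fuzzy membership update
#' ([updateMemberships()]), the possibilistic typicality update
#' ([updateTypicalities()]), and the prototype update by weighted
#' modified fuzzy medians ([updatePrototypes()]). The dataset scale
#' `beta` — the mean Levenshtein distance to the set median — is
#' computed once, up front, on the set being clustered. Initial
#' prototypes are chosen by farthest-first traversal over the distinct
#' strings: the first is sampled uniformly under `seed`, each further
#' one is the string maximising its minimum Levenshtein distance to the
#' prototypes already chosen (ties to the lowest index). Spread starts
#' keep the alternation from collapsing into a single dense region.
#'
#' Convergence is declared when the largest absolute change in any
#' membership entry falls below `tol`.
#'
#' @param strings character vector of N symbol strings, with more than
#'   `C` distinct values.
#' @param C number of clusters.
#' @param m,eta fuzzifiers (> 1; defaults 2 and 2).
#' @param a,b fuzzy and possibilistic weights (> 0; defaults 1 and 6).
#' @param tol convergence tolerance on `max |delta U|` (default 0.01).
#' @param maxIter iteration cap (default 100).
#' @param seed integer seed for the prototype initialisation; `NULL`
#'   uses the current RNG state.
#' @param alphabet a [SaxAlphabet-class] for the prototype edit search.
#' @param maxPasses accepted-edit cap per prototype update.
#' @return a [ClusterModel-class].
#' @examples
#' set.seed(7)
#' gen <- generateStringClusters(c("aaaaaaaa", "hhhhhhhh"),
#'                               mutationProb = 0.1, nPerCluster = 10)
#' fit <- sgupfcmed(gen$strings, C = 2, seed = 1)
#' prototypes(fit)
#' @export
sgupfcmed <- function(strings, C, m = 2, eta = 2, a = 1, b = 6,
                      tol = 0.01, maxIter = 100L, seed = NULL,
                      alphabet = saxAlphabet(), maxPasses = 10L) {
  stopifnot(length(strings) >= 2L, C >= 1L, C == round(C),
            m > 1, eta > 1, a > 0, b > 0, tol > 0, maxIter >= 1L)
  distinct <- unique(strings)
  if (length(distinct) == 1L)
    stop("degenerate dataset: all strings identical")
  if (C >= length(distinct))
    stop(sprintf("C = %d must be smaller than the number of distinct strings (%d)",
                 C, length(distinct)))
  beta <- betaScale(strings)
  V <- runWithSeed(seed, function() initPrototypes(distinct, C))
  Uprev <- NULL
  history <- numeric(0)
  reseeds <- 0L
  converged <- FALSE
  for (iter in seq_len(maxIter)) {
    U <- updateMemberships(strings, V, m)
    if (!is.null(Uprev) && max(abs(U - Uprev)) < tol) {
      Tm <- updateTypicalities(strings, V, beta, b, eta)
      history <- c(history, sgObjective(strings, U, Tm, V, beta, a, b, m, eta))
      converged <- TRUE
      break
    }
    Tm <- updateTypicalities(strings, V, beta, b, eta)
    Vnew <- updatePrototypes(strings, U, Tm, previous = V,
                             a = a, b = b, m = m, eta = eta,
                             alphabet = alphabet, maxPasses = maxPasses)
    reseeds <- reseeds + attr(Vnew, "reseeds")
    V <- as.character(Vnew)
    history <- c(history, sgObjective(strings, U, Tm, V, beta, a, b, m, eta))
    Uprev <- U
  }
  new("ClusterModel", prototypes = V, membership = U, typicality = Tm,
      beta = beta, objective = history,
      params = list(m = m, eta = eta, a = a, b = b, tol = tol,
                    maxIter = maxIter, maxPasses = maxPasses,
                    seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
                    converged = converged),
      nIter = length(history), reseeds = reseeds)
}

#' @export
setMethod("show", "ClusterModel", function(object) {
  cat(sprintf("ClusterModel: %d prototypes over %d strings, beta = %.3f\n",
              length(object@prototypes), ncol(object@membership),
              object@beta))
  cat(sprintf("  %d iterations (%s), objective %.4f\n", object@nIter,
              if (isTRUE(object@params$converged)) "converged"
              else "iteration cap reached",
              utils::tail(object@objective, 1)))
  for (p in object@prototypes)
    cat("  ", abbreviate(p, 60), "\n", sep = "")
})

#' Accessors for fitted cluster models and prototype sets
#'
#' `prototypes()` returns the prototype strings; `memberships()` the
#' fuzzy membership matrix (clusters x strings for a
#' [ClusterModel-class], prototypes x classes for a
#' [PrototypeSet-class]); `typicalities()` the possibilistic matrix;
#' `objectiveHistory()` the objective value after each iteration;
#' `betaScaleOf()` the fitted dataset scale.
#'
#' @param object a [ClusterModel-class] or [PrototypeSet-class].
#' @return see description.
#' @name model-accessors
#' @aliases prototypes memberships typicalities objectiveHistory
NULL

#' @rdname model-accessors
#' @export
setMethod("prototypes", "ClusterModel", function(object) object@prototypes)
#' @rdname model-accessors
#' @export
setMethod("memberships", "ClusterModel", function(object) object@membership)
#' @rdname model-accessors
#' @export
setMethod("typicalities", "ClusterModel", function(object) object@typicality)
#' @rdname model-accessors
#' @export
setMethod("objectiveHistory", "ClusterModel",
          function(object) object@objective)

#' @rdname model-accessors
#' @export
betaScaleOf <- function(object) object@beta

#' Serialise / restore a fitted cluster model
#'
#' Plain-text JSON round trip of every slot of a [ClusterModel-class].
#'
#' @param model a [ClusterModel-class].
#' @param path file path.
#' @return `writeClusterModel`: `path`, invisibly. `readClusterModel`:
#'   the restored [ClusterModel-class].
#' @export
writeClusterModel <- function(model, path) {
  payload <- list(prototypes = model@prototypes,
                  membership = model@membership,
                  typicality = model@typicality,
                  beta = model@beta, objective = model@objective,
                  params = model@params, nIter = model@nIter,
                  reseeds = model@reseeds)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeClusterModel
#' @export
readClusterModel <- function(path) {
  x <- jsonlite::fromJSON(path)
  new("ClusterModel", prototypes = as.character(x$prototypes),
      membership = as.matrix(x$membership),
      typicality = as.matrix(x$typicality),
      beta = as.numeric(x$beta), objective = as.numeric(x$objective),
      params = as.list(x$params), nIter = as.integer(x$nIter),
      reseeds = as.integer(x$reseeds))
}
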