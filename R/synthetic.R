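#' Construct a synthetic gait template
#'
#' @param classLabel one of `"ALS"`, `"HD"`, `"PD"`, `"CO"`.
#' @param meanStride mean stride interval in seconds.
#' @param sdStride stationary SD in seconds.
#' @param ar1 lag-1 autocorrelation in `[0, 1)`.
#' @param outlierRate probability that a stride is replaced by an
#'   outlier, in `[0, 1)`.
#' @param outlierMag outlier offset in multiples of `sdStride`.
#' @param modDepth amplitude of the deterministic rhythmic stride-time
#'   modulation, in multiples of `sdStride` (default 0, none).
#' @param modPeriod period of the modulation in strides (default 0,
#'   none).
#' @return a [GaitTemplate-class].
#' @export
gaitTemplate <- function(classLabel, meanStride, sdStride, ar1,
                         outlierRate = 0, outlierMag = 6,
                         modDepth = 0, modPeriod = 0) {
  new("GaitTemplate", classLabel = classLabel, meanStride = meanStride,
      sdStride = sdStride, ar1 = ar1, outlierRate = outlierRate,
      outlierMag = outlierMag, modDepth = modDepth,
      modPeriod = modPeriod)
}

#' @export
setMethod("show", "GaitTemplate", function(object) {
  cat(sprintf(
    "GaitTemplate %s: mean %.3f s, SD %.3f s, ar1 %.2f, outliers %.0f%% at %.0f SD\n",
    object@classLabel, object@meanStride, object@sdStride, object@ar1,
    100 * object@outlierRate, object@outlierMag))
})

#' Default class templates for synthetic gait fixtures
#'
#' Qualitative stand-ins for the four diagnostic groups. Means and SDs
#' are in the range reported for the respective patient groups
#' (controls near 1.1 s with ~2% stochastic variability; patients
#' slower and 2-4x more variable), short-range persistence increases
#' from CO to ALS, and occasional grossly prolonged strides exercise
#' the 3-SD median filter. Because z-normalisation removes mean and
#' scale before symbolisation, the separable class signature is the
#' rhythmic stride-time modulation: each template oscillates with a
#' class-specific period (fastest for the festination-like PD
#' template, slowest for CO), giving subjects of a class a shared
#' symbol waveform while the AR(1) fluctuation perturbs it
#' subject-specifically.
#'
#' @return named list of four [GaitTemplate-class] objects (CO, PD, HD,
#'   ALS).
#' @export
defaultGaitTemplates <- function() {
  list(CO  = gaitTemplate("CO",  meanStride = 1.10, sdStride = 0.025,
                          ar1 = 0.05, outlierRate = 0.01, outlierMag = 8,
                          modDepth = 5, modPeriod = 24),
       PD  = gaitTemplate("PD",  meanStride = 1.13, sdStride = 0.050,
                          ar1 = 0.30, outlierRate = 0.03, outlierMag = 8,
                          modDepth = 5, modPeriod = 6),
       HD  = gaitTemplate("HD",  meanStride = 1.15, sdStride = 0.075,
                          ar1 = 0.55, outlierRate = 0.05, outlierMag = 8,
                          modDepth = 5, modPeriod = 10),
       ALS = gaitTemplate("ALS", meanStride = 1.35, sdStride = 0.100,
                          ar1 = 0.80, outlierRate = 0.05, outlierMag = 8,
                          modDepth = 5, modPeriod = 15))
}

#' Generate synthetic gait records
#'
#' Each subject's series is a stationary AR(1) process with the
#' template's mean, SD and lag-1 autocorrelation; with probability
#' `outlierRate` a stride is prolonged by `outlierMag` SDs, emulating
#' hesitation strides. Large magnitudes (beyond roughly 3 inflated
#' SDs) exercise the 3-SD median filter; smaller ones survive it and
#' skew the stride distribution, which is what distinguishes the
#' pathological templates after z-normalisation. Strides are floored
#' at 0.2 s so intervals stay positive. Pure function of `seed` and
#' its parameters.
#'
#' @param templates list of [GaitTemplate-class] objects.
#' @param nPerClass subjects per template.
#' @param len strides per subject (> 20 so preprocessing survives).
#' @param seed integer seed.
#' @return list of [GaitRecord-class] objects.
#' @export
generateGaitRecords <- function(templates, nPerClass, len = 100L,
                                seed = 1L) {
  stopifnot(len > 20L, nPerClass >= 1L)
  runWithSeed(seed, function() {
    records <- list()
    for (tpl in templates) {
      for (subj in seq_len(nPerClass)) {
        phi <- tpl@ar1
        innovSD <- tpl@sdStride * sqrt(1 - phi^2)
        x <- numeric(len)
        x[[1L]] <- stats::rnorm(1, tpl@meanStride, tpl@sdStride)
        for (t in seq_len(len - 1L))
          x[[t + 1L]] <- tpl@meanStride +
            phi * (x[[t]] - tpl@meanStride) + stats::rnorm(1, 0, innovSD)
        if (tpl@modDepth > 0)
          x <- x + tpl@modDepth * tpl@sdStride *
            sin(2 * pi * seq_len(len) / tpl@modPeriod)
        hit <- stats::runif(len) < tpl@outlierRate
        if (any(hit))
          x[hit] <- x[hit] + tpl@outlierMag * tpl@sdStride
        x <- pmax(x, 0.2)
        prefix <- c(ALS = "als", HD = "hunt", PD = "park",
                    CO = "control")[[tpl@classLabel]]
        records[[length(records) + 1L]] <- new(
          "GaitRecord",
          subjectId = sprintf("%s%02d", prefix, subj),
          classLabel = tpl@classLabel, series = x, nRaw = as.integer(len))
      }
    }
    records
  })
}

#' Generate a string dataset with known cluster structure
#'
#' Each sample is one of the `centers` with independent per-symbol
#' substitutions at rate `mutationProb` (replacement drawn uniformly
#' from the other alphabet symbols). Substitution-only mutation keeps
#' the expected Hamming distance to the center at
#' `nchar(center) * mutationProb`. An optional indel mode additionally
#' deletes or duplicates symbols at rate `indelProb`.
#'
#' @param centers character vector of distinct center strings, one per
#'   cluster.
#' @param mutationProb per-symbol substitution probability in
#'   `[0, 0.5]`.
#' @param nPerCluster samples per center.
#' @param seed integer seed.
#' @param alphabet a [SaxAlphabet-class]; default 8 symbols a..h.
#' @param indelProb per-symbol insertion/deletion probability (default
#'   0, substitution-only).
#' @return list with `strings` (character vector), `cluster` (integer
#'   ground-truth index per string) and `centers`.
#' @export
generateStringClusters <- function(centers, mutationProb, nPerCluster,
                                   seed = 1L, alphabet = saxAlphabet(),
                                   indelProb = 0) {
  stopifnot(mutationProb >= 0, mutationProb <= 0.5,
            indelProb >= 0, indelProb < 0.5, nPerCluster >= 1L)
  if (anyDuplicated(centers)) stop("cluster centers must be distinct")
  syms <- alphabet@symbols
  runWithSeed(seed, function() {
    strings <- character(0)
    cluster <- integer(0)
    for (ci in seq_along(centers)) {
      chars0 <- strsplit(centers[[ci]], "", fixed = TRUE)[[1L]]
      for (s in seq_len(nPerCluster)) {
        chars <- chars0
        mut <- stats::runif(length(chars)) < mutationProb
        if (any(mut))
          chars[mut] <- vapply(chars[mut], function(old)
            sample(syms[syms != old], 1L), "", USE.NAMES = FALSE)
        if (indelProb > 0) {
          keep <- stats::runif(length(chars)) >= indelProb
          dup <- stats::runif(length(chars)) < indelProb
          reps <- 1L * keep + 1L * dup   # 0 = delete, 2 = duplicate
          chars <- rep(chars, reps)
          if (length(chars) == 0L) chars <- sample(syms, 1L)
        }
        strings <- c(strings, paste(chars, collapse = ""))
        cluster <- c(cluster, ci)
      }
    }
    list(strings = strings, cluster = cluster, centers = centers)
  })
}
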