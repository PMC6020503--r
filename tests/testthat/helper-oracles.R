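# Independent oracles and small fixture builders shared across tests.

# Brute-force recursive Levenshtein straight from the definition
# (exponential; fine for the short strings it is used on).
bruteLev <- function(a, b) {
  if (nchar(a) == 0L) return(nchar(b))
  if (nchar(b) == 0L) return(nchar(a))
  subCost <- as.integer(substr(a, 1L, 1L) != substr(b, 1L, 1L))
  ra <- substr(a, 2L, nchar(a))
  rb <- substr(b, 2L, nchar(b))
  min(bruteLev(ra, b) + 1L, bruteLev(a, rb) + 1L, bruteLev(ra, rb) + subCost)
}

# Every string over `syms` of length 0..maxLen (empty string first).
allStrings <- function(syms, maxLen) {
  out <- ""
  level <- ""
  for (L in seq_len(maxLen)) {
    level <- as.vector(outer(level, syms, paste0))
    out <- c(out, level)
  }
  out
}

# Whole-language edit-distance table computed bottom-up from the
# recursive definition only (no adist): the exhaustive oracle for the
# small-alphabet agreement check.
bruteLevTable <- function(strs) {
  n <- length(strs)
  tailId <- match(substring(strs, 2L), strs)
  headCh <- substr(strs, 1L, 1L)
  len <- nchar(strs)
  ord <- order(len)
  D <- matrix(0L, n, n)
  for (i in ord) {
    for (j in ord) {
      if (len[i] == 0L) { D[i, j] <- len[j]; next }
      if (len[j] == 0L) { D[i, j] <- len[i]; next }
      D[i, j] <- min(D[tailId[i], j] + 1L,
                     D[i, tailId[j]] + 1L,
                     D[tailId[i], tailId[j]] +
                       (headCh[i] != headCh[j]))
    }
  }
  D
}

randomString <- function(len, syms = letters[1:8]) {
  paste(sample(syms, len, replace = TRUE), collapse = "")
}

# Exhaustive global weighted median over all non-empty strings of
# length <= maxLen: enumeration oracle for the greedy edit search.
exhaustiveWeightedMedian <- function(strings, weights, syms, maxLen) {
  cands <- setdiff(allStrings(syms, maxLen), "")
  costs <- as.vector(utils::adist(cands, strings) %*% weights)
  list(string = cands[[which.min(costs)]], cost = min(costs))
}

weightedLevCost <- function(candidate, strings, weights) {
  sum(weights * as.vector(utils::adist(candidate, strings)))
}

hardAssign <- function(model) apply(memberships(model), 2L, which.max)

# Fixed two-center string fixture used by recovery tests.
twoCenterFixture <- function(seed, len = 30L, mutationProb = 0.05,
                             nPerCluster = 20L, minSep = 6L) {
  set.seed(seed)
  c1 <- randomString(len)
  c2 <- randomString(len)
  while (levenshtein(c1, c2) < minSep) c2 <- randomString(len)
  gen <- generateStringClusters(c(c1, c2), mutationProb, nPerCluster,
                                seed = seed + 5000L)
  gen
}
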