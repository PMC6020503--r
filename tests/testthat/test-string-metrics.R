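test_that("levenshtein matches the recursive definition on known pairs", {
  expect_identical(levenshtein("abc", "abc"), 0L)
  expect_identical(levenshtein("", "abc"), 3L)
  expect_identical(levenshtein("kitten", "sitting"), 3L)
  expect_identical(bruteLev("kitten", "sitting"), 3L)
  set.seed(11)
  for (rep in 1:25) {
    a <- randomString(sample(0:6, 1), letters[1:3])
    b <- randomString(sample(0:6, 1), letters[1:3])
    expect_identical(levenshtein(a, b), bruteLev(a, b))
  }
})

test_that("levenshtein is vectorised into distance matrices", {
  D <- levenshtein(c("ab", "cd"), c("ab", "abc", "zz"))
  expect_equal(dim(D), c(2L, 3L))
  expect_identical(D[1, ], c(0L, 1L, 2L))
})

test_that("edit distance satisfies the metric axioms", {
  set.seed(23)
  for (rep in 1:300) {
    s <- vapply(1:3, function(i) randomString(sample(0:8, 1)), "")
    d12 <- levenshtein(s[1], s[2])
    d13 <- levenshtein(s[1], s[3])
    d23 <- levenshtein(s[2], s[3])
    expect_gte(d12, 0L)
    expect_identical(d12, levenshtein(s[2], s[1]))
    expect_identical(d12 == 0L, s[1] == s[2])
    expect_lte(d13, d12 + d23)
  }
})

test_that("set median minimises total distance with lowest-index ties", {
  expect_equal(setMedianString(c("aa", "aa", "bb")), "aa")
  expect_equal(setMedianString("xyz"), "xyz")
  expect_equal(setMedianString(rep("qq", 4)), "qq")
  # brute check on a random set: no member has smaller total distance
  set.seed(5)
  s <- vapply(1:7, function(i) randomString(sample(1:5, 1), letters[1:3]), "")
  med <- setMedianString(s)
  totals <- rowSums(levenshtein(s, s))
  expect_equal(totals[match(med, s)], min(totals))
})

test_that("betaScale is the mean distance to the set median", {
  expect_equal(betaScale(c("aa", "aa", "bb", "bb")), 1.0)
  expect_equal(betaScale(c("aaa", "bbb")), 1.5)   # distance 3, either median
  expect_error(betaScale(rep("aa", 5)), "degenerate")
})

test_that("weighted median reduces to the set median and tracks weights", {
  s <- c("aa", "ab", "bb")
  expect_equal(weightedMedianString(s, c(1, 1, 1)), setMedianString(s))
  expect_equal(weightedMedianString(c("ab", "cd", "ef"), c(1, 0, 0)), "ab")
  expect_equal(weightedMedianString(s, c(0.1, 0.1, 10)), "bb")
  expect_error(weightedMedianString(s, c(1, 1)), "one weight per")
  expect_error(weightedMedianString(s, c(0, 0, 0)), "strictly positive")
  expect_error(weightedMedianString(s, c(1, -1, 1)), "non-negative")
})

test_that("modified fuzzy median descends to the global optimum on tiny sets", {
  ab <- saxAlphabet(symbols = c("a", "b"))
  S <- c("aaa", "aaa", "aaa", "aab")
  w <- rep(1, 4)
  res <- modifiedFuzzyMedian(S, w, start = "bbb", alphabet = ab)
  expect_equal(as.character(res), "aaa")
  oracle <- exhaustiveWeightedMedian(S, w, c("a", "b"), 4)
  expect_equal(attr(res, "cost"), oracle$cost)
})

test_that("modified fuzzy median is a no-op at a local optimum and never
           raises the cost", {
  ab <- saxAlphabet(symbols = c("a", "b"))
  S <- c("aa", "aa", "bb", "bb")
  res <- modifiedFuzzyMedian(S, rep(1, 4), start = "aa", alphabet = ab)
  expect_equal(as.character(res), "aa")       # 1-edit neighbourhood optimal
  set.seed(17)
  for (rep in 1:20) {
    S <- vapply(1:5, function(i) randomString(sample(2:5, 1), c("a", "b")), "")
    w <- runif(5)
    if (all(w == 0)) w[1] <- 1
    start <- weightedMedianString(S, w)
    res <- modifiedFuzzyMedian(S, w, start, alphabet = ab)
    expect_lte(attr(res, "cost"), weightedLevCost(start, S, w) + 1e-12)
  }
})
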