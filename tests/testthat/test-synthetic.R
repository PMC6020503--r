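test_that("generators are pure functions of their seed", {
  tpl <- defaultGaitTemplates()
  r1 <- generateGaitRecords(tpl, nPerClass = 2, len = 50, seed = 8)
  r2 <- generateGaitRecords(tpl, nPerClass = 2, len = 50, seed = 8)
  expect_identical(lapply(r1, strideSeries), lapply(r2, strideSeries))
  g1 <- generateStringClusters(c("abab", "ghgh"), 0.2, 5, seed = 4)
  g2 <- generateStringClusters(c("abab", "ghgh"), 0.2, 5, seed = 4)
  expect_identical(g1, g2)
})

test_that("zero mutation reproduces the centers exactly", {
  g <- generateStringClusters(c("acegaceg", "hfdbhfdb"), 0, 4, seed = 1)
  expect_equal(g$strings, rep(c("acegaceg", "hfdbhfdb"), each = 4))
  expect_equal(g$cluster, rep(1:2, each = 4))
})

test_that("mutation distance concentrates at length times probability", {
  L <- 200L
  p <- 0.1
  center <- randomString(L)
  g <- generateStringClusters(center, p, 50, seed = 6)
  hamming <- levenshtein(g$strings, center)
  # binomial mean Lp, SD sqrt(Lp(1-p)); the mean of 50 draws sits
  # within 4 standard errors
  se <- sqrt(L * p * (1 - p) / 50)
  expect_lt(abs(mean(hamming) - L * p), 4 * se)
})

test_that("indel mode changes lengths while the default preserves them", {
  g <- generateStringClusters("abcdefgh", 0.1, 20, seed = 2)
  expect_true(all(nchar(g$strings) == 8L))
  gi <- generateStringClusters("abcdefgh", 0.1, 20, seed = 2,
                               indelProb = 0.2)
  expect_true(any(nchar(gi$strings) != 8L))
})

test_that("outlier-free records lose exactly the startup strides", {
  tpl <- gaitTemplate("CO", 1.1, 0.02, 0.1, outlierRate = 0,
                      modDepth = 4, modPeriod = 12)
  recs <- generateGaitRecords(list(tpl), nPerClass = 3, len = 80,
                              seed = 13)
  for (r in recs)
    expect_length(preprocessStrides(strideSeries(r)), 60L)
})

test_that("generated series match their template mean", {
  tpl <- gaitTemplate("PD", 1.2, 0.05, 0)
  recs <- generateGaitRecords(list(tpl), nPerClass = 20, len = 400,
                              seed = 19)
  grand <- mean(unlist(lapply(recs, strideSeries)))
  se <- 0.05 / sqrt(20 * 400)
  expect_lt(abs(grand - 1.2), 3 * se)
  expect_true(all(unlist(lapply(recs, strideSeries)) > 0))
})

test_that("invalid templates are rejected", {
  expect_error(gaitTemplate("CO", -1, 0.05, 0), "positive")
  expect_error(gaitTemplate("CO", 1.1, 0.05, 1), "ar1")
  expect_error(gaitTemplate("CO", 1.1, 0.05, 0.2, outlierRate = 1),
               "outlierRate")
  expect_error(gaitTemplate("XX", 1.1, 0.05, 0.2), "classLabel")
  expect_error(gaitTemplate("CO", 1.1, 0.05, 0.2, modDepth = 2),
               "period")
  expect_error(generateStringClusters(c("aa", "aa"), 0.1, 3), "distinct")
})
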