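test_that("membership update matches the closed form", {
  # distances (1, 3) at m = 2 give (0.75, 0.25)
  U <- updateMemberships("abc", c("abd", "xyz"), m = 2)
  expect_equal(U[, 1], c(0.75, 0.25))
  # equidistant prototypes split uniformly
  U <- updateMemberships("ab", c("aa", "bb", "cb"), m = 2)
  expect_equal(U[, 1], rep(1 / 3, 3))
  # zero distance takes the whole membership
  U <- updateMemberships("aa", c("aa", "bb"), m = 2)
  expect_equal(U[, 1], c(1, 0))
  # shared equally among coincident prototypes
  U <- updateMemberships("aa", c("aa", "aa", "bb"), m = 2)
  expect_equal(U[, 1], c(0.5, 0.5, 0))
})

test_that("membership columns are stochastic for random configurations", {
  set.seed(3)
  for (rep in 1:25) {
    s <- vapply(1:12, function(i) randomString(sample(3:8, 1)), "")
    protos <- unique(s)[1:3]
    U <- updateMemberships(s, protos, m = runif(1, 1.2, 3))
    expect_equal(colSums(U), rep(1, 12), tolerance = 1e-9)
    expect_true(all(U >= 0 & U <= 1))
  }
})

test_that("typicality update matches the exponential closed form", {
  Tm <- updateTypicalities("ab", c("aa", "zz"), beta = 24, b = 6, eta = 2)
  expect_equal(Tm[1, 1], exp(-1))             # Lev = 1 at C = 2
  expect_equal(Tm[2, 1], exp(-2))
  Tm0 <- updateTypicalities("aa", c("aa", "bb"), beta = 5)
  expect_equal(Tm0[1, 1], 1)                  # exactly 1 on zero distance
  expect_lt(Tm0[2, 1], 1)
  # strictly decreasing in the distance
  Tm <- updateTypicalities(c("aaaa"), c("aaab", "aabb", "abbb"), beta = 10)
  expect_true(all(diff(Tm[, 1]) < 0))
  expect_error(updateTypicalities("ab", "aa", beta = 0), "positive")
})

test_that("objective reproduces hand-computed values", {
  S <- c("aa", "aa", "bb", "bb")
  V <- c("aa", "bb")
  U <- updateMemberships(S, V, m = 2)
  Tm <- updateTypicalities(S, V, beta = 1, b = 6, eta = 2)
  J <- sgObjective(S, U, Tm, V, beta = 1, a = 1, b = 6, m = 2, eta = 2)
  # entropy term (1/8) * (-4) dominates; cross terms carry t = e^-48
  expect_equal(J, -0.5, tolerance = 1e-6)
  # all t = 1 on zero distances: J = -(beta * N) / eta^2
  S2 <- c("aa", "aa")
  V2 <- c("aa", "aa")
  U2 <- updateMemberships(S2, V2, m = 2)
  Tm2 <- matrix(1, 2, 2)
  expect_equal(sgObjective(S2, U2, Tm2, V2, beta = 3), -3 * 2 / 4)
})

test_that("prototype update reduces to per-cluster set medians for crisp
           memberships", {
  S <- c("aa", "aa", "ab", "hh", "hh", "hg")
  U <- rbind(c(1, 1, 1, 0, 0, 0), c(0, 0, 0, 1, 1, 1))
  Tm <- matrix(.Machine$double.xmin, 2, 6)     # typicality ~ 0
  V <- updatePrototypes(S, U, Tm, a = 1, b = 6)
  expect_equal(sort(as.character(V)), c("aa", "hh"))
})

test_that("coincident prototypes are reseeded apart", {
  S <- c("aa", "ab", "ba", "bb")
  U <- matrix(0.5, 2, 4)                       # identical rows force a tie
  Tm <- matrix(.Machine$double.xmin, 2, 4)
  V <- updatePrototypes(S, U, Tm, a = 1, b = 6)
  expect_false(anyDuplicated(as.character(V)) > 0)
  expect_gte(attr(V, "reseeds"), 1L)
})

test_that("fit recovers two well-separated string clouds exactly", {
  gen <- generateStringClusters(c("aaaaaaaa", "hhhhhhhh"),
                                mutationProb = 0.1, nPerCluster = 20,
                                seed = 3)
  fit <- sgupfcmed(gen$strings, C = 2, seed = 1)
  dToTruth <- levenshtein(prototypes(fit), gen$centers)
  expect_lte(max(apply(dToTruth, 2, min)), 1L)
  hard <- hardAssign(fit)
  expect_equal(length(unique(paste(hard, gen$cluster))), 2L)  # exact match
})

test_that("single-cluster fit returns the fuzzy median with unit
           memberships", {
  s <- c("aaa", "aab", "abb", "aba")
  fit <- sgupfcmed(s, C = 1, seed = 2)
  expect_equal(unname(memberships(fit)[1, ]), rep(1, 4))
  w <- 1 * rep(1, 4)^2 + 6 * typicalities(fit)[1, ]^2
  direct <- modifiedFuzzyMedian(s, w, weightedMedianString(s, w))
  expect_equal(prototypes(fit), as.character(direct))
})

test_that("fitting is deterministic under a fixed seed", {
  gen <- generateStringClusters(c("abcdabcd", "ghefghef"), 0.15, 10,
                                seed = 9)
  f1 <- sgupfcmed(gen$strings, C = 2, seed = 42)
  f2 <- sgupfcmed(gen$strings, C = 2, seed = 42)
  expect_identical(prototypes(f1), prototypes(f2))
  expect_identical(memberships(f1), memberships(f2))
  expect_identical(objectiveHistory(f1), objectiveHistory(f2))
})

test_that("degenerate and over-parameterised inputs are rejected", {
  expect_error(sgupfcmed(rep("aa", 5), C = 1), "degenerate|identical")
  expect_error(sgupfcmed(c("aa", "ab", "aa"), C = 2), "smaller than")
  expect_error(sgupfcmed(c("aa", "ab", "ba"), C = 2, m = 1), "m > 1")
})

test_that("fit invariants hold across random datasets", {
  set.seed(60)
  for (rep in 1:10) {
    centers <- c(randomString(12), randomString(12))
    if (levenshtein(centers[1], centers[2]) < 4) next
    gen <- generateStringClusters(centers, 0.1, 8, seed = 100 + rep)
    fit <- sgupfcmed(gen$strings, C = 2, seed = rep)
    U <- memberships(fit)
    Tm <- typicalities(fit)
    expect_equal(colSums(U), rep(1, ncol(U)), tolerance = 1e-9)
    expect_true(all(Tm > 0 & Tm <= 1))
    D <- levenshtein(prototypes(fit), gen$strings)
    expect_identical(unname(Tm == 1), unname(D == 0L))
    expect_true(all(diff(objectiveHistory(fit)) <= 1e-9))
  }
})

test_that("cluster models serialise to JSON and back", {
  gen <- generateStringClusters(c("aaaaaa", "hhhhhh"), 0.1, 6, seed = 8)
  fit <- sgupfcmed(gen$strings, C = 2, seed = 5)
  path <- file.path(withr::local_tempdir(), "model.json")
  writeClusterModel(fit, path)
  back <- readClusterModel(path)
  expect_equal(prototypes(back), prototypes(fit))
  expect_equal(memberships(back), memberships(fit))
  expect_equal(typicalities(back), typicalities(fit))
  expect_equal(betaScaleOf(back), betaScaleOf(fit))
  expect_equal(objectiveHistory(back), objectiveHistory(fit))
})
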