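test_that("cluster p-values equal exhaustive sign-flip enumeration", {
  set.seed(3)
  P <- 8; S <- 3; Tn <- 5
  adj <- matrix(FALSE, S, S)
  adj[1, 2] <- adj[2, 1] <- adj[2, 3] <- adj[3, 2] <- TRUE
  for (rep in 1:3) {
    X <- array(rnorm(P * S * Tn), c(P, S, Tn))
    X[, 2, 2:4] <- X[, 2, 2:4] + rep * 0.6
    pv <- brutePvalues(X, adj)
    expect_equal(pv$impl, pv$oracle, tolerance = 1e-12)
  }
})

test_that("a constant single-site effect reaches the minimum attainable p", {
  set.seed(4)
  Y <- array(rnorm(10 * 4 * 20, 0, 0.1), c(10, 4, 20))
  Y[, 3, 6:15] <- Y[, 3, 6:15] + 5
  cs <- clusterOneSampleTest(Y, matrix(FALSE, 4, 4), nPerm = 199, seed = 9)
  ct <- clusterTable(cs)
  expect_equal(ct$p[1], 1 / 200)
  expect_true(all(cs@members[[1]][, "site"] == 3))
  # p-values bounded below by 1/(nPerm + 1)
  expect_true(all(ct$p >= 1 / 200 & ct$p <= 1))
})

test_that("negating the residuals mirrors clusters with identical masses and p", {
  set.seed(5)
  X <- array(rnorm(9 * 5 * 30), c(9, 5, 30))
  X[, 2, 5:20] <- X[, 2, 5:20] + 0.9
  adj <- adjacencyFromLayout(tinyLayout(5))
  a <- clusterOneSampleTest(X, adj, exhaustive = TRUE)
  b <- clusterOneSampleTest(-X, adj, exhaustive = TRUE)
  expect_equal(clusterTable(a)$p, clusterTable(b)$p)
  expect_equal(clusterTable(a)$mass, -clusterTable(b)$mass)
  expect_equal(clusterTable(a)$sign, -clusterTable(b)$sign)
})

test_that("cluster structure is invariant to site relabeling", {
  set.seed(6)
  S <- 6
  lay <- tinyLayout(S)
  adj <- adjacencyFromLayout(lay)
  X <- array(rnorm(8 * S * 15), c(8, S, 15))
  X[, 2, 4:12] <- X[, 2, 4:12] + 1
  X[, 4, 4:12] <- X[, 4, 4:12] + 1
  perm <- sample(S)
  a <- clusterOneSampleTest(X, adj, exhaustive = TRUE)
  b <- clusterOneSampleTest(X[, perm, , drop = FALSE],
                            adj[perm, perm], exhaustive = TRUE)
  expect_equal(sort(clusterTable(a)$mass), sort(clusterTable(b)$mass))
  expect_equal(sort(clusterTable(a)$p), sort(clusterTable(b)$p))
})

test_that("input validation rejects malformed cluster-test calls", {
  X <- array(rnorm(2 * 2 * 5), c(2, 2, 5))
  expect_error(clusterOneSampleTest(X[1, , , drop = FALSE],
                                    matrix(FALSE, 2, 2)), "at least 2")
  expect_error(clusterOneSampleTest(X, matrix(FALSE, 3, 3)), "cover")
  expect_error(clusterOneSampleTest(X, matrix(FALSE, 2, 2), nPerm = 0),
               "nPerm")
})

test_that("duration masking follows the (n-1)/sfreq span convention", {
  S <- 3; Tn <- 20
  sig <- matrix(FALSE, S, Tn)
  sig[1, 1:7] <- TRUE            # 7 samples at 500 Hz: 12 ms, excluded
  sig[2, 1:8] <- TRUE            # 8 samples: 14 ms, included
  cs <- methods::new("ClusterStats",
                     clusters = data.frame(cluster = 1L, sign = 1,
                                           mass = 1, n_points = 15L,
                                           p = 0.01),
                     members = list(cbind(site = 1L, sample = 1L)),
                     sigMask = sig, tmap = matrix(0, S, Tn), alpha = 0.05,
                     nPerm = 100L, seed = 1L, t = (1:Tn) / 500,
                     sites = sprintf("S%03d", 1:3), sfreq = 500)
  expect_equal(unname(durationMask(cs, 0.0125)), c(FALSE, TRUE, FALSE))
  # the alternative n/sfreq reading flags the 7-sample run too
  expect_equal(unname(durationMask(cs, 0.0125, convention = "count")),
               c(TRUE, TRUE, FALSE))
  cs@sigMask[] <- FALSE
  expect_false(any(durationMask(cs, 0.0125)))
})

test_that("mirror-symmetric residuals produce a null lateralization contrast", {
  lay <- tinyLayout(8)
  s <- siteTable(lay)
  P <- 8; Tn <- 40
  set.seed(11)
  base <- array(rnorm(P * 4 * Tn), c(P, 4, Tn))
  X <- array(0, c(P, 8, Tn))
  left <- order(s$x)[1:4]          # mirror order: left ascending x
  right <- order(-s$x)[1:4]        # matching right partners
  X[, left, ] <- base
  X[, right, ] <- base             # perfectly symmetric
  lt <- lateralizationTimecourse(X, lay, nPerm = 100, seed = 3)
  expect_true(all(abs(lt$difference) < 1e-12))
  expect_equal(nrow(clusterTable(lt$test)), 0)
})

test_that("a right-lateralized effect is detected as a negative left-minus-right difference", {
  lay <- tinyLayout(8)
  s <- siteTable(lay)
  P <- 12; Tn <- 60
  detected <- 0
  for (k in 1:20) {
    set.seed(100 + k)
    X <- array(rnorm(P * 8 * Tn, 0, 1), c(P, 8, Tn))
    X[, s$hemisphere == "right", 20:50] <-
      X[, s$hemisphere == "right", 20:50] + 1.2
    lt <- lateralizationTimecourse(X, lay, nPerm = 200, seed = 200 + k)
    ct <- clusterTable(lt$test)
    if (nrow(ct) && any(ct$p <= 0.05 & ct$sign < 0)) detected <- detected + 1
  }
  expect_gte(detected / 20, 0.9)
  # subgroup restriction runs the same contrast on a subset
  sub <- s$site[s$hemisphere != "midline"][1:6]
  lt2 <- lateralizationTimecourse(array(rnorm(P * 8 * Tn), c(P, 8, Tn)),
                                  lay, siteSubset = sub, nPerm = 50,
                                  seed = 1)
  expect_equal(dim(lt2$difference), c(P, Tn))
  expect_error(lateralizationTimecourse(X, lay,
                                        siteSubset = s$site[s$x > 0]),
               "non-empty")
})

test_that("paired hemisphere t-test matches its definition and degenerate cases", {
  expect_equal(pairedHemisphereTtest(c(1, 2, 3), c(1, 2, 3)),
               list(t = 0, df = 2L, p = 1, meanDiff = 0))
  set.seed(12)
  l <- rnorm(28); r <- rnorm(28)
  res <- pairedHemisphereTtest(l, r)
  expect_equal(res$df, 27)
  ref <- t.test(l - r)
  expect_equal(res$t, unname(ref$statistic))
  expect_equal(res$p, ref$p.value)
  deg <- pairedHemisphereTtest(2:5, 1:4)
  expect_true(is.infinite(deg$t) && deg$t > 0)
  expect_equal(deg$p, 0)
  expect_error(pairedHemisphereTtest(1, 2), "at least 2")
})

test_that("proportion tests combine Pearson chi-square with the Bayes factor", {
  eq <- proportionTests(10, 20, 10, 20)
  expect_equal(eq$chi2$statistic, 0)
  expect_equal(eq$chi2$p, 1)
  expect_equal(eq$chi2$df, 1)
  # equal proportions with n = 51 per side favour the null
  bfEq <- proportionTests(20, 51, 20, 51)
  expect_lt(bfEq$bf, 1)
  # extreme imbalance: large statistic, BF >> 1
  ex <- proportionTests(50, 51, 1, 51)
  expect_gt(ex$chi2$statistic, 30)
  expect_gt(ex$bf, 1000)
  # Bonferroni adjustment doubles (and caps) the p-value
  some <- proportionTests(30, 51, 20, 51)
  expect_equal(some$chi2$pAdjusted, min(1, 2 * some$chi2$p))
  expect_error(proportionTests(5, 0, 1, 10), "zero totals")
  expect_error(proportionTests(11, 10, 1, 10), "exceed")
})

test_that("the numerically integrated Bayes factor matches the conjugate closed form", {
  # independent Beta(a,a) priors admit a closed-form marginal likelihood
  closedForm <- function(kL, nL, kR, nR, a = 1) {
    m1 <- exp(lchoose(nL, kL) + lbeta(kL + a, nL - kL + a) - lbeta(a, a) +
              lchoose(nR, kR) + lbeta(kR + a, nR - kR + a) - lbeta(a, a))
    m0 <- exp(lchoose(nL, kL) + lchoose(nR, kR) +
              lbeta(kL + kR + a, nL + nR - kL - kR + a) - lbeta(a, a))
    m1 / m0
  }
  cases <- list(c(20, 51, 20, 51), c(50, 51, 1, 51), c(8, 30, 16, 40),
                c(0, 10, 5, 10))
  for (cs in cases) {
    got <- proportionTests(cs[1], cs[2], cs[3], cs[4])$bf
    expect_equal(got, closedForm(cs[1], cs[2], cs[3], cs[4]),
                 tolerance = 1e-6)
  }
  # prior concentration is honoured
  expect_equal(proportionTests(8, 30, 16, 40, priorConcentration = 2)$bf,
               closedForm(8, 30, 16, 40, a = 2), tolerance = 1e-6)
})

test_that("the cluster-size statistic is available behind a flag", {
  set.seed(21)
  X <- array(rnorm(10 * 4 * 20, 0, 0.2), c(10, 4, 20))
  X[, 2, 5:15] <- X[, 2, 5:15] + 3
  adj <- matrix(FALSE, 4, 4)
  a <- clusterOneSampleTest(X, adj, nPerm = 99, seed = 2, statistic = "size")
  ct <- clusterTable(a)
  expect_equal(abs(ct$mass[1]), ct$n_points[1])  # statistic is the count
  expect_lte(ct$p[1], 0.1)
  b <- clusterOneSampleTest(X, adj, nPerm = 99, seed = 2, statistic = "mass")
  expect_equal(clusterTable(b)$n_points[1], ct$n_points[1])
})
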