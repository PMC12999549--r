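test_that("the benchmark design is built as printed", {
  des <- makeDesign("main", seedDesign = 1)
  expect_equal(c(des@p, des@k, des@q, des@d, des@r), c(11, 1, 2, 1, 1))
  expect_true(all(des@betaX == 1.5))
  expect_equal(unname(des@betaZ[, 1]), c(-5, 2))
  expect_true(all(des@gammaX == 1))
  expect_equal(unname(des@gammaZ[, 1]), c(-0.1, 2.5))
  expect_equal(des@SigmaYcond, diag(3, 1))
  # 4 of 11 mediators active; inactive rows of Gamma exactly zero
  expect_equal(des@trueSelected, 1:4)
  expect_true(all(des@Gamma[5:11, ] == 0))
  expect_equal(crossprod(des@Gamma), diag(1), ignore_attr = TRUE)
  # realized covariance norms anchored to the printed values
  expect_equal(norm(des@Omega, "2"), 1.18, tolerance = 1e-10)
  expect_equal(norm(des@Omega0, "2"), 29.34, tolerance = 1e-10)
  # single draw per design seed: rebuilding reproduces it exactly
  expect_identical(des@Gamma, makeDesign("main", seedDesign = 1)@Gamma)
  expect_false(identical(des@Gamma, makeDesign("main", seedDesign = 2)@Gamma))
})

test_that("application-matched design has the published shape", {
  des <- makeDesign("matched_application", seedDesign = 1)
  expect_equal(c(des@n, des@p, des@k, des@q, des@d, des@r),
               c(612, 296, 1, 0, 2, 14))
  expect_equal(length(des@trueSelected), 74L)
  expect_true(all(des@Gamma[75:296, ] == 0))
  expect_equal(crossprod(des@Gamma), diag(2), ignore_attr = TRUE,
               tolerance = 1e-10)
})

test_that("generator moments match the design truth at large n", {
  des <- makeDesign("main", seedDesign = 2)
  dat <- simulateDataset(des, n = 100000, seedData = 4)
  expect_lt(abs(mean(exposures(dat)) - 0.5), 0.01)
  # conditional covariance of M given (X, Z)
  mom <- conditionalMoments(dat)
  truth <- designTruth(des)
  relErr <- norm(mom@S$MXZ - truth$SigmaMcond, "F") /
    norm(truth$SigmaMcond, "F")
  expect_lt(relErr, 0.02)
  # confounders: Bernoulli(0.1) and N(0, 0.1^2)
  Z <- confounders(dat)
  expect_lt(abs(mean(Z[, 1]) - 0.1), 0.01)
  expect_lt(abs(sd(Z[, 2]) - 0.1), 0.005)
})

test_that("c2 = 0 makes the true indirect effect exactly zero", {
  des <- makeDesign("main", seedDesign = 3, c2 = 0)
  expect_true(all(designTruth(des)$indirect == 0))
  expect_true(all(designTruth(des)$betaM == 0))
  # c1/c2 scale the truths linearly
  d2 <- makeDesign("main", seedDesign = 3, c1 = 2, c2 = 0.5)
  d1 <- makeDesign("main", seedDesign = 3)
  expect_equal(designTruth(d2)$betaX, 2 * designTruth(d1)$betaX)
  expect_equal(designTruth(d2)$betaM, 0.5 * designTruth(d1)$betaM)
})

test_that("non-normal error families keep the first two moments", {
  des <- makeDesign("main", seedDesign = 5, errorFamily = "chisq4")
  dat <- simulateDataset(des, n = 50000, seedData = 6)
  mom <- conditionalMoments(dat)
  truth <- designTruth(des)
  relErr <- norm(mom@S$MXZ - truth$SigmaMcond, "F") /
    norm(truth$SigmaMcond, "F")
  expect_lt(relErr, 0.05)
})

test_that("replication runs are deterministic and report OLS errors faithfully", {
  des <- makeDesign("main", seedDesign = 1)
  s1 <- runReplications(des, "ols", reps = 5, n = 120, seed = 9)
  s2 <- runReplications(des, "ols", reps = 5, n = 120, seed = 9)
  expect_identical(s1@rmseDirect, s2@rmseDirect)
  expect_identical(s1@rmseIndirect, s2@rmseIndirect)
  # independent OLS loop oracle
  truth <- designTruth(des)
  sq <- sapply(1:5, function(i) {
    dat <- simulateDataset(des, n = 120,
                           seedData = envmed:::.streamSeed(9, 1000 + i))
    df <- data.frame(y = outcomes(dat)[, 1], mediators(dat),
                     x = exposures(dat)[, 1], confounders(dat))
    cf <- coef(lm(y ~ ., data = df))
    (cf[["x"]] - truth$betaX[1, 1])^2
  })
  expect_equal(s1@rmseDirect[1], sqrt(mean(sq)), tolerance = 1e-8)
})

test_that("correlated exposures respect the copula correlation", {
  des <- makeDesign("multi_exposure", seedDesign = 2, rho = 0.5)
  dat <- simulateDataset(des, n = 50000, seedData = 3)
  X <- exposures(dat)
  expect_equal(dim(X)[2], 2L)
  expect_lt(abs(mean(X[, 1]) - 0.5), 0.01)
  # Bernoulli correlation induced by a Gaussian copula at rho = 0.5:
  # 2 * asin(rho) / (2 pi) * 4 ... empirical check against the closed form
  rhoB <- asin(0.5) / (pi / 2)  # tetrachoric-to-phi for p = 0.5 thresholds
  expect_lt(abs(cor(X[, 1], X[, 2]) - rhoB), 0.02)
})
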