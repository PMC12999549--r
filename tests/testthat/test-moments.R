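test_that("residuals match a per-column least-squares oracle on a toy", {
  dat <- toyData(n = 6, p = 3)
  mom <- conditionalMoments(dat)
  W <- cbind(scale(exposures(dat), scale = FALSE),
             scale(confounders(dat), scale = FALSE))
  Mc <- scale(mediators(dat), scale = FALSE)
  oracle <- apply(Mc, 2, function(m) residuals(lm(m ~ W - 1)))
  expect_equal(unname(mom@residMXZ), unname(oracle), tolerance = 1e-10)
  # residuals orthogonal to the centered design
  expect_lt(max(abs(crossprod(mom@residMXZ, W))) /
              max(abs(mom@residMXZ)), 1e-8)
  expect_lt(max(abs(crossprod(mom@residYXZ, W))) /
              max(abs(mom@residYXZ)), 1e-8)
})

test_that("with no covariates, residuals are the centered blocks", {
  set.seed(3)
  M <- matrix(rnorm(30), 10, 3)
  Y <- matrix(rnorm(10))
  dat <- MediationDataset(Y, M, X = NULL, Z = NULL)
  mom <- conditionalMoments(dat)
  expect_equal(mom@residMXZ, scale(M, scale = FALSE), ignore_attr = TRUE)
  expect_equal(mom@residYXZ, scale(Y, scale = FALSE), ignore_attr = TRUE)
})

test_that("every covariance block matches the outer-product oracle", {
  dat <- toyData(n = 12, p = 3, r = 2, seed = 21)
  mom <- conditionalMoments(dat)
  Y <- outcomes(dat); M <- mediators(dat)
  X <- exposures(dat); Z <- confounders(dat)
  W <- cbind(X, Z)
  expect_equal(mom@S$MXZ, oracleCondCov(M, W), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(mom@S$YXZ, oracleCondCov(Y, W), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(mom@S$YM.XZ, oracleCrossCov(Y, M, W), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(mom@S$X.Z, oracleCondCov(X, Z), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(mom@S$Z.X, oracleCondCov(Z, X), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(mom@S$XM.Z, oracleCrossCov(X, M, Z), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(mom@S$ZY.X, oracleCrossCov(Z, Y, X), tolerance = 1e-10,
               ignore_attr = TRUE)
  # Schur-complement identity holds to machine precision
  schur <- mom@S$MXZ - t(mom@S$YM.XZ) %*% solve(mom@S$YXZ, mom@S$YM.XZ)
  expect_equal(mom@S$MYXZ, (schur + t(schur)) / 2, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("S_{M|Y,X,Z} is dominated by S_{M|X,Z} in the PSD order", {
  for (seed in 1:5) {
    dat <- toyData(n = 15, p = 4, seed = seed)
    mom <- conditionalMoments(dat)
    ev <- eigen(mom@S$MXZ - mom@S$MYXZ, symmetric = TRUE,
                only.values = TRUE)$values
    expect_gte(min(ev), -1e-10)
  }
})

test_that("scaling one mediator column scales the covariance rows/columns", {
  dat <- toyData(n = 20, p = 3, seed = 9)
  mom1 <- conditionalMoments(dat)
  M2 <- mediators(dat); M2[, 2] <- 3 * M2[, 2]
  mom2 <- conditionalMoments(MediationDataset(outcomes(dat), M2,
                                              exposures(dat),
                                              confounders(dat)))
  Sc <- mom1@S$MXZ
  Sc[2, ] <- 3 * Sc[2, ]; Sc[, 2] <- 3 * Sc[, 2]
  expect_equal(mom2@S$MXZ, Sc, tolerance = 1e-10)
})

test_that("permuting mediator columns permutes the blocks consistently", {
  dat <- toyData(n = 20, p = 4, seed = 13)
  mom1 <- conditionalMoments(dat)
  perm <- c(3, 1, 4, 2)
  mom2 <- conditionalMoments(MediationDataset(outcomes(dat),
                                              mediators(dat)[, perm],
                                              exposures(dat),
                                              confounders(dat)))
  expect_equal(mom2@S$MXZ, mom1@S$MXZ[perm, perm], tolerance = 1e-12)
  expect_equal(mom2@S$YM.XZ, mom1@S$YM.XZ[, perm, drop = FALSE],
               tolerance = 1e-12)
  expect_equal(mom2@S$MYXZ, mom1@S$MYXZ[perm, perm], tolerance = 1e-12)
})

test_that("degenerate designs raise informative errors", {
  dat <- toyData(n = 10, p = 2)
  Zdup <- cbind(confounders(dat), confounders(dat))
  colnames(Zdup) <- c("z1", "z2")
  expect_error(conditionalMoments(
    MediationDataset(outcomes(dat), mediators(dat), exposures(dat), Zdup)),
    "singular design")
  small <- MediationDataset(outcomes(dat)[1:3, , drop = FALSE],
                            mediators(dat)[1:3, ],
                            exposures(dat)[1:3, , drop = FALSE],
                            confounders(dat)[1:3, , drop = FALSE])
  expect_error(conditionalMoments(small), "sample size")
})
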