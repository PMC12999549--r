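test_that("projectOls matches the normal-equation oracle in the S metric", {
  set.seed(17)
  S <- crossprod(matrix(rnorm(16), 4))
  Gamma <- qr.Q(qr(matrix(rnorm(8), 4, 2)))
  beta <- matrix(rnorm(8), 4, 2)
  proj <- projectOls(beta, Gamma, S)
  # oracle: solve min ||beta - Gamma a||_S column by column
  oracle <- apply(beta, 2, function(b)
    Gamma %*% solve(t(Gamma) %*% S %*% Gamma, t(Gamma) %*% S %*% b))
  expect_equal(proj, oracle, tolerance = 1e-10, ignore_attr = TRUE)
  # idempotent in the S inner product / fixed point on span(Gamma)
  expect_equal(projectOls(proj, Gamma, S), proj, tolerance = 1e-10)
  inSpan <- Gamma %*% matrix(rnorm(4), 2, 2)
  expect_equal(projectOls(inSpan, Gamma, S), inSpan, tolerance = 1e-10)
  # Euclidean case reduces to Gamma Gamma'
  expect_equal(projectOls(beta, Gamma, diag(4)),
               Gamma %*% crossprod(Gamma, beta), tolerance = 1e-12)
})

test_that("betaM is the S-projection of the OLS coefficient matrix", {
  md <- mainData(n = 250)
  mom <- conditionalMoments(md$data)
  bas <- fitEnvelope(mom, 1, seed = 4)
  fit <- estimateParameters(mom, bas)
  betaOls <- solve(mom@S$MXZ, t(mom@S$YM.XZ))
  expect_equal(fit@betaM, projectOls(betaOls, bas, mom@S$MXZ),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("the two printed expressions for each coefficient agree", {
  dat <- toyData(n = 30, p = 4, r = 2, seed = 77)
  mom <- conditionalMoments(dat)
  fit <- estimateParameters(mom, fitEnvelope(mom, 2, seed = 1))
  # recompute gammaX / betaX from unconditional covariance blocks:
  # gammaX = S_X|Z^{-1} (S_XM - S_XZ S_Z^{-1} S_ZM)
  cc <- function(A, B) crossprod(scale(A, scale = FALSE),
                                 scale(B, scale = FALSE)) / nrow(A)
  X <- exposures(dat); Z <- confounders(dat)
  M <- mediators(dat); Y <- outcomes(dat)
  SXZ <- cc(X, Z); SZ <- cc(Z, Z); SX <- cc(X, X)
  gX2 <- solve(cc(X, X) - SXZ %*% solve(SZ, t(SXZ)),
               cc(X, M) - SXZ %*% solve(SZ, cc(Z, M)))
  expect_equal(fit@gammaX, gX2, tolerance = 1e-9, ignore_attr = TRUE)
  gZ2 <- solve(SZ - t(SXZ) %*% solve(SX, SXZ),
               cc(Z, M) - t(SXZ) %*% solve(SX, cc(X, M)))
  expect_equal(fit@gammaZ, gZ2, tolerance = 1e-9, ignore_attr = TRUE)
  bX2 <- solve(SX - SXZ %*% solve(SZ, t(SXZ)),
               (cc(X, Y) - SXZ %*% solve(SZ, cc(Z, Y))) -
               (cc(X, M) - SXZ %*% solve(SZ, cc(Z, M))) %*% fit@betaM)
  expect_equal(fit@betaX, bX2, tolerance = 1e-9, ignore_attr = TRUE)
  bZ2 <- solve(SZ - t(SXZ) %*% solve(SX, SXZ),
               (cc(Z, Y) - t(SXZ) %*% solve(SX, cc(X, Y))) -
               (cc(Z, M) - t(SXZ) %*% solve(SX, cc(X, M))) %*% fit@betaM)
  expect_equal(fit@betaZ, bZ2, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("the structured mediator covariance splits cleanly across the basis", {
  md <- mainData(n = 150)
  mom <- conditionalMoments(md$data)
  fit <- estimateParameters(mom, fitEnvelope(mom, 1, seed = 2))
  G <- fit@basis@Gamma; G0 <- fit@basis@Gamma0
  # P Sigma Q = 0 in the envelope coordinates
  expect_lt(max(abs(crossprod(G, fit@SigmaMcond %*% G0))), 1e-9)
  expect_equal(crossprod(G, fit@SigmaMcond %*% G), fit@Omega,
               tolerance = 1e-9)
  expect_equal(crossprod(G0, fit@SigmaMcond %*% G0), fit@Omega0,
               tolerance = 1e-9)
})

test_that("d = 0 gives the no-mediation model", {
  dat <- toyData(n = 40, p = 3, seed = 8)
  mom <- conditionalMoments(dat)
  fit <- estimateParameters(mom, EnvelopeBasis(matrix(numeric(0), 3, 0),
                                               p = 3))
  expect_true(all(fit@betaM == 0))
  # betaX equals OLS of Y on (X, Z) ignoring M
  X <- exposures(dat); Z <- confounders(dat); Y <- outcomes(dat)
  cf <- coef(lm(Y ~ X + Z))
  expect_equal(as.numeric(fit@betaX), unname(cf[2]), tolerance = 1e-9)
  expect_equal(as.numeric(fit@betaZ), unname(cf[3]), tolerance = 1e-9)
})

test_that("estimator consistency: errors shrink from n = 250 to n = 1000", {
  des <- makeDesign("main", seedDesign = 9)
  err <- function(n, reps) {
    s <- runReplications(des, "eplsm", reps = reps, n = n, seed = 17)
    c(s@rmseDirect[1], s@rmseIndirect[1])
  }
  e250 <- err(250, 10)
  e1000 <- err(1000, 10)
  expect_true(all(e1000 < e250))
})

test_that("collinear exposures raise a collinearity error", {
  dat <- toyData(n = 20, p = 2)
  X2 <- cbind(exposures(dat), exposures(dat))
  colnames(X2) <- c("x1", "x2")
  d2 <- MediationDataset(outcomes(dat), mediators(dat), X2,
                         confounders(dat))
  expect_error(conditionalMoments(d2), "singular|collinear")
})
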