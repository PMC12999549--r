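test_that("objective at the full basis equals the log-det identity", {
  dat <- toyData(n = 25, p = 3)
  mom <- conditionalMoments(dat)
  val <- envelopeObjective(EnvelopeBasis(diag(3)), mom)
  S <- mom@S
  expected <- determinant(S$YXZ)$modulus - determinant(S$MXZ)$modulus +
    determinant(S$MYXZ)$modulus
  expect_equal(val, as.numeric(expected), tolerance = 1e-10)
})

test_that("objective is invariant under right rotation of the basis", {
  dat <- toyData(n = 30, p = 4)
  mom <- conditionalMoments(dat)
  set.seed(5)
  Gamma <- qr.Q(qr(matrix(rnorm(8), 4, 2)))
  O <- qr.Q(qr(matrix(rnorm(4), 2, 2)))
  expect_equal(envelopeObjective(Gamma, mom),
               envelopeObjective(Gamma %*% O, mom), tolerance = 1e-10)
})

test_that("optimizer matches the 1-D grid oracle for p in {2, 3}, d = 1", {
  for (p in 2:3) {
    set.seed(40 + p)
    n <- 20
    M <- matrix(rnorm(n * p), n)
    Y <- matrix(M[, 1] - 0.7 * M[, p] + 0.5 * rnorm(n))
    X <- matrix(rbinom(n, 1, 0.5))
    mom <- conditionalMoments(MediationDataset(Y, M, X))
    if (p == 2) {
      th <- seq(0, pi, by = 1e-4)
      cand <- rbind(cos(th), sin(th))
    } else {
      th <- seq(0, pi, length.out = 250)
      ph <- seq(0, pi, length.out = 250)
      g <- expand.grid(th = th, ph = ph)
      cand <- rbind(sin(g$th) * cos(g$ph), sin(g$th) * sin(g$ph), cos(g$th))
    }
    vals <- apply(cand, 2, function(v)
      envelopeObjective(matrix(v, ncol = 1), mom))
    best <- cand[, which.min(vals), drop = FALSE]
    bas <- fitEnvelope(mom, 1, seed = 2)
    expect_equal(envelopeObjective(bas, mom), min(vals),
                 tolerance = if (p == 2) 1e-6 else 1e-3)
    expect_lt(principalAngle(bas@Gamma, best), if (p == 2) 1e-3 else 0.05)
  }
})

test_that("d = p envelope reproduces OLS downstream exactly", {
  dat <- toyData(n = 40, p = 3, r = 2)
  mom <- conditionalMoments(dat)
  bas <- fitEnvelope(mom, 3)
  fit <- estimateParameters(mom, bas)
  betaOls <- solve(mom@S$MXZ, t(mom@S$YM.XZ))
  expect_equal(fit@betaM, betaOls, tolerance = 1e-8, ignore_attr = TRUE)
  ols <- olsBaseline(dat)
  expect_equal(fit@betaX, ols@betaX, tolerance = 1e-8)
  expect_equal(fit@betaM, ols@betaM, tolerance = 1e-8)
})

test_that("minimized objective is non-increasing in d", {
  dat <- toyData(n = 60, p = 4, r = 2, seed = 31)
  mom <- conditionalMoments(dat)
  vals <- vapply(1:4, function(d)
    envelopeObjective(fitEnvelope(mom, d, seed = 3), mom), numeric(1))
  expect_true(all(diff(vals) <= 1e-6))
})

test_that("estimated envelope converges to the truth at large n", {
  des <- makeDesign("main", seedDesign = 4)
  dat <- simulateDataset(des, n = 50000, seedData = 8)
  bas <- fitEnvelope(conditionalMoments(dat), 1, seed = 1)
  expect_lt(principalAngle(bas@Gamma, des@Gamma), 0.05)
})

test_that("basis canonicalization makes refits reproducible", {
  dat <- toyData(n = 50, p = 4)
  mom <- conditionalMoments(dat)
  b1 <- fitEnvelope(mom, 2, seed = 7)
  b2 <- fitEnvelope(mom, 2, seed = 7)
  expect_identical(b1@Gamma, b2@Gamma)
})

test_that("cross-validated dimension selection lands on the truth", {
  # true d = 1 in the benchmark design; check a few datasets rather than a
  # full frequency study (kept small for runtime)
  hits <- 0L
  for (s in 1:5) {
    dat <- simulateDataset(makeDesign("main", seedDesign = 6), n = 500,
                           seedData = s)
    dsel <- selectDimension(dat, dMax = 3, seed = s)
    expect_gte(dsel, 0); expect_lte(dsel, 3)
    hits <- hits + (dsel == 1L)
  }
  expect_gte(hits, 4L)
})

test_that("dimension selection flags a flat profile on pure noise", {
  set.seed(99)
  n <- 120
  M <- matrix(rnorm(n * 3), n)
  Y <- matrix(rnorm(n))
  X <- matrix(rbinom(n, 1, 0.5))
  dat <- MediationDataset(Y, M, X)
  res <- suppressWarnings(selectDimension(dat, dMax = 3, seed = 1))
  cv <- attr(res, "cvError")
  flat <- isTRUE(attr(res, "flatProfile"))
  expect_true(res == 0L || flat ||
                (max(cv) - min(cv)) / min(cv) < 0.05)
  expect_error(selectDimension(dat, folds = 1), "folds")
})
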