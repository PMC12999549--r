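test_that("SPICE approaches the sample covariance as the penalty vanishes", {
  set.seed(33)
  R <- matrix(rnorm(2000), 1000, 2) %*% chol(matrix(c(1, 0.4, 0.4, 1), 2))
  S <- crossprod(scale(R, scale = FALSE)) / nrow(R)
  est <- spiceCovariance(scale(R, scale = FALSE), penalty = 1e-6)
  expect_lt(norm(est@Sigma - S, "F"), 1e-3)
})

test_that("SPICE output is positive definite on rank-deficient input", {
  set.seed(7)
  for (i in 1:5) {
    n <- sample(5:15, 1); p <- n + sample(5:20, 1)   # p > n always
    R <- matrix(rnorm(n * p), n, p)
    est <- spiceCovariance(R, penalty = "auto")
    expect_gt(min(eigen(est@Sigma, symmetric = TRUE,
                        only.values = TRUE)$values), 0)
    expect_gt(min(eigen(est@Theta, symmetric = TRUE,
                        only.values = TRUE)$values), 0)
    expect_lt(max(abs(est@Sigma %*% est@Theta - diag(p))), 1e-4)
  }
})

test_that("SPICE matches a generic convex-solver oracle on a 3x3 toy", {
  set.seed(12)
  R <- matrix(rnorm(90), 30, 3)
  S <- crossprod(scale(R, scale = FALSE)) / 30
  rho <- 0.1
  dS <- sqrt(diag(S))
  W <- rho * (dS %o% dS); diag(W) <- 0
  obj <- function(par) {
    Th <- matrix(0, 3, 3)
    Th[upper.tri(Th, diag = TRUE)] <- par
    Th <- Th + t(Th) - diag(diag(Th))
    ev <- eigen(Th, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 1e-8) return(1e10)
    sum(S * Th) - as.numeric(determinant(Th)$modulus) + sum(W * abs(Th))
  }
  est <- spiceCovariance(scale(R, scale = FALSE), penalty = rho)
  init <- diag(1 / diag(S))
  o <- optim(init[upper.tri(init, diag = TRUE)], obj,
             method = "Nelder-Mead",
             control = list(maxit = 20000, reltol = 1e-12))
  o <- optim(o$par, obj, method = "Nelder-Mead",
             control = list(maxit = 20000, reltol = 1e-12))
  ours <- est@Theta[upper.tri(est@Theta, diag = TRUE)]
  expect_equal(obj(ours), o$value, tolerance = 1e-4)
  expect_equal(ours, o$par, tolerance = 1e-2, ignore_attr = TRUE)
})

test_that("inverse sparsity is monotone in the penalty", {
  set.seed(21)
  R <- matrix(rnorm(200), 40, 5)
  nearZeros <- sapply(c(0.01, 0.1, 0.5, 2), function(rho) {
    Th <- spiceCovariance(R, penalty = rho)@Theta
    sum(abs(Th[upper.tri(Th)]) < 1e-6)
  })
  expect_true(all(diff(nearZeros) >= 0))
})

test_that("high-dimensional fit runs at p > n and matches the low-dim path when forced", {
  # p > n feasibility on the published p > n shape (scaled down for runtime)
  des <- makeDesign("highdim", p = 60, seedDesign = 3)
  dat <- simulateDataset(des, n = 40, seedData = 2)
  fit <- fitHighdim(dat, d = 1, SparseConfig(lambda = 0.05), seed = 1)
  expect_s4_class(fit, "EsplsmFit")
  expect_lte(length(fit@pattern@selected), 60L)
  expect_gte(length(fit@pattern@selected), 1L)

  # p < n: surrogate path at small penalty stays close to the sample path
  md <- mainData(n = 800)
  fitLow <- fitEsplsm(md$data, d = 1, lambda = 0.01, seed = 2)
  momH <- conditionalMoments(md$data, requireInvertibleY = FALSE)
  surH <- envmed:::.spiceSurrogates(momH, penalty = 1e-4)
  pilotH <- fitEnvelope(momH, 1, seed = 2, surrogates = surH)
  sfH <- fitSparseEnvelope(momH, 1, SparseConfig(lambda = 0.01), seed = 2,
                           pilot = pilotH, surrogates = surH)
  fitHigh <- estimateParameters(momH, sfH$basis, sfH$pattern,
                                surrogates = surH)
  relDiff <- norm(fitHigh@betaM - fitLow@betaM, "F") /
    max(norm(fitLow@betaM, "F"), 1e-12)
  expect_lt(relDiff, 0.05)
})

test_that("sparse selection at p > n beats the unpenalized baseline", {
  # scaled-down version of the p > n selection experiment: compare TPR-1
  # balance of the penalized fit against a dense projection baseline
  des <- makeDesign("highdim", p = 60, seedDesign = 11)
  reps <- 4L
  tprS <- precS <- precB <- c()
  for (i in seq_len(reps)) {
    dat <- simulateDataset(des, n = 40, seedData = 30 + i)
    fit <- fitHighdim(dat, d = 1, seed = i, gridLength = 8)
    sm <- selectionMetrics(fit@pattern, SelectionTruth(1:4, 60))
    tprS <- c(tprS, sm["tpr"]); precS <- c(precS, sm["precision"])
    precB <- c(precB, 4 / 60)  # dense baseline selects everything
  }
  expect_gt(mean(precS), mean(precB))
})
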