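test_that("adaptive weights follow the inverse-norm rule", {
  G <- matrix(c(1, 0, 0, 0.5), 2, 2) # row norms 1 and 0.5
  cfg <- adaptiveWeights(EnvelopeBasis(qr.Q(qr(G))), exponent = 2)
  # equal row norms give equal weights
  Geq <- qr.Q(qr(matrix(c(1, 1, 1, -1), 2, 2)))
  cfgEq <- adaptiveWeights(EnvelopeBasis(Geq), exponent = 2)
  expect_equal(cfgEq@weights[1], cfgEq@weights[2], tolerance = 1e-10)
  # direct evaluation on raw norms
  cfg2 <- adaptiveWeights(structure(matrix(c(1, 0, 0, 0.5), 2, 2),
                                    class = "matrix"), exponent = 2)
  expect_equal(unname(cfg2@weights), c(1, 4), tolerance = 1e-6)
  # vanishing pilot row norm gives the finite cap
  cfg3 <- adaptiveWeights(matrix(c(1, 0), 2, 1), exponent = 2)
  expect_equal(cfg3@weights[2], 1e16, tolerance = 1e-3)
  expect_true(is.finite(cfg3@weights[2]))
})

test_that("lambda = 0 reproduces the unpenalized envelope objective", {
  md <- mainData(n = 200)
  mom <- conditionalMoments(md$data)
  pilot <- fitEnvelope(mom, 1, seed = 2, tol = 1e-12, maxit = 3000)
  sf <- fitSparseEnvelope(mom, 1, SparseConfig(lambda = 0), pilot = pilot,
                          tol = 1e-12, maxit = 3000)
  expect_equal(envelopeObjective(sf$basis, mom),
               envelopeObjective(pilot, mom), tolerance = 1e-6)
  expect_equal(length(sf$pattern@selected), 11L)
})

test_that("huge lambda shrinks every penalized row to zero", {
  md <- mainData(n = 300)
  mom <- conditionalMoments(md$data)
  pilot <- fitEnvelope(mom, 1, seed = 2)
  sf <- fitSparseEnvelope(mom, 1, SparseConfig(lambda = 1e8), pilot = pilot)
  # minimal support: only the d anchor rows survive
  expect_equal(length(sf$pattern@selected), 1L)
  expect_equal(sort(sf$pattern@selected), sort(sf$anchors))
})

test_that("zero basis rows give exactly zero betaM rows", {
  md <- mainData(n = 400)
  mom <- conditionalMoments(md$data)
  cfg <- selectLambda(mom, 1, seed = 3, gridLength = 12)
  sf <- fitSparseEnvelope(mom, 1, cfg, seed = 3)
  fit <- estimateParameters(mom, sf$basis, sf$pattern)
  excl <- excludedMediators(fit@pattern)
  expect_gt(length(excl), 0L)
  expect_true(all(fit@betaM[excl, ] == 0))
  expect_true(all(fit@basis@Gamma[excl, ] == 0))
  # and betaM = Gamma eta exactly
  expect_equal(fit@betaM, fit@basis@Gamma %*% fit@eta, tolerance = 1e-12)
})

test_that("penalized solution satisfies the feasibility bound", {
  md <- mainData(n = 200)
  mom <- conditionalMoments(md$data)
  pilot <- fitEnvelope(mom, 1, seed = 2)
  cfg <- adaptiveWeights(pilot)
  lam <- 0.01
  sf <- fitSparseEnvelope(mom, 1, initialize(cfg, lambda = lam),
                          pilot = pilot)
  sf0 <- fitSparseEnvelope(mom, 1, initialize(cfg, lambda = 0),
                           pilot = pilot)
  pen0 <- lam * sum(cfg@weights * sqrt(rowSums(sf0$basis@Gamma^2)))
  expect_lte(sf$objective, sf0$objective + pen0 + 1e-6)
})

test_that("joint scaling of the grid and weights leaves selection invariant", {
  md <- mainData(n = 300)
  mom <- conditionalMoments(md$data)
  pilot <- fitEnvelope(mom, 1, seed = 2)
  cfg <- adaptiveWeights(pilot)
  c_ <- 7.3
  lam <- 0.02
  sf1 <- fitSparseEnvelope(mom, 1, initialize(cfg, lambda = lam),
                           pilot = pilot)
  sf2 <- fitSparseEnvelope(mom, 1,
                           initialize(cfg, lambda = lam / c_,
                                      weights = cfg@weights * c_),
                           pilot = pilot)
  expect_identical(sf1$pattern@selected, sf2$pattern@selected)
  # single-element grid is returned as-is
  cfgG <- initialize(cfg, lambdaGrid = lam)
  sel <- selectLambda(mom, 1, cfgG, seed = 2, pilot = pilot)
  expect_equal(sel@lambda, lam)
})

test_that("tuned selection recovers the active set at n = 1000", {
  # selection-consistency regime: most replications recover a subset of the
  # truth containing its strong rows, and exclude all noise rows
  reps <- 12L
  exact <- 0L; noNoise <- 0L
  des <- makeDesign("main", seedDesign = 5)
  for (i in seq_len(reps)) {
    dat <- simulateDataset(des, n = 1000, seedData = 500 + i)
    fit <- fitEsplsm(dat, d = 1, lambda = "auto", seed = i, gridLength = 15)
    sel <- selectedMediators(fit@pattern)
    noNoise <- noNoise + all(sel %in% 1:4)
    exact <- exact + setequal(sel, 1:4)
  }
  expect_gte(noNoise, reps - 2L)   # false positives are rare
  expect_gte(exact, reps %/% 2)    # exact recovery in a majority
})

test_that("selection improves with sample size on average", {
  des <- makeDesign("main", seedDesign = 8)
  tr <- SelectionTruth(1:4, 11)
  score <- function(n, reps) {
    s <- runReplications(des, "esplsm", reps = reps, n = n, seed = 42,
                         gridLength = 12)
    c(s@tpr, s@tnr)
  }
  small <- score(100, 8)
  large <- score(1000, 8)
  expect_gte(mean(large, na.rm = TRUE), mean(small, na.rm = TRUE) - 0.05)
})
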