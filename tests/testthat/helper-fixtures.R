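# Shared fixtures, all generated in code at test time.

# small dataset with k = 1 exposure, q = 1 confounder, p mediators
toyData <- function(n = 6, p = 3, r = 1, seed = 11) {
  set.seed(seed)
  X <- matrix(rbinom(n, 1, 0.5), n, 1)
  Z <- matrix(rnorm(n), n, 1)
  M <- X %*% matrix(1, 1, p) + Z %*% matrix(0.5, 1, p) +
    matrix(rnorm(n * p), n, p)
  Y <- M %*% matrix(seq_len(p) / p, p, r) + X %*% matrix(1, 1, r) +
    matrix(rnorm(n * r), n, r)
  colnames(M) <- paste0("m", seq_len(p))
  MediationDataset(Y, M, X, Z)
}

# moderately sized draw from the benchmark generator
mainData <- function(n = 300, seedDesign = 2, seedData = 5) {
  des <- makeDesign("main", seedDesign = seedDesign)
  list(design = des, data = simulateDataset(des, n = n, seedData = seedData))
}

# brute-force conditional covariance of A given B (residual outer products,
# column-by-column least squares; independent of the package's QR path)
oracleCondCov <- function(A, B) {
  A <- scale(A, scale = FALSE)
  n <- nrow(A)
  if (!is.null(B) && ncol(B) > 0) {
    B <- scale(B, scale = FALSE)
    RA <- apply(A, 2, function(a) a - B %*% solve(crossprod(B), crossprod(B, a)))
  } else RA <- A
  crossprod(as.matrix(RA)) / n
}

oracleCrossCov <- function(A, C, B) {
  A <- scale(A, scale = FALSE); C <- scale(C, scale = FALSE)
  n <- nrow(A)
  resid <- function(V) {
    if (!is.null(B) && ncol(B) > 0) {
      Bc <- scale(B, scale = FALSE)
      apply(V, 2, function(v) v - Bc %*% solve(crossprod(Bc), crossprod(Bc, v)))
    } else V
  }
  crossprod(as.matrix(resid(A)), as.matrix(resid(C))) / n
}
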