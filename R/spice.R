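## Sparse permutation-invariant covariance estimation (SPICE) and the
## high-dimensional (p > n) fitting path.
##
## SPICE solves the penalized negative Gaussian log-determinant program
##   min_Theta  tr(S Theta) - log|Theta| + rho * sum_{i != j} |Theta_ij|
## over positive definite Theta. The solution is PD for every rho > 0 even
## when S is rank deficient, giving usable surrogates for S_{M|X,Z}^{-1}
## and S_{M|Y,X,Z}^{-1} in the p > n regime. Solved by ADMM: the
## Theta-update is a closed-form eigenvalue shrinkage, the splitting
## variable takes an elementwise soft threshold.

#' SPICE covariance and inverse-covariance estimate from residuals
#'
#' @param residuals n x p matrix of (centered) residuals, or a p x p sample
#'   covariance when \code{isCovariance = TRUE}.
#' @param penalty nonnegative off-diagonal l1 penalty, or \code{"auto"} for
#'   the rate-based default \code{0.5 * sqrt(log(p) / n)}.
#' @param isCovariance interpret \code{residuals} as a covariance matrix.
#' @param n sample size (needed with \code{isCovariance = TRUE} and
#'   \code{penalty = "auto"}).
#' @param maxit,tol ADMM controls.
#' @return A \linkS4class{SpiceEstimate}.
#' @examples
#' R <- matrix(rnorm(40 * 60), 40)  # n = 40 < p = 60
#' est <- spiceCovariance(R, penalty = "auto")
#' min(eigen(est@Sigma, only.values = TRUE)$values) > 0
#' @export
spiceCovariance <- function(residuals, penalty = "auto",
                            isCovariance = FALSE, n = NULL,
                            maxit = 1000L, tol = 1e-7) {
  if (isCovariance) {
    S <- .sym(as.matrix(residuals))
    p <- nrow(S)
  } else {
    R <- as.matrix(residuals)
    n <- nrow(R); p <- ncol(R)
    if (n < 2L) stop("need at least 2 observations", call. = FALSE)
    S <- crossprod(R) / n
  }
  if (identical(penalty, "auto")) {
    if (is.null(n)) stop("n required for the automatic penalty", call. = FALSE)
    penalty <- 0.5 * sqrt(log(max(p, 2)) / n)
  }
  penalty <- as.numeric(penalty)
  stopifnot(penalty >= 0)

  ## scale-aware: penalize correlations, i.e. weight by sqrt(S_ii S_jj)
  dS <- sqrt(pmax(diag(S), 1e-12))
  W <- penalty * (dS %o% dS)
  diag(W) <- 0

  rho <- 1                      # ADMM step
  Theta <- diag(1 / pmax(diag(S), 1e-8))
  Z <- Theta
  U <- matrix(0, p, p)
  converged <- FALSE
  for (it in seq_len(maxit)) {
    ## Theta-update: min tr(S Th) - log|Th| + rho/2 ||Th - Z + U||^2
    E <- eigen(.sym(rho * (Z - U) - S), symmetric = TRUE)
    ev <- (E$values + sqrt(E$values^2 + 4 * rho)) / (2 * rho)
    Theta <- E$vectors %*% (ev * t(E$vectors))
    ## Z-update: elementwise soft threshold (diagonal unpenalized)
    Zold <- Z
    V <- Theta + U
    Z <- sign(V) * pmax(abs(V) - W / rho, 0)
    diag(Z) <- diag(V)
    U <- U + Theta - Z
    pri <- sqrt(sum((Theta - Z)^2))
    dua <- rho * sqrt(sum((Z - Zold)^2))
    sc <- max(sqrt(sum(Theta^2)), sqrt(sum(Z^2)), 1e-12)
    if (pri / sc < tol && dua / sc < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("SPICE solver did not converge; last iterate returned")
  Theta <- .sym(Theta)
  ## guard exact PD of the reported inverse surrogate
  ev <- eigen(Theta, symmetric = TRUE)
  ev$values <- pmax(ev$values, 1e-10)
  Theta <- ev$vectors %*% (ev$values * t(ev$vectors))
  Sigma <- ev$vectors %*% ((1 / ev$values) * t(ev$vectors))
  new("SpiceEstimate", Sigma = .sym(Sigma), Theta = .sym(Theta),
      penalty = penalty, converged = converged)
}

## build the SPICE surrogates used inside the objective/estimators:
## Minv ~ Sigma_{M|X,Z}^{-1}; MYXZ ~ Sigma_{M|Y,X,Z} (from Y-adjusted
## residuals so positive definiteness is guaranteed, rather than differencing)
.spiceSurrogates <- function(moments, penalty = "auto") {
  RM <- moments@residMXZ
  RY <- moments@residYXZ
  sp1 <- spiceCovariance(RM, penalty = penalty)
  RMY <- .residualize(RM, RY)
  sp2 <- spiceCovariance(RMY, penalty = penalty)
  list(Minv = sp1@Theta, Sigma = sp1@Sigma, MYXZ = sp2@Sigma,
       spice = list(sp1, sp2))
}

#' Fit the sparse envelope mediation model in the p > n regime
#'
#' Runs the sparse-envelope pipeline with SPICE surrogates substituted for
#' the singular sample quantities: the inverse of S_{M|X,Z} in the objective
#' becomes the SPICE inverse of the mediator residual covariance, and
#' S_{M|Y,X,Z} becomes the SPICE covariance of the Y-adjusted residuals.
#' All downstream closed-form estimates use the surrogates wherever an
#' inverse of a singular block would be needed.
#'
#' @param data a \linkS4class{MediationDataset} (typically p > n; smaller
#'   problems may force this path for comparison).
#' @param d envelope dimension.
#' @param config a \linkS4class{SparseConfig}; \code{lambda = NA} triggers
#'   BIC tuning.
#' @param seed integer seed.
#' @param penalty SPICE penalty (\code{"auto"} = rate default).
#' @param gridLength lambda grid size when tuning.
#' @return An \linkS4class{EsplsmFit}.
#' @export
fitHighdim <- function(data, d, config = SparseConfig(), seed = 1L,
                       penalty = "auto", gridLength = 25L) {
  moments <- conditionalMoments(data, requireInvertibleY = FALSE)
  sur <- .spiceSurrogates(moments, penalty)
  pilot <- fitEnvelope(moments, d, seed = seed, surrogates = sur)
  if (is.na(config@lambda))
    config <- selectLambda(moments, d, config, criterion = "bic",
                           seed = seed, surrogates = sur,
                           gridLength = gridLength, pilot = pilot)
  sf <- fitSparseEnvelope(moments, d, config, seed = seed, surrogates = sur,
                          pilot = pilot)
  estimateParameters(moments, sf$basis, sf$pattern, config = sf$config,
                     surrogates = sur)
}
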