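## Closed-form parameter estimates given a (possibly sparse) envelope basis.
##
## With span(Gamma) fixed, every remaining parameter of the model
##   Y = muY + betaM'(M - muM) + betaX'(X - muX) + betaZ'(Z - muZ) + eps
##   M = muM + gammaX'(X - muX) + gammaZ'(Z - muZ) + e,
##   Sigma_{M|X,Z} = Gamma Omega Gamma' + Gamma0 Omega0 Gamma0'
## maximizes the Gaussian likelihood in closed form. betaM is the projection
## of the OLS coefficient matrix onto span(Gamma) in the S_{M|X,Z} inner
## product: betaM = Gamma eta = P_Gamma(S) betaM_ols.

#' Project a coefficient matrix onto the envelope in the S inner product
#'
#' Returns \code{Gamma (Gamma' S Gamma)^{-1} Gamma' S \%*\% betaOls}, the
#' projection of \code{betaOls} onto span(Gamma) with respect to the inner
#' product induced by the positive definite matrix \code{S}. Idempotent in
#' that metric.
#'
#' @param betaOls p x r coefficient matrix.
#' @param basis an \linkS4class{EnvelopeBasis} or a p x d orthonormal matrix.
#' @param S p x p positive definite weight matrix.
#' @return p x r projected coefficient matrix.
#' @export
projectOls <- function(betaOls, basis, S) {
  Gamma <- if (is(basis, "EnvelopeBasis")) basis@Gamma else as.matrix(basis)
  if (ncol(Gamma) == 0L) return(matrix(0, nrow(S), ncol(betaOls)))
  Gamma %*% .psolve(crossprod(Gamma, S %*% Gamma),
                    crossprod(Gamma, S %*% betaOls))
}

#' Compute all closed-form parameter estimates for a fixed envelope basis
#'
#' @param moments a \linkS4class{ConditionalMoments}.
#' @param basis an \linkS4class{EnvelopeBasis}.
#' @param pattern optional \linkS4class{SparsityPattern}; defaults to the
#'   rows of \code{Gamma} that are not exactly zero.
#' @param config optional \linkS4class{SparseConfig} recording tuning state.
#' @param surrogates optional SPICE surrogates for the high-dimensional path.
#' @return An \linkS4class{EsplsmFit}.
#' @examples
#' des <- makeDesign("main", seedDesign = 1)
#' dat <- simulateDataset(des, n = 200, seedData = 1)
#' mom <- conditionalMoments(dat)
#' fit <- estimateParameters(mom, fitEnvelope(mom, d = 1))
#' directEffect(fit)
#' @export
estimateParameters <- function(moments, basis, pattern = NULL, config = NULL,
                               surrogates = NULL) {
  stopifnot(is(moments, "ConditionalMoments"), is(basis, "EnvelopeBasis"))
  S <- moments@S
  n <- moments@n
  p <- ncol(moments@residMXZ); r <- ncol(moments@residYXZ)
  k <- length(moments@means$muX); q <- length(moments@means$muZ)
  d <- basis@d
  Gamma <- basis@Gamma; Gamma0 <- basis@Gamma0

  chkInv <- function(A, nm) {
    if (length(A) &&
        min(eigen(.sym(A), symmetric = TRUE, only.values = TRUE)$values) <
          1e-12 * max(1, max(abs(A))))
      stop(sprintf("%s is singular: exposures/confounders are collinear", nm),
           call. = FALSE)
  }
  chkInv(S$X.Z, "S_{X|Z}"); chkInv(S$Z.X, "S_{Z|X}")

  gammaX <- if (k) .psolve(S$X.Z, S$XM.Z) else matrix(0, 0L, p)
  gammaZ <- if (q) .psolve(S$Z.X, S$ZM.X) else matrix(0, 0L, p)

  ## in the p > n regime the sample S_{M|X,Z} is singular; the SPICE
  ## covariance surrogate stands in wherever its PD-ness is needed
  Smxz <- if (!is.null(surrogates) && !is.null(surrogates$Sigma))
    surrogates$Sigma else S$MXZ
  SMY <- t(S$YM.XZ)                        # S_{(M,Y)|X,Z}, p x r
  if (d > 0L) {
    GSG <- crossprod(Gamma, Smxz %*% Gamma)
    eta <- .psolve(GSG, crossprod(Gamma, SMY))
    betaM <- Gamma %*% eta
    Omega <- .sym(GSG)
  } else {
    eta <- matrix(0, 0L, r)
    betaM <- matrix(0, p, r)
    Omega <- matrix(numeric(0), 0L, 0L)
  }
  ## exact zeros on excluded rows (floating-point dust from Gamma zeros)
  if (is.null(pattern)) {
    nz <- if (d > 0L) which(rowSums(abs(Gamma)) > 0) else integer(0)
    pattern <- SparsityPattern(nz, p)
  }
  betaM[pattern@excluded, ] <- 0

  betaX <- if (k) .psolve(S$X.Z, S$XY.Z - S$XM.Z %*% betaM) else matrix(0, 0L, r)
  betaZ <- if (q) .psolve(S$Z.X, S$ZY.X - S$ZM.X %*% betaM) else matrix(0, 0L, r)

  Omega0 <- if (p - d > 0L) .sym(crossprod(Gamma0, Smxz %*% Gamma0))
            else matrix(numeric(0), 0L, 0L)

  ## Sigma_{Y|M,X,Z} = (1/n) RY' Q_{RM Gamma} RY
  RY <- moments@residYXZ
  if (d > 0L) {
    F <- moments@residMXZ %*% Gamma          # n x d
    RYadj <- .residualize(RY, F)
    SigmaYcond <- .sym(crossprod(RYadj) / n)
  } else SigmaYcond <- .sym(S$YXZ)

  ## envelope-structured mediator covariance P S P + Q S Q
  if (d > 0L && p - d > 0L) {
    SigmaMcond <- .sym(Gamma %*% Omega %*% t(Gamma) +
                       Gamma0 %*% Omega0 %*% t(Gamma0))
  } else SigmaMcond <- .sym(Smxz)

  obj <- .envObj(Gamma, .objectiveParts(moments, surrogates))

  ## maximized Gaussian log-likelihood (trace terms collapse at the MLE)
  ldM <- if (d > 0L && p - d > 0L) .logdet(Omega) + .logdet(Omega0)
         else .logdet(SigmaMcond)
  ll <- -n * (p + r) / 2 * (1 + log(2 * pi)) -
        n / 2 * (.logdet(SigmaYcond) + ldM)

  if (is.null(config)) config <- SparseConfig(lambda = 0)
  new("EsplsmFit",
      means = moments@means, gammaX = gammaX, gammaZ = gammaZ, eta = eta,
      betaM = betaM, betaX = betaX, betaZ = betaZ, Omega = Omega,
      Omega0 = Omega0, SigmaYcond = SigmaYcond, SigmaMcond = SigmaMcond,
      basis = basis, pattern = pattern, config = config,
      objective = obj, logLik = ll, n = n, moments = moments)
}

#' Predict outcomes from new mediator/exposure/confounder values
#'
#' @param fit an \linkS4class{EsplsmFit}.
#' @param M,X,Z new data blocks (rows are subjects; \code{Z = NULL} when the
#'   model has no confounders).
#' @return matrix of predicted outcomes, rows matching the input.
#' @export
predictOutcome <- function(fit, M, X, Z = NULL) {
  M <- as.matrix(M); X <- as.matrix(X)
  n <- nrow(M)
  mu <- fit@means
  pred <- matrix(rep(mu$muY, each = n), n)
  pred <- pred + sweep(M, 2L, mu$muM) %*% fit@betaM
  if (length(mu$muX)) pred <- pred + sweep(X, 2L, mu$muX) %*% fit@betaX
  if (length(mu$muZ)) {
    Z <- as.matrix(Z)
    pred <- pred + sweep(Z, 2L, mu$muZ) %*% fit@betaZ
  }
  pred
}
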