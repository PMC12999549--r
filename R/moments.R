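## Centered residuals and conditional covariance blocks.
##
## All covariances use the 1/n normalization (maximum-likelihood convention),
## not 1/(n-1): the envelope objective and the closed-form estimators are
## derived from the Gaussian likelihood, where 1/n is the natural scaling.

## residuals of centered A after projecting off the column space of centered B
## (numerically: QR of the centered design, never normal equations)
.residualize <- function(Ac, Bc) {
  if (ncol(Bc) == 0L) return(Ac)
  qrB <- qr(Bc)
  if (qrB$rank < ncol(Bc)) {
    bad <- colnames(Bc)[setdiff(seq_len(ncol(Bc)), qrB$pivot[seq_len(qrB$rank)])]
    stop("singular design: centered covariate columns are collinear",
         if (length(bad)) paste0(" (", paste(bad, collapse = ", "), ")"),
         call. = FALSE)
  }
  qr.resid(qrB, Ac)
}

.center <- function(A) {
  if (ncol(A) == 0L) return(list(c = A, mu = numeric(0)))
  mu <- colMeans(A)
  list(c = sweep(A, 2L, mu), mu = mu)
}

#' Center the data and residualize mediators and outcomes off (X, Z)
#'
#' Computes per-block sample means, centers every block, and projects the
#' centered mediator and outcome blocks off the column space of the centered
#' combined design W = (X, Z) (X first). With q = 0 the design is X alone;
#' with k = q = 0 the residuals are simply the centered matrices. Then fills
#' every conditional covariance block, including the Schur-complement
#' identity S_{M|Y,X,Z} = S_{M|X,Z} - S_{(Y,M)|X,Z}' S_{Y|X,Z}^{-1}
#' S_{(Y,M)|X,Z} (computed exactly by that identity when S_{Y|X,Z} is
#' invertible).
#'
#' @param data a \linkS4class{MediationDataset}.
#' @param requireInvertibleY if \code{TRUE} (default), error when S_{Y|X,Z}
#'   is singular; the high-dimensional path passes \code{FALSE} and builds
#'   S_{M|Y,X,Z} from Y-adjusted residuals instead.
#' @return A \linkS4class{ConditionalMoments}.
#' @examples
#' d <- simulateDataset(makeDesign("main", seedDesign = 1), n = 50, seedData = 2)
#' mom <- conditionalMoments(d)
#' mom
#' @export
conditionalMoments <- function(data, requireInvertibleY = TRUE) {
  stopifnot(is(data, "MediationDataset"))
  validObject(data)
  n <- nSamples(data)
  k <- ncol(data@X); q <- ncol(data@Z)
  if (n <= k + q + 1L && ncol(data@M) <= n)
    stop(sprintf("sample size n = %d too small for k + q + 1 = %d covariates",
                 n, k + q + 1L), call. = FALSE)

  cy <- .center(data@Y); cm <- .center(data@M)
  cx <- .center(data@X); cz <- .center(data@Z)
  Wc <- cbind(cx$c, cz$c)   # X first, then Z
  nm <- function(block, pre) {
    cn <- colnames(block)
    if (is.null(cn) && ncol(block)) cn <- paste0(pre, seq_len(ncol(block)))
    cn
  }
  colnames(Wc) <- c(nm(data@X, "X"), nm(data@Z, "Z"))

  RM <- .residualize(cm$c, Wc)
  RY <- .residualize(cy$c, Wc)

  S <- list(
    MXZ  = crossprod(RM) / n,
    YXZ  = crossprod(RY) / n,
    YM.XZ = crossprod(RY, RM) / n)

  ## partial blocks given Z alone / X alone
  RX.Z <- .residualize(cx$c, cz$c)
  RZ.X <- .residualize(cz$c, cx$c)
  S$X.Z  <- crossprod(RX.Z) / n
  S$Z.X  <- crossprod(RZ.X) / n
  S$XM.Z <- crossprod(RX.Z, cm$c) / n
  S$ZM.X <- crossprod(RZ.X, cm$c) / n
  S$XY.Z <- crossprod(RX.Z, cy$c) / n
  S$ZY.X <- crossprod(RZ.X, cy$c) / n

  ## Schur complement: mediator covariance given (Y, X, Z)
  okY <- ncol(RY) > 0 &&
    min(eigen(.sym(S$YXZ), symmetric = TRUE, only.values = TRUE)$values) >
      1e-12 * max(1, max(abs(S$YXZ)))
  if (okY) {
    S$MYXZ <- .sym(S$MXZ - t(S$YM.XZ) %*% .psolve(S$YXZ, S$YM.XZ))
  } else if (requireInvertibleY) {
    stop("S_{Y|X,Z} is singular; use the high-dimensional path (fitHighdim)",
         call. = FALSE)
  } else {
    ## Y-adjusted residuals keep the block well-defined without inverting
    RMY <- .residualize(RM, RY)
    S$MYXZ <- crossprod(RMY) / n
  }

  new("ConditionalMoments",
      means = list(muY = cy$mu, muM = cm$mu, muX = cx$mu, muZ = cz$mu),
      residMXZ = RM, residYXZ = RY, S = S, n = as.integer(n))
}
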