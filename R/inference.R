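## Asymptotic covariances of the direct- and indirect-effect estimators,
## Wald tests, and nonparametric (case-resampling) bootstrap inference.
##
## Under joint normality of the errors, sqrt(n) vec(betaX_hat - betaX) and
## sqrt(n) vec((gammaX betaM)_hat - gammaX betaM) are asymptotically normal
## with covariances built from Kronecker products of the fitted blocks. The
## shared middle term involves the inverse (Moore-Penrose where singular) of
##   K = eta Sigma_{Y|M,X,Z}^{-1} eta' (x) Omega0 + Omega (x) Omega0^{-1}
##     + Omega^{-1} (x) Omega0 - 2 I_d (x) I_{p-d}.

#' Asymptotic covariance matrices of the effect estimators
#'
#' Plugs the fitted parameters into the closed-form expressions for the
#' covariance of \code{sqrt(n) vec(betaX_hat)} (\code{Vdirect}) and
#' \code{sqrt(n) vec((gammaX betaM)_hat)} (\code{Vindirect}), both kr x kr
#' and symmetrized. Moore-Penrose inverses are used wherever an inner matrix
#' is singular. \code{d = 0} is the no-mediator case: the direct covariance
#' reduces to \code{Sigma_{Y|X,Z} (x) S_{X|Z}^{-1}} and the indirect
#' covariance is zero.
#'
#' @param fit an \linkS4class{EsplsmFit} from the low-dimensional path.
#' @return list with elements \code{Vdirect}, \code{Vindirect} (kr x kr)
#'   and \code{SigmaXZ} (the k x k conditional exposure covariance used
#'   inside both).
#' @export
asymptoticCov <- function(fit) {
  stopifnot(is(fit, "EsplsmFit"))
  S <- fit@moments@S
  k <- nrow(fit@betaX); r <- ncol(fit@betaX)
  d <- fit@basis@d
  p <- nrow(fit@betaM)
  if (k == 0L) stop("no exposures: effect covariances are undefined",
                    call. = FALSE)
  SXZ <- .sym(S$X.Z)
  SXZinv <- .psolve(SXZ)
  Gamma <- fit@basis@Gamma; Gamma0 <- fit@basis@Gamma0
  Sig <- fit@SigmaYcond

  if (d > 0L) {
    Oinv <- .psolve(fit@Omega)
    gGO <- fit@gammaX %*% Gamma %*% Oinv %*% crossprod(Gamma, t(fit@gammaX))
  } else gGO <- matrix(0, k, k)

  ## shared middle term from the Gamma0 (immaterial) block
  middle <- matrix(0, k * r, k * r)
  if (d > 0L && p - d > 0L) {
    eta <- fit@eta
    O <- fit@Omega; O0 <- fit@Omega0
    K <- kronecker(eta %*% .psolve(Sig, t(eta)), O0) +
         kronecker(O, .pinv(O0)$inv) +
         kronecker(.psolve(O), O0) -
         2 * diag(d * (p - d))
    L <- kronecker(t(eta), fit@gammaX %*% Gamma0)   # (r k) x (d (p-d))
    middle <- L %*% .pinv(.sym(K))$inv %*% t(L)
  }

  Vdirect <- .sym(kronecker(Sig, gGO + SXZinv) + middle)
  Vindirect <- .sym(kronecker(Sig, gGO) + middle +
                    (if (d > 0L)
                       kronecker(crossprod(fit@eta, fit@Omega %*% fit@eta),
                                 SXZinv)
                     else matrix(0, k * r, k * r)))
  list(Vdirect = Vdirect, Vindirect = Vindirect, SigmaXZ = SXZ)
}

#' Joint Wald test of a matrix-valued effect
#'
#' Statistic \code{n * vec(effect)' V^+ vec(effect)} referred to the
#' chi-square distribution with \code{df = rank(V)} (numerical rank of the
#' possibly singular covariance, Moore-Penrose inverse). The null is the
#' zero effect.
#'
#' @param effect k x r estimated effect.
#' @param V kr x kr asymptotic covariance of \code{sqrt(n) vec(effect)}.
#' @param n sample size.
#' @param effectName label carried in the result.
#' @return A \linkS4class{TestResult}.
#' @examples
#' waldTest(matrix(0.2), matrix(1), n = 100)  # statistic 4, p ~= 0.0455
#' @export
waldTest <- function(effect, V, n, effectName = "effect") {
  effect <- as.matrix(effect)
  v <- as.vector(effect)
  pv <- .pinv(.sym(as.matrix(V)))
  stat <- as.numeric(n * t(v) %*% pv$inv %*% v)
  df <- pv$rank
  pval <- if (df == 0L) 1 else stats::pchisq(stat, df, lower.tail = FALSE)
  new("TestResult", effectName = effectName, estimate = effect,
      statistic = stat, df = as.integer(df), pValue = pval,
      ciLower = matrix(NA_real_, nrow(effect), ncol(effect)),
      ciUpper = matrix(NA_real_, nrow(effect), ncol(effect)),
      method = "wald", B = 0L, seed = NULL)
}

#' Wald tests for the direct and indirect effects of a fit
#'
#' @param fit an \linkS4class{EsplsmFit}.
#' @return named list of \linkS4class{TestResult}s (\code{direct},
#'   \code{indirect}), each with per-entry z-test p-values attached as the
#'   \code{"entryPValues"} attribute.
#' @export
waldInference <- function(fit) {
  ac <- asymptoticCov(fit)
  n <- fit@n
  res <- list(
    direct = waldTest(fit@betaX, ac$Vdirect, n, "direct"),
    indirect = waldTest(indirectEffect(fit), ac$Vindirect, n, "indirect"))
  for (nm in names(res)) {
    est <- res[[nm]]@estimate
    V <- if (nm == "direct") ac$Vdirect else ac$Vindirect
    se <- matrix(sqrt(pmax(diag(V), 0) / n), nrow(est), ncol(est))
    z <- est / pmax(se, 1e-300)
    attr(res[[nm]], "entryPValues") <-
      2 * stats::pnorm(abs(z), lower.tail = FALSE)
  }
  res
}

#' Nonparametric bootstrap inference for the direct and indirect effects
#'
#' Case-resampling bootstrap: subject rows are resampled with replacement,
#' the model is refit per resample (the penalty is re-selected by default so
#' selection uncertainty propagates), and percentile confidence intervals
#' are formed per effect entry. The two-sided p-value for each entry is
#' \code{2 * min(fraction of bootstrap effects <= 0, >= 0)} with a
#' \code{1/(B+1)} floor; the reported joint p-value is the smallest entry
#' p-value Bonferroni-adjusted (equal to the entry p-value when k = r = 1).
#' Identical seeds give identical output.
#'
#' @param data a \linkS4class{MediationDataset}.
#' @param d envelope dimension (fixed across resamples).
#' @param B number of bootstrap replicates (>= 100).
#' @param seed integer seed.
#' @param lambda \code{"auto"} (re-tune per resample) or a fixed value.
#' @param level confidence level for the percentile intervals.
#' @param gridLength lambda grid size when re-tuning.
#' @return named list of \linkS4class{TestResult}s (\code{direct},
#'   \code{indirect}); per-entry p-values in the \code{"entryPValues"}
#'   attribute.
#' @export
bootstrapInference <- function(data, d, B = 500L, seed = 1L,
                               lambda = "auto", level = 0.95,
                               gridLength = 15L) {
  stopifnot(is(data, "MediationDataset"), B >= 100L)
  n <- nSamples(data); q <- ncol(data@Z)
  fit0 <- fitEsplsm(data, d = d, lambda = lambda, seed = seed,
                    gridLength = gridLength)
  est0 <- list(direct = fit0@betaX, indirect = indirectEffect(fit0))
  kk <- nrow(est0$direct); rr <- ncol(est0$direct)

  idxAll <- .withSeed(.streamSeed(seed, 101L),
                      matrix(sample.int(n, n * B, replace = TRUE), n, B))
  boots <- list(direct = array(NA_real_, c(kk, rr, B)),
                indirect = array(NA_real_, c(kk, rr, B)))
  failures <- 0L
  for (b in seq_len(B)) {
    ii <- idxAll[, b]
    db <- MediationDataset(data@Y[ii, , drop = FALSE],
                           data@M[ii, , drop = FALSE],
                           data@X[ii, , drop = FALSE],
                           if (q) data@Z[ii, , drop = FALSE] else NULL)
    fb <- tryCatch(fitEsplsm(db, d = d, lambda = lambda, seed = seed,
                             gridLength = gridLength),
                   error = function(e) NULL)
    if (is.null(fb)) { failures <- failures + 1L; next }
    boots$direct[, , b] <- fb@betaX
    boots$indirect[, , b] <- indirectEffect(fb)
  }
  if (failures > 0.1 * B)
    warning(sprintf("%d of %d bootstrap refits failed", failures, B))

  alpha <- 1 - level
  out <- list()
  for (nm in c("direct", "indirect")) {
    arr <- boots[[nm]]
    lo <- hi <- pv <- matrix(NA_real_, kk, rr)
    for (i in seq_len(kk)) for (j in seq_len(rr)) {
      v <- arr[i, j, ]; v <- v[is.finite(v)]
      lo[i, j] <- stats::quantile(v, alpha / 2, names = FALSE)
      hi[i, j] <- stats::quantile(v, 1 - alpha / 2, names = FALSE)
      pv[i, j] <- max(2 * min(mean(v <= 0), mean(v >= 0)), 1 / (B + 1))
    }
    pJoint <- min(1, min(pv) * kk * rr)
    pJoint <- max(pJoint, 1 / (B + 1))
    res <- new("TestResult", effectName = nm, estimate = est0[[nm]],
               statistic = NA_real_, df = as.integer(kk * rr),
               pValue = pJoint, ciLower = lo, ciUpper = hi,
               method = "bootstrap", B = as.integer(B),
               seed = as.numeric(seed))
    attr(res, "entryPValues") <- pv
    attr(res, "failures") <- failures
    attr(res, "bootSE") <- apply(arr, c(1, 2), stats::sd, na.rm = TRUE)
    out[[nm]] <- res
  }
  out
}
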