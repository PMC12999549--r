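#' Fit the sparse envelope mediation model (ESPLSM)
#'
#' One-call pipeline: conditional moments, envelope dimension (fixed or
#' cross-validated), adaptive-group-lasso sparse envelope with a tuned or
#' fixed penalty, and all closed-form parameter estimates. When p >= n (or
#' \code{highdim = TRUE}) the singular sample covariances are replaced by
#' SPICE surrogates.
#'
#' @param data a \linkS4class{MediationDataset} (or pass \code{Y}, \code{M},
#'   \code{X}, \code{Z} to have one built).
#' @param d envelope dimension: an integer in 0..p, or \code{"cv"} for
#'   cross-validated selection.
#' @param lambda group-lasso penalty: a nonnegative number, \code{0} for the
#'   unpenalized (dense) envelope fit, or \code{"auto"} for BIC tuning.
#' @param criterion tuning criterion for \code{lambda = "auto"}:
#'   \code{"bic"} (default, outcome-model BIC -- targets effect
#'   estimation), \code{"bic-full"} (joint-likelihood BIC -- targets
#'   recovery of the full sparsity structure), or \code{"cv"} (held-out
#'   outcome prediction error).
#' @param seed integer seed controlling optimizer starts and folds.
#' @param weightExponent adaptive-weight exponent (default 2).
#' @param nStarts random multi-starts for the pilot envelope fit.
#' @param gridLength lambda grid size for tuning.
#' @param highdim force the SPICE-surrogate path even when p < n.
#' @param Y,M,X,Z raw blocks, used only when \code{data} is missing.
#' @return An \linkS4class{EsplsmFit}.
#' @examples
#' des <- makeDesign("main", seedDesign = 1)
#' dat <- simulateDataset(des, n = 300, seedData = 7)
#' fit <- fitEsplsm(dat, d = 1, lambda = "auto", seed = 7)
#' fit
#' @export
fitEsplsm <- function(data, d = "cv", lambda = "auto",
                      criterion = c("bic", "bic-full", "cv"), seed = 1L,
                      weightExponent = 2, nStarts = 5L, gridLength = 25L,
                      highdim = FALSE, Y = NULL, M = NULL, X = NULL,
                      Z = NULL) {
  criterion <- match.arg(criterion)
  if (missing(data)) data <- MediationDataset(Y, M, X, Z)
  stopifnot(is(data, "MediationDataset"))
  n <- nSamples(data); p <- nMediators(data)
  useHighdim <- isTRUE(highdim) || p >= n

  if (identical(d, "cv")) {
    if (useHighdim)
      stop("cross-validated d selection is not supported on the high-dimensional path; supply d",
           call. = FALSE)
    d <- selectDimension(data, seed = seed)
  }
  d <- as.integer(d)

  if (useHighdim) {
    cfg <- SparseConfig(lambda = if (identical(lambda, "auto")) NA_real_
                                 else as.numeric(lambda),
                        weightExponent = weightExponent)
    return(fitHighdim(data, d, cfg, seed = seed, gridLength = gridLength))
  }

  moments <- conditionalMoments(data)
  if (d == 0L) {
    return(estimateParameters(moments, EnvelopeBasis(matrix(numeric(0), p, 0L),
                                                     p = p)))
  }
  if (identical(lambda, 0) || identical(lambda, 0L)) {
    basis <- fitEnvelope(moments, d, nStarts = nStarts, seed = seed)
    return(estimateParameters(moments, basis,
                              SparsityPattern(seq_len(p), p),
                              config = SparseConfig(lambda = 0)))
  }
  cfg <- SparseConfig(weightExponent = weightExponent)
  pilot <- fitEnvelope(moments, d, nStarts = nStarts, seed = seed)
  if (identical(lambda, "auto")) {
    cfg <- selectLambda(moments, d, cfg, criterion = criterion, seed = seed,
                        data = data, gridLength = gridLength, pilot = pilot)
  } else cfg <- initialize(cfg, lambda = as.numeric(lambda))
  sf <- fitSparseEnvelope(moments, d, cfg, seed = seed, pilot = pilot)
  estimateParameters(moments, sf$basis, sf$pattern, config = sf$config)
}
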