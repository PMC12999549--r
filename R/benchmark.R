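## Evaluation metrics: Frobenius RMSE over replications, selection metrics
## against a known active set, empirical power, and the unstructured
## least-squares baseline packaged in the common fit container.

#' True active-mediator set for selection scoring
#'
#' @slot trueSelected integer indices of truly active mediators.
#' @slot p total number of mediators.
#' @export
setClass("SelectionTruth",
  representation(trueSelected = "integer", p = "integer"))

setValidity("SelectionTruth", function(object) {
  if (length(object@trueSelected) &&
      (min(object@trueSelected) < 1L || max(object@trueSelected) > object@p))
    "trueSelected must be a subset of 1..p" else TRUE
})

#' @rdname SelectionTruth-class
#' @param trueSelected integer indices of active mediators.
#' @param p total number of mediators.
#' @export
SelectionTruth <- function(trueSelected, p) {
  new("SelectionTruth", trueSelected = sort(as.integer(trueSelected)),
      p = as.integer(p))
}

#' Square-root mean squared Frobenius error over replications
#'
#' Returns \code{sqrt(mean_b ||est_b - truth||_F^2)} with a delta-method
#' Monte-Carlo standard error (\code{sd} of the squared errors over
#' \code{sqrt(reps)}, divided by twice the RMSE).
#'
#' @param estimates list of matrices (one per replication).
#' @param truth matrix of the same shape.
#' @return named numeric: \code{rmse}, \code{se}.
#' @export
frobeniusRmse <- function(estimates, truth) {
  if (!length(estimates)) stop("empty estimate list", call. = FALSE)
  truth <- as.matrix(truth)
  sq <- vapply(estimates, function(e) sum((as.matrix(e) - truth)^2),
               numeric(1))
  v <- sqrt(mean(sq))
  se <- if (length(sq) > 1L)
    stats::sd(sq) / sqrt(length(sq)) / (2 * max(v, 1e-12)) else NA_real_
  c(rmse = v, se = se)
}

#' Selection metrics: TPR, TNR, precision
#'
#' \code{tpr = |A ∩ T| / |T|}, \code{tnr = |I ∩ T^c| / |T^c|},
#' \code{precision = |A ∩ T| / |A|}, where A is the selected set, I the
#' excluded set and T the true active set. When both A and T are empty the
#' metrics whose denominators vanish are defined as 1; any other zero
#' denominator raises an error rather than returning a silent NaN.
#'
#' @param pattern a \linkS4class{SparsityPattern}.
#' @param truth a \linkS4class{SelectionTruth} with matching p.
#' @return named numeric \code{(tpr, tnr, precision)}.
#' @export
selectionMetrics <- function(pattern, truth) {
  stopifnot(is(pattern, "SparsityPattern"), is(truth, "SelectionTruth"))
  if (pattern@p != truth@p)
    stop("pattern and truth disagree on p", call. = FALSE)
  A <- pattern@selected; T_ <- truth@trueSelected
  Tc <- setdiff(seq_len(truth@p), T_)
  tpr <- if (length(T_)) length(intersect(A, T_)) / length(T_)
         else if (!length(A)) 1
         else stop("TPR undefined: empty true set, nonempty selection",
                   call. = FALSE)
  tnr <- if (length(Tc)) length(intersect(pattern@excluded, Tc)) / length(Tc)
         else 1
  precision <- if (length(A)) length(intersect(A, T_)) / length(A)
               else if (!length(T_)) 1
               else stop("precision undefined: empty selection, nonempty true set",
                         call. = FALSE)
  c(tpr = tpr, tnr = tnr, precision = precision)
}

#' Empirical rejection rate at a level
#'
#' @param testResults list of \linkS4class{TestResult}s (or a numeric
#'   vector of p-values).
#' @param alpha level in (0, 1); default 0.05.
#' @return named numeric: \code{power} (fraction with p < alpha) and
#'   binomial \code{se}.
#' @export
empiricalPower <- function(testResults, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  pvals <- if (is.numeric(testResults)) testResults
           else vapply(testResults, function(t) t@pValue, numeric(1))
  if (!length(pvals)) stop("no test results", call. = FALSE)
  pw <- mean(pvals < alpha)
  c(power = pw, se = sqrt(pw * (1 - pw) / length(pvals)))
}

#' Unstructured multivariate least-squares baseline
#'
#' Fits both regressions of the mediation model by ordinary least squares
#' (no envelope structure, no selection: equivalent to the envelope model
#' at d = p) and packages the result as an \linkS4class{EsplsmFit} so every
#' metric applies unchanged.
#'
#' @param data a \linkS4class{MediationDataset} with n > p + k + q + 1.
#' @return An \linkS4class{EsplsmFit} with \code{d = p}.
#' @export
olsBaseline <- function(data) {
  stopifnot(is(data, "MediationDataset"))
  n <- nSamples(data); p <- nMediators(data)
  k <- ncol(data@X); q <- ncol(data@Z)
  if (n <= p + k + q + 1L)
    stop("OLS baseline needs n > p + k + q + 1", call. = FALSE)
  moments <- conditionalMoments(data)
  estimateParameters(moments, EnvelopeBasis(diag(p)),
                     SparsityPattern(seq_len(p), p))
}
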