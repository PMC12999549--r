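#' @import methods
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

## ---------------------------------------------------------------------------
## MediationDataset: the observed (Y, M, X, Z) blocks with aligned rows
## ---------------------------------------------------------------------------

#' Observed data for a mediation analysis
#'
#' Container for the outcome block \code{Y} (n x r), mediator block \code{M}
#' (n x p), exposure block \code{X} (n x k, binary coding allowed) and an
#' optional confounder block \code{Z} (n x q, q may be 0). All blocks share
#' the sample index; rows are subjects.
#'
#' @slot Y numeric matrix of outcomes, n x r.
#' @slot M numeric matrix of mediators, n x p.
#' @slot X numeric matrix of exposures, n x k.
#' @slot Z numeric matrix of confounders, n x q (zero columns when absent).
#' @export
setClass("MediationDataset",
  representation(Y = "matrix", M = "matrix", X = "matrix", Z = "matrix"))

setValidity("MediationDataset", function(object) {
  msgs <- character(0)
  n <- nrow(object@Y)
  for (b in c("M", "X", "Z")) {
    if (nrow(slot(object, b)) != n)
      msgs <- c(msgs, sprintf("block %s has %d rows, Y has %d",
                              b, nrow(slot(object, b)), n))
  }
  if (n < 2L) msgs <- c(msgs, "need at least 2 observations")
  for (b in c("Y", "M", "X", "Z")) {
    v <- slot(object, b)
    if (length(v) && !all(is.finite(v)))
      msgs <- c(msgs, sprintf("block %s contains non-finite entries", b))
    cn <- colnames(v)
    if (!is.null(cn) && anyDuplicated(cn))
      msgs <- c(msgs, sprintf("block %s has duplicated column names", b))
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a MediationDataset
#'
#' @param Y,M,X numeric matrices (or vectors, treated as single columns) with
#'   one row per subject.
#' @param Z optional confounder matrix; \code{NULL} means no confounders
#'   (an n x 0 block, never columns of zeros).
#' @return A \linkS4class{MediationDataset}.
#' @examples
#' d <- MediationDataset(Y = rnorm(10), M = matrix(rnorm(30), 10),
#'                       X = rbinom(10, 1, 0.5))
#' nSamples(d)
#' @export
MediationDataset <- function(Y, M, X = NULL, Z = NULL) {
  Y <- as.matrix(Y)
  storage.mode(Y) <- "double"
  n <- nrow(Y)
  asBlock <- function(v) {
    if (is.null(v)) return(.emptyMat(n))
    v <- as.matrix(v)
    storage.mode(v) <- "double"
    v
  }
  new("MediationDataset", Y = Y, M = asBlock(M), X = asBlock(X),
      Z = asBlock(Z))
}

#' @describeIn MediationDataset number of subjects
#' @param object,x a \code{MediationDataset}
#' @export
nSamples <- function(object) nrow(object@Y)

#' @describeIn MediationDataset number of mediators
#' @export
nMediators <- function(object) ncol(object@M)

#' @rdname MediationDataset
#' @export
outcomes <- function(object) object@Y

#' @rdname MediationDataset
#' @export
mediators <- function(object) object@M

#' @rdname MediationDataset
#' @export
exposures <- function(object) object@X

#' @rdname MediationDataset
#' @export
confounders <- function(object) object@Z

#' @rdname MediationDataset
#' @export
setMethod("show", "MediationDataset", function(object) {
  cat(sprintf(
    "MediationDataset: n = %d, r = %d outcome(s), p = %d mediator(s), k = %d exposure(s), q = %d confounder(s)\n",
    nSamples(object), ncol(object@Y), ncol(object@M), ncol(object@X),
    ncol(object@Z)))
})

## ---------------------------------------------------------------------------
## ConditionalMoments
## ---------------------------------------------------------------------------

#' Centered residuals and conditional covariance blocks
#'
#' Holds the sample means of each block, the residuals of the centered
#' mediators and outcomes after projection off the centered (X, Z) design,
#' and every conditional covariance block (1/n normalization) consumed by the
#' envelope objective and the closed-form estimators.
#'
#' @slot means named list of per-block sample means (muY, muM, muX, muZ).
#' @slot residMXZ n x p residuals of centered M off centered (X, Z).
#' @slot residYXZ n x r residuals of centered Y off centered (X, Z).
#' @slot S named list of covariance blocks: \code{MXZ} (S_{M|X,Z}),
#'   \code{YXZ} (S_{Y|X,Z}), \code{YM.XZ} (S_{(Y,M)|X,Z}, r x p),
#'   \code{MYXZ} (S_{M|Y,X,Z}), \code{X.Z} (S_{X|Z}), \code{Z.X} (S_{Z|X}),
#'   \code{XM.Z}, \code{ZM.X}, \code{XY.Z}, \code{ZY.X}.
#' @slot n integer sample size.
#' @export
setClass("ConditionalMoments",
  representation(means = "list", residMXZ = "matrix", residYXZ = "matrix",
                 S = "list", n = "integer"))

setValidity("ConditionalMoments", function(object) {
  msgs <- character(0)
  for (nm in c("MXZ", "YXZ")) {
    A <- object@S[[nm]]
    if (!is.null(A) && length(A) &&
        max(abs(A - t(A))) > 1e-8 * (1 + max(abs(A))))
      msgs <- c(msgs, sprintf("S$%s is not symmetric", nm))
  }
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "ConditionalMoments", function(object) {
  cat(sprintf("ConditionalMoments: n = %d, p = %d, r = %d\n",
              object@n, ncol(object@residMXZ), ncol(object@residYXZ)))
})

## ---------------------------------------------------------------------------
## EnvelopeBasis
## ---------------------------------------------------------------------------

#' Orthonormal basis of the mediator envelope and its complement
#'
#' @slot Gamma p x d orthonormal basis of the envelope (material subspace).
#' @slot Gamma0 p x (p - d) orthonormal basis of the orthogonal complement.
#' @slot d integer envelope dimension, 0 <= d <= p.
#' @slot converged logical, optimizer convergence flag.
#' @export
setClass("EnvelopeBasis",
  representation(Gamma = "matrix", Gamma0 = "matrix", d = "integer",
                 converged = "logical"),
  prototype(converged = TRUE))

setValidity("EnvelopeBasis", function(object) {
  msgs <- character(0)
  d <- object@d
  G <- object@Gamma; G0 <- object@Gamma0
  p <- nrow(G)
  if (ncol(G) != d) msgs <- c(msgs, "ncol(Gamma) != d")
  tol <- 1e-8
  if (d > 0 && max(abs(crossprod(G) - diag(d))) > tol)
    msgs <- c(msgs, "Gamma columns are not orthonormal")
  if (ncol(G0) > 0 && max(abs(crossprod(G0) - diag(ncol(G0)))) > tol)
    msgs <- c(msgs, "Gamma0 columns are not orthonormal")
  if (d > 0 && ncol(G0) > 0 && max(abs(crossprod(G, G0))) > tol)
    msgs <- c(msgs, "Gamma and Gamma0 are not orthogonal")
  if (length(msgs)) msgs else TRUE
})

#' Construct an EnvelopeBasis, filling in the orthogonal complement
#'
#' @param Gamma p x d matrix with orthonormal columns (a p-vector is taken as
#'   one column). \code{d = 0} is represented by a p x 0 matrix.
#' @param p number of mediators (needed when \code{Gamma} is empty).
#' @param converged optimizer convergence flag.
#' @return An \linkS4class{EnvelopeBasis}.
#' @export
EnvelopeBasis <- function(Gamma, p = nrow(as.matrix(Gamma)), converged = TRUE) {
  Gamma <- as.matrix(Gamma)
  if (length(Gamma) == 0L) Gamma <- matrix(numeric(0), p, 0L)
  new("EnvelopeBasis", Gamma = Gamma, Gamma0 = .orthcomp(Gamma, p),
      d = ncol(Gamma), converged = converged)
}

setMethod("show", "EnvelopeBasis", function(object) {
  cat(sprintf("EnvelopeBasis: p = %d, d = %d%s\n", nrow(object@Gamma),
              object@d,
              if (isTRUE(object@converged)) "" else " (not converged)"))
})

## ---------------------------------------------------------------------------
## SparsityPattern
## ---------------------------------------------------------------------------

#' Selected / excluded mediator index sets
#'
#' A mediator is sparsity-selected when its row of the envelope basis is
#' nonzero (it lies in the material subspace with an active outcome-side
#' effect) and sparsity-excluded otherwise.
#'
#' @slot selected integer indices of sparsity-selected mediators.
#' @slot excluded integer indices of sparsity-excluded mediators.
#' @slot p total number of mediators.
#' @export
setClass("SparsityPattern",
  representation(selected = "integer", excluded = "integer", p = "integer"))

setValidity("SparsityPattern", function(object) {
  msgs <- character(0)
  all_ <- sort(c(object@selected, object@excluded))
  if (!identical(all_, seq_len(object@p)))
    msgs <- c(msgs, "selected and excluded must partition 1..p")
  if (length(msgs)) msgs else TRUE
})

#' @rdname SparsityPattern-class
#' @param selected integer vector of selected mediator indices.
#' @param p total number of mediators.
#' @export
SparsityPattern <- function(selected, p) {
  selected <- sort(as.integer(selected))
  new("SparsityPattern", selected = selected,
      excluded = setdiff(seq_len(as.integer(p)), selected), p = as.integer(p))
}

#' @rdname SparsityPattern-class
#' @param object a \code{SparsityPattern}
#' @export
selectedMediators <- function(object) object@selected

#' @rdname SparsityPattern-class
#' @export
excludedMediators <- function(object) object@excluded

setMethod("show", "SparsityPattern", function(object) {
  cat(sprintf("SparsityPattern: %d of %d mediators selected\n",
              length(object@selected), object@p))
})

## ---------------------------------------------------------------------------
## SparseConfig
## ---------------------------------------------------------------------------

#' Tuning state for the adaptive group lasso on the envelope basis rows
#'
#' @slot lambda nonnegative penalty level (NA until tuned).
#' @slot weights positive adaptive weights, one per penalized row (empty
#'   until computed from a pilot fit).
#' @slot weightExponent positive exponent for the adaptive weights.
#' @slot lambdaGrid decreasing positive candidate grid for tuning.
#' @export
setClass("SparseConfig",
  representation(lambda = "numeric", weights = "numeric",
                 weightExponent = "numeric", lambdaGrid = "numeric"),
  prototype(lambda = NA_real_, weights = numeric(0), weightExponent = 2,
            lambdaGrid = numeric(0)))

setValidity("SparseConfig", function(object) {
  msgs <- character(0)
  if (!is.na(object@lambda) && object@lambda < 0)
    msgs <- c(msgs, "lambda must be nonnegative")
  if (length(object@weights) && any(object@weights <= 0))
    msgs <- c(msgs, "weights must be positive")
  if (object@weightExponent <= 0)
    msgs <- c(msgs, "weightExponent must be positive")
  if (length(object@lambdaGrid) > 1 && any(diff(object@lambdaGrid) > 0))
    msgs <- c(msgs, "lambdaGrid must be decreasing")
  if (length(msgs)) msgs else TRUE
})

#' @rdname SparseConfig-class
#' @param lambda penalty level, or \code{NA} to tune later.
#' @param weights adaptive weights (may be empty until a pilot fit exists).
#' @param weightExponent exponent used when deriving weights from pilot row
#'   norms; default 2.
#' @param lambdaGrid decreasing candidate grid (empty = build automatically).
#' @export
SparseConfig <- function(lambda = NA_real_, weights = numeric(0),
                         weightExponent = 2, lambdaGrid = numeric(0)) {
  new("SparseConfig", lambda = as.numeric(lambda),
      weights = as.numeric(weights),
      weightExponent = as.numeric(weightExponent),
      lambdaGrid = as.numeric(lambdaGrid))
}

setMethod("show", "SparseConfig", function(object) {
  cat(sprintf("SparseConfig: lambda = %s, %d weight(s), exponent = %g\n",
              format(object@lambda), length(object@weights),
              object@weightExponent))
})

## ---------------------------------------------------------------------------
## EsplsmFit
## ---------------------------------------------------------------------------

#' Fitted sparse envelope mediation model
#'
#' Every closed-form parameter estimate given the (possibly sparse) envelope
#' basis, plus the tuning state and the attained objective value. Slot names
#' follow the model: \code{betaM = Gamma eta} is the mediator-to-outcome
#' coefficient block (p x r), \code{betaX} the direct effect (k x r),
#' \code{gammaX} the exposure-to-mediator coefficients (k x p).
#'
#' @slot means named list (muY, muM, muX, muZ).
#' @slot gammaX k x p; \code{gammaZ} q x p.
#' @slot gammaZ q x p confounder-to-mediator coefficients.
#' @slot eta d x r envelope coordinates of betaM.
#' @slot betaM p x r; \code{betaX} k x r; \code{betaZ} q x r.
#' @slot betaX k x r direct-effect coefficients.
#' @slot betaZ q x r confounder-to-outcome coefficients.
#' @slot Omega d x d material covariance coordinates.
#' @slot Omega0 (p-d) x (p-d) immaterial covariance coordinates.
#' @slot SigmaYcond r x r residual outcome covariance Sigma_{Y|M,X,Z}.
#' @slot SigmaMcond p x p envelope-structured Sigma_{M|X,Z}.
#' @slot basis the \linkS4class{EnvelopeBasis} used.
#' @slot pattern the \linkS4class{SparsityPattern}.
#' @slot config the \linkS4class{SparseConfig} (tuning state).
#' @slot objective attained value of the envelope objective.
#' @slot logLik maximized Gaussian log-likelihood of the model.
#' @slot n sample size.
#' @slot moments the \linkS4class{ConditionalMoments} used (kept for
#'   inference).
#' @export
setClass("EsplsmFit",
  representation(means = "list", gammaX = "matrix", gammaZ = "matrix",
                 eta = "matrix", betaM = "matrix", betaX = "matrix",
                 betaZ = "matrix", Omega = "matrix", Omega0 = "matrix",
                 SigmaYcond = "matrix", SigmaMcond = "matrix",
                 basis = "EnvelopeBasis", pattern = "SparsityPattern",
                 config = "SparseConfig", objective = "numeric",
                 logLik = "numeric", n = "integer",
                 moments = "ConditionalMoments"))

setValidity("EsplsmFit", function(object) {
  msgs <- character(0)
  d <- object@basis@d
  if (d > 0) {
    diff <- max(abs(object@betaM - object@basis@Gamma %*% object@eta))
    if (diff > 1e-8 * (1 + max(abs(object@betaM))))
      msgs <- c(msgs, "betaM != Gamma %*% eta")
  }
  excl <- object@pattern@excluded
  if (length(excl) && any(object@betaM[excl, ] != 0))
    msgs <- c(msgs, "excluded mediators must have exactly zero betaM rows")
  if (length(msgs)) msgs else TRUE
})

#' @rdname EsplsmFit-class
#' @param object an \code{EsplsmFit}
#' @export
directEffect <- function(object) object@betaX

#' @rdname EsplsmFit-class
#' @export
indirectEffect <- function(object) object@gammaX %*% object@betaM

#' @rdname EsplsmFit-class
#' @export
mediatorEffect <- function(object) object@betaM

#' @rdname EsplsmFit-class
#' @export
envelopeBasis <- function(object) object@basis

#' @rdname EsplsmFit-class
#' @export
sparsityPattern <- function(object) object@pattern

setMethod("show", "EsplsmFit", function(object) {
  cat(sprintf(
    "EsplsmFit: n = %d, p = %d, d = %d, %d mediator(s) selected\n",
    object@n, nrow(object@betaM), object@basis@d,
    length(object@pattern@selected)))
  cat("  direct effect (betaX):\n")
  print(signif(object@betaX, 4))
  cat("  indirect effect (gammaX betaM):\n")
  print(signif(indirectEffect(object), 4))
})

## ---------------------------------------------------------------------------
## SpiceEstimate
## ---------------------------------------------------------------------------

#' Sparse permutation-invariant covariance estimate
#'
#' Positive-definite covariance / inverse-covariance surrogate obtained by
#' minimizing the penalized negative Gaussian log-determinant objective with
#' an l1 penalty on the off-diagonal entries of the inverse. Used when
#' sample conditional covariances are singular (p > n).
#'
#' @slot Sigma p x p PD covariance surrogate.
#' @slot Theta p x p PD inverse surrogate.
#' @slot penalty the penalty level used.
#' @slot converged solver convergence flag.
#' @export
setClass("SpiceEstimate",
  representation(Sigma = "matrix", Theta = "matrix", penalty = "numeric",
                 converged = "logical"))

setValidity("SpiceEstimate", function(object) {
  msgs <- character(0)
  if (min(eigen(.sym(object@Sigma), symmetric = TRUE,
                only.values = TRUE)$values) <= 0)
    msgs <- c(msgs, "Sigma is not positive definite")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "SpiceEstimate", function(object) {
  cat(sprintf("SpiceEstimate: p = %d, penalty = %.4g, converged = %s\n",
              nrow(object@Sigma), object@penalty, object@converged))
})

## ---------------------------------------------------------------------------
## TestResult
## ---------------------------------------------------------------------------

#' Result of a Wald or bootstrap test for a mediation effect
#'
#' @slot effectName "direct", "indirect" or "total".
#' @slot estimate k x r effect estimate.
#' @slot statistic Wald statistic (NA for bootstrap).
#' @slot df degrees of freedom (rank of the covariance).
#' @slot pValue joint p-value in [0, 1].
#' @slot ciLower,ciUpper k x r percentile CI bounds (bootstrap only).
#' @slot method "wald" or "bootstrap".
#' @slot B bootstrap replicate count (0 for Wald).
#' @slot seed seed used (NA for Wald).
#' @export
setClass("TestResult",
  representation(effectName = "character", estimate = "matrix",
                 statistic = "numeric", df = "integer", pValue = "numeric",
                 ciLower = "matrix", ciUpper = "matrix", method = "character",
                 B = "integer", seed = "numericOrNULL"))

setValidity("TestResult", function(object) {
  msgs <- character(0)
  if (!is.na(object@pValue) && (object@pValue < 0 || object@pValue > 1))
    msgs <- c(msgs, "pValue must lie in [0, 1]")
  if (!object@method %in% c("wald", "bootstrap"))
    msgs <- c(msgs, "method must be 'wald' or 'bootstrap'")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "TestResult", function(object) {
  cat(sprintf("TestResult [%s, %s]: statistic = %s, df = %d, p = %.4g\n",
              object@effectName, object@method,
              format(signif(object@statistic, 4)), object@df, object@pValue))
})

## ---------------------------------------------------------------------------
## SimulationDesign
## ---------------------------------------------------------------------------

#' A generative benchmark design with known truth
#'
#' All population parameters of one simulation scenario; drawn once per
#' design seed and reused across replications.
#'
#' @slot n,p,k,q,d,r integer dimensions.
#' @slot Gamma,Gamma0 true envelope bases.
#' @slot eta d x r; \code{Omega} d x d; \code{Omega0} (p-d) x (p-d).
#' @slot Omega,Omega0 PD coordinate covariance blocks.
#' @slot betaX k x r; \code{betaZ} q x r; \code{gammaX} k x p;
#'   \code{gammaZ} q x p.
#' @slot betaZ,gammaX,gammaZ regression coefficient blocks.
#' @slot SigmaYcond r x r outcome error covariance.
#' @slot c1,c2 effect scaling factors applied to betaX and eta.
#' @slot trueSelected indices of sparsity-selected mediators.
#' @slot scenario scenario name.
#' @slot errorFamily "normal", "t3", "chisq4" or "uniform01".
#' @slot rho exposure correlation (multi-exposure scenario).
#' @slot gammaU,betaU unobserved-confounder loadings (confounded scenario).
#' @slot seedDesign design-draw seed.
#' @export
setClass("SimulationDesign",
  representation(n = "integer", p = "integer", k = "integer", q = "integer",
                 d = "integer", r = "integer", Gamma = "matrix",
                 Gamma0 = "matrix", eta = "matrix", Omega = "matrix",
                 Omega0 = "matrix", betaX = "matrix", betaZ = "matrix",
                 gammaX = "matrix", gammaZ = "matrix", SigmaYcond = "matrix",
                 c1 = "numeric", c2 = "numeric", trueSelected = "integer",
                 scenario = "character", errorFamily = "character",
                 rho = "numeric", gammaU = "matrix", betaU = "matrix",
                 seedDesign = "integer"))

setValidity("SimulationDesign", function(object) {
  msgs <- character(0)
  d <- object@d
  if (d > 0 && max(abs(crossprod(object@Gamma) - diag(d))) > 1e-8)
    msgs <- c(msgs, "true Gamma is not orthonormal")
  inactive <- setdiff(seq_len(object@p), object@trueSelected)
  if (length(inactive) && any(object@Gamma[inactive, ] != 0))
    msgs <- c(msgs, "rows of Gamma outside trueSelected must be exactly zero")
  for (nm in c("Omega", "Omega0", "SigmaYcond")) {
    A <- slot(object, nm)
    if (length(A) &&
        min(eigen(.sym(A), symmetric = TRUE, only.values = TRUE)$values) <= 0)
      msgs <- c(msgs, sprintf("%s is not positive definite", nm))
  }
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "SimulationDesign", function(object) {
  cat(sprintf(
    "SimulationDesign ['%s']: n = %d, p = %d, k = %d, q = %d, d = %d, r = %d; %d active mediator(s); c1 = %g, c2 = %g\n",
    object@scenario, object@n, object@p, object@k, object@q, object@d,
    object@r, length(object@trueSelected), object@c1, object@c2))
})
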