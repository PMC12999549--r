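## Row-sparse envelope estimation via an adaptive group lasso.
##
## The penalized objective adds lambda * sum_i w_i ||Gamma_i||_2 over the
## penalized rows of the basis. Because the objective depends on Gamma only
## through its span, rows cannot all be penalized: the subspace is
## parameterized in a coordinate chart in which the d rows with the largest
## pilot-estimate norms are anchored to the identity block and the remaining
## p - d rows (the matrix B) carry the penalty. A row of B is zero exactly
## when the corresponding row of Gamma is zero, so group soft-thresholding
## on B induces row sparsity in Gamma. The chart objective is
##   f(B) = log|G'AG| + log|G'CG| - 2 log|G'G|,  G = [I_d; B] (rows permuted),
## with A = S_{M|X,Z}^{-1} and C = S_{M|Y,X,Z} (or SPICE surrogates), and is
## minimized by proximal gradient descent with backtracking (deterministic
## given the pilot), warm-started along the lambda path.

#' Adaptive group-lasso weights from a pilot envelope fit
#'
#' \code{w_i = (||row i of pilot Gamma||_2 + eps)^(-exponent)} with
#' \code{eps = 1e-8}: rows the unpenalized pilot estimates near zero receive
#' large (finite, capped) weights.
#'
#' @param pilot an \linkS4class{EnvelopeBasis} from an unpenalized fit at
#'   the same dimension.
#' @param exponent positive weight exponent (default 2).
#' @param config optional \linkS4class{SparseConfig} to fill.
#' @return A \linkS4class{SparseConfig} with one weight per mediator row.
#' @export
adaptiveWeights <- function(pilot, exponent = 2, config = NULL) {
  Gamma <- if (is(pilot, "EnvelopeBasis")) pilot@Gamma else as.matrix(pilot)
  norms <- sqrt(rowSums(Gamma^2))
  w <- (norms + 1e-8)^(-exponent)
  if (is.null(config)) config <- SparseConfig(weightExponent = exponent)
  initialize(config, weights = w, weightExponent = as.numeric(exponent))
}

## gradient of the chart objective with respect to G
.chartGrad <- function(G, parts) {
  u1 <- parts$Minv %*% G
  u2 <- parts$C %*% G
  if (ncol(G) == 1L)
    return(2 * (u1 / sum(G * u1) + u2 / sum(G * u2) - 2 * G / sum(G * G)))
  2 * (u1 %*% .psolve(crossprod(G, u1)) + u2 %*% .psolve(crossprod(G, u2)) -
       2 * G %*% .psolve(crossprod(G)))
}

.chartObj <- function(G, parts) {
  if (ncol(G) == 1L) {                # scalar fast path
    a1 <- sum(G * (parts$Minv %*% G))
    a2 <- sum(G * (parts$C %*% G))
    a3 <- sum(G * G)
    if (a1 <= 0 || a2 <= 0 || a3 <= 0) return(Inf)
    return(log(a1) + log(a2) - 2 * log(a3))
  }
  e1 <- determinant(.sym(crossprod(G, parts$Minv %*% G)), logarithm = TRUE)
  e2 <- determinant(.sym(crossprod(G, parts$C %*% G)), logarithm = TRUE)
  e3 <- determinant(.sym(crossprod(G)), logarithm = TRUE)
  if (e1$sign <= 0 || e2$sign <= 0 || e3$sign <= 0) return(Inf)
  as.numeric(e1$modulus) + as.numeric(e2$modulus) - 2 * as.numeric(e3$modulus)
}

## accelerated proximal gradient (FISTA with monotone restart) on the
## penalized rows B; anchors stay fixed at I_d
.sparseSolve <- function(B, anchorIdx, freeIdx, parts, lambda, w,
                         maxit = 300L, tol = 1e-7) {
  p <- length(anchorIdx) + length(freeIdx)
  d <- length(anchorIdx)
  buildG <- function(B) {
    G <- matrix(0, p, d)
    G[anchorIdx, ] <- diag(d)
    G[freeIdx, ] <- B
    G
  }
  pen <- function(B) if (nrow(B)) lambda * sum(w * sqrt(rowSums(B^2))) else 0
  prox <- function(V, t_) {
    nv <- sqrt(rowSums(V^2))
    V * pmax(0, 1 - t_ * lambda * w / pmax(nv, 1e-300))
  }
  f <- .chartObj(buildG(B), parts)
  obj <- f + pen(B)
  Bprev <- B
  theta <- 1
  t_ <- 1
  converged <- FALSE
  for (it in seq_len(maxit)) {
    ## extrapolation point
    thetaNew <- (1 + sqrt(1 + 4 * theta^2)) / 2
    Bext <- B + ((theta - 1) / thetaNew) * (B - Bprev)
    Gext <- buildG(Bext)
    fext <- .chartObj(Gext, parts)
    if (!is.finite(fext)) { Bext <- B; Gext <- buildG(B); fext <- f }
    grad <- .chartGrad(Gext, parts)[freeIdx, , drop = FALSE]
    t_ <- min(t_ * 2, 10)
    repeat {
      Bnew <- prox(Bext - t_ * grad, t_)
      fnew <- .chartObj(buildG(Bnew), parts)
      dB <- Bnew - Bext
      if (is.finite(fnew) &&
          fnew <= fext + sum(grad * dB) + sum(dB^2) / (2 * t_) + 1e-12) break
      t_ <- t_ / 2
      if (t_ < 1e-14) { Bnew <- Bext; fnew <- fext; break }
    }
    objnew <- fnew + pen(Bnew)
    if (objnew > obj + 1e-12) {          # monotone restart from B
      theta <- 1
      grad <- .chartGrad(buildG(B), parts)[freeIdx, , drop = FALSE]
      repeat {
        Bnew <- prox(B - t_ * grad, t_)
        fnew <- .chartObj(buildG(Bnew), parts)
        dB <- Bnew - B
        if (is.finite(fnew) &&
            fnew <= f + sum(grad * dB) + sum(dB^2) / (2 * t_) + 1e-12) break
        t_ <- t_ / 2
        if (t_ < 1e-14) { Bnew <- B; fnew <- f; break }
      }
      objnew <- fnew + pen(Bnew)
      thetaNew <- 1
    }
    rel <- abs(obj - objnew) / (abs(obj) + 1e-12)
    Bprev <- B; B <- Bnew; f <- fnew; obj <- objnew; theta <- thetaNew
    if (rel < tol && it > 2L) { converged <- TRUE; break }
    if (t_ < 1e-14) break
  }
  list(B = B, value = obj, smooth = f, converged = converged)
}

#' Fit the row-sparse envelope at a given penalty
#'
#' Minimizes the adaptive-group-lasso-penalized envelope objective. Rows of
#' the returned basis with norm below 1e-6 are set exactly to zero and
#' reported as excluded; the basis is re-orthonormalized on its nonzero rows
#' so that \code{Gamma = rbind(Gamma_A, 0)} (up to row order) with
#' \code{Gamma_A' Gamma_A = I_d}. \code{lambda = 0} reduces to
#' \code{\link{fitEnvelope}} up to canonicalization.
#'
#' @param moments a \linkS4class{ConditionalMoments}.
#' @param d envelope dimension, 1 <= d <= p.
#' @param config a \linkS4class{SparseConfig}; \code{lambda} must be set
#'   (weights are computed from the pilot when missing).
#' @param seed seed for the pilot fit's random starts.
#' @param pilot optional precomputed unpenalized \linkS4class{EnvelopeBasis}
#'   at the same d (avoids refitting along a lambda path).
#' @param warmB optional warm-start chart coordinates from a previous,
#'   larger lambda.
#' @param surrogates optional SPICE surrogates for the p > n regime.
#' @param maxit,tol solver controls.
#' @return list with elements \code{basis} (\linkS4class{EnvelopeBasis}),
#'   \code{pattern} (\linkS4class{SparsityPattern}), \code{config} (with
#'   weights filled), \code{objective} (penalized value), \code{B} (chart
#'   coordinates for warm starting), \code{anchors}.
#' @export
fitSparseEnvelope <- function(moments, d, config, seed = 1L, pilot = NULL,
                              warmB = NULL, surrogates = NULL,
                              maxit = 300L, tol = 1e-7) {
  d <- as.integer(d)
  p <- ncol(moments@residMXZ)
  stopifnot(d >= 1L, d <= p)
  lambda <- config@lambda
  if (is.na(lambda) || lambda < 0)
    stop("config@lambda must be a nonnegative number (use selectLambda)",
         call. = FALSE)
  parts <- .objectiveParts(moments, surrogates)
  if (is.null(pilot))
    pilot <- fitEnvelope(moments, d, seed = seed, surrogates = surrogates)
  if (d == p) {
    return(list(basis = pilot, pattern = SparsityPattern(seq_len(p), p),
                config = config, objective = .envObj(pilot@Gamma, parts),
                B = matrix(0, 0L, d), anchors = seq_len(d)))
  }
  if (length(config@weights) != p)
    config <- adaptiveWeights(pilot, config@weightExponent, config)

  norms <- sqrt(rowSums(pilot@Gamma^2))
  anchorIdx <- order(norms, decreasing = TRUE)[seq_len(d)]
  freeIdx <- setdiff(seq_len(p), anchorIdx)
  Ganc <- pilot@Gamma[anchorIdx, , drop = FALSE]
  if (abs(det(Ganc)) < 1e-10)
    stop("anchor block of the pilot basis is singular; cannot build the sparse chart",
         call. = FALSE)
  B0 <- if (!is.null(warmB)) warmB
        else pilot@Gamma[freeIdx, , drop = FALSE] %*% solve(Ganc)
  w <- config@weights[freeIdx]

  sol <- .sparseSolve(B0, anchorIdx, freeIdx, parts, lambda, w,
                      maxit = maxit, tol = tol)

  ## zero rows: measured on the orthonormalized basis scale
  G <- matrix(0, p, d)
  G[anchorIdx, ] <- diag(d)
  G[freeIdx, ] <- sol$B
  GammaFull <- .orth(G)
  rn <- sqrt(rowSums(GammaFull^2))
  active <- sort(c(anchorIdx, freeIdx[rn[freeIdx] >= 1e-6]))
  if (length(active) < d)
    stop("over-shrinkage: fewer active rows than the envelope dimension; decrease lambda",
         call. = FALSE)
  pattern <- SparsityPattern(active, p)

  ## re-orthonormalize on the active rows only, exact zeros elsewhere
  Gact <- G[active, , drop = FALSE]
  GammaA <- .orth(Gact)
  Gamma <- matrix(0, p, d)
  Gamma[active, ] <- GammaA
  Gamma <- .canonicalize(Gamma, moments@S$MXZ)
  basis <- EnvelopeBasis(Gamma, converged = sol$converged)
  if (!sol$converged)
    warning("sparse envelope solver did not converge; best iterate returned")

  list(basis = basis, pattern = pattern, config = initialize(config),
       objective = sol$value, B = sol$B, anchors = anchorIdx)
}

## default lambda grid: from the smallest lambda that zeroes every penalized
## row at the chart origin down by 3 decades, log-spaced
.lambdaGrid <- function(moments, d, config, pilot, surrogates = NULL,
                        length.out = 50L, decades = 3) {
  p <- ncol(moments@residMXZ)
  parts <- .objectiveParts(moments, surrogates)
  norms <- sqrt(rowSums(pilot@Gamma^2))
  anchorIdx <- order(norms, decreasing = TRUE)[seq_len(d)]
  freeIdx <- setdiff(seq_len(p), anchorIdx)
  G0 <- matrix(0, p, d); G0[anchorIdx, ] <- diag(d)
  g <- .chartGrad(G0, parts)[freeIdx, , drop = FALSE]
  w <- config@weights[freeIdx]
  lmax <- max(sqrt(rowSums(g^2)) / w)
  if (!is.finite(lmax) || lmax <= 0) lmax <- 1
  exp(seq(log(lmax), log(lmax) - decades * log(10),
          length.out = length.out))
}

#' Select the group-lasso penalty by BIC or cross-validation
#'
#' Walks a decreasing lambda grid with warm starts. BIC is
#' \code{-2 logLik + log(n) * (d (p_A - d) + d r)}, charging each fit the
#' Grassmann dimension of its active-row subspace plus the envelope
#' coordinates. CV refits on folds and scores held-out outcome prediction
#' error (requires \code{data}).
#'
#' @param moments a \linkS4class{ConditionalMoments}.
#' @param d envelope dimension.
#' @param config a \linkS4class{SparseConfig}; an empty \code{lambdaGrid} is
#'   filled automatically.
#' @param criterion \code{"bic"} (default): BIC on the conditional
#'   outcome-model likelihood, the scale on which mediator selection is
#'   defined; \code{"bic-full"}: BIC on the full joint likelihood (the
#'   mediator-covariance term then dominates and can favor dense bases when
#'   the outcome signal is weak); \code{"cv"}: held-out outcome prediction
#'   error.
#' @param seed seed (pilot starts and CV folds).
#' @param data the \linkS4class{MediationDataset}, required for
#'   \code{criterion = "cv"}.
#' @param folds CV folds (default 5).
#' @param surrogates optional SPICE surrogates.
#' @param gridLength grid size when the grid is built automatically.
#' @param pilot optional precomputed unpenalized pilot basis at the same d.
#' @param gridDecades span of the automatic grid in log10 units below the
#'   all-zeroing lambda (default 3).
#' @return the \linkS4class{SparseConfig} with \code{lambda} set (and the
#'   grid and weights recorded); attribute \code{"criterionPath"} holds the
#'   criterion values along the grid.
#' @export
selectLambda <- function(moments, d, config = SparseConfig(),
                         criterion = c("bic", "bic-full", "cv"), seed = 1L,
                         data = NULL,
                         folds = 5L, surrogates = NULL, gridLength = 50L,
                         pilot = NULL, gridDecades = 3) {
  criterion <- match.arg(criterion)
  d <- as.integer(d)
  p <- ncol(moments@residMXZ)
  r <- ncol(moments@residYXZ)
  n <- moments@n
  if (is.null(pilot))
    pilot <- fitEnvelope(moments, d, seed = seed, surrogates = surrogates)
  if (length(config@weights) != p)
    config <- adaptiveWeights(pilot, config@weightExponent, config)
  grid <- config@lambdaGrid
  if (!length(grid))
    grid <- .lambdaGrid(moments, d, config, pilot, surrogates,
                        length.out = gridLength, decades = gridDecades)
  if (!length(grid)) stop("empty lambda grid", call. = FALSE)

  crit <- rep(NA_real_, length(grid))
  warmB <- NULL
  best <- NULL
  for (i in seq_along(grid)) {
    cfg_i <- initialize(config, lambda = grid[i])
    sf <- tryCatch(
      fitSparseEnvelope(moments, d, cfg_i, seed = seed, pilot = pilot,
                        warmB = warmB, surrogates = surrogates),
      error = function(e) NULL)
    if (is.null(sf)) next
    warmB <- sf$B
    if (criterion %in% c("bic", "bic-full")) {
      fit <- estimateParameters(moments, sf$basis, sf$pattern,
                                surrogates = surrogates)
      pA <- length(sf$pattern@selected)
      df <- d * (pA - d) + d * r
      ll <- if (criterion == "bic")
        -n / 2 * determinant(fit@SigmaYcond)$modulus else fit@logLik
      crit[i] <- -2 * as.numeric(ll) + log(n) * df
    } else {
      crit[i] <- .cvLambdaError(data, d, cfg_i, folds, seed, surrogates)
    }
    if (is.null(best) || (is.finite(crit[i]) && crit[i] < best$crit)) {
      best <- list(crit = crit[i], lambda = grid[i])
    }
  }
  if (is.null(best)) stop("no lambda on the grid produced a valid fit",
                          call. = FALSE)
  out <- initialize(config, lambda = best$lambda, lambdaGrid = grid)
  attr(out, "criterionPath") <- crit
  out
}

## held-out outcome prediction error for one lambda
.cvLambdaError <- function(data, d, config, folds, seed, surrogates = NULL) {
  if (is.null(data))
    stop("criterion = 'cv' requires the data argument", call. = FALSE)
  n <- nSamples(data); q <- ncol(data@Z)
  idx <- .withSeed(.streamSeed(seed, 11L), sample.int(n))
  fold <- rep(seq_len(folds), length.out = n)[order(idx)]
  errs <- 0; m <- 0
  for (f in seq_len(folds)) {
    tr <- fold != f
    dtr <- MediationDataset(data@Y[tr, , drop = FALSE],
                            data@M[tr, , drop = FALSE],
                            data@X[tr, , drop = FALSE],
                            if (q) data@Z[tr, , drop = FALSE] else NULL)
    momTr <- conditionalMoments(dtr, requireInvertibleY = is.null(surrogates))
    sf <- tryCatch(fitSparseEnvelope(momTr, d, config, seed = seed,
                                     surrogates = surrogates),
                   error = function(e) NULL)
    if (is.null(sf)) return(Inf)
    fit <- estimateParameters(momTr, sf$basis, sf$pattern,
                              surrogates = surrogates)
    te <- which(!tr)
    pred <- predictOutcome(fit, data@M[te, , drop = FALSE],
                           data@X[te, , drop = FALSE],
                           if (q) data@Z[te, , drop = FALSE] else NULL)
    errs <- errs + sum((data@Y[te, , drop = FALSE] - pred)^2)
    m <- m + length(te)
  }
  errs / m
}
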