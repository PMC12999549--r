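## Envelope objective on the Grassmann manifold and its minimization.
##
## For a fixed envelope dimension d the profile objective is
##   J(Gamma) = log|S_{Y|X,Z}| + log|Gamma' S_{M|X,Z}^{-1} Gamma|
##            + log|Gamma' S_{M|Y,X,Z} Gamma|,
## minimized over span(Gamma) in the Grassmannian of d-planes in R^p. The
## objective depends on Gamma only through its span (invariant under right
## rotation), so optimization uses a projected-gradient scheme with QR
## retraction and multi-start.

## assemble the pieces the objective needs; surrogates (SPICE) may replace
## the inverse of S_{M|X,Z} and the matrix S_{M|Y,X,Z} in the p > n regime
.objectiveParts <- function(moments, surrogates = NULL) {
  S <- moments@S
  if (is.null(surrogates)) {
    Minv <- .psolve(S$MXZ)
    C <- S$MYXZ
  } else {
    Minv <- surrogates$Minv
    C <- surrogates$MYXZ
  }
  list(const = .logdet(S$YXZ), Minv = .sym(Minv), C = .sym(C))
}

## core objective given precomputed parts (no constant term handling twice)
.envObj <- function(Gamma, parts) {
  d <- ncol(Gamma)
  if (d == 0L) return(parts$const)
  if (d == 1L) {                      # scalar fast path
    a1 <- sum(Gamma * (parts$Minv %*% Gamma))
    a2 <- sum(Gamma * (parts$C %*% Gamma))
    if (a1 <= 0 || a2 <= 0) return(Inf)
    return(parts$const + log(a1) + log(a2))
  }
  A1 <- crossprod(Gamma, parts$Minv %*% Gamma)
  A2 <- crossprod(Gamma, parts$C %*% Gamma)
  e1 <- determinant(.sym(A1), logarithm = TRUE)
  e2 <- determinant(.sym(A2), logarithm = TRUE)
  if (e1$sign <= 0 || e2$sign <= 0) return(Inf)
  parts$const + as.numeric(e1$modulus) + as.numeric(e2$modulus)
}

#' Evaluate the envelope objective at a basis
#'
#' Returns \code{log|S_YXZ| + log|Gamma' S_MXZ^{-1} Gamma| +
#' log|Gamma' S_MYXZ Gamma|}. The value depends on \code{Gamma} only through
#' its span.
#'
#' @param basis an \linkS4class{EnvelopeBasis} (or a p x d matrix with
#'   orthonormal columns).
#' @param moments a \linkS4class{ConditionalMoments}.
#' @param surrogates optional list with elements \code{Minv} and \code{MYXZ}
#'   replacing the sample quantities (high-dimensional path).
#' @return scalar objective value.
#' @export
envelopeObjective <- function(basis, moments, surrogates = NULL) {
  Gamma <- if (is(basis, "EnvelopeBasis")) basis@Gamma else as.matrix(basis)
  parts <- .objectiveParts(moments, surrogates)
  val <- .envObj(Gamma, parts)
  if (!is.finite(val))
    stop("envelope objective degenerate: inner determinant non-positive",
         call. = FALSE)
  val
}

## Euclidean gradient of J at Gamma (ignoring the constant)
.envGrad <- function(Gamma, parts) {
  u1 <- parts$Minv %*% Gamma
  u2 <- parts$C %*% Gamma
  if (ncol(Gamma) == 1L)
    return(2 * (u1 / sum(Gamma * u1) + u2 / sum(Gamma * u2)))
  2 * (u1 %*% .psolve(crossprod(Gamma, u1)) +
       u2 %*% .psolve(crossprod(Gamma, u2)))
}

## one local descent from a starting orthonormal basis; QR retraction,
## Armijo backtracking on the Grassmann (horizontal) gradient
.grassmannDescent <- function(Gamma, parts, maxit = 500L, tol = 1e-8) {
  f <- .envObj(Gamma, parts)
  step <- 1
  converged <- FALSE
  for (it in seq_len(maxit)) {
    G <- .envGrad(Gamma, parts)
    H <- G - Gamma %*% crossprod(Gamma, G)   # horizontal component
    gnorm2 <- sum(H^2)
    if (gnorm2 < 1e-18) { converged <- TRUE; break }
    step <- min(step * 2, 1)
    improved <- FALSE
    d1 <- ncol(Gamma) == 1L
    for (ls in 1:40) {
      Gnew <- Gamma - step * H
      Gnew <- if (d1) Gnew / sqrt(sum(Gnew^2))
              else qr.Q(qr(Gnew))[, seq_len(ncol(Gamma)), drop = FALSE]
      fnew <- .envObj(Gnew, parts)
      if (is.finite(fnew) && fnew <= f - 1e-4 * step * gnorm2) {
        improved <- TRUE; break
      }
      step <- step / 2
    }
    if (!improved) { converged <- TRUE; break }  # no descent direction left
    relchange <- abs(f - fnew) / (abs(f) + 1e-12)
    Gamma <- Gnew; f <- fnew
    if (relchange < tol) { converged <- TRUE; break }
  }
  list(Gamma = Gamma, value = f, converged = converged)
}

## deterministic canonical form: order columns by decreasing diagonal of
## Gamma' S Gamma, then make the first entry of largest magnitude positive
.canonicalize <- function(Gamma, S) {
  d <- ncol(Gamma)
  if (d == 0L) return(Gamma)
  dg <- diag(crossprod(Gamma, S %*% Gamma))
  Gamma <- Gamma[, order(dg, decreasing = TRUE), drop = FALSE]
  for (j in seq_len(d)) {
    i <- which.max(abs(Gamma[, j]))
    if (Gamma[i, j] < 0) Gamma[, j] <- -Gamma[, j]
  }
  Gamma
}

#' Fit the envelope subspace of a given dimension
#'
#' Minimizes the envelope objective over the Grassmannian by multi-start
#' projected gradient descent with QR retraction. Starting values combine
#' (a) the span of the OLS mediator-outcome coefficient matrix padded with
#' eigenvectors of S_{M|X,Z}, (b) a greedy eigenvector pursuit that adds one
#' direction at a time, and (c) seeded random orthonormal draws. The
#' returned basis is canonicalized (columns ordered by decreasing material
#' variance, sign fixed) so runs are reproducible.
#'
#' @param moments a \linkS4class{ConditionalMoments}.
#' @param d envelope dimension, 0 <= d <= p. \code{d = 0} returns the empty
#'   basis, \code{d = p} the identity basis (no reduction: OLS).
#' @param nStarts number of additional random starts (default 5).
#' @param seed integer seed for the random starts.
#' @param maxit,tol optimizer controls (relative objective change).
#' @param tieTol near-tie tolerance on the objective across multi-start
#'   minima: among minima within \code{tieTol} of the best value the basis
#'   with the largest material variance \code{|Gamma' S Gamma|} is
#'   returned. When the envelope is weakly identified (e.g. no outcome
#'   signal at the working dimension) the objective ties across
#'   eigendirections at the population level, and picking a near-tied
#'   minimum with near-zero material variance collapses the variance of
#'   \code{eta} downstream; the default \code{d * r * log(n) / n} scales
#'   with the sampling noise of the tied values.
#' @param surrogates optional SPICE surrogates (see
#'   \code{\link{envelopeObjective}}).
#' @return An \linkS4class{EnvelopeBasis}; \code{converged} records
#'   optimizer state.
#' @export
fitEnvelope <- function(moments, d, nStarts = 5L, seed = 1L,
                        maxit = 500L, tol = 1e-8, tieTol = NULL,
                        surrogates = NULL) {
  p <- ncol(moments@residMXZ)
  d <- as.integer(d)
  stopifnot(d >= 0L, d <= p)
  if (d == 0L) return(EnvelopeBasis(matrix(numeric(0), p, 0L), p = p))
  if (d == p) return(EnvelopeBasis(diag(p)))

  parts <- .objectiveParts(moments, surrogates)

  ## ---- starting candidates ----
  starts <- list()
  ## OLS-span start: betaM_ols = S_MXZ^{-1} S_(M,Y)|X,Z; in the surrogate
  ## path, Minv plays the inverse role directly
  bOls <- parts$Minv %*% t(moments@S$YM.XZ)
  sv <- svd(bOls)
  nb <- sum(sv$d > 1e-10 * max(sv$d, 1))
  base <- sv$u[, seq_len(min(nb, d)), drop = FALSE]
  eigS <- eigen(.sym(parts$C), symmetric = TRUE)$vectors
  if (ncol(base) < d) {
    ## pad with eigenvectors of the conditional covariance not yet spanned
    for (j in seq_len(p)) {
      if (ncol(base) == d) break
      v <- eigS[, j]
      v <- v - base %*% crossprod(base, v)
      if (sqrt(sum(v^2)) > 1e-6) base <- cbind(base, v / sqrt(sum(v^2)))
    }
  }
  starts[[1]] <- .orth(base)
  ## greedy eigenvector pursuit: pick d eigenvectors (of either matrix)
  ## one at a time, each minimizing the objective jointly with those chosen
  eigM <- eigen(.sym(parts$Minv), symmetric = TRUE)$vectors
  cand <- cbind(eigS, eigM)
  chosen <- NULL
  for (j in seq_len(d)) {
    best <- NULL; bestval <- Inf
    for (c_ in seq_len(ncol(cand))) {
      v <- cand[, c_]
      if (!is.null(chosen)) {
        v <- v - chosen %*% crossprod(chosen, v)
        nv <- sqrt(sum(v^2))
        if (nv < 1e-8) next
        v <- v / nv
      }
      val <- .envObj(cbind(chosen, v), parts)
      if (is.finite(val) && val < bestval) { bestval <- val; best <- v }
    }
    chosen <- cbind(chosen, best)
  }
  starts[[2]] <- chosen
  ## top-variance start: leading eigenvectors of the mediator conditional
  ## covariance (the stable candidate under weak identification)
  starts[[3]] <- eigen(.sym(moments@S$MXZ),
                       symmetric = TRUE)$vectors[, seq_len(d), drop = FALSE]
  if (nStarts > 0L) {
    rs <- .withSeed(.streamSeed(seed, 77L), {
      lapply(seq_len(nStarts), function(i)
        .orth(matrix(stats::rnorm(p * d), p, d)))
    })
    starts <- c(starts, rs)
  }

  if (is.null(tieTol))
    tieTol <- d * ncol(moments@residYXZ) * log(moments@n) / moments@n
  sols <- list()
  for (st in starts) {
    if (is.null(st) || ncol(st) != d) next
    sols[[length(sols) + 1L]] <- .grassmannDescent(st, parts, maxit = maxit,
                                                   tol = tol)
  }
  vals <- vapply(sols, `[[`, numeric(1), "value")
  near <- which(vals <= min(vals) + tieTol)
  matVar <- vapply(sols[near], function(s_)
    .logdet(crossprod(s_$Gamma, moments@S$MXZ %*% s_$Gamma)), numeric(1))
  best <- sols[[near[which.max(matVar)]]]
  if (!best$converged)
    warning("envelope optimizer did not converge; best iterate returned")
  EnvelopeBasis(.canonicalize(best$Gamma, moments@S$MXZ),
                converged = best$converged)
}

## evaluate code with a local RNG seed, restoring global state
.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Choose the envelope dimension by cross-validation
#'
#' K-fold cross-validation on the mean squared prediction error of the
#' outcomes from (M, X, Z) under the fitted envelope model, for each
#' candidate d in 0..dMax, with the one-standard-error rule: the smallest d
#' whose CV error is within one standard error of the minimizer (beyond the
#' true dimension the profile is flat, so the raw argmin follows noise
#' upward; exact ties also resolve toward smaller d). d = 0 is the
#' no-mediation model (betaM = 0), estimable and comparable in CV.
#'
#' @param data a \linkS4class{MediationDataset}.
#' @param dMax largest candidate dimension (default min(p, n - k - q - 2)).
#' @param folds number of folds (default 5; must be >= 2).
#' @param seed seed controlling the fold split and optimizer starts.
#' @param nStarts random starts per envelope fit.
#' @return the selected dimension (integer). A \code{flatProfile} attribute
#'   flags CV profiles indistinguishable across d (relative spread < 1%).
#' @export
selectDimension <- function(data, dMax = NULL, folds = 5L, seed = 1L,
                            nStarts = 2L) {
  stopifnot(is(data, "MediationDataset"))
  if (folds < 2L) stop("folds must be at least 2", call. = FALSE)
  n <- nSamples(data); p <- nMediators(data)
  k <- ncol(data@X); q <- ncol(data@Z)
  if (is.null(dMax)) dMax <- min(p, max(0L, n - k - q - 2L))
  dMax <- min(as.integer(dMax), p)

  idx <- .withSeed(.streamSeed(seed, 3L), sample.int(n))
  fold <- rep(seq_len(folds), length.out = n)[order(idx)]

  cvErr <- numeric(dMax + 1L)
  foldErr <- matrix(0, dMax + 1L, folds)   # per-fold MSEs for the 1-SE rule
  for (d in 0:dMax) {
    errs <- 0; m <- 0
    for (f in seq_len(folds)) {
      tr <- fold != f
      dtr <- MediationDataset(data@Y[tr, , drop = FALSE],
                              data@M[tr, , drop = FALSE],
                              data@X[tr, , drop = FALSE],
                              if (q) data@Z[tr, , drop = FALSE] else NULL)
      momTr <- conditionalMoments(dtr)
      bas <- fitEnvelope(momTr, d, nStarts = nStarts, seed = seed)
      fit <- estimateParameters(momTr, bas)
      te <- which(!tr)
      pred <- predictOutcome(fit, data@M[te, , drop = FALSE],
                             data@X[te, , drop = FALSE],
                             if (q) data@Z[te, , drop = FALSE] else NULL)
      sqErr <- sum((data@Y[te, , drop = FALSE] - pred)^2)
      foldErr[d + 1L, f] <- sqErr / length(te)
      errs <- errs + sqErr
      m <- m + length(te)
    }
    cvErr[d + 1L] <- errs / m
  }
  ## one-standard-error rule: smallest d whose CV error is within one SE of
  ## the minimizer's (beyond the true dimension the profile is flat and the
  ## raw argmin follows CV noise upward)
  imin <- which.min(cvErr)
  seMin <- stats::sd(foldErr[imin, ]) / sqrt(folds)
  sel <- which(cvErr <= cvErr[imin] + seMin)[1L] - 1L
  spread <- (max(cvErr) - min(cvErr)) / (abs(min(cvErr)) + 1e-12)
  out <- as.integer(sel)
  attr(out, "cvError") <- cvErr
  attr(out, "cvSE") <- apply(foldErr, 1L, stats::sd) / sqrt(folds)
  if (spread < 0.01) {
    attr(out, "flatProfile") <- TRUE
    warning("cross-validation profile is flat across d; selection is weakly identified")
  }
  out
}
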