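# Internal linear-algebra helpers. All contracts are on values, not methods:
# inverses go through solves/factorizations, pseudo-inverses through SVD.

#' @importFrom stats rnorm runif rbinom rt rchisq sd var quantile pchisq pnorm
NULL

## symmetrize (guards tiny asymmetries from floating point)
.sym <- function(A) (A + t(A)) / 2

## log-determinant of a symmetric PD matrix via Cholesky
.logdet <- function(A) {
  if (length(A) == 0L) return(0)
  2 * sum(log(diag(chol(.sym(A)))))
}

## solve A x = B for symmetric PD A
.psolve <- function(A, B = diag(nrow(A))) {
  ch <- chol(.sym(A))
  backsolve(ch, backsolve(ch, B, transpose = TRUE))
}

## Moore-Penrose pseudo-inverse with relative rank tolerance, plus rank
.pinv <- function(A, tol = 1e-8) {
  if (length(A) == 0L) return(list(inv = A, rank = 0L))
  s <- svd(A)
  keep <- s$d > tol * max(s$d, 0)
  r <- sum(keep)
  if (r == 0L) return(list(inv = matrix(0, ncol(A), nrow(A)), rank = 0L))
  inv <- s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
  list(inv = inv, rank = as.integer(r))
}

## orthonormal basis of the column space (QR with column pivoting)
.orth <- function(A) {
  if (NCOL(A) == 0L) return(matrix(0, nrow(A), 0L))
  qr.Q(qr(A))[, seq_len(NCOL(A)), drop = FALSE]
}

## orthonormal complement of an orthonormal p x d basis
.orthcomp <- function(Gamma, p = nrow(Gamma)) {
  d <- NCOL(Gamma)
  if (d == 0L) return(diag(p))
  if (d == p) return(matrix(0, p, 0L))
  qr.Q(qr(Gamma), complete = TRUE)[, (d + 1L):p, drop = FALSE]
}

#' Largest principal angle between two subspaces
#'
#' @param A,B matrices whose column spans are compared (orthonormalized
#'   internally).
#' @return the largest principal angle in radians.
#' @export
principalAngle <- function(A, B) {
  A <- .orth(as.matrix(A)); B <- .orth(as.matrix(B))
  s <- svd(crossprod(A, B))$d
  acos(min(1, max(-1, min(s))))
}

## symmetric PD square root
.sqrtm <- function(A) {
  e <- eigen(.sym(A), symmetric = TRUE)
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

## draw n rows from N(0, Sigma) given its square root factor (n x m %*% t(L))
.rmvnorm <- function(n, Sigma) {
  m <- nrow(Sigma)
  if (m == 0L) return(matrix(0, n, 0L))
  matrix(stats::rnorm(n * m), n, m) %*% chol(.sym(Sigma) + diag(1e-12, m))
}

## empty matrix convention for absent blocks (q = 0, k = 0)
.emptyMat <- function(n) matrix(numeric(0), nrow = n, ncol = 0L)

## derive a stream seed below 2^31 from a master seed and a stream label
.streamSeed <- function(seed, stream) {
  (as.integer(seed) %% 1000003L) * 2011L + as.integer(stream) %% 2011L
}
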