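# Spherical-spline scalp interpolation (Perrin-style).
#
# The kernel is g(x) = (1/4pi) * sum_{n=1..N} (2n+1) / (n^m (n+1)^m) P_n(x),
# evaluated at cosines of great-circle angles. Per time sample we solve the
# standard bordered system (ridge lambda on the kernel diagonal, constant
# term enforced exactly) and evaluate at the target electrodes. Because the
# solve is linear in the data, a single transfer matrix maps observed to
# target values for a whole window at once.

# Legendre polynomials P_1..P_n at x (vector); returns length(x) x n matrix
.legendreTable <- function(x, n) {
  out <- matrix(0, length(x), n)
  pm1 <- rep(1, length(x))       # P_0
  p <- x                         # P_1
  out[, 1] <- p
  if (n >= 2) for (k in 1:(n - 1)) {
    pn <- ((2 * k + 1) * x * p - k * pm1) / (k + 1)
    pm1 <- p
    p <- pn
    out[, k + 1] <- p
  }
  out
}

# g kernel at cosine values (vector or matrix)
.splineG <- function(cosang, m, nTerms) {
  n <- seq_len(nTerms)
  w <- (2 * n + 1) / (n^m * (n + 1)^m) / (4 * pi)
  P <- .legendreTable(as.vector(cosang), nTerms)
  out <- P %*% w
  if (is.matrix(cosang)) dim(out) <- dim(cosang)
  out
}

#' Spherical-spline transfer matrix
#'
#' Linear operator mapping values observed at \code{goodIdx} electrodes to
#' interpolated values at \code{targetIdx} electrodes of the same montage.
#'
#' @param montage a [Montage-class].
#' @param goodIdx,targetIdx 1-based electrode indices.
#' @param m spline order (stiffness), default 4.
#' @param lambda ridge regularizer on the kernel diagonal, default 1e-5.
#' @param nTerms number of Legendre terms, default 50.
#' @return a \code{length(targetIdx) x length(goodIdx)} matrix.
#' @export
splineTransferMatrix <- function(montage, goodIdx, targetIdx, m = 4,
                                 lambda = 1e-5, nTerms = 50) {
  if (length(goodIdx) < 4)
    stop("spherical-spline interpolation needs at least 4 good electrodes")
  P <- montage@positions
  cosGG <- tcrossprod(P[goodIdx, , drop = FALSE])
  cosTG <- tcrossprod(P[targetIdx, , drop = FALSE], P[goodIdx, , drop = FALSE])
  G <- .splineG(pmin(pmax(cosGG, -1), 1), m, nTerms)
  Gt <- .splineG(pmin(pmax(cosTG, -1), 1), m, nTerms)
  ng <- length(goodIdx)
  A <- rbind(cbind(G + diag(lambda, ng), rep(1, ng)), c(rep(1, ng), 0))
  # columns of the inverse acting on [v; 0] give coefficients per data site
  sol <- tryCatch(solve(A, rbind(diag(ng), rep(0, ng))),
                  error = function(e)
                    stop("singular spline system; increase lambda"))
  Cc <- sol[seq_len(ng), , drop = FALSE]       # kernel coefficients
  c0 <- sol[ng + 1, ]                          # constant term
  Gt %*% Cc + matrix(c0, length(targetIdx), ng, byrow = TRUE)
}

#' Reconstruct electrode values by spherical splines
#'
#' Interpolates the scalp field observed at \code{goodIdx} onto
#' \code{targetIdx}, independently at every time sample (vectorized through
#' one linear solve).
#'
#' @param x an [EEGWindow-class] or a channels x samples matrix aligned with
#'   the montage (rows at \code{goodIdx} are used).
#' @inheritParams splineTransferMatrix
#' @return \code{length(targetIdx) x samples} matrix of interpolated values.
#' @examples
#' mon <- buildStandardMontage(16)
#' f <- matrix(mon@positions[, 3], 16, 10)  # first-harmonic field, constant in time
#' est <- sphericalSplineReconstruct(f, 1:12, 13:16, mon)
#' @export
sphericalSplineReconstruct <- function(x, goodIdx, targetIdx, montage = NULL,
                                       m = 4, lambda = 1e-5, nTerms = 50) {
  if (is(x, "EEGWindow")) {
    if (is.null(montage)) montage <- windowMontage(x)
    x <- windowData(x)
  }
  if (is.null(montage)) stop("montage required when x is a matrix")
  W <- splineTransferMatrix(montage, goodIdx, targetIdx, m, lambda, nTerms)
  W %*% x[goodIdx, , drop = FALSE]
}
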