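#' Skinny singular value decomposition
#'
#' Economy SVD that keeps only singular triplets above a relative rank
#' tolerance and applies a fixed sign convention (the largest-magnitude
#' entry of each left singular vector is made positive) so that repeated
#' calls on the same matrix are bit-identical.
#'
#' @param M Numeric matrix (p x q), all entries finite.
#' @param rank_tol Nonnegative relative tolerance: singular values
#'   \eqn{\sigma \le rank\_tol \cdot \sigma_{max}} are dropped.
#' @return A list of class `"skinny_svd"` with components `u` (p x r,
#'   orthonormal columns), `d` (length-r nonincreasing nonnegative singular
#'   values) and `v` (q x r, orthonormal columns), so that
#'   `u %*% diag(d, r) %*% t(v)` reconstructs `M` up to the dropped rank.
#' @seealso [svt()], [soft_threshold()]
#' @export
skinny_svd <- function(M, rank_tol = 1e-12) {
  check_finite_matrix(M)
  if (rank_tol < 0) stop_invalid("'rank_tol' must be >= 0")
  sv <- robust_svd(M)
  smax <- if (length(sv$d)) sv$d[1] else 0
  keep <- which(sv$d > rank_tol * smax & sv$d > 0)
  r <- length(keep)
  U <- sv$u[, keep, drop = FALSE]
  V <- sv$v[, keep, drop = FALSE]
  d <- sv$d[keep]
  # sign convention: largest-|entry| of each U column positive
  if (r > 0) {
    for (i in seq_len(r)) {
      j <- which.max(abs(U[, i]))
      if (U[j, i] < 0) {
        U[, i] <- -U[, i]
        V[, i] <- -V[, i]
      }
    }
  }
  structure(list(u = U, d = d, v = V, rank = r), class = "skinny_svd")
}

#' Elementwise soft thresholding
#'
#' The proximal operator of \eqn{\tau \|\cdot\|_1}:
#' \eqn{sign(m) \max(|m| - \tau, 0)} applied entrywise. Used for the
#' sparse-noise update of the LatLRR solver and inside the l1 coder.
#'
#' @param M Numeric matrix or vector.
#' @param tau Nonnegative threshold.
#' @return Object of the same shape as `M`.
#' @export
soft_threshold <- function(M, tau) {
  if (!is.numeric(tau) || length(tau) != 1 || is.na(tau) || tau < 0) {
    stop_invalid("'tau' must be a single nonnegative number")
  }
  sign(M) * pmax(abs(M) - tau, 0)
}

#' Singular value thresholding
#'
#' The proximal operator of \eqn{\tau \|\cdot\|_*} (nuclear norm): shrink
#' every singular value of `M` by `tau` (floored at zero) and reconstruct.
#' A zero matrix is returned immediately without an SVD.
#'
#' @param M Numeric matrix, all entries finite.
#' @param tau Nonnegative threshold.
#' @return Matrix of the same dimension as `M`.
#' @export
svt <- function(M, tau) {
  check_finite_matrix(M)
  if (!is.numeric(tau) || length(tau) != 1 || is.na(tau) || tau < 0) {
    stop_invalid("'tau' must be a single nonnegative number")
  }
  if (all(M == 0)) return(M)
  sv <- robust_svd(M)
  d <- pmax(sv$d - tau, 0)
  keep <- d > 0
  if (!any(keep)) return(matrix(0, nrow(M), ncol(M), dimnames = dimnames(M)))
  sv$u[, keep, drop = FALSE] %*%
    (d[keep] * t(sv$v[, keep, drop = FALSE]))
}

#' Nuclear norm (sum of singular values)
#'
#' @param M Numeric matrix.
#' @return Nonnegative scalar.
#' @export
nuclear_norm <- function(M) {
  check_finite_matrix(M)
  if (all(M == 0)) return(0)
  sum(robust_svd(M, nu = 0, nv = 0)$d)
}
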