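#' l1-regularized least squares (sparse coding)
#'
#' Solves \deqn{J(x, \lambda) = \min_x \|Wx - y\|_2^2 + \lambda \|x\|_1}
#' by cyclic coordinate descent with exact coordinate minimization,
#' iterating until the subgradient optimality (KKT) gap falls below `tol`.
#' With `g = -2 W' (Wx - y)`, the returned `x` satisfies
#' `|g_j| <= lambda + tol` everywhere and `|g_j - lambda * sign(x_j)| <= tol`
#' on the support.
#'
#' @param W Dictionary matrix (m x n). Columns need not be unit norm;
#'   all-zero columns receive a zero coefficient.
#' @param y Target vector of length m.
#' @param lambda Positive l1 weight.
#' @param tol Positive KKT tolerance (default 1e-6).
#' @param max_iter Maximum full coordinate sweeps (default 1e5).
#' @return A list of class `"sparse_code"`: `x` (coefficients), `lambda`,
#'   `objective` (achieved J), `residual_norm` (\eqn{\|Wx-y\|_2}),
#'   `kkt_gap`, `n_iter`, `converged`.
#' @examples
#' W <- diag(2); y <- c(1, 0.1)
#' solve_l1ls(W, y, lambda = 0.4)$x   # c(0.8, 0): soft(W'y, lambda/2)
#' @export
solve_l1ls <- function(W, y, lambda, tol = 1e-6, max_iter = 100000) {
  if (!is.matrix(W)) W <- as.matrix(W)
  check_finite_matrix(W, "W")
  y <- as.numeric(y)
  if (any(!is.finite(y))) stop_invalid("'y' contains non-finite entries")
  if (length(y) != nrow(W)) {
    stop_invalid(sprintf("length(y) = %d does not match nrow(W) = %d",
                         length(y), nrow(W)))
  }
  if (!is.numeric(lambda) || length(lambda) != 1 || is.na(lambda) || lambda <= 0) {
    stop_invalid("'lambda' must be a single positive number")
  }
  if (tol <= 0) stop_invalid("'tol' must be > 0")

  G <- crossprod(W)           # W'W, n x n
  b <- drop(crossprod(W, y))  # W'y
  fit <- .cd_l1ls(G, b, lambda, tol, as.integer(max_iter))
  x <- fit$x
  kkt <- fit$kkt_gap
  it <- fit$n_iter
  res <- drop(W %*% x) - y
  rnorm <- sqrt(sum(res^2))
  structure(list(
    x = x, lambda = lambda,
    objective = sum(res^2) + lambda * sum(abs(x)),
    residual_norm = rnorm,
    kkt_gap = kkt, n_iter = it, converged = kkt <= tol
  ), class = "sparse_code")
}

#' KKT gap of a candidate l1 solution
#'
#' Maximum violation of the subgradient optimality conditions of
#' \eqn{\min_x \|Wx-y\|_2^2 + \lambda\|x\|_1} at `x`: with
#' `g = -2 W'(Wx - y)`, off the support `max(|g_j| - lambda, 0)` and on
#' the support `|g_j - lambda sign(x_j)|`.
#'
#' @param W Dictionary matrix.
#' @param y Target vector.
#' @param x Candidate coefficients.
#' @param lambda Positive l1 weight.
#' @return Nonnegative scalar; 0 iff `x` is optimal.
#' @export
l1ls_kkt_gap <- function(W, y, x, lambda) {
  g <- 2 * drop(crossprod(W, y - W %*% x))
  on_support <- x != 0
  gap <- 0
  if (any(!on_support)) {
    gap <- max(gap, max(abs(g[!on_support])) - lambda, 0)
  }
  if (any(on_support)) {
    gap <- max(gap, max(abs(g[on_support] - lambda * sign(x[on_support]))))
  }
  gap
}

#' @export
print.sparse_code <- function(x, ...) {
  nz <- sum(x$x != 0)
  cat(sprintf(
    "l1-regularized least-squares code: %d/%d nonzero, lambda = %g\n",
    nz, length(x$x), x$lambda))
  cat(sprintf("  objective %.6g, residual norm %.6g, KKT gap %.3g (%d sweeps)\n",
              x$objective, x$residual_norm, x$kkt_gap, x$n_iter))
  invisible(x)
}

#' Per-class coefficient selector
#'
#' The characteristic function \eqn{\delta_i(x)}: keeps the coefficients of
#' `x` whose dictionary column belongs to class `class_id` and zeroes the
#' rest. Summing the masks over all classes returns `x` exactly.
#'
#' @param x Coefficient vector.
#' @param classes Class assignment of each coefficient (same length as `x`).
#' @param class_id A class present in `classes`.
#' @return Vector of the same length as `x`.
#' @export
delta_mask <- function(x, classes, class_id) {
  if (length(classes) != length(x)) {
    stop_invalid("'classes' must assign a class to every coefficient")
  }
  if (!class_id %in% classes) {
    stop_invalid(sprintf("unknown class id '%s'", as.character(class_id)))
  }
  out <- numeric(length(x))
  sel <- classes == class_id
  out[sel] <- x[sel]
  out
}
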