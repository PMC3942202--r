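#' Control parameters for the LatLRR inexact-ALM solver
#'
#' @param mu0 Initial penalty \eqn{\mu > 0} of the augmented Lagrangian.
#' @param rho Penalty growth factor \eqn{\rho > 1} applied each iteration.
#' @param mu_max Penalty cap.
#' @param tol Feasibility tolerance: the solver stops when the largest of
#'   the three constraint gaps (entrywise, scaled by `max(abs(X))`) and the
#'   relative Frobenius primal residual both fall below `tol`.
#' @param max_iter Iteration cap.
#' @return List of class `"latlrr_control"`.
#' @export
latlrr_control <- function(mu0 = 1e-6, rho = 1.1, mu_max = 1e6,
                           tol = 1e-6, max_iter = 1000L) {
  if (mu0 <= 0) stop_invalid("'mu0' must be > 0")
  if (rho <= 1) stop_invalid("'rho' must be > 1")
  if (mu_max < mu0) stop_invalid("'mu_max' must be >= mu0")
  if (tol <= 0) stop_invalid("'tol' must be > 0")
  if (max_iter < 1) stop_invalid("'max_iter' must be >= 1")
  structure(list(mu0 = mu0, rho = rho, mu_max = mu_max, tol = tol,
                 max_iter = as.integer(max_iter)),
            class = "latlrr_control")
}

#' Latent low-rank representation of an expression matrix
#'
#' Decomposes a column-normalized genes-by-samples matrix `X` into
#' principal features `XZ`, salient features `LX` and sparse noise `E` by
#' solving \deqn{\min_{Z,L,E} \|Z\|_* + \|L\|_* + \lambda \|E\|_1
#'   \quad s.t. \quad X = XZ + LX + E} with an inexact augmented Lagrange
#' multiplier (ALM) scheme. Auxiliary variables `J = Z`, `S = L` carry the
#' nuclear-norm proximal steps; each block update is the closed-form
#' minimizer of the augmented Lagrangian in that block.
#'
#' The m-by-m system in the `L` update is never formed densely: it is
#' applied through the economy SVD of `X` (computed once), and `L`, `S`
#' and their multiplier are carried as rank-limited factors on the left
#' singular basis of `X`, which is exact because every term entering the
#' `L` update has row space inside the column space of `X`.
#'
#' @param X Numeric matrix (m genes x n samples) with unit-l2 columns;
#'   see [normalize_columns()]. Set `normalize = TRUE` to normalize here.
#' @param lambda Positive sparsity weight on `E`. Small values remove more
#'   "noise" into `E`; as `lambda` grows the solution approaches the
#'   noise-free model `X = XZ + LX`.
#' @param control A [latlrr_control()] list.
#' @param normalize If `TRUE`, columns of `X` are l2-normalized before
#'   solving; if `FALSE` (default) non-normalized input is an error.
#' @return List of class `"latlrr"` with components `Z` (n x n), `L`
#'   (m x m), `E` (m x n), `objective`, `primal_residual`
#'   (\eqn{\|X-XZ-LX-E\|_F/\|X\|_F}), `E_l1`, `n_iter`, `converged`,
#'   `lambda`, `control`.
#' @seealso [feasible_baseline()], [latlrr_objective()], [srclatlrr()]
#' @export
fit_latlrr <- function(X, lambda, control = latlrr_control(),
                       normalize = FALSE) {
  check_finite_matrix(X, "X")
  if (!is.numeric(lambda) || length(lambda) != 1 || is.na(lambda) || lambda <= 0) {
    stop_invalid("'lambda' must be a single positive number")
  }
  if (!inherits(control, "latlrr_control")) {
    control <- do.call(latlrr_control, as.list(control))
  }
  if (ncol(X) < 2) stop_invalid("'X' must have at least 2 columns (samples)")
  cn <- sqrt(colSums(X^2))
  if (normalize) {
    if (any(cn == 0)) stop_invalid("cannot normalize: all-zero column in 'X'")
    X <- sweep(X, 2, cn, "/")
  } else if (any(abs(cn - 1) > 1e-8)) {
    stop_invalid(
      "columns of 'X' must be l2-normalized (see normalize_columns); ",
      "or call with normalize = TRUE")
  }

  m <- nrow(X); n <- ncol(X)
  sv <- robust_svd(X)
  pos <- sv$d > max(sv$d[1], .Machine$double.eps) * 1e-14
  U <- sv$u[, pos, drop = FALSE]     # m x r
  s <- sv$d[pos]
  V <- sv$v[, pos, drop = FALSE]     # n x r
  r <- length(s)
  VS  <- V * rep(s, each = n)        # V diag(s), n x r
  SVt <- t(VS)                       # diag(s) V', r x n; U %*% SVt == X
  Wn  <- V %*% (t(V) * (s^2 / (1 + s^2)))  # (I + X'X)^{-1} = I - Wn
  dinv <- 1 / (1 + s^2)              # column scaling for the L update

  Z  <- matrix(0, n, n); J  <- matrix(0, n, n); Y2 <- matrix(0, n, n)
  E  <- matrix(0, m, n); Y1 <- matrix(0, m, n)
  Lf <- matrix(0, m, r); Sf <- matrix(0, m, r); Y3f <- matrix(0, m, r)

  mu <- control$mu0
  xmax <- max(abs(X))
  xfro <- frob(X)
  converged <- FALSE
  it <- 0L
  LX <- matrix(0, m, n)

  while (it < control$max_iter) {
    it <- it + 1L

    J  <- svt(Z + Y2 / mu, 1 / mu)
    Sf <- svt_factor(Lf + Y3f / mu, 1 / mu)

    # Z <- (I + X'X)^{-1} (X'(X - LX - E) + J + (X'Y1 - Y2)/mu)
    T1 <- X - LX - E
    RZ <- VS %*% (crossprod(U, T1)) + J +
      (VS %*% crossprod(U, Y1) - Y2) / mu
    Z <- RZ - Wn %*% RZ

    # L <- ((X - XZ - E) X' + S + (Y1 X' - Y3)/mu) (I + XX')^{-1}, factored on U
    XZ <- X %*% Z
    B <- (X - XZ - E) %*% VS + Sf + (Y1 %*% VS - Y3f) / mu
    Lf <- B * rep(dinv, each = m)
    LX <- Lf %*% SVt

    E <- soft_threshold(X - XZ - LX + Y1 / mu, lambda / mu)

    R <- X - XZ - LX - E
    Y1 <- Y1 + mu * R
    Y2 <- Y2 + mu * (Z - J)
    Y3f <- Y3f + mu * (Lf - Sf)

    gap <- max(max(abs(R)), max(abs(Z - J)), frob(Lf - Sf))
    if (gap <= control$tol * xmax && frob(R) <= control$tol * xfro) {
      converged <- TRUE
      break
    }
    mu <- min(control$rho * mu, control$mu_max)
  }

  if (!converged) {
    warning(sprintf(
      "LatLRR did not reach tol = %g in %d iterations (gap %.3g); returning last iterate",
      control$tol, it, max(max(abs(X - X %*% Z - LX - E)), max(abs(Z - J)), frob(Lf - Sf))),
      call. = FALSE)
  }

  L <- Lf %*% t(U)
  E_l1 <- sum(abs(E))
  obj <- nuclear_norm_factor(Z) + nuclear_norm_factor(Lf) + lambda * E_l1
  structure(list(
    Z = Z, L = L, E = E,
    objective = obj,
    primal_residual = frob(X - X %*% Z - L %*% X - E) / xfro,
    E_l1 = E_l1,
    n_iter = it, converged = converged,
    lambda = lambda, control = control
  ), class = "latlrr")
}

# svt of A %*% t(U) (U orthonormal columns) expressed on the factor A:
# the SVD of A t(U) is Ua Sa (U Va)', so shrinking singular values of A
# shrinks those of A t(U).
svt_factor <- function(A, tau) {
  if (all(A == 0)) return(A)
  sv <- robust_svd(A)
  d <- pmax(sv$d - tau, 0)
  keep <- d > 0
  if (!any(keep)) return(matrix(0, nrow(A), ncol(A)))
  sv$u[, keep, drop = FALSE] %*% (d[keep] * t(sv$v[, keep, drop = FALSE]))
}

# nuclear norm via economy SVD of a (possibly skinny) matrix
nuclear_norm_factor <- function(A) {
  if (all(A == 0)) return(0)
  sum(robust_svd(A, nu = 0, nv = 0)$d)
}

#' LatLRR objective value
#'
#' \eqn{\|Z\|_* + \|L\|_* + \lambda \|E\|_1}, with nuclear norms computed
#' through [skinny_svd()].
#'
#' @param Z n x n coefficient matrix.
#' @param L m x m projection matrix.
#' @param E m x n sparse-noise matrix.
#' @param lambda Positive sparsity weight.
#' @return Nonnegative scalar.
#' @export
latlrr_objective <- function(Z, L, E, lambda) {
  check_finite_matrix(Z, "Z"); check_finite_matrix(L, "L")
  check_finite_matrix(E, "E")
  if (nrow(Z) != ncol(Z)) stop_invalid("'Z' must be square (n x n)")
  if (nrow(L) != ncol(L)) stop_invalid("'L' must be square (m x m)")
  if (nrow(E) != nrow(L) || ncol(E) != ncol(Z)) {
    stop_invalid("'E' must be m x n, conformable with L (m x m) and Z (n x n)")
  }
  sum(skinny_svd(Z)$d) + sum(skinny_svd(L)$d) + lambda * sum(abs(E))
}

#' Closed-form feasible point for the LatLRR constraint
#'
#' The shape-interaction point `Z = VV'` from the skinny SVD of `X`, with
#' `L = 0`, `E = 0`, satisfies `X = XZ` exactly; its objective equals the
#' rank of `X`. Used as an optimality upper bound for [fit_latlrr()].
#'
#' @param X Numeric matrix (m x n).
#' @return List with `Z`, `L`, `E` and `objective` (= rank of `X`).
#' @export
feasible_baseline <- function(X) {
  check_finite_matrix(X, "X")
  sv <- skinny_svd(X)
  list(Z = tcrossprod(sv$v),
       L = matrix(0, nrow(X), nrow(X)),
       E = matrix(0, nrow(X), ncol(X)),
       objective = sv$rank)
}

#' @export
print.latlrr <- function(x, ...) {
  cat(sprintf("Latent low-rank representation (lambda = %g)\n", x$lambda))
  cat(sprintf("  Z: %d x %d, L: %d x %d, E: %d x %d\n",
              nrow(x$Z), ncol(x$Z), nrow(x$L), ncol(x$L),
              nrow(x$E), ncol(x$E)))
  cat(sprintf("  objective ||Z||* + ||L||* + lambda||E||1 = %.6g\n", x$objective))
  cat(sprintf("  ||E||1 = %.6g, primal residual = %.3g\n",
              x$E_l1, x$primal_residual))
  cat(sprintf("  %s after %d iterations\n",
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  invisible(x)
}

#' Save / load a LatLRR decomposition
#'
#' The archive is an RDS file holding the decomposition list unchanged
#' (keys `Z`, `L`, `E`, `objective`, `primal_residual`, `E_l1`, `n_iter`,
#' `converged`, `lambda`, `control`); it round-trips bit-exactly.
#'
#' @param x A `"latlrr"` object.
#' @param path File path.
#' @return `load_latlrr` returns the `"latlrr"` object.
#' @export
save_latlrr <- function(x, path) {
  stopifnot(inherits(x, "latlrr"))
  saveRDS(x, path)
  invisible(path)
}

#' @rdname save_latlrr
#' @export
load_latlrr <- function(path) {
  x <- readRDS(path)
  if (!inherits(x, "latlrr")) stop_invalid("'path' does not hold a latlrr archive")
  x
}
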