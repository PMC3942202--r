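#' @keywords internal
#' @importFrom stats predict rnorm
#' @importFrom Rcpp evalCpp
#' @useDynLib srclatlrr, .registration = TRUE
"_PACKAGE"

# Run `code` with the RNG seeded to `seed`, restoring the caller's RNG state.
local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

stop_invalid <- function(...) {
  stop(..., call. = FALSE)
}

check_finite_matrix <- function(M, name = "M") {
  if (!is.matrix(M) || !is.numeric(M)) {
    stop_invalid(sprintf("'%s' must be a numeric matrix", name))
  }
  if (!all(is.finite(M))) {
    stop_invalid(sprintf("'%s' contains non-finite entries", name))
  }
  invisible(M)
}

frob <- function(M) sqrt(sum(M^2))

# svd() with fallbacks: LAPACK's divide-and-conquer routine (dgesdd) can
# fail sporadically on valid input; retry on the transpose, then via the
# QR-based route, before giving up.
robust_svd <- function(M, nu = min(dim(M)), nv = min(dim(M))) {
  tryCatch(svd(M, nu = nu, nv = nv), error = function(e1) {
    tryCatch({
      sv <- svd(t(M), nu = nv, nv = nu)
      list(d = sv$d, u = sv$v, v = sv$u)
    }, error = function(e2) {
      qrM <- qr(M)
      R <- qr.R(qrM)
      sv <- svd(R, nu = min(dim(R)), nv = nv)
      u <- qr.Q(qrM) %*% sv$u
      list(d = sv$d, u = u[, seq_len(nu), drop = FALSE], v = sv$v)
    })
  })
}
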