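#' Column l2 normalization
#'
#' Scales every column of a genes-by-samples matrix to unit l2 norm and
#' records the original norms (needed to apply the same convention to test
#' samples and to report scale).
#'
#' @param X Numeric matrix (m x n).
#' @return List with `X` (normalized matrix) and `norms` (original column
#'   l2 norms, named by sample when column names are present).
#' @export
normalize_columns <- function(X) {
  check_finite_matrix(X, "X")
  norms <- sqrt(colSums(X^2))
  zero <- which(norms == 0)
  if (length(zero)) {
    ids <- if (!is.null(colnames(X))) colnames(X)[zero] else as.character(zero)
    stop_invalid("all-zero column(s): ", paste(ids, collapse = ", "))
  }
  Xn <- sweep(X, 2, norms, "/")
  if (!is.null(colnames(X))) names(norms) <- colnames(X)
  list(X = Xn, norms = norms)
}

#' Sparse-representation tumor classifier with optional LatLRR denoising
#'
#' Fits a sparse-representation classifier (SRC) on a genes-by-samples
#' training matrix. For `method = "src-latlrr"`, the normalized training
#' matrix is first decomposed by latent low-rank representation
#' (`X = XZ + LX + E`, see [fit_latlrr()]); the salient-feature component
#' `D = LX` becomes the classification dictionary and the projector `L` is
#' stored so test samples can be mapped to the same feature space (`Ly`).
#' For `method = "src"` the dictionary is the normalized training matrix
#' itself and `L` is the identity.
#'
#' @param x Numeric matrix, genes in rows, samples in columns. Row and
#'   column names, when present, are kept as gene and sample identifiers.
#' @param labels Class labels, one per sample (character or factor, at
#'   least 2 distinct classes, each with at least one sample).
#' @param method `"src-latlrr"` (default) or `"src"`.
#' @param lambda Positive LatLRR sparsity weight (ignored for
#'   `method = "src"`). Smaller values move more signal into the noise
#'   term `E`; see [lambda_sweep()] for tuning.
#' @param control [latlrr_control()] solver settings.
#' @return Object of class `"srclatlrr"`: a list with `method`, `D`
#'   (dictionary, m x n), `L` (projector, m x m; identity for src),
#'   `labels` (per-column classes), `classes` (sorted class set used for
#'   residual ordering and tie-breaks), `gene_ids`, `sample_ids`, `norms`
#'   (original training column norms), `lambda`, and `latlrr`
#'   (decomposition diagnostics: `objective`, `primal_residual`, `E_l1`,
#'   `n_iter`, `converged`; `NULL` for src).
#' @examples
#' sim <- generate_subspace_data(n_genes = 60, n_per_class = 8, seed = 1)
#' fit <- srclatlrr(sim$x, sim$labels, method = "src")
#' predict(fit, sim$x[, 1])
#' @seealso [predict.srclatlrr()], [cross_validate()], [bw_ratio()]
#' @export
srclatlrr <- function(x, labels, method = c("src-latlrr", "src"),
                      lambda = 0.1, control = latlrr_control()) {
  method <- match.arg(method)
  if (!is.matrix(x)) x <- as.matrix(x)
  check_finite_matrix(x, "x")
  labels <- as.character(labels)
  if (length(labels) != ncol(x)) {
    stop_invalid("'labels' must have one entry per sample (column)")
  }
  classes <- sort(unique(labels))
  if (length(classes) < 2) {
    stop_invalid("training data must contain at least 2 classes")
  }

  nm <- normalize_columns(x)
  Xn <- nm$X
  m <- nrow(Xn)

  if (method == "src-latlrr") {
    dec <- fit_latlrr(Xn, lambda = lambda, control = control)
    L <- dec$L
    D <- L %*% Xn
    meta <- dec[c("objective", "primal_residual", "E_l1", "n_iter", "converged")]
  } else {
    L <- diag(m)
    D <- Xn
    meta <- NULL
  }

  structure(list(
    method = method, D = D, L = L,
    labels = labels, classes = classes,
    gene_ids = rownames(x), sample_ids = colnames(x),
    norms = nm$norms,
    lambda = if (method == "src-latlrr") lambda else NA_real_,
    latlrr = meta
  ), class = "srclatlrr")
}

#' Classify test samples by minimum class residual
#'
#' Each test column `y` is l2-normalized, projected to `Ly`, sparse-coded
#' over the dictionary (`min_x ||Dx - Ly||^2 + lambda ||x||_1`,
#' [solve_l1ls()]), and assigned the class `i` minimizing the residual
#' \eqn{r_i(y) = \|Ly - D\delta_i(x)\|_2}, where \eqn{\delta_i} keeps only
#' the coefficients of class `i`. Exact residual ties are broken by the
#' smallest class in the model's sorted class order.
#'
#' @param object A fitted [srclatlrr()] model.
#' @param newdata Numeric vector (one sample) or matrix with samples in
#'   columns; rows must match the training genes (by rowname when both
#'   sides are named, otherwise by position).
#' @param lambda Positive sparse-coding weight (default 0.01).
#' @param tol KKT tolerance passed to [solve_l1ls()].
#' @param ... Unused.
#' @return Object of class `"srclatlrr_prediction"`: list with `class`
#'   (predicted class per sample), `residuals` (samples x classes matrix),
#'   `codes` (list of [solve_l1ls()] results) and `projected` (matrix of
#'   `Ly` columns).
#' @export
predict.srclatlrr <- function(object, newdata, lambda = 0.01, tol = 1e-6, ...) {
  Y <- if (is.matrix(newdata)) newdata else
    matrix(newdata, ncol = 1,
           dimnames = list(names(newdata), NULL))
  if (!is.numeric(Y)) stop_invalid("'newdata' must be numeric")
  if (!all(is.finite(Y))) stop_invalid("'newdata' contains non-finite entries")
  m <- nrow(object$D)
  if (nrow(Y) != m) {
    stop_invalid(sprintf(
      "test samples have %d genes but the model expects %d", nrow(Y), m))
  }
  if (!is.null(rownames(Y)) && !is.null(object$gene_ids) &&
      !identical(rownames(Y), object$gene_ids)) {
    if (!setequal(rownames(Y), object$gene_ids)) {
      stop_invalid("test gene ids do not match the model's genes")
    }
    Y <- Y[object$gene_ids, , drop = FALSE]
  }

  q <- ncol(Y)
  classes <- object$classes
  res <- matrix(NA_real_, q, length(classes),
                dimnames = list(colnames(Y), classes))
  pred <- character(q)
  codes <- vector("list", q)
  proj <- matrix(NA_real_, m, q, dimnames = list(object$gene_ids, colnames(Y)))
  src_identity <- object$method == "src"

  for (i in seq_len(q)) {
    y <- Y[, i]
    ny <- sqrt(sum(y^2))
    if (ny == 0) {
      id <- if (!is.null(colnames(Y))) colnames(Y)[i] else as.character(i)
      stop_invalid("all-zero test sample: ", id)
    }
    y <- y / ny
    Ly <- if (src_identity) y else drop(object$L %*% y)
    code <- solve_l1ls(object$D, Ly, lambda = lambda, tol = tol)
    for (k in seq_along(classes)) {
      rk <- Ly - drop(object$D %*% delta_mask(code$x, object$labels, classes[k]))
      res[i, k] <- sqrt(sum(rk^2))
    }
    pred[i] <- classes[which.min(res[i, ])]  # first minimum = lowest class
    codes[[i]] <- code
    proj[, i] <- Ly
  }

  structure(list(class = pred, residuals = res, codes = codes,
                 projected = proj, lambda = lambda),
            class = "srclatlrr_prediction")
}

#' @export
print.srclatlrr_prediction <- function(x, ...) {
  n <- length(x$class)
  cat(sprintf("srclatlrr predictions for %d sample(s) (lambda = %g)\n",
              n, x$lambda))
  df <- data.frame(predicted = x$class, round(x$residuals, 4),
                   check.names = FALSE)
  print(utils::head(df, 10))
  if (n > 10) cat(sprintf("... %d more\n", n - 10))
  invisible(x)
}

#' @export
print.srclatlrr <- function(x, ...) {
  cat(sprintf("Sparse-representation classifier (%s)\n", x$method))
  cat(sprintf("  dictionary: %d genes x %d training samples, %d classes (%s)\n",
              nrow(x$D), ncol(x$D), length(x$classes),
              paste(x$classes, collapse = ", ")))
  if (!is.null(x$latlrr)) {
    cat(sprintf("  LatLRR: lambda = %g, ||E||1 = %.4g, primal residual %.3g (%s, %d iter)\n",
                x$lambda, x$latlrr$E_l1, x$latlrr$primal_residual,
                if (x$latlrr$converged) "converged" else "not converged",
                x$latlrr$n_iter))
  }
  invisible(x)
}

#' @export
summary.srclatlrr <- function(object, ...) {
  counts <- table(object$labels)
  cat(sprintf("Sparse-representation classifier (%s)\n", object$method))
  cat(sprintf("  %d genes, %d training samples\n",
              nrow(object$D), ncol(object$D)))
  cat("  class sizes:\n")
  for (cl in object$classes) {
    cat(sprintf("    %s: %d\n", cl, counts[[cl]]))
  }
  if (!is.null(object$latlrr)) {
    cat(sprintf("  LatLRR decomposition: objective %.6g, ||E||1 = %.6g,\n",
                object$latlrr$objective, object$latlrr$E_l1))
    cat(sprintf("    primal residual %.3g after %d iterations (%s)\n",
                object$latlrr$primal_residual, object$latlrr$n_iter,
                if (object$latlrr$converged) "converged" else "not converged"))
  }
  invisible(object)
}

#' Save / load a fitted classifier
#'
#' The archive is an RDS file with the model list unchanged (documented
#' keys: `method`, `D`, `L`, `labels`, `classes`, `gene_ids`,
#' `sample_ids`, `norms`, `lambda`, `latlrr`); predictions after a
#' round-trip are bit-identical.
#'
#' @param model A `"srclatlrr"` object.
#' @param path File path.
#' @return `load_model` returns the `"srclatlrr"` object.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "srclatlrr"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  x <- readRDS(path)
  if (!inherits(x, "srclatlrr")) stop_invalid("'path' does not hold a model archive")
  x
}
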