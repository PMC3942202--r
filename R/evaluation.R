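#' Stratified k-fold partition
#'
#' Splits samples into `k` folds preserving class proportions: within each
#' class the sample indices are shuffled (deterministically from `seed`)
#' and dealt round-robin to the folds, so every fold's class count differs
#' from the proportional share by at most one.
#'
#' @param labels Class labels, one per sample.
#' @param k Number of folds, `2 <= k <=` smallest class size.
#' @param seed Integer seed; the caller's RNG state is left untouched.
#' @return List of `k` elements, each `list(train =, test =)` of integer
#'   indices; the test sets partition `seq_along(labels)`.
#' @export
stratified_kfold <- function(labels, k, seed = 1L) {
  labels <- as.character(labels)
  n <- length(labels)
  if (!is.numeric(k) || length(k) != 1 || k != round(k) || k < 2) {
    stop_invalid("'k' must be an integer >= 2")
  }
  counts <- table(labels)
  small <- names(counts)[which.min(counts)]
  if (k > min(counts)) {
    stop_invalid(sprintf(
      "k = %d exceeds the size of the smallest class ('%s', %d samples)",
      k, small, min(counts)))
  }
  fold_of <- integer(n)
  local_seed(seed, {
    for (cl in sort(unique(labels))) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      fold_of[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  lapply(seq_len(k), function(f) {
    list(train = which(fold_of != f), test = which(fold_of == f))
  })
}

#' Stratified cross-validation of the classifier
#'
#' Runs stratified k-fold cross-validation of [srclatlrr()]: within each
#' fold, genes are optionally reduced by BW selection (on the training
#' fold only unless `global_selection = TRUE`), the model is fitted on the
#' training fold and every held-out sample is classified. The projector
#' `L` and the gene selection never see the test fold (no leakage) unless
#' global selection is explicitly requested.
#'
#' @param x Genes x samples matrix.
#' @param labels Class labels, one per sample.
#' @param k Number of folds (default 10).
#' @param seed Fold-assignment seed.
#' @param method `"src-latlrr"` or `"src"`.
#' @param lambda_latlrr LatLRR sparsity weight (used for src-latlrr).
#' @param lambda_src Sparse-coding weight for prediction.
#' @param n_genes Optional number of BW-selected genes; `NULL` keeps all.
#' @param global_selection If `TRUE`, BW scores are computed once on the
#'   full data (mimics whole-dataset selection; leaks label information
#'   across folds — off by default).
#' @param control [latlrr_control()] solver settings.
#' @return Object of class `"srclatlrr_cv"`: list with `pooled_accuracy`
#'   (total correct / total samples), `fold_accuracy`, `predictions`
#'   (data.frame: sample, fold, truth, predicted, correct),
#'   `fold_diagnostics` (per-fold LatLRR `E_l1`, `objective`,
#'   `primal_residual`, `converged`; NULL for src) and `config`.
#' @export
cross_validate <- function(x, labels, k = 10, seed = 1L,
                           method = c("src-latlrr", "src"),
                           lambda_latlrr = 0.1, lambda_src = 0.01,
                           n_genes = NULL, global_selection = FALSE,
                           control = latlrr_control()) {
  method <- match.arg(method)
  if (!is.matrix(x)) x <- as.matrix(x)
  check_finite_matrix(x, "x")
  labels <- as.character(labels)
  if (length(labels) != ncol(x)) {
    stop_invalid("'labels' must have one entry per sample (column)")
  }
  folds <- stratified_kfold(labels, k, seed)
  sample_ids <- if (!is.null(colnames(x))) colnames(x) else
    as.character(seq_len(ncol(x)))

  global_keep <- NULL
  if (!is.null(n_genes) && global_selection) {
    sc <- bw_ratio(x, labels)
    global_keep <- select_top_genes(x, sc, n_genes)$gene_ids
  }

  pred_rows <- vector("list", length(folds))
  fold_acc <- numeric(length(folds))
  fold_diag <- vector("list", length(folds))

  for (f in seq_along(folds)) {
    tr <- folds[[f]]$train
    te <- folds[[f]]$test
    xtr <- x[, tr, drop = FALSE]
    xte <- x[, te, drop = FALSE]
    if (!is.null(n_genes)) {
      if (global_selection) {
        keep <- global_keep
        xtr <- xtr[keep, , drop = FALSE]
        xte <- xte[keep, , drop = FALSE]
      } else {
        sc <- bw_ratio(xtr, labels[tr])
        sel <- select_top_genes(xtr, sc, n_genes)
        xtr <- sel$X
        xte <- xte[sel$gene_ids, , drop = FALSE]
      }
    }
    fit <- srclatlrr(xtr, labels[tr], method = method,
                     lambda = lambda_latlrr, control = control)
    pr <- predict(fit, xte, lambda = lambda_src)
    correct <- pr$class == labels[te]
    fold_acc[f] <- mean(correct)
    pred_rows[[f]] <- data.frame(
      sample = sample_ids[te], fold = f,
      truth = labels[te], predicted = pr$class,
      correct = correct, stringsAsFactors = FALSE)
    fold_diag[[f]] <- if (method == "src-latlrr") fit$latlrr else NULL
  }

  predictions <- do.call(rbind, pred_rows)
  rownames(predictions) <- NULL
  structure(list(
    pooled_accuracy = mean(predictions$correct),
    fold_accuracy = fold_acc,
    predictions = predictions,
    fold_diagnostics = fold_diag,
    config = list(k = k, seed = seed, method = method,
                  lambda_latlrr = lambda_latlrr, lambda_src = lambda_src,
                  n_genes = n_genes, global_selection = global_selection,
                  control = unclass(control))
  ), class = "srclatlrr_cv")
}

#' @export
print.srclatlrr_cv <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Stratified %d-fold cross-validation (%s)\n", cfg$k, cfg$method))
  cat(sprintf("  pooled accuracy: %.4f (%d/%d)\n", x$pooled_accuracy,
              sum(x$predictions$correct), nrow(x$predictions)))
  cat(sprintf("  per-fold: %s\n",
              paste(sprintf("%.3f", x$fold_accuracy), collapse = " ")))
  invisible(x)
}

#' @export
summary.srclatlrr_cv <- function(object, ...) {
  print(object)
  tab <- table(truth = object$predictions$truth,
               predicted = object$predictions$predicted)
  cat("  confusion (truth x predicted):\n")
  print(tab)
  invisible(object)
}

#' Accuracy / removed-noise curve over the LatLRR lambda grid
#'
#' Runs [cross_validate()] once per `lambda` value, reusing the same fold
#' assignment (same `seed`) so the curves isolate the effect of lambda.
#' Reports, per lambda, the pooled accuracy and the mean `||E||_1` of the
#' per-fold LatLRR decompositions — the "amount of noise removed", which
#' is non-increasing in lambda.
#'
#' @param x,labels,k,seed,lambda_src,n_genes,global_selection,control As
#'   in [cross_validate()] (method is fixed to `"src-latlrr"`).
#' @param lambdas Strictly increasing positive LatLRR weights.
#' @return Data.frame of class `"srclatlrr_sweep"` with columns `lambda`,
#'   `accuracy`, `mean_E_l1`; the full CV reports are kept in
#'   `attr(, "reports")`.
#' @export
lambda_sweep <- function(x, labels, lambdas, k = 10, seed = 1L,
                         lambda_src = 0.01, n_genes = NULL,
                         global_selection = FALSE,
                         control = latlrr_control()) {
  lambdas <- as.numeric(lambdas)
  if (length(lambdas) < 1) stop_invalid("'lambdas' must be non-empty")
  if (any(lambdas <= 0) || any(diff(lambdas) <= 0)) {
    stop_invalid("'lambdas' must be strictly increasing positive values")
  }
  reports <- lapply(lambdas, function(lam) {
    cross_validate(x, labels, k = k, seed = seed, method = "src-latlrr",
                   lambda_latlrr = lam, lambda_src = lambda_src,
                   n_genes = n_genes, global_selection = global_selection,
                   control = control)
  })
  out <- data.frame(
    lambda = lambdas,
    accuracy = vapply(reports, function(r) r$pooled_accuracy, numeric(1)),
    mean_E_l1 = vapply(reports, function(r) {
      mean(vapply(r$fold_diagnostics, function(d) d$E_l1, numeric(1)))
    }, numeric(1)))
  structure(out, class = c("srclatlrr_sweep", "data.frame"),
            reports = reports)
}

#' Plot an accuracy / noise-level sweep
#'
#' Two-axis base-graphics plot: pooled CV accuracy (left axis) and mean
#' removed noise `||E||_1` (right axis) against lambda on a log scale.
#'
#' @param x A [lambda_sweep()] table.
#' @param ... Passed to [plot()].
#' @export
plot.srclatlrr_sweep <- function(x, ...) {
  op <- graphics::par(mar = c(5, 4, 2, 4))
  on.exit(graphics::par(op))
  plot(x$lambda, x$accuracy, type = "b", log = "x", pch = 19,
       xlab = expression(lambda), ylab = "pooled CV accuracy",
       ylim = c(0, 1), ...)
  graphics::par(new = TRUE)
  plot(x$lambda, x$mean_E_l1, type = "b", log = "x", pch = 1, lty = 2,
       axes = FALSE, xlab = "", ylab = "")
  graphics::axis(4)
  graphics::mtext(expression("mean " * group("||", E, "||")[1]),
                  side = 4, line = 2.5)
  graphics::legend("left", legend = c("accuracy", "removed noise"),
                   pch = c(19, 1), lty = c(1, 2), bty = "n")
  invisible(x)
}
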