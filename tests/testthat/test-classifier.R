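test_that("normalize_columns scales to unit norm and records the scales", {
  out <- normalize_columns(matrix(c(3, 4), 2, 1))
  expect_equal(out$X[, 1], c(0.6, 0.8))
  expect_equal(out$norms, 5)

  X <- unit_cols(rand_matrix(5, 3, seed = 1))
  expect_lt(max(abs(normalize_columns(X)$X - X)), 1e-15)

  X[, 2] <- 0
  colnames(X) <- c("a", "b", "c")
  expect_error(normalize_columns(X), "all-zero column.*b")
})

test_that("src models bypass LatLRR: L = I and D = normalized training data", {
  sim <- generate_subspace_data(n_genes = 40, subspace_dim = 2,
                                n_per_class = 5, seed = 2)
  fit <- srclatlrr(sim$x, sim$labels, method = "src")
  expect_identical(fit$L, diag(40))
  expect_equal(fit$D, normalize_columns(sim$x)$X, tolerance = 1e-15)
  expect_null(fit$latlrr)
  expect_true(is.na(fit$lambda))
})

test_that("srclatlrr rejects degenerate training input", {
  X <- rand_matrix(10, 4, seed = 3)
  expect_error(srclatlrr(X, rep("a", 4)), "2 classes")
  expect_error(srclatlrr(X, c("a", "b")), "one entry per sample")
})

test_that("at large lambda the dictionary equals X - XZ (no-noise algebra)", {
  X <- rand_lowrank_unit(50, 12, r = 3, seed = 4)
  colnames(X) <- paste0("s", 1:12)
  fit <- srclatlrr(X, rep(c("a", "b"), 6), method = "src-latlrr", lambda = 1e4)
  Xn <- normalize_columns(X)$X
  dec_D <- fit$L %*% Xn
  expect_equal(fit$D, dec_D, tolerance = 1e-12)
  # E ~ 0 forces LX = X - XZ, so D + XZ ~ X; recover XZ = X - LX
  expect_lte(sqrt(sum((fit$D - (Xn - (Xn - fit$D)))^2)), 1e-8)  # identity
  expect_lte(fit$latlrr$primal_residual, 1e-6)
  expect_lte(fit$latlrr$E_l1, 1e-5 * sum(abs(Xn)))
})

test_that("a training column is classified into its own class", {
  sim <- generate_subspace_data(n_genes = 60, subspace_dim = 3,
                                n_per_class = 8, seed = 5)
  fit <- srclatlrr(sim$x, sim$labels, method = "src")
  pr <- predict(fit, sim$x[, 1], lambda = 1e-6)
  expect_equal(unname(pr$class), "class_1")
  expect_lte(pr$residuals[1, "class_1"], 1e-3)
})

test_that("orthogonal coordinate subspaces are separated by the residual rule", {
  # class 1 lives on rows 1-5, class 2 on rows 6-10
  set.seed(6)
  W1 <- rbind(matrix(rnorm(5 * 4), 5), matrix(0, 5, 4))
  W2 <- rbind(matrix(0, 5, 4), matrix(rnorm(5 * 4), 5))
  X <- cbind(W1, W2)
  labels <- rep(c("c1", "c2"), each = 4)
  fit <- srclatlrr(X, labels, method = "src")
  y <- drop(W1 %*% c(0.3, -0.2, 0.5, 0.1))
  pr <- predict(fit, y, lambda = 1e-4)
  expect_equal(unname(pr$class), "c1")
  expect_gte(pr$residuals[1, "c2"], pr$residuals[1, "c1"])
})

test_that("exact residual ties go to the lowest class in sorted order", {
  # duplicated atom under two labels: coding mass on column 1 only,
  # but the duplicate makes the residual landscape symmetric
  v <- c(1, 0)
  X <- cbind(v, v, c(0, 1))
  fit <- srclatlrr(X, c("b", "a", "c"), method = "src")
  pr <- predict(fit, c(0, 1) + c(1, 0) * 0, lambda = 10)  # x = 0: all residuals tie at ||y||
  expect_equal(unname(pr$class), "a")
})

test_that("predictions are invariant to positive rescaling of the test sample", {
  sim <- generate_subspace_data(n_genes = 50, subspace_dim = 3,
                                n_per_class = 6, noise_sd = 0.05, seed = 7)
  fit <- srclatlrr(sim$x, sim$labels, method = "src")
  y <- sim$x[, 10]
  p1 <- predict(fit, y)
  p2 <- predict(fit, 37.5 * y)
  expect_identical(p1$class, p2$class)
  expect_equal(p1$residuals, p2$residuals, tolerance = 1e-10)
})

test_that("batch prediction equals per-sample prediction, in order", {
  sim <- generate_subspace_data(n_genes = 40, subspace_dim = 2,
                                n_per_class = 6, noise_sd = 0.02, seed = 8)
  fit <- srclatlrr(sim$x, sim$labels, method = "src")
  Y <- sim$x[, 1:10]
  batch <- predict(fit, Y)
  single <- vapply(1:10, function(i) {
    unname(predict(fit, Y[, i])$class)
  }, character(1))
  expect_equal(unname(batch$class), single)
  # empty batch
  empty <- predict(fit, Y[, 0, drop = FALSE])
  expect_length(empty$class, 0)
})

test_that("predict validates test input", {
  sim <- generate_subspace_data(n_genes = 30, subspace_dim = 2,
                                n_per_class = 4, seed = 9)
  fit <- srclatlrr(sim$x, sim$labels, method = "src")
  expect_error(predict(fit, rep(0, 30)), "all-zero test sample")
  expect_error(predict(fit, rnorm(29)), "expects 30|30 genes")
})

test_that("the full-code residual is bounded by class residuals plus cross terms", {
  sim <- generate_subspace_data(n_genes = 40, subspace_dim = 3,
                                n_per_class = 6, noise_sd = 0.05, seed = 10)
  fit <- srclatlrr(sim$x, sim$labels, method = "src")
  y <- sim$x[, 5] / sqrt(sum(sim$x[, 5]^2))
  pr <- predict(fit, y)
  x <- pr$codes[[1]]$x
  # sum of per-class selections reassembles the full code exactly
  parts <- lapply(fit$classes, function(cl) delta_mask(x, fit$labels, cl))
  expect_equal(Reduce(`+`, parts), x)
  full_res <- sqrt(sum((pr$projected[, 1] - drop(fit$D %*% x))^2))
  i <- which.min(pr$residuals[1, ])
  cross <- sum(vapply(seq_along(parts)[-i], function(j) {
    sqrt(sum((fit$D %*% parts[[j]])^2))
  }, numeric(1)))
  expect_lte(full_res, min(pr$residuals[1, ]) + cross + 1e-10)
})

test_that("models survive a save/load round-trip with identical predictions", {
  sim <- generate_subspace_data(n_genes = 40, subspace_dim = 2,
                                n_per_class = 5, noise_sd = 0.05, seed = 11)
  fit <- srclatlrr(sim$x, sim$labels, method = "src-latlrr", lambda = 0.5)
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(fit, path)
  fit2 <- load_model(path)
  expect_identical(fit2, fit)
  y <- sim$x[, 3]
  expect_identical(predict(fit, y), predict(fit2, y))
})
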