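test_that("stratified folds partition samples and preserve class balance", {
  labels <- rep(c("A", "B"), each = 5)
  folds <- stratified_kfold(labels, k = 5, seed = 1)
  for (f in folds) {
    expect_equal(sum(labels[f$test] == "A"), 1)
    expect_equal(sum(labels[f$test] == "B"), 1)
    expect_setequal(c(f$train, f$test), seq_along(labels))
  }
  tests <- unlist(lapply(folds, `[[`, "test"))
  expect_setequal(tests, seq_along(labels))
  expect_equal(length(tests), length(unique(tests)))

  # determinism and seed sensitivity
  expect_identical(folds, stratified_kfold(labels, k = 5, seed = 1))
  labels2 <- rep(c("A", "B"), each = 50)
  expect_false(identical(stratified_kfold(labels2, 5, seed = 1),
                         stratified_kfold(labels2, 5, seed = 2)))

  # uneven classes: fold proportions within +/- 1 sample per class
  labels3 <- c(rep("A", 13), rep("B", 7))
  for (f in stratified_kfold(labels3, 3, seed = 3)) {
    expect_lte(abs(sum(labels3[f$test] == "A") - 13 / 3), 1)
    expect_lte(abs(sum(labels3[f$test] == "B") - 7 / 3), 1)
  }

  expect_error(stratified_kfold(labels, k = 6, seed = 1),
               "smallest class.*'A'|'A'.*5")
})

test_that("cross-validation separates noiseless subspace classes perfectly", {
  sim <- generate_subspace_data(n_genes = 80, subspace_dim = 3,
                                n_per_class = 10, seed = 21)
  cv <- cross_validate(sim$x, sim$labels, k = 5, seed = 21, method = "src")
  expect_equal(cv$pooled_accuracy, 1.0)
  # per-sample records cover every sample exactly once
  expect_setequal(cv$predictions$sample, colnames(sim$x))
  expect_equal(nrow(cv$predictions), ncol(sim$x))
})

test_that("shuffled labels give chance-level accuracy", {
  sim <- generate_subspace_data(n_classes = 2, n_genes = 60, subspace_dim = 3,
                                n_per_class = 20, noise_sd = 0.1, seed = 22)
  set.seed(23)
  shuffled <- sample(sim$labels)
  cv <- cross_validate(sim$x, shuffled, k = 5, seed = 23, method = "src")
  expect_gte(cv$pooled_accuracy, 0.3)
  expect_lte(cv$pooled_accuracy, 0.7)
})

test_that("the smallest stratified case (k = 2, two classes of two) works", {
  set.seed(24)
  X <- matrix(rnorm(20 * 4), 20)
  colnames(X) <- paste0("s", 1:4)
  labels <- c("a", "a", "b", "b")
  cv <- cross_validate(X, labels, k = 2, seed = 24, method = "src")
  expect_equal(nrow(cv$predictions), 4)
  expect_setequal(cv$predictions$sample, colnames(X))
  expect_length(cv$fold_accuracy, 2)
})

test_that("pooled accuracy equals the fold mean for equal-sized folds", {
  sim <- generate_subspace_data(n_genes = 60, subspace_dim = 3,
                                n_per_class = 10, noise_sd = 0.2, seed = 25)
  cv <- cross_validate(sim$x, sim$labels, k = 5, seed = 25, method = "src")
  expect_equal(cv$pooled_accuracy, mean(cv$fold_accuracy), tolerance = 1e-12)
})

test_that("no test sample is seen by the model that classifies it", {
  labels <- rep(c("A", "B", "C"), each = 9)
  folds <- stratified_kfold(labels, k = 3, seed = 26)
  for (f in folds) {
    expect_length(intersect(f$train, f$test), 0)
  }
})

test_that("per-fold BW selection runs inside cross-validation", {
  sim <- generate_de_genes_data(n_genes = 200, n_per_class = 10,
                                n_informative = 20, shift = 3, seed = 27)
  cv <- cross_validate(sim$x, sim$labels, k = 5, seed = 27, method = "src",
                       n_genes = 30)
  expect_gte(cv$pooled_accuracy, 0.9)
  cvg <- cross_validate(sim$x, sim$labels, k = 5, seed = 27, method = "src",
                        n_genes = 30, global_selection = TRUE)
  expect_gte(cvg$pooled_accuracy, 0.9)
})

test_that("lambda_sweep reuses folds and reports non-increasing noise", {
  sim <- generate_subspace_data(n_classes = 2, n_genes = 50, subspace_dim = 3,
                                n_per_class = 8, corrupt_frac = 0.05,
                                corrupt_magnitude = 0.5, seed = 28)
  sw <- lambda_sweep(sim$x, sim$labels, lambdas = c(0.05, 0.5, 5), k = 4,
                     seed = 28)
  expect_equal(sw$lambda, c(0.05, 0.5, 5))
  expect_true(all(diff(sw$mean_E_l1) <= 1e-6))

  # single-lambda sweep equals a plain cross_validate run
  sw1 <- lambda_sweep(sim$x, sim$labels, lambdas = 0.5, k = 4, seed = 28)
  cv <- cross_validate(sim$x, sim$labels, k = 4, seed = 28,
                       method = "src-latlrr", lambda_latlrr = 0.5)
  expect_equal(sw1$accuracy, cv$pooled_accuracy)
  expect_equal(sw1$mean_E_l1,
               mean(sapply(cv$fold_diagnostics, `[[`, "E_l1")))

  expect_error(lambda_sweep(sim$x, sim$labels, numeric(0)), "non-empty")
  expect_error(lambda_sweep(sim$x, sim$labels, c(0.5, 0.1)), "increasing")
})

test_that("identical seed and config give bit-identical CV reports", {
  sim <- generate_subspace_data(n_genes = 50, subspace_dim = 3,
                                n_per_class = 8, noise_sd = 0.1, seed = 29)
  cv1 <- cross_validate(sim$x, sim$labels, k = 4, seed = 29,
                        method = "src-latlrr", lambda_latlrr = 0.5)
  cv2 <- cross_validate(sim$x, sim$labels, k = 4, seed = 29,
                        method = "src-latlrr", lambda_latlrr = 0.5)
  expect_identical(cv1, cv2)
})
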