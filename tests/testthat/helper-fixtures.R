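# Shared fixture builders; all randomness goes through an explicit seed.

rand_matrix <- function(m, n, seed) {
  set.seed(seed)
  matrix(rnorm(m * n), m, n)
}

# low-rank matrix with unit-l2 columns
rand_lowrank_unit <- function(m, n, r, seed) {
  set.seed(seed)
  A <- matrix(rnorm(m * r), m) %*% matrix(rnorm(r * n), r)
  sweep(A, 2, sqrt(colSums(A^2)), "/")
}

unit_cols <- function(M) sweep(M, 2, sqrt(colSums(M^2)), "/")

rnorm_fixed <- function(n, seed) {
  set.seed(seed)
  rnorm(n)
}
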