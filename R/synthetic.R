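#' Union-of-subspaces expression-like data
#'
#' Generates a genes-by-samples matrix whose classes lie on distinct
#' low-dimensional linear subspaces — the structure the sparse
#' representation model assumes — optionally corrupted by dense Gaussian
#' noise and sparse gross "spikes" (the `E` of the LatLRR model). Class
#' bases are orthonormal (QR of i.i.d. normals); with
#' `orthogonal_classes = TRUE` (default) one shared basis is drawn and
#' partitioned so the class subspaces are mutually orthogonal.
#'
#' Defaults mirror the regime the method targets: many more genes than
#' samples, a few classes of tens of samples each on 4-dimensional
#' subspaces.
#'
#' @param n_classes Number of classes k.
#' @param subspace_dim Dimension d of each class subspace (`d < n_genes`).
#' @param n_genes Number of genes m.
#' @param n_per_class Samples per class.
#' @param noise_sd Standard deviation of dense Gaussian noise (0 = none).
#' @param corrupt_frac Fraction of matrix entries receiving sparse spikes,
#'   in `[0, 1)`; exactly `round(corrupt_frac * m * n)` entries are hit.
#' @param corrupt_magnitude Absolute spike size; signs are random.
#' @param orthogonal_classes Draw mutually orthogonal class subspaces.
#' @param seed Integer seed; output is bit-reproducible.
#' @return List with `x` (m x n matrix, dimnames `gene_*` / `sample_*`),
#'   `labels` (character vector `class_1..class_k`, one per column) and
#'   `truth`: `bases` (list of m x d orthonormal matrices), `clean`,
#'   `noise`, `spikes` (m x n matrices with
#'   `x = clean + noise + spikes`) and `mask` (logical corruption mask).
#' @export
generate_subspace_data <- function(n_classes = 3, subspace_dim = 4,
                                   n_genes = 300, n_per_class = 30,
                                   noise_sd = 0, corrupt_frac = 0,
                                   corrupt_magnitude = 0.5,
                                   orthogonal_classes = TRUE, seed = 1L) {
  if (n_classes < 2) stop_invalid("'n_classes' must be >= 2")
  if (subspace_dim < 1 || subspace_dim >= n_genes) {
    stop_invalid("'subspace_dim' must satisfy 1 <= d < n_genes")
  }
  if (n_per_class < 1) stop_invalid("'n_per_class' must be >= 1")
  if (corrupt_frac < 0 || corrupt_frac >= 1) {
    stop_invalid("'corrupt_frac' must be in [0, 1)")
  }
  if (orthogonal_classes && n_classes * subspace_dim > n_genes) {
    stop_invalid("orthogonal classes need n_classes * subspace_dim <= n_genes")
  }
  m <- n_genes
  n <- n_classes * n_per_class

  local_seed(seed, {
    if (orthogonal_classes) {
      Q <- qr.Q(qr(matrix(stats::rnorm(m * n_classes * subspace_dim), m)))
      bases <- lapply(seq_len(n_classes), function(k) {
        Q[, (k - 1) * subspace_dim + seq_len(subspace_dim), drop = FALSE]
      })
    } else {
      bases <- lapply(seq_len(n_classes), function(k) {
        qr.Q(qr(matrix(stats::rnorm(m * subspace_dim), m)))
      })
    }
    clean <- matrix(0, m, n)
    labels <- character(n)
    for (k in seq_len(n_classes)) {
      cols <- (k - 1) * n_per_class + seq_len(n_per_class)
      coeffs <- matrix(stats::rnorm(subspace_dim * n_per_class), subspace_dim)
      clean[, cols] <- bases[[k]] %*% coeffs
      labels[cols] <- paste0("class_", k)
    }
    noise <- if (noise_sd > 0) {
      matrix(stats::rnorm(m * n, sd = noise_sd), m)
    } else matrix(0, m, n)
    mask <- matrix(FALSE, m, n)
    spikes <- matrix(0, m, n)
    n_corrupt <- round(corrupt_frac * m * n)
    if (n_corrupt > 0) {
      hit <- sample.int(m * n, n_corrupt)
      mask[hit] <- TRUE
      spikes[hit] <- sample(c(-1, 1), n_corrupt, replace = TRUE) *
        corrupt_magnitude
    }
    x <- clean + noise + spikes
    dimnames(x) <- list(paste0("gene_", seq_len(m)),
                        paste0("sample_", seq_len(n)))
    names(labels) <- colnames(x)
    list(x = x, labels = labels,
         truth = list(bases = bases, clean = clean, noise = noise,
                      spikes = spikes, mask = mask))
  })
}

#' Expression-like data with planted differential genes
#'
#' Background genes are pure Gaussian noise; `n_informative` planted genes
#' receive a class-specific mean shift of size `shift` (the shifted class
#' cycles over the informative genes), the structure the BW gene filter is
#' meant to detect.
#'
#' @param n_genes Total number of genes m.
#' @param n_per_class Samples per class.
#' @param n_classes Number of classes k.
#' @param n_informative Number of planted discriminative genes (`<= m`).
#' @param shift Mean shift applied to the elevated class.
#' @param noise_sd Gaussian noise standard deviation.
#' @param seed Integer seed.
#' @return List with `x` (m x n matrix), `labels`, and `informative`
#'   (ids of the planted genes; empty when `n_informative = 0`).
#' @export
generate_de_genes_data <- function(n_genes = 2000, n_per_class = 30,
                                   n_classes = 2, n_informative = 100,
                                   shift = 2, noise_sd = 1, seed = 1L) {
  if (n_informative > n_genes) stop_invalid("'n_informative' must be <= n_genes")
  if (n_informative < 0) stop_invalid("'n_informative' must be >= 0")
  if (n_classes < 2) stop_invalid("'n_classes' must be >= 2")
  if (n_per_class < 1) stop_invalid("'n_per_class' must be >= 1")
  m <- n_genes
  n <- n_classes * n_per_class
  labels <- rep(paste0("class_", seq_len(n_classes)), each = n_per_class)

  local_seed(seed, {
    x <- matrix(stats::rnorm(m * n, sd = noise_sd), m, n)
    informative <- integer(0)
    if (n_informative > 0) {
      informative <- seq_len(n_informative)
      up_class <- rep_len(seq_len(n_classes), n_informative)
      for (j in informative) {
        sel <- labels == paste0("class_", up_class[j])
        x[j, sel] <- x[j, sel] + shift
      }
    }
    dimnames(x) <- list(paste0("gene_", seq_len(m)),
                        paste0("sample_", seq_len(n)))
    names(labels) <- colnames(x)
    list(x = x, labels = labels,
         informative = if (length(informative)) {
           paste0("gene_", informative)
         } else character(0))
  })
}
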