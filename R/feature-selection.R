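#' BW-ratio gene scores
#'
#' Ranks genes by the ratio of between-class to within-class sums of
#' squares. For gene `j` with class means \eqn{\bar x_{kj}} and overall
#' mean \eqn{\bar x_{\cdot j}}:
#' \deqn{BW_j = \frac{\sum_i \sum_k I(y_i = k)(\bar x_{kj} - \bar x_{\cdot j})^2}
#'                   {\sum_i \sum_k I(y_i = k)(x_{ij} - \bar x_{kj})^2 + \epsilon}}
#' with \eqn{\epsilon = 10^{-12}} guarding genes with zero within-class
#' scatter. Genes constant across all samples score 0. Ties in the
#' ranking keep input order.
#'
#' @param X Numeric matrix, genes in rows, samples in columns.
#' @param labels Class labels, one per sample; at least 2 classes.
#' @return A data.frame of class `"bw_scores"` with columns `gene_id`,
#'   `score`, `rank` (1 = highest score), in input gene order.
#' @seealso [select_top_genes()]
#' @export
bw_ratio <- function(X, labels) {
  if (!is.matrix(X)) X <- as.matrix(X)
  check_finite_matrix(X, "X")
  labels <- as.character(labels)
  if (length(labels) != ncol(X)) {
    stop_invalid("'labels' must have one entry per sample (column)")
  }
  classes <- unique(labels)
  if (length(classes) < 2) stop_invalid("BW scoring needs at least 2 classes")

  overall <- rowMeans(X)
  between <- numeric(nrow(X))
  within <- numeric(nrow(X))
  for (cl in classes) {
    sel <- labels == cl
    nc <- sum(sel)
    mcl <- rowMeans(X[, sel, drop = FALSE])
    between <- between + nc * (mcl - overall)^2
    within <- within + rowSums((X[, sel, drop = FALSE] - mcl)^2)
  }
  score <- ifelse(between == 0 & within == 0, 0, between / (within + 1e-12))
  ord <- order(-score)  # stable: ties keep input order
  rank <- integer(length(score))
  rank[ord] <- seq_along(score)
  gene_id <- if (!is.null(rownames(X))) rownames(X) else
    as.character(seq_len(nrow(X)))
  structure(data.frame(gene_id = gene_id, score = score, rank = rank,
                       stringsAsFactors = FALSE),
            class = c("bw_scores", "data.frame"))
}

#' Reduce a matrix to its top-ranked genes
#'
#' @param X Genes x samples matrix the scores were computed on (or any
#'   matrix with the same rows).
#' @param scores A [bw_ratio()] table.
#' @param g Number of genes to keep, `1 <= g <= nrow(X)`.
#' @return List with `X` (the `g` top-ranked gene rows, in rank order) and
#'   `gene_ids` (their identifiers).
#' @export
select_top_genes <- function(X, scores, g) {
  if (!is.matrix(X)) X <- as.matrix(X)
  if (!inherits(scores, "bw_scores")) stop_invalid("'scores' must come from bw_ratio()")
  if (nrow(X) != nrow(scores)) {
    stop_invalid("'X' and 'scores' disagree on the number of genes")
  }
  if (!is.numeric(g) || length(g) != 1 || is.na(g) || g < 1 || g > nrow(X) ||
      g != round(g)) {
    stop_invalid(sprintf("'g' must be an integer in [1, %d]", nrow(X)))
  }
  keep <- order(scores$rank)[seq_len(g)]
  list(X = X[keep, , drop = FALSE], gene_ids = scores$gene_id[keep])
}

#' Write a BW score table as TSV
#'
#' @param scores A [bw_ratio()] table.
#' @param path Output path.
#' @export
write_bw_scores <- function(scores, path) {
  if (!inherits(scores, "bw_scores")) stop_invalid("'scores' must come from bw_ratio()")
  utils::write.table(scores, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
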