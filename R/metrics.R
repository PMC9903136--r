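# Evaluation statistics for annotation and integration quality.

#' Classification accuracy
#'
#' Fraction of exact matches between predicted and true labels.
#'
#' @param pred,truth equal-length nonempty label vectors.
#' @return number in [0, 1].
#' @export
accuracy <- function(pred, truth) {
  stop_if(length(pred) != length(truth), "pred and truth lengths differ")
  stop_if(length(pred) == 0, "empty label vectors")
  mean(as.character(pred) == as.character(truth))
}

#' Adjusted Rand index
#'
#' Pair-counting agreement between two partitions, corrected for chance:
#' \deqn{ARI = \frac{\sum_{ij}\binom{n_{ij}}{2} - E}{\tfrac12(\sum_i\binom{a_i}{2} + \sum_j\binom{b_j}{2}) - E}}
#' with \eqn{E = \sum_i\binom{a_i}{2}\sum_j\binom{b_j}{2} / \binom{n}{2}},
#' computed from the contingency table of the two labelings.
#'
#' @param pred,truth equal-length (>= 2) label vectors; label values are
#'   arbitrary (only the induced partitions matter).
#' @return number in [-1, 1]; 1 for identical partitions.
#' @export
adjusted_rand <- function(pred, truth) {
  stop_if(length(pred) != length(truth), "pred and truth lengths differ")
  n <- length(pred)
  stop_if(n < 2, "need at least 2 items")
  tab <- table(as.character(pred), as.character(truth))
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  npairs <- choose2(n)
  expected <- sum_a * sum_b / npairs
  max_index <- (sum_a + sum_b) / 2
  if (abs(max_index - expected) < .Machine$double.eps * 4) return(1)
  (sum_ij - expected) / (max_index - expected)
}

#' Batch-mixing entropy
#'
#' Mean over cells of the Shannon entropy (base = number of batches) of the
#' batch labels among each cell's k nearest Euclidean neighbors, excluding
#' the cell itself. 1 = batches perfectly mixed in every neighborhood,
#' 0 = batches fully separated.
#'
#' @param coords cells x m numeric matrix (embedding or 2-D coordinates).
#' @param batches per-cell batch labels (>= 2 distinct values).
#' @param k neighborhood size (default 15); requires at least k+1 cells.
#' @return number in [0, 1].
#' @export
batch_mixing_entropy <- function(coords, batches, k = 15L) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  stop_if(length(batches) != n, "batches length must match cells")
  batches <- as.character(batches)
  nb <- length(unique(batches))
  stop_if(nb < 2, "batch-mixing entropy is undefined for a single batch")
  stop_if(n < k + 1, "need at least k+1 cells")
  nn <- RANN::nn2(coords, coords, k = k + 1L)$nn.idx
  ent <- vapply(seq_len(n), function(i) {
    idx <- nn[i, ]
    idx <- idx[idx != i][seq_len(k)]     # exclude self, keep k neighbors
    p <- tabulate(factor(batches[idx], levels = unique(batches)), nb) / k
    p <- p[p > 0]
    -sum(p * log(p)) / log(nb)
  }, numeric(1))
  mean(ent)
}

#' Truncated-SVD baseline embedding
#'
#' Classical linear baseline for integration comparisons: counts are
#' library-size normalized, log1p-transformed, gene-centered, and projected
#' on the top principal components.
#'
#' @param data a \code{\link{count_matrix}}.
#' @param n_components number of components (default 50).
#' @param size_factor scaling of the normalization (default: median library
#'   size).
#' @return cells x n_components matrix of component scores.
#' @export
svd_embedding <- function(data, n_components = 50L, size_factor = NULL) {
  X <- cm_dense(data)
  if (is.null(size_factor)) size_factor <- stats::median(rowSums(X))
  Xl <- encode_input(X, size_factor)
  Xc <- sweep(Xl, 2L, colMeans(Xl))
  k <- min(n_components, nrow(Xc) - 1L, ncol(Xc))
  sv <- svd(Xc, nu = k, nv = 0)
  sv$u %*% diag(sv$d[seq_len(k)], k)
}
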