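# Post-training inference: embeddings, annotation, batch-corrected usage,
# and 2-D visualization coordinates.

# Align a query CountMatrix to the model's gene vocabulary and return the
# encoder input matrix.
.model_input <- function(data, model) {
  data <- align_genes(data, model$gene_ids)
  encode_input(cm_dense(data), model$size_factor)
}

#' Latent embedding of cells
#'
#' Posterior mean of \eqn{q(z_y | X)} for every cell: the d-dimensional
#' embedding used for visualization, integration, and annotation.
#' Deterministic (no sampling).
#'
#' @param data a \code{\link{count_matrix}} whose genes match the model's
#'   training genes (matched by gene id; missing model genes are imputed as
#'   zeros with a warning, extra query genes are an error).
#' @param model a fitted \code{scfactor_model} from \code{\link{svi_fit}}.
#' @return cells x d numeric matrix.
#' @export
embed <- function(data, model) {
  Xin <- .model_input(data, model)
  mlp_forward(model$var$encoder, Xin)$out$mu
}

#' Cell-type annotation
#'
#' Applies the classifier \eqn{q(y | z_y)} to the posterior-mean embedding
#' of each cell. The predicted label is the argmax class; exact probability
#' ties resolve to the lowest vocabulary index.
#'
#' @inheritParams embed
#' @return list with \code{y_prob} (cells x L, rows summing to 1) and
#'   \code{y_hat} (character labels from the model vocabulary).
#' @export
classify <- function(data, model) {
  zy <- embed(data, model)
  logits <- mlp_forward(model$var$classifier, zy)$out$logits
  y_prob <- softmax_rows(logits)
  colnames(y_prob) <- model$label_vocabulary
  idx <- apply(y_prob, 1L, which.max)   # which.max takes the first maximum
  list(y_prob = y_prob, y_hat = model$label_vocabulary[idx], y_idx = idx)
}

#' Batch-corrected expression (gene usage)
#'
#' Reconstructs each cell's expected gene usage with the nuisance factor
#' fixed at its prior mean: row i is \code{decode_usage} of the
#' conditional-prior mean at (y = predicted type of cell i, z1 = mu0). All
#' nuisance/batch variation is removed by construction; rows are simplex
#' vectors (relative usage, not counts).
#'
#' @inheritParams embed
#' @return cells x genes matrix with rows summing to 1.
#' @export
correct_expression <- function(data, model) {
  cl <- classify(data, model)
  L <- model$prior$L
  # one decode per type, then index: cells of the same predicted type share
  # the corrected row
  z1_ref <- matrix(model$prior$mu0, L, model$prior$d1, byrow = TRUE)
  cp <- conditional_prior(diag(L), z1_ref, model$gen)
  usage_by_type <- decode_usage(cp$mu, model$gen)$usage
  out <- usage_by_type[cl$y_idx, , drop = FALSE]
  rownames(out) <- NULL
  colnames(out) <- model$gene_ids
  out
}

#' 2-D UMAP coordinates
#'
#' Projects embeddings to two dimensions with uniform manifold
#' approximation and projection (15 neighbors, min_dist 0.1, Euclidean
#' metric), reproducibly for a fixed seed.
#'
#' @param embeddings cells x d numeric matrix.
#' @param seed integer seed.
#' @param n_neighbors neighborhood size (default 15); automatically shrunk
#'   with a warning when there are fewer cells.
#' @return cells x 2 numeric matrix.
#' @export
umap2d <- function(embeddings, seed = 0L, n_neighbors = 15L) {
  n <- nrow(embeddings)
  stop_if(n < 3, "umap2d needs at least 3 cells")
  if (n_neighbors >= n) {
    n_neighbors <- max(2L, n - 1L)
    warning(sprintf("n_neighbors shrunk to %d for %d cells", n_neighbors, n))
  }
  coords <- with_seed(seed, {
    uwot::umap(embeddings, n_neighbors = n_neighbors, min_dist = 0.1,
               metric = "euclidean", n_threads = 1, n_sgd_threads = 1,
               verbose = FALSE)
  })
  unname(coords)
}
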