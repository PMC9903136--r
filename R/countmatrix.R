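#' Construct a cells-by-genes count matrix
#'
#' Light container for observed single-cell counts: a (sparse or dense)
#' non-negative integer matrix with unique cell and gene identifiers.
#'
#' @param counts cells x genes matrix of non-negative integers
#'   (\code{Matrix} sparse classes allowed).
#' @param cell_ids character vector of unique cell identifiers, length
#'   \code{nrow(counts)}.
#' @param gene_ids character vector of unique gene identifiers, length
#'   \code{ncol(counts)}.
#' @return An object of class \code{CountMatrix} with fields
#'   \code{counts}, \code{cell_ids}, \code{gene_ids}.
#' @export
count_matrix <- function(counts, cell_ids, gene_ids) {
  stop_if(length(cell_ids) != nrow(counts),
          sprintf("cell_ids length (%d) != rows (%d)", length(cell_ids), nrow(counts)))
  stop_if(length(gene_ids) != ncol(counts),
          sprintf("gene_ids length (%d) != columns (%d)", length(gene_ids), ncol(counts)))
  stop_if(anyDuplicated(cell_ids) > 0, "cell_ids must be unique")
  stop_if(anyDuplicated(gene_ids) > 0, "gene_ids must be unique")
  vals <- if (inherits(counts, "sparseMatrix")) counts@x else as.numeric(counts)
  stop_if(any(vals < 0), "counts must be non-negative")
  stop_if(any(vals != round(vals)), "counts must be integer-valued")
  structure(list(counts = counts,
                 cell_ids = as.character(cell_ids),
                 gene_ids = as.character(gene_ids)),
            class = "CountMatrix")
}

#' @export
dim.CountMatrix <- function(x) dim(x$counts)

#' @export
print.CountMatrix <- function(x, ...) {
  cat(sprintf("CountMatrix: %d cells x %d genes (%s storage)\n",
              nrow(x$counts), ncol(x$counts),
              if (inherits(x$counts, "sparseMatrix")) "sparse" else "dense"))
  invisible(x)
}

# Dense numeric matrix of counts (internal).
cm_dense <- function(x) as_dense(x$counts)

# Reorder/align the columns of a query CountMatrix to a model's gene
# vocabulary. Genes absent from the query are imputed as zero counts (with
# a warning); genes absent from the model raise an alignment error.
align_genes <- function(data, gene_ids) {
  if (identical(data$gene_ids, gene_ids)) return(data)
  missing_in_model <- setdiff(data$gene_ids, gene_ids)
  stop_if(length(missing_in_model) > 0,
          paste0("query genes absent from model vocabulary: ",
                 paste(utils::head(missing_in_model, 5), collapse = ", "),
                 if (length(missing_in_model) > 5) ", ..." else ""),
          class = "scfactor_alignment_error")
  idx <- match(gene_ids, data$gene_ids)
  absent <- is.na(idx)
  X <- matrix(0, nrow(data$counts), length(gene_ids))
  X[, !absent] <- as_dense(data$counts[, idx[!absent], drop = FALSE])
  if (any(absent)) {
    warning(sprintf("%d model genes absent from query; imputed as zero counts",
                    sum(absent)))
  }
  count_matrix(X, data$cell_ids, gene_ids)
}
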