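# Readers/writers: Matrix Market counts with TSV sidecars, TSV outputs,
# and JSON model serialization.

#' Read a counts matrix from Matrix Market + TSV sidecars
#'
#' Reads a sparse coordinate \code{.mtx} file together with one-column TSV
#' sidecars of gene and cell identifiers. Orientation (cells x genes vs
#' genes x cells) is auto-detected from the sidecar lengths; entries must
#' be whole numbers.
#'
#' @param mtx_path path to the Matrix Market file.
#' @param genes_tsv path to a TSV whose first column holds gene ids.
#' @param cells_tsv path to a TSV whose first column holds cell ids.
#' @return A \code{\link{count_matrix}} (cells x genes).
#' @export
read_counts <- function(mtx_path, genes_tsv, cells_tsv) {
  stop_if(!file.exists(mtx_path), paste("no such file:", mtx_path))
  m <- Matrix::readMM(mtx_path)
  genes <- utils::read.table(genes_tsv, sep = "\t",
                             stringsAsFactors = FALSE)[[1]]
  cells <- utils::read.table(cells_tsv, sep = "\t",
                             stringsAsFactors = FALSE)[[1]]
  if (inherits(m, "sparseMatrix")) {
    sm <- Matrix::summary(methods::as(m, "TsparseMatrix"))
    bad <- which(sm$x != round(sm$x))
    if (length(bad) > 0) {
      stop_if(TRUE, sprintf(
        "non-integer entry %.4g at (%d, %d) in %s",
        sm$x[bad[1]], sm$i[bad[1]], sm$j[bad[1]], mtx_path),
        class = "scfactor_format_error")
    }
    m <- methods::as(m, "CsparseMatrix")
  } else {
    m <- as.matrix(m)
    bad <- which(m != round(m), arr.ind = TRUE)
    if (nrow(bad) > 0) {
      stop_if(TRUE, sprintf(
        "non-integer entry %.4g at (%d, %d) in %s",
        m[bad[1, 1], bad[1, 2]], bad[1, 1], bad[1, 2], mtx_path),
        class = "scfactor_format_error")
    }
  }
  if (nrow(m) == length(cells) && ncol(m) == length(genes)) {
    # already cells x genes
  } else if (nrow(m) == length(genes) && ncol(m) == length(cells)) {
    message(sprintf("read_counts: %s is genes x cells; transposing", mtx_path))
    m <- Matrix::t(m)
  } else {
    stop_if(TRUE, sprintf(
      "matrix is %d x %d but sidecars give %d cells / %d genes",
      nrow(m), ncol(m), length(cells), length(genes)),
      class = "scfactor_format_error")
  }
  count_matrix(m, cell_ids = cells, gene_ids = genes)
}

#' Write a counts matrix as Matrix Market + TSV sidecars
#'
#' @param data a \code{\link{count_matrix}}.
#' @param dir output directory (created if absent). Writes
#'   \code{counts.mtx}, \code{genes.tsv}, \code{cells.tsv}.
#' @return Invisibly, the paths written.
#' @export
write_counts <- function(data, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("counts.mtx", "genes.tsv", "cells.tsv"))
  m <- data$counts
  if (!inherits(m, "sparseMatrix")) m <- Matrix::Matrix(m, sparse = TRUE)
  Matrix::writeMM(m, paths[1])
  writeLines(data$gene_ids, paths[2])
  writeLines(data$cell_ids, paths[3])
  invisible(paths)
}

# Write one cells x k numeric matrix as TSV with cell_id first column,
# full precision.
write_matrix_tsv <- function(path, cell_ids, mat, col_names) {
  df <- data.frame(cell_id = cell_ids, format(mat, digits = 17, trim = TRUE),
                   check.names = FALSE)
  names(df) <- c("cell_id", col_names)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write annotation outputs to a directory
#'
#' Writes TSVs (header, cell_id first column, full precision) for whichever
#' of embeddings, labels, probabilities, clusters, and corrected usage are
#' supplied, plus a run-metadata JSON recording the seed, configuration and
#' package version.
#'
#' @param dir output directory.
#' @param cell_ids character vector of cell identifiers.
#' @param embeddings optional cells x d matrix.
#' @param labels optional per-cell predicted labels.
#' @param probabilities optional cells x L matrix (columns = vocabulary).
#' @param clusters optional per-cell cluster indices.
#' @param corrected optional cells x G corrected usage matrix.
#' @param seed integer seed recorded in the metadata.
#' @param config optional list recorded in the metadata.
#' @return Invisibly, the paths written.
#' @export
write_outputs <- function(dir, cell_ids, embeddings = NULL, labels = NULL,
                          probabilities = NULL, clusters = NULL,
                          corrected = NULL, seed = NA_integer_,
                          config = list()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- length(cell_ids)
  paths <- character(0)
  chk <- function(x, nm) {
    stop_if(nrow(as.matrix(x)) != n, paste(nm, "row count != cells"))
  }
  if (!is.null(embeddings)) {
    chk(embeddings, "embeddings")
    paths <- c(paths, write_matrix_tsv(
      file.path(dir, "embeddings.tsv"), cell_ids, embeddings,
      sprintf("dim_%d", seq_len(ncol(embeddings)))))
  }
  if (!is.null(labels)) {
    stop_if(length(labels) != n, "labels length != cells")
    p <- file.path(dir, "labels.tsv")
    utils::write.table(data.frame(cell_id = cell_ids, label = labels),
                       p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  if (!is.null(probabilities)) {
    chk(probabilities, "probabilities")
    cn <- colnames(probabilities)
    if (is.null(cn)) cn <- sprintf("class_%d", seq_len(ncol(probabilities)))
    paths <- c(paths, write_matrix_tsv(
      file.path(dir, "probabilities.tsv"), cell_ids, probabilities, cn))
  }
  if (!is.null(clusters)) {
    stop_if(length(clusters) != n, "clusters length != cells")
    p <- file.path(dir, "clusters.tsv")
    utils::write.table(data.frame(cell_id = cell_ids, cluster = clusters),
                       p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  if (!is.null(corrected)) {
    chk(corrected, "corrected")
    cn <- colnames(corrected)
    if (is.null(cn)) cn <- sprintf("gene_%d", seq_len(ncol(corrected)))
    paths <- c(paths, write_matrix_tsv(
      file.path(dir, "corrected_usage.tsv"), cell_ids, corrected, cn))
  }
  meta <- list(seed = seed, config = config,
               package = "scfactor",
               version = as.character(utils::packageVersion("scfactor")),
               timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(meta, file.path(dir, "run_metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(paths, file.path(dir, "run_metadata.json")))
}

# --- model serialization --------------------------------------------------

flatten_net <- function(net) {
  lapply(list(W1 = net$W1, b1 = net$b1, W2 = net$W2, b2 = net$b2,
              heads = lapply(net$heads, function(h) list(W = h$W, b = h$b))),
         identity)
}

#' Save a fitted model as JSON
#'
#' Serializes the prior configuration, label vocabulary, gene ids, size
#' factor, training history, and all network parameter arrays (with shapes)
#' into a single JSON file.
#'
#' @param model a \code{scfactor_model}.
#' @param path output file path.
#' @return Invisibly, \code{path}.
#' @export
save_model <- function(model, path) {
  enc_mat <- function(x) {
    if (is.matrix(x)) list(dim = dim(x), data = as.numeric(x))
    else list(dim = length(x), data = as.numeric(x))
  }
  enc_net <- function(net) {
    list(W1 = enc_mat(net$W1), b1 = enc_mat(net$b1),
         W2 = enc_mat(net$W2), b2 = enc_mat(net$b2),
         heads = lapply(net$heads, function(h)
           list(W = enc_mat(h$W), b = enc_mat(h$b))))
  }
  obj <- list(
    format = "scfactor_model_v1",
    prior = unclass(model$prior),
    label_vocabulary = model$label_vocabulary,
    gene_ids = model$gene_ids,
    size_factor = model$size_factor,
    cfg = unclass(model$cfg),
    history = model$history,
    gen = list(G = model$gen$G, hidden = model$gen$hidden,
               cond_prior = enc_net(model$gen$cond_prior),
               decoder = enc_net(model$gen$decoder)),
    var = list(G = model$var$G, hidden = model$var$hidden,
               encoder = enc_net(model$var$encoder),
               classifier = enc_net(model$var$classifier),
               nuisance = enc_net(model$var$nuisance)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a model saved by \code{\link{save_model}}
#'
#' @param path path to the JSON file.
#' @return A \code{scfactor_model}.
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  stop_if(!identical(obj$format, "scfactor_model_v1"),
          "not an scfactor model file", class = "scfactor_format_error")
  dec_mat <- function(e) {
    if (length(e$dim) == 2) matrix(e$data, e$dim[1], e$dim[2])
    else as.numeric(e$data)
  }
  dec_net <- function(e) {
    heads <- lapply(e$heads, function(h) list(W = dec_mat(h$W), b = dec_mat(h$b)))
    structure(list(W1 = dec_mat(e$W1), b1 = dec_mat(e$b1),
                   W2 = dec_mat(e$W2), b2 = dec_mat(e$b2), heads = heads),
              class = "scfactor_mlp")
  }
  prior <- do.call(prior_config, obj$prior[c("L", "d", "d1", "alpha0",
                                             "mu0", "sigma0")])
  gen <- structure(list(cond_prior = dec_net(obj$gen$cond_prior),
                        decoder = dec_net(obj$gen$decoder),
                        G = as.integer(obj$gen$G),
                        hidden = as.integer(obj$gen$hidden)),
                   class = "generative_nets")
  var <- structure(list(encoder = dec_net(obj$var$encoder),
                        classifier = dec_net(obj$var$classifier),
                        nuisance = dec_net(obj$var$nuisance),
                        G = as.integer(obj$var$G),
                        hidden = as.integer(obj$var$hidden)),
                   class = "variational_nets")
  structure(list(prior = prior, gen = gen, var = var,
                 label_vocabulary = obj$label_vocabulary,
                 gene_ids = obj$gene_ids,
                 size_factor = obj$size_factor,
                 cfg = do.call(train_config, obj$cfg[c(
                   "epochs", "minibatch_size", "learning_rate", "mc_samples",
                   "kl_warmup_epochs", "classifier_weight", "seed", "hidden")]),
                 history = as.data.frame(obj$history)),
            class = "scfactor_model")
}
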