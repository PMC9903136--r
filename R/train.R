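# Stochastic variational inference for the semi-supervised factor model.

#' Training configuration
#'
#' @param epochs number of passes over the data (default 200).
#' @param minibatch_size cells per gradient step (default 128).
#' @param learning_rate Adam step size (default 1e-3).
#' @param mc_samples Monte-Carlo samples per cell per step (default 1).
#' @param kl_warmup_epochs epochs over which the KL weight ramps linearly
#'   from 0 to 1 (default 50); must not exceed \code{epochs} when
#'   \code{epochs > 0}.
#' @param classifier_weight weight w of the supervised auxiliary term
#'   \eqn{-w \log q(y = y_i | z_y)} per labeled cell (default 1).
#' @param seed integer seed controlling initialization, minibatch order and
#'   reparameterization noise (default 0).
#' @param hidden hidden-layer width of all networks (default 128).
#' @return A \code{train_config} list.
#' @export
train_config <- function(epochs = 200L, minibatch_size = 128L,
                         learning_rate = 1e-3, mc_samples = 1L,
                         kl_warmup_epochs = 50L, classifier_weight = 1,
                         seed = 0L, hidden = HIDDEN_DEFAULT) {
  stop_if(epochs < 0, "epochs must be >= 0")
  stop_if(minibatch_size < 1, "minibatch_size must be >= 1")
  stop_if(learning_rate <= 0, "learning_rate must be positive")
  stop_if(mc_samples < 1, "mc_samples must be >= 1")
  stop_if(kl_warmup_epochs < 0, "kl_warmup_epochs must be >= 0")
  stop_if(epochs > 0 && kl_warmup_epochs > epochs,
          "kl_warmup_epochs must be <= epochs")
  stop_if(classifier_weight < 0, "classifier_weight must be >= 0")
  structure(list(epochs = as.integer(epochs),
                 minibatch_size = as.integer(minibatch_size),
                 learning_rate = learning_rate,
                 mc_samples = as.integer(mc_samples),
                 kl_warmup_epochs = as.integer(kl_warmup_epochs),
                 classifier_weight = classifier_weight,
                 seed = as.integer(seed),
                 hidden = as.integer(hidden)),
            class = "train_config")
}

# --- flat parameter vector <-> nested tree -------------------------------

param_flatten <- function(tree) {
  as.numeric(unlist(tree, use.names = FALSE))
}

param_unflatten <- function(vec, skeleton) {
  pos <- 0L
  walk <- function(node) {
    if (is.list(node)) {
      out <- lapply(node, walk)
      attributes(out) <- attributes(node)
      out
    } else {
      k <- length(node)
      piece <- if (k == 0L) vec[integer(0)] else vec[(pos + 1L):(pos + k)]
      pos <<- pos + k
      attributes(piece) <- attributes(node)
      piece
    }
  }
  walk(skeleton)
}

# --------------------------------------------------------------------------

#' Fit the model by stochastic variational inference
#'
#' Minibatch gradient ascent on the evidence lower bound: labeled cells
#' contribute the labeled ELBO plus the supervised classifier term;
#' unlabeled cells contribute the ELBO with the label enumerated and
#' weighted by the classifier. Optimization is Adam; a linear KL warm-up
#' ramps the weight on the Kullback-Leibler terms to avoid posterior
#' collapse. Fully reproducible given \code{cfg$seed}.
#'
#' @param data a \code{\link{count_matrix}}.
#' @param labels character vector (length = cells) of cell-type labels with
#'   \code{NA} for unlabeled cells, or \code{NULL} for fully unsupervised
#'   fitting (then \code{vocabulary} is required).
#' @param prior optional \code{\link{prior_config}}; defaults to the
#'   standard priors with L inferred from the label vocabulary.
#' @param cfg a \code{\link{train_config}}.
#' @param vocabulary optional explicit ordered label vocabulary; defaults to
#'   the sorted distinct non-NA labels.
#' @return A \code{scfactor_model}: prior, fitted generative and variational
#'   networks, label vocabulary, encoder size factor, and per-epoch history
#'   (mean ELBO and mean classifier loss).
#' @export
svi_fit <- function(data, labels = NULL, prior = NULL, cfg = train_config(),
                    vocabulary = NULL) {
  stop_if(!inherits(data, "CountMatrix"), "data must be a CountMatrix")
  n <- nrow(data$counts); G <- ncol(data$counts)
  stop_if(n == 0 || G == 0, "count matrix is empty")
  if (is.null(labels)) labels <- rep(NA_character_, n)
  stop_if(length(labels) != n, "labels length must match cells")
  labels <- as.character(labels)
  if (is.null(vocabulary)) {
    vocabulary <- sort(unique(labels[!is.na(labels)]))
  }
  stop_if(length(vocabulary) == 0,
          "no labels and no explicit vocabulary supplied",
          class = "scfactor_vocabulary_error")
  bad <- !is.na(labels) & !(labels %in% vocabulary)
  stop_if(any(bad),
          paste0("labels outside vocabulary: ",
                 paste(unique(labels[bad]), collapse = ", ")),
          class = "scfactor_vocabulary_error")
  if (is.null(prior)) prior <- prior_config(L = length(vocabulary))
  stop_if(prior$L != length(vocabulary),
          "prior L does not match vocabulary size",
          class = "scfactor_vocabulary_error")

  X <- cm_dense(data)
  size_factor <- stats::median(rowSums(X))
  Xin_all <- encode_input(X, size_factor)
  y <- match(labels, vocabulary)          # NA for unlabeled

  gen <- var <- NULL
  history <- data.frame(epoch = integer(), mean_elbo = numeric(),
                        mean_class_loss = numeric())

  with_seed(cfg$seed, {
    gen <- generative_nets(prior, G, hidden = cfg$hidden)
    var <- variational_nets(prior, G, hidden = cfg$hidden)

    params <- list(gen = gen[c("cond_prior", "decoder")],
                   var = var[c("encoder", "classifier", "nuisance")])
    theta <- param_flatten(params)
    m <- v <- numeric(length(theta))
    b1 <- 0.9; b2 <- 0.999; adam_eps <- 1e-8; t_step <- 0L

    for (epoch in seq_len(cfg$epochs)) {
      beta <- if (cfg$kl_warmup_epochs == 0) 1 else
        min(1, epoch / cfg$kl_warmup_epochs)
      perm <- sample.int(n)
      starts <- seq(1L, n, by = cfg$minibatch_size)
      ep_elbo <- 0; ep_closs <- 0; n_lab_seen <- 0L
      for (s in starts) {
        idx <- perm[s:min(s + cfg$minibatch_size - 1L, n)]
        nb <- length(idx)
        lab <- idx[!is.na(y[idx])]
        unl <- idx[is.na(y[idx])]
        g_sum <- NULL
        for (mc in seq_len(cfg$mc_samples)) {
          if (length(lab) > 0) {
            e1 <- matrix(stats::rnorm(length(lab) * prior$d),
                         length(lab), prior$d)
            e2 <- matrix(stats::rnorm(length(lab) * prior$d1),
                         length(lab), prior$d1)
            rl <- elbo_engine_labeled(
              X[lab, , drop = FALSE], Xin_all[lab, , drop = FALSE],
              y[lab], gen, var, prior, e1, e2, beta = beta,
              w = cfg$classifier_weight, grads = TRUE)
            g_sum <- param_add(g_sum, rl$grads)
            ep_elbo <- ep_elbo + sum(rl$elbo) / cfg$mc_samples
            ep_closs <- ep_closs + sum(rl$class_loss) / cfg$mc_samples
          }
          if (length(unl) > 0) {
            e1 <- matrix(stats::rnorm(length(unl) * prior$d),
                         length(unl), prior$d)
            e2 <- matrix(stats::rnorm(length(unl) * prior$d1),
                         length(unl), prior$d1)
            ru <- elbo_engine_unlabeled(
              X[unl, , drop = FALSE], Xin_all[unl, , drop = FALSE],
              gen, var, prior, e1, e2, beta = beta, grads = TRUE)
            g_sum <- param_add(g_sum, ru$grads)
            ep_elbo <- ep_elbo + sum(ru$elbo) / cfg$mc_samples
          }
        }
        n_lab_seen <- n_lab_seen + length(lab)
        g <- param_flatten(g_sum) / (nb * cfg$mc_samples)
        stop_if(any(!is.finite(g)), "non-finite gradient encountered")
        t_step <- t_step + 1L
        m <- b1 * m + (1 - b1) * g
        v <- b2 * v + (1 - b2) * g^2
        mhat <- m / (1 - b1^t_step)
        vhat <- v / (1 - b2^t_step)
        theta <- theta - cfg$learning_rate * mhat / (sqrt(vhat) + adam_eps)
        params <- param_unflatten(theta, params)
        gen$cond_prior <- params$gen$cond_prior
        gen$decoder <- params$gen$decoder
        var$encoder <- params$var$encoder
        var$classifier <- params$var$classifier
        var$nuisance <- params$var$nuisance
      }
      history[nrow(history) + 1L, ] <- list(
        epoch, ep_elbo / n,
        if (n_lab_seen > 0) ep_closs / n_lab_seen else NA_real_)
    }
  })

  structure(list(prior = prior, gen = gen, var = var,
                 label_vocabulary = vocabulary,
                 gene_ids = data$gene_ids,
                 size_factor = size_factor,
                 cfg = cfg, history = history),
            class = "scfactor_model")
}

#' @export
print.scfactor_model <- function(x, ...) {
  cat(sprintf(paste0("scfactor model: L=%d types, d=%d, d1=%d, G=%d genes; ",
                     "%d epochs trained\n"),
              x$prior$L, x$prior$d, x$prior$d1, length(x$gene_ids),
              nrow(x$history)))
  cat("vocabulary:", paste(x$label_vocabulary, collapse = ", "), "\n")
  invisible(x)
}
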