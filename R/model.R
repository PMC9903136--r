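# Generative model and variational family.
#
# Per cell, the generative process is:
#   y  ~ Categorical(alpha0)                     (cell type)
#   z1 ~ Normal(mu0, diag(sigma0^2))             (nuisance / batch factor)
#   zy ~ Normal(mu_zy(y, z1), diag(sigma_zy^2))  (complete hidden cell state)
#   alpha = Decoder(zy)                          (Dirichlet concentrations)
#   eta ~ Dirichlet(alpha)                       (gene usage)
#   X  ~ Multinomial(n, eta)                     (observed counts)
# eta is marginalized analytically, giving a Dirichlet-multinomial
# X-likelihood conditioned on the observed per-cell total.
#
# The variational family factorizes as
#   q(zy | X) q(y | zy) q(z1 | y, zy)
# with diagonal-Gaussian q(zy|X) and q(z1|y,zy) and a categorical
# classifier q(y|zy). All conditionals are 2-hidden-layer MLPs.

SIGMA_LO <- 1e-3
SIGMA_HI <- 10
ALPHA_LO <- 1e-6
ALPHA_HI <- 1e6
HIDDEN_DEFAULT <- 128L

#' Prior configuration of the factor model
#'
#' @param L number of cell types (>= 1).
#' @param d dimension of the complete hidden cell state z_y (default 50).
#' @param d1 dimension of the nuisance factor z1 (default 10).
#' @param alpha0 length-L positive concentration of the Categorical prior on
#'   the cell type; default all ones (uniform).
#' @param mu0 length-d1 prior mean of z1; default zeros.
#' @param sigma0 length-d1 positive prior standard deviations of z1; default
#'   ones (identity diagonal covariance).
#' @return A \code{prior_config} list.
#' @export
prior_config <- function(L, d = 50L, d1 = 10L,
                         alpha0 = rep(1, L), mu0 = rep(0, d1),
                         sigma0 = rep(1, d1)) {
  stop_if(L < 1, "L must be >= 1")
  stop_if(d < 1, "d must be >= 1")
  stop_if(d1 < 0, "d1 must be >= 0")
  stop_if(length(alpha0) != L || any(alpha0 <= 0) || any(!is.finite(alpha0)),
          "alpha0 must be length L and strictly positive")
  stop_if(length(mu0) != d1, "mu0 must have length d1")
  stop_if(length(sigma0) != d1 || any(sigma0 <= 0),
          "sigma0 must have length d1 and be strictly positive")
  structure(list(L = as.integer(L), d = as.integer(d), d1 = as.integer(d1),
                 alpha0 = as.numeric(alpha0), mu0 = as.numeric(mu0),
                 sigma0 = as.numeric(sigma0)),
            class = "prior_config")
}

#' Initialize the generative networks
#'
#' The conditional prior maps (one-hot y, z1) to the mean and scale of z_y;
#' the decoder maps z_y to the Dirichlet concentrations over genes.
#'
#' @param prior a \code{\link{prior_config}}.
#' @param G number of genes.
#' @param hidden hidden-layer width (default 128).
#' @param init_scale multiplier on the fan-in-scaled random initialization.
#' @param seed optional integer; when given, initialization is drawn under
#'   this seed without disturbing the caller's RNG.
#' @return A \code{generative_nets} list with elements \code{cond_prior} and
#'   \code{decoder}.
#' @export
generative_nets <- function(prior, G, hidden = HIDDEN_DEFAULT,
                            init_scale = 1, seed = NULL) {
  build <- function() {
    structure(list(
      cond_prior = mlp_init(prior$L + prior$d1, hidden,
                            c(mu = prior$d, sig = prior$d), init_scale),
      decoder = mlp_init(prior$d, hidden, c(alpha = G), init_scale),
      G = as.integer(G), hidden = as.integer(hidden)
    ), class = "generative_nets")
  }
  if (is.null(seed)) build() else with_seed(seed, build())
}

#' Initialize the variational networks
#'
#' Encoder: normalized expression row -> q(z_y|X). Classifier: z_y ->
#' q(y|z_y). Nuisance encoder: (one-hot y, z_y) -> q(z1|y,z_y).
#'
#' @inheritParams generative_nets
#' @return A \code{variational_nets} list with elements \code{encoder},
#'   \code{classifier}, \code{nuisance}.
#' @export
variational_nets <- function(prior, G, hidden = HIDDEN_DEFAULT,
                             init_scale = 1, seed = NULL) {
  build <- function() {
    structure(list(
      encoder = mlp_init(G, hidden, c(mu = prior$d, sig = prior$d), init_scale),
      classifier = mlp_init(prior$d, hidden, c(logits = prior$L), init_scale),
      nuisance = mlp_init(prior$L + prior$d, hidden,
                          c(mu = prior$d1, sig = prior$d1), init_scale),
      G = as.integer(G), hidden = as.integer(hidden)
    ), class = "variational_nets")
  }
  if (is.null(seed)) build() else with_seed(seed, build())
}

#' Conditional prior p(z_y | y, z1)
#'
#' Evaluates the diagonal-Gaussian parameters of the complete-state prior
#' for given cell type and nuisance factor. Deterministic for fixed nets.
#'
#' @param y_onehot length-L one-hot vector (or n x L matrix of one-hot rows).
#' @param z1 length-d1 vector (or n x d1 matrix).
#' @param nets a \code{\link{generative_nets}}.
#' @return list with \code{mu} and \code{sigma}, each n x d.
#' @export
conditional_prior <- function(y_onehot, z1, nets) {
  if (is.null(dim(y_onehot))) y_onehot <- matrix(y_onehot, nrow = 1)
  if (is.null(dim(z1))) z1 <- matrix(z1, nrow = nrow(y_onehot))
  bad <- abs(rowSums(y_onehot) - 1) > 1e-9 |
    apply(y_onehot != 0 & y_onehot != 1, 1L, any)
  stop_if(any(bad), "y_onehot rows must be valid one-hot vectors")
  stop_if(any(!is.finite(z1)), "z1 must be finite")
  d_in <- nrow(nets$cond_prior$W1)
  stop_if(ncol(y_onehot) + ncol(z1) != d_in,
          sprintf("input width %d does not match network input %d",
                  ncol(y_onehot) + ncol(z1), d_in),
          class = "scfactor_shape_error")
  fw <- mlp_forward(nets$cond_prior, cbind(y_onehot, z1))
  list(mu = fw$out$mu, sigma = pos_transform(fw$out$sig, SIGMA_LO, SIGMA_HI))
}

#' Decode gene usage from the hidden cell state
#'
#' Maps z_y to Dirichlet concentrations alpha over genes and the implied
#' expected gene usage alpha / sum(alpha) (the Dirichlet mean of eta).
#'
#' @param zy length-d vector or n x d matrix of hidden states.
#' @param nets a \code{\link{generative_nets}}.
#' @return list with \code{alpha} (n x G, strictly positive) and
#'   \code{usage} (n x G, rows summing to 1).
#' @export
decode_usage <- function(zy, nets) {
  if (is.null(dim(zy))) zy <- matrix(zy, nrow = 1)
  stop_if(any(!is.finite(zy)), "zy must be finite")
  fw <- mlp_forward(nets$decoder, zy)
  alpha <- pos_transform(fw$out$alpha, ALPHA_LO, ALPHA_HI)
  list(alpha = alpha, usage = alpha / rowSums(alpha))
}

# Encoder input transform: counts are row-normalized to relative abundance,
# scaled by a common size factor (median training library size), then
# log1p-transformed.
encode_input <- function(X, size_factor) {
  tot <- rowSums(X)
  tot[tot == 0] <- 1
  log1p(X / tot * size_factor)
}

# ---------------------------------------------------------------------------
# ELBO engine (batched forward + analytic backward)
# ---------------------------------------------------------------------------

# Shared first stage: encoder and reparameterized zy.
.enc_stage <- function(Xin, var, eps_zy) {
  enc <- mlp_forward(var$encoder, Xin)
  sigq <- pos_transform(enc$out$sig, SIGMA_LO, SIGMA_HI)
  list(enc = enc, muq = enc$out$mu, sq_raw = enc$out$sig, sigq = sigq,
       zy = enc$out$mu + sigq * eps_zy)
}

# One (y, z1) branch: nuisance encoder, reparameterized z1, conditional
# prior. Returns the per-cell log terms and the caches for backward.
.branch_stage <- function(Yoh, zy, z1eps, gen, var, prior) {
  nenc <- mlp_forward(var$nuisance, cbind(Yoh, zy))
  sigq1 <- pos_transform(nenc$out$sig, SIGMA_LO, SIGMA_HI)
  muq1 <- nenc$out$mu
  z1 <- muq1 + sigq1 * z1eps
  cp <- mlp_forward(gen$cond_prior, cbind(Yoh, z1))
  sigp <- pos_transform(cp$out$sig, SIGMA_LO, SIGMA_HI)
  mup <- cp$out$mu
  n <- nrow(zy)
  mu0m <- matrix(prior$mu0, n, prior$d1, byrow = TRUE)
  s0m <- matrix(prior$sigma0, n, prior$d1, byrow = TRUE)
  list(nenc = nenc, muq1 = muq1, sq1_raw = nenc$out$sig, sigq1 = sigq1,
       z1 = z1, cp = cp, mup = mup, sp_raw = cp$out$sig, sigp = sigp,
       mu0m = mu0m, s0m = s0m,
       logp_zy = gauss_logpdf_rows(zy, mup, sigp),
       logp_z1 = gauss_logpdf_rows(z1, mu0m, s0m),
       logq_z1 = gauss_logpdf_rows(z1, muq1, sigq1))
}

# Backward through one branch given per-cell weights wgt (length n; all 1
# for the labeled path, beta * pi_y for enumerated unlabeled branches).
# Accumulates into an environment `acc` holding grad trees and g_zy.
.branch_backward <- function(br, zy, z1eps, gen, var, prior, wgt, beta, acc) {
  n <- nrow(zy); L <- prior$L; d1 <- prior$d1
  cw <- -beta * wgt                       # coefficient on +logp_zy etc in J
  p_zy <- gauss_logpdf_partials(zy, br$mup, br$sigp)
  g_mup <- cw * p_zy$mu
  g_sp_raw <- (cw * p_zy$sigma) * pos_transform_grad(br$sp_raw, SIGMA_LO, SIGMA_HI)
  cpb <- mlp_backward(gen$cond_prior, br$cp$cache,
                      list(mu = g_mup, sig = g_sp_raw))
  acc$g_cond <- param_add(acc$g_cond, cpb$grads)
  g_z1 <- cpb$g_input[, L + seq_len(d1), drop = FALSE]
  p1 <- gauss_logpdf_partials(br$z1, br$mu0m, br$s0m)
  q1 <- gauss_logpdf_partials(br$z1, br$muq1, br$sigq1)
  g_z1 <- g_z1 + cw * p1$z - cw * q1$z
  g_muq1 <- g_z1 - cw * q1$mu
  g_sq1_raw <- (g_z1 * z1eps - cw * q1$sigma) *
    pos_transform_grad(br$sq1_raw, SIGMA_LO, SIGMA_HI)
  nb <- mlp_backward(var$nuisance, br$nenc$cache,
                     list(mu = g_muq1, sig = g_sq1_raw))
  acc$g_nuis <- param_add(acc$g_nuis, nb$grads)
  acc$g_zy <- acc$g_zy + nb$g_input[, L + seq_len(prior$d), drop = FALSE] +
    cw * p_zy$z
  invisible(NULL)
}

param_add <- function(a, b) {
  if (is.null(a)) return(b)
  param_map2(a, b, `+`)
}

zero_like <- function(a) param_map(a, function(x) x * 0)

# Core labeled-cell objective. Returns per-cell ELBO, classifier loss, and
# (optionally) the gradient of sum_i(-elbo_i + w * classloss_i) wrt all
# network parameters.
elbo_engine_labeled <- function(X, Xin, y, gen, var, prior, eps_zy, eps_z1,
                                beta = 1, w = 1, grads = FALSE) {
  n <- nrow(X); L <- prior$L
  es <- .enc_stage(Xin, var, eps_zy)
  zy <- es$zy
  cls <- mlp_forward(var$classifier, zy)
  logpi <- log_softmax_rows(cls$out$logits)
  Yoh <- onehot(y, L)
  br <- .branch_stage(Yoh, zy, eps_z1, gen, var, prior)
  dec <- mlp_forward(gen$decoder, zy)
  alpha <- pos_transform(dec$out$alpha, ALPHA_LO, ALPHA_HI)
  loglik <- dirmult_logpmf_rows(X, alpha)
  logq_zy <- gauss_logpdf_rows(zy, es$muq, es$sigq)
  logpy <- log(prior$alpha0 / sum(prior$alpha0))[y]
  elbo <- loglik + beta * (br$logp_zy + logpy + br$logp_z1 -
                             logq_zy - br$logq_z1)
  class_loss <- -logpi[cbind(seq_len(n), y)]
  out <- list(elbo = elbo, class_loss = class_loss, zy = zy, logpi = logpi)
  if (!grads) return(out)

  acc <- new.env(parent = emptyenv())
  acc$g_cond <- NULL; acc$g_nuis <- NULL
  acc$g_zy <- matrix(0, n, prior$d)

  # decoder / likelihood
  g_alpha_raw <- (-dirmult_logpmf_grad_alpha(X, alpha)) *
    pos_transform_grad(dec$out$alpha, ALPHA_LO, ALPHA_HI)
  db <- mlp_backward(gen$decoder, dec$cache, list(alpha = g_alpha_raw))
  acc$g_zy <- acc$g_zy + db$g_input

  # classifier auxiliary loss
  pi_ <- exp(logpi)
  g_logits <- w * (pi_ - Yoh)
  cb <- mlp_backward(var$classifier, cls$cache, list(logits = g_logits))
  acc$g_zy <- acc$g_zy + cb$g_input

  # conditional prior / nuisance branch (unit weights)
  .branch_backward(br, zy, eps_z1, gen, var, prior, rep(1, n), beta, acc)

  # encoder (q(zy|X) entropy term + all accumulated zy gradients)
  qp <- gauss_logpdf_partials(zy, es$muq, es$sigq)
  g_zy <- acc$g_zy + beta * qp$z
  g_muq <- g_zy + beta * qp$mu
  g_sq_raw <- (g_zy * eps_zy + beta * qp$sigma) *
    pos_transform_grad(es$sq_raw, SIGMA_LO, SIGMA_HI)
  eb <- mlp_backward(var$encoder, es$enc$cache,
                     list(mu = g_muq, sig = g_sq_raw))

  out$grads <- list(
    gen = list(cond_prior = acc$g_cond, decoder = db$grads),
    var = list(encoder = eb$grads, classifier = cb$grads, nuisance = acc$g_nuis))
  out
}

# Core unlabeled-cell objective: y is enumerated over the L classes and
# weighted by the classifier q(y|zy); the entropy of q(y|zy) is added.
elbo_engine_unlabeled <- function(X, Xin, gen, var, prior, eps_zy, eps_z1,
                                  beta = 1, grads = FALSE) {
  n <- nrow(X); L <- prior$L
  es <- .enc_stage(Xin, var, eps_zy)
  zy <- es$zy
  cls <- mlp_forward(var$classifier, zy)
  logpi <- log_softmax_rows(cls$out$logits)
  pi_ <- exp(logpi)
  dec <- mlp_forward(gen$decoder, zy)
  alpha <- pos_transform(dec$out$alpha, ALPHA_LO, ALPHA_HI)
  loglik <- dirmult_logpmf_rows(X, alpha)
  logq_zy <- gauss_logpdf_rows(zy, es$muq, es$sigq)
  logpy_all <- log(prior$alpha0 / sum(prior$alpha0))

  branches <- vector("list", L)
  Amat <- matrix(0, n, L)
  for (k in seq_len(L)) {
    Yoh <- onehot(rep(k, n), L)
    br <- .branch_stage(Yoh, zy, eps_z1, gen, var, prior)
    branches[[k]] <- br
    Amat[, k] <- br$logp_zy + logpy_all[k] + br$logp_z1 - br$logq_z1
  }
  B <- Amat - logpi
  elbo <- loglik + beta * (rowSums(pi_ * B) - logq_zy)
  out <- list(elbo = elbo, zy = zy, logpi = logpi)
  if (!grads) return(out)

  acc <- new.env(parent = emptyenv())
  acc$g_cond <- NULL; acc$g_nuis <- NULL
  acc$g_zy <- matrix(0, n, prior$d)

  g_alpha_raw <- (-dirmult_logpmf_grad_alpha(X, alpha)) *
    pos_transform_grad(dec$out$alpha, ALPHA_LO, ALPHA_HI)
  db <- mlp_backward(gen$decoder, dec$cache, list(alpha = g_alpha_raw))
  acc$g_zy <- acc$g_zy + db$g_input

  # classifier: d/dlogits of -beta * sum_y pi_y (A_y - log pi_y)
  g_logits <- -beta * pi_ * (B - rowSums(pi_ * B))
  cb <- mlp_backward(var$classifier, cls$cache, list(logits = g_logits))
  acc$g_zy <- acc$g_zy + cb$g_input

  for (k in seq_len(L)) {
    .branch_backward(branches[[k]], zy, eps_z1, gen, var, prior,
                     pi_[, k], beta, acc)
  }

  qp <- gauss_logpdf_partials(zy, es$muq, es$sigq)
  g_zy <- acc$g_zy + beta * qp$z
  g_muq <- g_zy + beta * qp$mu
  g_sq_raw <- (g_zy * eps_zy + beta * qp$sigma) *
    pos_transform_grad(es$sq_raw, SIGMA_LO, SIGMA_HI)
  eb <- mlp_backward(var$encoder, es$enc$cache,
                     list(mu = g_muq, sig = g_sq_raw))

  out$grads <- list(
    gen = list(cond_prior = acc$g_cond, decoder = db$grads),
    var = list(encoder = eb$grads, classifier = cb$grads, nuisance = acc$g_nuis))
  out
}

#' Monte-Carlo ELBO of one labeled cell
#'
#' Reparameterized Monte-Carlo estimate of the evidence lower bound
#' \eqn{E_q[\log p(X, z_y, y, z_1) - \log q(z_y, z_1 | \cdot)]} for a cell
#' with observed type label, averaged over \code{n_mc} samples.
#'
#' @param counts_row length-G non-negative integer vector.
#' @param y_label integer in 1..L.
#' @param gen,var,prior model components.
#' @param n_mc number of Monte-Carlo samples (>= 1).
#' @param rng_seed integer seed; the estimate is reproducible given the seed.
#' @param size_factor scaling used in the encoder input transform; defaults
#'   to the row total.
#' @return The averaged ELBO estimate (a single number).
#' @export
elbo_labeled <- function(counts_row, y_label, gen, var, prior, n_mc = 1L,
                         rng_seed = 0L, size_factor = NULL) {
  stop_if(n_mc < 1, "n_mc must be >= 1")
  stop_if(y_label < 1 || y_label > prior$L || y_label != round(y_label),
          "y_label out of range", class = "scfactor_range_error")
  X <- matrix(rep(as.numeric(counts_row), n_mc), nrow = n_mc, byrow = TRUE)
  if (is.null(size_factor)) size_factor <- max(sum(counts_row), 1)
  Xin <- encode_input(X, size_factor)
  with_seed(rng_seed, {
    eps_zy <- matrix(stats::rnorm(n_mc * prior$d), n_mc, prior$d)
    eps_z1 <- matrix(stats::rnorm(n_mc * prior$d1), n_mc, prior$d1)
    res <- elbo_engine_labeled(X, Xin, rep(as.integer(y_label), n_mc),
                               gen, var, prior, eps_zy, eps_z1)
    mean(res$elbo)
  })
}

#' Monte-Carlo ELBO of one unlabeled cell
#'
#' As \code{\link{elbo_labeled}} but with the cell type enumerated over all
#' L classes, weighted by the classifier \eqn{q(y|z_y)}, plus the entropy of
#' \eqn{q(y|z_y)}.
#'
#' @inheritParams elbo_labeled
#' @return The averaged ELBO estimate (a single number).
#' @export
elbo_unlabeled <- function(counts_row, gen, var, prior, n_mc = 1L,
                           rng_seed = 0L, size_factor = NULL) {
  stop_if(n_mc < 1, "n_mc must be >= 1")
  X <- matrix(rep(as.numeric(counts_row), n_mc), nrow = n_mc, byrow = TRUE)
  if (is.null(size_factor)) size_factor <- max(sum(counts_row), 1)
  Xin <- encode_input(X, size_factor)
  with_seed(rng_seed, {
    eps_zy <- matrix(stats::rnorm(n_mc * prior$d), n_mc, prior$d)
    eps_z1 <- matrix(stats::rnorm(n_mc * prior$d1), n_mc, prior$d1)
    res <- elbo_engine_unlabeled(X, Xin, gen, var, prior, eps_zy, eps_z1)
    mean(res$elbo)
  })
}

#' Sample cells from the generative model
#'
#' Draws cell types, nuisance factors, hidden states, gene usages, and
#' multinomial counts following the generative process, conditioning each
#' cell's total on the requested library size.
#'
#' @param gen a \code{\link{generative_nets}}.
#' @param prior a \code{\link{prior_config}}.
#' @param n_cells number of cells to draw.
#' @param totals length-n positive integer library sizes (recycled if
#'   length 1).
#' @param rng_seed integer seed; identical seeds give identical output.
#' @return list with \code{data} (a \code{\link{count_matrix}}) and
#'   \code{truth} (sampled y, z1, zy, eta per cell).
#' @export
sample_generative <- function(gen, prior, n_cells, totals, rng_seed = 0L) {
  totals <- rep_len(as.integer(totals), n_cells)
  stop_if(any(totals < 1), "totals must be >= 1")
  G <- gen$G
  with_seed(rng_seed, {
    y <- sample.int(prior$L, n_cells, replace = TRUE,
                    prob = prior$alpha0 / sum(prior$alpha0))
    z1 <- matrix(stats::rnorm(n_cells * prior$d1), n_cells, prior$d1)
    z1 <- sweep(sweep(z1, 2, prior$sigma0, "*"), 2, prior$mu0, "+")
    cp <- conditional_prior(onehot(y, prior$L), z1, gen)
    zy <- cp$mu + cp$sigma * matrix(stats::rnorm(n_cells * prior$d),
                                    n_cells, prior$d)
    alpha <- decode_usage(zy, gen)$alpha
    gam <- matrix(stats::rgamma(n_cells * G, shape = alpha), n_cells, G)
    gam[gam <= 0] <- .Machine$double.xmin
    eta <- gam / rowSums(gam)
    counts <- matrix(0, n_cells, G)
    for (i in seq_len(n_cells)) {
      counts[i, ] <- stats::rmultinom(1, totals[i], eta[i, ])
    }
    data <- count_matrix(counts,
                         cell_ids = sprintf("cell_%d", seq_len(n_cells)),
                         gene_ids = sprintf("gene_%d", seq_len(G)))
    list(data = data,
         truth = list(y = y, z1 = z1, zy = zy, eta = eta, seed = rng_seed))
  })
}
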