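# Minimal multilayer-perceptron machinery for the amortized networks.
#
# Every network in the model is a 2-hidden-layer perceptron with a tanh
# (smooth, saturating) nonlinearity and one or more linear output heads.
# Positivity constraints (scales, concentrations) are applied outside the
# MLP by a clamped softplus so the backward pass stays purely linear/tanh.
#
# Parameters are stored as plain matrices; gradients mirror the structure,
# which keeps the Adam update a structural walk over named lists.

# Create a 2-hidden-layer MLP with input width d_in, hidden width `hidden`,
# and linear heads of the given output widths (named integer vector).
# Weights are fan-in scaled Gaussian; draws come from the current RNG state.
mlp_init <- function(d_in, hidden, heads, init_scale = 1) {
  rmat <- function(nr, nc) {
    matrix(stats::rnorm(nr * nc, sd = init_scale / sqrt(max(nr, 1))), nr, nc)
  }
  net <- list(
    W1 = rmat(d_in, hidden), b1 = rep(0, hidden),
    W2 = rmat(hidden, hidden), b2 = rep(0, hidden),
    heads = lapply(heads, function(k) list(W = rmat(hidden, k), b = rep(0, k)))
  )
  names(net$heads) <- names(heads)
  class(net) <- "scfactor_mlp"
  net
}

# Forward pass for a batch X (n x d_in). Returns the raw (linear) head
# outputs plus the cache needed for the backward pass.
mlp_forward <- function(net, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  h1 <- tanh(sweep(X %*% net$W1, 2, net$b1, "+"))
  h2 <- tanh(sweep(h1 %*% net$W2, 2, net$b2, "+"))
  out <- lapply(net$heads, function(h) sweep(h2 %*% h$W, 2, h$b, "+"))
  list(out = out, cache = list(X = X, h1 = h1, h2 = h2))
}

# Backward pass. g_heads is a named list of gradients wrt the raw head
# outputs (each n x k or NULL to skip a head). Returns parameter gradients
# in the same structure as the net, plus the gradient wrt the input rows.
mlp_backward <- function(net, cache, g_heads) {
  X <- cache$X; h1 <- cache$h1; h2 <- cache$h2
  n_heads <- names(net$heads)
  g_h2 <- matrix(0, nrow(h2), ncol(h2))
  grads_heads <- vector("list", length(n_heads)); names(grads_heads) <- n_heads
  for (nm in n_heads) {
    g <- g_heads[[nm]]
    if (is.null(g)) {
      grads_heads[[nm]] <- list(W = net$heads[[nm]]$W * 0,
                                b = net$heads[[nm]]$b * 0)
      next
    }
    grads_heads[[nm]] <- list(W = crossprod(h2, g), b = colSums(g))
    g_h2 <- g_h2 + g %*% t(net$heads[[nm]]$W)
  }
  d2 <- g_h2 * (1 - h2^2)           # through tanh
  gW2 <- crossprod(h1, d2); gb2 <- colSums(d2)
  g_h1 <- d2 %*% t(net$W2)
  d1 <- g_h1 * (1 - h1^2)
  gW1 <- crossprod(X, d1); gb1 <- colSums(d1)
  g_input <- d1 %*% t(net$W1)
  list(grads = list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2,
                    heads = grads_heads),
       g_input = g_input)
}

# Structural zip over two parameter trees (net-shaped nested lists).
param_map2 <- function(a, b, f) {
  if (is.list(a)) {
    out <- mapply(param_map2, a, b, MoreArgs = list(f = f), SIMPLIFY = FALSE)
    class(out) <- class(a)
    out
  } else {
    f(a, b)
  }
}

param_map <- function(a, f) {
  if (is.list(a)) {
    out <- lapply(a, param_map, f = f)
    class(out) <- class(a)
    out
  } else {
    f(a)
  }
}

# Sum of f over all leaves (used for diagnostics, e.g. finiteness checks).
param_all_finite <- function(a) {
  if (is.list(a)) all(vapply(a, param_all_finite, logical(1))) else all(is.finite(a))
}
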