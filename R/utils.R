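# Internal numeric helpers shared across the model code.

# Numerically stable softplus: log(1 + exp(x)).
softplus <- function(x) {
  ifelse(x > 30, x, log1p(exp(pmin(x, 30))))
}

# Derivative of softplus = logistic sigmoid.
softplus_grad <- function(x) {
  1 / (1 + exp(-pmax(pmin(x, 30), -30)))
}

# Hard clamp; gradient is taken as zero outside [lo, hi].
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Positive transform used for scale/concentration outputs: clamped softplus.
# Returns the value; the backward pass multiplies incoming gradients by
# softplus_grad(x) masked to the interior of the clamp interval.
pos_transform <- function(x, lo, hi) clamp(softplus(x), lo, hi)

pos_transform_grad <- function(x, lo, hi) {
  s <- softplus(x)
  softplus_grad(x) * as.numeric(s > lo & s < hi)
}

# Row-wise log-softmax for an n x K matrix.
log_softmax_rows <- function(logits) {
  m <- apply(logits, 1L, max)
  z <- logits - m
  z - log(rowSums(exp(z)))
}

softmax_rows <- function(logits) {
  p <- exp(log_softmax_rows(logits))
  p / rowSums(p)
}

# One-hot encode integer labels in 1..L into an n x L matrix.
onehot <- function(y, L) {
  n <- length(y)
  out <- matrix(0, n, L)
  out[cbind(seq_len(n), y)] <- 1
  out
}

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards. Keeps library functions from
# clobbering user-level reproducibility.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

stop_if <- function(cond, msg, class = "scfactor_error") {
  if (cond) stop(structure(class = c(class, "error", "condition"),
                           list(message = msg, call = sys.call(-1))))
}

as_dense <- function(x) {
  if (inherits(x, "Matrix")) as.matrix(x) else x
}
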