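#' Dirichlet-multinomial log probability mass
#'
#' Log-pmf of the compound distribution obtained by drawing a probability
#' vector \eqn{\eta \sim \mathrm{Dirichlet}(\alpha)} and counts
#' \eqn{X \sim \mathrm{Multinomial}(n, \eta)}, conditioned on the observed
#' total \eqn{n = \sum_g x_g}. Marginalizing \eqn{\eta} analytically gives
#' \deqn{P(x \mid \alpha) = \frac{n!}{\prod_g x_g!}
#'   \frac{\Gamma(A)}{\Gamma(A+n)} \prod_g
#'   \frac{\Gamma(x_g+\alpha_g)}{\Gamma(\alpha_g)}, \quad A = \sum_g \alpha_g.}
#' This is the per-cell likelihood of the count model: the gene usage
#' (relative abundance) is Dirichlet-distributed and the observed counts are
#' multinomial draws from it.
#'
#' @param counts_row Non-negative integer vector of length G (counts of one
#'   cell).
#' @param alpha Positive finite numeric vector of length G (Dirichlet
#'   concentrations).
#' @return The log probability (a single number, \eqn{\le 0}).
#' @examples
#' dirichlet_multinomial_logpmf(c(2, 0), c(1, 1))  # log(1/3)
#' @export
dirichlet_multinomial_logpmf <- function(counts_row, alpha) {
  stop_if(length(counts_row) != length(alpha),
          "counts_row and alpha must have equal length")
  stop_if(any(!is.finite(alpha)) || any(alpha <= 0),
          "alpha must be finite and strictly positive")
  stop_if(any(counts_row < 0) || any(counts_row != round(counts_row)),
          "counts must be non-negative integers")
  n <- sum(counts_row)
  if (n == 0) return(0)
  A <- sum(alpha)
  lgamma(n + 1) - sum(lgamma(counts_row + 1)) +
    lgamma(A) - lgamma(A + n) +
    sum(lgamma(counts_row + alpha) - lgamma(alpha))
}

# Row-wise Dirichlet-multinomial log-pmf for an n x G count matrix and an
# n x G concentration matrix. Returns a length-n vector.
dirmult_logpmf_rows <- function(X, alpha) {
  n_tot <- rowSums(X)
  A <- rowSums(alpha)
  lgamma(n_tot + 1) - rowSums(lgamma(X + 1)) +
    lgamma(A) - lgamma(A + n_tot) +
    rowSums(lgamma(X + alpha) - lgamma(alpha))
}

# Gradient of dirmult_logpmf_rows with respect to alpha (n x G matrix).
dirmult_logpmf_grad_alpha <- function(X, alpha) {
  n_tot <- rowSums(X)
  A <- rowSums(alpha)
  # digamma(A) - digamma(A + n) broadcast over genes, plus per-gene terms
  (digamma(A) - digamma(A + n_tot)) + digamma(X + alpha) - digamma(alpha)
}

# Diagonal-Gaussian log-density, row-wise: z, mu, sigma are n x d matrices
# (sigma is the standard deviation). Returns a length-n vector.
gauss_logpdf_rows <- function(z, mu, sigma) {
  d <- ncol(z)
  -rowSums(log(sigma)) - 0.5 * d * log(2 * pi) -
    0.5 * rowSums(((z - mu) / sigma)^2)
}

# Partial derivatives of gauss_logpdf_rows wrt z, mu, sigma (each n x d).
gauss_logpdf_partials <- function(z, mu, sigma) {
  u <- (z - mu) / sigma^2
  list(z = -u, mu = u, sigma = -1 / sigma + (z - mu)^2 / sigma^3)
}
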