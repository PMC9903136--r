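# Dirichlet-process Gaussian-mixture subclustering of 2-D cell coordinates.
#
# Truncated stick-breaking variational DP-GMM with full covariances,
# fit by coordinate-ascent variational inference (CAVI):
#   v_k ~ Beta(1, gamma), pi_k = v_k * prod_{j<k}(1 - v_j)   (sticks)
#   (mu_k, Lambda_k) ~ Normal-Wishart(m0, beta0, W0, nu0)
#   x_i | z_i = k ~ Normal(mu_k, Lambda_k^{-1})
# The variational posterior truncates the sticks at `max_components` and
# the number of subpopulations is read off as the number of components
# that retain appreciable mass.

#' Dirichlet-process mixture clustering
#'
#' Clusters 2-D coordinates (typically UMAP output) with a truncated
#' variational Dirichlet-process Gaussian mixture and automatically
#' estimates the number of occupied subpopulations.
#'
#' @param coords cells x m numeric matrix (m = 2 for UMAP coordinates).
#' @param max_components stick-breaking truncation level (default 20).
#' @param weight_floor minimum mixing proportion for a component to count
#'   as occupied (default 0.01).
#' @param seed integer seed controlling the k-means initialization.
#' @param max_iter CAVI iteration cap (default 500).
#' @param tol convergence tolerance on the responsibility change.
#' @return A \code{SubclusterResult} list: \code{labels} (per-cell component
#'   index, renumbered 1..K in order of decreasing weight among occupied
#'   components, 0 never occurs), \code{K_effective}, \code{weights}
#'   (per-component proportions summing to 1), \code{max_components},
#'   \code{seed}.
#' @export
dp_cluster <- function(coords, max_components = 20L, weight_floor = 0.01,
                       seed = 0L, max_iter = 500L, tol = 1e-7) {
  coords <- as.matrix(coords)
  n <- nrow(coords); D <- ncol(coords)
  stop_if(n < 2, "dp_cluster needs at least 2 cells")
  stop_if(max_components < 1, "max_components must be >= 1")

  # degenerate input: all points (numerically) identical
  if (all(apply(coords, 2L, function(v) diff(range(v))) < 1e-12)) {
    warning("all coordinates identical; returning a single component")
    return(structure(list(labels = rep(1L, n), K_effective = 1L,
                          weights = 1, max_components = as.integer(max_components),
                          seed = as.integer(seed)),
                     class = "SubclusterResult"))
  }

  T_ <- as.integer(max_components)
  gamma0 <- 1 / T_                         # DP concentration prior
  m0 <- colMeans(coords)
  beta0 <- 1
  nu0 <- D + 2
  cov_d <- stats::cov(coords)
  cov_d <- cov_d + diag(1e-8 * max(diag(cov_d), 1e-12), D)
  W0inv <- cov_d * nu0                     # prior scatter ~ data covariance
  W0 <- solve(W0inv)

  # seeded k-means initialization of responsibilities
  r <- with_seed(seed, {
    centers <- min(T_, nrow(unique(coords)))
    km <- suppressWarnings(stats::kmeans(coords, centers = centers,
                                         nstart = 5, iter.max = 50))
    r0 <- matrix(1e-8, n, T_)
    r0[cbind(seq_len(n), km$cluster)] <- 1
    r0 / rowSums(r0)
  })

  logdet <- function(M) as.numeric(determinant(M, logarithm = TRUE)$modulus)

  for (iter in seq_len(max_iter)) {
    Nk <- colSums(r)
    # --- update q(v): stick-breaking Beta parameters (v_T fixed at 1)
    if (T_ > 1) {
      tail_sums <- rev(cumsum(rev(Nk)))     # sum_{j >= k} N_j
      ak <- (1 + Nk)[-T_]
      bk <- gamma0 + tail_sums[-1]          # gamma0 + sum_{j > k} N_j
      Elogv <- c(digamma(ak) - digamma(ak + bk), 0)
      Elog1mv <- c(digamma(bk) - digamma(ak + bk), 0)
      Elogpi <- Elogv + c(0, cumsum(Elog1mv[-T_]))
    } else {
      Elogpi <- 0
    }
    # --- update q(mu, Lambda): Normal-Wishart
    betak <- beta0 + Nk
    nuk <- nu0 + Nk
    Elogdet <- numeric(T_)
    quad <- matrix(0, n, T_)
    for (k in seq_len(T_)) {
      if (Nk[k] > 1e-10) {
        xbar <- colSums(r[, k] * coords) / Nk[k]
        xc <- sweep(coords, 2L, xbar)
        Sk <- crossprod(xc * sqrt(r[, k])) / Nk[k]
      } else {
        xbar <- m0
        Sk <- matrix(0, D, D)
      }
      mk <- (beta0 * m0 + Nk[k] * xbar) / betak[k]
      dm <- xbar - m0
      Winv_k <- W0inv + Nk[k] * Sk +
        (beta0 * Nk[k] / (beta0 + Nk[k])) * tcrossprod(dm)
      Winv_k <- Winv_k + diag(1e-10 * max(diag(Winv_k)), D)
      Wk <- solve(Winv_k)
      Elogdet[k] <- sum(digamma((nuk[k] + 1 - seq_len(D)) / 2)) +
        D * log(2) + logdet(Wk)
      xm <- sweep(coords, 2L, mk)
      quad[, k] <- D / betak[k] + nuk[k] * rowSums((xm %*% Wk) * xm)
    }
    # --- update q(z): responsibilities
    logrho <- sweep(quad, 2L, Elogpi + 0.5 * Elogdet, function(q, c) c - 0.5 * q) -
      0.5 * D * log(2 * pi)
    r_new <- exp(logrho - apply(logrho, 1L, max))
    r_new <- r_new / rowSums(r_new)
    delta <- max(abs(r_new - r))
    r <- r_new
    if (delta < tol) break
  }

  Nk <- colSums(r)
  weights <- Nk / n
  hard <- apply(r, 1L, which.max)
  occupied <- which(weights >= weight_floor & tabulate(hard, T_) >= 1)
  if (length(occupied) == 0) occupied <- which.max(weights)
  # cells in pruned components are reassigned to their best occupied one
  relab <- integer(n)
  ord <- occupied[order(weights[occupied], decreasing = TRUE)]
  for (i in seq_len(n)) {
    k <- hard[i]
    if (!(k %in% ord)) k <- ord[which.max(r[i, ord])]
    relab[i] <- match(k, ord)
  }
  structure(list(labels = relab,
                 K_effective = length(ord),
                 weights = weights[ord] / sum(weights[ord]),
                 max_components = T_,
                 seed = as.integer(seed)),
            class = "SubclusterResult")
}

#' @export
print.SubclusterResult <- function(x, ...) {
  cat(sprintf("DP-mixture subclustering: K_effective = %d (truncation %d)\n",
              x$K_effective, x$max_components))
  cat("weights:", paste(sprintf("%.3f", x$weights), collapse = " "), "\n")
  invisible(x)
}
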