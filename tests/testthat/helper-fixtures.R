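# Shared fixtures: tiny models and datasets built in code.

tiny_prior <- function(L = 3, d = 4, d1 = 2) prior_config(L = L, d = d, d1 = d1)

tiny_nets <- function(prior = tiny_prior(), G = 6, hidden = 5,
                      seed_gen = 1, seed_var = 2, init_scale = 1) {
  list(gen = generative_nets(prior, G, hidden = hidden,
                             init_scale = init_scale, seed = seed_gen),
       var = variational_nets(prior, G, hidden = hidden,
                              init_scale = init_scale, seed = seed_var),
       prior = prior, G = G)
}

# Gaussian blobs in 2-D, n points each, centers as rows of `centers`.
make_blobs <- function(centers, n = 300, sd = 0.1, seed = 0) {
  scfactor:::with_seed(seed, {
    coords <- do.call(rbind, lapply(seq_len(nrow(centers)), function(k) {
      cbind(rnorm(n, centers[k, 1], sd), rnorm(n, centers[k, 2], sd))
    }))
    list(coords = coords, truth = rep(seq_len(nrow(centers)), each = n))
  })
}

# A quick-to-fit, well-separated training problem for functional tests.
quick_fit <- function(n_cells = 150, G = 40, epochs = 30, seed = 0,
                      labeled_fraction = 0.8, batch_strength = 0.5) {
  sim <- simulate_dataset(L = 3, G = G, B = 2, n_cells = n_cells,
                          batch_strength = batch_strength,
                          labeled_fraction = labeled_fraction, seed = seed)
  prior <- prior_config(L = 3, d = 8, d1 = 3)
  cfg <- train_config(epochs = epochs, minibatch_size = 64,
                      kl_warmup_epochs = min(10, epochs), hidden = 32,
                      seed = seed)
  model <- svi_fit(sim$data, sim$labels, prior = prior, cfg = cfg)
  list(sim = sim, model = model)
}

# Brute-force adjusted Rand index by enumerating all item pairs.
ari_bruteforce <- function(a, b) {
  n <- length(a)
  s_ab <- s_a <- s_b <- npairs <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    same_a <- a[i] == a[j]; same_b <- b[i] == b[j]
    npairs <- npairs + 1
    if (same_a) s_a <- s_a + 1
    if (same_b) s_b <- s_b + 1
    if (same_a && same_b) s_ab <- s_ab + 1
  }
  expected <- s_a * s_b / npairs
  max_index <- (s_a + s_b) / 2
  if (abs(max_index - expected) < 1e-12) return(1)
  (s_ab - expected) / (max_index - expected)
}

# All compositions of total n into G non-negative parts.
compositions <- function(n, G) {
  if (G == 1) return(matrix(n, 1, 1))
  out <- NULL
  for (k in 0:n) {
    rest <- compositions(n - k, G - 1)
    out <- rbind(out, cbind(k, rest))
  }
  unname(out)
}
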