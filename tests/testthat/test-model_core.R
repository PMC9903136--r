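# Dirichlet-multinomial likelihood, conditional prior, decoder, ELBO.

test_that("dirichlet-multinomial log-pmf matches closed-form and degenerate cases", {
  # single category: only one outcome given the total
  expect_equal(dirichlet_multinomial_logpmf(5, 2.3), 0)
  # zero total count
  expect_equal(dirichlet_multinomial_logpmf(c(0, 0, 0), c(2, 3, 4)), 0)
  # closed form cross-checked by numerical integration of the binomial
  # likelihood over a Dirichlet(1,1) (= uniform) prior on eta
  expect_equal(dirichlet_multinomial_logpmf(c(2, 0), c(1, 1)), log(1 / 3),
               tolerance = 1e-12)
  oracle <- stats::integrate(function(p) dbinom(2, 2, p), 0, 1)$value
  expect_equal(exp(dirichlet_multinomial_logpmf(c(2, 0), c(1, 1))), oracle,
               tolerance = 1e-8)
})

test_that("dirichlet-multinomial is a proper pmf over compositions", {
  for (G in 2:3) for (n in c(1, 4, 6)) {
    alpha <- seq(0.5, length.out = G, by = 0.7)
    cc <- compositions(n, G)
    total <- sum(apply(cc, 1, dirichlet_multinomial_logpmf, alpha = alpha,
                       simplify = TRUE) |> exp())
    expect_equal(total, 1, tolerance = 1e-8)
  }
})

test_that("large-concentration limit recovers the multinomial pmf", {
  p <- c(0.2, 0.5, 0.3)
  x <- c(3, 1, 2)
  dm <- dirichlet_multinomial_logpmf(x, 1e6 * p)
  expect_equal(dm, dmultinom(x, prob = p, log = TRUE), tolerance = 1e-3)
})

test_that("dirichlet-multinomial rejects invalid inputs", {
  expect_error(dirichlet_multinomial_logpmf(c(1, 2), c(1, -1)), "positive")
  expect_error(dirichlet_multinomial_logpmf(c(1, 2), c(1, Inf)), "finite")
  expect_error(dirichlet_multinomial_logpmf(c(-1, 2), c(1, 1)), "non-negative")
})

test_that("conditional prior: zero-weight baseline, determinism, clamped scales", {
  tn <- tiny_nets()
  zero_gen <- scfactor:::param_map(tn$gen, function(x) x * 0)
  zero_gen$G <- tn$gen$G
  y1 <- c(1, 0, 0)
  out0 <- conditional_prior(y1, c(0.3, -0.2), zero_gen)
  expect_equal(as.numeric(out0$mu), rep(0, tn$prior$d))
  expect_equal(as.numeric(out0$sigma), rep(log(2), tn$prior$d),
               tolerance = 1e-12)  # softplus(0)
  a <- conditional_prior(y1, c(1.5, 2), tn$gen)
  b <- conditional_prior(y1, c(1.5, 2), tn$gen)
  expect_identical(a, b)
  # scale outputs stay inside the clamp bounds for random inputs
  scfactor:::with_seed(7, {
    for (rep in 1:50) {
      y <- scfactor:::onehot(sample(3, 20, replace = TRUE), 3)
      z1 <- matrix(rnorm(20 * 2, sd = 5), 20, 2)
      s <- conditional_prior(y, z1, tn$gen)$sigma
      expect_true(all(s >= 1e-3 & s <= 10))
    }
  })
  expect_error(conditional_prior(c(0.5, 0.5, 0), c(0, 0), tn$gen), "one-hot")
  expect_error(conditional_prior(c(1, 0), c(0, 0), tn$gen),
               class = "scfactor_shape_error")
})

test_that("decode_usage returns positive concentrations on the simplex", {
  tn <- tiny_nets()
  scfactor:::with_seed(11, {
    zy <- matrix(rnorm(100 * tn$prior$d, sd = 3), 100, tn$prior$d)
    out <- decode_usage(zy, tn$gen)
    expect_true(all(out$alpha > 0))
    expect_equal(rowSums(out$usage), rep(1, 100), tolerance = 1e-6)
    expect_equal(out$usage, out$alpha / rowSums(out$alpha), tolerance = 1e-10)
  })
  expect_error(decode_usage(c(1, NA, 0, 0), tn$gen), "finite")
})

test_that("constant decoder gives the analytic Dirichlet mean", {
  prior <- prior_config(L = 1, d = 2, d1 = 0)
  gen <- generative_nets(prior, G = 2, hidden = 3, seed = 1)
  gen$decoder <- scfactor:::param_map(gen$decoder, function(x) x * 0)
  # force alpha = (3, 1) through the head bias (softplus^{-1})
  gen$decoder$heads$alpha$b <- log(exp(c(3, 1)) - 1)
  out <- decode_usage(c(0.4, -1), gen)
  expect_equal(as.numeric(out$alpha), c(3, 1), tolerance = 1e-12)
  expect_equal(as.numeric(out$usage), c(0.75, 0.25), tolerance = 1e-12)
})

test_that("analytic ELBO gradients agree with finite differences", {
  tn <- tiny_nets()
  prior <- tn$prior; G <- tn$G
  scfactor:::with_seed(42, {
    n <- 3
    X <- matrix(rpois(n * G, 8), n, G)
    Xin <- scfactor:::encode_input(X, median(rowSums(X)))
    y <- c(1L, 2L, 3L)
    eps_zy <- matrix(rnorm(n * prior$d), n, prior$d)
    eps_z1 <- matrix(rnorm(n * prior$d1), n, prior$d1)
    beta <- 0.7; w <- 1.3
    params <- list(gen = tn$gen[c("cond_prior", "decoder")],
                   var = tn$var[c("encoder", "classifier", "nuisance")])
    theta <- scfactor:::param_flatten(params)
    rebuild <- function(th) {
      p <- scfactor:::param_unflatten(th, params)
      gen <- tn$gen; gen$cond_prior <- p$gen$cond_prior; gen$decoder <- p$gen$decoder
      var <- tn$var; var$encoder <- p$var$encoder
      var$classifier <- p$var$classifier; var$nuisance <- p$var$nuisance
      list(gen = gen, var = var)
    }
    objectives <- list(
      labeled = function(nets) {
        r <- scfactor:::elbo_engine_labeled(X, Xin, y, nets$gen, nets$var,
                                            prior, eps_zy, eps_z1,
                                            beta = beta, w = w)
        sum(-r$elbo + w * r$class_loss)
      },
      unlabeled = function(nets) {
        r <- scfactor:::elbo_engine_unlabeled(X, Xin, nets$gen, nets$var,
                                              prior, eps_zy, eps_z1,
                                              beta = beta)
        sum(-r$elbo)
      })
    analytic <- list(
      labeled = scfactor:::elbo_engine_labeled(
        X, Xin, y, tn$gen, tn$var, prior, eps_zy, eps_z1,
        beta = beta, w = w, grads = TRUE)$grads,
      unlabeled = scfactor:::elbo_engine_unlabeled(
        X, Xin, tn$gen, tn$var, prior, eps_zy, eps_z1,
        beta = beta, grads = TRUE)$grads)
    for (case in names(objectives)) {
      ga <- scfactor:::param_flatten(analytic[[case]])
      idx <- sort(sample(length(theta), 40))
      h <- 1e-5
      gn <- vapply(idx, function(j) {
        tp <- theta; tp[j] <- tp[j] + h
        tm <- theta; tm[j] <- tm[j] - h
        (objectives[[case]](rebuild(tp)) - objectives[[case]](rebuild(tm))) / (2 * h)
      }, numeric(1))
      rel <- abs(gn - ga[idx]) / pmax(abs(gn) + abs(ga[idx]), 1e-8)
      expect_lt(max(rel), 1e-4)
    }
  })
})

test_that("ELBO is bounded by quadrature log-evidence on the 1-D toy model", {
  # toy: L = 1, d = 1, d1 = 0, G = 2, small fixed networks
  prior <- prior_config(L = 1, d = 1, d1 = 0)
  gen <- generative_nets(prior, G = 2, hidden = 3, init_scale = 1.5, seed = 5)
  var <- variational_nets(prior, G = 2, hidden = 3, seed = 6)
  x <- c(7, 3)
  # independent oracle: fine-grid quadrature of p(x | zy) over p(zy | y)
  cp <- conditional_prior(1, matrix(0, 1, 0), gen)
  cp <- list(mu = as.numeric(cp$mu), sigma = as.numeric(cp$sigma))
  grid <- seq(cp$mu - 10 * cp$sigma, cp$mu + 10 * cp$sigma, length.out = 4001)
  h <- diff(grid[1:2])
  dens <- vapply(grid, function(z) {
    a <- decode_usage(z, gen)$alpha
    exp(dirichlet_multinomial_logpmf(x, as.numeric(a))) *
      dnorm(z, cp$mu, cp$sigma)
  }, numeric(1))
  logZ <- log(sum(dens) * h)
  expect_lte(logZ, 0)  # log-evidence of a discrete observation
  # MC ELBO with per-sample standard error
  n_mc <- 10000
  X <- matrix(rep(x, n_mc), n_mc, byrow = TRUE)
  Xin <- scfactor:::encode_input(X, sum(x))
  res <- scfactor:::with_seed(0, {
    eps_zy <- matrix(rnorm(n_mc), n_mc, 1)
    eps_z1 <- matrix(0, n_mc, 0)
    scfactor:::elbo_engine_labeled(X, Xin, rep(1L, n_mc), gen, var, prior,
                                   eps_zy, eps_z1)
  })
  est <- mean(res$elbo)
  se <- sd(res$elbo) / sqrt(n_mc)
  expect_lte(est, logZ + 3 * se)
  expect_lte(est, 0 + 3 * se)
})

test_that("unlabeled ELBO collapses to the labeled one for L = 1 and matches the enumerated bound for symmetric classes", {
  prior1 <- prior_config(L = 1, d = 2, d1 = 1)
  gen1 <- generative_nets(prior1, G = 4, hidden = 4, seed = 3)
  var1 <- variational_nets(prior1, G = 4, hidden = 4, seed = 4)
  x <- c(2, 0, 5, 1)
  e_lab <- elbo_labeled(x, 1, gen1, var1, prior1, n_mc = 50, rng_seed = 9)
  e_unl <- elbo_unlabeled(x, gen1, var1, prior1, n_mc = 50, rng_seed = 9)
  expect_equal(e_lab, e_unl, tolerance = 1e-10)
  # determinism under a fixed seed
  expect_identical(e_lab,
                   elbo_labeled(x, 1, gen1, var1, prior1, n_mc = 50,
                                rng_seed = 9))
  # L = 2 with exactly symmetric classes: enumeration oracle. Making both
  # branches identical (tied one-hot columns) means the enumerated bound
  # must equal the single-class bound minus the entropy deficit, which for
  # a uniform classifier is zero net: check against direct enumeration.
  prior2 <- prior_config(L = 2, d = 2, d1 = 1)
  gen2 <- generative_nets(prior2, G = 4, hidden = 4, seed = 3)
  var2 <- variational_nets(prior2, G = 4, hidden = 4, seed = 4)
  # tie the class columns so both labels induce identical distributions
  gen2$cond_prior$W1[2, ] <- gen2$cond_prior$W1[1, ]
  var2$nuisance$W1[2, ] <- var2$nuisance$W1[1, ]
  # classifier output does not matter for the A-terms now; the unlabeled
  # bound equals labeled bound + entropy of q(y|zy)
  n_mc <- 200
  X <- matrix(rep(x, n_mc), n_mc, byrow = TRUE)
  Xin <- scfactor:::encode_input(X, sum(x))
  both <- scfactor:::with_seed(17, {
    eps_zy <- matrix(rnorm(n_mc * 2), n_mc, 2)
    eps_z1 <- matrix(rnorm(n_mc), n_mc, 1)
    lab <- scfactor:::elbo_engine_labeled(X, Xin, rep(1L, n_mc), gen2, var2,
                                          prior2, eps_zy, eps_z1)
    unl <- scfactor:::elbo_engine_unlabeled(X, Xin, gen2, var2, prior2,
                                            eps_zy, eps_z1)
    list(lab = lab, unl = unl)
  })
  logpi <- both$lab$logpi
  entropy <- -rowSums(exp(logpi) * logpi)
  # both branches identical => enumeration gives exactly the labeled bound
  # plus the entropy of q(y|zy)
  expect_equal(both$unl$elbo, both$lab$elbo + entropy, tolerance = 1e-8)
})

test_that("generative sampling conserves totals, matches prior frequencies, and is seed-reproducible", {
  prior <- prior_config(L = 3, d = 3, d1 = 2)
  gen <- generative_nets(prior, G = 5, hidden = 4, seed = 8)
  totals <- sample(50:200, 400, replace = TRUE)
  s1 <- sample_generative(gen, prior, 400, totals, rng_seed = 21)
  s2 <- sample_generative(gen, prior, 400, totals, rng_seed = 21)
  expect_identical(s1$data$counts, s2$data$counts)
  expect_equal(rowSums(s1$data$counts), as.numeric(totals))
  expect_equal(rowSums(s1$truth$eta), rep(1, 400), tolerance = 1e-9)
  # empirical type frequencies within 3 binomial standard errors of 1/3
  big <- sample_generative(gen, prior, 20000, 1, rng_seed = 22)
  freq <- tabulate(big$truth$y, 3) / 20000
  se <- sqrt((1 / 3) * (2 / 3) / 20000)
  expect_true(all(abs(freq - 1 / 3) < 3 * se))
})
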