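# Embedding, annotation, batch-corrected usage, UMAP.

qf <- quick_fit(n_cells = 120, G = 30, epochs = 20, seed = 3)

test_that("embed returns the encoder posterior mean, deterministically", {
  zy <- embed(qf$sim$data, qf$model)
  expect_equal(ncol(zy), qf$model$prior$d)
  expect_equal(nrow(zy), 120)
  expect_true(all(is.finite(zy)))
  # direct recomputation oracle
  Xin <- scfactor:::encode_input(scfactor:::cm_dense(qf$sim$data),
                                 qf$model$size_factor)
  mu <- scfactor:::mlp_forward(qf$model$var$encoder, Xin)$out$mu
  expect_equal(zy, mu, tolerance = 1e-10)
  # duplicated cells embed identically
  dup <- count_matrix(qf$sim$data$counts[c(1, 1, 2), ],
                      c("a", "b", "c"), qf$sim$data$gene_ids)
  zd <- embed(dup, qf$model)
  expect_identical(zd[1, ], zd[2, ])
})

test_that("classify outputs simplex rows, composes with embed, and breaks ties low", {
  cl <- classify(qf$sim$data, qf$model)
  expect_equal(rowSums(cl$y_prob), rep(1, 120), tolerance = 1e-6)
  expect_true(all(cl$y_prob >= 0))
  # compositionality: probabilities equal classifier applied to embed()
  zy <- embed(qf$sim$data, qf$model)
  logits <- scfactor:::mlp_forward(qf$model$var$classifier, zy)$out$logits
  expect_equal(unname(cl$y_prob), scfactor:::softmax_rows(logits),
               tolerance = 1e-12)
  # declared tie-break: exact tie -> lowest vocabulary index
  p_tie <- matrix(1 / 3, 1, 3)
  expect_equal(which.max(p_tie[1, ]), 1L)
})

test_that("gene alignment matches by id and flags mismatches", {
  perm <- sample(seq_len(30))
  data_perm <- count_matrix(qf$sim$data$counts[, perm],
                            qf$sim$data$cell_ids,
                            qf$sim$data$gene_ids[perm])
  expect_equal(embed(data_perm, qf$model), embed(qf$sim$data, qf$model),
               tolerance = 1e-12)
  alien <- count_matrix(qf$sim$data$counts,
                        qf$sim$data$cell_ids,
                        c(sprintf("other_%d", 1:29), qf$sim$data$gene_ids[30]))
  expect_error(embed(alien, qf$model), class = "scfactor_alignment_error")
  # missing model genes are imputed as zeros, with a warning
  sub <- count_matrix(qf$sim$data$counts[, 1:25],
                      qf$sim$data$cell_ids, qf$sim$data$gene_ids[1:25])
  expect_warning(embed(sub, qf$model), "imputed")
})

test_that("corrected expression is a per-type simplex free of library-size effects", {
  corr <- correct_expression(qf$sim$data, qf$model)
  expect_equal(rowSums(corr), rep(1, 120), tolerance = 1e-6)
  cl <- classify(qf$sim$data, qf$model)
  # cells with the same predicted type share the same corrected row
  same <- which(cl$y_hat == cl$y_hat[1])
  expect_true(all(apply(corr[same, , drop = FALSE], 1,
                        function(r) identical(r, corr[same[1], ]))))
  # doubling a cell's counts leaves its corrected row unchanged
  X2 <- scfactor:::cm_dense(qf$sim$data)
  X2[1, ] <- X2[1, ] * 2
  d2 <- count_matrix(X2, qf$sim$data$cell_ids, qf$sim$data$gene_ids)
  corr2 <- correct_expression(d2, qf$model)
  expect_equal(corr2[1, ], corr[1, ], tolerance = 1e-9)
})

test_that("with no nuisance dimension the corrected row is the type decode alone", {
  sim <- simulate_dataset(L = 2, G = 15, n_cells = 40, seed = 4)
  prior <- prior_config(L = 2, d = 4, d1 = 0)
  cfg <- train_config(epochs = 5, kl_warmup_epochs = 5, hidden = 8, seed = 0)
  m <- svi_fit(sim$data, sim$labels, prior = prior, cfg = cfg)
  corr <- correct_expression(sim$data, m)
  cl <- classify(sim$data, m)
  cp <- conditional_prior(diag(2), matrix(0, 2, 0), m$gen)
  usage <- decode_usage(cp$mu, m$gen)$usage
  expect_equal(unname(corr), unname(usage[cl$y_idx, ]), tolerance = 1e-12)
})

test_that("umap2d is seeded, finite, and shrinks neighbors on tiny inputs", {
  zy <- embed(qf$sim$data, qf$model)
  u1 <- umap2d(zy, seed = 1)
  u2 <- umap2d(zy, seed = 1)
  expect_identical(u1, u2)
  expect_equal(dim(u1), c(120, 2))
  expect_true(all(is.finite(u1)))
  expect_warning(umap2d(zy[1:8, ], seed = 1), "shrunk")
  expect_error(umap2d(zy[1:2, ], seed = 1), "at least 3")
})
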