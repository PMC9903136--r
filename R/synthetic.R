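# Seeded generator of multi-batch labeled scRNA-seq benchmarks, plus the
# packaged sample-bookkeeping manifest.
#
# The simulator mirrors the model's own generative assumptions: each cell
# type owns a gene-usage profile on the simplex; batches perturb profiles
# multiplicatively (lognormal factors, renormalized); per-cell usage is
# Dirichlet-distributed around the perturbed profile (overdispersion); and
# observed counts are multinomial draws at a lognormal library size.

#' Per-type gene-usage profiles
#'
#' Draws L distinct points on the G-simplex. \code{sparsity} controls the
#' fraction of genes per type that are pushed to near-zero usage, which in
#' turn controls the pairwise separation between types.
#'
#' @param L number of cell types (>= 1).
#' @param G number of genes (>= 2).
#' @param sparsity fraction in [0, 1) of near-zero genes per type
#'   (default 0.5).
#' @param seed integer seed.
#' @return L x G matrix with rows on the simplex.
#' @export
make_profiles <- function(L, G, sparsity = 0.5, seed = 0L) {
  stop_if(L < 1, "L must be >= 1")
  stop_if(G < 2, "G must be >= 2")
  stop_if(sparsity < 0 || sparsity >= 1, "sparsity must be in [0, 1)")
  with_seed(seed, {
    prof <- matrix(stats::rgamma(L * G, shape = 1), L, G)
    n_zero <- floor(sparsity * G)
    if (n_zero > 0) {
      for (l in seq_len(L)) {
        off <- sample.int(G, n_zero)
        prof[l, off] <- prof[l, off] * 1e-4
      }
    }
    prof / rowSums(prof)
  })
}

#' Simulate a multi-batch labeled scRNA-seq benchmark
#'
#' Per cell: a type and a batch are drawn uniformly; the type profile is
#' perturbed by the batch's multiplicative lognormal(0, batch_strength)
#' gene factors and renormalized; per-cell usage eta is drawn from
#' Dirichlet(dirichlet_conc x perturbed profile); counts are multinomial at
#' a lognormal library size (median \code{mean_library}, minimum 1).
#' Exactly \code{round(labeled_fraction * n_cells)} cells keep their label;
#' the rest are NA (the held-out/unlabeled set).
#'
#' @param L,G,B numbers of types, genes, batches.
#' @param n_cells number of cells (default 600).
#' @param batch_strength lognormal sd of the multiplicative batch factors
#'   (default 0.5; 0 disables batch effects).
#' @param dirichlet_conc concentration multiplier of the per-cell Dirichlet
#'   (default 50; larger = less overdispersion).
#' @param mean_library median library size (default 2000).
#' @param labeled_fraction fraction of cells carrying labels (default 0.8).
#' @param sparsity profile sparsity passed to \code{\link{make_profiles}}.
#' @param seed integer seed; output is bit-reproducible given the seed.
#' @return list with \code{data} (a \code{\link{count_matrix}}),
#'   \code{labels} (character with NA for unlabeled cells), and
#'   \code{truth} (profiles, batch_effects, true_labels, true_batches,
#'   library_sizes, per_cell_eta, seed).
#' @export
simulate_dataset <- function(L = 3L, G = 200L, B = 2L, n_cells = 600L,
                             batch_strength = 0.5, dirichlet_conc = 50,
                             mean_library = 2000L, labeled_fraction = 0.8,
                             sparsity = 0.5, seed = 0L) {
  stop_if(n_cells < 1 || B < 1 || dirichlet_conc <= 0 || mean_library < 1,
          "all size/concentration parameters must be positive")
  stop_if(batch_strength < 0, "batch_strength must be >= 0")
  stop_if(labeled_fraction < 0 || labeled_fraction > 1,
          "labeled_fraction must be in [0, 1]")
  profiles <- make_profiles(L, G, sparsity = sparsity, seed = seed)
  with_seed(seed + 1L, {
    batch_fx <- matrix(exp(stats::rnorm(B * G, sd = batch_strength)), B, G)
    y <- sample.int(L, n_cells, replace = TRUE)
    batch <- sample.int(B, n_cells, replace = TRUE)
    lib <- pmax(1L, as.integer(round(
      stats::rlnorm(n_cells, meanlog = log(mean_library), sdlog = 0.3))))
    # batch-perturbed, renormalized per-(type, batch) expected usage
    pert <- array(0, dim = c(L, B, G))
    for (l in seq_len(L)) for (b in seq_len(B)) {
      p <- profiles[l, ] * batch_fx[b, ]
      pert[l, b, ] <- p / sum(p)
    }
    conc <- matrix(0, n_cells, G)
    for (i in seq_len(n_cells)) {
      conc[i, ] <- dirichlet_conc * pert[y[i], batch[i], ]
    }
    gam <- matrix(stats::rgamma(n_cells * G, shape = conc), n_cells, G)
    gam[gam <= 0] <- .Machine$double.xmin
    eta <- gam / rowSums(gam)
    counts <- matrix(0, n_cells, G)
    for (i in seq_len(n_cells)) {
      counts[i, ] <- stats::rmultinom(1, lib[i], eta[i, ])
    }
    type_names <- sprintf("type_%d", seq_len(L))
    labels <- type_names[y]
    n_lab <- round(labeled_fraction * n_cells)
    lab_idx <- sample.int(n_cells, n_lab)
    labels_obs <- rep(NA_character_, n_cells)
    labels_obs[lab_idx] <- labels[lab_idx]
    data <- count_matrix(counts,
                         cell_ids = sprintf("cell_%d", seq_len(n_cells)),
                         gene_ids = sprintf("gene_%d", seq_len(G)))
    list(data = data, labels = labels_obs,
         truth = list(profiles = profiles, batch_effects = batch_fx,
                      expected_usage = pert,
                      true_labels = labels, true_batches = batch,
                      library_sizes = lib, per_cell_eta = eta, seed = seed))
  })
}

#' Packaged sample-bookkeeping manifest
#'
#' The per-group cell and patient counts of the six source datasets behind
#' the integrated atlas: total cells, cells split by age group (adult /
#' aged), and donor counts by age group. Group 6 has no published age
#' split; its adult/aged entries are absent (NA), never zero.
#'
#' @return A data.frame with columns \code{group}, \code{total_cells},
#'   \code{adult_cells}, \code{aged_cells}, \code{adult_patients},
#'   \code{aged_patients}.
#' @export
table1_manifest <- function() {
  data.frame(
    group = 1:6,
    total_cells = c(1901L, 11786L, 84969L, 15935L, 415L, 17982L),
    adult_cells = c(1645L, 0L, 71053L, 12259L, 415L, NA),
    aged_cells = c(256L, 11786L, 13916L, 3676L, 0L, NA),
    adult_patients = c(3L, 0L, 5L, 1L, 1L, NA),
    aged_patients = c(1L, 6L, 2L, 4L, 0L, NA)
  )
}

#' Summarize a dataset manifest
#'
#' Column sums of the manifest: the age-split sums skip absent (NA)
#' entries, while the grand total includes every group.
#'
#' @param m a manifest as returned by \code{\link{table1_manifest}}.
#' @return list with \code{total_cells}, \code{adult_cells},
#'   \code{aged_cells}, \code{total_patients}.
#' @export
dataset_summary <- function(m) {
  list(total_cells = sum(m$total_cells),
       adult_cells = sum(m$adult_cells, na.rm = TRUE),
       aged_cells = sum(m$aged_cells, na.rm = TRUE),
       total_patients = sum(m$adult_patients, na.rm = TRUE) +
         sum(m$aged_patients, na.rm = TRUE))
}
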