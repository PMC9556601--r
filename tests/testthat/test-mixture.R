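# The three-component bivariate normal mixture: density, posterior, EM fit,
# component labelling, serialisation.

test_that("mixture density matches the term-by-term oracle", {
  set.seed(101)
  for (i in 1:50) {
    model <- random_model()
    x <- runif(2, -2, 12)
    expect_equal(mixture_density(model, x), naive_density(model, x),
                 tolerance = 1e-10)
  }
})

test_that("mixture density collapses correctly in degenerate models", {
  # Single effective component at its mean with identity covariance: the
  # bivariate normal mode height 1/(2*pi).
  m <- toy_model()
  m$weights <- c(1, 0, 0)
  m$covariances <- replicate(3, diag(1, 2), simplify = FALSE)
  expect_equal(mixture_density(m, m$means[1, ]), 1 / (2 * pi),
               tolerance = 1e-12)
  # Three identical components: mixture equals the single component pdf.
  m2 <- toy_model()
  m2$means <- matrix(rep(c(4, 4), each = 3), 3, 2)
  expect_equal(mixture_density(m2, c(4.3, 3.9)),
               naive_bvn_pdf(c(4.3, 3.9), c(4, 4), m2$covariances[[1]]),
               tolerance = 1e-12)
})

test_that("posterior matches the direct Bayes-rule oracle", {
  set.seed(202)
  for (i in 1:200) {
    model <- random_model()
    x <- runif(2, -2, 12)
    p <- as.numeric(posterior(model, x))
    expect_equal(sum(p), 1, tolerance = 1e-12)
    # The direct products tau_k phi_k underflow below ~1e-308 where the
    # log-space path still carries the value; the oracle is trusted only on
    # entries whose product is comfortably normal.
    dens <- naive_weighted_dens(model, x)
    s <- sum(dens)
    if (s < 1e-280) next  # oracle itself out of range for this pair
    rep_ok <- dens >= 1e-290
    expect_equal(p[rep_ok], dens[rep_ok] / s, tolerance = 1e-10)
    expect_true(all(p[!rep_ok] <= 1e-289 / s))
  }
})

test_that("posterior respects symmetry and uninformative likelihoods", {
  # Components 1 and 3 symmetric about the point, component 2 negligible.
  m <- toy_model()
  m$means <- matrix(c(6, 1, 100, 100, 1, 6), 3, 2, byrow = TRUE)
  p <- posterior(m, c(3.5, 3.5))
  expect_equal(as.numeric(p), c(0.5, 0, 0.5), tolerance = 1e-10)
  # Identical components, equal weights: posterior is uniform everywhere.
  m2 <- toy_model()
  m2$means <- matrix(rep(c(4, 4), each = 3), 3, 2)
  for (x in list(c(0, 0), c(4, 4), c(9, -3))) {
    expect_equal(as.numeric(posterior(m2, x)), rep(1 / 3, 3),
                 tolerance = 1e-12)
  }
})

test_that("posterior rows sum to one and extreme points do not give NaN", {
  set.seed(303)
  m <- toy_model()
  X <- cbind(runif(10000, -5, 15), runif(10000, -5, 15))
  P <- posterior(m, X)
  expect_lt(max(abs(rowSums(P) - 1)), 1e-10)
  # A point astronomically far from every component underflows cleanly.
  Pfar <- posterior(m, c(1e200, -1e200))
  expect_true(attr(Pfar, "degenerate"))
  expect_true(all(is.na(Pfar)))
  expect_error(posterior(m, c(Inf, 0)), class = "bf_domain_error")
})

test_that("components are labelled by the butterfly geometry", {
  means <- matrix(c(6, 1, 4, 4, 1, 6), 3, 2, byrow = TRUE)
  ord <- label_components(rep(1 / 3, 3), means)
  expect_equal(ord, 1:3)  # AA (A-high/B-low) first, BB last
  # Order-invariance: permuting the components permutes the map accordingly.
  perm <- c(3, 1, 2)
  ord2 <- label_components(rep(1 / 3, 3), means[perm, ])
  expect_equal(means[perm, ][ord2, ], means)
  # Ties on mean(B' - A') are broken by mean A', with a message.
  tied <- matrix(c(3, 3, 3, 3, 1, 6), 3, 2, byrow = TRUE)
  expect_message(ord3 <- label_components(rep(1 / 3, 3), tied), "tie")
  expect_equal(ord3, c(1, 2, 3))
})

test_that("EM log-likelihood is non-decreasing and the fit converges", {
  for (seed in 1:5) {
    sim <- simulate_sample(sim_config(n_snps = 3000), seed = seed)
    pts <- cbind(log_transform(sim$intensities$mean_a),
                 log_transform(sim$intensities$mean_b))
    model <- fit_mixture(pts, seed = seed)
    trace <- model$fit_info$loglik
    expect_true(all(diff(trace) >= -1e-8 * abs(trace[-length(trace)])))
    expect_true(model$fit_info$converged)
  }
})

test_that("EM recovers generating weights and means on separated clusters", {
  # Beta(1/3, 1/3) allele frequencies give genotype weights (0.4, 0.2, 0.4).
  cfg <- sim_config(n_snps = 10000, allele_freq_shape = c(1 / 3, 1 / 3),
                    dropout_prob = 0, outlier_prob = 0)
  sim <- simulate_sample(cfg, seed = 11)
  pts <- cbind(log_transform(sim$intensities$mean_a),
               log_transform(sim$intensities$mean_b))
  model <- fit_mixture(pts, seed = 11)
  expect_lt(max(abs(model$weights - c(0.4, 0.2, 0.4))), 0.02)
  expect_lt(max(abs(model$means - cfg$cluster_means)), 0.05)
})

test_that("fitting is deterministic given data and seed", {
  sim <- simulate_sample(sim_config(n_snps = 2000), seed = 5)
  pts <- cbind(log_transform(sim$intensities$mean_a),
               log_transform(sim$intensities$mean_b))
  m1 <- fit_mixture(pts, seed = 99)
  m2 <- fit_mixture(pts, seed = 99)
  expect_identical(m1$weights, m2$weights)
  expect_identical(m1$means, m2$means)
  expect_identical(m1$covariances, m2$covariances)
})

test_that("degenerate inputs raise a fit error", {
  expect_error(fit_mixture(matrix(1, 10, 2)), class = "bf_fit_error")
  expect_error(fit_mixture(matrix(1, 100, 2), seed = 1),
               class = "bf_fit_error")  # identical points: singular everywhere
  expect_error(fit_mixture(matrix(rnorm(10), 5, 2)), class = "bf_fit_error")
})

test_that("origin points are excluded from fitting by default", {
  sim <- simulate_sample(sim_config(n_snps = 2000, dropout_prob = 0.2),
                         seed = 8)
  pts <- cbind(log_transform(sim$intensities$mean_a),
               log_transform(sim$intensities$mean_b))
  model <- fit_mixture(pts, seed = 8)
  expect_equal(model$fit_info$n_points, sum(!(pts[, 1] == 0 & pts[, 2] == 0)))
})

test_that("the fit agrees with an independent mixture implementation", {
  suppressPackageStartupMessages(library(mclust))
  sim <- simulate_sample(sim_config(n_snps = 5000), seed = 21)
  pts <- cbind(log_transform(sim$intensities$mean_a),
               log_transform(sim$intensities$mean_b))
  pts <- pts[!(pts[, 1] == 0 & pts[, 2] == 0), ]
  ours <- fit_mixture(pts, seed = 21)
  ref <- mclust::Mclust(pts, G = 3, modelNames = "VVV", verbose = FALSE)
  # Same optimum: log-likelihood and sorted component means agree.
  expect_equal(max(ours$fit_info$loglik), ref$loglik, tolerance = 1e-4)
  ref_means <- t(ref$parameters$mean)
  ref_means <- ref_means[order(ref_means[, 2] - ref_means[, 1]), ]
  expect_equal(unname(ours$means), unname(ref_means), tolerance = 0.02)
  expect_equal(sort(ours$weights), sort(as.numeric(ref$parameters$pro)),
               tolerance = 0.01)
})

test_that("model JSON round trip is bit-exact", {
  sim <- simulate_sample(sim_config(n_snps = 1000), seed = 2)
  model <- fit_mixture(cbind(log_transform(sim$intensities$mean_a),
                             log_transform(sim$intensities$mean_b)), seed = 2)
  path <- withr::local_tempfile(fileext = ".json")
  write_model(model, path)
  back <- read_model(path)
  expect_identical(back$weights, model$weights)
  expect_identical(back$means, model$means)
  expect_identical(back$covariances, model$covariances)
  expect_identical(back$label_map, model$label_map)
})
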