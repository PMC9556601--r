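# Synthetic butterfly-shaped intensity data with ground-truth genotypes.
#
# Genotypes are drawn under Hardy-Weinberg equilibrium with a per-SNP allele
# frequency from a Beta prior; transformed intensities come from the
# genotype's bivariate normal cluster (so the mixture model family is exactly
# correct under defaults), then the log transform is inverted back to raw
# signal units. Bead counts follow a shifted negative binomial calibrated to
# the empirical bead-count distribution (median 13, middle 95% in [5, 23]).

# Default cluster geometry: qualitative butterfly in ln-intensity units.
# Illustrative package defaults, fully configurable.
.default_cluster_means <- matrix(c(7.5, 3.5,   # AA: A-high, B-low
                                   7.0, 7.0,   # AB
                                   3.5, 7.5),  # BB
                                 nrow = 3, byrow = TRUE,
                                 dimnames = list(c("AA", "AB", "BB"), NULL))
.default_cluster_covs <- list(
  AA = matrix(c(0.15, 0.02, 0.02, 0.08), 2),
  AB = matrix(c(0.12, 0.03, 0.03, 0.12), 2),
  BB = matrix(c(0.08, 0.02, 0.02, 0.15), 2))

# Bead-count parameters frozen from calibrate_bead_dist() defaults:
# 1 + NegBin(size, mu) has median 13 and 2.5/97.5% quantiles 5 and 23.
.default_bead_params <- list(family = "shifted_nbinom", size = 17.5, mu = 11.9)

#' Simulation configuration
#'
#' @param n_snps number of SNPs to simulate.
#' @param allele_freq_shape two Beta shape parameters for the per-SNP allele
#'   A frequency (default `c(1, 1)`, i.e. uniform — array content is
#'   ascertained towards common variants, so no rare-variant skew is
#'   imposed by default).
#' @param cluster_means 3 x 2 matrix of genotype cluster means in
#'   transformed (A', B') space, rows AA, AB, BB.
#' @param cluster_covs list of three 2x2 SPD covariance matrices.
#' @param probe_type_fraction_I fraction of SNPs assayed with type I probes
#'   (default 135419 / 4055428, the type I share of a filtered high-density
#'   manifest).
#' @param bead_params bead-count distribution parameters, e.g. from
#'   [calibrate_bead_dist()].
#' @param dropout_prob probability that a SNP's raw means are both set to 0
#'   (scanner dropout; forced no-call downstream).
#' @param outlier_prob probability a SNP's intensity deviation is inflated
#'   by `outlier_scale` (heavy-tail contamination).
#' @param outlier_scale multiplier on the cluster standard deviation for
#'   outliers.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_snps = 10000L,
                       allele_freq_shape = c(1, 1),
                       cluster_means = .default_cluster_means,
                       cluster_covs = .default_cluster_covs,
                       probe_type_fraction_I = 135419 / 4055428,
                       bead_params = .default_bead_params,
                       dropout_prob = 0.002,
                       outlier_prob = 0.001,
                       outlier_scale = 4) {
  cluster_means <- as.matrix(cluster_means)
  stopifnot(nrow(cluster_means) == 3, ncol(cluster_means) == 2,
            length(cluster_covs) == 3,
            probe_type_fraction_I >= 0, probe_type_fraction_I <= 1,
            dropout_prob >= 0, dropout_prob <= 1,
            outlier_prob >= 0, outlier_prob <= 1)
  for (s in cluster_covs) {
    ev <- eigen(as.matrix(s), symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0) {
      bf_stop("bf_config_error", "cluster covariances must be positive definite")
    }
  }
  structure(list(n_snps = as.integer(n_snps),
                 allele_freq_shape = allele_freq_shape,
                 cluster_means = cluster_means,
                 cluster_covs = lapply(cluster_covs, as.matrix),
                 probe_type_fraction_I = probe_type_fraction_I,
                 bead_params = bead_params,
                 dropout_prob = dropout_prob,
                 outlier_prob = outlier_prob,
                 outlier_scale = outlier_scale),
            class = "sim_config")
}

#' Calibrate the bead-count distribution
#'
#' Searches a shifted negative binomial family `1 + NegBin(size, mu)`
#' (support starting at one bead) for parameters whose median equals
#' `target_median` and whose 2.5%/97.5% quantiles match the ends of
#' `target_central95` to within one bead. A degenerate request
#' (`target_central95 == c(m, m) == target_median`) returns a point mass.
#'
#' @param target_median target median bead count.
#' @param target_central95 two-vector, the target central-95% interval.
#' @return List with `family` and its parameters.
#' @export
calibrate_bead_dist <- function(target_median = 13L,
                                target_central95 = c(5L, 23L)) {
  lo <- target_central95[1]; hi <- target_central95[2]
  if (lo == hi && lo == target_median) {
    return(list(family = "point", value = as.numeric(target_median)))
  }
  grid <- expand.grid(size = seq(1, 120, by = 0.5),
                      mu = seq(max(target_median - 6, 0.5),
                               target_median + 6, by = 0.05))
  q <- function(p, s, m) 1 + stats::qnbinom(p, size = s, mu = m)
  med <- q(0.5, grid$size, grid$mu)
  q025 <- q(0.025, grid$size, grid$mu)
  q975 <- q(0.975, grid$size, grid$mu)
  obj <- 1000 * (med - target_median)^2 + (q025 - lo)^2 + (q975 - hi)^2
  i <- which.min(obj)
  if (med[i] != target_median || abs(q025[i] - lo) > 1 || abs(q975[i] - hi) > 1) {
    bf_stop("bf_calibration_error",
            paste("targets not achievable by a shifted negative binomial",
                  "(best: median %d, central 95%% [%d, %d]); consider a",
                  "different family"), med[i], q025[i], q975[i])
  }
  list(family = "shifted_nbinom", size = grid$size[i], mu = grid$mu[i])
}

#' Draw bead counts
#'
#' @param n number of draws.
#' @param params parameters from [calibrate_bead_dist()].
#' @return Integer vector of bead counts (all `>= 1`).
#' @export
draw_beads <- function(n, params = .default_bead_params) {
  if (params$family == "point") return(rep(as.integer(params$value), n))
  as.integer(1L + stats::rnbinom(n, size = params$size, mu = params$mu))
}

#' Expected genotype proportions under the simulator
#'
#' Hardy-Weinberg proportions integrated over the Beta(a, b) allele
#' frequency prior: `E[p^2]`, `E[2p(1-p)]`, `E[(1-p)^2]` in closed form.
#'
#' @param shape two Beta shape parameters.
#' @return Named numeric vector over AA, AB, BB, summing to 1.
#' @export
expected_genotype_props <- function(shape = c(1, 1)) {
  a <- shape[1]; b <- shape[2]
  denom <- (a + b) * (a + b + 1)
  c(AA = a * (a + 1) / denom,
    AB = 2 * a * b / denom,
    BB = b * (b + 1) / denom)
}

#' Simulate one sample with ground truth
#'
#' Per SNP: draw an allele A frequency p from the Beta prior; draw the
#' genotype from Hardy-Weinberg proportions (p^2, 2p(1-p), (1-p)^2); draw
#' (A', B') from the genotype's bivariate normal cluster (outliers get a
#' deviation inflated by `outlier_scale`); invert the transform
#' (`raw = exp(value) - 1`, clamped at 0); draw bead counts (type I probes:
#' one draw per allele; type II: a single draw shared by both alleles); and
#' apply dropout (both raw means forced to 0; the true genotype is still
#' recorded). Generation is a pure function of `(config, seed)`.
#'
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @param sample_id sample identifier.
#' @return List with `intensities` (tibble as in [read_intensities()]) and
#'   `truth` (tibble `snp_id`, `genotype` in AA/AB/BB).
#' @export
simulate_sample <- function(config = sim_config(), seed = 1L,
                            sample_id = "sim1") {
  set.seed(seed)
  n <- config$n_snps
  snp_id <- sprintf("snp%07d", seq_len(n))
  p <- stats::rbeta(n, config$allele_freq_shape[1], config$allele_freq_shape[2])
  u <- stats::runif(n)
  geno <- ifelse(u < p^2, 1L, ifelse(u < p^2 + 2 * p * (1 - p), 2L, 3L))

  # Cluster draws via per-component Cholesky factors.
  z <- matrix(stats::rnorm(2 * n), n, 2)
  scale <- ifelse(stats::runif(n) < config$outlier_prob,
                  config$outlier_scale, 1)
  pts <- matrix(0, n, 2)
  for (k in 1:3) {
    sel <- geno == k
    if (!any(sel)) next
    L <- chol(config$cluster_covs[[k]])
    pts[sel, ] <- sweep(scale[sel] * (z[sel, , drop = FALSE] %*% L), 2,
                        config$cluster_means[k, ], `+`)
  }
  raw <- pmax(exp(pts) - 1, 0)
  dropout <- stats::runif(n) < config$dropout_prob
  raw[dropout, ] <- 0

  type1 <- stats::runif(n) < config$probe_type_fraction_I
  beads_a <- draw_beads(n, config$bead_params)
  beads_b <- beads_a
  if (any(type1)) beads_b[type1] <- draw_beads(sum(type1), config$bead_params)

  intensities <- tibble::tibble(
    sample_id = sample_id, snp_id = snp_id,
    probe_type = ifelse(type1, "I", "II"),
    mean_a = raw[, 1], mean_b = raw[, 2],
    sd_a = NA_real_, sd_b = NA_real_,
    beads_a = beads_a, beads_b = beads_b)
  truth <- tibble::tibble(snp_id = snp_id,
                          genotype = c("AA", "AB", "BB")[geno])
  list(intensities = intensities, truth = truth)
}

# Model object holding the generating parameters (weights = HWE-integrated
# genotype proportions), used by the Bayes-bound oracle.
#' @noRd
true_model <- function(config) {
  structure(list(weights = unname(expected_genotype_props(config$allele_freq_shape)),
                 means = config$cluster_means,
                 covariances = config$cluster_covs,
                 label_map = c("AA", "AB", "BB"),
                 fit_info = list(loglik = numeric(0), n_iter = 0L,
                                 converged = TRUE, seed = NULL, n_points = 0L)),
            class = "butterfly_model")
}

#' Monte-Carlo Bayes bound for calling accuracy
#'
#' Upper bound on the concordance achievable by any caller under the
#' generating process: draws labelled points from the true generating model
#' (genotype weights integrated over the allele-frequency prior, including
#' outlier contamination; dropouts excluded, as both the oracle and the
#' caller force them to no-calls) and classifies them with the
#' true-parameter posterior at the given threshold. Accuracy is measured
#' among the points whose maximum posterior reaches the threshold, i.e. the
#' same conditioning as a concordance rate among called SNPs.
#'
#' @param config a [sim_config()].
#' @param posterior_min posterior no-call threshold applied by the oracle.
#' @param n number of Monte-Carlo draws.
#' @param seed integer seed.
#' @return List with `accuracy` (the bound), `called_fraction`, and `n`.
#' @export
bayes_bound <- function(config = sim_config(), posterior_min = 0.8,
                        n = 200000L, seed = 1L) {
  set.seed(seed)
  w <- unname(expected_genotype_props(config$allele_freq_shape))
  geno <- sample.int(3, n, replace = TRUE, prob = w)
  z <- matrix(stats::rnorm(2 * n), n, 2)
  scale <- ifelse(stats::runif(n) < config$outlier_prob,
                  config$outlier_scale, 1)
  pts <- matrix(0, n, 2)
  for (k in 1:3) {
    sel <- geno == k
    if (!any(sel)) next
    L <- chol(config$cluster_covs[[k]])
    pts[sel, ] <- sweep(scale[sel] * (z[sel, , drop = FALSE] %*% L), 2,
                        config$cluster_means[k, ], `+`)
  }
  P <- posterior(true_model(config), pts)
  max_post <- suppressWarnings(apply(P, 1, max))
  pred <- max.col(replace(P, is.na(P), -1), ties.method = "first")
  called <- !attr(P, "degenerate") & !is.na(max_post) & max_post >= posterior_min
  list(accuracy = mean(pred[called] == geno[called]),
       called_fraction = mean(called),
       n = n)
}

#' Write simulator outputs
#'
#' Writes `<prefix>_intensities.tsv`, `<prefix>_truth.tsv` and
#' `<prefix>_config.json` (the generating configuration with resolved
#' defaults).
#'
#' @param sim result of [simulate_sample()].
#' @param config the [sim_config()] used.
#' @param prefix output path prefix.
#' @return Character vector of the paths written, invisibly.
#' @export
write_simulation <- function(sim, config, prefix) {
  paths <- paste0(prefix, c("_intensities.tsv", "_truth.tsv", "_config.json"))
  write_intensities(sim$intensities, paths[1])
  write_tsv_plain(as.data.frame(sim$truth), paths[2])
  cfg <- config
  cfg$cluster_means <- as.vector(t(cfg$cluster_means))
  cfg$cluster_covs <- lapply(cfg$cluster_covs, function(s) as.vector(t(s)))
  jsonlite::write_json(unclass(cfg), paths[3], digits = NA, auto_unbox = TRUE)
  invisible(paths)
}
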