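# Genotype calling: maximum a posteriori calls with explicit no-call rules,
# under the three model variants (per-sample, per-sample-per-probe-type,
# ensemble).

#' No-call thresholds
#'
#' @param posterior_min no-call if the maximum genotype posterior is strictly
#'   below this; must be in `[0.5, 1)` so that at most one genotype can pass.
#' @param beads_min no-call if a relevant bead count is strictly below this
#'   (`0` disables the rule). Type I probes have a bead count per allele and
#'   both must pass; type II probes have a single count.
#' @return A list of class `"call_thresholds"`.
#' @export
call_thresholds <- function(posterior_min = 0.8, beads_min = 5L) {
  if (!is.numeric(posterior_min) || posterior_min < 0.5 || posterior_min >= 1) {
    bf_stop("bf_config_error", "posterior_min must be in [0.5, 1), got %s",
            format(posterior_min))
  }
  if (!is.numeric(beads_min) || beads_min < 0) {
    bf_stop("bf_config_error", "beads_min must be a non-negative integer")
  }
  structure(list(posterior_min = posterior_min, beads_min = as.integer(beads_min)),
            class = "call_thresholds")
}

# Vectorised calling core. snps: intensity tibble; returns the call columns.
# No-call rule precedence: (1) both raw means zero; (2) too few beads;
# (3) degenerate posterior; (4) max posterior below threshold (strict <;
# a call at exactly posterior_min is made). Argmax ties -> no-call.
#' @noRd
call_intensities <- function(model, snps, thresholds) {
  n <- nrow(snps)
  zero <- snps$mean_a == 0 & snps$mean_b == 0
  bmin <- thresholds$beads_min
  low_beads <- ifelse(snps$probe_type == "I",
                      snps$beads_a < bmin | snps$beads_b < bmin,
                      snps$beads_a < bmin)
  P <- posterior(model, cbind(log_transform(snps$mean_a),
                              log_transform(snps$mean_b)))
  degenerate <- attr(P, "degenerate")
  max_post <- suppressWarnings(apply(P, 1, max))
  which_max <- max.col(replace(P, is.na(P), -1), ties.method = "first")
  tie <- !degenerate & rowSums(P == max_post, na.rm = TRUE) > 1

  call <- model$label_map[which_max]
  nc_reason <- rep("none", n)
  nc_reason[which(max_post < thresholds$posterior_min | tie)] <- "low_posterior"
  nc_reason[which(degenerate)] <- "degenerate"
  nc_reason[which(low_beads)] <- "low_beads"
  nc_reason[which(zero)] <- "zero_intensity"
  call[nc_reason != "none"] <- "NC"
  max_post[degenerate] <- NA_real_
  tibble::tibble(snp_id = snps$snp_id, call = call,
                 max_posterior = max_post, nc_reason = nc_reason)
}

#' Call a single SNP
#'
#' Applies the no-call rules in order: (1) both raw mean intensities zero;
#' (2) bead count below `beads_min` (either allele's count for type I, the
#' single count for type II); (3) posterior degenerate (numerical
#' underflow); (4) maximum posterior strictly below `posterior_min`.
#' Otherwise the genotype with the maximum a posteriori probability is
#' called. The first matching no-call rule is recorded as `nc_reason`.
#'
#' @param model a fitted `"butterfly_model"`.
#' @param snp a one-row intensity tibble (columns `snp_id`, `probe_type`,
#'   `mean_a`, `mean_b`, `beads_a`, `beads_b`).
#' @param thresholds a [call_thresholds()].
#' @return One-row tibble: `snp_id`, `call` (AA/AB/BB/NC), `max_posterior`,
#'   `nc_reason` (none/zero_intensity/low_beads/low_posterior/degenerate).
#' @export
call_snp <- function(model, snp, thresholds = call_thresholds()) {
  stopifnot(nrow(snp) == 1)
  call_intensities(model, snp, thresholds)
}

# Fit the model(s) a variant needs. Returns list(models, assign) where
# assign(snps) yields the model index per row.
#' @noRd
fit_variant_models <- function(sample, variant, all_samples, config, seed) {
  pts <- function(x) cbind(log_transform(x$mean_a), log_transform(x$mean_b))
  if (variant == "per_sample") {
    models <- list(fit_mixture(pts(sample), config, seed))
    assign <- function(snps) rep(1L, nrow(snps))
  } else if (variant == "per_sample_per_probe_type") {
    models <- vector("list", 2)
    for (i in seq_along(c("I", "II"))) {
      type <- c("I", "II")[i]
      sub <- sample[sample$probe_type == type, , drop = FALSE]
      if (nrow(sub) < config$min_points) {
        bf_stop("bf_fit_error",
                "probe type %s stratum has only %d SNPs (need %d)",
                type, nrow(sub), config$min_points)
      }
      models[[i]] <- fit_mixture(pts(sub), config, seed)
    }
    assign <- function(snps) ifelse(snps$probe_type == "I", 1L, 2L)
  } else { # ensemble
    if (is.null(all_samples)) {
      bf_stop("bf_config_error", "ensemble variant requires all_samples")
    }
    pooled <- do.call(rbind, lapply(all_samples, pts))
    models <- list(fit_mixture(pooled, config, seed))
    assign <- function(snps) rep(1L, nrow(snps))
  }
  list(models = models, assign = assign)
}

#' Call every SNP of a sample
#'
#' Fits the mixture and calls each SNP, under one of three variants:
#' `"per_sample"` fits one model on this sample's SNPs (the within-sample
#' design: no other sample influences the calls); `"per_sample_per_probe_type"`
#' fits separate models for type I and type II probes of this sample;
#' `"ensemble"` fits a single model on the pooled transformed intensities of
#' `all_samples` and applies it to this sample.
#'
#' @param sample intensity tibble for one sample (see [read_intensities()]).
#' @param variant model variant.
#' @param thresholds a [call_thresholds()].
#' @param all_samples list of intensity tibbles (required for `"ensemble"`).
#' @param config a [mixture_config()].
#' @param seed optional integer seed forwarded to [fit_mixture()].
#' @return A tibble of class `"call_set"` with columns `sample_id`,
#'   `snp_id`, `call`, `max_posterior`, `nc_reason`; attributes `variant`,
#'   `thresholds` and `models` (the fitted model list).
#' @export
call_sample <- function(sample,
                        variant = c("per_sample", "per_sample_per_probe_type",
                                    "ensemble"),
                        thresholds = call_thresholds(),
                        all_samples = NULL,
                        config = mixture_config(), seed = NULL) {
  variant <- match.arg(variant)
  fv <- fit_variant_models(sample, variant, all_samples, config, seed)
  idx <- fv$assign(sample)
  parts <- lapply(seq_along(fv$models), function(i) {
    sub <- sample[idx == i, , drop = FALSE]
    if (nrow(sub) == 0) return(NULL)
    cbind(row = which(idx == i),
          call_intensities(fv$models[[i]], sub, thresholds))
  })
  res <- do.call(rbind, parts)
  res <- res[order(res$row), c("snp_id", "call", "max_posterior", "nc_reason")]
  out <- tibble::tibble(sample_id = sample$sample_id[1], res)
  attr(out, "variant") <- variant
  attr(out, "thresholds") <- thresholds
  attr(out, "models") <- fv$models
  class(out) <- c("call_set", class(out))
  out
}

#' Fraction of SNPs with a (non-NC) call
#'
#' @param calls a call tibble with a `call` column.
#' @return `mean(call != "NC")`.
#' @export
call_rate <- function(calls) mean(calls$call != "NC")

#' Sweep the no-call thresholds
#'
#' Fits the variant's model(s) once and evaluates the call rate over a grid
#' of posterior and bead-count thresholds. The call rate is non-increasing
#' in each threshold at the other held fixed.
#'
#' @param sample intensity tibble for one sample.
#' @param variant model variant (see [call_sample()]).
#' @param posterior_grid numeric vector of posterior thresholds in
#'   `[0.5, 1)`.
#' @param beads_grid integer vector of bead-count thresholds.
#' @param all_samples list of samples for the ensemble variant.
#' @param config a [mixture_config()].
#' @param seed optional seed.
#' @return Tibble with columns `posterior_min`, `beads_min`, `call_rate`,
#'   `n_called`, `n_snps`.
#' @export
threshold_sweep <- function(sample,
                            variant = "per_sample",
                            posterior_grid = c(0.5, 0.8, 0.9, 0.99, 0.999),
                            beads_grid = c(0L, 5L),
                            all_samples = NULL,
                            config = mixture_config(), seed = NULL) {
  stopifnot(length(posterior_grid) > 0, length(beads_grid) > 0)
  variant <- match.arg(variant,
                       c("per_sample", "per_sample_per_probe_type", "ensemble"))
  fv <- fit_variant_models(sample, variant, all_samples, config, seed)
  idx <- fv$assign(sample)

  # Per-SNP quantities that do not depend on the thresholds.
  zero <- sample$mean_a == 0 & sample$mean_b == 0
  max_post <- rep(NA_real_, nrow(sample))
  degenerate <- rep(FALSE, nrow(sample))
  for (i in seq_along(fv$models)) {
    sel <- idx == i
    if (!any(sel)) next
    P <- posterior(fv$models[[i]],
                   cbind(log_transform(sample$mean_a[sel]),
                         log_transform(sample$mean_b[sel])))
    degenerate[sel] <- attr(P, "degenerate")
    max_post[sel] <- suppressWarnings(apply(P, 1, max))
  }
  min_beads <- ifelse(sample$probe_type == "I",
                      pmin(sample$beads_a, sample$beads_b), sample$beads_a)

  grid <- expand.grid(posterior_min = posterior_grid,
                      beads_min = as.integer(beads_grid))
  n <- nrow(sample)
  rows <- lapply(seq_len(nrow(grid)), function(g) {
    called <- !zero & !degenerate &
      min_beads >= grid$beads_min[g] &
      !is.na(max_post) & max_post >= grid$posterior_min[g]
    tibble::tibble(posterior_min = grid$posterior_min[g],
                   beads_min = grid$beads_min[g],
                   call_rate = sum(called) / n,
                   n_called = sum(called), n_snps = n)
  })
  do.call(rbind, rows)
}

#' Write a call set as TSV
#'
#' Columns `sample_id`, `snp_id`, `call`, `max_posterior`, `nc_reason`, plus
#' a plus-strand `genotype` column when a manifest is supplied (see
#' [translate_calls()]).
#'
#' @param calls a `"call_set"` tibble.
#' @param path output path.
#' @param manifest optional filtered manifest for base translation.
#' @export
write_calls <- function(calls, path, manifest = NULL) {
  if (!is.null(manifest)) calls <- translate_calls(calls, manifest)
  write_tsv_plain(as.data.frame(calls), path)
}
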