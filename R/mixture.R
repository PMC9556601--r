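# Three-component bivariate normal mixture with unconstrained ("VVV")
# component covariances, fitted by EM on log-transformed A/B intensities.
#
# The mixture density is f(A', B') = sum_i tau_i * phi_i(A', B') with
# i in {AA, AB, BB}, and genotype posteriors are
# P(k | A', B') = tau_k phi_k / sum_i tau_i phi_i.

#' EM configuration for [fit_mixture()]
#'
#' @param tol convergence tolerance on the relative log-likelihood change.
#' @param max_iter maximum EM iterations.
#' @param init initialisation: `"tertile"` splits points into three groups at
#'   the 1/3 and 2/3 quantiles of `B' - A'` (deterministic, matches the
#'   butterfly geometry); `"kmeans"` uses [stats::kmeans()] with 3 centres.
#' @param reg_eps ridge added to a component covariance (scaled by its mean
#'   diagonal) when it becomes numerically singular or its condition number
#'   exceeds `cond_max`.
#' @param cond_max condition-number threshold triggering regularisation.
#' @param weight_floor a component weight below this triggers a restart.
#' @param max_restarts restarts attempted (with k-means init) before failing.
#' @param min_points minimum number of points required to fit.
#' @param exclude_origin drop points at exactly (0, 0) in transformed space
#'   (raw zero-intensity dropouts) before fitting; they are forced no-calls
#'   downstream and would otherwise put a point mass at the origin.
#' @return A list of class `"mixture_config"`.
#' @export
mixture_config <- function(tol = 1e-8, max_iter = 500L,
                           init = c("tertile", "kmeans"),
                           reg_eps = 1e-6, cond_max = 1e12,
                           weight_floor = 1e-6, max_restarts = 3L,
                           min_points = 30L, exclude_origin = TRUE) {
  init <- match.arg(init)
  structure(list(tol = tol, max_iter = as.integer(max_iter), init = init,
                 reg_eps = reg_eps, cond_max = cond_max,
                 weight_floor = weight_floor,
                 max_restarts = as.integer(max_restarts),
                 min_points = as.integer(min_points),
                 exclude_origin = exclude_origin),
            class = "mixture_config")
}

# Log density of a bivariate normal at the rows of x (n x 2), closed form.
#' @noRd
ldmvnorm2 <- function(x, mu, sigma) {
  s11 <- sigma[1, 1]; s12 <- sigma[1, 2]; s22 <- sigma[2, 2]
  det <- s11 * s22 - s12 * s12
  if (!is.finite(det) || det <= 0) {
    bf_stop("bf_fit_error", "singular component covariance (det = %g)", det)
  }
  dx <- x[, 1] - mu[1]; dy <- x[, 2] - mu[2]
  q <- (s22 * dx * dx - 2 * s12 * dx * dy + s11 * dy * dy) / det
  -log(2 * pi) - 0.5 * log(det) - 0.5 * q
}

# Regularise a 2x2 covariance if singular or ill-conditioned.
#' @noRd
regularize_cov <- function(sigma, reg_eps, cond_max) {
  scale <- mean(diag(sigma))
  if (!is.finite(scale) || scale <= 0) {
    bf_stop("bf_fit_error",
            "component covariance collapsed to zero (all points identical?)")
  }
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (ev[2] <= 0 || ev[1] / max(ev[2], .Machine$double.xmin) > cond_max) {
    sigma <- sigma + diag(reg_eps * scale, 2)
    ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
    if (ev[2] <= 0) {
      bf_stop("bf_fit_error",
              "component covariance is degenerate even after regularisation")
    }
  }
  sigma
}

# One weighted M-step: parameters from responsibilities (n x 3).
#' @noRd
m_step <- function(X, resp, config) {
  n <- nrow(X)
  nk <- colSums(resp)
  tau <- nk / n
  means <- matrix(0, 3, 2)
  covs <- vector("list", 3)
  for (k in 1:3) {
    w <- resp[, k]
    mu <- colSums(X * w) / nk[k]
    dx <- sweep(X, 2, mu)
    sigma <- crossprod(dx * w, dx) / nk[k]
    sigma <- (sigma + t(sigma)) / 2
    means[k, ] <- mu
    covs[[k]] <- regularize_cov(sigma, config$reg_eps, config$cond_max)
  }
  list(tau = tau, means = means, covs = covs)
}

# log densities (n x 3) including mixing weights.
#' @noRd
weighted_logdens <- function(X, tau, means, covs) {
  ld <- matrix(0, nrow(X), 3)
  for (k in 1:3) {
    ld[, k] <- log(tau[k]) + ldmvnorm2(X, means[k, ], covs[[k]])
  }
  ld
}

#' @noRd
row_logsumexp <- function(ld) {
  m <- pmax(ld[, 1], ld[, 2], ld[, 3])
  finite <- is.finite(m)
  out <- rep(-Inf, nrow(ld))
  out[finite] <- m[finite] +
    log(exp(ld[finite, 1] - m[finite]) + exp(ld[finite, 2] - m[finite]) +
        exp(ld[finite, 3] - m[finite]))
  out
}

#' @noRd
init_params <- function(X, config, method) {
  n <- nrow(X)
  groups <- if (method == "tertile") {
    d <- X[, 2] - X[, 1]
    qs <- stats::quantile(d, c(1 / 3, 2 / 3), names = FALSE)
    findInterval(d, qs, rightmost.closed = FALSE) + 1L
  } else {
    stats::kmeans(X, centers = 3, nstart = 5)$cluster
  }
  # Hard assignments -> responsibilities -> one M-step.
  resp <- matrix(0, n, 3)
  for (k in 1:3) resp[groups == k, k] <- 1
  nk <- colSums(resp)
  if (any(nk < 2)) {
    # Pathological split (e.g. massed quantiles): fall back to random thirds.
    groups <- sample(rep_len(1:3, n))
    resp[] <- 0
    for (k in 1:3) resp[groups == k, k] <- 1
  }
  m_step(X, resp, mixture_config(reg_eps = max(config$reg_eps, 1e-4),
                                 cond_max = config$cond_max))
}

#' Fit the three-component bivariate normal mixture by EM
#'
#' Fits weights \eqn{\tau_1..\tau_3}, component means and full (unconstrained)
#' 2x2 covariances to points in transformed intensity space
#' \eqn{(A', B') = (\ln(A+1), \ln(B+1))}. After fitting, components are
#' labelled AA/AB/BB by the butterfly geometry (see [label_components()])
#' and reordered so component 1 = AA, 2 = AB, 3 = BB.
#'
#' @param points numeric matrix (or 2-column data frame) of transformed
#'   intensities, one row per SNP.
#' @param config a [mixture_config()].
#' @param seed optional integer seed; only consumed by stochastic
#'   initialisers (restarts, k-means), so identical inputs and seed give
#'   bit-identical fits.
#' @return An object of class `"butterfly_model"`: a list with `weights`
#'   (length 3), `means` (3 x 2 matrix), `covariances` (list of three 2x2
#'   matrices), `label_map` (`c("AA","AB","BB")` after reordering), and
#'   `fit_info` (`loglik` trace, `n_iter`, `converged`, `seed`, `n_points`).
#' @export
fit_mixture <- function(points, config = mixture_config(), seed = NULL) {
  X <- as.matrix(points)
  if (ncol(X) != 2) bf_stop("bf_fit_error", "points must have two columns")
  storage.mode(X) <- "double"
  if (any(!is.finite(X))) bf_stop("bf_fit_error", "points must be finite")
  if (config$exclude_origin) {
    X <- X[!(X[, 1] == 0 & X[, 2] == 0), , drop = FALSE]
  }
  if (nrow(X) < config$min_points) {
    bf_stop("bf_fit_error", "need at least %d points to fit, got %d",
            config$min_points, nrow(X))
  }
  if (!is.null(seed)) set.seed(seed)

  fit <- NULL
  for (attempt in 0:config$max_restarts) {
    method <- if (attempt == 0) config$init else "kmeans"
    params <- init_params(X, config, method)
    res <- em_loop(X, params, config)
    if (!res$collapsed) { fit <- res; break }
  }
  if (is.null(fit)) {
    bf_stop("bf_fit_error",
            "a component weight collapsed below %g in all %d attempts (degenerate data?)",
            config$weight_floor, config$max_restarts + 1)
  }

  ord <- label_components(fit$tau, fit$means, fit$covs)
  structure(list(
    weights = fit$tau[ord],
    means = fit$means[ord, , drop = FALSE],
    covariances = fit$covs[ord],
    label_map = c("AA", "AB", "BB"),
    fit_info = list(loglik = fit$ll_trace, n_iter = fit$iter,
                    converged = fit$converged, seed = seed,
                    n_points = nrow(X))
  ), class = "butterfly_model")
}

#' @noRd
em_loop <- function(X, params, config) {
  tau <- params$tau; means <- params$means; covs <- params$covs
  ll_prev <- -Inf
  ll_trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    ld <- weighted_logdens(X, tau, means, covs)
    lse <- row_logsumexp(ld)
    ll <- sum(lse)
    ll_trace <- c(ll_trace, ll)
    resp <- exp(ld - lse)
    resp[!is.finite(resp)] <- 1 / 3  # fully-underflowed points: uninformative
    if (any(colSums(resp) / nrow(X) < config$weight_floor)) {
      return(list(collapsed = TRUE))
    }
    if (is.finite(ll_prev) &&
        abs(ll - ll_prev) <= config$tol * (abs(ll_prev) + .Machine$double.eps)) {
      converged <- TRUE
      break
    }
    if (iter >= config$max_iter) break
    step <- m_step(X, resp, config)
    tau <- step$tau; means <- step$means; covs <- step$covs
    ll_prev <- ll
  }
  list(collapsed = FALSE, tau = tau, means = means, covs = covs,
       ll_trace = ll_trace, iter = iter, converged = converged)
}

#' Map unlabelled mixture components to genotypes
#'
#' In the butterfly geometry, the AA cluster is A-high/B-low, BB is
#' A-low/B-high, and AB sits between; components are therefore sorted by the
#' mean of \eqn{B' - A'} ascending and assigned AA, AB, BB in that order.
#' Ties on the sort key are broken by ascending mean \eqn{A'} and reported
#' with a message.
#'
#' @param weights,means,covariances fitted parameters (means is 3 x 2).
#' @return Integer permutation `ord` such that `means[ord, ]` is in
#'   AA, AB, BB order.
#' @export
label_components <- function(weights, means, covariances = NULL) {
  key <- means[, 2] - means[, 1]
  if (anyDuplicated(key)) {
    message("label_components: tie on mean(B' - A'); breaking by mean A'")
  }
  order(key, means[, 1])
}

#' Mixture density
#'
#' Evaluates \eqn{f(A', B') = \sum_i \tau_i \phi_i(A', B')} at each row of
#' `points`.
#'
#' @param model a `"butterfly_model"`.
#' @param points matrix (or 2-vector) of transformed intensities.
#' @return Numeric vector of densities, strictly positive for finite points.
#' @export
mixture_density <- function(model, points) {
  X <- point_matrix(points)
  ld <- weighted_logdens(X, model$weights, model$means, model$covariances)
  exp(row_logsumexp(ld))
}

#' Genotype posterior probabilities
#'
#' Computes \eqn{P(k \mid A', B') = \tau_k \phi_k(A', B') /
#' \sum_i \tau_i \phi_i(A', B')} for each genotype k, accumulated in log
#' space so that points far from all components do not produce `NaN`. Rows
#' where all three component log densities underflow to `-Inf` are flagged
#' degenerate (all-`NA` row plus the `"degenerate"` attribute) and should be
#' treated as no-calls downstream.
#'
#' @param model a `"butterfly_model"`.
#' @param points matrix (or 2-vector) of transformed intensities.
#' @return An n x 3 matrix with columns named by `model$label_map`; rows sum
#'   to 1. Attribute `"degenerate"`: logical vector marking underflowed rows.
#' @export
posterior <- function(model, points) {
  X <- point_matrix(points)
  if (any(!is.finite(X))) bf_stop("bf_domain_error", "points must be finite")
  ld <- weighted_logdens(X, model$weights, model$means, model$covariances)
  m <- pmax(ld[, 1], ld[, 2], ld[, 3])
  degenerate <- !is.finite(m)
  p <- exp(ld - ifelse(is.finite(m), m, 0))
  p <- p / rowSums(p)
  p[degenerate, ] <- NA_real_
  colnames(p) <- model$label_map
  attr(p, "degenerate") <- degenerate
  p
}

#' @noRd
point_matrix <- function(points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 2)
  X <- as.matrix(points)
  if (ncol(X) != 2) bf_stop("bf_domain_error", "points must have two columns")
  storage.mode(X) <- "double"
  X
}

#' Serialise / restore a fitted model as JSON
#'
#' Full double precision (17 significant digits) is written so that a
#' write/read round trip reproduces the parameters bit-exactly.
#'
#' @param model a `"butterfly_model"`.
#' @param path file path.
#' @return `read_model` returns the model; `write_model` returns `path`
#'   invisibly.
#' @export
write_model <- function(model, path) {
  # 17 significant digits round-trip IEEE doubles exactly; jsonlite's
  # maximum-precision mode stops at 15, so numbers are formatted explicitly.
  num <- function(x) sprintf("%.17g", x)
  arr <- function(x) paste0("[", paste(num(x), collapse = ","), "]")
  strs <- function(x) paste0("[", paste0("\"", x, "\"", collapse = ","), "]")
  fi <- model$fit_info
  json <- paste0(
    "{\n",
    "  \"weights\": ", arr(model$weights), ",\n",
    "  \"means\": ", arr(as.vector(t(model$means))), ",\n",  # row-major
    "  \"covariances\": [",
    paste(vapply(model$covariances,
                 function(s) arr(as.vector(t(s))), ""), collapse = ","),
    "],\n",
    "  \"label_map\": ", strs(model$label_map), ",\n",
    "  \"fit_info\": {\"loglik\": ", arr(fi$loglik),
    ", \"n_iter\": ", fi$n_iter %||% 0L,
    ", \"converged\": ", tolower(isTRUE(fi$converged)),
    ", \"seed\": ", if (is.null(fi$seed)) "null" else fi$seed,
    ", \"n_points\": ", fi$n_points %||% 0L, "}\n",
    "}\n")
  writeLines(json, path, sep = "")
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  covs <- obj$covariances
  if (is.matrix(covs)) covs <- lapply(seq_len(nrow(covs)), function(i) covs[i, ])
  structure(list(
    weights = as.numeric(obj$weights),
    means = matrix(as.numeric(obj$means), 3, 2, byrow = TRUE),
    covariances = lapply(covs,
                         function(s) matrix(as.numeric(s), 2, 2, byrow = TRUE)),
    label_map = as.character(obj$label_map),
    fit_info = obj$fit_info
  ), class = "butterfly_model")
}

#' @export
#' @method print butterfly_model
print.butterfly_model <- function(x, ...) {
  cat("Three-component bivariate normal mixture (unconstrained covariances)\n")
  cat(sprintf("  fitted on %d points, %d EM iterations (%s)\n",
              x$fit_info$n_points, x$fit_info$n_iter,
              if (isTRUE(x$fit_info$converged)) "converged" else "not converged"))
  for (k in 1:3) {
    cat(sprintf("  %s: weight %.4f, mean (%.3f, %.3f)\n", x$label_map[k],
                x$weights[k], x$means[k, 1], x$means[k, 2]))
  }
  invisible(x)
}
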