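# Independent oracles and fixture builders, deliberately implemented with
# different primitives than the package (solve/det instead of the closed-form
# 2x2 kernel) so they stay an independent check.

# Naive bivariate normal pdf via generic matrix algebra.
naive_bvn_pdf <- function(x, mu, sigma) {
  d <- x - mu
  exp(-0.5 * drop(t(d) %*% solve(sigma) %*% d)) / (2 * pi * sqrt(det(sigma)))
}

# Term-by-term mixture density: sum_i tau_i phi_i(x).
naive_density <- function(model, x) {
  sum(vapply(1:3, function(k) {
    model$weights[k] * naive_bvn_pdf(x, model$means[k, ], model$covariances[[k]])
  }, 0))
}

# The three weighted component densities tau_k phi_k(x).
naive_weighted_dens <- function(model, x) {
  vapply(1:3, function(k) {
    model$weights[k] * naive_bvn_pdf(x, model$means[k, ], model$covariances[[k]])
  }, 0)
}

# Direct genotype posterior: tau_k phi_k / sum_i tau_i phi_i.
naive_posterior <- function(model, x) {
  dens <- naive_weighted_dens(model, x)
  dens / sum(dens)
}

# Random valid mixture model (moderate scale so the naive oracle does not
# underflow).
random_model <- function() {
  w <- stats::rgamma(3, 2); w <- w / sum(w)
  means <- matrix(stats::runif(6, 0, 10), 3, 2)
  covs <- lapply(1:3, function(k) {
    a <- matrix(stats::rnorm(4, sd = 0.5), 2, 2)
    a %*% t(a) + diag(0.05, 2)
  })
  structure(list(weights = w, means = means, covariances = covs,
                 label_map = c("AA", "AB", "BB"),
                 fit_info = list(loglik = numeric(0), n_iter = 0L,
                                 converged = TRUE, seed = NULL,
                                 n_points = 0L)),
            class = "butterfly_model")
}

# Symmetric, well-separated toy model for calling tests.
toy_model <- function(sd2 = 0.04) {
  structure(list(weights = rep(1 / 3, 3),
                 means = matrix(c(6, 1, 4, 4, 1, 6), 3, 2, byrow = TRUE),
                 covariances = replicate(3, diag(sd2, 2), simplify = FALSE),
                 label_map = c("AA", "AB", "BB"),
                 fit_info = list(loglik = numeric(0), n_iter = 0L,
                                 converged = TRUE, seed = NULL,
                                 n_points = 0L)),
            class = "butterfly_model")
}

# Manifest tibble builder with sensible defaults per probe.
mk_manifest <- function(rsid,
                        chromosome = "1",
                        probe_type = "II",
                        allele_a = "A", allele_b = "G",
                        ref_strand = "+",
                        mapping_comment = "",
                        is_indel = FALSE,
                        probe_name = rsid) {
  n <- length(rsid)
  tibble::tibble(
    probe_name = rep_len(probe_name, n),
    rsid = rsid,
    chromosome = rep_len(chromosome, n),
    position = seq_len(n) * 100L,
    probe_type = rep_len(probe_type, n),
    allele_a = rep_len(allele_a, n),
    allele_b = rep_len(allele_b, n),
    ref_strand = rep_len(ref_strand, n),
    mapping_comment = rep_len(mapping_comment, n),
    is_indel = rep_len(is_indel, n),
    address_a = seq_len(n) + 1000L,
    address_b = ifelse(rep_len(probe_type, n) == "I", seq_len(n) + 2000L,
                       NA_integer_)
  )
}

# One-row intensity record for call_snp tests.
mk_snp <- function(mean_a, mean_b, beads_a = 13L, beads_b = beads_a,
                   probe_type = "II", snp_id = "snp1") {
  tibble::tibble(sample_id = "s1", snp_id = snp_id, probe_type = probe_type,
                 mean_a = mean_a, mean_b = mean_b,
                 sd_a = NA_real_, sd_b = NA_real_,
                 beads_a = as.integer(beads_a), beads_b = as.integer(beads_b))
}

# Small minimal VCF written as text; returns the path.
write_test_vcf <- function(path, sample = "S1") {
  lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t", sample),
    "1\t100\trs1\tA\tG\t50\tPASS\t.\tGT:DP\t0/1:30",   # kept het {A,G}
    "1\t200\trs2\tC\tT\t50\tPASS\t.\tGT:DP\t1/1:40",   # kept hom TT
    "1\t300\trs3\tA\tG\t50\tPASS\t.\tGT:DP\t0/1:24",   # low depth
    "1\t400\trs4\tA\tG,T\t50\tPASS\t.\tGT:DP\t0/1:30", # triallelic
    "1\t500\trs5\tAT\tA\t50\tPASS\t.\tGT:DP\t0/1:30",  # indel
    "1\t600\trs6\tG\tC\t50\tPASS\t.\tGT:DP\t./.:30",   # no genotype
    "1\t700\t.\tT\tC\t50\tPASS\t.\tGT:DP\t0/0:35"      # kept, no ID
  )
  writeLines(lines, path)
  path
}
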