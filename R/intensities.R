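# Per-SNP intensity assembly from address-level records, log transform, and
# the TSV interchange format.

#' Natural-log transform of raw mean intensities
#'
#' Computes `ln(x + 1)`. Raw mean signal intensities can be exactly 0 (e.g.
#' dropouts), where a plain log would be `-Inf`; shifting by one keeps the
#' transform finite and maps 0 to 0.
#'
#' @param x numeric vector of raw mean intensities, all `>= 0`.
#' @return `log(x + 1)`, same length as `x`.
#' @export
log_transform <- function(x) {
  if (any(!is.finite(x)) || any(x < 0)) {
    bf_stop("bf_domain_error", "intensities must be finite and >= 0")
  }
  log1p(x)
}

#' Assemble per-SNP A/B intensities from address-level records
#'
#' Raw scanner output is one record per bead address per colour channel
#' (red detects A/T bases, green detects C/G). This assembles them into one
#' row per SNP:
#' \itemize{
#'   \item type II probes have a single address; the A and B allele
#'     intensities are the red/green measurements there, assigned by which
#'     SNP base each channel detects. Both alleles share the one bead count.
#'   \item type I probes have two addresses, both read on the probe's
#'     designated channel (the channel of its SNP bases; when the two bases
#'     would sit on different channels, allele A's channel is used and a
#'     warning is issued). Allele A comes from `address_a`, allele B from
#'     `address_b`, each with its own bead count.
#' }
#' Probes whose addresses are missing from `raw`, or type II probes whose
#' two bases sit on the same channel (unassignable), are dropped and counted.
#'
#' @param raw data frame with columns `address`, `channel` ("red"/"green"),
#'   `mean`, `sd`, `n_beads`.
#' @param manifest a filtered manifest tibble.
#' @param sample_id sample identifier stored in the output.
#' @return A tibble with columns `sample_id`, `snp_id`, `probe_type`,
#'   `mean_a`, `mean_b`, `sd_a`, `sd_b`, `beads_a`, `beads_b`. Attributes
#'   `n_dropped_missing` and `n_dropped_unassignable` count dropped probes.
#' @export
assemble_from_raw <- function(raw, manifest, sample_id = "sample") {
  stopifnot(all(c("address", "channel", "mean", "n_beads") %in% names(raw)))
  if (!"sd" %in% names(raw)) raw$sd <- NA_real_
  key <- paste(raw$address, raw$channel)
  lookup <- function(address, channel) match(paste(address, channel), key)

  chan_a <- channel_of_base(manifest$allele_a)
  chan_b <- channel_of_base(manifest$allele_b)
  type2 <- manifest$probe_type == "II"

  unassignable <- type2 & (is.na(chan_a) | is.na(chan_b) | chan_a == chan_b)
  mixed_type1 <- !type2 & !is.na(chan_a) & !is.na(chan_b) & chan_a != chan_b
  if (any(mixed_type1)) {
    warning(sprintf(paste("%d type I probe(s) have alleles on different colour",
                          "channels; using allele A's channel"),
                    sum(mixed_type1)))
  }

  # Index of the raw record feeding each allele. Allele A always comes from
  # address_a on its own channel; allele B from the other channel (type II)
  # or the second address on the designated channel (type I).
  ia <- lookup(manifest$address_a, chan_a)
  ib <- ifelse(type2, lookup(manifest$address_a, chan_b),
               lookup(manifest$address_b, chan_a))
  missing <- !unassignable & (is.na(ia) | is.na(ib))
  keep <- !unassignable & !missing

  out <- tibble::tibble(
    sample_id = sample_id,
    snp_id = manifest$rsid[keep],
    probe_type = manifest$probe_type[keep],
    mean_a = raw$mean[ia[keep]],
    mean_b = raw$mean[ib[keep]],
    sd_a = raw$sd[ia[keep]],
    sd_b = raw$sd[ib[keep]],
    beads_a = as.integer(raw$n_beads[ia[keep]]),
    beads_b = as.integer(raw$n_beads[ib[keep]])
  )
  # Type II: one set of beads captures both alleles, so there is one count.
  out$beads_b[out$probe_type == "II"] <- out$beads_a[out$probe_type == "II"]
  n_miss <- sum(missing); n_unas <- sum(unassignable)
  if (n_miss > 0) message(sprintf("assemble_from_raw: dropped %d probe(s) with missing address records", n_miss))
  if (n_unas > 0) message(sprintf("assemble_from_raw: dropped %d unassignable type II probe(s)", n_unas))
  attr(out, "n_dropped_missing") <- n_miss
  attr(out, "n_dropped_unassignable") <- n_unas
  out
}

#' Read / write the per-SNP intensity TSV
#'
#' The interchange format is a tab-separated table with one row per SNP per
#' sample and columns `sample_id`, `snp_id`, `probe_type`, `mean_a`,
#' `mean_b`, `sd_a`, `sd_b`, `beads_a`, `beads_b`. Raw (untransformed) means
#' are stored: the zero-intensity no-call rule is defined on raw means, and
#' `ln(x+1)` is applied at modelling time.
#'
#' @param x intensity tibble.
#' @param path file path.
#' @return `read_intensities` returns the tibble; `write_intensities`
#'   returns `path` invisibly.
#' @export
write_intensities <- function(x, path) {
  cols <- c("sample_id", "snp_id", "probe_type", "mean_a", "mean_b",
            "sd_a", "sd_b", "beads_a", "beads_b")
  missing <- setdiff(cols, names(x))
  for (m in missing) x[[m]] <- NA_real_
  write_tsv_plain(as.data.frame(x)[, cols], path)
}

#' @rdname write_intensities
#' @export
read_intensities <- function(path) {
  x <- read_tsv_plain(path)
  x$sample_id <- as.character(x$sample_id)
  x$snp_id <- as.character(x$snp_id)
  x$probe_type <- as.character(x$probe_type)
  if (anyDuplicated(paste(x$sample_id, x$snp_id))) {
    bf_stop("bf_parse_error", "duplicate snp_id within a sample in %s", path)
  }
  x
}
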