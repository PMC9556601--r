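# Evaluation against a reference call set: call rate, concordance,
# discordance cross-tabs, and no-call-conditional distributions.

#' Load reference genotype calls from a VCF
#'
#' Emulates a high-confidence whole-genome-sequencing reference: keeps
#' biallelic SNV records (single-base REF and ALT) with a genotype for the
#' requested sample and per-sample read depth `DP >= min_depth`; resolves
#' each genotype to an unordered plus-strand base pair. Multi-allelic
#' sites, indels, missing genotypes and low-depth records are dropped and
#' counted.
#'
#' @param path VCF file (plain or bgzipped).
#' @param sample sample name in the VCF.
#' @param min_depth minimum per-sample read depth (default 25).
#' @return A tibble of class `"reference_calls"` with columns `snp_id` (the
#'   VCF ID, or `chrom:pos` when missing), `chrom`, `pos`, `genotype`
#'   (two-base string, bases in lexicographic order). Attribute `"dropped"`
#'   counts the records removed per rule.
#' @export
load_reference_calls <- function(path, sample, min_depth = 25L) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  gt_all <- vcfR::extract.gt(v, element = "GT")
  if (!sample %in% colnames(gt_all)) {
    bf_stop("bf_config_error", "sample '%s' not found in VCF (have: %s)",
            sample, paste(colnames(gt_all), collapse = ", "))
  }
  gt <- gt_all[, sample]
  dp <- suppressWarnings(as.numeric(vcfR::extract.gt(v, element = "DP")[, sample]))

  bases <- c("A", "C", "G", "T")
  biallelic <- fix$REF %in% bases & fix$ALT %in% bases
  has_gt <- !is.na(gt) & !grepl("^\\.([/|]\\.)?$", gt)
  deep <- !is.na(dp) & dp >= min_depth
  keep <- biallelic & has_gt & deep

  alleles <- strsplit(gt[keep], "[/|]")
  ok_gt <- vapply(alleles, function(a) length(a) == 2 && all(a %in% c("0", "1")), TRUE)
  dropped <- c(multiallelic_or_indel = sum(!biallelic),
               no_genotype = sum(biallelic & !has_gt),
               low_depth = sum(biallelic & has_gt & !deep),
               malformed = sum(!ok_gt))
  idx <- which(keep)[ok_gt]
  alleles <- alleles[ok_gt]
  ref <- fix$REF[idx]; alt <- fix$ALT[idx]
  g1 <- ifelse(vapply(alleles, `[`, "", 1) == "0", ref, alt)
  g2 <- ifelse(vapply(alleles, `[`, "", 2) == "0", ref, alt)
  genotype <- unname(ifelse(g1 <= g2, paste0(g1, g2), paste0(g2, g1)))
  id <- fix$ID[idx]
  id[is.na(id) | id == "."] <- paste0(fix$CHROM[idx], ":", fix$POS[idx])[is.na(id) | id == "."]
  out <- tibble::tibble(snp_id = id, chrom = fix$CHROM[idx],
                        pos = as.integer(fix$POS[idx]), genotype = genotype)
  attr(out, "dropped") <- dropped
  class(out) <- c("reference_calls", class(out))
  out
}

#' Load reference genotypes from a TSV
#'
#' Simple alternative to a VCF, e.g. simulator truth: a tab-separated table
#' with columns `snp_id` and `genotype` (either base pairs like `"AG"` or
#' A/B genotypes like `"AB"`).
#'
#' @param path TSV path.
#' @return Tibble with `snp_id` and `genotype`.
#' @export
read_reference_tsv <- function(path) {
  x <- read_tsv_plain(path)
  stopifnot(all(c("snp_id", "genotype") %in% names(x)))
  x
}

#' Concordance of a call set with a reference
#'
#' Restricted to the intersection of the reference-called SNPs and the
#' method's SNP universe: the call rate is the non-no-call fraction among
#' reference-called SNPs; concordance is computed on SNPs called by both,
#' comparing genotypes as unordered strings. Discordant pairs populate a
#' reference x method cross-tab and a homozygous/heterozygous 2x2 summary.
#'
#' Method and reference genotypes must live in the same space: either both
#' plus-strand base pairs (use [translate_calls()] on the call set) or both
#' A/B genotypes (e.g. against simulator truth).
#'
#' @param method tibble with columns `snp_id` and either `genotype` or
#'   `call`; `"NC"` (or `NA`) marks a no-call. A `"call_set"` from
#'   [call_sample()] works directly.
#' @param reference tibble with columns `snp_id`, `genotype` (no-call-free;
#'   rows with `NA` or `"NC"` genotype are excluded from the universe).
#' @return A list of class `"concordance_report"`: `n_reference_called`,
#'   `n_method_called`, `call_rate`, `n_both_called`, `n_concordant`,
#'   `concordance`, `crosstab` (discordant reference x method counts),
#'   `homhet_summary` (2x2 hom/het discordance counts).
#' @export
concordance <- function(method, reference) {
  mcall <- if ("genotype" %in% names(method)) method$genotype else method$call
  mcall[is.na(mcall)] <- "NC"
  ref <- reference[!is.na(reference$genotype) & reference$genotype != "NC", ]
  idx <- match(ref$snp_id, method$snp_id)
  in_universe <- !is.na(idx)
  if (!any(in_universe)) {
    bf_stop("bf_eval_error",
            "no overlap between reference-called SNPs and the method's SNP universe")
  }
  rg <- ref$genotype[in_universe]
  mg <- mcall[idx[in_universe]]
  n_ref <- length(rg)
  called <- mg != "NC"
  n_called <- sum(called)
  conc <- rg[called] == mg[called]
  n_conc <- sum(conc)
  disc_ref <- rg[called][!conc]
  disc_met <- mg[called][!conc]
  crosstab <- table(reference = disc_ref, method = disc_met)
  is_hom <- function(g) substr(g, 1, 1) == substr(g, 2, 2)
  zyg <- function(g) factor(ifelse(is_hom(g), "hom", "het"),
                            levels = c("hom", "het"))
  homhet <- table(reference = zyg(disc_ref), method = zyg(disc_met))
  structure(list(n_reference_called = n_ref,
                 n_method_called = n_called,
                 call_rate = n_called / n_ref,
                 n_both_called = n_called,
                 n_concordant = n_conc,
                 concordance = if (n_called > 0) n_conc / n_called else NA_real_,
                 crosstab = crosstab,
                 homhet_summary = homhet),
            class = "concordance_report")
}

#' @export
#' @method print concordance_report
print.concordance_report <- function(x, ...) {
  cat("Concordance report\n")
  cat(sprintf("  reference-called SNPs: %d\n", x$n_reference_called))
  cat(sprintf("  call rate:             %.4f (%d called)\n",
              x$call_rate, x$n_method_called))
  cat(sprintf("  concordance:           %.4f (%d of %d)\n",
              x$concordance, x$n_concordant, x$n_both_called))
  if (sum(x$crosstab) > 0) {
    cat("  discordant calls (reference x method):\n")
    print(x$crosstab)
  }
  invisible(x)
}

#' Write a concordance report
#'
#' Writes `<prefix>.json` with the scalar summaries and
#' `<prefix>_crosstab.tsv` with the discordance cross-tab in long form.
#'
#' @param report a `"concordance_report"`.
#' @param prefix output path prefix.
#' @export
write_concordance <- function(report, prefix) {
  scalars <- report[c("n_reference_called", "n_method_called", "call_rate",
                      "n_both_called", "n_concordant", "concordance")]
  jsonlite::write_json(scalars, paste0(prefix, ".json"),
                       digits = NA, auto_unbox = TRUE)
  ct <- as.data.frame(report$crosstab, stringsAsFactors = FALSE)
  write_tsv_plain(ct, paste0(prefix, "_crosstab.tsv"))
  invisible(prefix)
}

#' Call distribution conditional on another method's no-calls
#'
#' Restricted to SNPs where `method_a` made a no-call, tabulates
#' `method_b`'s calls (including its own no-calls) and, when a reference is
#' supplied, how often each agrees with it.
#'
#' @param method_a,method_b call tibbles with `snp_id` and `call` (or
#'   `genotype`) columns, on the same SNP universe.
#' @param reference optional reference tibble (`snp_id`, `genotype`).
#' @return Tibble with `call`, `n`, `fraction` and (with a reference)
#'   `n_concordant`.
#' @export
conditional_on_nc <- function(method_a, method_b, reference = NULL) {
  get_call <- function(m) {
    g <- if ("genotype" %in% names(m)) m$genotype else m$call
    g[is.na(g)] <- "NC"
    g
  }
  a <- get_call(method_a); b <- get_call(method_b)
  idx <- match(method_a$snp_id[a == "NC"], method_b$snp_id)
  idx <- idx[!is.na(idx)]
  if (length(idx) == 0) {
    return(tibble::tibble(call = character(), n = integer(),
                          fraction = numeric()))
  }
  bc <- b[idx]
  tab <- table(bc)
  out <- tibble::tibble(call = names(tab), n = as.integer(tab),
                        fraction = as.integer(tab) / length(bc))
  if (!is.null(reference)) {
    rg <- reference$genotype[match(method_b$snp_id[idx], reference$snp_id)]
    agree <- tapply(!is.na(rg) & bc == rg, bc, sum)
    out$n_concordant <- as.integer(agree[out$call])
  }
  out
}
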