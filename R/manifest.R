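# Probe-manifest handling: loading, sequential filtering, allele translation.

#' Default rsIDs excluded at filtering step 1
#'
#' Two type II probes whose assay design is ambiguous; they are removed by
#' name before any other rule (see [filter_probes()]).
#'
#' @export
default_named_exclusions <- c("rs28362918", "rs28897688")

#' Column map for manifest tables
#'
#' Maps the standard internal field names onto the column headers of a
#' delimited manifest file. Defaults match the headers Illumina uses in its
#' manifest CSV exports. `mapping_comment` and `is_indel` columns are
#' optional: a missing `mapping_comment` column is read as all-empty, and a
#' missing `is_indel` column is derived from the allele field (bracketed
#' pairs containing `I`, `D` or `-` are treated as indels).
#'
#' @param probe_name,rsid,chromosome,position,probe_type,snp_alleles,ref_strand,mapping_comment,is_indel,address_a,address_b
#'   column names in the input file.
#' @return Named list of column names, class `"manifest_col_map"`.
#' @export
manifest_col_map <- function(probe_name = "IlmnID",
                             rsid = "Name",
                             chromosome = "Chr",
                             position = "MapInfo",
                             probe_type = "Infinium_Design_Type",
                             snp_alleles = "SNP",
                             ref_strand = "RefStrand",
                             mapping_comment = "MappingComment",
                             is_indel = "IsIndel",
                             address_a = "AddressA_ID",
                             address_b = "AddressB_ID") {
  structure(list(probe_name = probe_name, rsid = rsid,
                 chromosome = chromosome, position = position,
                 probe_type = probe_type, snp_alleles = snp_alleles,
                 ref_strand = ref_strand, mapping_comment = mapping_comment,
                 is_indel = is_indel, address_a = address_a,
                 address_b = address_b),
            class = "manifest_col_map")
}

# Mandatory fields; mapping_comment/is_indel/address_b may be absent from the
# file and are then filled with defaults.
.mandatory_manifest_fields <- c("probe_name", "rsid", "chromosome", "position",
                                "probe_type", "snp_alleles", "ref_strand",
                                "address_a")

#' Load a probe manifest from a delimited table
#'
#' Reads a CSV/TSV probe manifest into a tibble with one row per probe and
#' the standardised columns `probe_name`, `rsid`, `chromosome`, `position`,
#' `probe_type` ("I"/"II"), `allele_a`, `allele_b` (the two SNP bases, allele
#' A first, parsed from a bracketed pair such as `"[A/G]"`), `ref_strand`
#' ("+"/"-"), `mapping_comment`, `is_indel`, `address_a`, `address_b`
#' (`NA` for type II probes, which have a single bead address). Duplicate
#' `probe_name` values are retained — the filtering pipeline needs them.
#'
#' Rows whose allele field cannot be parsed (on non-indel rows) are dropped
#' and reported with their row numbers; if more than `max_bad_frac` of rows
#' fail, loading aborts.
#'
#' @param path path to the manifest file.
#' @param col_map a [manifest_col_map()], or a path to a YAML file whose keys
#'   are the `manifest_col_map()` argument names.
#' @param sep field separator; `NULL` (default) auto-detects `,` vs tab from
#'   the header line.
#' @param max_bad_frac abort if the fraction of unparseable rows exceeds this.
#' @return A tibble of class `"manifest_table"`. The attribute `"bad_rows"`
#'   holds the row numbers that failed to parse.
#' @export
load_manifest <- function(path, col_map = manifest_col_map(), sep = NULL,
                          max_bad_frac = 0.05) {
  if (!file.exists(path)) bf_stop("bf_io_error", "manifest file not found: %s", path)
  if (is.character(col_map) && length(col_map) == 1) {
    col_map <- do.call(manifest_col_map, yaml::read_yaml(col_map))
  }
  header <- readLines(path, n = 1L)
  if (length(header) == 0L) {
    warning("empty manifest file: ", path)
    return(empty_manifest())
  }
  if (is.null(sep)) {
    sep <- if (grepl("\t", header)) "\t" else ","
  }
  raw <- utils::read.table(path, sep = sep, header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           quote = "\"", comment.char = "")
  if (nrow(raw) == 0L) {
    warning("manifest has a header but no rows: ", path)
    return(empty_manifest())
  }
  missing_cols <- setdiff(unlist(col_map[.mandatory_manifest_fields]),
                          names(raw))
  if (length(missing_cols) > 0) {
    bf_stop("bf_config_error", "manifest is missing mandatory column(s): %s",
            paste(missing_cols, collapse = ", "))
  }
  get_col <- function(field, default = NULL) {
    cn <- col_map[[field]]
    if (cn %in% names(raw)) raw[[cn]] else default
  }
  n <- nrow(raw)
  probe_type <- toupper(trimws(as.character(get_col("probe_type"))))
  if (!all(probe_type %in% c("I", "II"))) {
    bad <- which(!probe_type %in% c("I", "II"))
    bf_stop("bf_parse_error", "invalid probe_type at row(s) %s",
            paste(utils::head(bad, 5), collapse = ", "))
  }
  alleles_raw <- trimws(as.character(get_col("snp_alleles")))
  indel_col <- get_col("is_indel")
  is_indel <- if (is.null(indel_col)) {
    grepl("[ID-]", alleles_raw)
  } else {
    as.logical(indel_col) %in% TRUE
  }
  m <- regmatches(alleles_raw,
                  regexec("^\\[([ACGT])/([ACGT])\\]$", alleles_raw))
  allele_a <- vapply(m, function(x) if (length(x) == 3) x[2] else NA_character_, "")
  allele_b <- vapply(m, function(x) if (length(x) == 3) x[3] else NA_character_, "")
  bad_rows <- which(is.na(allele_a) & !is_indel)
  if (length(bad_rows) > max_bad_frac * n) {
    bf_stop("bf_parse_error",
            "%d of %d rows have unparseable SNP alleles (first bad rows: %s)",
            length(bad_rows), n, paste(utils::head(bad_rows, 5), collapse = ", "))
  }
  if (length(bad_rows) > 0) {
    warning(sprintf("dropped %d manifest row(s) with unparseable SNP alleles (rows %s)",
                    length(bad_rows),
                    paste(utils::head(bad_rows, 10), collapse = ", ")))
  }
  strand_raw <- trimws(as.character(get_col("ref_strand")))
  ref_strand <- ifelse(strand_raw %in% c("+", "plus", "Plus"), "+",
                       ifelse(strand_raw %in% c("-", "minus", "Minus"), "-",
                              NA_character_))
  comment_col <- get_col("mapping_comment")
  mapping_comment <- if (is.null(comment_col)) rep("", n) else {
    x <- as.character(comment_col); x[is.na(x)] <- ""; trimws(x)
  }
  address_b <- suppressWarnings(as.integer(get_col("address_b",
                                                   rep(NA_integer_, n))))
  address_b[probe_type == "II"] <- NA_integer_
  out <- tibble::tibble(
    probe_name = as.character(get_col("probe_name")),
    rsid = as.character(get_col("rsid")),
    chromosome = as.character(get_col("chromosome")),
    position = as.integer(get_col("position")),
    probe_type = probe_type,
    allele_a = allele_a,
    allele_b = allele_b,
    ref_strand = ref_strand,
    mapping_comment = mapping_comment,
    is_indel = is_indel,
    address_a = as.integer(get_col("address_a")),
    address_b = address_b
  )
  if (length(bad_rows) > 0) out <- out[-bad_rows, ]
  attr(out, "bad_rows") <- bad_rows
  class(out) <- c("manifest_table", class(out))
  out
}

#' @noRd
empty_manifest <- function() {
  out <- tibble::tibble(probe_name = character(), rsid = character(),
                        chromosome = character(), position = integer(),
                        probe_type = character(), allele_a = character(),
                        allele_b = character(), ref_strand = character(),
                        mapping_comment = character(), is_indel = logical(),
                        address_a = integer(), address_b = integer())
  class(out) <- c("manifest_table", class(out))
  out
}

.filter_step_descriptions <- c(
  "Manifest file",
  "Named ambiguous SNPs",
  "Chromosome 0 (probe problems)",
  "Chromosome X/Y/mitochondria",
  "Non-empty mapping comment (probe problems)",
  "INDELs (insertion-deletions)",
  "Multiple probes binding to same rsID",
  "Multiple rsIDs for a probe name")

#' Sequentially filter a probe manifest
#'
#' Applies the seven filtering rules in order, each acting on the survivors
#' of the previous step:
#' \enumerate{
#'   \item remove probes whose rsID is in `named_exclusions`;
#'   \item remove chromosome "0" (unmapped / problem probes);
#'   \item remove chromosomes X, Y and the mitochondrion (labels are
#'     normalised case-insensitively; "MT", "M" and "chrM" all match);
#'   \item remove probes with a non-empty mapping comment;
#'   \item remove indel probes;
#'   \item remove \emph{every} probe whose rsID is shared by more than one
#'     remaining probe (no representative is kept — there is no principled
#'     tie-break);
#'   \item remove every probe whose `probe_name` is associated with more than
#'     one distinct remaining rsID.
#' }
#' The step counts are order-dependent by construction: a probe matching
#' several rules is counted at the first rule that removes it.
#'
#' @param manifest a manifest tibble from [load_manifest()].
#' @param named_exclusions character vector of rsIDs removed at step 1.
#' @return A list with `manifest` (the surviving rows) and `report`, a tibble
#'   of class `"filter_report"` with columns `step` (0–7), `description`,
#'   `snps_removed`, `snps_left`; step 0 is the input row count.
#' @export
filter_probes <- function(manifest, named_exclusions = default_named_exclusions) {
  stopifnot(is.data.frame(manifest))
  cur <- manifest
  removed <- integer(7)
  left <- integer(8)
  left[1] <- nrow(cur)
  drop_step <- function(cur, keep) cur[keep, , drop = FALSE]

  chrom <- normalize_chrom(cur$chromosome)
  keep <- !(cur$rsid %in% named_exclusions)
  removed[1] <- sum(!keep); cur <- drop_step(cur, keep); chrom <- chrom[keep]
  left[2] <- nrow(cur)

  keep <- chrom != "0"
  removed[2] <- sum(!keep); cur <- drop_step(cur, keep); chrom <- chrom[keep]
  left[3] <- nrow(cur)

  keep <- !(chrom %in% c("X", "Y", "MT"))
  removed[3] <- sum(!keep); cur <- drop_step(cur, keep); chrom <- chrom[keep]
  left[4] <- nrow(cur)

  keep <- is.na(cur$mapping_comment) | nchar(trimws(cur$mapping_comment)) == 0
  removed[4] <- sum(!keep); cur <- drop_step(cur, keep)
  left[5] <- nrow(cur)

  keep <- !cur$is_indel
  removed[5] <- sum(!keep); cur <- drop_step(cur, keep)
  left[6] <- nrow(cur)

  dup_rsid <- cur$rsid %in% cur$rsid[duplicated(cur$rsid)]
  removed[6] <- sum(dup_rsid); cur <- drop_step(cur, !dup_rsid)
  left[7] <- nrow(cur)

  n_rsids <- tapply(cur$rsid, cur$probe_name, function(x) length(unique(x)))
  multi <- names(n_rsids)[n_rsids > 1]
  keep <- !(cur$probe_name %in% multi)
  removed[7] <- sum(!keep); cur <- drop_step(cur, keep)
  left[8] <- nrow(cur)

  if (nrow(cur) == 0) message("filter_probes: no probes survived filtering")
  report <- tibble::tibble(step = 0:7,
                           description = .filter_step_descriptions,
                           snps_removed = c(0L, removed),
                           snps_left = left)
  class(report) <- c("filter_report", class(report))
  list(manifest = cur, report = report)
}

#' Write a filter report as TSV
#'
#' @param report a `"filter_report"` tibble from [filter_probes()].
#' @param path output path.
#' @export
write_filter_report <- function(report, path) {
  write_tsv_plain(as.data.frame(report), path)
}

#' Translate A/B genotype calls to plus-strand bases
#'
#' Allele A maps to the first SNP base of the probe and allele B to the
#' second; for probes designed against the minus strand both bases are
#' complemented. The result is an unordered genotype written as a
#' two-character string with the bases in lexicographic order (so a
#' heterozygote never depends on A/B orientation).
#'
#' All arguments are vectorised and recycled to a common length.
#'
#' @param call genotype call(s), each one of `"AA"`, `"AB"`, `"BB"`.
#' @param allele_a,allele_b the probe's SNP bases (allele A first).
#' @param ref_strand `"+"` or `"-"`.
#' @param is_indel logical; indel probes are not translatable.
#' @return Character vector of two-base genotypes, e.g. `"AG"`, `"TT"`.
#' @examples
#' ab_to_bases("AB", "A", "G", "+")  # "AG"
#' ab_to_bases("AA", "A", "G", "-")  # "TT"
#' @export
ab_to_bases <- function(call, allele_a, allele_b, ref_strand, is_indel = FALSE) {
  n <- max(length(call), length(allele_a), length(allele_b),
           length(ref_strand), length(is_indel))
  call <- rep_len(call, n); allele_a <- rep_len(allele_a, n)
  allele_b <- rep_len(allele_b, n); ref_strand <- rep_len(ref_strand, n)
  is_indel <- rep_len(is_indel, n)
  if (any(is_indel)) {
    bf_stop("bf_unsupported_probe", "cannot translate calls for indel probes")
  }
  if (any(!call %in% c("AA", "AB", "BB"))) {
    bf_stop("bf_invalid_call",
            "translation is undefined for no-calls; got: %s",
            paste(unique(call[!call %in% c("AA", "AB", "BB")]), collapse = ", "))
  }
  minus <- ref_strand == "-"
  a <- ifelse(minus, complement_base(allele_a), allele_a)
  b <- ifelse(minus, complement_base(allele_b), allele_b)
  first <- ifelse(call == "BB", b, a)
  second <- ifelse(call == "AA", a, b)
  ifelse(first <= second, paste0(first, second), paste0(second, first))
}

#' Translate a call set's A/B calls to plus-strand genotypes
#'
#' Joins a call table to a manifest by `snp_id` = `rsid` and adds a
#' `genotype` column with plus-strand bases; no-calls get `"NC"`.
#'
#' @param calls tibble with columns `snp_id` and `call` (e.g. from
#'   [call_sample()]).
#' @param manifest a filtered manifest tibble.
#' @return `calls` with an added `genotype` column; SNPs absent from the
#'   manifest get `NA`.
#' @export
translate_calls <- function(calls, manifest) {
  idx <- match(calls$snp_id, manifest$rsid)
  genotype <- rep(NA_character_, nrow(calls))
  ok <- !is.na(idx) & calls$call %in% c("AA", "AB", "BB")
  if (any(ok)) {
    genotype[ok] <- ab_to_bases(calls$call[ok],
                                manifest$allele_a[idx[ok]],
                                manifest$allele_b[idx[ok]],
                                manifest$ref_strand[idx[ok]],
                                manifest$is_indel[idx[ok]])
  }
  genotype[!is.na(idx) & calls$call == "NC"] <- "NC"
  calls$genotype <- genotype
  calls
}
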