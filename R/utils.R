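# Internal helpers shared across modules.

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# DNA complement for A/C/G/T vectors.
#' @noRd
complement_base <- function(x) chartr("ACGT", "TGCA", x)

# Colour channel interrogating a base: red detects A/T, green detects C/G.
#' @noRd
channel_of_base <- function(base) {
  ifelse(base %in% c("A", "T"), "red",
         ifelse(base %in% c("C", "G"), "green", NA_character_))
}

# Normalise chromosome labels: strip "chr" prefix, upper-case, map M -> MT.
#' @noRd
normalize_chrom <- function(chrom) {
  x <- toupper(trimws(as.character(chrom)))
  x <- sub("^CHR", "", x)
  x[x == "M"] <- "MT"
  x
}

#' @noRd
write_tsv_plain <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "NA")
  invisible(path)
}

#' @noRd
read_tsv_plain <- function(path) {
  if (!file.exists(path)) bf_stop("bf_io_error", "file not found: %s", path)
  tibble::as_tibble(utils::read.delim(path, sep = "\t", header = TRUE,
                                      stringsAsFactors = FALSE,
                                      na.strings = "NA",
                                      check.names = FALSE))
}

# Stop with a classed condition so callers can distinguish error families.
#' @noRd
bf_stop <- function(class, msg, ...) {
  stop(structure(class = c(class, "butterflycall_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}
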