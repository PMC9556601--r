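# Manifest loading, the sequential filtering pipeline, and A/B-to-base
# translation.

test_that("load_manifest parses a delimited table through the column map", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "IlmnID,Name,Chr,MapInfo,Infinium_Design_Type,SNP,RefStrand,AddressA_ID,AddressB_ID",
    "probe1,rs123,1,1000,II,[A/G],+,1001,",
    "probe2,rs124,2,2000,I,[C/G],-,1002,2002",
    "probe3,rs125,3,3000,II,[I/D],+,1003,"
  ), path)
  man <- load_manifest(path)
  expect_equal(nrow(man), 3)
  expect_equal(man$probe_type, c("II", "I", "II"))
  expect_equal(man$allele_a[1], "A")
  expect_equal(man$allele_b[1], "G")
  expect_true(is.na(man$address_b[1]))       # type II: single bead address
  expect_equal(man$address_b[2], 2002L)      # type I: two addresses
  expect_true(man$is_indel[3])               # derived from [I/D]
  expect_equal(man$ref_strand, c("+", "-", "+"))
})

test_that("load_manifest handles degenerate and malformed input", {
  empty <- withr::local_tempfile(fileext = ".csv")
  file.create(empty)
  expect_warning(man <- load_manifest(empty), "empty")
  expect_equal(nrow(man), 0)

  missing_col <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("IlmnID,Name,Chr", "p1,rs1,1"), missing_col)
  expect_error(load_manifest(missing_col), class = "bf_config_error")

  bad_allele <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "IlmnID,Name,Chr,MapInfo,Infinium_Design_Type,SNP,RefStrand,AddressA_ID,AddressB_ID",
    "p1,rs1,1,100,II,[A/G],+,1,",
    "p2,rs2,1,200,II,oops,+,2,"
  ), bad_allele)
  expect_error(load_manifest(bad_allele, max_bad_frac = 0),
               class = "bf_parse_error")
  expect_warning(man <- load_manifest(bad_allele, max_bad_frac = 0.9),
                 "unparseable")
  expect_equal(man$rsid, "rs1")
  expect_equal(attr(man, "bad_rows"), 2L)
})

test_that("the seven filtering rules remove the hand-derived rows in order", {
  man <- rbind(
    mk_manifest("rsA", chromosome = "1"),
    mk_manifest("rsB", chromosome = "0"),
    mk_manifest("rsC", chromosome = "X"),
    mk_manifest("rsD", chromosome = "2", mapping_comment = "bad"),
    mk_manifest("rsE", chromosome = "3", is_indel = TRUE),
    mk_manifest("rsF", chromosome = "4"))
  res <- filter_probes(man)
  expect_equal(sort(res$manifest$rsid), c("rsA", "rsF"))
  expect_equal(res$report$snps_removed[-1], c(0, 1, 1, 1, 1, 0, 0))
  expect_equal(res$report$snps_left[1], 6)
  expect_equal(res$report$snps_left[8], 2)
})

test_that("filter report counts telescope on any input", {
  set.seed(42)
  for (rep in 1:5) {
    n <- sample(10:60, 1)
    man <- mk_manifest(
      rsid = sample(sprintf("rs%d", 1:40), n, replace = TRUE),
      chromosome = sample(c("1", "2", "0", "X", "Y", "MT", "chrM"), n,
                          replace = TRUE),
      mapping_comment = sample(c("", "", "", "odd"), n, replace = TRUE),
      is_indel = sample(c(FALSE, FALSE, TRUE), n, replace = TRUE),
      probe_name = sample(sprintf("p%d", 1:40), n, replace = TRUE))
    rp <- filter_probes(man)$report
    expect_equal(rp$snps_left[1], n)
    expect_equal(rp$snps_left[-1], rp$snps_left[-8] - rp$snps_removed[-1])
  }
})

test_that("removal is attributed to the first matching rule", {
  # A chrX probe that also has a mapping comment falls at the chromosome
  # step, not the comment step.
  man <- rbind(mk_manifest("rs1", chromosome = "X", mapping_comment = "odd"),
               mk_manifest("rs2"))
  rp <- filter_probes(man)$report
  expect_equal(rp$snps_removed[rp$step == 3], 1)
  expect_equal(rp$snps_removed[rp$step == 4], 0)
})

test_that("rule 6 removes all probes of a multiply-probed rsID, none otherwise", {
  man <- mk_manifest(c("rsX", "rsX"), probe_name = c("p1", "p2"))
  res <- filter_probes(man)
  expect_equal(nrow(res$manifest), 0)
  expect_equal(res$report$snps_removed[res$report$step == 6], 2)

  # Unique rsIDs: rule 6 is inert.
  man2 <- mk_manifest(sprintf("rs%d", 1:20))
  rp2 <- filter_probes(man2)$report
  expect_equal(rp2$snps_removed[rp2$step == 6], 0)
})

test_that("rule 7 removes probe names mapping to multiple rsIDs", {
  man <- rbind(mk_manifest("rs1", probe_name = "pA"),
               mk_manifest("rs2", probe_name = "pA"),
               mk_manifest("rs3", probe_name = "pB"))
  res <- filter_probes(man)
  expect_equal(res$manifest$rsid, "rs3")
  expect_equal(res$report$snps_removed[res$report$step == 7], 2)
})

test_that("named exclusions are removed at step 1", {
  man <- mk_manifest(c("rs28362918", "rs28897688", "rsOK"))
  rp <- filter_probes(man)$report
  expect_equal(rp$snps_removed[rp$step == 1], 2)
  expect_equal(rp$snps_left[8], 1)
})

test_that("ab_to_bases maps alleles, complements minus-strand probes", {
  expect_equal(ab_to_bases("AB", "A", "G", "+"), "AG")
  expect_equal(ab_to_bases("AA", "A", "G", "-"), "TT")
  expect_equal(ab_to_bases("BB", "C", "T", "-"), "AA")
  # Heterozygotes come out in lexicographic order regardless of A/B order.
  expect_equal(ab_to_bases("AB", "G", "A", "+"), "AG")
})

test_that("ab_to_bases rejects no-calls and indel probes", {
  expect_error(ab_to_bases("NC", "A", "G", "+"), class = "bf_invalid_call")
  expect_error(ab_to_bases("AA", "A", "G", "+", is_indel = TRUE),
               class = "bf_unsupported_probe")
})

test_that("strand flip is an involution on translated genotypes", {
  pairs <- expand.grid(a = c("A", "C", "G", "T"), b = c("A", "C", "G", "T"),
                       call = c("AA", "AB", "BB"),
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$a != pairs$b, ]
  plus <- ab_to_bases(pairs$call, pairs$a, pairs$b, "+")
  # Flipping strand twice: complement the allele pair and flip again.
  comp <- function(x) chartr("ACGT", "TGCA", x)
  flipped_twice <- ab_to_bases(pairs$call, comp(comp(pairs$a)),
                               comp(comp(pairs$b)), "+")
  expect_equal(flipped_twice, plus)
  # And minus-strand output equals complemented plus-strand output (re-sorted).
  minus <- ab_to_bases(pairs$call, pairs$a, pairs$b, "-")
  resort <- function(g) {
    vapply(strsplit(g, ""), function(x) paste(sort(x), collapse = ""), "")
  }
  expect_equal(minus, resort(comp(plus)))
})

test_that("translate_calls joins by rsID and passes no-calls through", {
  man <- mk_manifest(c("rs1", "rs2"), allele_a = c("A", "C"),
                     allele_b = c("G", "T"), ref_strand = c("+", "-"))
  calls <- tibble::tibble(snp_id = c("rs1", "rs2", "rs2", "rsZ"),
                          call = c("AB", "BB", "NC", "AA"))
  out <- translate_calls(calls, man)
  expect_equal(out$genotype, c("AG", "AA", "NC", NA))
})

test_that("the bundled example manifest loads and filters as documented", {
  path <- system.file("extdata", "example_manifest.csv",
                      package = "butterflycall")
  man <- load_manifest(path)
  expect_equal(nrow(man), 20)
  res <- filter_probes(man)
  expect_equal(res$report$snps_removed[-1], c(1, 1, 3, 1, 1, 2, 0))
  expect_equal(nrow(res$manifest), 11)
})
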