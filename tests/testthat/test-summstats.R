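test_that("well-formed files parse row-for-row", {
  f <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(SNP = c("rs1", "rs2", "rs3"), CHR = "1",
                   POS = c(100L, 200L, 300L), EA = "A", OA = "G",
                   EAF = 0.3, BETA = c(0.1, -0.2, 0.05), SE = 0.02,
                   P = c(1e-6, 1e-8, 1e-3), N = 8000)
  write_ss_file(df, f)
  ds <- quiet(read_summary_stats(f, trait_type = "continuous"))
  expect_s3_class(ds, "trait_dataset")
  expect_equal(nrow(ds), 3L)
  expect_equal(ds$variant_id, df$SNP)
  expect_equal(ds$beta, df$BETA)
})

test_that("rows with missing required fields are dropped and counted", {
  f <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(SNP = c("rs1", "rs2", "rs3"), CHR = "1",
                   POS = c(100L, 200L, 300L), EA = "A", OA = "G",
                   EAF = 0.3, BETA = c(0.1, -0.2, 0.05),
                   SE = c("0.02", "", "0.02"),
                   P = c(1e-6, 1e-8, 1e-3), N = 8000)
  write_ss_file(df, f)
  ds <- quiet(read_summary_stats(f, trait_type = "continuous"))
  expect_equal(nrow(ds), 2L)
  expect_equal(attr(ds, "n_dropped"), 1L)
  expect_false("rs2" %in% ds$variant_id)
})

test_that("duplicate variant ids keep the smallest p-value, first on ties", {
  f <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(SNP = c("rs1", "rs1", "rs2", "rs2"), CHR = "1",
                   POS = c(100L, 100L, 200L, 200L), EA = c("A", "A", "C", "C"),
                   OA = c("G", "G", "T", "T"), EAF = 0.3,
                   BETA = c(0.10, 0.20, 0.30, 0.40), SE = 0.02,
                   P = c(1e-3, 1e-6, 1e-4, 1e-4), N = 8000)
  write_ss_file(df, f)
  ds <- quiet(read_summary_stats(f, trait_type = "continuous"))
  expect_equal(nrow(ds), 2L)
  expect_equal(attr(ds, "n_dedup"), 2L)
  expect_equal(ds$pval[ds$variant_id == "rs1"], 1e-6)   # smallest p wins
  expect_equal(ds$beta[ds$variant_id == "rs2"], 0.30)   # tie -> first kept
})

test_that("multi-allelic and indel rows are rejected on read", {
  f <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(SNP = c("rs1", "rs2", "rs3"), CHR = "1",
                   POS = c(100L, 200L, 300L),
                   EA = c("A", "AT", "C"), OA = c("G", "G", "C"),
                   EAF = 0.3, BETA = 0.1, SE = 0.02, P = 1e-6, N = 8000)
  write_ss_file(df, f)
  ds <- quiet(read_summary_stats(f, trait_type = "continuous"))
  expect_equal(ds$variant_id, "rs1")  # indel rs2 and same-allele rs3 rejected
})

test_that("write/read round-trips all fields bit-identically", {
  sim <- simulate_summary_stats(sim_config(n_snps = 12, seed = 11))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_summary_stats(sim$exposure, f)
  back <- quiet(read_summary_stats(f, trait_type = "continuous",
                                   trait_name = "exposure"))
  for (col in c("variant_id", "chrom", "pos", "effect_allele", "other_allele",
                "eaf", "beta", "se", "pval", "n")) {
    expect_identical(back[[col]], sim$exposure[[col]])
  }
})

test_that("comma-delimited and gzipped input are accepted", {
  f <- withr::local_tempfile(fileext = ".csv.gz")
  df <- data.frame(SNP = c("rs1", "rs2"), CHR = "2", POS = c(5L, 10L),
                   EA = "T", OA = "C", EAF = 0.2, BETA = 0.15, SE = 0.03,
                   P = 1e-7, N = 5000)
  con <- gzfile(f, "wt")
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  close(con)
  ds <- quiet(read_summary_stats(f, trait_type = "continuous"))
  expect_equal(nrow(ds), 2L)
})

test_that("custom column maps override the defaults field-by-field", {
  f <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(rsid = "rs9", CHR = "3", POS = 77L, EA = "G", OA = "A",
                   EAF = 0.4, effect = -0.3, stderr = 0.05, P = 1e-9,
                   N = 9000)
  write_ss_file(df, f)
  ds <- quiet(read_summary_stats(
    f, column_map = c(variant_id = "rsid", beta = "effect", se = "stderr"),
    trait_type = "binary"))
  expect_equal(ds$beta, -0.3)
  expect_error(read_summary_stats(f, column_map = c(bogus = "x")), "unknown")
})

test_that("unreadable and empty inputs fail loudly", {
  expect_error(read_summary_stats(tempfile(), trait_type = "continuous"),
               "cannot read")
  f <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(SNP = "rs1", CHR = "1", POS = 1L, EA = "A", OA = "G",
                   EAF = 0.3, BETA = NA, SE = NA, P = 0.5, N = 100)
  write_ss_file(df, f)
  expect_error(quiet(read_summary_stats(f, trait_type = "continuous")),
               "no valid rows")
})

test_that("report tables follow the journal formatting conventions", {
  rows <- data.frame(exposure = c("PDGF-BB", "null"), outcome = "VTE",
                     method = "ivw", n_snp = 12L,
                     beta = c(0.103, 0), se = c(0.026, 0.02),
                     pval = c(9.29e-5, 0.5),
                     or = exp(c(0.103, 0)),
                     ci_low = exp(c(0.103, 0) - 1.96 * c(0.026, 0.02)),
                     ci_high = exp(c(0.103, 0) + 1.96 * c(0.026, 0.02)),
                     stringsAsFactors = FALSE)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_report(rows, f)
  lines <- readLines(f)
  expect_length(lines, 3L)
  fields <- strsplit(lines[2], "\t")[[1]]
  expect_equal(fields[8], "1.108")      # exp(0.103) printed to 3 decimals
  expect_equal(fields[7], "9.29E-05")   # scientific p with 2 decimals
  expect_equal(strsplit(lines[3], "\t")[[1]][8], "1.000")  # exp(0) = 1
  expect_error(write_report(rows[0, ], f), "non-empty")
})

test_that("dataset validation enforces the record invariants", {
  base <- data.frame(variant_id = "rs1", chrom = "1", pos = 1L,
                     effect_allele = "A", other_allele = "G", eaf = 0.3,
                     beta = 0.1, se = 0.02, pval = 1e-6, n = 100)
  expect_s3_class(trait_dataset(base, "t", "continuous"), "trait_dataset")
  bad <- base; bad$se <- -1
  expect_error(trait_dataset(bad, "t"), "se")
  bad <- base; bad$other_allele <- "A"
  expect_error(trait_dataset(bad, "t"), "differ")
  bad <- base; bad$pval <- 0
  expect_error(trait_dataset(bad, "t"), "pval")
  # soft consistency check: p far from the beta/se implied value only warns
  odd <- base; odd$pval <- 0.9
  expect_warning(trait_dataset(odd, "t"), "inconsistent")
})
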