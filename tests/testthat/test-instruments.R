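test_that("p-value screening is strictly below the threshold", {
  ds <- make_ds(3, pval = c(1e-6, 2e-5, 1e-5))
  kept <- quiet(select_by_pvalue(ds, 1e-5))
  expect_equal(kept$variant_id, "rs001")  # 2e-5 above, exactly 1e-5 excluded
  expect_error(select_by_pvalue(ds, 0), "threshold")
})

test_that("greedy clumping keeps the best of a correlated in-window pair", {
  ds <- make_ds(2, pval = c(1e-6, 1e-8), pos = c(1000L, 6000L))
  ld <- data.frame(variant_a = "rs001", variant_b = "rs002", r2 = 0.5)
  kept <- greedy_clump(ds, ld, r2_max = 0.001, window_kb = 10000)
  expect_equal(kept$variant_id, "rs002")  # the p=1e-8 variant wins

  ld$r2 <- 0.0005
  expect_equal(nrow(greedy_clump(ds, ld, r2_max = 0.001)), 2L)

  # different chromosomes: window does not apply, LD undefined is fine
  ds2 <- make_ds(2, pval = c(1e-6, 1e-8), chrom = c("1", "2"))
  expect_equal(nrow(greedy_clump(ds2, NULL, missing_ld = "correlated")), 2L)
})

test_that("missing in-window LD follows the configured policy", {
  ds <- make_ds(2, pval = c(1e-8, 1e-6), pos = c(1000L, 6000L))
  expect_equal(nrow(quiet(greedy_clump(ds, NULL, missing_ld = "correlated"))), 1L)
  expect_equal(nrow(greedy_clump(ds, NULL, missing_ld = "independent")), 2L)
})

test_that("clumping matches a brute-force replay and leaves no violating pair", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(4:9, 1)
    df <- data.frame(
      variant_id = sprintf("v%02d", 1:n),
      chrom = as.character(sample(1:2, n, replace = TRUE)),
      pos = sample.int(3e7, n),
      effect_allele = "A", other_allele = "G", eaf = 0.3,
      beta = 0.1, se = 0.02,
      pval = stats::runif(n, 1e-10, 1e-5), n = 8000,
      stringsAsFactors = FALSE)
    ds <- trait_dataset(df, "t", "continuous", check_pval = FALSE)
    pairs <- t(utils::combn(n, 2))
    ld <- data.frame(variant_a = df$variant_id[pairs[, 1]],
                     variant_b = df$variant_id[pairs[, 2]],
                     r2 = stats::runif(nrow(pairs)))
    kept <- greedy_clump(ds, ld, r2_max = 0.1, window_kb = 10000)
    expect_identical(sort(kept$variant_id),
                     clump_oracle(df, ld, 0.1, 10000))

    # invariant: no same-chromosome in-window pair with r2 above threshold
    if (nrow(kept) > 1) {
      kp <- t(utils::combn(nrow(kept), 2))
      for (r in seq_len(nrow(kp))) {
        i <- kp[r, 1]; j <- kp[r, 2]
        if (kept$chrom[i] == kept$chrom[j] &&
            abs(kept$pos[i] - kept$pos[j]) <= 1e7) {
          hit <- (ld$variant_a == kept$variant_id[i] & ld$variant_b == kept$variant_id[j]) |
            (ld$variant_b == kept$variant_id[i] & ld$variant_a == kept$variant_id[j])
          expect_lte(ld$r2[hit], 0.1)
        }
      }
    }

    # row-order invariance
    shuf <- trait_dataset(df[sample.int(n), ], "t", "continuous",
                          check_pval = FALSE)
    kept2 <- greedy_clump(shuf, ld, r2_max = 0.1, window_kb = 10000)
    expect_identical(kept2$variant_id, kept$variant_id)
  }
})

test_that("palindromic variants are dropped only at intermediate frequency", {
  ds <- make_ds(3, ea = c("A", "A", "A"), oa = c("T", "T", "G"),
                eaf = c(0.50, 0.10, 0.50))
  kept <- quiet(drop_palindromes(ds))
  expect_identical(kept$variant_id, c("rs002", "rs003"))
})

test_that("confounder exclusion is a plain set difference", {
  ds <- make_ds(22)
  expect_identical(exclude_listed_snps(ds, character(0)), ds)
  expect_equal(nrow(quiet(exclude_listed_snps(ds, c("rs001", "rs002")))), 20L)
  expect_warning(suppressMessages(exclude_listed_snps(ds, ds$variant_id)),
                 "all variants")
})

test_that("explained variance and F follow the standardized-trait formulas", {
  ds <- make_ds(1, eaf = 0.3, beta = 0.1, nn = 8299)
  d <- compute_instrument_strength(ds)
  expect_equal(d$r2, 2 * 0.3 * 0.7 * 0.01)     # 0.0042
  expect_equal(d$f_stat, (8299 - 2) * d$r2 / (1 - d$r2), tolerance = 1e-12)
  expect_equal(d$f_stat, 34.99, tolerance = 1e-3)

  null <- make_ds(1, beta = 0)
  expect_equal(compute_instrument_strength(null)$f_stat, 0)

  big <- make_ds(1, beta = 10, eaf = 0.5)
  expect_error(compute_instrument_strength(big), "R\\^2")
})

test_that("F is monotone in |beta| and in N at fixed MAF", {
  f_of <- function(beta, nn) {
    compute_instrument_strength(make_ds(1, beta = beta, nn = nn))$f_stat
  }
  betas <- c(0.02, 0.05, 0.1, 0.2)
  expect_true(all(diff(vapply(betas, f_of, numeric(1), nn = 8000)) > 0))
  ns <- c(1000, 5000, 20000)
  expect_true(all(diff(vapply(ns, function(nn) f_of(0.1, nn), numeric(1))) > 0))
})

test_that("generator defaults give instrument strength inside the observed envelope", {
  sim <- simulate_summary_stats(sim_config(n_snps = 200, n_mediator_snps = 0,
                                           seed = 42))
  d <- compute_instrument_strength(sim$exposure)
  expect_gte(mean(d$f_stat >= 19.5 & d$f_stat <= 5308.35), 0.95)
  # set-level F is reported on panels whose total explained variance is < 1
  small <- simulate_summary_stats(sim_config(n_snps = 15, seed = 42))
  expect_gt(attr(compute_instrument_strength(small$exposure), "set_f"), 0)
})

test_that("harmonization aligns, flips, and drops as the alleles dictate", {
  exp <- make_ds(3, ea = c("A", "A", "A"), oa = c("G", "G", "G"),
                 beta = c(0.1, 0.1, 0.1))
  out <- make_ds(3, ea = c("G", "A", "A"), oa = c("A", "C", "G"),
                 beta = c(-0.05, 0.02, 0.05))
  h <- quiet(harmonize(exp, out))
  expect_equal(h$alignment_flag[h$variant_id == "rs001"], "flipped")
  expect_equal(h$capital_gamma[h$variant_id == "rs001"], 0.05)
  expect_false("rs002" %in% h$variant_id)  # A/C vs A/G: unresolvable
  expect_equal(h$alignment_flag[h$variant_id == "rs003"], "kept-as-is")
  expect_equal(h$capital_gamma[h$variant_id == "rs003"], 0.05)
  expect_equal(attr(h, "dropped")$alignment_flag, "dropped-missing")
})

test_that("harmonization drops strand-unresolvable palindromes", {
  exp <- make_ds(2, ea = c("A", "C"), oa = c("T", "G"), eaf = c(0.5, 0.1))
  out <- make_ds(2, ea = c("A", "C"), oa = c("T", "G"), eaf = c(0.5, 0.1),
                 beta = c(0.2, 0.2))
  h <- quiet(harmonize(exp, out))
  expect_false("rs001" %in% h$variant_id)   # eaf 0.5: ambiguous
  expect_true("rs002" %in% h$variant_id)    # eaf 0.1: frequency resolves it
})

test_that("harmonization is idempotent", {
  sim <- simulate_summary_stats(sim_config(n_snps = 15, seed = 3))
  h1 <- harmonize(sim$exposure, sim$outcome)
  # re-express the aligned set as two datasets and harmonize again
  as_ds <- function(beta, se, pval) {
    trait_dataset(data.frame(
      variant_id = h1$variant_id, chrom = h1$chrom, pos = h1$pos,
      effect_allele = h1$effect_allele, other_allele = h1$other_allele,
      eaf = h1$eaf, beta = beta, se = se, pval = pval, n = 1000),
      "t", "continuous", check_pval = FALSE)
  }
  h2 <- harmonize(as_ds(h1$gamma, h1$se_gamma, h1$pval_gamma),
                  as_ds(h1$capital_gamma, h1$se_capital_gamma, h1$pval_outcome))
  expect_true(all(h2$alignment_flag == "kept-as-is"))
  expect_equal(h2$gamma, h1$gamma)
  expect_equal(h2$capital_gamma, h1$capital_gamma)
})

test_that("harmonization fails informatively on an empty intersection", {
  a <- make_ds(2)
  b <- make_ds(2)
  b$variant_id <- c("rsX", "rsY")
  b <- trait_dataset(as.data.frame(b), "other", "binary", check_pval = FALSE)
  expect_error(harmonize(a, b), "no shared variants")
})
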