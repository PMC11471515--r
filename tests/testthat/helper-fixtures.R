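# Shared fixtures and independent oracles for the test suite.

# Harmonized instrument set built directly from aligned effect vectors.
make_h <- function(gamma, se_gamma, capital_gamma, se_capital_gamma,
                   delta = NULL, se_delta = NULL) {
  mrmediate:::new_harmonized_set(gamma, se_gamma, capital_gamma,
                                 se_capital_gamma, delta, se_delta)
}

# Build a small trait_dataset from a compact spec.
make_ds <- function(n = 5, name = "trait", type = "continuous",
                    pval = NULL, chrom = NULL, pos = NULL,
                    ea = NULL, oa = NULL, eaf = NULL, beta = NULL,
                    se = NULL, nn = 8000) {
  if (is.null(pval)) pval <- rep(1e-6, n)
  if (is.null(chrom)) chrom <- rep("1", n)
  if (is.null(pos)) pos <- seq_len(n) * 1000L
  if (is.null(ea)) ea <- rep("A", n)
  if (is.null(oa)) oa <- rep("G", n)
  if (is.null(eaf)) eaf <- rep(0.3, n)
  if (is.null(beta)) beta <- rep(0.1, n)
  if (is.null(se)) se <- rep(0.02, n)
  trait_dataset(data.frame(
    variant_id = sprintf("rs%03d", seq_len(n)), chrom = chrom, pos = pos,
    effect_allele = ea, other_allele = oa, eaf = eaf,
    beta = beta, se = se, pval = pval, n = nn,
    stringsAsFactors = FALSE),
    trait_name = name, trait_type = type, check_pval = FALSE)
}

write_ss_file <- function(df, path, sep = "\t") {
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  path
}

# Independent brute-force BH step-up: literal definition, no p.adjust.
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  adj <- ps * m / seq_len(m)
  # step-up: running minimum from the largest rank down
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[ord] <- adj
  out
}

# Independent weighted-median: dense numeric search over the weighted
# empirical CDF interpolation (no shared code with the implementation).
weighted_median_oracle <- function(values, weights) {
  ord <- order(values)
  b <- values[ord]
  w <- weights[ord] / sum(weights)
  pj <- cumsum(w) - w / 2
  stats::approx(pj, b, xout = 0.5, rule = 2)$y
}

# Brute-force clumping oracle: replays the greedy rule literally on a pair
# matrix, used to cross-check greedy_clump on small instances.
clump_oracle <- function(df, ld_pairs, r2_max, window_kb,
                         missing_policy = "independent") {
  r2_of <- function(a, b) {
    hit <- (ld_pairs$variant_a == a & ld_pairs$variant_b == b) |
      (ld_pairs$variant_a == b & ld_pairs$variant_b == a)
    if (any(hit)) ld_pairs$r2[which(hit)[1]] else
      if (missing_policy == "correlated") 1 else 0
  }
  ord <- order(df$pval, df$chrom, df$pos)
  df <- df[ord, ]
  kept <- character(0)
  for (i in seq_len(nrow(df))) {
    ok <- TRUE
    for (k in kept) {
      krow <- df[df$variant_id == k, ]
      if (krow$chrom == df$chrom[i] &&
          abs(krow$pos - df$pos[i]) <= window_kb * 1000 &&
          r2_of(k, df$variant_id[i]) > r2_max) {
        ok <- FALSE
        break
      }
    }
    if (ok) kept <- c(kept, df$variant_id[i])
  }
  sort(kept)
}

quiet <- function(expr) suppressMessages(suppressWarnings(expr))
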