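#' Configuration for the summary-statistic simulator
#'
#' Defines an exposure -> mediator -> outcome structural model and the GWAS
#' designs that measure it. Defaults emulate the study conditions this
#' package is calibrated against: a continuous metabolite exposure measured
#' in ~8,300 individuals, a continuous cytokine mediator in ~8,293, and a
#' large case-control thrombosis-like endpoint (21,021 cases / 391,160
#' controls) on the log-odds scale. The default structural coefficients are
#' the glycocholate - PDGF-BB - VTE pathway estimates (exposure-to-mediator
#' -0.097, adjusted mediator-to-outcome 0.089, direct exposure effect
#' -0.0504, so the total effect is about -0.059).
#'
#' True instrument effects are drawn on the standardized scale from a
#' two-sided normal with scale `effect_sd`, restricted so each SNP's
#' F-statistic falls in `f_range`: this emulates instruments that have
#' already passed a genome-wide significance screen, which is what
#' published instrument sets are (observed F-statistics for such panels
#' span roughly 20 to 5,300).
#'
#' @param n_snps number of exposure instruments (default 30).
#' @param n_mediator_snps mediator-specific instruments with zero exposure
#'   effect (default `n_snps`); these make the multivariable design full
#'   rank.
#' @param n_exposure,n_mediator continuous-trait GWAS sample sizes.
#' @param n_outcome_cases,n_outcome_controls case-control outcome sizes.
#' @param theta_em true exposure-to-mediator effect (tau).
#' @param theta_mo true mediator-to-outcome effect.
#' @param theta_direct direct exposure-to-outcome effect; total causal
#'   effect is `theta_direct + theta_em * theta_mo`.
#' @param pleiotropy_mode `"none"`, `"balanced"` (zero-mean direct SNP
#'   effects on the outcome) or `"directional"` (positive-mean).
#' @param pleiotropy_sd,pleiotropy_mean pleiotropic effect scale and (for
#'   directional mode) mean.
#' @param maf_range uniform range for minor-allele frequencies, within
#'   (0, 0.5].
#' @param effect_sd scale of true instrument effects (standardized trait).
#' @param f_range admissible per-SNP F-statistic range for generated
#'   instruments.
#' @param palindrome_fraction fraction of variants assigned A/T or C/G
#'   allele pairs (default 0).
#' @param noiseless if `TRUE`, observed effects equal the structural truth
#'   (no sampling noise); useful for exact-identity tests.
#' @param seed integer RNG seed (mandatory for reproducibility).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_snps = 30L, n_mediator_snps = n_snps,
                       n_exposure = 8299L, n_mediator = 8293L,
                       n_outcome_cases = 21021L, n_outcome_controls = 391160L,
                       theta_em = -0.097, theta_mo = 0.089,
                       theta_direct = -0.0504,
                       pleiotropy_mode = c("none", "balanced", "directional"),
                       pleiotropy_sd = 0.05, pleiotropy_mean = 0.05,
                       maf_range = c(0.1, 0.45), effect_sd = 0.25,
                       f_range = c(30, 5000), palindrome_fraction = 0,
                       noiseless = FALSE, seed = 1L) {
  pleiotropy_mode <- match.arg(pleiotropy_mode)
  stopifnot(n_snps >= 1, n_mediator_snps >= 0,
            n_exposure > 0, n_mediator > 0,
            n_outcome_cases > 0, n_outcome_controls > 0,
            length(maf_range) == 2L, maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2],
            length(f_range) == 2L, f_range[1] > 0, f_range[1] < f_range[2],
            palindrome_fraction >= 0, palindrome_fraction <= 1)
  if (effect_sd <= 0) {
    stop("sim_config: effect_sd must be positive (instruments must satisfy the relevance assumption)")
  }
  structure(list(n_snps = as.integer(n_snps),
                 n_mediator_snps = as.integer(n_mediator_snps),
                 n_exposure = n_exposure, n_mediator = n_mediator,
                 n_outcome_cases = n_outcome_cases,
                 n_outcome_controls = n_outcome_controls,
                 theta_em = theta_em, theta_mo = theta_mo,
                 theta_direct = theta_direct,
                 theta_total = theta_direct + theta_em * theta_mo,
                 pleiotropy_mode = pleiotropy_mode,
                 pleiotropy_sd = pleiotropy_sd,
                 pleiotropy_mean = pleiotropy_mean,
                 maf_range = maf_range, effect_sd = effect_sd,
                 f_range = f_range,
                 palindrome_fraction = palindrome_fraction,
                 noiseless = noiseless, seed = as.integer(seed)),
            class = "sim_config")
}

# |effect| from a half-normal(scale) truncated to [a, b], via inverse CDF;
# vectorized over a, b, u.
rtrunc_halfnorm <- function(u, scale, a, b) {
  Fa <- 2 * stats::pnorm(a / scale) - 1
  Fb <- 2 * stats::pnorm(b / scale) - 1
  scale * stats::qnorm((Fa + u * (Fb - Fa) + 1) / 2)
}

# admissible |beta| band implied by an F-statistic range at given maf and N
strength_band <- function(maf, n, f_range) {
  r2 <- f_range / (n - 2 + f_range)   # invert F = (N-2) R2/(1-R2)
  denom <- 2 * maf * (1 - maf)
  list(lo = sqrt(r2[1] / denom), hi = sqrt(pmin(r2[2] / denom, 0.999 / denom)))
}

#' Simulate multi-trait GWAS summary statistics under a known structural model
#'
#' Generates per-SNP summary statistics for an exposure, a mediator and a
#' binary outcome under the structural model
#' `delta_j = theta_em * gamma_j` (exposure instruments),
#' `Gamma_j = theta_direct * gamma_j + theta_mo * delta_j + alpha_j`,
#' where `alpha_j` is the per-SNP pleiotropic effect (zero, balanced, or
#' directional per the config). Mediator-specific instruments have
#' `gamma_j = 0` and their own `delta_j`.
#'
#' Standard errors follow the standardized-trait approximation
#' `se = 1 / sqrt(2 * MAF * (1 - MAF) * N)`, with the binary outcome's
#' effective sample size `N_eff = 4 / (1/cases + 1/controls)`. Observed
#' effects are the structural truth plus `Normal(0, se^2)` noise unless
#' `noiseless = TRUE`; p-values are two-sided normal. Variants are placed
#' 20 Mb apart along chromosomes 1-22 (no LD is simulated, so default
#' clumping retains all of them), and allele pairs are drawn from the
#' non-palindromic combinations except for a configurable palindromic
#' fraction. Everything is reproducible from `config$seed`.
#'
#' @param config a [sim_config].
#' @return list of class `mr_simulation`: `exposure`, `mediator`, `outcome`
#'   ([trait_dataset]s with consistent variants and alleles), `truth` (the
#'   echoed config) and `truth_effects` (per-SNP true `gamma`, `delta`,
#'   `capital_gamma`, `alpha`).
#' @export
simulate_summary_stats <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  rng <- local_rng(config$seed)
  on.exit(rng())

  nE <- config$n_snps
  nM <- config$n_mediator_snps
  n <- nE + nM
  variant_id <- sprintf("rs%06d", seq_len(n))
  chrom <- as.character(rep_len(1:22, n))
  pos <- integer(n)
  for (c22 in unique(chrom)) {
    idx <- which(chrom == c22)
    pos[idx] <- 2e7L * seq_along(idx)   # 20 Mb apart: outside any clump window
  }

  maf <- stats::runif(n, config$maf_range[1], config$maf_range[2])
  eaf <- ifelse(stats::runif(n) < 0.5, maf, 1 - maf)

  nonpal <- list(c("A", "C"), c("A", "G"), c("C", "A"), c("C", "T"),
                 c("G", "A"), c("G", "T"), c("T", "C"), c("T", "G"))
  pal <- list(c("A", "T"), c("T", "A"), c("C", "G"), c("G", "C"))
  is_pal <- stats::runif(n) < config$palindrome_fraction
  pair_idx <- ifelse(is_pal, sample.int(4L, n, replace = TRUE),
                     sample.int(8L, n, replace = TRUE))
  ea <- oa <- character(n)
  for (i in seq_len(n)) {
    p <- if (is_pal[i]) pal[[pair_idx[i]]] else nonpal[[pair_idx[i]]]
    ea[i] <- p[1]; oa[i] <- p[2]
  }

  # true instrument effects: strength-truncated two-sided normal
  gamma_true <- numeric(n)
  delta_true <- numeric(n)
  exp_idx <- seq_len(nE)
  band_e <- strength_band(maf[exp_idx], config$n_exposure, config$f_range)
  u <- stats::runif(nE)
  sgn <- sample(c(-1, 1), nE, replace = TRUE)
  gamma_true[exp_idx] <- sgn * rtrunc_halfnorm(u, config$effect_sd,
                                               band_e$lo, band_e$hi)
  delta_true[exp_idx] <- config$theta_em * gamma_true[exp_idx]
  if (nM > 0) {
    med_idx <- nE + seq_len(nM)
    band_m <- strength_band(maf[med_idx], config$n_mediator, config$f_range)
    u <- stats::runif(nM)
    sgn <- sample(c(-1, 1), nM, replace = TRUE)
    delta_true[med_idx] <- sgn * rtrunc_halfnorm(u, config$effect_sd,
                                                 band_m$lo, band_m$hi)
  }

  alpha <- switch(config$pleiotropy_mode,
                  none = numeric(n),
                  balanced = stats::rnorm(n, 0, config$pleiotropy_sd),
                  directional = stats::rnorm(n, config$pleiotropy_mean,
                                             config$pleiotropy_sd))
  capital_gamma_true <- config$theta_direct * gamma_true +
    config$theta_mo * delta_true + alpha

  n_eff_outcome <- 4 / (1 / config$n_outcome_cases + 1 / config$n_outcome_controls)
  se_of <- function(n_eff) 1 / sqrt(2 * maf * (1 - maf) * n_eff)
  se_e <- se_of(config$n_exposure)
  se_m <- se_of(config$n_mediator)
  se_o <- se_of(n_eff_outcome)

  observe <- function(truth, se) {
    if (config$noiseless) truth else truth + stats::rnorm(n, 0, se)
  }
  beta_e <- observe(gamma_true, se_e)
  beta_m <- observe(delta_true, se_m)
  beta_o <- observe(capital_gamma_true, se_o)

  mk <- function(beta, se, nn, name, type) {
    trait_dataset(data.frame(
      variant_id = variant_id, chrom = chrom, pos = pos,
      effect_allele = ea, other_allele = oa, eaf = eaf,
      beta = beta, se = se,
      pval = pmax(2 * stats::pnorm(-abs(beta / se)), 1e-300),
      n = nn, stringsAsFactors = FALSE),
      trait_name = name, trait_type = type, check_pval = FALSE)
  }

  structure(list(
    exposure = mk(beta_e, se_e, config$n_exposure, "exposure", "continuous"),
    mediator = mk(beta_m, se_m, config$n_mediator, "mediator", "continuous"),
    outcome = mk(beta_o, se_o,
                 config$n_outcome_cases + config$n_outcome_controls,
                 "outcome", "binary"),
    truth = config,
    truth_effects = data.frame(variant_id = variant_id, gamma = gamma_true,
                               delta = delta_true,
                               capital_gamma = capital_gamma_true,
                               alpha = alpha, stringsAsFactors = FALSE)),
    class = "mr_simulation")
}

#' @export
print.mr_simulation <- function(x, ...) {
  cfg <- x$truth
  cat(sprintf("<mr_simulation> %d exposure + %d mediator instruments (seed %d)\n",
              cfg$n_snps, cfg$n_mediator_snps, cfg$seed))
  cat(sprintf("  structural model: EM %.3f, MO %.3f, direct %.4f (total %.4f); pleiotropy: %s\n",
              cfg$theta_em, cfg$theta_mo, cfg$theta_direct, cfg$theta_total,
              cfg$pleiotropy_mode))
  invisible(x)
}

#' Shift one variant's effect to create a pleiotropic outlier
#'
#' Fixture generator for outlier-detection power experiments: shifts the
#' named variant's `beta` by `shift_in_se` times its standard error,
#' leaving everything else (including the p-value column) untouched.
#'
#' @param dataset a [trait_dataset].
#' @param variant_id variant to perturb (must exist).
#' @param shift_in_se shift expressed in SE units (may be negative).
#' @return the modified [trait_dataset].
#' @export
inject_outlier <- function(dataset, variant_id, shift_in_se) {
  stopifnot(inherits(dataset, "trait_dataset"))
  i <- match(variant_id, dataset$variant_id)
  if (is.na(i)) stop("inject_outlier: unknown variant '", variant_id, "'")
  dataset$beta[i] <- dataset$beta[i] + shift_in_se * dataset$se[i]
  dataset
}
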