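#' Cochran's Q heterogeneity test
#'
#' Weighted sum of squared deviations of the per-SNP Wald ratios from the
#' fitted model, `Q = sum(w_j * (ratio_j - fit_j)^2)` with IVW weights
#' `w_j = gamma_j^2 / se_Gamma_j^2`. For the IVW variant `fit_j` is the
#' pooled estimate (df = J - 1); for the Egger variant it is the fitted
#' value of the intercept-included regression (df = J - 2). The p-value is
#' the upper chi-square tail; p > 0.05 is conventionally read as no
#' significant heterogeneity. The IVW-variant Q is identical to the
#' statistic driving [mr_ivw]'s random-effects fallback.
#'
#' @param h a `harmonized_set`.
#' @param variant `"ivw"` or `"egger"`.
#' @return list of class `heterogeneity_result`: `q_stat`, `df`, `pval`,
#'   `variant`, `n_snp`.
#' @export
cochran_q <- function(h, variant = c("ivw", "egger")) {
  variant <- match.arg(variant)
  stopifnot(inherits(h, "harmonized_set"))
  h <- h[h$gamma != 0, , drop = FALSE]
  J <- nrow(h)
  df <- if (variant == "ivw") J - 1L else J - 2L
  if (df < 1L) stop("cochran_q: insufficient instruments for df >= 1")
  w <- h$gamma^2 / h$se_capital_gamma^2
  ratio <- h$capital_gamma / h$gamma
  if (variant == "ivw") {
    fit <- sum(w * ratio) / sum(w)
    q_stat <- sum(w * (ratio - fit)^2)
  } else {
    sgn <- sign(h$gamma)
    g <- h$gamma * sgn
    G <- h$capital_gamma * sgn
    reg <- stats::lm(G ~ g, weights = 1 / h$se_capital_gamma^2)
    q_stat <- sum(stats::residuals(reg)^2 / h$se_capital_gamma^2)
  }
  structure(list(q_stat = q_stat, df = df,
                 pval = stats::pchisq(q_stat, df, lower.tail = FALSE),
                 variant = variant, n_snp = J),
            class = "heterogeneity_result")
}

#' @export
print.heterogeneity_result <- function(x, ...) {
  cat(sprintf("Cochran's Q (%s): Q = %.4f on %d df, p = %.4g\n",
              x$variant, x$q_stat, x$df, x$pval))
  invisible(x)
}

# leave-one-out IVW slopes for every SNP, vectorized:
# beta_{-j} = (S1 - w_j r_j) / (S0 - w_j)
loo_slopes <- function(ratio, weight) {
  s1 <- sum(weight * ratio)
  s0 <- sum(weight)
  (s1 - weight * ratio) / (s0 - weight)
}

#' MR-PRESSO: pleiotropy residual sum and outlier test
#'
#' Simulation-based detection of horizontally pleiotropic outlier SNPs in
#' the IVW regression, with three components:
#' \itemize{
#'   \item \strong{Global test}: for each SNP the leave-one-out IVW slope
#'     `beta_{-j}` gives a residual `r_j = Gamma_j - beta_{-j} * gamma_j`;
#'     the observed weighted residual sum of squares
#'     `RSS = sum(r_j^2 / se_Gamma_j^2)` is compared against `n_sim`
#'     replicates in which `Gamma*_j ~ N(beta_{-j} * gamma_j, se_Gamma_j^2)`
#'     and the whole statistic is recomputed. The Monte-Carlo p-value is
#'     `(1 + #\{RSS* >= RSS\}) / (n_sim + 1)`, never exactly zero.
#'   \item \strong{Outlier test}: each SNP's observed weighted squared
#'     residual is compared against its own simulated null; per-SNP p-values
#'     are Bonferroni-adjusted by the number of SNPs, and SNPs below
#'     `outlier_threshold` are flagged — only when the global test itself is
#'     below `outlier_threshold`.
#'   \item \strong{Distortion test}: when outliers are flagged, the
#'     outlier-corrected IVW estimate is compared with estimates after
#'     removing random same-size SNP subsets; the two-sided empirical
#'     p-value measures whether the outliers distort the estimate more than
#'     chance removals would.
#' }
#'
#' @param h a `harmonized_set` with at least 4 instruments.
#' @param n_sim simulation replicates (default 1000, minimum 100).
#' @param outlier_threshold significance level for the global and
#'   (adjusted) per-SNP tests (default 0.05).
#' @param seed integer RNG seed.
#' @return list of class `mr_presso_result`: `rss_obs`, `global_p`,
#'   `n_sim`, `outlier_indices`, `outlier_ids`, `outlier_pvals` (Bonferroni
#'   adjusted), `distortion_p`, `corrected_estimate` (IVW sans outliers, or
#'   `NULL`), `seed`.
#' @export
mr_presso <- function(h, n_sim = 1000, outlier_threshold = 0.05, seed) {
  stopifnot(inherits(h, "harmonized_set"))
  h <- h[h$gamma != 0, , drop = FALSE]
  J <- nrow(h)
  if (J < 4L) stop("mr_presso: at least 4 instruments required")
  if (n_sim < 100L) stop("mr_presso: n_sim must be at least 100")
  if (n_sim < 1 / outlier_threshold) {
    warning("mr_presso: n_sim too small for the requested outlier threshold resolution")
  }
  # order-invariance: work in a canonical variant order, map indices back
  ord <- order(h$variant_id)
  hs <- h[ord, , drop = FALSE]

  g <- hs$gamma
  G <- hs$capital_gamma
  seG <- hs$se_capital_gamma
  w <- g^2 / seG^2
  ratio <- G / g
  b_loo <- loo_slopes(ratio, w)
  resid_obs <- G - b_loo * g
  rss_j_obs <- resid_obs^2 / seG^2
  rss_obs <- sum(rss_j_obs)

  rng <- local_rng(seed)
  on.exit(rng())
  # simulate Gamma* under the per-SNP leave-one-out null and recompute the
  # full statistic each replicate (matrix form: n_sim x J)
  Gstar <- matrix(stats::rnorm(n_sim * J, mean = rep(b_loo * g, each = n_sim),
                               sd = rep(seG, each = n_sim)),
                  nrow = n_sim, ncol = J)
  ratio_star <- sweep(Gstar, 2L, g, `/`)
  s1 <- ratio_star %*% w
  s0 <- sum(w)
  b_loo_star <- sweep(-sweep(ratio_star, 2L, w, `*`), 1L, s1, `+`)
  b_loo_star <- sweep(b_loo_star, 2L, s0 - w, `/`)
  resid_star <- Gstar - sweep(b_loo_star, 2L, g, `*`)
  rss_j_star <- sweep(resid_star^2, 2L, seG^2, `/`)
  rss_star <- rowSums(rss_j_star)

  global_p <- (1 + sum(rss_star >= rss_obs)) / (n_sim + 1)
  p_j <- (1 + colSums(sweep(rss_j_star, 2L, rss_j_obs, `>=`))) / (n_sim + 1)
  p_j_adj <- pmin(1, p_j * J)

  outlier_sorted <- integer(0)
  if (global_p < outlier_threshold) {
    outlier_sorted <- which(p_j_adj < outlier_threshold)
  }
  outlier_indices <- ord[outlier_sorted]  # positions in the input set
  outlier_ids <- hs$variant_id[outlier_sorted]

  corrected <- NULL
  distortion_p <- NA_real_
  if (length(outlier_sorted) && length(outlier_sorted) <= J - 2L) {
    keep <- setdiff(seq_len(J), outlier_sorted)
    corrected <- mr_ivw(hs[keep, , drop = FALSE])
    b_full <- sum(w * ratio) / s0
    d_obs <- corrected$beta - b_full
    n_dist <- min(n_sim, 1000L)
    d_null <- numeric(n_dist)
    for (i in seq_len(n_dist)) {
      drop_i <- sample.int(J, length(outlier_sorted))
      ki <- setdiff(seq_len(J), drop_i)
      d_null[i] <- sum(w[ki] * ratio[ki]) / sum(w[ki]) - b_full
    }
    distortion_p <- (1 + sum(abs(d_null) >= abs(d_obs))) / (n_dist + 1)
  }

  structure(list(rss_obs = rss_obs, global_p = global_p, n_sim = n_sim,
                 outlier_indices = outlier_indices, outlier_ids = outlier_ids,
                 outlier_pvals = stats::setNames(p_j_adj[outlier_sorted],
                                                 outlier_ids),
                 distortion_p = distortion_p,
                 corrected_estimate = corrected, seed = seed),
            class = "mr_presso_result")
}

#' @export
print.mr_presso_result <- function(x, ...) {
  cat(sprintf("MR-PRESSO: RSS = %.4f, global p = %.4g (%d simulations)\n",
              x$rss_obs, x$global_p, x$n_sim))
  if (length(x$outlier_ids)) {
    cat("Outliers:", paste(x$outlier_ids, collapse = ", "), "\n")
    if (!is.na(x$distortion_p)) {
      cat(sprintf("Distortion test p = %.4g\n", x$distortion_p))
    }
    if (!is.null(x$corrected_estimate)) {
      cat("Outlier-corrected ")
      print(x$corrected_estimate)
    }
  } else {
    cat("No outliers detected.\n")
  }
  invisible(x)
}

#' Leave-one-out sensitivity analysis
#'
#' Re-estimates the IVW causal effect once per instrument, each time
#' excluding that instrument, to reveal single-SNP influence on the pooled
#' estimate.
#'
#' @param h a `harmonized_set` with at least 3 instruments.
#' @return data.frame of class `loo_result` with one row per left-out
#'   variant: `variant_id`, `beta`, `se`, `pval`.
#' @export
leave_one_out <- function(h) {
  stopifnot(inherits(h, "harmonized_set"))
  h <- h[h$gamma != 0, , drop = FALSE]
  J <- nrow(h)
  if (J < 3L) stop("leave_one_out: at least 3 instruments required")
  rows <- lapply(seq_len(J), function(j) {
    est <- mr_ivw(h[-j, , drop = FALSE])
    data.frame(variant_id = h$variant_id[j], beta = est$beta, se = est$se,
               pval = est$pval, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("loo_result", "data.frame")
  out
}
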