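#' Convert a log-odds effect to an odds ratio with 95% CI
#'
#' @param beta effect on the log-odds scale.
#' @param se standard error (>= 0).
#' @param level confidence level (default 0.95).
#' @return named numeric vector `or`, `ci_low`, `ci_high`.
#' @export
beta_to_or <- function(beta, se, level = 0.95) {
  stopifnot(all(se >= 0))
  z <- stats::qnorm(1 - (1 - level) / 2)
  c(or = exp(beta), ci_low = exp(beta - z * se), ci_high = exp(beta + z * se))
}

#' Per-SNP Wald ratio estimates
#'
#' The per-variant causal estimate is `ratio_j = Gamma_j / gamma_j` with
#' first-order standard error `se_j = se_Gamma_j / |gamma_j|` (the SNP-exposure
#' uncertainty is ignored, the usual two-sample convention; a second-order SE
#' adding the `ratio^2 * se_gamma^2 / gamma^2` term is available).
#'
#' Variants with `gamma_j = 0` are excluded with a warning.
#'
#' @param h a `harmonized_set`.
#' @param second_order include the SNP-exposure variance term in the SE.
#' @return data.frame `variant_id`, `ratio`, `se`, `weight` where
#'   `weight = gamma^2 / se_Gamma^2` (the IVW weight of each ratio).
#' @export
wald_ratios <- function(h, second_order = FALSE) {
  stopifnot(inherits(h, "harmonized_set"))
  zero <- h$gamma == 0
  if (any(zero)) {
    warning(sprintf("wald_ratios: excluding %d variant(s) with zero exposure effect",
                    sum(zero)))
    h <- h[!zero, , drop = FALSE]
  }
  ratio <- h$capital_gamma / h$gamma
  se <- h$se_capital_gamma / abs(h$gamma)
  if (second_order) {
    se <- sqrt(se^2 + ratio^2 * h$se_gamma^2 / h$gamma^2)
  }
  data.frame(variant_id = h$variant_id, ratio = ratio, se = se,
             weight = 1 / se^2, stringsAsFactors = FALSE)
}

new_mr_estimate <- function(method, beta, se, pval, n_snp,
                            egger_intercept = NA_real_,
                            egger_intercept_p = NA_real_,
                            model = "fixed") {
  orci <- beta_to_or(beta, se)
  structure(
    data.frame(method = method, n_snp = n_snp, beta = beta, se = se,
               pval = pval, or = orci[["or"]], ci_low = orci[["ci_low"]],
               ci_high = orci[["ci_high"]], egger_intercept = egger_intercept,
               egger_intercept_p = egger_intercept_p, model = model,
               stringsAsFactors = FALSE),
    class = c("mr_estimate", "data.frame"))
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("%s: beta = %.4f (SE %.4f), OR = %.3f (%.3f-%.3f), p = %.3g, nSNP = %d%s\n",
              x$method, x$beta, x$se, x$or, x$ci_low, x$ci_high, x$pval,
              x$n_snp,
              if (x$model == "multiplicative-random") " [random effects]" else ""))
  if (!is.na(x$egger_intercept)) {
    cat(sprintf("  intercept = %.4f (p = %.3g)\n",
                x$egger_intercept, x$egger_intercept_p))
  }
  invisible(x)
}

#' Inverse-variance weighted estimator
#'
#' Pools the Wald ratios with weights `w_j = gamma_j^2 / se_Gamma_j^2`
#' (equivalently, weighted regression of the SNP-outcome effects on the
#' SNP-exposure effects through the origin with weights `1/se_Gamma^2`).
#' The fixed-effect SE is `1/sqrt(sum(w))`; when Cochran's Q exceeds its
#' degrees of freedom the SE is inflated by `sqrt(Q/df)` (multiplicative
#' random effects) and the model is flagged accordingly. The p-value is
#' two-sided normal.
#'
#' @param h a `harmonized_set` with at least 2 instruments.
#' @return an `mr_estimate` (one-row data.frame); attributes `q_stat` and
#'   `q_df` carry the heterogeneity statistic used for the random-effects
#'   decision.
#' @export
mr_ivw <- function(h) {
  w <- wald_ratios(h)
  J <- nrow(w)
  if (J < 2L) stop("mr_ivw: at least 2 instruments required")
  beta <- sum(w$weight * w$ratio) / sum(w$weight)
  q_stat <- sum(w$weight * (w$ratio - beta)^2)
  df <- J - 1L
  se <- 1 / sqrt(sum(w$weight))
  model <- "fixed"
  if (q_stat / df > 1) {
    se <- se * sqrt(q_stat / df)
    model <- "multiplicative-random"
  }
  pval <- 2 * stats::pnorm(-abs(beta / se))
  est <- new_mr_estimate("ivw", beta, se, pval, J, model = model)
  attr(est, "q_stat") <- q_stat
  attr(est, "q_df") <- df
  est
}

#' MR-Egger regression
#'
#' Weighted regression of the SNP-outcome effects on the SNP-exposure
#' effects with a free intercept, weights `1/se_Gamma^2`. The slope is the
#' pleiotropy-adjusted causal estimate (consistent under the InSIDE
#' assumption); the intercept estimates the average directional pleiotropy
#' and its p-value is the usual directional-pleiotropy diagnostic. Standard
#' errors use multiplicative overdispersion with the residual variance
#' factor floored at 1; p-values are t-distributed on `J - 2` df.
#'
#' @param h a `harmonized_set` with at least 3 instruments.
#' @return an `mr_estimate` carrying `egger_intercept` and
#'   `egger_intercept_p`.
#' @export
mr_egger <- function(h) {
  stopifnot(inherits(h, "harmonized_set"))
  h <- h[h$gamma != 0, , drop = FALSE]
  J <- nrow(h)
  if (J < 3L) stop("mr_egger: at least 3 instruments required")
  # orient so all exposure effects are positive (standard Egger convention;
  # makes the intercept interpretable as average directional pleiotropy)
  sgn <- sign(h$gamma)
  g <- h$gamma * sgn
  G <- h$capital_gamma * sgn
  wt <- 1 / h$se_capital_gamma^2
  fit <- stats::lm(G ~ g, weights = wt)
  sm <- summary(fit)
  disp <- max(1, sm$sigma)  # overdispersion factor floored at 1
  co <- sm$coefficients
  se_slope <- co["g", "Std. Error"] / sm$sigma * disp
  se_int <- co["(Intercept)", "Std. Error"] / sm$sigma * disp
  beta <- co["g", "Estimate"]
  intercept <- co["(Intercept)", "Estimate"]
  pval <- 2 * stats::pt(-abs(beta / se_slope), df = J - 2)
  p_int <- 2 * stats::pt(-abs(intercept / se_int), df = J - 2)
  new_mr_estimate("egger", beta, se_slope, pval, J,
                  egger_intercept = intercept, egger_intercept_p = p_int,
                  model = if (sm$sigma > 1) "multiplicative-random" else "fixed")
}

# Weighted median of ordered values: normalized cumulative weights, linear
# interpolation at cumulative probability 0.5 (Bowden et al.'s convention:
# the j-th order statistic sits at S_j - w_j/2).
weighted_median_point <- function(values, weights) {
  ord <- order(values)
  b <- values[ord]
  w <- weights[ord] / sum(weights)
  s <- cumsum(w) - w / 2
  if (0.5 <= s[1]) return(b[1])
  if (0.5 >= s[length(s)]) return(b[length(b)])
  k <- max(which(s < 0.5))
  b[k] + (b[k + 1] - b[k]) * (0.5 - s[k]) / (s[k + 1] - s[k])
}

boot_resample <- function(h, n_boot, seed, statistic) {
  # parametric bootstrap: redraw per-SNP effects from their sampling normals
  est <- numeric(n_boot)
  J <- nrow(h)
  rng <- local_rng(seed)
  on.exit(rng())
  for (b in seq_len(n_boot)) {
    g <- stats::rnorm(J, h$gamma, h$se_gamma)
    G <- stats::rnorm(J, h$capital_gamma, h$se_capital_gamma)
    ratio <- G / g
    w <- g^2 / h$se_capital_gamma^2
    est[b] <- statistic(ratio, w)
  }
  stats::sd(est)
}

#' Weighted-median estimator
#'
#' The weighted median of the Wald ratios, consistent when instruments
#' carrying at least half the total weight are valid. Ratios are ordered,
#' inverse-variance weights normalized, and the estimate is linearly
#' interpolated at cumulative weight 0.5. The SE comes from a seeded
#' parametric bootstrap that redraws each SNP's exposure and outcome effects
#' from normal distributions with their reported SEs.
#'
#' @param h a `harmonized_set` with at least 3 instruments.
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed integer RNG seed for the bootstrap (mandatory for
#'   reproducibility).
#' @return an `mr_estimate`.
#' @export
mr_weighted_median <- function(h, n_boot = 1000, seed) {
  w <- wald_ratios(h)
  J <- nrow(w)
  if (J < 3L) stop("mr_weighted_median: at least 3 instruments required")
  h <- h[h$gamma != 0, , drop = FALSE]
  beta <- weighted_median_point(w$ratio, w$weight)
  se <- boot_resample(h, n_boot, seed,
                      function(ratio, wt) weighted_median_point(ratio, wt))
  pval <- 2 * stats::pnorm(-abs(beta / se))
  new_mr_estimate("weighted_median", beta, se, pval, J)
}

mode_point <- function(ratio, weights, bandwidth_factor) {
  if (length(unique(ratio)) == 1L) return(ratio[1])
  s <- 0.9 * min(stats::sd(ratio), stats::mad(ratio)) * length(ratio)^(-1 / 5)
  if (s <= 0) s <- 0.9 * stats::sd(ratio) * length(ratio)^(-1 / 5)
  bw <- bandwidth_factor * s
  w <- weights / sum(weights)
  grid <- seq(min(ratio) - 3 * bw, max(ratio) + 3 * bw, length.out = 512L)
  dens <- vapply(grid, function(x) sum(w * stats::dnorm(x, ratio, bw)),
                 numeric(1))
  grid[which.max(dens)]
}

#' Mode-based estimator (weighted or simple mode)
#'
#' The argmax of a Gaussian-kernel-smoothed density of the Wald ratios,
#' consistent when the largest group of instruments sharing a causal
#' estimate (by weight, or by count for the simple mode) is valid (the
#' ZEMPA assumption). Bandwidth follows a median-absolute-deviation rule,
#' `0.9 * min(sd, mad) * J^(-1/5)`, scaled by `bandwidth_factor`; the
#' density is maximized on a fixed 512-point grid. SE by seeded parametric
#' bootstrap.
#'
#' @param h a `harmonized_set` with at least 3 instruments.
#' @param weighted use inverse-variance weights (`TRUE`, the weighted mode)
#'   or uniform weights (`FALSE`, the simple mode).
#' @param bandwidth_factor multiplier on the default bandwidth (default 1).
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed integer RNG seed for the bootstrap.
#' @return an `mr_estimate` with method `weighted_mode` or `simple_mode`.
#' @export
mr_mode <- function(h, weighted = TRUE, bandwidth_factor = 1,
                    n_boot = 1000, seed) {
  w <- wald_ratios(h)
  J <- nrow(w)
  if (J < 3L) stop("mr_mode: at least 3 instruments required")
  h <- h[h$gamma != 0, , drop = FALSE]
  wt <- if (weighted) w$weight else rep(1, J)
  beta <- mode_point(w$ratio, wt, bandwidth_factor)
  se <- boot_resample(h, n_boot, seed, function(ratio, wts) {
    mode_point(ratio, if (weighted) wts else rep(1, length(ratio)),
               bandwidth_factor)
  })
  pval <- 2 * stats::pnorm(-abs(beta / se))
  new_mr_estimate(if (weighted) "weighted_mode" else "simple_mode",
                  beta, se, pval, J)
}

#' Fit a battery of two-sample MR estimators
#'
#' The central fitting function: runs the requested univariable estimators
#' on one harmonized exposure-outcome instrument set and bundles them with
#' heterogeneity diagnostics into an `mr_fit` object.
#'
#' @param h a `harmonized_set` (see [harmonize]).
#' @param methods which estimators to run; any subset of
#'   `c("ivw", "egger", "weighted_median", "weighted_mode", "simple_mode")`.
#'   Estimators whose instrument minimum is not met are skipped with a
#'   message.
#' @param n_boot bootstrap replicates for the median/mode SEs.
#' @param seed integer RNG seed for the bootstraps.
#' @param bandwidth_factor bandwidth multiplier for the mode estimators.
#' @return an object of class `mr_fit`: a list with `estimates` (data.frame
#'   of `mr_estimate` rows), `heterogeneity` (Cochran's Q, IVW and Egger
#'   variants where available), `data` (the harmonized set) and `call`.
#' @seealso [mr_ivw], [mr_egger], [mr_weighted_median], [mr_mode],
#'   [cochran_q], [mr_presso], [leave_one_out]
#' @export
#' @examples
#' sim <- simulate_summary_stats(sim_config(n_snps = 20, seed = 7))
#' h <- harmonize(select_by_pvalue(sim$exposure, 1e-5), sim$outcome)
#' fit <- mr_fit(h, seed = 7, n_boot = 200)
#' fit
#' coef(fit)
mr_fit <- function(h,
                   methods = c("ivw", "egger", "weighted_median",
                               "weighted_mode", "simple_mode"),
                   n_boot = 1000, seed = 1L, bandwidth_factor = 1) {
  stopifnot(inherits(h, "harmonized_set"))
  methods <- match.arg(methods, several.ok = TRUE)
  runners <- list(
    ivw = function() mr_ivw(h),
    egger = function() mr_egger(h),
    weighted_median = function() mr_weighted_median(h, n_boot, seed),
    weighted_mode = function() mr_mode(h, TRUE, bandwidth_factor, n_boot, seed),
    simple_mode = function() mr_mode(h, FALSE, bandwidth_factor, n_boot, seed))
  rows <- list()
  for (m in methods) {
    est <- tryCatch(runners[[m]](), error = function(e) {
      message(sprintf("mr_fit: skipping %s (%s)", m, conditionMessage(e)))
      NULL
    })
    if (!is.null(est)) rows[[m]] <- as.data.frame(est)
  }
  if (!length(rows)) stop("mr_fit: no estimator could be run")
  estimates <- do.call(rbind, rows)
  rownames(estimates) <- NULL
  het <- list()
  if (nrow(h) >= 2L) het$ivw <- cochran_q(h, "ivw")
  if (nrow(h) >= 3L) het$egger <- cochran_q(h, "egger")
  structure(list(estimates = estimates, heterogeneity = het, data = h,
                 n_boot = n_boot, seed = seed, call = match.call()),
            class = "mr_fit")
}

#' @export
print.mr_fit <- function(x, ...) {
  cat(sprintf("Two-sample MR: %s -> %s (%d instruments)\n\n",
              attr(x$data, "exposure_name"), attr(x$data, "outcome_name"),
              nrow(x$data)))
  df <- x$estimates
  show <- data.frame(method = df$method, nSNP = df$n_snp,
                     beta = sprintf("%.3f", df$beta),
                     se = sprintf("%.3f", df$se),
                     `OR (95% CI)` = sprintf("%.3f (%.3f-%.3f)", df$or,
                                             df$ci_low, df$ci_high),
                     p = sprintf("%.2E", df$pval),
                     check.names = FALSE)
  print(show, row.names = FALSE)
  invisible(x)
}

#' @export
summary.mr_fit <- function(object, ...) {
  het <- object$heterogeneity
  structure(list(fit = object, heterogeneity = het), class = "summary.mr_fit")
}

#' @export
print.summary.mr_fit <- function(x, ...) {
  print(x$fit)
  eg <- x$fit$estimates[x$fit$estimates$method == "egger", ]
  if (nrow(eg) && !is.na(eg$egger_intercept)) {
    cat(sprintf("\nEgger intercept: %.4f (p = %.3g)\n",
                eg$egger_intercept, eg$egger_intercept_p))
  }
  for (v in names(x$heterogeneity)) {
    q <- x$heterogeneity[[v]]
    cat(sprintf("Cochran's Q (%s): Q = %.3f on %d df, p = %.3g\n",
                v, q$q_stat, q$df, q$pval))
  }
  invisible(x)
}

#' @export
coef.mr_fit <- function(object, ...) {
  stats::setNames(object$estimates$beta, object$estimates$method)
}

#' @export
confint.mr_fit <- function(object, parm, level = 0.95, ...) {
  df <- object$estimates
  if (!missing(parm)) df <- df[df$method %in% parm, , drop = FALSE]
  z <- stats::qnorm(1 - (1 - level) / 2)
  out <- cbind(df$beta - z * df$se, df$beta + z * df$se)
  dimnames(out) <- list(df$method,
                        sprintf("%.1f %%", 100 * c((1 - level) / 2,
                                                   1 - (1 - level) / 2)))
  out
}

#' @export
residuals.mr_fit <- function(object, method = "ivw", ...) {
  df <- object$estimates
  if (!method %in% df$method) stop("residuals.mr_fit: method not fitted")
  beta <- df$beta[df$method == method]
  a <- if (method == "egger") df$egger_intercept[df$method == "egger"] else 0
  h <- object$data
  sgn <- if (method == "egger") sign(h$gamma) else 1
  stats::setNames(h$capital_gamma * sgn - a - beta * h$gamma * sgn,
                  h$variant_id)
}

#' Scatter plot of SNP-outcome vs SNP-exposure effects with fitted slopes
#'
#' @param x an `mr_fit`.
#' @param ... passed to [graphics::plot].
#' @export
plot.mr_fit <- function(x, ...) {
  h <- x$data
  graphics::plot(h$gamma, h$capital_gamma,
                 xlab = "SNP effect on exposure",
                 ylab = "SNP effect on outcome",
                 pch = 19, ...)
  graphics::segments(h$gamma, h$capital_gamma - 1.96 * h$se_capital_gamma,
                     h$gamma, h$capital_gamma + 1.96 * h$se_capital_gamma,
                     col = "grey70")
  df <- x$estimates
  cols <- c(ivw = "black", egger = "firebrick", weighted_median = "steelblue",
            weighted_mode = "darkgreen", simple_mode = "orange")
  for (i in seq_len(nrow(df))) {
    a <- if (df$method[i] == "egger") df$egger_intercept[i] else 0
    graphics::abline(a = a, b = df$beta[i], col = cols[[df$method[i]]],
                     lty = if (df$method[i] == "ivw") 1 else 2)
  }
  graphics::legend("topleft", legend = df$method, bty = "n",
                   col = cols[df$method],
                   lty = ifelse(df$method == "ivw", 1, 2))
  invisible(x)
}
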