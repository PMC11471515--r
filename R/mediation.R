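#' Multivariable MR: direct effects of exposure and mediator on the outcome
#'
#' Weighted multivariable regression of the SNP-outcome effects on the
#' SNP-exposure and SNP-mediator effect columns jointly, with no intercept
#' and weights `1/se_Gamma^2`. The exposure coefficient is the direct effect
#' of the exposure on the outcome adjusted for the mediator; the mediator
#' coefficient is the mediator's direct effect adjusted for the exposure —
#' the adjusted `beta'` quantities of a two-step mediation analysis.
#' Standard errors use multiplicative overdispersion floored at 1;
#' instrument sets should be the harmonized union of the exposure's and
#' mediator's instruments. A Q-statistic-based conditional instrument
#' strength is reported per exposure (weighted residual variance of one
#' effect column after regressing out the other, over `J - 2` df).
#'
#' @param h a `harmonized_set` carrying mediator columns (`delta`,
#'   `se_delta`), with at least 4 instruments.
#' @return list of class `mvmr_fit`: `direct_exposure_effect` and
#'   `direct_mediator_effect` (each `estimate`, `se`, `ci_low`, `ci_high`,
#'   `pval`), `n_snp`, `conditional_f` (named vector), `sigma`.
#' @export
mvmr_fit <- function(h) {
  stopifnot(inherits(h, "harmonized_set"))
  if (is.null(h$delta)) stop("mvmr_fit: harmonized set has no mediator effects")
  J <- nrow(h)
  if (J < 4L) stop("mvmr_fit: at least 4 instruments required")
  if (all(h$delta == 0)) {
    # degenerate nested case: no mediator pathway in the data; the direct
    # exposure effect reduces to the univariable IVW estimate
    uni <- mr_ivw(h)
    return(structure(list(
      direct_exposure_effect = list(estimate = uni$beta, se = uni$se,
                                    ci_low = uni$beta - 1.96 * uni$se,
                                    ci_high = uni$beta + 1.96 * uni$se,
                                    pval = uni$pval),
      direct_mediator_effect = list(estimate = 0, se = NA_real_,
                                    ci_low = NA_real_, ci_high = NA_real_,
                                    pval = NA_real_),
      n_snp = J,
      conditional_f = c(exposure = NA_real_, mediator = 0),
      sigma = NA_real_,
      exposure_name = attr(h, "exposure_name"),
      mediator_name = attr(h, "mediator_name"),
      outcome_name = attr(h, "outcome_name")),
      class = "mvmr_fit"))
  }
  if (stats::var(h$gamma) == 0 || stats::var(h$delta) == 0) {
    stop("mvmr_fit: an exposure column has no variation")
  }
  X <- cbind(exposure = h$gamma, mediator = h$delta)
  if (qr(X)$rank < 2L) {
    stop("mvmr_fit: design is rank-deficient (exposure and mediator instrument effects are collinear)")
  }
  wt <- 1 / h$se_capital_gamma^2
  fit <- stats::lm(h$capital_gamma ~ 0 + X, weights = wt)
  sm <- summary(fit)
  disp <- max(1, sm$sigma)
  co <- sm$coefficients
  se <- co[, "Std. Error"] / sm$sigma * disp
  est <- co[, "Estimate"]
  pval <- 2 * stats::pnorm(-abs(est / se))

  pack <- function(i) {
    list(estimate = unname(est[i]), se = unname(se[i]),
         ci_low = unname(est[i] - 1.96 * se[i]),
         ci_high = unname(est[i] + 1.96 * se[i]),
         pval = unname(pval[i]))
  }

  cond_f <- function(target, other, se_target) {
    r <- stats::residuals(stats::lm(target ~ 0 + other,
                                    weights = 1 / se_target^2))
    sum(r^2 / se_target^2) / (J - 2L)
  }
  conditional_f <- c(
    exposure = cond_f(h$gamma, h$delta, h$se_gamma),
    mediator = cond_f(h$delta, h$gamma,
                      if (!is.null(h$se_delta)) h$se_delta else h$se_gamma))

  structure(list(direct_exposure_effect = pack(1L),
                 direct_mediator_effect = pack(2L),
                 n_snp = J, conditional_f = conditional_f,
                 sigma = sm$sigma,
                 exposure_name = attr(h, "exposure_name"),
                 mediator_name = attr(h, "mediator_name"),
                 outcome_name = attr(h, "outcome_name")),
            class = "mvmr_fit")
}

#' @export
print.mvmr_fit <- function(x, ...) {
  cat(sprintf("Multivariable MR (%d instruments)\n", x$n_snp))
  fmt <- function(label, e) {
    cat(sprintf("  %s: %.4f (95%% CI %.4f, %.4f), p = %.3g\n",
                label, e$estimate, e$ci_low, e$ci_high, e$pval))
  }
  fmt("direct exposure effect  (beta'_EO)", x$direct_exposure_effect)
  fmt("direct mediator effect  (beta'_MO)", x$direct_mediator_effect)
  cat(sprintf("  conditional F: exposure %.1f, mediator %.1f\n",
              x$conditional_f[["exposure"]], x$conditional_f[["mediator"]]))
  invisible(x)
}

#' Bundle the three univariable IVW legs of a two-step mediation analysis
#'
#' Repackages the exposure-to-mediator, mediator-to-outcome and
#' exposure-to-outcome IVW estimates as the two-step-MR triplet
#' (beta_EM, beta_MO, beta_EO) and applies the screening gate: a candidate
#' is flagged for multivariable-MR confirmation only when all three legs
#' have p < `gate_p`. When the flagged triplet's implied indirect path
#' (sign of beta_EM * beta_MO) opposes the sign of the total effect, it is
#' additionally labelled `inconsistent_direction`.
#'
#' @param em,mo,eo `mr_estimate`s from [mr_ivw] for the three legs.
#' @param gate_p significance gate (default 0.05).
#' @return list of class `tsmr_triplet`: `beta_em`, `se_em`, `p_em`,
#'   `beta_mo`, `se_mo`, `p_mo`, `beta_eo`, `se_eo`, `p_eo`, `flagged`,
#'   `inconsistent_direction`.
#' @export
two_step_effects <- function(em, mo, eo, gate_p = 0.05) {
  for (e in list(em, mo, eo)) {
    if (!inherits(e, "mr_estimate")) stop("two_step_effects: inputs must be mr_estimate objects")
    if (e$method != "ivw") stop("two_step_effects: all three legs must be IVW estimates")
  }
  flagged <- em$pval < gate_p && mo$pval < gate_p && eo$pval < gate_p
  inconsistent <- flagged && sign(em$beta * mo$beta) != sign(eo$beta)
  structure(list(beta_em = em$beta, se_em = em$se, p_em = em$pval,
                 beta_mo = mo$beta, se_mo = mo$se, p_mo = mo$pval,
                 beta_eo = eo$beta, se_eo = eo$se, p_eo = eo$pval,
                 flagged = flagged, inconsistent_direction = inconsistent),
            class = "tsmr_triplet")
}

#' @export
print.tsmr_triplet <- function(x, ...) {
  cat(sprintf("TSMR triplet: beta_EM = %.3f (p=%.3g), beta_MO = %.3f (p=%.3g), beta_EO = %.3f (p=%.3g)\n",
              x$beta_em, x$p_em, x$beta_mo, x$p_mo, x$beta_eo, x$p_eo))
  cat(if (x$flagged) "  flagged for MVMR confirmation" else "  gate not met")
  if (isTRUE(x$inconsistent_direction)) cat(" [inconsistent direction]")
  cat("\n")
  invisible(x)
}

#' Product-of-coefficients mediated effect with delta-method SE
#'
#' The mediated (indirect) effect of the exposure on the outcome through
#' the mediator is the product of the exposure-to-mediator effect and the
#' mediator's MVMR-adjusted effect on the outcome:
#' `beta_EMO = beta_EM * beta'_MO`, with delta-method standard error
#' `SE_EMO = sqrt(beta'_MO^2 * SE_EM^2 + beta_EM^2 * SE'_MO^2)`,
#' 95% CI `beta_EMO +/- 1.96 * SE_EMO`, two-sided normal p, and mediated
#' proportion `beta_EMO / beta_EO` (undefined when the total effect is
#' zero). The proportion is reported even when the mediated-effect CI
#' crosses zero, with `ci_includes_zero` flagging that case.
#'
#' @param beta_em exposure-to-mediator effect.
#' @param se_em its standard error (>= 0).
#' @param beta_prime_mo MVMR-adjusted mediator-to-outcome effect.
#' @param se_prime_mo its standard error (>= 0).
#' @param beta_eo total exposure-to-outcome effect (for the proportion).
#' @return list of class `mr_mediation`: `beta_emo`, `se_emo`, `ci_low`,
#'   `ci_high`, `p_emo`, `proportion`, `proportion_pct`,
#'   `ci_includes_zero`, plus the echoed inputs.
#' @export
#' @examples
#' mediation_effect(-0.097, 0.036, 0.089, se_from_ci(0.041, 0.136), -0.059)
mediation_effect <- function(beta_em, se_em, beta_prime_mo, se_prime_mo,
                             beta_eo) {
  stopifnot(se_em >= 0, se_prime_mo >= 0)
  beta_emo <- beta_em * beta_prime_mo
  se_emo <- sqrt(beta_prime_mo^2 * se_em^2 + beta_em^2 * se_prime_mo^2)
  ci_low <- beta_emo - 1.96 * se_emo
  ci_high <- beta_emo + 1.96 * se_emo
  p_emo <- if (se_emo > 0) 2 * stats::pnorm(-abs(beta_emo / se_emo)) else
    as.numeric(beta_emo == 0)
  if (beta_eo == 0) {
    warning("mediation_effect: total effect is zero; mediated proportion undefined")
    proportion <- NA_real_
  } else {
    proportion <- beta_emo / beta_eo
  }
  structure(list(beta_em = beta_em, se_em = se_em,
                 beta_prime_mo = beta_prime_mo, se_prime_mo = se_prime_mo,
                 beta_eo = beta_eo,
                 beta_emo = beta_emo, se_emo = se_emo,
                 ci_low = ci_low, ci_high = ci_high, p_emo = p_emo,
                 proportion = proportion,
                 proportion_pct = 100 * proportion,
                 ci_includes_zero = ci_low <= 0 && ci_high >= 0),
            class = "mr_mediation")
}

#' @export
print.mr_mediation <- function(x, ...) {
  cat(sprintf("Mediated effect: %.3f (95%% CI %.3f, %.3f), SE = %.3f, p = %.2E\n",
              round_half_up(x$beta_emo), round_half_up(x$ci_low),
              round_half_up(x$ci_high), round_half_up(x$se_emo), x$p_emo))
  if (!is.na(x$proportion)) {
    cat(sprintf("Mediated proportion: %.3f%%%s\n", x$proportion_pct,
                if (x$ci_includes_zero) " [mediated-effect CI includes zero]" else ""))
  } else {
    cat("Mediated proportion: undefined (zero total effect)\n")
  }
  invisible(x)
}
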