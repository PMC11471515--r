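#' Analysis configuration for the screening and mediation pipelines
#'
#' Bundles every tunable of the pipeline with the conventional defaults:
#' instrument p-value thresholds of 1e-5 for metabolite-style exposure
#' panels and 5e-6 for cytokine-style mediator panels (5e-8 for
#' binary-trait exposures in reverse analyses), clumping at r-squared 0.001
#' within 10,000 kb, palindromic exclusion at eaf in \[0.42, 0.58\],
#' per-SNP F >= 10, MR-PRESSO with 1000 simulations at threshold 0.05, and
#' BH-FDR tiering at 0.05.
#'
#' @param p_threshold instrument p-value threshold for exposures.
#' @param p_threshold_mediator threshold for the mediator panel.
#' @param p_reverse threshold for binary traits used as exposures in
#'   reverse-direction analyses.
#' @param clump_r2,clump_kb LD-clumping parameters.
#' @param maf_band palindromic-ambiguity eaf band.
#' @param min_f weak-instrument exclusion threshold.
#' @param n_boot bootstrap replicates for median/mode SEs.
#' @param bandwidth_factor mode-estimator bandwidth multiplier.
#' @param presso_n_sim,presso_threshold MR-PRESSO settings.
#' @param fdr_alpha,fdr_method tiering level and adjustment family.
#' @param ld optional LD pair table for [greedy_clump]; `NULL` means no LD
#'   information, in which case instruments are treated as independent.
#' @param missing_ld policy when `ld` is supplied but lacks an in-window
#'   pair.
#' @param exclude character vector of confounder-associated variant ids to
#'   remove before analysis.
#' @param seed integer RNG seed used by every stochastic stage.
#' @return list of class `analysis_config`.
#' @export
analysis_config <- function(p_threshold = 1e-5, p_threshold_mediator = 5e-6,
                            p_reverse = 5e-8,
                            clump_r2 = 0.001, clump_kb = 10000,
                            maf_band = c(0.42, 0.58), min_f = 10,
                            n_boot = 1000, bandwidth_factor = 1,
                            presso_n_sim = 1000, presso_threshold = 0.05,
                            fdr_alpha = 0.05, fdr_method = "BH",
                            ld = NULL, missing_ld = "correlated",
                            exclude = character(0), seed = 1L) {
  structure(list(p_threshold = p_threshold,
                 p_threshold_mediator = p_threshold_mediator,
                 p_reverse = p_reverse,
                 clump_r2 = clump_r2, clump_kb = clump_kb,
                 maf_band = maf_band, min_f = min_f,
                 n_boot = n_boot, bandwidth_factor = bandwidth_factor,
                 presso_n_sim = presso_n_sim,
                 presso_threshold = presso_threshold,
                 fdr_alpha = fdr_alpha, fdr_method = fdr_method,
                 ld = ld, missing_ld = missing_ld,
                 exclude = exclude, seed = as.integer(seed)),
            class = "analysis_config")
}

#' Instrument selection for one exposure panel
#'
#' Applies, in order: the p-value screen, greedy LD clumping, palindromic
#' exclusion, the confounder exclusion list, and the weak-instrument
#' (F < `min_f`) filter.
#'
#' @param dataset a [trait_dataset].
#' @param config an [analysis_config].
#' @param threshold p-value threshold; defaults to `config$p_threshold`.
#' @return the selected instrument [trait_dataset].
#' @export
select_instruments <- function(dataset, config = analysis_config(),
                               threshold = config$p_threshold) {
  iv <- select_by_pvalue(dataset, threshold)
  if (nrow(iv) >= 2L) {
    policy <- if (is.null(config$ld)) "independent" else config$missing_ld
    iv <- greedy_clump(iv, ld = config$ld, r2_max = config$clump_r2,
                       window_kb = config$clump_kb, missing_ld = policy)
  }
  iv <- drop_palindromes(iv, config$maf_band)
  if (length(config$exclude)) iv <- exclude_listed_snps(iv, config$exclude)
  if (nrow(iv)) iv <- filter_by_f(iv, min_f = config$min_f)
  iv
}

screen_one_pair <- function(exposure, outcome, config, threshold, log_add) {
  ename <- trait_name(exposure); oname <- trait_name(outcome)
  iv <- select_instruments(exposure, config, threshold)
  if (nrow(iv) < 2L) {
    log_add(sprintf("skip %s->%s: insufficient instruments after selection (%d)",
                    ename, oname, nrow(iv)))
    return(NULL)
  }
  h <- tryCatch(harmonize(iv, outcome, pal_band = config$maf_band),
                error = function(e) {
                  log_add(sprintf("skip %s->%s: %s", ename, oname,
                                  conditionMessage(e)))
                  NULL
                })
  if (is.null(h) || nrow(h) < 2L) {
    if (!is.null(h)) log_add(sprintf("skip %s->%s: <2 harmonized instruments",
                                     ename, oname))
    return(NULL)
  }
  fit <- mr_fit(h, n_boot = config$n_boot, seed = config$seed,
                bandwidth_factor = config$bandwidth_factor)
  qres <- fit$heterogeneity$ivw
  presso <- NULL
  if (nrow(h) >= 4L) {
    presso <- mr_presso(h, n_sim = config$presso_n_sim,
                        outlier_threshold = config$presso_threshold,
                        seed = config$seed)
    if (length(presso$outlier_ids) && !is.null(presso$corrected_estimate) &&
        presso$corrected_estimate$pval > 0.05) {
      log_add(sprintf(
        "drop %s->%s: association lost after MR-PRESSO outlier correction (p=%.3g)",
        ename, oname, presso$corrected_estimate$pval))
      return(NULL)
    }
  }
  df <- fit$estimates
  rows <- data.frame(exposure = ename, outcome = oname, method = df$method,
                     n_snp = df$n_snp, beta = df$beta, se = df$se,
                     pval = df$pval, or = df$or, ci_low = df$ci_low,
                     ci_high = df$ci_high,
                     p_fdr = NA_real_,
                     het_q_p = ifelse(df$method == "ivw",
                                      if (!is.null(qres)) qres$pval else NA_real_,
                                      NA_real_),
                     presso_p = ifelse(df$method == "ivw",
                                       if (!is.null(presso)) presso$global_p else NA_real_,
                                       NA_real_),
                     tier = NA_character_,
                     stringsAsFactors = FALSE)
  rows
}

#' Run a multi-exposure MR screen against one or more outcomes
#'
#' For every exposure-outcome pair: instrument selection, harmonization,
#' the five univariable estimators, Cochran's Q and MR-PRESSO. Exposures
#' whose association is lost after MR-PRESSO outlier correction (corrected
#' IVW p > 0.05) are excluded from the report. Within each outcome, IVW
#' p-values across the surviving exposures are BH-FDR adjusted and tiered
#' (`significant` / `suggestive` / `none`). Failures in one pair are logged
#' and the screen continues.
#'
#' @param exposures a [trait_dataset] or (named) list of them, one per
#'   exposure trait in the panel.
#' @param outcomes a [trait_dataset] or (named) list of them.
#' @param config an [analysis_config].
#' @param threshold instrument p-value threshold (default
#'   `config$p_threshold`).
#' @param fdr_m size of the FDR family; defaults to the number of exposures
#'   screened, but can be set to the full panel size when only a subset is
#'   being re-analyzed.
#' @return data.frame of report rows (one per exposure-outcome-method) with
#'   `p_fdr` and `tier` filled on the IVW rows; attribute `log` holds the
#'   skip/drop audit trail.
#' @export
run_screen <- function(exposures, outcomes, config = analysis_config(),
                       threshold = config$p_threshold, fdr_m = NULL) {
  if (inherits(exposures, "trait_dataset")) exposures <- list(exposures)
  if (inherits(outcomes, "trait_dataset")) outcomes <- list(outcomes)
  logs <- character(0)
  log_add <- function(msg) logs <<- c(logs, msg)

  all_rows <- list()
  for (outcome in outcomes) {
    orows <- list()
    for (exposure in exposures) {
      rows <- screen_one_pair(exposure, outcome, config, threshold, log_add)
      if (!is.null(rows)) orows[[length(orows) + 1L]] <- rows
    }
    if (!length(orows)) next
    odf <- do.call(rbind, orows)
    ivw <- odf$method == "ivw"
    m <- if (is.null(fdr_m)) sum(ivw) else fdr_m
    praw <- odf$pval[ivw]
    # pad the family to the full panel size with p = 1 placeholders when the
    # screen covers only a subset of it
    pad <- max(0L, m - length(praw))
    adj <- bh_fdr(c(praw, rep(1, pad)), method = config$fdr_method)[seq_along(praw)]
    tiers <- assign_tiers(praw, adj, alpha = config$fdr_alpha)
    odf$p_fdr[ivw] <- adj
    odf$tier[ivw] <- tiers$tier
    all_rows[[length(all_rows) + 1L]] <- odf
  }
  out <- if (length(all_rows)) do.call(rbind, all_rows) else
    data.frame()
  attr(out, "log") <- logs
  out
}

#' Reverse-direction MR screen
#'
#' Runs [run_screen] with outcome and exposure roles swapped: each (binary)
#' outcome trait becomes the exposure, instrumented at the genome-wide
#' threshold `config$p_reverse`, and each original exposure becomes the
#' outcome. Used to check whether apparent forward effects could reflect
#' reverse causation.
#'
#' @inheritParams run_screen
#' @return as [run_screen].
#' @export
run_reverse <- function(exposures, outcomes, config = analysis_config()) {
  run_screen(exposures = outcomes, outcomes = exposures, config = config,
             threshold = config$p_reverse)
}

#' Two-step + multivariable MR mediation pipeline
#'
#' Reproduces the full mediation workflow for one
#' exposure - mediator - outcome triple:
#' \enumerate{
#'   \item univariable IVW legs: exposure->mediator and exposure->outcome on
#'     the exposure's instruments, mediator->outcome on the mediator's
#'     instruments;
#'   \item the two-step gate: all three legs must have p < 0.05
#'     ([two_step_effects]);
#'   \item multivariable MR on the union of the exposure's and mediator's
#'     instruments (jointly re-clumped, re-harmonized to outcome and
#'     mediator) for the direct effects;
#'   \item the product-of-coefficients mediated effect with delta-method SE
#'     and mediated proportion ([mediation_effect]).
#' }
#'
#' @param exposure,mediator,outcome [trait_dataset]s.
#' @param config an [analysis_config].
#' @return list of class `mediation_pipeline`: `tsmr` (the
#'   [two_step_effects] triplet), `mvmr` (the [mvmr_fit], or `NULL` when
#'   the gate fails), `mediation` (the [mediation_effect], or `NULL`),
#'   `table3` and `table4` (journal-style data.frames, empty when the gate
#'   fails), `log`.
#' @export
run_mediation <- function(exposure, mediator, outcome,
                          config = analysis_config()) {
  logs <- character(0)
  iv_e <- select_instruments(exposure, config, config$p_threshold)
  if (nrow(iv_e) < 2L) stop("run_mediation: insufficient exposure instruments")
  iv_m <- select_instruments(mediator, config, config$p_threshold_mediator)
  if (nrow(iv_m) < 2L) stop("run_mediation: insufficient mediator instruments")

  em <- mr_ivw(harmonize(iv_e, mediator, pal_band = config$maf_band))
  eo <- mr_ivw(harmonize(iv_e, outcome, pal_band = config$maf_band))
  mo <- mr_ivw(harmonize(iv_m, outcome, pal_band = config$maf_band))
  tsmr <- two_step_effects(em, mo, eo)

  empty <- data.frame()
  if (!tsmr$flagged) {
    logs <- c(logs, "two-step gate not met (a leg has p >= 0.05); MVMR not run")
    return(structure(list(tsmr = tsmr, mvmr = NULL, mediation = NULL,
                          table3 = empty, table4 = empty, log = logs),
                     class = "mediation_pipeline"))
  }

  # MVMR instrument set: union of both panels' instruments, drawn from the
  # full exposure dataset (so mediator-specific SNPs keep their exposure
  # effects), jointly re-clumped on the stronger of the two association
  # p-values, then harmonized to outcome and mediator
  union_ids <- union(iv_e$variant_id, iv_m$variant_id)
  exp_union <- exposure[exposure$variant_id %in% union_ids, , drop = FALSE]
  exp_union <- restamp_dataset(exp_union, exposure)
  med_p <- mediator$pval[match(exp_union$variant_id, mediator$variant_id)]
  rank_p <- pmin(exp_union$pval, med_p, na.rm = TRUE)
  clump_in <- exp_union
  clump_in$pval <- rank_p
  policy <- if (is.null(config$ld)) "independent" else config$missing_ld
  kept <- greedy_clump(restamp_dataset(clump_in, exposure), ld = config$ld,
                       r2_max = config$clump_r2, window_kb = config$clump_kb,
                       missing_ld = policy)
  exp_union <- restamp_dataset(
    exp_union[exp_union$variant_id %in% kept$variant_id, , drop = FALSE],
    exposure)

  h3 <- harmonize(exp_union, outcome, mediator = mediator,
                  pal_band = config$maf_band)
  mv <- mvmr_fit(h3)
  med <- mediation_effect(beta_em = tsmr$beta_em, se_em = tsmr$se_em,
                          beta_prime_mo = mv$direct_mediator_effect$estimate,
                          se_prime_mo = mv$direct_mediator_effect$se,
                          beta_eo = tsmr$beta_eo)

  ename <- trait_name(exposure); mname <- trait_name(mediator)
  oname <- trait_name(outcome)
  table3 <- data.frame(
    exposure = ename, mediator = mname, outcome = oname,
    beta_em = tsmr$beta_em, se_em = tsmr$se_em, p_em = tsmr$p_em,
    beta_mo = tsmr$beta_mo, se_mo = tsmr$se_mo, p_mo = tsmr$p_mo,
    beta_eo = tsmr$beta_eo, se_eo = tsmr$se_eo, p_eo = tsmr$p_eo,
    stringsAsFactors = FALSE)
  table4 <- data.frame(
    exposure = ename, mediator = mname, outcome = oname,
    beta_em = tsmr$beta_em,
    beta_prime_mo = mv$direct_mediator_effect$estimate,
    beta_prime_mo_ci_low = mv$direct_mediator_effect$ci_low,
    beta_prime_mo_ci_high = mv$direct_mediator_effect$ci_high,
    beta_prime_eo = mv$direct_exposure_effect$estimate,
    beta_eo = tsmr$beta_eo,
    beta_emo = med$beta_emo, se_emo = med$se_emo,
    emo_ci_low = med$ci_low, emo_ci_high = med$ci_high, p_emo = med$p_emo,
    proportion = med$proportion, proportion_pct = med$proportion_pct,
    stringsAsFactors = FALSE)
  structure(list(tsmr = tsmr, mvmr = mv, mediation = med,
                 table3 = table3, table4 = table4, log = logs),
            class = "mediation_pipeline")
}

#' @export
print.mediation_pipeline <- function(x, ...) {
  print(x$tsmr)
  if (!is.null(x$mvmr)) {
    print(x$mvmr)
    print(x$mediation)
  } else {
    cat("MVMR/mediation not run:", paste(x$log, collapse = "; "), "\n")
  }
  invisible(x)
}
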