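test_that("Wald ratios follow the first-order delta rule", {
  h <- make_h(gamma = c(0.2, 0.2, -0.2), se_gamma = rep(0.01, 3),
              capital_gamma = c(0.1, 0, 0.1), se_capital_gamma = rep(0.02, 3))
  w <- wald_ratios(h)
  expect_equal(w$ratio, c(0.5, 0, -0.5))
  expect_equal(w$se, rep(0.1, 3))
  h0 <- make_h(c(0.2, 0), c(0.01, 0.01), c(0.1, 0.1), c(0.02, 0.02))
  expect_warning(w0 <- wald_ratios(h0), "zero exposure effect")
  expect_equal(nrow(w0), 1L)
})

test_that("IVW pools ratios by inverse variance with a random-effects fallback", {
  # perfectly homogeneous ratios: estimate exact, Q = 0, fixed model
  h <- make_h(c(0.1, 0.2, 0.4), rep(0.01, 3),
              c(0.05, 0.10, 0.20), c(0.02, 0.01, 0.03))
  est <- mr_ivw(h)
  expect_equal(est$beta, 0.5)
  expect_equal(attr(est, "q_stat"), 0)
  expect_equal(est$model, "fixed")

  # two-point hand computation: ratios (0.5, 1.5), unit weights
  h2 <- make_h(c(1, 1), c(0.01, 0.01), c(0.5, 1.5), c(1, 1))
  est2 <- mr_ivw(h2)
  expect_equal(est2$beta, 1.0)
  expect_equal(attr(est2, "q_stat"), 0.5)
  expect_equal(est2$se, 1 / sqrt(2))   # Q/df = 0.5 < 1: no inflation

  # heterogeneous data trips the multiplicative random-effects inflation
  h3 <- make_h(c(1, 1, 1), rep(0.01, 3), c(0, 1, 5), c(0.5, 0.5, 0.5))
  est3 <- mr_ivw(h3)
  expect_equal(est3$model, "multiplicative-random")
  q <- attr(est3, "q_stat")
  expect_equal(est3$se, sqrt(q / 2) / sqrt(3 / 0.25), tolerance = 1e-12)

  expect_error(mr_ivw(make_h(0.1, 0.01, 0.05, 0.01)), "at least 2")
})

test_that("IVW equals the weighted regression through the origin", {
  set.seed(5)
  h <- make_h(stats::rnorm(10, 0.2, 0.05), rep(0.01, 10),
              stats::rnorm(10, 0.08, 0.02), stats::runif(10, 0.01, 0.05))
  est <- mr_ivw(h)
  fit <- stats::lm(capital_gamma ~ 0 + gamma, data = h,
                   weights = 1 / h$se_capital_gamma^2)
  expect_equal(est$beta, unname(coef(fit)[1]), tolerance = 1e-12)
})

test_that("effect-scale conversion reproduces published odds ratios", {
  expect_equal(round(beta_to_or(0.103, 0.026)[["or"]], 3), 1.108)
  expect_equal(round(beta_to_or(0.103, 0.026)[["ci_low"]], 3), 1.053)
  # the published upper bound (1.167) comes from unrounded inputs; from the
  # printed beta/se the bound lands within one unit in the third decimal
  expect_equal(beta_to_or(0.103, 0.026)[["ci_high"]], 1.167, tolerance = 1e-3)
  expect_equal(round(beta_to_or(0.087, 0.036)[["or"]], 3), 1.091)
  expect_equal(round(beta_to_or(-0.199, 0.04)[["or"]], 3), 0.820)
  o <- beta_to_or(0, 0.1)
  expect_equal(o[["or"]], 1)
  expect_equal(o[["ci_low"]] * o[["ci_high"]], 1, tolerance = 1e-12)
})

test_that("Egger recovers exact linear data and reports the intercept", {
  g <- c(0.1, 0.15, 0.2, 0.3, 0.4)
  h <- make_h(g, rep(0.01, 5), 0.02 + 0.4 * g, rep(0.03, 5))
  est <- mr_egger(h)
  expect_equal(est$beta, 0.4, tolerance = 1e-10)
  expect_equal(est$egger_intercept, 0.02, tolerance = 1e-10)
  expect_error(mr_egger(make_h(c(0.1, 0.2), c(0.01, 0.01),
                               c(0.05, 0.1), c(0.01, 0.01))), "at least 3")
})

test_that("Egger with a null intercept matches IVW on single-cluster data", {
  # exact proportional data: intercept estimates ~0 and slope equals IVW
  g <- c(0.1, 0.2, 0.3, 0.5)
  h <- make_h(g, rep(0.01, 4), 0.4 * g, rep(0.02, 4))
  expect_equal(mr_egger(h)$beta, mr_ivw(h)$beta, tolerance = 1e-9)
})

test_that("Egger intercept p-values are calibrated under balanced pleiotropy", {
  pvals <- vapply(1:150, function(s) {
    sim <- simulate_summary_stats(sim_config(n_snps = 25, n_mediator_snps = 0,
                                             pleiotropy_mode = "balanced",
                                             pleiotropy_sd = 0.02, seed = s))
    h <- harmonize(select_by_pvalue(sim$exposure, 1e-5), sim$outcome)
    mr_egger(h)$egger_intercept_p
  }, numeric(1))
  # under the balanced null the intercept p should be roughly uniform
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
  expect_lt(mean(pvals < 0.05), 0.12)
})

test_that("weighted median interpolates the inverse-variance-weighted CDF", {
  # symmetric ratios, equal weights: plain median
  h <- make_h(c(1, 1, 1), rep(0.01, 3), c(0.1, 0.5, 0.9), rep(0.05, 3))
  expect_equal(mr_weighted_median(h, n_boot = 50, seed = 1)$beta, 0.5)

  # two-point interpolation against the independent oracle
  vals <- c(0, 1); wts <- c(0.25, 0.75)
  est <- mrmediate:::weighted_median_point(vals, wts)
  expect_equal(est, weighted_median_oracle(vals, wts))
  expect_equal(est, 0.75)

  # random cases against the oracle
  set.seed(9)
  for (i in 1:50) {
    v <- stats::rnorm(sample(3:12, 1))
    w <- stats::runif(length(v), 0.1, 2)
    expect_equal(mrmediate:::weighted_median_point(v, w),
                 weighted_median_oracle(v, w), tolerance = 1e-12)
  }
})

test_that("bootstrap SEs are reproducible under a fixed seed", {
  sim <- simulate_summary_stats(sim_config(n_snps = 12, seed = 4))
  h <- harmonize(select_by_pvalue(sim$exposure, 1e-5), sim$outcome)
  a <- mr_weighted_median(h, n_boot = 200, seed = 99)
  b <- mr_weighted_median(h, n_boot = 200, seed = 99)
  expect_identical(a$se, b$se)
  c1 <- mr_mode(h, weighted = TRUE, n_boot = 100, seed = 7)
  c2 <- mr_mode(h, weighted = TRUE, n_boot = 100, seed = 7)
  expect_identical(c1$se, c2$se)
})

test_that("mode estimators find the dominant ratio cluster", {
  h <- make_h(rep(1, 4), rep(0.01, 4), c(0.5, 0.5, 0.5, 3.0), rep(0.1, 4))
  expect_equal(mr_mode(h, weighted = TRUE, n_boot = 50, seed = 1)$beta, 0.5,
               tolerance = 0.05)

  # equal weights: weighted and simple modes coincide
  hw <- make_h(rep(1, 5), rep(0.01, 5), c(0.2, 0.21, 0.19, 0.8, 0.82),
               rep(0.1, 5))
  expect_equal(mr_mode(hw, weighted = TRUE, n_boot = 50, seed = 2)$beta,
               mr_mode(hw, weighted = FALSE, n_boot = 50, seed = 2)$beta)

  # bimodal ratios: the weighted mode follows the heavier-weighted cluster
  hb <- make_h(c(1, 1, 1, 1), c(0.01, 0.01, 0.01, 0.01),
               c(0.2, 0.2, 1.0, 1.0), c(0.02, 0.02, 0.4, 0.4))
  expect_equal(mr_mode(hb, weighted = TRUE, n_boot = 50, seed = 3)$beta, 0.2,
               tolerance = 0.05)
})

test_that("all five estimators are sign-flip equivariant", {
  sim <- simulate_summary_stats(sim_config(n_snps = 15, seed = 21))
  h <- harmonize(select_by_pvalue(sim$exposure, 1e-5), sim$outcome)
  hf <- h
  hf$gamma <- -hf$gamma   # flipping the exposure allele negates gamma only
  run_all <- function(hh) {
    list(ivw = mr_ivw(hh), egger = mr_egger(hh),
         med = mr_weighted_median(hh, n_boot = 100, seed = 5),
         wm = mr_mode(hh, TRUE, n_boot = 100, seed = 5),
         sm = mr_mode(hh, FALSE, n_boot = 100, seed = 5))
  }
  a <- run_all(h); b <- run_all(hf)
  for (m in names(a)) {
    expect_equal(b[[m]]$beta, -a[[m]]$beta, tolerance = 1e-8, label = m)
  }
  # analytic SEs are exactly invariant; bootstrap SEs carry MC noise
  expect_equal(b$ivw$se, a$ivw$se, tolerance = 1e-12)
  expect_equal(b$egger$se, a$egger$se, tolerance = 1e-10)
})

test_that("Egger is less biased than IVW under directional pleiotropy (InSIDE)", {
  # oriented instruments (all gamma > 0) with a common positive pleiotropic
  # shift: the classic setting where IVW is biased and Egger is not
  truth <- 0.3
  bias <- vapply(1:80, function(s) {
    set.seed(2000 + s)
    J <- 30
    g <- stats::runif(J, 0.08, 0.3)
    seG <- stats::runif(J, 0.01, 0.02)
    alpha <- stats::rnorm(J, 0.03, 0.01)   # directional, InSIDE holds
    G <- truth * g + alpha + stats::rnorm(J, 0, seG)
    h <- make_h(g, rep(0.005, J), G, seG)
    c(mr_ivw(h)$beta, mr_egger(h)$beta)
  }, numeric(2))
  expect_lt(abs(mean(bias[2, ]) - truth), abs(mean(bias[1, ]) - truth))
})

test_that("mr_fit bundles estimators with accessor methods", {
  sim <- simulate_summary_stats(sim_config(n_snps = 15, seed = 8))
  h <- harmonize(select_by_pvalue(sim$exposure, 1e-5), sim$outcome)
  fit <- mr_fit(h, n_boot = 50, seed = 8)
  expect_s3_class(fit, "mr_fit")
  expect_setequal(fit$estimates$method,
                  c("ivw", "egger", "weighted_median", "weighted_mode",
                    "simple_mode"))
  expect_named(coef(fit), fit$estimates$method)
  ci <- confint(fit)
  expect_true(all(ci[, 1] < ci[, 2]))
  expect_length(residuals(fit), nrow(h))
  expect_output(print(fit), "ivw")
  expect_output(print(summary(fit)), "Cochran")
  # OR columns respect the mr_estimate invariant
  expect_equal(fit$estimates$or, exp(fit$estimates$beta))
  expect_true(all(fit$estimates$ci_low <= fit$estimates$or &
                    fit$estimates$or <= fit$estimates$ci_high))
})
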