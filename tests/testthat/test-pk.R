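test_that("a noise-free mono-exponential profile is identified exactly", {
  d <- data.frame(time_h = c(1, 2, 4, 8, 16, 24, 48),
                  conc_mg_per_L = 10 * exp(-0.1 * c(1, 2, 4, 8, 16, 24, 48)))
  fit <- fit_monoexponential(d)
  expect_equal(fit$C0, 10, tolerance = 1e-6)
  expect_equal(fit$k, 0.1, tolerance = 1e-6)
  expect_false(fit$boundary)
  expect_error(fit_monoexponential(d[1:2, ]), "insufficient data")
})

test_that("constant concentrations flag the zero-decay boundary", {
  d <- data.frame(time_h = c(1, 2, 4, 8, 24), conc_mg_per_L = rep(5, 5))
  fit <- fit_monoexponential(d)
  expect_true(fit$boundary)
  expect_equal(fit$C0, 5, tolerance = 1e-3)
})

test_that("mono-exponential rate recovery is nearly unbiased at 5% CV", {
  times <- seq(2, 48, length.out = 10)
  sdlog <- sqrt(log(1 + 0.05^2))
  ks <- vapply(1:20, function(s) {
    set.seed(s)
    d <- data.frame(time_h = times,
                    conc_mg_per_L = 10 * exp(-0.1 * times) *
                      rlnorm(10, -sdlog^2 / 2, sdlog))
    fit_monoexponential(d)$k
  }, numeric(1))
  expect_lt(abs(mean(ks) - 0.1) / 0.1, 0.02)
})

test_that("a noise-free bi-exponential profile is recovered to 4 significant figures", {
  d <- bi_profile()
  fit <- fit_biexponential(d)
  expect_equal(signif(fit$C0a, 4), 76.4)
  expect_equal(signif(fit$C0b, 4), 45.1)
  expect_equal(signif(log(2) / fit$alpha, 4), 5)
  expect_equal(signif(log(2) / fit$beta, 4), 96.3)
  expect_equal(fit$C0, fit$C0a + fit$C0b)
  expect_gt(fit$alpha, fit$beta)
  expect_error(fit_biexponential(d[1:4, ]), "at least 5")
})

test_that("the F-test is computed from the extra sum of squares", {
  mono <- structure(list(model = "mono", C0 = 1, k = 1, rss = 4, n = 10,
                         boundary = FALSE), class = "exp_fit")
  bi_same <- structure(list(model = "bi", C0a = .5, alpha = 2, C0b = .5,
                            beta = 1, C0 = 1, rss = 4, n = 10), class = "exp_fit")
  sel <- extra_ss_f_test(mono, bi_same)
  expect_equal(sel$F, 0)
  expect_equal(sel$p, 1)
  expect_identical(sel$chosen, "mono")
  bi_better <- bi_same; bi_better$rss <- 1
  sel2 <- extra_ss_f_test(mono, bi_better)
  expect_equal(sel2$F, ((4 - 1) / 2) / (1 / 6))
  expect_equal(sel2$p, pf(sel2$F, 2, 6, lower.tail = FALSE))
  small <- mono; small$n <- 4
  bi_small <- bi_same; bi_small$n <- 4
  expect_error(extra_ss_f_test(small, bi_small), "more than 4")
})

test_that("an effectively mono truth collapses the bi fit and mono is selected", {
  times <- c(1, 2, 4, 8, 24, 48, 72, 96, 120, 144)
  picks <- vapply(1:10, function(s) {
    set.seed(s)
    d <- data.frame(time_h = times,
                    conc_mg_per_L = 10 * exp(-0.03 * times) +
                      rnorm(10, 0, 0.1))
    d$conc_mg_per_L <- pmax(d$conc_mg_per_L, 1e-6)
    extra_ss_f_test(fit_monoexponential(d), fit_biexponential(d))$chosen
  }, character(1))
  expect_gte(sum(picks == "mono"), 9)
})

test_that("a clearly two-phase truth is selected by the F-test at 5% CV", {
  times <- c(1, 2, 4, 8, 24, 48, 72, 96, 120, 144)
  mu <- bi_profile()$conc_mg_per_L
  sdlog <- sqrt(log(1 + 0.05^2))
  picks <- vapply(1:40, function(s) {
    set.seed(s)
    d <- data.frame(time_h = times,
                    conc_mg_per_L = mu * rlnorm(10, -sdlog^2 / 2, sdlog))
    extra_ss_f_test(fit_monoexponential(d), fit_biexponential(d))$chosen
  }, character(1))
  expect_gte(mean(picks == "bi"), 0.95)
})

test_that("NCA reproduces the defining identities", {
  # constant concentration 1 mg/L over 0-2 h integrates to 2 mg h/L
  flatfit <- structure(list(model = "mono", C0 = 1, k = 1e-12, rss = 0, n = 2,
                            boundary = TRUE), class = "exp_fit")
  d <- data.frame(time_h = c(1, 2), conc_mg_per_L = c(1, 1))
  res <- nca(d, flatfit, t_end = 2, dose = 1)
  expect_equal(res$AUC, 2)
  # identity chain on a fitted arm
  prof <- bi_profile()
  fit <- fit_biexponential(prof)
  p <- nca(prof, fit, dose = 15)
  expect_equal(p$CL * p$AUC, 15 * 1000, tolerance = 1e-9)
  expect_equal(p$VDss / p$CL, p$MRT, tolerance = 1e-9)
  expect_equal(p$t_half_beta, log(2) / fit$beta, tolerance = 1e-12)
  expect_equal(p$C0, fit$C0a + fit$C0b)
  # model-based MRT equals the moment formula
  expect_equal(p$MRT,
               (fit$C0a / fit$alpha^2 + fit$C0b / fit$beta^2) /
                 (fit$C0a / fit$alpha + fit$C0b / fit$beta))
  expect_equal(log(2) / 0.0071974, 96.305, tolerance = 1e-4)
})

test_that("AUC is additive over a split of the integration range", {
  prof <- bi_profile()
  fit <- fit_biexponential(prof)
  full <- nca(prof, fit, t_end = 144, dose = 15)
  head_ <- nca(prof, fit, t_end = 48, dose = 15)
  sel <- prof$time_h >= 48
  tail_auc <- pracma::trapz(prof$time_h[sel], prof$conc_mg_per_L[sel])
  expect_equal(full$AUC, head_$AUC + tail_auc, tolerance = 1e-9)
})

test_that("doubling concentrations doubles AUC, halves CL and keeps t1/2 beta", {
  prof <- bi_profile()
  prof2 <- prof; prof2$conc_mg_per_L <- 2 * prof$conc_mg_per_L
  f1 <- fit_biexponential(prof); f2 <- fit_biexponential(prof2)
  p1 <- nca(prof, f1, dose = 15); p2 <- nca(prof2, f2, dose = 15)
  expect_equal(p2$AUC, 2 * p1$AUC, tolerance = 1e-6)
  expect_equal(p2$CL, p1$CL / 2, tolerance = 1e-6)
  expect_equal(p2$t_half_beta, p1$t_half_beta, tolerance = 1e-6)
  expect_equal(p2$MRT, p1$MRT, tolerance = 1e-6)
})

test_that("LOQ censoring flags points, truncates the AUC and can starve the fit", {
  d <- pk_dataset("x", dose = 5, time_h = c(1, 2, 4, 8, 24, 48, 72, 96),
                  conc_mg_per_L = c(8, 7, 6, 5, 2, 0.5, 0.1, 0.05), loq = 0.3)
  expect_identical(d$censored, c(rep(FALSE, 6), TRUE, TRUE))
  d_clear <- censor_loq(d, 0.01)
  expect_true(all(!d_clear$censored))
  all_gone <- censor_loq(d, 100)
  expect_error(fit_monoexponential(all_gone), "insufficient data")
  fit <- fit_monoexponential(d)
  expect_warning(nca(d, fit, t_end = 144, dose = 5), "truncated")
  expect_error(censor_loq(d, -1), "positive")
})

test_that("the low-dose parental arm is censored beyond 48 h and resolves to mono", {
  for (s in 1:5) {
    study <- generate_pk_study(generator_config(s))
    arm <- study[["2-DIQMAQ-K @ 5 mg/kg"]]
    gm <- pk_group_mean(arm)
    expect_true(all(gm$censored[gm$time_h > 48]))
    expect_true(all(!gm$censored[gm$time_h <= 48]))
    res <- pk_analyze_arm(arm)
    expect_identical(res$fit$model, "mono")
  }
})

test_that("terminal half-life is recovered within 5% on average from the simulated study", {
  rel_err <- vapply(1:20, function(s) {
    study <- generate_pk_study(generator_config(s))
    fit <- fit_biexponential(pk_group_mean(study[["9-EIVLGE @ 15 mg/kg"]]))
    abs(log(2) / fit$beta - 96.3) / 96.3
  }, numeric(1))
  expect_lt(mean(rel_err), 0.05)
  expect_lt(max(rel_err), 0.12)
})
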