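test_that("the default configuration yields the nine-entry panel", {
  res <- generate_variant_panel(generator_config(1))
  expect_equal(nrow(res$panel), 9)
  expect_identical(vapply(res$regions, `[[`, "", "label"), c("1-4", "66", "79"))
})

test_that("panel size follows the planted mismatch structure", {
  none <- generate_variant_panel(generator_config(1, planted_mutations = character(0)))
  expect_equal(nrow(none$panel), 1)
  four <- generate_variant_panel(generator_config(
    1, planted_mutations = c("9" = "A", "20" = "A", "40" = "T", "70" = "S"),
    include_lysine_parental = FALSE))
  expect_equal(length(four$regions), 4)
  expect_equal(nrow(four$panel), 16)
})

test_that("the same seed reproduces every generated dataset exactly", {
  cfg <- generator_config(123)
  p1 <- generate_variant_panel(cfg); p2 <- generate_variant_panel(cfg)
  s1 <- generate_assay_suite(cfg, p1); s2 <- generate_assay_suite(cfg, p2)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$sensorgrams, s2$sensorgrams)
  expect_identical(s1$melt_curves, s2$melt_curves)
  expect_identical(s1$titers, s2$titers)
  k1 <- generate_pk_study(cfg); k2 <- generate_pk_study(cfg)
  expect_identical(lapply(k1, as.data.frame), lapply(k2, as.data.frame))
})

test_that("generated truths respect the study's effect-size envelope", {
  for (s in 1:5) {
    cfg <- generator_config(s)
    suite <- generate_assay_suite(cfg, generate_variant_panel(cfg))
    tr <- suite$truth
    parental_kd <- tr$KD[tr$name == "DIQMAQ"]
    expect_true(all(pmax(tr$KD / parental_kd, parental_kd / tr$KD) <= 2 + 1e-9))
    expect_true(all(tr$ka[-(1:2)] >= 1.3e5 & tr$ka[-(1:2)] <= 3.1e5))
    expect_true(all(tr$kd[-(1:2)] >= 2.9e-4 & tr$kd[-(1:2)] <= 6.4e-4))
    has66 <- grepl("G", substr(tr$name, 5, 5))
    expect_true(all(tr$titer_fold[has66] >= 3))
    expect_true(all(tr$titer_fold[has66] <= 10))
    expect_true(all(abs(tr$tm - 70) <= 4.5))
  }
})

test_that("with noise switched off the fits recover the planted truths", {
  cfg <- generator_config(3,
                          spr = list(noise_sd = 0),
                          dsf = list(noise_frac = 0),
                          titer = list(cv = 1e-9))
  panel <- generate_variant_panel(cfg)
  suite <- generate_assay_suite(cfg, panel)
  i <- which(suite$truth$name == "EIVLGE")
  fit <- fit_langmuir_1to1(suite$sensorgrams[[i]])
  expect_equal(fit$ka, suite$truth$ka[i], tolerance = 1e-3)
  expect_equal(fit$kd, suite$truth$kd[i], tolerance = 1e-3)
  tm <- extract_tm(suite$melt_curves[[i]])
  expect_equal(tm$tm, suite$truth$tm[i], tolerance = 0.1)
  expect_equal(mean(suite$titers[[i]]), suite$truth$titer_mean[i],
               tolerance = 1e-4)
})

test_that("a noise-free LOQ-free PK study returns the generating half-life", {
  cfg <- generator_config(2, pk = list(cv = 0, loq = NA_real_))
  study <- generate_pk_study(cfg)
  arm <- study[["9-EIVLGE @ 15 mg/kg"]]
  expect_true(all(!arm$censored))
  fit <- fit_biexponential(pk_group_mean(arm))
  p <- nca(pk_group_mean(arm), fit, dose = 15)
  expect_equal(p$t_half_beta, 96.3, tolerance = 1e-4)
  expect_equal(p$C0, 76.4 + 45.1, tolerance = 1e-4)
})

test_that("the generated exposure gain at 30 mg/kg is an order of magnitude", {
  cfg <- generator_config(1)
  truth <- attr(generate_pk_study(cfg), "truth")
  auc_model <- function(row, t_end = 144) {
    beta <- log(2) / row$t_half_beta_h
    alpha <- log(2) / row$t_half_alpha_h
    a <- if (row$model == "mono") 0 else row$C0a_mg_per_L / alpha * (1 - exp(-alpha * t_end))
    a + row$C0b_mg_per_L / beta * (1 - exp(-beta * t_end))
  }
  v30 <- truth[truth$antibody == "9-EIVLGE" & truth$dose_mg_per_kg == 30, ]
  p30 <- truth[truth$antibody == "2-DIQMAQ-K" & truth$dose_mg_per_kg == 30, ]
  expect_gt(auc_model(v30) / auc_model(p30), 10)
})

test_that("the synthetic stability coupling yields a detectable Tm-titer correlation", {
  hits <- vapply(1:20, function(s) {
    cfg <- generator_config(s)
    suite <- generate_assay_suite(cfg, generate_variant_panel(cfg))
    tm <- vapply(suite$melt_curves, function(m) extract_tm(m)$tm, numeric(1))
    titer <- vapply(suite$titers, mean, numeric(1))
    spearman_tm_titer(data.frame(tm = tm, titer = titer))$p < 0.05
  }, logical(1))
  expect_gt(mean(hits), 0.5)
})
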