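#' Construct a plasma concentration-time dataset
#'
#' @param antibody antibody identifier.
#' @param dose dose, mg/kg.
#' @param time_h sampling times, h (>= 0, increasing within animal).
#' @param conc_mg_per_L plasma concentrations, mg/L.
#' @param animal_id animal identifier per row (default one group profile).
#' @param body_weight_kg body weight, kg (default 0.030, mouse).
#' @param loq assay limit of quantification, mg/L (`NA` for none).
#' @return Data frame (class `pk_dataset`) with a logical `censored` column
#'   and attributes `antibody`, `dose`, `body_weight_kg`, `loq`.
#' @export
pk_dataset <- function(antibody, dose, time_h, conc_mg_per_L,
                       animal_id = 1L, body_weight_kg = 0.030, loq = NA_real_) {
  if (any(time_h < 0)) stop("times must be >= 0")
  d <- data.frame(animal_id = animal_id, dose_mg_per_kg = dose,
                  time_h = time_h, conc_mg_per_L = conc_mg_per_L,
                  censored = FALSE)
  d <- structure(d, class = c("pk_dataset", "data.frame"),
                 antibody = antibody, dose = dose,
                 body_weight_kg = body_weight_kg, loq = loq)
  if (is.finite(loq)) d <- censor_loq(d, loq) else d
}

#' Flag concentrations below the limit of quantification
#'
#' Points below `loq` are flagged censored and excluded from all fitting; when
#' fewer than 5 uncensored points remain, downstream model selection must fall
#' back to the mono-exponential fit (the bi-exponential fit requires >= 5
#' points).
#'
#' @param data a [pk_dataset()] or data frame with columns `time_h`,
#'   `conc_mg_per_L`.
#' @param loq limit of quantification, mg/L (> 0).
#' @return The dataset with its `censored` column updated and attribute `loq`
#'   set.
#' @export
censor_loq <- function(data, loq) {
  if (!is.finite(loq) || loq <= 0) stop("loq must be positive")
  data$censored <- data$conc_mg_per_L < loq
  attr(data, "loq") <- loq
  data
}

uncensored_profile <- function(data) {
  keep <- if ("censored" %in% names(data)) !data$censored else rep(TRUE, nrow(data))
  d <- data[keep, c("time_h", "conc_mg_per_L")]
  d[order(d$time_h), ]
}

#' Average animals into a group-mean profile
#'
#' Mean concentration across animals at each sampling time (the presentation
#' used for group PK curves), re-censored against the dataset LOQ when one is
#' set.
#'
#' @param data a [pk_dataset()].
#' @return A `pk_dataset` with one row per time point.
#' @export
pk_group_mean <- function(data) {
  agg <- stats::aggregate(conc_mg_per_L ~ time_h, data = data, FUN = mean)
  pk_dataset(antibody = attr(data, "antibody") %||% "group",
             dose = attr(data, "dose") %||% unique(data$dose_mg_per_kg)[1],
             time_h = agg$time_h, conc_mg_per_L = agg$conc_mg_per_L,
             body_weight_kg = attr(data, "body_weight_kg") %||% 0.030,
             loq = attr(data, "loq") %||% NA_real_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit a mono-exponential (one-compartment) plasma decay
#'
#' Least-squares fit of C(t) = C0 e^(-k t) on the linear concentration scale,
#' initialized by log-linear regression. Censored points are excluded.
#'
#' @param data a [pk_dataset()] or data frame with `time_h`, `conc_mg_per_L`.
#' @return An `exp_fit` list: `model = "mono"`, `C0`, `k`, `rss`, `n`,
#'   `boundary` (`TRUE` when k collapsed to the zero-decay boundary).
#' @export
fit_monoexponential <- function(data) {
  d <- uncensored_profile(data)
  if (nrow(d) < 3) stop("insufficient data: at least 3 uncensored points are required")
  if (any(d$conc_mg_per_L <= 0)) stop("uncensored concentrations must be positive")
  ll <- stats::lm(log(conc_mg_per_L) ~ time_h, data = d)
  k0 <- max(-stats::coef(ll)[[2]], 1e-8)
  c00 <- exp(stats::coef(ll)[[1]])
  fit <- tryCatch(
    minpack.lm::nlsLM(
      conc_mg_per_L ~ exp(lC0) * exp(-exp(lk) * time_h), data = d,
      start = list(lC0 = log(c00), lk = log(k0)),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    # degenerate profile (no measurable decay): keep the log-linear estimates
    C0 <- mean(d$conc_mg_per_L)
    return(structure(list(model = "mono", C0 = C0, k = k0,
                          rss = sum((d$conc_mg_per_L - C0 * exp(-k0 * d$time_h))^2),
                          n = nrow(d), boundary = TRUE),
                     class = "exp_fit"))
  }
  cf <- stats::coef(fit)
  k <- exp(cf[["lk"]])
  structure(list(model = "mono", C0 = exp(cf[["lC0"]]), k = k,
                 rss = sum(stats::residuals(fit)^2), n = nrow(d),
                 boundary = k < 1e-6),
            class = "exp_fit")
}

## curve peeling: terminal log-linear regression, then log-linear fit of the
## positive early-phase residuals
peel_init <- function(d) {
  n <- nrow(d)
  tail_idx <- seq.int(max(3L, n - max(3L, n %/% 2) + 1L), n)
  tail_fit <- stats::lm(log(conc_mg_per_L) ~ time_h, data = d[tail_idx, ])
  beta0 <- max(-stats::coef(tail_fit)[[2]], 1e-6)
  B0 <- exp(stats::coef(tail_fit)[[1]])
  resid <- d$conc_mg_per_L - B0 * exp(-beta0 * d$time_h)
  early <- resid > 0 & seq_len(n) < min(tail_idx)
  if (sum(early) >= 2) {
    pf_ <- stats::lm(log(resid[early]) ~ d$time_h[early])
    alpha0 <- max(-stats::coef(pf_)[[2]], beta0 * 1.5)
    A0 <- exp(stats::coef(pf_)[[1]])
  } else {
    alpha0 <- beta0 * 5
    A0 <- max(d$conc_mg_per_L[1] - B0, 0.1 * B0)
  }
  list(A = A0, B = B0, alpha = alpha0, beta = beta0)
}

## Profiled amplitude solve for fixed rates (a1 > a2): exact linear least
## squares; under the positivity constraint the better feasible boundary
## solution replaces an infeasible interior one.
bi_amplitudes <- function(X, y, constrain) {
  fit <- stats::.lm.fit(X, y)
  cf <- fit$coefficients
  if (!constrain || all(cf >= 0)) {
    return(list(A = cf[1], B = cf[2], rss = sum(fit$residuals^2)))
  }
  cand <- list()
  for (j in 1:2) {
    c1 <- sum(X[, j] * y) / sum(X[, j]^2)
    if (c1 >= 0) {
      cf1 <- c(0, 0); cf1[j] <- c1
      cand[[length(cand) + 1]] <- list(A = cf1[1], B = cf1[2],
                                       rss = sum((y - X %*% cf1)^2))
    }
  }
  cand[[length(cand) + 1]] <- list(A = 0, B = 0, rss = sum(y^2))
  cand[[which.min(vapply(cand, `[[`, 0, "rss"))]]
}

## Global search for the bi-exponential least-squares optimum: exhaustive rate
## grid with profiled amplitudes, then a Levenberg-Marquardt polish started
## from the grid optimum and from the curve-peeling estimates.
bi_global_fit <- function(d, constrain) {
  t <- d$time_h; y <- d$conc_mg_per_L
  ll <- stats::lm(log(y) ~ t)
  k0 <- max(-stats::coef(ll)[[2]], 1e-4)
  rates <- exp(seq(log(k0 / 30), log(max(5, 20 * k0)), length.out = 26))
  best <- list(rss = Inf)
  for (i in seq_along(rates)) {
    for (j in seq_len(i - 1)) {
      X <- cbind(exp(-rates[i] * t), exp(-rates[j] * t))
      sol <- bi_amplitudes(X, y, constrain)
      if (sol$rss < best$rss) {
        best <- c(sol, list(alpha = rates[i], beta = rates[j]))
      }
    }
  }
  peel <- peel_init(d)
  starts <- list(best,
                 list(A = peel$A, B = peel$B, alpha = peel$alpha,
                      beta = peel$beta))
  for (st in starts) {
    polish <- tryCatch({
      if (constrain) {
        f <- minpack.lm::nlsLM(
          conc_mg_per_L ~ exp(lA) * exp(-(exp(lb) + exp(ld)) * time_h) +
            exp(lB) * exp(-exp(lb) * time_h),
          data = d,
          start = list(lA = log(max(st$A, 1e-10)), lB = log(max(st$B, 1e-10)),
                       lb = log(max(st$beta, 1e-8)),
                       ld = log(max(st$alpha - st$beta, 1e-3 * st$beta))),
          control = minpack.lm::nls.lm.control(maxiter = 500))
        cf <- stats::coef(f)
        list(A = exp(cf[["lA"]]), B = exp(cf[["lB"]]),
             beta = exp(cf[["lb"]]),
             alpha = exp(cf[["lb"]]) + exp(cf[["ld"]]),
             rss = sum(stats::residuals(f)^2))
      } else {
        f <- minpack.lm::nlsLM(
          conc_mg_per_L ~ A * exp(-(exp(lb) + exp(ld)) * time_h) +
            B * exp(-exp(lb) * time_h),
          data = d,
          start = list(A = st$A, B = st$B, lb = log(max(st$beta, 1e-8)),
                       ld = log(max(st$alpha - st$beta, 1e-3 * st$beta))),
          control = minpack.lm::nls.lm.control(maxiter = 500))
        cf <- stats::coef(f)
        list(A = cf[["A"]], B = cf[["B"]],
             beta = exp(cf[["lb"]]),
             alpha = exp(cf[["lb"]]) + exp(cf[["ld"]]),
             rss = sum(stats::residuals(f)^2))
      }
    }, error = function(e) NULL)
    if (!is.null(polish) && polish$rss < best$rss) best <- polish
  }
  if (!is.finite(best$rss)) stop("bi-exponential fit did not converge")
  best
}

#' Fit a bi-exponential (two-compartment) plasma decay
#'
#' Least-squares fit of C(t) = C0a e^(-alpha t) + C0b e^(-beta t) with
#' alpha > beta > 0. The optimum is located by an exhaustive rate grid with
#' exactly profiled amplitudes, then polished by Levenberg-Marquardt (also
#' started from curve-peeling estimates: terminal log-linear regression
#' followed by a log-linear fit of the early-phase residuals). Censored
#' points are excluded.
#'
#' With `constrain_positive = TRUE` (default) both amplitudes are restricted
#' to be non-negative, the physically meaningful two-compartment solution
#' after an intravenous bolus. `constrain_positive = FALSE` fits the
#' unconstrained nested family, the variant under which the
#' extra-sum-of-squares F-test attains its nominal size; the constrained fit
#' makes the test conservative when the truth is mono-exponential.
#'
#' @param data a [pk_dataset()] or data frame with `time_h`, `conc_mg_per_L`.
#' @param constrain_positive restrict amplitudes to be non-negative.
#' @return An `exp_fit` list: `model = "bi"`, `C0a`, `alpha`, `C0b`, `beta`,
#'   `C0` (= C0a + C0b), `rss`, `n`.
#' @export
fit_biexponential <- function(data, constrain_positive = TRUE) {
  d <- uncensored_profile(data)
  if (nrow(d) < 5) stop("insufficient data: at least 5 uncensored points are required")
  if (any(d$conc_mg_per_L <= 0)) stop("uncensored concentrations must be positive")
  best <- bi_global_fit(d, constrain = constrain_positive)
  A <- if (constrain_positive) max(best$A, 1e-12) else best$A
  B <- if (constrain_positive) max(best$B, 1e-12) else best$B
  structure(list(model = "bi",
                 C0a = A, alpha = best$alpha,
                 C0b = B, beta = best$beta,
                 C0 = A + B,
                 rss = best$rss, n = nrow(d)),
            class = "exp_fit")
}

#' @export
print.exp_fit <- function(x, ...) {
  if (x$model == "mono") {
    cat(sprintf("<exp_fit mono> C0 = %.3g mg/L, k = %.4g 1/h (t1/2 %.1f h), RSS %.3g, n %d\n",
                x$C0, x$k, log(2) / x$k, x$rss, x$n))
  } else {
    cat(sprintf("<exp_fit bi> C0a = %.3g, alpha = %.4g; C0b = %.3g, beta = %.4g (t1/2b %.1f h), RSS %.3g, n %d\n",
                x$C0a, x$alpha, x$C0b, x$beta, log(2) / x$beta, x$rss, x$n))
  }
  invisible(x)
}

#' Extra-sum-of-squares F-test between nested decay models
#'
#' F = ((SS_mono - SS_bi)/2) / (SS_bi/(n - 4)), referred to F(2, n-4); the
#' bi-exponential model is chosen iff p < alpha. A bi-exponential fit that
#' fails to improve on the mono fit yields F = 0.
#'
#' @param mono,bi `exp_fit` objects fitted to the same data.
#' @param alpha significance level (default 0.05).
#' @return A `model_selection` list: `F`, `p`, `chosen` (`"mono"`/`"bi"`),
#'   `df` (= c(2, n-4)).
#' @export
extra_ss_f_test <- function(mono, bi, alpha = 0.05) {
  stopifnot(mono$model == "mono", bi$model == "bi")
  if (mono$n != bi$n) stop("fits are not on the same data")
  n <- bi$n
  if (n <= 4) stop("F-test requires more than 4 points")
  Fstat <- max(0, ((mono$rss - bi$rss) / 2) / (bi$rss / (n - 4)))
  p <- stats::pf(Fstat, 2, n - 4, lower.tail = FALSE)
  structure(list(F = Fstat, p = p,
                 chosen = if (p < alpha) "bi" else "mono",
                 df = c(2, n - 4)),
            class = "model_selection")
}

#' Non-compartmental analysis of a plasma decay
#'
#' AUC by the trapezoidal rule over the observed (uncensored) points from 0 to
#' `t_end`, with the fitted model value anchoring C(0); CL = dose/AUC scaled
#' to mL/h/kg; t1/2,beta = ln 2 / beta. MRT defaults to the model-based
#' moments (C0a/alpha^2 + C0b/beta^2)/(C0a/alpha + C0b/beta) (1/k for a
#' mono fit); `mrt_method = "trapezoid"` uses AUMC/AUC from the observed
#' moments instead. V_D,ss = CL x MRT.
#'
#' @param data a [pk_dataset()] (or data frame with `time_h`,
#'   `conc_mg_per_L`, optional `censored`).
#' @param fit an `exp_fit` for the same profile.
#' @param t_end AUC upper limit, h (default 144).
#' @param dose dose, mg/kg; taken from the dataset attribute when present.
#' @param mrt_method `"model"` (default) or `"trapezoid"`.
#' @return A `pk_parameters` list: `C0` (mg/L), `t_half_beta` (h), `AUC`
#'   (mg h/L), `AUMC` (mg h^2/L), `MRT` (h), `CL` (mL/h/kg), `VDss` (mL/kg),
#'   `t_last` (h).
#' @export
nca <- function(data, fit, t_end = 144, dose = attr(data, "dose"),
                mrt_method = c("model", "trapezoid")) {
  mrt_method <- match.arg(mrt_method)
  if (is.null(dose)) stop("dose (mg/kg) is required")
  d <- uncensored_profile(data)
  if (nrow(d) < 2) stop("empty fit: no uncensored profile to integrate")
  c0 <- if (fit$model == "mono") fit$C0 else fit$C0a + fit$C0b
  tt <- c(0, d$time_h)
  cc <- c(c0, d$conc_mg_per_L)
  if (max(tt) < t_end) {
    warning(sprintf("profile censored beyond %g h; AUC truncated at the last uncensored point",
                    max(tt)))
    t_end <- max(tt)
  }
  keep <- tt <= t_end
  if (max(tt[keep]) < t_end) {
    cut <- stats::approx(tt, cc, xout = t_end)$y
    tt <- c(tt[keep], t_end); cc <- c(cc[keep], cut)
  } else {
    tt <- tt[keep]; cc <- cc[keep]
  }
  auc <- pracma::trapz(tt, cc)
  aumc <- pracma::trapz(tt, tt * cc)
  beta <- if (fit$model == "mono") fit$k else fit$beta
  mrt <- if (mrt_method == "trapezoid") aumc / auc
         else if (fit$model == "mono") 1 / fit$k
         else (fit$C0a / fit$alpha^2 + fit$C0b / fit$beta^2) /
              (fit$C0a / fit$alpha + fit$C0b / fit$beta)
  cl <- dose / auc * 1000
  structure(list(C0 = c0, t_half_beta = log(2) / beta, AUC = auc, AUMC = aumc,
                 MRT = mrt, CL = cl, VDss = cl * mrt, t_last = max(tt),
                 dose = dose, mrt_method = mrt_method),
            class = "pk_parameters")
}

#' @export
print.pk_parameters <- function(x, ...) {
  cat(sprintf(
    "<pk_parameters> dose %g mg/kg: C0 %.1f mg/L, AUC(0-%g) %.1f mg h/L, CL %.2f mL/h/kg, t1/2b %.1f h, MRT %.1f h (%s), VDss %.0f mL/kg\n",
    x$dose, x$C0, x$t_last, x$AUC, x$CL, x$t_half_beta, x$MRT, x$mrt_method,
    x$VDss))
  invisible(x)
}

#' Fit, select and summarize one PK arm
#'
#' Group-means the profile, fits the mono-exponential always and the
#' bi-exponential when at least 5 uncensored points remain, selects between
#' them by the extra-sum-of-squares F-test, and runs [nca()] on the selected
#' model.
#'
#' @param data a [pk_dataset()].
#' @param t_end AUC upper limit, h.
#' @param alpha F-test significance level.
#' @return List with `fit_mono`, `fit_bi` (or `NULL`), `selection` (or `NULL`
#'   when the mono fallback was forced), `fit` (selected), `nca`.
#' @export
pk_analyze_arm <- function(data, t_end = 144, alpha = 0.05) {
  prof <- pk_group_mean(data)
  mono <- fit_monoexponential(prof)
  n_unc <- sum(!prof$censored)
  bi <- NULL; sel <- NULL
  if (n_unc >= 5) {
    bi <- tryCatch(fit_biexponential(prof), error = function(e) NULL)
  }
  if (!is.null(bi)) {
    sel <- extra_ss_f_test(mono, bi, alpha = alpha)
    fit <- if (sel$chosen == "bi") bi else mono
  } else {
    fit <- mono
  }
  res <- suppressWarnings(nca(prof, fit, t_end = t_end))
  list(fit_mono = mono, fit_bi = bi, selection = sel, fit = fit, nca = res,
       n_uncensored = n_unc)
}
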