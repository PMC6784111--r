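## 1:1 Langmuir association/dissociation response at time t for one analyte
## concentration. t_stop separates the two phases.
langmuir_response <- function(t, ka, kd, Rmax, conc, t_stop) {
  kobs <- conc * ka + kd
  req <- Rmax * conc * ka / kobs
  r_assoc <- req * (1 - exp(-kobs * pmin(t, t_stop)))
  r_stop <- req * (1 - exp(-kobs * t_stop))
  ifelse(t <= t_stop, r_assoc, r_stop * exp(-kd * (t - t_stop)))
}

#' Simulate 1:1 Langmuir SPR sensorgrams
#'
#' Association follows R(t) = Rmax C ka/(C ka + kd) (1 - e^-(C ka + kd) t) and
#' dissociation decays from the injection-stop response with rate kd; Gaussian
#' noise is added on the response.
#'
#' @param ka association rate, 1/(M s).
#' @param kd dissociation rate, 1/s.
#' @param Rmax surface capacity, RU.
#' @param concentrations analyte concentrations, M.
#' @param times sampling times, s (must cover both phases).
#' @param t_stop injection stop (association end), s.
#' @param noise_sd Gaussian noise standard deviation, RU.
#' @param seed optional integer seed.
#' @return Data frame (class `sensorgram_set`) with columns `time_s`,
#'   `response_RU`, `conc_M`, `phase` (`"association"`/`"dissociation"`), and
#'   attributes `t_stop` and `truth` (the generating parameters).
#' @export
simulate_sensorgram <- function(ka, kd, Rmax, concentrations,
                                times = seq(0, 600, by = 2), t_stop = 300,
                                noise_sd = 0.5, seed = NULL) {
  if (ka <= 0 || kd <= 0 || Rmax <= 0) stop("rate constants and Rmax must be positive")
  if (any(concentrations <= 0)) stop("analyte concentrations must be positive")
  if (is.unsorted(times, strictly = TRUE)) stop("times must be strictly increasing")
  if (max(times) <= t_stop) stop("times must cover the dissociation phase")
  if (!is.null(seed)) set.seed(seed)
  out <- do.call(rbind, lapply(concentrations, function(conc) {
    r <- langmuir_response(times, ka, kd, Rmax, conc, t_stop)
    data.frame(time_s = times,
               response_RU = r + stats::rnorm(length(times), 0, noise_sd),
               conc_M = conc,
               phase = ifelse(times <= t_stop, "association", "dissociation"),
               stringsAsFactors = FALSE)
  }))
  structure(out, class = c("sensorgram_set", "data.frame"),
            t_stop = t_stop, truth = list(ka = ka, kd = kd, Rmax = Rmax))
}

## Deterministic initial estimates: kd from a log-linear fit to the
## dissociation tail of the highest concentration; Rmax and KD from a
## double-reciprocal regression of the near-plateau association responses.
langmuir_init <- function(data, t_stop) {
  hi <- data[data$conc_M == max(data$conc_M) & data$phase == "dissociation", ]
  hi <- hi[hi$response_RU > 0, ]
  kd0 <- if (nrow(hi) >= 3) {
    max(1e-6, -stats::coef(stats::lm(log(response_RU) ~ time_s, data = hi))[[2]])
  } else 1e-3
  plateau <- vapply(split(data, data$conc_M), function(d) {
    a <- d[d$phase == "association", ]
    mean(utils::tail(a$response_RU, max(3L, nrow(a) %/% 10)))
  }, numeric(1))
  concs <- as.numeric(names(plateau))
  keep <- plateau > 0
  if (sum(keep) >= 2) {
    fit <- stats::lm(I(1 / plateau[keep]) ~ I(1 / concs[keep]))
    rmax0 <- 1 / stats::coef(fit)[[1]]
    kD0 <- stats::coef(fit)[[2]] * rmax0
    if (!is.finite(rmax0) || rmax0 <= 0) rmax0 <- max(data$response_RU)
    if (!is.finite(kD0) || kD0 <= 0) kD0 <- stats::median(concs)
  } else {
    rmax0 <- max(data$response_RU)
    kD0 <- stats::median(concs)
  }
  list(ka = kd0 / kD0, kd = kd0, Rmax = rmax0)
}

#' Globally fit the 1:1 Langmuir model to sensorgrams
#'
#' Least-squares fit of shared ka, kd and Rmax across all analyte
#' concentrations (log-parameterized to enforce positivity), initialized from
#' a dissociation-phase log-linear regression and an equilibrium-plateau
#' double-reciprocal regression.
#'
#' @param data a [simulate_sensorgram()] frame or any data frame with columns
#'   `time_s`, `response_RU`, `conc_M`, `phase`.
#' @param t_stop injection stop time; taken from the data attribute when
#'   present.
#' @return A `kinetic_fit` list: `ka`, `kd`, `Rmax`, `KD` (= kd/ka), `rss`,
#'   `n`, `converged`.
#' @export
fit_langmuir_1to1 <- function(data, t_stop = attr(data, "t_stop")) {
  stopifnot(all(c("time_s", "response_RU", "conc_M", "phase") %in% names(data)))
  if (length(unique(data$conc_M)) < 2) stop("at least 2 analyte concentrations are required")
  if (is.null(t_stop)) t_stop <- max(data$time_s[data$phase == "association"])
  init <- langmuir_init(data, t_stop)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      response_RU ~ langmuir_response(time_s, exp(lka), exp(lkd), exp(lRmax),
                                      conc_M, t_stop),
      data = data,
      start = list(lka = log(init$ka), lkd = log(init$kd), lRmax = log(init$Rmax)),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) {
      stop(sprintf("Langmuir fit failed (last iterate ka=%.3g, kd=%.3g, Rmax=%.3g): %s",
                   init$ka, init$kd, init$Rmax, conditionMessage(e)))
    }
  )
  cf <- exp(stats::coef(fit))
  structure(list(ka = cf[["lka"]], kd = cf[["lkd"]], Rmax = cf[["lRmax"]],
                 KD = cf[["lkd"]] / cf[["lka"]],
                 rss = sum(stats::residuals(fit)^2), n = nrow(data),
                 converged = TRUE),
            class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf("<kinetic_fit> ka = %.3g 1/(M s), kd = %.3g 1/s, KD = %.3g M, Rmax = %.1f RU (RSS %.3g, n %d)\n",
              x$ka, x$kd, x$KD, x$Rmax, x$rss, x$n))
  invisible(x)
}

#' Read sensorgrams from a delimited table
#'
#' @param path tab- or comma-delimited file with columns `time_s`,
#'   `response_RU`, `conc_M`, `phase`.
#' @param t_stop injection stop time; inferred from the last association
#'   sample when omitted.
#' @return A `sensorgram_set` data frame.
#' @export
read_sensorgrams <- function(path, t_stop = NULL) {
  d <- utils::read.delim(path, sep = "", header = TRUE)
  stopifnot(all(c("time_s", "response_RU", "conc_M", "phase") %in% names(d)))
  if (is.null(t_stop)) t_stop <- max(d$time_s[d$phase == "association"])
  structure(d, class = c("sensorgram_set", "data.frame"), t_stop = t_stop)
}
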