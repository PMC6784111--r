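two_state_sigmoid <- function(T, tm, slope, pre, post) {
  f <- 1 / (1 + exp((tm - T) / slope))
  (pre[1] + pre[2] * T) + ((post[1] + post[2] * T) - (pre[1] + pre[2] * T)) * f
}

#' Simulate a thermal-shift (DSF) melt curve
#'
#' One transition uses the two-state form
#' F(T) = (a0 + a1 T) + (b0 + b1 T - a0 - a1 T) / (1 + e^((tm - T)/slope));
#' several transitions are built as the pre-baseline plus a sum of logistic
#' steps with the given amplitudes.
#'
#' @param tm transition midpoint(s), deg C; must lie inside the grid.
#' @param slope transition width(s), deg C (> 0), recycled over `tm`.
#' @param pre pre-transition baseline `c(a0, a1)`.
#' @param post post-transition baseline `c(b0, b1)` (single transition only).
#' @param amplitudes per-transition fluorescence step heights (required when
#'   `length(tm) > 1`; for a single transition they are implied by `post`).
#' @param grid temperature grid, deg C, strictly increasing, spacing <= 1.
#' @param noise_sd Gaussian noise sd (fluorescence units).
#' @param seed optional integer seed.
#' @return Data frame (class `melt_curve`) with columns `temp_C`,
#'   `fluorescence`; generating parameters in attribute `truth`.
#' @export
simulate_melt_curve <- function(tm, slope = 1.5, pre = c(1000, 0),
                                post = c(6000, 0), amplitudes = NULL,
                                grid = seq(25, 95, by = 0.5),
                                noise_sd = 0, seed = NULL) {
  if (any(slope <= 0)) stop("slope must be positive")
  if (is.unsorted(grid, strictly = TRUE)) stop("temperature grid must be strictly increasing")
  if (max(diff(grid)) > 1 + 1e-9) stop("temperature grid spacing must be <= 1 deg C")
  if (any(tm <= min(grid)) || any(tm >= max(grid))) stop("tm outside the temperature grid")
  if (!is.null(seed)) set.seed(seed)
  slope <- rep_len(slope, length(tm))
  if (length(tm) == 1) {
    f <- two_state_sigmoid(grid, tm, slope, pre, post)
  } else {
    if (is.null(amplitudes)) stop("amplitudes are required for multiple transitions")
    amplitudes <- rep_len(amplitudes, length(tm))
    f <- pre[1] + pre[2] * grid
    for (i in seq_along(tm)) {
      f <- f + amplitudes[i] / (1 + exp((tm[i] - grid) / slope[i]))
    }
  }
  structure(data.frame(temp_C = grid, fluorescence = f +
                         stats::rnorm(length(grid), 0, noise_sd)),
            class = c("melt_curve", "data.frame"),
            truth = list(tm = tm, slope = slope, pre = pre, post = post,
                         amplitudes = amplitudes))
}

## Savitzky-Golay smoothed first derivative dF/dT on an evenly spaced grid.
smoothed_derivative <- function(temp, fluor, window = 11L, degree = 3L) {
  h <- stats::median(diff(temp))
  window <- min(window, if (length(fluor) %% 2 == 0) length(fluor) - 1 else length(fluor))
  if (window %% 2 == 0) window <- window - 1L
  sm <- signal::sgolayfilt(fluor, p = min(degree, window - 1L), n = window)
  d <- c(NA, diff(sm, lag = 2) / (2 * h), NA)  # central differences
  list(smooth = sm, deriv = d, h = h)
}

## parabolic (three-point) interpolation of a discrete peak apex
parabolic_peak <- function(x, y, i) {
  if (i <= 1 || i >= length(x)) return(x[i])
  denom <- y[i - 1] - 2 * y[i] + y[i + 1]
  if (denom >= 0) return(x[i])
  x[i] + 0.5 * (y[i - 1] - y[i + 1]) / denom * (x[i + 1] - x[i])
}

#' Extract the melting temperature from a melt curve
#'
#' The default `derivative` method reports the temperature of the first
#' (lowest-temperature) local maximum of the smoothed dF/dT that qualifies as
#' a transition; the apex is refined by three-point parabolic interpolation.
#' A peak qualifies when its height reaches `threshold` times the global
#' derivative maximum and stands clear of the derivative noise floor. The
#' `sigmoid-fit` method refits the two-state model inside a window around the
#' first qualifying derivative peak.
#'
#' @param curve a [simulate_melt_curve()] frame or data frame with columns
#'   `temp_C`, `fluorescence` (>= 20 grid points).
#' @param method `"derivative"` (default) or `"sigmoid-fit"`.
#' @param threshold qualifying fraction of the global derivative maximum
#'   (default 0.1).
#' @param snr minimum ratio of peak height to the derivative noise floor
#'   (median absolute derivative), guarding against flat curves.
#' @param window smoothing window, odd number of grid points (default 15).
#' @return A `tm_result` list: `tm`, `method`, `amplitude` (fluorescence rise
#'   across the transition), `peak_height`.
#' @export
extract_tm <- function(curve, method = c("derivative", "sigmoid-fit"),
                       threshold = 0.1, snr = 5, window = 15L) {
  method <- match.arg(method)
  stopifnot(all(c("temp_C", "fluorescence") %in% names(curve)))
  if (nrow(curve) < 20) stop("at least 20 grid points are required")
  temp <- curve$temp_C
  sd_ <- smoothed_derivative(temp, curve$fluorescence, window = window)
  d <- sd_$deriv
  inner <- which(!is.na(d))
  peaks <- inner[which(diff(sign(diff(d[inner]))) == -2) + 1]
  gmax <- max(d[inner])
  floor_ <- stats::median(abs(d[inner]), na.rm = TRUE)
  qualifying <- peaks[d[peaks] > 0 &
                        d[peaks] >= threshold * gmax &
                        d[peaks] >= snr * max(floor_, .Machine$double.eps)]
  if (length(qualifying) == 0 || gmax <= 0) {
    stop("no qualifying unfolding transition found")
  }
  i <- qualifying[1]
  tm_hat <- parabolic_peak(temp, d, i)
  # transition amplitude: fluorescence rise across ~4 widths around the peak
  lo <- max(min(temp), tm_hat - 8); hi <- min(max(temp), tm_hat + 8)
  amp <- diff(range(sd_$smooth[temp >= lo & temp <= hi]))
  if (method == "sigmoid-fit") {
    win <- temp >= lo & temp <= hi
    dat <- data.frame(T = temp[win], F = curve$fluorescence[win])
    fit <- tryCatch(
      minpack.lm::nlsLM(
        F ~ a0 + (b0 - a0) / (1 + exp((tm - T) / exp(lslope))),
        data = dat,
        start = list(a0 = min(dat$F), b0 = max(dat$F), tm = tm_hat,
                     lslope = log(1.5)),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) stop("sigmoid fit failed: ", conditionMessage(e)))
    tm_hat <- stats::coef(fit)[["tm"]]
    amp <- stats::coef(fit)[["b0"]] - stats::coef(fit)[["a0"]]
  }
  if (tm_hat <= min(temp) || tm_hat >= max(temp)) {
    stop("no qualifying unfolding transition inside the grid")
  }
  structure(list(tm = tm_hat, method = method, amplitude = amp,
                 peak_height = d[i]),
            class = "tm_result")
}

#' @export
print.tm_result <- function(x, ...) {
  cat(sprintf("<tm_result> Tm = %.2f degC (%s method, amplitude %.3g)\n",
              x$tm, x$method, x$amplitude))
  invisible(x)
}

#' Melting-point shift between a variant and its parental antibody
#'
#' @param variant,parental `tm_result` objects produced with the same method.
#' @return Tm difference variant - parental, deg C.
#' @export
delta_tm <- function(variant, parental) {
  stopifnot(inherits(variant, "tm_result"), inherits(parental, "tm_result"))
  if (variant$method != parental$method) {
    stop("Tm estimates were produced with different methods")
  }
  variant$tm - parental$tm
}
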