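SEC_SPECIES <- c("aggregate", "dimer", "monomer", "fragment")

#' Simulate an SE-HPLC chromatogram
#'
#' Sum of Gaussian peaks (one per species, in elution order aggregate < dimer
#' < monomer < fragment) over a linear baseline, with Gaussian noise. Peak
#' areas are the planted truth and are recorded alongside the trace.
#'
#' @param areas named numeric vector of peak areas (mAU min) for a subset of
#'   `aggregate`, `dimer`, `monomer`, `fragment`.
#' @param retention named numeric vector of retention times (min) for the same
#'   species.
#' @param widths Gaussian sigma per species, min (recycled).
#' @param baseline `c(intercept, slope)` in mAU and mAU/min.
#' @param times elution-time grid, min.
#' @param noise_sd Gaussian noise sd, mAU.
#' @param seed optional integer seed.
#' @return Data frame (class `chromatogram`) with columns `time_min`, `mAU`;
#'   attributes `truth` (areas and fractions) and `retention`.
#' @export
simulate_chromatogram <- function(areas, retention, widths = 0.12,
                                  baseline = c(0, 0),
                                  times = seq(4, 14, by = 0.01),
                                  noise_sd = 0, seed = NULL) {
  sp <- names(areas)
  stopifnot(!is.null(sp), all(sp %in% SEC_SPECIES), all(sp %in% names(retention)))
  retention <- retention[sp]
  ord <- SEC_SPECIES[SEC_SPECIES %in% sp]
  if (any(diff(retention[ord]) <= 0)) {
    stop("retention order must be aggregate < dimer < monomer < fragment")
  }
  widths <- rep_len(widths, length(sp))
  if (any(widths <= 0)) stop("peak widths must be positive")
  names(widths) <- sp
  if (!is.null(seed)) set.seed(seed)
  y <- baseline[1] + baseline[2] * times
  for (s in sp) y <- y + areas[[s]] * stats::dnorm(times, retention[[s]], widths[[s]])
  y <- y + stats::rnorm(length(times), 0, noise_sd)
  structure(data.frame(time_min = times, mAU = y),
            class = c("chromatogram", "data.frame"),
            truth = list(areas = areas, fractions = areas / sum(areas)),
            retention = retention)
}

#' Quantify species fractions from a chromatogram
#'
#' Fits a linear baseline to the configured blank regions, integrates the
#' baseline-subtracted trace by the trapezoidal rule inside each retention
#' window, and normalizes the areas to fractions.
#'
#' @param trace data frame with columns `time_min`, `mAU`.
#' @param windows named list of `c(from, to)` retention windows (min), ordered
#'   and non-overlapping, named by species.
#' @param blank list of `c(from, to)` regions used for the baseline fit;
#'   defaults to the leading and trailing 5% of the trace.
#' @return A `species_table` data frame: `species`, `area`, `fraction`
#'   (fractions sum to 1).
#' @export
quantify_species <- function(trace, windows, blank = NULL) {
  stopifnot(all(c("time_min", "mAU") %in% names(trace)))
  w <- do.call(rbind, windows)
  ord <- order(w[, 1])
  if (any(w[ord, 1][-1] < w[ord, 2][-nrow(w)])) stop("retention windows overlap")
  tt <- trace$time_min
  if (is.null(blank)) {
    span <- diff(range(tt))
    blank <- list(c(min(tt), min(tt) + 0.05 * span),
                  c(max(tt) - 0.05 * span, max(tt)))
  }
  in_blank <- Reduce(`|`, lapply(blank, function(b) tt >= b[1] & tt <= b[2]))
  base <- if (sum(in_blank) >= 2) {
    stats::predict(stats::lm(mAU ~ time_min, data = trace[in_blank, ]),
                   newdata = trace)
  } else rep(0, nrow(trace))
  y <- trace$mAU - base
  areas <- vapply(windows, function(b) {
    sel <- tt >= b[1] & tt <= b[2]
    if (sum(sel) < 2) return(0)
    pracma::trapz(tt[sel], y[sel])
  }, numeric(1))
  areas <- pmax(areas, 0)
  total <- sum(areas)
  if (total <= 0) stop("total integrated area is not positive")
  structure(data.frame(species = names(windows), area = unname(areas),
                       fraction = unname(areas / total),
                       stringsAsFactors = FALSE),
            class = c("species_table", "data.frame"))
}

#' Default SE-HPLC retention windows
#'
#' Matches the retention times used by [simulate_chromatogram()]'s defaults in
#' the synthetic assay suite.
#'
#' @param retention named vector of peak retention times (min).
#' @param half_width window half-width, min.
#' @return Named list of `c(from, to)` windows in elution order.
#' @export
sec_default_windows <- function(retention = c(aggregate = 6.0, dimer = 7.2,
                                              monomer = 8.6, fragment = 11.0),
                                half_width = 0.55) {
  ret <- sort(retention)
  mids <- (utils::head(ret, -1) + utils::tail(ret, -1)) / 2
  out <- lapply(seq_along(ret), function(i) {
    lo <- if (i == 1) ret[i] - half_width else max(ret[i] - half_width, mids[i - 1])
    hi <- if (i == length(ret)) ret[i] + half_width else min(ret[i] + half_width, mids[i])
    c(unname(lo), unname(hi))
  })
  names(out) <- names(ret)
  out
}

#' Summarize a storage-stability SEC time course
#'
#' @param course list with elements `weeks` (non-decreasing numeric) and
#'   `tables` (one `species_table` per week).
#' @return A `stability_summary` data frame with per-week monomer percent and
#'   the change from week 0, plus attributes `min_monomer_pct` and
#'   `total_delta_pct` (end minus start).
#' @export
summarize_timecourse <- function(course) {
  stopifnot(is.list(course), length(course$weeks) == length(course$tables))
  if (length(course$weeks) < 2) stop("at least 2 time points are required")
  if (is.unsorted(course$weeks)) stop("weeks must be non-decreasing")
  mono <- vapply(course$tables, function(tab) {
    100 * tab$fraction[tab$species == "monomer"]
  }, numeric(1))
  out <- data.frame(week = course$weeks, monomer_pct = mono,
                    delta_pct = mono - mono[1])
  structure(out, class = c("stability_summary", "data.frame"),
            min_monomer_pct = min(mono),
            total_delta_pct = mono[length(mono)] - mono[1])
}
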