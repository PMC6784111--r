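#' Spearman correlation between thermal stability and expression titer
#'
#' Rank correlation with average ranks on ties. The p-value is computed by
#' exact permutation for n <= `exact_max_n` (every arrangement of one rank
#' vector is enumerated) and by the t-approximation
#' t = rho sqrt((n-2)/(1-rho^2)) otherwise. The default alternative is
#' one-sided positive: the working hypothesis is that more stable variants
#' express better.
#'
#' @param summaries data frame with columns `tm` (deg C) and `titer` (mg/L),
#'   one row per variant; or a numeric vector (then `titer` must be given).
#' @param titer optional numeric vector when `summaries` is a vector.
#' @param alternative `"greater"` (default), `"two.sided"` or `"less"`.
#' @param exact_max_n largest n for which the exact permutation p is used
#'   (default 10).
#' @return A `correlation_result` list: `rho`, `p`, `n`, `p_method`
#'   (`"exact-permutation"` or `"t-approximation"`), `alternative`.
#' @export
spearman_tm_titer <- function(summaries, titer = NULL,
                              alternative = c("greater", "two.sided", "less"),
                              exact_max_n = 10) {
  alternative <- match.arg(alternative)
  if (is.data.frame(summaries)) {
    x <- summaries$tm; y <- summaries$titer
  } else {
    x <- summaries; y <- titer
  }
  if (is.null(y)) stop("both tm and titer values are required")
  if (anyNA(x) || anyNA(y)) stop("missing values are not allowed")
  n <- length(x)
  if (n < 4 || length(y) != n) stop("at least 4 complete pairs are required")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("rho is undefined for a constant vector")
  }
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n <= exact_max_n) {
    p <- spearman_exact_perm_p(rx, ry, alternative)
    method <- "exact-permutation"
  } else {
    tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- switch(alternative,
                greater = stats::pt(tstat, n - 2, lower.tail = FALSE),
                less = stats::pt(tstat, n - 2),
                two.sided = 2 * stats::pt(abs(tstat), n - 2, lower.tail = FALSE))
    p <- min(p, 1)
    method <- "t-approximation"
  }
  structure(list(rho = rho, p = p, n = n, p_method = method,
                 alternative = alternative),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation_result> Spearman rho = %.3f, p = %.4f (%s, %s, n = %d)\n",
              x$rho, x$p, x$alternative, x$p_method, x$n))
  invisible(x)
}

#' One-way ANOVA with Tukey's post-hoc test
#'
#' Screens the pooled residuals for normality with the Kolmogorov-Smirnov
#' test, then runs one-way ANOVA and Tukey's HSD (studentized range; the
#' Tukey-Kramer adjustment applies automatically for unequal group sizes).
#'
#' @param groups named list of replicate value vectors (at least 2 groups,
#'   each with at least 2 replicates).
#' @return An `anova_tukey_result` list: `ks_p` (normality screen on
#'   standardized residuals), `F`, `p`, `df`, and `tukey` (data frame of
#'   pairwise mean differences with Tukey-adjusted p-values).
#' @export
anova_tukey <- function(groups) {
  if (length(groups) < 2) stop("at least 2 groups are required")
  sizes <- lengths(groups)
  if (any(sizes < 2)) {
    stop("singleton group(s): ", paste(names(groups)[sizes < 2], collapse = ", "))
  }
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  d <- data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), sizes), levels = names(groups)))
  fit <- stats::aov(value ~ group, data = d)
  res <- stats::residuals(fit)
  ks <- suppressWarnings(stats::ks.test(res / stats::sd(res), "pnorm"))
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$group
  tukey <- data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                      lwr = tk[, "lwr"], upr = tk[, "upr"],
                      p_adj = tk[, "p adj"], row.names = NULL)
  structure(list(ks_p = ks$p.value,
                 F = an$`F value`[1], p = an$`Pr(>F)`[1],
                 df = c(an$Df[1], an$Df[2]), tukey = tukey),
            class = "anova_tukey_result")
}

#' @export
print.anova_tukey_result <- function(x, ...) {
  cat(sprintf("<anova_tukey_result> KS normality p = %.3f; F(%d, %d) = %.2f, p = %.4g\n",
              x$ks_p, x$df[1], x$df[2], x$F, x$p))
  print(x$tukey)
  invisible(x)
}

#' Fold-change screen against a reference variant
#'
#' For each value the fold difference max(v/ref, ref/v) is computed; the
#' screen passes iff the maximum fold over all variants is <= `bound`
#' (inclusive). Used for the affinity claim that no variant's KD differs from
#' the parental antibody's by more than a factor of two.
#'
#' @param values named positive numeric vector (one value per variant,
#'   reference included or not).
#' @param reference reference value (numeric) or the name of the reference
#'   entry in `values`.
#' @param bound inclusive fold bound (default 2).
#' @return A `fold_check_result` list: `pass`, `max_fold`, `worst` (name of
#'   the most divergent variant), `folds`.
#' @export
fold_check <- function(values, reference, bound = 2) {
  if (is.character(reference)) {
    if (!reference %in% names(values)) stop("reference name not found in values")
    ref <- values[[reference]]
  } else {
    ref <- reference
  }
  if (any(values <= 0) || ref <= 0) stop("all values must be positive")
  folds <- pmax(values / ref, ref / values)
  structure(list(pass = max(folds) <= bound, max_fold = max(folds),
                 worst = if (!is.null(names(folds))) names(folds)[which.max(folds)] else which.max(folds),
                 folds = folds, bound = bound),
            class = "fold_check_result")
}

#' @export
print.fold_check_result <- function(x, ...) {
  cat(sprintf("<fold_check_result> max fold %.2f (%s) vs bound %g: %s\n",
              x$max_fold, x$worst, x$bound, if (x$pass) "PASS" else "FAIL"))
  invisible(x)
}
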