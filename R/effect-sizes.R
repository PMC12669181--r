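# Effect sizes with the magnitude labels used throughout the results:
# omega^2 (< .01 small, < .06 medium, > .14 large), Hedges g (<= .2 small,
# < .5 medium, >= .5 large), Cliff's delta (.147 / .33 / .474). Labels at a
# cutpoint are closed on the larger-effect side.

effect_size_row <- function(kind, value, label) {
  tibble::tibble(kind = kind, value = value, label = label)
}

label_hedges_g <- function(g) {
  a <- abs(g)
  if (a <= 0.2) "small" else if (a < 0.5) "medium" else "large"
}

label_cliffs_delta <- function(d) {
  a <- abs(d)
  if (a < 0.147) "none" else if (a < 0.33) "small" else if (a < 0.474) "moderate" else "large"
}

label_omega_squared <- function(w) {
  if (w < 0.01) "small" else if (w < 0.06) "medium" else if (w <= 0.14) "medium" else "large"
}

#' Hedges' g with small-sample correction
#'
#' Pooled-SD Cohen's d multiplied by the small-sample correction
#' `J = 1 - 3 / (4 df - 1)` with `df = n1 + n2 - 2`. Magnitude labels:
#' `|g| <= 0.2` small, `< 0.5` medium, `>= 0.5` large.
#'
#' @param x,y Numeric samples, each of length at least 2.
#' @return A one-row tibble: `kind`, `value`, `label`.
#' @examples
#' hedges_g(rnorm(7, 1), rnorm(7))
#' @export
hedges_g <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2L || n2 < 2L) abort("each sample needs at least 2 values.")
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / df
  if (sp2 == 0) abort("zero pooled variance: g undefined.")
  d <- (mean(x) - mean(y)) / sqrt(sp2)
  g <- d * (1 - 3 / (4 * df - 1))
  effect_size_row("hedges_g", g, label_hedges_g(g))
}

#' Cliff's delta by exhaustive pair enumeration
#'
#' `delta = (#\{x_i > y_j\} - #\{x_i < y_j\}) / (n1 * n2)` over all pairs;
#' ties contribute zero. Labels: `|delta| < 0.147` none, `>= 0.147` small,
#' `>= 0.33` moderate, `>= 0.474` large. Antisymmetric under swapping the
#' samples.
#'
#' @param x,y Non-empty numeric samples.
#' @return A one-row tibble: `kind`, `value`, `label`.
#' @export
cliffs_delta <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) == 0L || length(y) == 0L) abort("samples must be non-empty.")
  cmp <- outer(x, y, "-")
  delta <- (sum(cmp > 0) - sum(cmp < 0)) / (length(x) * length(y))
  effect_size_row("cliffs_delta", delta, label_cliffs_delta(delta))
}

#' Omega squared from the one-way ANOVA decomposition
#'
#' `omega^2 = (SS_between - df_between * MS_within) / (SS_total + MS_within)`.
#' Labels: `< 0.01` small, `< 0.06` medium, `> 0.14` large (values between
#' 0.06 and 0.14 are labeled medium).
#'
#' @param values Numeric vector of observations.
#' @param group Group labels, same length as `values` (at least 2 groups,
#'   each with at least 2 observations).
#' @return A one-row tibble: `kind`, `value`, `label`.
#' @export
omega_squared <- function(values, group) {
  keep <- !is.na(values) & !is.na(group)
  values <- values[keep]; group <- factor(group[keep])
  if (nlevels(group) < 2L) abort("need at least 2 groups.")
  if (any(table(group) < 2L)) abort("each group needs at least 2 values.")
  if (var(values) == 0) abort("zero total variance: omega squared undefined.")
  fit <- stats::aov(values ~ group)
  tab <- summary(fit)[[1]]
  ss_b <- tab["group", "Sum Sq"]
  df_b <- tab["group", "Df"]
  ms_w <- tab["Residuals", "Mean Sq"]
  ss_t <- ss_b + tab["Residuals", "Sum Sq"]
  w2 <- (ss_b - df_b * ms_w) / (ss_t + ms_w)
  effect_size_row("omega_squared", w2, label_omega_squared(w2))
}
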