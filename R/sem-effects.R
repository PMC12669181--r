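# Standardized direct, indirect and total effects derived from the
# path-model posterior, the explained variance of the granule cell
# equation, the free-vs-restricted multigroup comparison, and MCMC-based
# group differences.

# Standardization factors sd(predictor) / sd(outcome) computed on the data
# the user supplied (before any internal scaling).
std_factors <- function(fit) {
  s <- fit$scales
  c(
    a1 = s[["PV_H"]] / s[["MC"]],
    a2 = s[["MC"]] / s[["PV_GL"]],
    b1 = s[["MC"]] / s[["GC"]],
    b2 = s[["PV_GL"]] / s[["GC"]],
    b3 = s[["PV_H"]] / s[["GC"]]
  )
}

# Draws of standardized path coefficients (matrix draws x coefficients).
# A fit on unit-SD data already samples standardized betas; only raw-scale
# fits need the sd(predictor)/sd(outcome) factors.
std_coef_draws <- function(fit) {
  m <- draws_matrix(fit)
  coefs <- intersect(c("a1", "a2", "b1", "b2", "b3"), colnames(m))
  out <- m[, coefs, drop = FALSE]
  if (!isTRUE(fit$standardize)) {
    out <- sweep(out, 2, std_factors(fit)[coefs], `*`)
  }
  out
}

summarize_draws_ci <- function(x) {
  tibble::tibble(
    estimate = mean(x),
    conf.low = quantile(x, 0.025, names = FALSE),
    conf.high = quantile(x, 0.975, names = FALSE)
  )
}

#' Standardized direct, indirect and total effects
#'
#' Standardizes every path-coefficient draw by `sd(predictor) / sd(outcome)`
#' of the observed data, then forms, draw by draw, the mediation quantities
#' of the full model: the indirect effects MC -> PV_GL -> GC (`a2 * b2`) and
#' PV_H -> MC -> GC (`a1 * b1`), and the totals MC -> GC (`b1 + a2 * b2`)
#' and PV_H -> GC (`b3 + a1 * b1`). The three-path chain
#' PV_H -> MC -> PV_GL -> GC (`a1 * a2 * b2`) is reported separately and not
#' folded into the total. An effect is flagged significant when its central
#' 95% credible interval excludes zero.
#'
#' @param fit A model-1 [fit_path_model()] result.
#' @return A tibble of class `effect_summary`: `effect`, `type`
#'   (direct / indirect / total), `estimate` (posterior mean of the
#'   standardized draws), `conf.low`, `conf.high`, `significant`. The
#'   per-draw effect values are attached as attribute `"draws"` (named list
#'   of vectors).
#' @export
derived_effects <- function(fit) {
  stopifnot(inherits(fit, "dg_path_fit"))
  if (fit$spec$model != "model1") {
    abort("derived effects require the full model (model1).")
  }
  if (any(fit$scales == 0)) abort("zero variance: standardization undefined.")
  d <- std_coef_draws(fit)
  eff <- list(
    `PV_H->MC` = list("direct", d[, "a1"]),
    `MC->PV_GL` = list("direct", d[, "a2"]),
    `MC->GC` = list("direct", d[, "b1"]),
    `PV_GL->GC` = list("direct", d[, "b2"]),
    `PV_H->GC` = list("direct", d[, "b3"]),
    `MC->PV_GL->GC` = list("indirect", d[, "a2"] * d[, "b2"]),
    `PV_H->MC->GC` = list("indirect", d[, "a1"] * d[, "b1"]),
    `PV_H->MC->PV_GL->GC` = list(
      "indirect", d[, "a1"] * d[, "a2"] * d[, "b2"]
    ),
    `total MC->GC` = list("total", d[, "b1"] + d[, "a2"] * d[, "b2"]),
    `total PV_H->GC` = list("total", d[, "b3"] + d[, "a1"] * d[, "b1"])
  )
  out <- purrr::imap_dfr(eff, function(e, nm) {
    dplyr::bind_cols(
      tibble::tibble(effect = nm, type = e[[1]]),
      summarize_draws_ci(e[[2]])
    )
  })
  out <- dplyr::mutate(out,
    significant = .data$conf.low > 0 | .data$conf.high < 0
  )
  attr(out, "draws") <- purrr::map(eff, 2)
  class(out) <- c("effect_summary", class(out))
  out
}

#' Bayesian R-squared of the granule cell equation
#'
#' Per draw, the variance of the GC linear predictor over the fitted data is
#' divided by itself plus the residual variance; the posterior mean of this
#' ratio is returned.
#'
#' @param fit A [fit_path_model()] result (any model with a GC equation).
#' @return A number in `[0, 1]`.
#' @export
r_squared_gc <- function(fit) {
  stopifnot(inherits(fit, "dg_path_fit"))
  m <- draws_matrix(fit)
  d <- fit$data
  r2 <- vapply(seq_len(nrow(m)), function(s) {
    mu <- m[s, "b1"] * d$MC + m[s, "b2"] * d$PV_GL + m[s, "b3"] * d$PV_H
    v <- var(mu)
    v / (v + m[s, "sigma_GC"]^2)
  }, numeric(1))
  mean(r2)
}

#' Multigroup comparison: free versus restricted coefficients
#'
#' Fits the full path model separately to every group (free version) and
#' once with path coefficients shared across groups but group-specific
#' residual scales (restricted version), then compares the two by total
#' DIC. A lower DIC for the free version supports genuine between-group
#' differences in the microcircuit coefficients.
#'
#' @param data Microcircuit table with a `group` column (at least 2 groups,
#'   each with at least 4 animals).
#' @param spec A [path_model_spec()] (model 1).
#' @param chains,warmup,draws,seed Sampler settings, as in
#'   [fit_path_model()].
#' @param standardize Standardize within group (default `TRUE`).
#' @return A list: `free` (named list of per-group fits), `restricted`
#'   (multigroup fit), `dic_free`, `dic_restricted`, `preferred`
#'   (`"free"` or `"restricted"`).
#' @export
multigroup_fit_compare <- function(data, spec = path_model_spec(),
                                   chains = 4L, warmup = 1000L,
                                   draws = 5000L, seed = 1L,
                                   standardize = TRUE) {
  if (!"group" %in% names(data)) abort("`data` needs a `group` column.")
  groups <- unique(data$group)
  if (length(groups) < 2L) abort("need at least 2 groups.")
  free <- purrr::map(setNames(groups, groups), function(g) {
    sub <- dplyr::filter(data, .data$group == g)
    tryCatch(
      fit_path_model(sub, spec,
        chains = chains, warmup = warmup,
        draws = draws, seed = derive_seed(seed, "free", match(g, groups)),
        standardize = standardize
      ),
      error = function(e) {
        abort(sprintf("fit failed for group %s: %s", g, conditionMessage(e)))
      }
    )
  })
  dic_free <- sum(vapply(
    free, function(f) information_criteria(f)$DIC, numeric(1)
  ))

  restricted <- fit_restricted_multigroup(
    data, spec,
    chains = chains, warmup = warmup, draws = draws,
    seed = derive_seed(seed, "restricted"), standardize = standardize
  )
  dic_restricted <- restricted_dic(restricted)
  list(
    free = free, restricted = restricted,
    dic_free = dic_free, dic_restricted = dic_restricted,
    preferred = if (dic_free <= dic_restricted) "free" else "restricted"
  )
}

# Restricted multigroup model-1 fit: shared a1..b3, per-group residuals.
fit_restricted_multigroup <- function(data, spec, chains, warmup, draws,
                                      seed, standardize = TRUE) {
  groups <- unique(data$group)
  sub <- data |>
    dplyr::group_by(.data$group) |>
    dplyr::mutate(dplyr::across(
      dplyr::all_of(microcircuit_vars),
      if (standardize) ~ as.numeric(scale(.x)) else ~ .x - mean(.x)
    )) |>
    dplyr::ungroup()
  jdata <- c(
    as.list(sub[, microcircuit_vars]),
    list(
      N = nrow(sub),
      g = match(sub$group, groups),
      G = length(groups),
      coef_prec = 1 / spec$prior_coef_sd^2,
      sigma_prec = 1 / spec$prior_sigma_scale^2
    )
  )
  monitors <- c(
    "a1", "a2", "b1", "b2", "b3",
    "sigma_PVH", "sigma_MC", "sigma_PVGL", "sigma_GC"
  )
  samples <- run_jags(
    jags_code_model1_restricted(), jdata, monitors, chains, warmup, draws,
    seed
  )
  structure(
    list(
      samples = samples,
      params = colnames(as.matrix(samples[[1]])),
      groups = groups, group_index = jdata$g,
      data = sub, spec = spec, chains = chains, warmup = warmup,
      n_draws = draws, seed = seed, standardize = standardize
    ),
    class = "dg_path_fit_restricted"
  )
}

# DIC of the restricted multigroup fit from its pointwise log-likelihood.
restricted_dic <- function(fit) {
  m <- do.call(rbind, lapply(fit$samples, as.matrix))
  d <- fit$data
  gi <- fit$group_index
  loglik_for <- function(th) {
    mu_mc <- th[["a1"]] * d$PV_H
    mu_pvgl <- th[["a2"]] * d$MC
    mu_gc <- th[["b1"]] * d$MC + th[["b2"]] * d$PV_GL + th[["b3"]] * d$PV_H
    s_pvh <- th[paste0("sigma_PVH[", gi, "]")]
    s_mc <- th[paste0("sigma_MC[", gi, "]")]
    s_pvgl <- th[paste0("sigma_PVGL[", gi, "]")]
    s_gc <- th[paste0("sigma_GC[", gi, "]")]
    sum(
      dnorm(d$PV_H, 0, s_pvh, log = TRUE) +
        dnorm(d$MC, mu_mc, s_mc, log = TRUE) +
        dnorm(d$PV_GL, mu_pvgl, s_pvgl, log = TRUE) +
        dnorm(d$GC, mu_gc, s_gc, log = TRUE)
    )
  }
  dev <- -2 * vapply(seq_len(nrow(m)), function(s) loglik_for(m[s, ]), numeric(1))
  d_hat <- -2 * loglik_for(colMeans(m))
  p_dic <- mean(dev) - d_hat
  d_hat + 2 * p_dic
}

#' MCMC-based group differences in standardized coefficients
#'
#' For every path coefficient shared by two group fits, forms the
#' distribution of the difference between the groups' standardized MCMC
#' draws (paired after truncation to a common number of draws) and
#' summarizes it by its mean, 95% credible interval, and the probabilities
#' of the difference being positive or negative. A parameter is flagged
#' when the credible interval excludes zero or a sign probability exceeds
#' 0.95.
#'
#' @param fit_a,fit_b [fit_path_model()] results for the two groups.
#' @return A tibble: `term`, `estimate`, `conf.low`, `conf.high`, `p_gt0`,
#'   `p_lt0`, `flagged`.
#' @export
group_difference <- function(fit_a, fit_b) {
  da <- std_coef_draws(fit_a)
  db <- std_coef_draws(fit_b)
  shared <- intersect(colnames(da), colnames(db))
  if (length(shared) == 0L) abort("the fits share no path coefficients.")
  S <- min(nrow(da), nrow(db))
  purrr::map_dfr(shared, function(p) {
    diff <- da[seq_len(S), p] - db[seq_len(S), p]
    ci <- summarize_draws_ci(diff)
    p_gt <- mean(diff > 0)
    p_lt <- mean(diff < 0)
    tibble::tibble(
      term = p,
      estimate = ci$estimate, conf.low = ci$conf.low,
      conf.high = ci$conf.high,
      p_gt0 = p_gt, p_lt0 = p_lt,
      flagged = (ci$conf.low > 0 | ci$conf.high < 0) |
        p_gt > 0.95 | p_lt > 0.95
    )
  })
}
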