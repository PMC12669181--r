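# Bayesian path (mediation) model of the dentate-gyrus microcircuit.
#
# The model is a fully observed recursive linear-Gaussian path system over
# (MC, PV_H, PV_GL, GC), so the likelihood factorizes into regressions:
#   model 1 (with indirect paths):
#     PV_H  ~ N(0, sigma_PVH^2)                 (exogenous scale)
#     MC    ~ N(a1 * PV_H, sigma_MC^2)
#     PV_GL ~ N(a2 * MC, sigma_PVGL^2)
#     GC    ~ N(b1 * MC + b2 * PV_GL + b3 * PV_H, sigma_GC^2)
#   model 2 (direct effects only): the single GC regression, predictors
#     treated as exogenous.
# Priors: normal(0, prior_coef_sd) on path coefficients and half-normal
# (prior_sigma_scale) on residual scales, recorded in the fit so results are
# self-describing. MCMC via JAGS with per-chain fixed RNG seeds. Variables
# are centered before fitting (the system carries no intercepts); with
# `standardize = TRUE` they are also scaled to unit SD, so raw coefficients
# coincide with standardized betas.

microcircuit_vars <- c("MC", "PV_H", "PV_GL", "GC")

#' Specify the Bayesian microcircuit path model
#'
#' @param model `"model1"` (direct paths plus the two mediation chains
#'   MC -> PV_GL -> GC and PV_H -> MC -> GC modeled through the MC and
#'   PV_GL equations) or `"model2"` (the GC regression only; direct effects).
#' @param prior_coef_sd Standard deviation of the normal(0, sd) prior on
#'   path coefficients; default 10 (weakly informative).
#' @param prior_sigma_scale Scale of the half-normal prior on residual
#'   standard deviations; default 5.
#' @return An object of class `path_model_spec`.
#' @export
path_model_spec <- function(model = c("model1", "model2"),
                            prior_coef_sd = 10, prior_sigma_scale = 5) {
  model <- match.arg(model)
  check_positive_scalar(prior_coef_sd, "prior_coef_sd")
  check_positive_scalar(prior_sigma_scale, "prior_sigma_scale")
  structure(
    list(
      model = model, prior_coef_sd = prior_coef_sd,
      prior_sigma_scale = prior_sigma_scale
    ),
    class = "path_model_spec"
  )
}

jags_code_model1 <- function() {
  "model {
    for (i in 1:N) {
      PV_H[i]  ~ dnorm(0, tau_pvh)
      MC[i]    ~ dnorm(a1 * PV_H[i], tau_mc)
      PV_GL[i] ~ dnorm(a2 * MC[i], tau_pvgl)
      GC[i]    ~ dnorm(b1 * MC[i] + b2 * PV_GL[i] + b3 * PV_H[i], tau_gc)
    }
    a1 ~ dnorm(0, coef_prec)
    a2 ~ dnorm(0, coef_prec)
    b1 ~ dnorm(0, coef_prec)
    b2 ~ dnorm(0, coef_prec)
    b3 ~ dnorm(0, coef_prec)
    sigma_PVH  ~ dnorm(0, sigma_prec) T(0,)
    sigma_MC   ~ dnorm(0, sigma_prec) T(0,)
    sigma_PVGL ~ dnorm(0, sigma_prec) T(0,)
    sigma_GC   ~ dnorm(0, sigma_prec) T(0,)
    tau_pvh  <- pow(sigma_PVH, -2)
    tau_mc   <- pow(sigma_MC, -2)
    tau_pvgl <- pow(sigma_PVGL, -2)
    tau_gc   <- pow(sigma_GC, -2)
  }"
}

jags_code_model2 <- function() {
  "model {
    for (i in 1:N) {
      GC[i] ~ dnorm(b1 * MC[i] + b2 * PV_GL[i] + b3 * PV_H[i], tau_gc)
    }
    b1 ~ dnorm(0, coef_prec)
    b2 ~ dnorm(0, coef_prec)
    b3 ~ dnorm(0, coef_prec)
    sigma_GC ~ dnorm(0, sigma_prec) T(0,)
    tau_gc <- pow(sigma_GC, -2)
  }"
}

# Restricted multigroup model 1: shared path coefficients, group-specific
# residual scales.
jags_code_model1_restricted <- function() {
  "model {
    for (i in 1:N) {
      PV_H[i]  ~ dnorm(0, tau_pvh[g[i]])
      MC[i]    ~ dnorm(a1 * PV_H[i], tau_mc[g[i]])
      PV_GL[i] ~ dnorm(a2 * MC[i], tau_pvgl[g[i]])
      GC[i]    ~ dnorm(b1 * MC[i] + b2 * PV_GL[i] + b3 * PV_H[i], tau_gc[g[i]])
    }
    a1 ~ dnorm(0, coef_prec)
    a2 ~ dnorm(0, coef_prec)
    b1 ~ dnorm(0, coef_prec)
    b2 ~ dnorm(0, coef_prec)
    b3 ~ dnorm(0, coef_prec)
    for (j in 1:G) {
      sigma_PVH[j]  ~ dnorm(0, sigma_prec) T(0,)
      sigma_MC[j]   ~ dnorm(0, sigma_prec) T(0,)
      sigma_PVGL[j] ~ dnorm(0, sigma_prec) T(0,)
      sigma_GC[j]   ~ dnorm(0, sigma_prec) T(0,)
      tau_pvh[j]  <- pow(sigma_PVH[j], -2)
      tau_mc[j]   <- pow(sigma_MC[j], -2)
      tau_pvgl[j] <- pow(sigma_PVGL[j], -2)
      tau_gc[j]   <- pow(sigma_GC[j], -2)
    }
  }"
}

path_params <- function(model) {
  switch(model,
    model1 = c(
      "a1", "a2", "b1", "b2", "b3",
      "sigma_PVH", "sigma_MC", "sigma_PVGL", "sigma_GC"
    ),
    model2 = c("b1", "b2", "b3", "sigma_GC")
  )
}

run_jags <- function(code, data, monitors, chains, warmup, draws, seed) {
  inits <- lapply(seq_len(chains), function(i) {
    list(
      .RNG.name = "base::Mersenne-Twister",
      .RNG.seed = derive_seed(seed, "jags-chain", i)
    )
  })
  jm <- rjags::jags.model(
    textConnection(code),
    data = data, n.chains = chains, inits = inits, quiet = TRUE
  )
  update(jm, n.iter = warmup, progress.bar = "none")
  rjags::coda.samples(jm, variable.names = monitors, n.iter = draws,
                      progress.bar = "none")
}

#' Fit the Bayesian microcircuit path model
#'
#' Samples the joint posterior of all path coefficients and residual scales
#' of the specified model by MCMC (JAGS), with fixed per-chain seeds so the
#' same seed reproduces the same draws.
#'
#' @param data A microcircuit table with numeric columns `MC`, `PV_H`,
#'   `PV_GL`, `GC` (no missing values; at least 4 rows).
#' @param spec A [path_model_spec()].
#' @param chains Number of chains; default 4.
#' @param warmup Burn-in iterations per chain; default 1000.
#' @param draws Retained iterations per chain; default 5000.
#' @param seed Integer seed.
#' @param standardize Center and scale each variable to unit SD before
#'   fitting (default `TRUE`), so coefficients are standardized betas. With
#'   `FALSE` the variables are only centered and coefficients stay on the
#'   raw scale.
#' @return An object of class `dg_path_fit`: list with `samples` (a coda
#'   `mcmc.list`), `params`, `spec`, `data` (as fitted), `data_raw`,
#'   `scales`, `chains`, `warmup`, `n_draws`, `seed`, `standardize`.
#' @examples
#' \donttest{
#' dat <- simulate_dg_microcircuit(microcircuit_spec(n_animals = 50), seed = 2)
#' fit <- fit_path_model(dat, chains = 2, warmup = 200, draws = 500, seed = 1)
#' tidy(fit)
#' }
#' @export
fit_path_model <- function(data, spec = path_model_spec(), chains = 4L,
                           warmup = 1000L, draws = 5000L, seed = 1L,
                           standardize = TRUE) {
  stopifnot(inherits(spec, "path_model_spec"))
  miss <- setdiff(microcircuit_vars, names(data))
  if (length(miss) > 0L) {
    abort(paste0("`data` lacks column(s): ", paste(miss, collapse = ", ")))
  }
  raw <- tibble::as_tibble(data[, microcircuit_vars])
  if (nrow(raw) < 4L) abort("need at least 4 animals.")
  if (any(!vapply(raw, is.numeric, logical(1))) ||
      any(!vapply(raw, function(x) all(is.finite(x)), logical(1)))) {
    abort("all microcircuit variables must be finite numerics.")
  }
  if (chains < 2L) abort("need at least 2 chains for convergence diagnostics.")
  scales <- vapply(raw, sd, numeric(1))
  if (any(scales == 0)) abort("constant microcircuit variable: cannot fit.")
  centered <- dplyr::mutate(raw, dplyr::across(
    dplyr::everything(),
    if (standardize) ~ as.numeric(scale(.x)) else ~ .x - mean(.x)
  ))
  jdata <- c(
    as.list(centered),
    list(
      N = nrow(centered),
      coef_prec = 1 / spec$prior_coef_sd^2,
      sigma_prec = 1 / spec$prior_sigma_scale^2
    )
  )
  code <- switch(spec$model,
    model1 = jags_code_model1(),
    model2 = jags_code_model2()
  )
  params <- path_params(spec$model)
  samples <- run_jags(code, jdata, params, chains, warmup, draws, seed)
  structure(
    list(
      samples = samples, params = params, spec = spec,
      data = centered, data_raw = raw, scales = scales,
      chains = as.integer(chains), warmup = as.integer(warmup),
      n_draws = as.integer(draws), seed = seed, standardize = standardize
    ),
    class = "dg_path_fit"
  )
}

#' @export
print.dg_path_fit <- function(x, ...) {
  cat(sprintf(
    "<dg_path_fit> %s, n = %d, %d chains x %d draws (warmup %d)\n",
    x$spec$model, nrow(x$data), x$chains, x$n_draws, x$warmup
  ))
  print(tidy.dg_path_fit(x))
  invisible(x)
}

# All retained draws as an (iterations * chains) x parameter matrix.
draws_matrix <- function(fit) {
  m <- do.call(rbind, lapply(fit$samples, as.matrix))
  m[, fit$params, drop = FALSE]
}

# Draws as [iteration, chain, parameter] array (for split-R-hat).
draws_array <- function(fit) {
  mats <- lapply(fit$samples, function(ch) as.matrix(ch)[, fit$params, drop = FALSE])
  arr <- array(
    unlist(mats),
    dim = c(nrow(mats[[1]]), length(fit$params), length(mats)),
    dimnames = list(NULL, fit$params, NULL)
  )
  aperm(arr, c(1, 3, 2))
}

#' @describeIn fit_path_model Posterior summaries per parameter: mean, sd,
#'   95% credible interval, split R-hat.
#' @param x A `dg_path_fit`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
#' @export
tidy.dg_path_fit <- function(x, ...) {
  m <- draws_matrix(x)
  rh <- rhat(x)
  tibble::tibble(
    term = colnames(m),
    estimate = colMeans(m),
    std.error = apply(m, 2, sd),
    conf.low = apply(m, 2, quantile, 0.025, names = FALSE),
    conf.high = apply(m, 2, quantile, 0.975, names = FALSE),
    rhat = unname(rh[colnames(m)])
  )
}

#' @describeIn fit_path_model One-row model overview: sample size, sampler
#'   settings, worst R-hat, and the posterior-mean R-squared of the granule
#'   cell equation.
#' @exportS3Method generics::glance
#' @export
glance.dg_path_fit <- function(x, ...) {
  tibble::tibble(
    model = x$spec$model,
    nobs = nrow(x$data),
    chains = x$chains,
    n_draws = x$n_draws,
    rhat_max = max(rhat(x), na.rm = TRUE),
    r_squared_gc = r_squared_gc(x)
  )
}
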