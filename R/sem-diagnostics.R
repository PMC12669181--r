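# Convergence and fit diagnostics for the path-model posterior: split-chain
# R-hat, a moment-based posterior predictive p-value, and DIC / WAIC / LOOIC
# from the pointwise log-likelihood.

#' Split-chain potential scale reduction factor (R-hat)
#'
#' Each chain is split in half and the classical potential scale reduction
#' factor is computed over the resulting 2 x chains sequences. Values close
#' to 1 indicate convergence. Parameters with zero within-chain variance
#' return `NA` with a warning.
#'
#' @param fit A [fit_path_model()] result (at least 2 chains).
#' @return Named numeric vector, one R-hat per parameter.
#' @export
rhat <- function(fit) {
  stopifnot(inherits(fit, "dg_path_fit"))
  if (fit$chains < 2L) abort("R-hat needs at least 2 chains.")
  arr <- draws_array(fit)
  n <- dim(arr)[1]
  half <- floor(n / 2)
  out <- vapply(seq_len(dim(arr)[3]), function(k) {
    chains <- cbind(
      arr[seq_len(half), , k, drop = TRUE],
      arr[(n - half + 1):n, , k, drop = TRUE]
    )
    W <- mean(apply(chains, 2, var))
    if (W == 0) return(NA_real_)
    B <- half * var(colMeans(chains))
    var_plus <- (half - 1) / half * W + B / half
    sqrt(var_plus / W)
  }, numeric(1))
  names(out) <- dimnames(arr)[[3]]
  if (anyNA(out)) warn("zero within-chain variance: R-hat undefined for some parameters.")
  out
}

# Model-implied covariance of (MC, PV_H, PV_GL, GC) for one parameter draw.
# Model 2 takes the exogenous block at its sample (ML) covariance.
implied_sigma_draw <- function(theta, model, s_xx = NULL) {
  v <- c("MC", "PV_H", "PV_GL", "GC")
  if (model == "model1") {
    # shocks: (pv_h innovation, e_mc, e_pvgl, e_gc)
    a1 <- theta[["a1"]]; a2 <- theta[["a2"]]
    b1 <- theta[["b1"]]; b2 <- theta[["b2"]]; b3 <- theta[["b3"]]
    L <- rbind(
      MC    = c(a1, 1, 0, 0),
      PV_H  = c(1, 0, 0, 0),
      PV_GL = c(a2 * a1, a2, 1, 0),
      GC    = c(b1 * a1 + b2 * a2 * a1 + b3, b1 + b2 * a2, b2, 1)
    )
    D <- diag(c(
      theta[["sigma_PVH"]]^2, theta[["sigma_MC"]]^2,
      theta[["sigma_PVGL"]]^2, theta[["sigma_GC"]]^2
    ))
    S <- L %*% D %*% t(L)
  } else {
    b <- c(theta[["b1"]], theta[["b2"]], theta[["b3"]])
    # s_xx over (MC, PV_GL, PV_H) in the GC-equation predictor order
    cov_gx <- as.vector(s_xx %*% b)
    var_g <- as.numeric(t(b) %*% s_xx %*% b) + theta[["sigma_GC"]]^2
    # reorder predictors into (MC, PV_H, PV_GL)
    ord <- c(1, 3, 2)
    S <- matrix(0, 4, 4)
    S[1:3, 1:3] <- s_xx[ord, ord]
    S[4, 1:3] <- cov_gx[ord]
    S[1:3, 4] <- cov_gx[ord]
    S[4, 4] <- var_g
  }
  dimnames(S) <- list(v, v)
  S
}

# ML (1/n) covariance of the fitted data in (MC, PV_H, PV_GL, GC) order.
ml_cov <- function(data) {
  x <- as.matrix(data[, c("MC", "PV_H", "PV_GL", "GC")])
  n <- nrow(x)
  cov(x) * (n - 1) / n
}

# Maximum-likelihood discrepancy between a sample covariance and the
# model-implied covariance.
f_ml <- function(S, Sigma) {
  p <- nrow(S)
  as.numeric(
    determinant(Sigma, logarithm = TRUE)$modulus +
      sum(diag(S %*% solve(Sigma))) -
      determinant(S, logarithm = TRUE)$modulus - p
  )
}

# Evenly thinned draw indices.
thin_indices <- function(total, ndraws) {
  if (is.null(ndraws) || ndraws >= total) return(seq_len(total))
  unique(round(seq(1, total, length.out = ndraws)))
}

#' Posterior predictive p-value
#'
#' For each retained draw, a replicate dataset of the same size is simulated
#' from the model-implied distribution and the maximum-likelihood moment
#' discrepancy between sample and model-implied covariance is computed for
#' the replicate and for the observed data. The PPP is the fraction of draws
#' in which the replicate discrepancy is at least the observed one; values
#' near 0.5 indicate that the observed moments look like typical model
#' draws, values near 0 indicate misfit.
#'
#' @param fit A [fit_path_model()] result.
#' @param ndraws Number of (evenly thinned) draws to use; default 500.
#' @param seed Integer seed for the replicate simulation.
#' @return A number in `[0, 1]`.
#' @export
posterior_predictive_p <- function(fit, ndraws = 500L, seed = 1L) {
  stopifnot(inherits(fit, "dg_path_fit"))
  n <- nrow(fit$data)
  if (n <= 4L) abort("PPP needs more animals than observed variables.")
  m <- draws_matrix(fit)
  idx <- thin_indices(nrow(m), ndraws)
  S_obs <- ml_cov(fit$data)
  s_xx <- NULL
  if (fit$spec$model == "model2") {
    x <- as.matrix(fit$data[, c("MC", "PV_GL", "PV_H")])
    s_xx <- cov(x) * (n - 1) / n
  }
  with_seed(derive_seed(seed, "ppp"), {
    ge <- vapply(idx, function(s) {
      Sigma <- implied_sigma_draw(m[s, ], fit$spec$model, s_xx)
      d_obs <- f_ml(S_obs, Sigma)
      z <- matrix(rnorm(n * 4), n, 4) %*% chol(Sigma)
      S_rep <- crossprod(scale(z, scale = FALSE)) / n
      d_rep <- f_ml(S_rep, Sigma)
      as.numeric(d_rep >= d_obs)
    }, numeric(1))
    mean(ge)
  })
}

# Pointwise log-likelihood matrix (draws x observations) over the model's
# equations; model 2 scores the GC equation only.
pointwise_loglik <- function(fit, ndraws = NULL) {
  m <- draws_matrix(fit)
  idx <- thin_indices(nrow(m), ndraws)
  d <- fit$data
  model <- fit$spec$model
  L <- matrix(0, length(idx), nrow(d))
  for (r in seq_along(idx)) {
    th <- m[idx[r], ]
    mu_gc <- th[["b1"]] * d$MC + th[["b2"]] * d$PV_GL + th[["b3"]] * d$PV_H
    ll <- dnorm(d$GC, mu_gc, th[["sigma_GC"]], log = TRUE)
    if (model == "model1") {
      ll <- ll +
        dnorm(d$PV_H, 0, th[["sigma_PVH"]], log = TRUE) +
        dnorm(d$MC, th[["a1"]] * d$PV_H, th[["sigma_MC"]], log = TRUE) +
        dnorm(d$PV_GL, th[["a2"]] * d$MC, th[["sigma_PVGL"]], log = TRUE)
    }
    L[r, ] <- ll
  }
  L
}

log_sum_exp <- function(x) {
  mx <- max(x)
  mx + log(sum(exp(x - mx)))
}

#' Bayesian information criteria: DIC, WAIC, LOOIC
#'
#' DIC uses the posterior-mean-deviance form with effective parameters
#' `p_D = mean deviance - deviance at the posterior mean`. WAIC uses the
#' pointwise log predictive density with the variance penalty. LOOIC uses
#' importance-sampling leave-one-out with truncated weights; observations
#' whose raw importance weights are dominated by a single draw are counted
#' in `n_flagged` and reported with a warning.
#'
#' @param fit A [fit_path_model()] result.
#' @param ndraws Number of (evenly thinned) draws; default all.
#' @return A one-row tibble: `DIC`, `p_dic`, `WAIC`, `p_waic`, `LOOIC`,
#'   `n_flagged`.
#' @export
information_criteria <- function(fit, ndraws = NULL) {
  stopifnot(inherits(fit, "dg_path_fit"))
  L <- pointwise_loglik(fit, ndraws)
  S <- nrow(L)
  dev <- -2 * rowSums(L)
  dbar <- mean(dev)
  m <- draws_matrix(fit)
  idx <- thin_indices(nrow(m), ndraws)
  theta_hat <- colMeans(m[idx, , drop = FALSE])
  L_hat <- {
    mh <- matrix(theta_hat, 1, dimnames = list(NULL, names(theta_hat)))
    fh <- fit
    fh$samples <- coda::mcmc.list(coda::mcmc(mh))
    pointwise_loglik(fh)
  }
  d_hat <- -2 * sum(L_hat)
  p_dic <- dbar - d_hat
  dic <- d_hat + 2 * p_dic

  lppd <- sum(apply(L, 2, function(l) log_sum_exp(l) - log(S)))
  p_waic <- sum(apply(L, 2, var))
  waic <- -2 * (lppd - p_waic)

  trunc_at <- sqrt(S) / S # truncation of normalized weights (Ionides-style)
  loo_terms <- apply(L, 2, function(l) {
    logw <- -l
    w <- exp(logw - log_sum_exp(logw))
    flagged <- max(w) > 0.4
    w_t <- pmin(w, trunc_at)
    w_t <- w_t / sum(w_t)
    lmax <- max(l)
    elpd <- lmax + log(sum(w_t * exp(l - lmax)))
    c(elpd = elpd, flagged = as.numeric(flagged))
  })
  n_flagged <- as.integer(sum(loo_terms["flagged", ]))
  if (n_flagged > 0L) {
    warn(sprintf("unstable importance weights for %d observation(s) in LOO.", n_flagged))
  }
  looic <- -2 * sum(loo_terms["elpd", ])
  tibble::tibble(
    DIC = dic, p_dic = p_dic, WAIC = waic, p_waic = p_waic,
    LOOIC = looic, n_flagged = n_flagged
  )
}
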