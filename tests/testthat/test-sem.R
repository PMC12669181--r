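# Bayesian path model: recovery, diagnostics, derived effects, multigroup
# comparison, and group differences. Sampler settings are reduced relative
# to release defaults; the posterior contract is unchanged.

fit_quick <- function(data, ..., chains = 4, warmup = 250, draws = 750,
                      seed = 1) {
  fit_path_model(data, ..., chains = chains, warmup = warmup, draws = draws,
                 seed = seed)
}

# Minimal hand-built fit for diagnostic unit tests.
fake_fit <- function(chain_list) {
  params <- colnames(chain_list[[1]])
  structure(
    list(
      samples = coda::mcmc.list(lapply(chain_list, coda::mcmc)),
      params = params,
      spec = path_model_spec(),
      chains = length(chain_list),
      n_draws = nrow(chain_list[[1]])
    ),
    class = "dg_path_fit"
  )
}

truth_spec <- microcircuit_spec(
  a1 = -0.5, a2 = 0.5, b1 = 0.6, b2 = -0.7, b3 = 0.3, n_animals = 2000
)

test_that("the posterior recovers generator coefficients at large n", {
  dat <- simulate_dg_microcircuit(truth_spec, seed = 73)
  fit <- fit_quick(dat, standardize = FALSE)
  est <- tidy(fit)
  truth <- c(a1 = -0.5, a2 = 0.5, b1 = 0.6, b2 = -0.7, b3 = 0.3,
             sigma_PVH = 1, sigma_MC = 1, sigma_PVGL = 1, sigma_GC = 1)
  expect_true(all(abs(est$estimate - truth[est$term]) < 0.05))
  expect_true(all(est$rhat < 1.01))
})

test_that("a pure-noise outcome leaves all GC paths covering zero", {
  spec <- microcircuit_spec(
    a1 = -0.5, a2 = 0.5, b1 = 0, b2 = 0, b3 = 0, n_animals = 1500
  )
  dat <- simulate_dg_microcircuit(spec, seed = 72)
  fit <- fit_quick(dat, standardize = FALSE)
  est <- tidy(fit)
  for (b in c("b1", "b2", "b3")) {
    row <- est[est$term == b, ]
    expect_true(row$conf.low < 0 && row$conf.high > 0)
  }
})

test_that("fits are byte-identical under the same seed", {
  dat <- simulate_dg_microcircuit(microcircuit_spec(n_animals = 60), seed = 4)
  f1 <- fit_quick(dat, chains = 2, warmup = 100, draws = 200, seed = 7)
  f2 <- fit_quick(dat, chains = 2, warmup = 100, draws = 200, seed = 7)
  expect_identical(tidy(f1), tidy(f2))
  f3 <- fit_quick(dat, chains = 2, warmup = 100, draws = 200, seed = 8)
  expect_false(identical(tidy(f1)$estimate, tidy(f3)$estimate))
})

test_that("input validation rejects unusable data", {
  dat <- simulate_dg_microcircuit(microcircuit_spec(n_animals = 10), seed = 1)
  expect_error(fit_path_model(dat[, -2]), "lacks column")
  bad <- dat; bad$GC[1] <- NA
  expect_error(fit_path_model(bad), "finite")
  expect_error(fit_path_model(dat[1:3, ]), "at least 4")
  expect_error(fit_path_model(dat, chains = 1), "2 chains")
})

test_that("split R-hat is near 1 for iid chains and large for split ones", {
  set.seed(81)
  iid <- lapply(1:4, function(i) {
    matrix(rnorm(1000), ncol = 1, dimnames = list(NULL, "b1"))
  })
  r <- rhat(fake_fit(iid))
  expect_gt(r[["b1"]], 0.99)
  expect_lt(r[["b1"]], 1.02)
  shifted <- iid
  shifted[[1]] <- shifted[[1]] + 10
  expect_gt(rhat(fake_fit(shifted))[["b1"]], 1.5)
  one <- fake_fit(iid[1])
  expect_error(rhat(one), "2 chains")
  const <- lapply(1:4, function(i) {
    matrix(1, 100, 1, dimnames = list(NULL, "b1"))
  })
  expect_warning(rc <- rhat(fake_fit(const)), "zero within-chain")
  expect_true(is.na(rc[["b1"]]))
})

test_that("PPP is a proportion, moderate for true-model data, tiny under
           gross misspecification", {
  dat <- simulate_dg_microcircuit(microcircuit_spec(n_animals = 200), seed = 83)
  fit <- fit_quick(dat)
  p <- posterior_predictive_p(fit, ndraws = 300, seed = 1)
  expect_gte(p, 0)
  expect_lte(p, 1)
  expect_gt(p, 0.05)
  # gross structural misspecification: a strong direct PV_H -> PV_GL path
  # the model omits, violating the implied-covariance proportionality
  set.seed(84)
  pv_h <- rnorm(200)
  mc <- 0.5 * pv_h + rnorm(200)
  pv_gl <- 2 * pv_h - 0.8 * mc + 0.3 * rnorm(200)
  bad <- tibble::tibble(
    MC = mc, PV_H = pv_h, PV_GL = pv_gl,
    GC = 0.5 * mc - 0.5 * pv_gl + rnorm(200, sd = 0.5)
  )
  fit_bad <- fit_quick(bad)
  expect_lt(posterior_predictive_p(fit_bad, ndraws = 300, seed = 1), 0.05)
})

test_that("WAIC prefers the true model over a path-omitting one", {
  wins <- vapply(1:8, function(s) {
    spec <- microcircuit_spec(
      a1 = -0.5, a2 = 0.5, b1 = 0.7, b2 = -0.7, b3 = 0.3, n_animals = 100
    )
    dat <- simulate_dg_microcircuit(spec, seed = 400 + s)
    # score the GC equation under both: the true predictor set vs one where
    # the strong MC path is severed (MC replaced by independent noise)
    full <- fit_quick(dat, path_model_spec("model2"), seed = s)
    noised <- dat
    set.seed(600 + s)
    noised$MC <- rnorm(nrow(dat))
    reduced <- fit_quick(noised, path_model_spec("model2"), seed = s)
    information_criteria(full, ndraws = 600)$WAIC <
      information_criteria(reduced, ndraws = 600)$WAIC
  }, logical(1))
  expect_gte(sum(wins), 7)
})

test_that("duplicating the data doubles the deviance scale of the criteria", {
  dat <- simulate_dg_microcircuit(microcircuit_spec(n_animals = 150), seed = 85)
  f1 <- fit_quick(dat)
  f2 <- fit_quick(dplyr::bind_rows(dat, dat))
  ic1 <- information_criteria(f1, ndraws = 600)
  ic2 <- suppressWarnings(information_criteria(f2, ndraws = 600))
  expect_equal(ic2$DIC / ic1$DIC, 2, tolerance = 0.05)
  expect_equal(ic2$WAIC / ic1$WAIC, 2, tolerance = 0.05)
  expect_equal(ic2$LOOIC / ic1$LOOIC, 2, tolerance = 0.05)
})

test_that("WAIC and LOOIC agree for a well-behaved true-model fit", {
  dat <- simulate_dg_microcircuit(microcircuit_spec(n_animals = 200), seed = 86)
  ic <- information_criteria(fit_quick(dat))
  expect_lt(abs(ic$WAIC - ic$LOOIC), 2)
  expect_equal(ic$n_flagged, 0L)
})

test_that("indirect draws equal the product of component draws exactly", {
  dat <- simulate_dg_microcircuit(microcircuit_spec(n_animals = 60), seed = 87)
  fit <- fit_quick(dat, chains = 2, warmup = 100, draws = 300)
  eff <- derived_effects(fit)
  dr <- attr(eff, "draws")
  expect_identical(dr[["MC->PV_GL->GC"]], dr[["MC->PV_GL"]] * dr[["PV_GL->GC"]])
  expect_identical(dr[["PV_H->MC->GC"]], dr[["PV_H->MC"]] * dr[["MC->GC"]])
  expect_identical(
    dr[["PV_H->MC->PV_GL->GC"]],
    dr[["PV_H->MC"]] * dr[["MC->PV_GL"]] * dr[["PV_GL->GC"]]
  )
  expect_identical(dr[["total MC->GC"]], dr[["MC->GC"]] + dr[["MC->PV_GL->GC"]])
  expect_identical(
    dr[["total PV_H->GC"]], dr[["PV_H->GC"]] + dr[["PV_H->MC->GC"]]
  )
  expect_error(derived_effects(fit_quick(dat, path_model_spec("model2"),
                                         chains = 2, warmup = 100,
                                         draws = 200)),
               "model1")
})

test_that("the standardized indirect effect matches the closed-form oracle", {
  spec <- microcircuit_spec(
    a1 = 0, a2 = 0.5, b1 = 0, b2 = -0.7, b3 = 0, n_animals = 2000
  )
  dat <- simulate_dg_microcircuit(spec, seed = 88)
  fit <- fit_quick(dat)
  eff <- derived_effects(fit)
  V <- oracle_microcircuit_cov(0, 0.5, 0, -0.7, 0)
  want <- 0.5 * (-0.7) * sqrt(V["MC", "MC"]) / sqrt(V["GC", "GC"])
  got <- eff$estimate[eff$effect == "MC->PV_GL->GC"]
  expect_equal(got, want, tolerance = 0.05 / abs(want))
  expect_true(eff$significant[eff$effect == "MC->PV_GL->GC"])
})

test_that("standardized effects are invariant to rescaling a variable", {
  dat <- simulate_dg_microcircuit(microcircuit_spec(n_animals = 120), seed = 89)
  f1 <- fit_quick(dat, chains = 2, warmup = 150, draws = 400)
  scaled <- dplyr::mutate(dat, MC = MC * 37)
  f2 <- fit_quick(scaled, chains = 2, warmup = 150, draws = 400)
  e1 <- derived_effects(f1)
  e2 <- derived_effects(f2)
  expect_equal(e1$estimate, e2$estimate, tolerance = 1e-8)
})

test_that("Bayesian R-squared tracks the analytic variance decomposition", {
  dat0 <- simulate_dg_microcircuit(
    microcircuit_spec(a1 = -0.5, a2 = 0.5, b1 = 0, b2 = 0, b3 = 0,
                      n_animals = 1000),
    seed = 90
  )
  expect_lt(r_squared_gc(fit_quick(dat0)), 0.05)
  spec <- microcircuit_spec(
    a1 = -0.5, a2 = 0.5, b1 = 0.6, b2 = -0.7, b3 = 0.3,
    residual_sd = c(1, 1, 0.3), n_animals = 2000
  )
  dat <- simulate_dg_microcircuit(spec, seed = 91)
  V <- oracle_microcircuit_cov(-0.5, 0.5, 0.6, -0.7, 0.3, c(1, 1, 0.3))
  want <- (V["GC", "GC"] - 0.09) / V["GC", "GC"]
  expect_equal(r_squared_gc(fit_quick(dat)), want, tolerance = 0.05 / want)
})

test_that("multigroup DIC prefers the truth-matching structure", {
  shared_spec <- microcircuit_spec(
    a1 = -0.5, a2 = 0.5, b1 = 0.6, b2 = -0.7, b3 = 0.3, n_animals = 50
  )
  make_groups <- function(specs, seed) {
    purrr::imap_dfr(specs, function(sp, g) {
      simulate_dg_microcircuit(sp, seed = seed + match(g, names(specs)),
                               group = g)
    })
  }
  # identical coefficients across groups: restricted should win mostly
  same_wins <- vapply(1:6, function(s) {
    dat <- make_groups(list(A = shared_spec, B = shared_spec), 1000 + 10 * s)
    cmp <- multigroup_fit_compare(dat, chains = 2, warmup = 200, draws = 400,
                                  seed = s)
    cmp$preferred == "restricted"
  }, logical(1))
  expect_gte(sum(same_wins), 4)
  # a large b2 difference: free should win
  diff_spec <- microcircuit_spec(
    a1 = -0.5, a2 = 0.5, b1 = 0.6, b2 = 0, b3 = 0.3, n_animals = 50
  )
  diff_wins <- vapply(1:6, function(s) {
    dat <- make_groups(list(A = shared_spec, B = diff_spec), 2000 + 10 * s)
    cmp <- multigroup_fit_compare(dat, chains = 2, warmup = 200, draws = 400,
                                  seed = s)
    cmp$preferred == "free"
  }, logical(1))
  expect_gte(sum(diff_wins), 5)
  one <- simulate_dg_microcircuit(shared_spec, seed = 1, group = "A")
  expect_error(multigroup_fit_compare(one), "at least 2 groups")
})

test_that("group differences flag the parameter that truly differs", {
  # only b1 differs; the other GC paths are zero so their standardized
  # values stay put despite the change in sd(GC)
  spec_a <- microcircuit_spec(
    a1 = -0.5, a2 = 0.5, b1 = 1.0, b2 = 0, b3 = 0, n_animals = 200
  )
  spec_b <- microcircuit_spec(
    a1 = -0.5, a2 = 0.5, b1 = 0.0, b2 = 0, b3 = 0, n_animals = 200
  )
  flags <- purrr::map_dfr(1:6, function(s) {
    fa <- fit_quick(simulate_dg_microcircuit(spec_a, seed = 3000 + s), seed = s)
    fb <- fit_quick(simulate_dg_microcircuit(spec_b, seed = 4000 + s), seed = s)
    group_difference(fa, fb)
  })
  b1_rate <- mean(flags$flagged[flags$term == "b1"])
  other_rate <- mean(flags$flagged[!flags$term %in% "b1"])
  expect_gte(b1_rate, 0.9)
  expect_lte(other_rate, 0.15)
  # identity: comparing a fit with itself flags nothing
  fa <- fit_quick(simulate_dg_microcircuit(spec_a, seed = 5000), seed = 1)
  self <- group_difference(fa, fa)
  expect_true(all(self$estimate == 0))
  expect_false(any(self$flagged))
  expect_true(all(abs(self$p_gt0 + self$p_lt0 - 1) <= 1))
})
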