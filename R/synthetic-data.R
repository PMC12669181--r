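#' Specify a latent-factor model for regional activation counts
#'
#' Describes the generative model used by [simulate_activation_table()]:
#' regions belong to modules, each module has one latent per-animal factor,
#' and a region's activation is a log-normal count whose log-scale mean loads
#' on its module factor. Regions sharing a module are therefore positively
#' rank-correlated, with the expected Spearman correlation increasing in
#' `loading` — the structure the co-activation network stage assumes.
#'
#' @param n_regions Number of brain regions (columns of the table).
#' @param module_assignment Integer vector of length `n_regions` mapping each
#'   region to a module id. Default: `n_modules` contiguous blocks.
#' @param n_modules Used only to build the default `module_assignment`.
#' @param loading Factor loading(s) in `[0, 1]`, recycled to `n_regions`.
#' @param noise_sd Positive log-scale residual standard deviation.
#' @param baseline_count Positive mean cell count per region (log-normal
#'   median). Raw count magnitudes are not constrained by the analysis (the
#'   pipeline normalizes to percent of group mean and then ranks), so the
#'   default of 100 cells is an arbitrary plausible scale.
#' @param group_effect Named numeric vector of per-group multipliers applied
#'   to the loadings, encoding connectivity (not mean) differences between
#'   groups. Groups absent from the vector get multiplier 1.
#' @param region_names Optional region labels; default `R01, R02, ...`.
#'
#' @return An object of class `factor_spec`.
#' @seealso [simulate_activation_table()]
#' @export
factor_spec <- function(n_regions = 24L,
                        module_assignment = NULL,
                        n_modules = 3L,
                        loading = 0.8,
                        noise_sd = 0.4,
                        baseline_count = 100,
                        group_effect = NULL,
                        region_names = NULL) {
  n_regions <- as.integer(n_regions)
  if (n_regions < 2L) abort("`n_regions` must be at least 2.")
  if (is.null(module_assignment)) {
    module_assignment <- sort(rep_len(seq_len(n_modules), n_regions))
  }
  module_assignment <- as.integer(module_assignment)
  if (length(module_assignment) != n_regions) {
    abort("`module_assignment` must give exactly one module per region.")
  }
  loading <- rep_len(as.numeric(loading), n_regions)
  if (any(loading < 0 | loading > 1)) abort("`loading` must lie in [0, 1].")
  check_positive_scalar(noise_sd, "noise_sd")
  check_positive_scalar(baseline_count, "baseline_count")
  if (is.null(region_names)) {
    region_names <- sprintf("R%02d", seq_len(n_regions))
  }
  structure(
    list(
      n_regions = n_regions,
      module_assignment = module_assignment,
      loading = loading,
      noise_sd = noise_sd,
      baseline_count = baseline_count,
      group_effect = group_effect,
      region_names = region_names
    ),
    class = "factor_spec"
  )
}

#' Simulate a per-animal regional activation table
#'
#' Draws one latent factor per module per animal and generates region values
#' as `baseline_count * exp(loading * factor + noise)`. The output has the
#' layout the whole pipeline consumes: one row per animal, a `group` label,
#' and one column per region with non-negative activation values.
#'
#' @param spec A [factor_spec()].
#' @param group_sizes Named integer vector, group label -> number of animals
#'   (each at least 4, the minimum for the correlation stage).
#' @param seed Integer seed; the same spec and seed give identical tables.
#'
#' @return A tibble with columns `animal_id`, `group`, then one column per
#'   region.
#' @examples
#' tab <- simulate_activation_table(factor_spec(n_regions = 6),
#'                                  group_sizes = c(NOR = 7), seed = 1)
#' @export
simulate_activation_table <- function(spec = factor_spec(),
                                      group_sizes = c(
                                        NOR = 7L, DIST = 7L,
                                        `25` = 7L, `50` = 6L, `75` = 6L
                                      ),
                                      seed = 1L) {
  stopifnot(inherits(spec, "factor_spec"))
  if (is.null(names(group_sizes)) || any(!nzchar(names(group_sizes)))) {
    abort("`group_sizes` must be a named vector (group -> n animals).")
  }
  group_sizes <- vapply(group_sizes, as.integer, integer(1))
  if (any(group_sizes < 1L)) abort("group sizes must be positive.")
  if (any(group_sizes < 4L)) {
    warn("groups with fewer than 4 animals cannot enter the correlation stage.")
  }
  n_modules <- max(spec$module_assignment)
  with_seed(seed, {
    rows <- purrr::imap(group_sizes, function(n, grp) {
      mult <- 1
      if (!is.null(spec$group_effect) && grp %in% names(spec$group_effect)) {
        mult <- spec$group_effect[[grp]]
      }
      factors <- matrix(rnorm(n * n_modules), nrow = n)
      noise <- matrix(rnorm(n * spec$n_regions, sd = spec$noise_sd), nrow = n)
      logval <- factors[, spec$module_assignment, drop = FALSE] *
        rep(spec$loading * mult, each = n) + noise
      vals <- spec$baseline_count * exp(logval)
      colnames(vals) <- spec$region_names
      dplyr::bind_cols(
        tibble::tibble(group = grp),
        tibble::as_tibble(vals)
      )
    })
    out <- dplyr::bind_rows(rows)
    out <- dplyr::mutate(out,
      animal_id = sprintf("a%03d", dplyr::row_number()),
      .before = 1L
    )
    out
  })
}

#' Specify the dentate-gyrus microcircuit generator
#'
#' Structural coefficients of the recursive path system used to generate
#' four-variable microcircuit data: `PV_H` (activated PV+ interneurons in the
#' hilus) is exogenous standard normal; `MC` (activated hilar cells, putative
#' mossy cells) receives `a1 * PV_H`; `PV_GL` (activated PV+ interneurons in
#' the granule cell layer) receives `a2 * MC`; and `GC` (activated granule
#' cells) receives `b1 * MC + b2 * PV_GL + b3 * PV_H`. Each endogenous
#' equation has Gaussian residual noise.
#'
#' @param a1,a2,b1,b2,b3 Structural path coefficients (see Description).
#' @param residual_sd Positive residual standard deviation(s), recycled to
#'   the three endogenous equations (MC, PV_GL, GC).
#' @param n_animals Number of animals (rows), at least 4.
#'
#' @return An object of class `microcircuit_spec`.
#' @export
microcircuit_spec <- function(a1 = -0.5, a2 = 0.5, b1 = 0.6, b2 = -0.7,
                              b3 = 0.3, residual_sd = 1, n_animals = 7L) {
  residual_sd <- rep_len(as.numeric(residual_sd), 3L)
  if (any(residual_sd <= 0)) abort("`residual_sd` must be positive.")
  n_animals <- as.integer(n_animals)
  if (n_animals < 4L) abort("`n_animals` must be at least 4.")
  coefs <- c(a1 = a1, a2 = a2, b1 = b1, b2 = b2, b3 = b3)
  if (any(!is.finite(coefs))) abort("path coefficients must be finite.")
  structure(
    list(
      a1 = a1, a2 = a2, b1 = b1, b2 = b2, b3 = b3,
      residual_sd = residual_sd, n_animals = n_animals
    ),
    class = "microcircuit_spec"
  )
}

#' Simulate microcircuit data from known path coefficients
#'
#' Generates per-animal `(MC, PV_H, PV_GL, GC)` values from the structural
#' equations in [microcircuit_spec()]. Used both as a test fixture with a
#' known truth for the Bayesian path model and to emulate the per-animal
#' PV+/c-Fos+ counts the analysis expects.
#'
#' @param spec A [microcircuit_spec()].
#' @param seed Integer seed.
#' @param group Optional group label column value.
#' @return A tibble with columns `animal_id`, (optionally `group`,) `MC`,
#'   `PV_H`, `PV_GL`, `GC`.
#' @export
simulate_dg_microcircuit <- function(spec = microcircuit_spec(), seed = 1L,
                                     group = NULL) {
  stopifnot(inherits(spec, "microcircuit_spec"))
  n <- spec$n_animals
  with_seed(seed, {
    pv_h <- rnorm(n)
    mc <- spec$a1 * pv_h + rnorm(n, sd = spec$residual_sd[1])
    pv_gl <- spec$a2 * mc + rnorm(n, sd = spec$residual_sd[2])
    gc <- spec$b1 * mc + spec$b2 * pv_gl + spec$b3 * pv_h +
      rnorm(n, sd = spec$residual_sd[3])
    out <- tibble::tibble(
      animal_id = sprintf("m%03d", seq_len(n)),
      MC = mc, PV_H = pv_h, PV_GL = pv_gl, GC = gc
    )
    if (!is.null(group)) out <- dplyr::mutate(out, group = group, .after = 1L)
    out
  })
}

# Model-implied covariance of (MC, PV_H, PV_GL, GC) under the generator's
# structural equations; the independent algebra the generator is tested
# against lives in the test helpers.
implied_microcircuit_cov <- function(spec) {
  s <- spec$residual_sd^2
  # reduced form in terms of (pv_h, e1, e2, e3), Var(pv_h) = 1
  # MC  = a1 pv_h + e1
  # PVG = a2 a1 pv_h + a2 e1 + e2
  # GC  = (b1 a1 + b2 a2 a1 + b3) pv_h + (b1 + b2 a2) e1 + b2 e2 + e3
  L <- rbind(
    MC    = c(spec$a1, 1, 0, 0),
    PV_H  = c(1, 0, 0, 0),
    PV_GL = c(spec$a2 * spec$a1, spec$a2, 1, 0),
    GC    = c(
      spec$b1 * spec$a1 + spec$b2 * spec$a2 * spec$a1 + spec$b3,
      spec$b1 + spec$b2 * spec$a2, spec$b2, 1
    )
  )
  D <- diag(c(1, s[1], s[2], s[3]))
  V <- L %*% D %*% t(L)
  dimnames(V) <- list(rownames(L), rownames(L))
  V
}

#' Simulate novel-object-recognition exploration trials
#'
#' Generates a behavioral trial table (one row per animal and trial) with
#' exploration times of the novel and familiar object. Total exploration per
#' trial is log-normal around `total_time_mean`; the novel object's share of
#' it is `0.5 + novel_bias / 2` plus Gaussian noise, clipped to `[0, 1]`, so
#' the expected per-trial discrimination index D1 is approximately
#' `novel_bias`.
#'
#' @param n_animals,n_trials Table dimensions (`n_trials >= 1`).
#' @param novel_bias Real in `[0, 1)`: expected D1.
#' @param total_time_mean Mean total exploration time per trial, seconds.
#' @param share_sd Standard deviation of the novel-share noise.
#' @param seed Integer seed.
#' @return A tibble with columns `animal_id`, `trial`, `t_novel`,
#'   `t_familiar` (seconds).
#' @export
simulate_behavior_trials <- function(n_animals = 7L, n_trials = 4L,
                                     novel_bias = 0.3, total_time_mean = 30,
                                     share_sd = 0.1, seed = 1L) {
  n_animals <- as.integer(n_animals)
  n_trials <- as.integer(n_trials)
  if (n_trials < 1L) abort("`n_trials` must be at least 1.")
  check_positive_scalar(total_time_mean, "total_time_mean")
  if (novel_bias < 0 || novel_bias >= 1) abort("`novel_bias` must be in [0, 1).")
  with_seed(seed, {
    n <- n_animals * n_trials
    total <- rlnorm(n, meanlog = log(total_time_mean) - 0.125, sdlog = 0.5)
    share <- pmin(pmax(0.5 + novel_bias / 2 + rnorm(n, sd = share_sd), 0), 1)
    tibble::tibble(
      animal_id = rep(sprintf("b%03d", seq_len(n_animals)), each = n_trials),
      trial = rep(seq_len(n_trials), times = n_animals),
      t_novel = total * share,
      t_familiar = total * (1 - share)
    )
  })
}
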