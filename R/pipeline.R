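# End-to-end orchestration: simulate -> behavior -> normalize -> network ->
# metrics -> compare -> path model, from one config, with per-stage seeds
# derived from a single master seed and a manifest of every written
# artifact.

write_stage_csv <- function(df, path, stage, seed, manifest_env) {
  utils::write.csv(df, path, row.names = FALSE)
  manifest_env$rows[[length(manifest_env$rows) + 1L]] <- tibble::tibble(
    stage = stage, path = path, seed = seed,
    md5 = unname(tools::md5sum(path))
  )
  invisible(path)
}

#' Default pipeline configuration
#'
#' @param seed Master seed; per-stage seeds are derived from it.
#' @param alpha Edge significance threshold.
#' @param B Null-ensemble size and permutation count.
#' @param resolution_grid Candidate Louvain resolutions.
#' @param chains,warmup,draws Sampler settings for the path model.
#' @param group_sizes Named group sizes for the simulation stage.
#' @param n_regions Number of simulated regions.
#' @return A named list accepted by [run_pipeline()].
#' @export
pipeline_config <- function(seed = 1L, alpha = 0.05, B = 100L,
                            resolution_grid = c(0.5, 1, 1.3),
                            chains = 4L, warmup = 1000L, draws = 5000L,
                            group_sizes = c(
                              NOR = 7L, DIST = 7L, `25` = 7L,
                              `50` = 6L, `75` = 6L
                            ),
                            n_regions = 24L) {
  list(
    seed = seed, alpha = alpha, B = B, resolution_grid = resolution_grid,
    chains = chains, warmup = warmup, draws = draws,
    group_sizes = group_sizes, n_regions = n_regions
  )
}

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order on simulated study data (or on a
#' user-supplied activation table): behavioral indices and inclusion,
#' percent-of-group-mean normalization, per-group Spearman networks, node
#' metrics with hub detection against shuffle nulls, normalized global
#' metrics, between-group edge-proportion chi-square tests, and the
#' Bayesian microcircuit path model. Every artifact is written as CSV under
#' `out_dir` and listed, with its MD5 checksum and stage seed, in the
#' returned manifest (also written as `manifest.csv`). A failing stage
#' aborts with the stage named and leaves a `FAILED` marker beside the
#' partial outputs.
#'
#' @param config A [pipeline_config()] list (or a path to a YAML file with
#'   the same fields, read with the `yaml` package).
#' @param out_dir Output directory, created if needed.
#' @param activation Optional activation table to use instead of simulating
#'   one.
#' @param microcircuit Optional microcircuit table (columns `MC`, `PV_H`,
#'   `PV_GL`, `GC`) to use instead of simulating one.
#' @return The manifest tibble, invisibly; its attribute `"results"` holds
#'   the in-memory stage outputs.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempdir(),
                         activation = NULL, microcircuit = NULL) {
  if (is.character(config) && length(config) == 1L) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      abort("reading a YAML config requires the yaml package.")
    }
    config <- utils::modifyList(pipeline_config(), yaml::read_yaml(config))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- new.env()
  manifest$rows <- list()
  st <- new.env() # cross-stage state
  seed <- config$seed

  run_stage <- function(stage_name, fn) {
    tryCatch(fn(), error = function(e) {
      writeLines(stage_name, file.path(out_dir, "FAILED"))
      abort(sprintf(
        "pipeline stage '%s' failed: %s", stage_name, conditionMessage(e)
      ))
    })
  }

  run_stage("simulate", function() {
    st$activation <- if (is.null(activation)) {
      simulate_activation_table(
        factor_spec(n_regions = config$n_regions),
        group_sizes = config$group_sizes,
        seed = derive_seed(seed, "simulate-activation")
      )
    } else {
      activation
    }
    st$microcircuit <- if (is.null(microcircuit)) {
      simulate_dg_microcircuit(
        microcircuit_spec(n_animals = sum(config$group_sizes)),
        seed = derive_seed(seed, "simulate-microcircuit")
      )
    } else {
      microcircuit
    }
    st$trials <- simulate_behavior_trials(
      n_animals = sum(config$group_sizes),
      seed = derive_seed(seed, "simulate-behavior")
    )
    write_stage_csv(st$activation, file.path(out_dir, "activation.csv"),
                    "simulate", seed, manifest)
    write_stage_csv(st$microcircuit, file.path(out_dir, "microcircuit.csv"),
                    "simulate", seed, manifest)
    write_stage_csv(st$trials, file.path(out_dir, "behavior_trials.csv"),
                    "simulate", seed, manifest)
  })

  run_stage("behavior", function() {
    st$inclusion <- suppressMessages(d2_inclusion(st$trials))
    write_stage_csv(st$inclusion, file.path(out_dir, "d2_inclusion.csv"),
                    "behavior", seed, manifest)
  })

  run_stage("normalize", function() {
    st$normalized <- normalize_activation(st$activation)
    write_stage_csv(st$normalized,
                    file.path(out_dir, "activation_normalized.csv"),
                    "normalize", seed, manifest)
  })

  run_stage("network", function() {
    groups <- unique(st$normalized$group)
    st$networks <- purrr::map(setNames(groups, groups), function(g) {
      tab <- dplyr::filter(st$normalized, .data$group == g)
      cm <- suppressMessages(spearman_matrix(tab))
      list(cormat = cm, network = build_network(cm, alpha = config$alpha))
    })
    edges_all <- purrr::map_dfr(st$networks, ~ .x$network$edges, .id = "group")
    write_stage_csv(edges_all, file.path(out_dir, "edges.csv"),
                    "network", seed, manifest)
  })

  run_stage("metrics", function() {
    groups <- names(st$networks)
    st$ensembles <- purrr::imap(st$networks, function(x, g) {
      shuffle_null_models(x$cormat, B = config$B,
                          seed = derive_seed(seed, "null", match(g, groups)))
    })
    met <- purrr::imap_dfr(st$networks, function(x, g) {
      nm <- null_node_metrics(st$ensembles[[g]], alpha = config$alpha)
      hubs <- detect_hubs(node_centralities(x$network), nm)
      dplyr::mutate(hubs, group = g, .before = 1L)
    })
    st$node_metrics <- met
    write_stage_csv(met, file.path(out_dir, "node_metrics.csv"),
                    "metrics", seed, manifest)
    glob <- purrr::imap_dfr(st$networks, function(x, g) {
      lat <- lattice_reference(
        x$network, seed = derive_seed(seed, "lattice", match(g, groups))
      )
      purrr::map_dfr(
        c("efficiency", "clustering", "modularity", "mean_strength"),
        ~ suppressMessages(normalize_metric(
          x$network, st$ensembles[[g]], .x, lattice = lat,
          seed = derive_seed(seed, "norm", match(g, groups))
        ))
      ) |> dplyr::mutate(group = g, .before = 1L)
    })
    st$global_metrics <- glob
    write_stage_csv(glob, file.path(out_dir, "global_metrics.csv"),
                    "metrics", seed, manifest)
  })

  run_stage("compare", function() {
    st$edge_tests <- edge_count_tests(purrr::map(st$networks, "network"))
    write_stage_csv(st$edge_tests$pairwise,
                    file.path(out_dir, "edge_tests_pairwise.csv"),
                    "compare", seed, manifest)
    write_stage_csv(st$edge_tests$omnibus,
                    file.path(out_dir, "edge_tests_omnibus.csv"),
                    "compare", seed, manifest)
  })

  run_stage("sem", function() {
    fit <- fit_path_model(
      st$microcircuit,
      chains = config$chains, warmup = config$warmup, draws = config$draws,
      seed = derive_seed(seed, "sem")
    )
    st$path_fit <- fit
    st$effects <- derived_effects(fit)
    write_stage_csv(tidy(fit), file.path(out_dir, "path_posterior.csv"),
                    "sem", seed, manifest)
    write_stage_csv(tibble::as_tibble(st$effects),
                    file.path(out_dir, "path_effects.csv"),
                    "sem", seed, manifest)
  })

  out <- dplyr::bind_rows(manifest$rows)
  utils::write.csv(out, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  attr(out, "results") <- as.list(st)
  invisible(out)
}
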