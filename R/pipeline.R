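#' Run a configured pipeline stage
#'
#' Dispatches a YAML (or JSON) configuration to one of the pipeline stages
#' and writes tidy CSV outputs plus a manifest (`manifest.yaml`: the config
#' echo, the master seed, and the package version) into the output
#' directory. Stages:
#' \describe{
#'   \item{`simulate`}{One session: needs `task`, `agents` (list of
#'     parameter maps), writes `session.csv`.}
#'   \item{`sweep`}{Parameter grid: needs `task`, `grid` (map of vectors,
#'     crossed), optional `n_agents`, `replicates`; writes `sweep.csv`.}
#'   \item{`heterogeneous`}{Needs `task`, `compositions` (named maps of
#'     member parameter lists), `replicates`; writes `members.csv`,
#'     `groups.csv`.}
#'   \item{`horizons`}{Needs `task`, `params`, `horizons`; writes
#'     `horizons.csv`.}
#'   \item{`ode`}{Needs `params` (N, e, pl, ph, theta) and `sigma_grid`;
#'     writes `equilibria.csv`.}
#'   \item{`generate`}{Needs a `design` block; writes a dataset directory
#'     via [write_dataset()].}
#'   \item{`fit`}{Needs `dataset` (path) and optional `variant`, `mcmc`
#'     block; writes `globals.csv`, `individual.csv`, `diagnostics.csv`.}
#'   \item{`compare`}{Needs `dataset` and `variants`; writes `waic.csv` and
#'     `model_comparison.csv`.}
#'   \item{`recover`}{Needs `design`, optional `mcmc`; writes
#'     `correlations.csv`, `coverage.csv`.}
#'   \item{`posthoc`}{Needs `fit_dataset` inputs (`dataset`, `variant`,
#'     `mcmc`) plus `replicates`, `group_size`; writes `posthoc.csv`.}
#' }
#' Every stage requires a top-level integer `seed`.
#'
#' @param config_path Path to the YAML/JSON config file.
#' @param out_dir Output directory (created; defaults to the config's
#'   `out_dir` or the config file's directory).
#' @return Invisibly, a list of the objects produced.
#' @export
run_pipeline <- function(config_path, out_dir = NULL) {
  cfg <- yaml::read_yaml(config_path)
  for (field in c("stage", "seed")) {
    if (is.null(cfg[[field]])) {
      stop("config validation: missing required field '", field, "'",
           call. = FALSE)
    }
  }
  stages <- c("simulate", "sweep", "heterogeneous", "horizons", "ode",
              "generate", "fit", "compare", "recover", "posthoc")
  if (!cfg$stage %in% stages) {
    stop("unknown stage '", cfg$stage, "'; valid stages: ",
         paste(stages, collapse = ", "), call. = FALSE)
  }
  out_dir <- out_dir %||% cfg$out_dir %||% dirname(config_path)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(cfg$seed)
  get_task <- function() {
    if (is.character(cfg$task)) make_preset_task(cfg$task)
    else task_from_config(cfg$task)
  }
  get_mcmc <- function() {
    m <- cfg$mcmc %||% list()
    mcmc_control(chains = m$chains %||% 4, warmup = m$warmup %||% 1000,
                 iter = m$iter %||% 1000)
  }
  fit_from_cfg <- function() {
    experiment <- apply_inclusion_filter(read_dataset(cfg$dataset))
    fit_hierarchical(experiment,
                     hier_model_spec(cfg$variant %||% "decision_biasing"),
                     control = get_mcmc(), seed = seed)
  }
  w <- function(df, name) readr::write_csv(df, file.path(out_dir, name))

  result <- switch(cfg$stage,
    simulate = {
      agents <- purrr::map(cfg$agents, ~ do.call(agent_params, .x))
      sess <- run_session(get_task(), agents, seed = seed)
      w(sess, "session.csv")
      sess
    },
    sweep = {
      grid <- do.call(tidyr::expand_grid, cfg$grid)
      out <- sweep_parameter_grid(get_task(), grid,
                                  n_agents = cfg$n_agents %||% 10,
                                  replicates = cfg$replicates %||% 1000,
                                  seed = seed)
      w(out, "sweep.csv")
      out
    },
    heterogeneous = {
      comps <- purrr::map(cfg$compositions, ~ dplyr::bind_rows(.x))
      out <- run_heterogeneous(get_task(), comps,
                               replicates = cfg$replicates %||% 20000,
                               seed = seed)
      w(out$members, "members.csv")
      w(out$groups, "groups.csv")
      out
    },
    horizons = {
      out <- compare_horizons(get_task(), do.call(agent_params, cfg$params),
                              horizons = cfg$horizons,
                              n_agents = cfg$n_agents %||% 1,
                              replicates = cfg$replicates %||% 1000,
                              seed = seed)
      w(out, "horizons.csv")
      out
    },
    ode = {
      p <- cfg$params
      pp <- population_params(p$N, p$e, p$pl, p$ph, theta = p$theta %||% 0)
      out <- stable_equilibria_scan(pp, sigma_grid = cfg$sigma_grid)
      w(out, "equilibria.csv")
      out
    },
    generate = {
      d <- cfg$design
      design <- experiment_design(
        task = d$task %||% "exp_1r1s_pos", n_groups = d$n_groups %||% 10,
        n_individual = d$n_individual %||% 0,
        dropout_hazard = d$dropout_hazard %||% 0,
        globals = if (is.null(d$globals)) example_group_globals()
                  else do.call(hier_globals, d$globals),
        variant = d$variant %||% "decision_biasing", seed = seed
      )
      experiment <- generate_experiment(design)
      write_dataset(experiment, file.path(out_dir, "dataset"))
      experiment
    },
    fit = {
      fit <- fit_from_cfg()
      w(tidy(fit), "globals.csv")
      w(fit$individual, "individual.csv")
      w(fit$diagnostics, "diagnostics.csv")
      fit
    },
    compare = {
      experiment <- apply_inclusion_filter(read_dataset(cfg$dataset))
      waics <- purrr::map_dfr(cfg$variants, function(v) {
        f <- fit_hierarchical(experiment, hier_model_spec(v),
                              control = get_mcmc(), seed = seed)
        dplyr::mutate(compute_waic(f), model = v)
      })
      w(waics, "waic.csv")
      cmp <- bayesian_model_selection(waics)
      w(tidy(cmp), "model_comparison.csv")
      cmp
    },
    recover = {
      d <- cfg$design
      design <- experiment_design(
        task = d$task %||% "exp_1r1s_pos", n_groups = d$n_groups %||% 10,
        n_individual = d$n_individual %||% 0,
        variant = d$variant %||% "decision_biasing", seed = seed
      )
      globals <- if (is.null(d$globals)) example_group_globals()
                 else do.call(hier_globals, d$globals)
      rep <- parameter_recovery(globals, design, control = get_mcmc(),
                                seed = seed)
      w(rep$correlations, "correlations.csv")
      w(rep$coverage, "coverage.csv")
      rep
    },
    posthoc = {
      fit <- fit_from_cfg()
      out <- posthoc_simulate(fit, get_task(),
                              replicates = cfg$replicates %||% 1000,
                              group_size = cfg$group_size %||% 6,
                              seed = seed)
      w(out, "posthoc.csv")
      out
    }
  )
  yaml::write_yaml(
    list(config = cfg, seed = seed,
         package_version = as.character(utils::packageVersion("socbandit"))),
    file.path(out_dir, "manifest.yaml")
  )
  invisible(result)
}
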