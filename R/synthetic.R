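#' Global (population-level) generative parameters
#'
#' Location and scale of the hierarchical generative model on the
#' transformed scales: `alpha_i = logistic(mu_logit_alpha + v_alpha z)`,
#' `beta_i = exp(mu_log_beta + v_beta z)`,
#' `sigma_i = logistic(mu_logit_sigma + v_sigma z)`,
#' `theta_i = mu_theta + v_theta z`, with `z ~ N(0, 1)`.
#'
#' @param mu_logit_alpha,mu_log_beta,mu_logit_sigma,mu_theta Global means on
#'   the transformed scales.
#' @param v_alpha,v_beta,v_sigma,v_theta Global scales (> 0).
#' @return A named list of class `hier_globals`.
#' @export
hier_globals <- function(mu_logit_alpha, mu_log_beta, mu_logit_sigma = -2,
                         mu_theta = 1, v_alpha = 1, v_beta = 0.5,
                         v_sigma = 1, v_theta = 1) {
  v <- c(v_alpha, v_beta, v_sigma, v_theta)
  if (any(v < 0)) stop("global scales must be >= 0", call. = FALSE)
  structure(list(
    mu_logit_alpha = mu_logit_alpha, mu_log_beta = mu_log_beta,
    mu_logit_sigma = mu_logit_sigma, mu_theta = mu_theta,
    v_alpha = v_alpha, v_beta = v_beta, v_sigma = v_sigma, v_theta = v_theta
  ), class = "hier_globals")
}

#' Representative fitted globals for human group play
#'
#' Global location estimates representative of hierarchical fits to human
#' group play on the positive risk premium 1-risky-1-safe task
#' (`mu_logit_alpha = -2.2`, `mu_log_beta = 1.4`, `mu_logit_sigma = -2.4`,
#' `mu_theta = 1.4`, implying mean alpha near 0.10, mean beta near 4, mean
#' sigma near 0.08). The between-subject spreads are a modelling choice: they are set wide enough that a human-scale population
#' contains both near-asocial and strongly social members and conformity
#' exponents spanning anti-conformist to strongly conformist play, the
#' regime in which individual-level social parameters are recoverable from
#' 70-trial sessions (see the methods vignette).
#'
#' @return A [hier_globals] object.
#' @export
example_group_globals <- function() {
  hier_globals(mu_logit_alpha = -2.2, mu_log_beta = 1.4,
               mu_logit_sigma = -2.4, mu_theta = 1.4,
               v_alpha = 1, v_beta = 0.75, v_sigma = 1.5, v_theta = 2)
}

#' Synthetic experiment design
#'
#' Describes a group bandit study to emulate: a preset task, a mixture of
#' group sizes (uniform over 2..8 by default, matching the range realised in
#' online group sessions), a number of solo (individual-condition) subjects
#' who see no social information (`sigma = 0`), 70 trials, and an optional
#' per-trial dropout hazard that truncates subjects independently of their
#' behaviour.
#'
#' @param task Preset task name (see [make_preset_task()]) or a
#'   [bandit_task].
#' @param n_groups Number of groups.
#' @param group_sizes Optional integer vector of group sizes (length
#'   `n_groups`); sampled uniformly from `size_range` when `NULL`.
#' @param size_range Candidate group sizes (default `2:8`).
#' @param n_individual Number of individual-condition subjects.
#' @param trials Trials per session (default the task horizon, 70 for the
#'   experimental presets).
#' @param dropout_hazard Per-trial probability of disconnecting, in
#'   \[0, 1).
#' @param globals A [hier_globals] generative model.
#' @param variant Generating model variant.
#' @param seed Master seed.
#' @return Object of class `experiment_design`.
#' @export
experiment_design <- function(task = "exp_1r1s_pos", n_groups = 10,
                              group_sizes = NULL, size_range = 2:8,
                              n_individual = 0, trials = NULL,
                              dropout_hazard = 0,
                              globals = example_group_globals(),
                              variant = c("decision_biasing", "asocial",
                                          "value_shaping"),
                              seed = 1) {
  variant <- match.arg(variant)
  if (is.character(task)) task <- make_preset_task(task)
  stopifnot(inherits(task, "bandit_task"), inherits(globals, "hier_globals"))
  trials <- as.integer(trials %||% task$horizon)
  if (trials < 1) stop("trials must be >= 1", call. = FALSE)
  if (dropout_hazard < 0 || dropout_hazard >= 1) {
    stop("dropout hazard must lie in [0, 1)", call. = FALSE)
  }
  if (!is.null(group_sizes)) {
    stopifnot(length(group_sizes) == n_groups)
    if (any(group_sizes < 1 | group_sizes > 8)) {
      stop("group sizes must lie in 1..8", call. = FALSE)
    }
  }
  structure(list(task = task, n_groups = n_groups, group_sizes = group_sizes,
                 size_range = size_range, n_individual = n_individual,
                 trials = trials, dropout_hazard = dropout_hazard,
                 globals = globals, variant = variant, seed = seed),
            class = "experiment_design")
}

#' Draw individual parameters from the generative hierarchy
#'
#' @param globals A [hier_globals].
#' @param n Number of subjects.
#' @param social If `FALSE`, subjects are individual-condition: `sigma = 0`,
#'   `theta = 0`.
#' @return Tibble with columns `alpha, beta, sigma, theta` (all in range by
#'   construction of the transforms).
#' @export
draw_individual_params <- function(globals, n, social = TRUE) {
  stopifnot(inherits(globals, "hier_globals"))
  g <- globals
  out <- tibble::tibble(
    alpha = stats::plogis(g$mu_logit_alpha + g$v_alpha * stats::rnorm(n)),
    beta = exp(g$mu_log_beta + g$v_beta * stats::rnorm(n)),
    sigma = if (social) {
      stats::plogis(g$mu_logit_sigma + g$v_sigma * stats::rnorm(n))
    } else rep(0, n),
    theta = if (social) g$mu_theta + g$v_theta * stats::rnorm(n) else rep(0, n)
  )
  out
}

#' Generate a synthetic experiment dataset
#'
#' Draws per-subject parameters from the design's hierarchical generative
#' model, simulates every group session (and each individual-condition
#' subject as a session of one asocial-information learner), applies the
#' dropout process, and returns the long-format choice data together with
#' the true parameter table.
#'
#' @param design An [experiment_design].
#' @return A list of class `synthetic_experiment` with elements `sessions`
#'   (tibble: `subject_id, group_id, condition, task, trial, choice, payoff,
#'   count_1..K`), `truth` (tibble of per-subject true parameters and
#'   completed trials), `task`, and `design`.
#' @export
generate_experiment <- function(design) {
  stopifnot(inherits(design, "experiment_design"))
  set.seed(design$seed)
  task <- design$task
  K <- length(task$options)
  sizes <- design$group_sizes
  if (is.null(sizes) && design$n_groups > 0) {
    sizes <- sample(design$size_range, design$n_groups, replace = TRUE)
  }
  n_grp_subj <- sum(sizes %||% 0)
  n_ind <- design$n_individual
  n <- n_grp_subj + n_ind

  pars_g <- if (n_grp_subj > 0) {
    draw_individual_params(design$globals, n_grp_subj, social = TRUE)
  } else NULL
  pars_i <- if (n_ind > 0) {
    draw_individual_params(design$globals, n_ind, social = FALSE)
  } else NULL
  pars <- dplyr::bind_rows(pars_g, pars_i)
  condition <- c(rep("group", n_grp_subj), rep("individual", n_ind))
  group_id <- c(
    if (n_grp_subj > 0) rep(seq_along(sizes), times = sizes) else integer(0),
    if (n_ind > 0) max(0, length(sizes)) + seq_len(n_ind) else integer(0)
  )

  # dropout: completed trials; hazard applied per trial, independent of play
  T <- design$trials
  if (design$dropout_hazard > 0) {
    completed <- pmin(T, stats::rgeom(n, design$dropout_hazard) + 1L)
  } else {
    completed <- rep(T, n)
  }

  vcode <- c(asocial = 0L, decision_biasing = 1L, value_shaping = 2L)
  par <- list(alpha = pars$alpha, beta = pars$beta, sigma = pars$sigma,
              theta = pars$theta,
              variant = ifelse(condition == "individual", 0L,
                               vcode[[design$variant]]))
  res <- .sim_engine(task, par, group = group_id - 1L,
                     n_groups = max(group_id), horizon = T,
                     last_trial = completed, exclude_self = TRUE,
                     record = TRUE)
  sess <- .session_tibble(res, n, T, K, group_id = group_id,
                          agent_id = seq_len(n))
  sess <- dplyr::rename(sess, subject_id = "agent", group_id = "group")
  sess$condition <- condition[sess$subject_id]
  sess$task <- task$name
  sess <- dplyr::relocate(sess, "subject_id", "group_id", "condition",
                          "task", "trial", "choice", "payoff")

  truth <- dplyr::mutate(pars,
    subject_id = seq_len(n), group_id = group_id, condition = condition,
    completed_trials = completed, .before = 1)

  structure(list(sessions = sess, truth = truth, task = task,
                 design = design),
            class = "synthetic_experiment")
}

#' @export
print.synthetic_experiment <- function(x, ...) {
  cat(sprintf(
    "<synthetic_experiment> %s: %d subjects (%d group / %d individual), %d rows\n",
    x$task$name, nrow(x$truth), sum(x$truth$condition == "group"),
    sum(x$truth$condition == "individual"), nrow(x$sessions)))
  invisible(x)
}

#' Apply the minimum-rounds inclusion rule
#'
#' Removes subjects who completed fewer than `min_rounds` trials (the
#' inclusion rule: at least the first 35 rounds completed). Subjects completing
#' exactly `min_rounds` are retained. Because dropout is independent of
#' behaviour, the filter induces no selection on parameters.
#'
#' @param experiment A `synthetic_experiment`.
#' @param min_rounds Minimum completed rounds (default 35).
#' @return The filtered `synthetic_experiment`, with attribute
#'   `removed_subjects` listing excluded ids. Warns if nobody survives.
#' @export
apply_inclusion_filter <- function(experiment, min_rounds = 35) {
  stopifnot(inherits(experiment, "synthetic_experiment"))
  done <- experiment$sessions |>
    dplyr::count(.data$subject_id, name = "completed")
  keep <- done$subject_id[done$completed >= min_rounds]
  removed <- setdiff(experiment$truth$subject_id, keep)
  experiment$sessions <- dplyr::filter(experiment$sessions,
                                       .data$subject_id %in% keep)
  experiment$truth <- dplyr::filter(experiment$truth,
                                    .data$subject_id %in% keep)
  if (length(keep) == 0) {
    warning("inclusion filter removed every subject", call. = FALSE)
  }
  attr(experiment, "removed_subjects") <- removed
  experiment
}

.session_schema <- c("subject_id", "group_id", "condition", "task", "trial",
                     "choice", "payoff")
.truth_schema <- c("subject_id", "group_id", "condition", "completed_trials",
                   "alpha", "beta", "sigma", "theta")

#' Write and read a synthetic dataset
#'
#' `write_dataset()` stores the session table, truth table, and task
#' configuration as plain text (`sessions.csv`, `truth.csv`, `meta.yaml`)
#' under `path`; `read_dataset()` restores them, validating the schema and
#' naming any missing column. Extra columns are preserved.
#'
#' @param experiment A `synthetic_experiment`.
#' @param path Directory to write to / read from (created if needed).
#' @return `write_dataset()` returns `path` invisibly; `read_dataset()`
#'   returns a `synthetic_experiment` (without the original design object).
#' @export
write_dataset <- function(experiment, path) {
  stopifnot(inherits(experiment, "synthetic_experiment"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(experiment$sessions, file.path(path, "sessions.csv"))
  readr::write_csv(experiment$truth, file.path(path, "truth.csv"))
  yaml::write_yaml(list(schema_version = 1L,
                        task = task_to_config(experiment$task)),
                   file.path(path, "meta.yaml"))
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  f <- function(x) file.path(path, x)
  for (x in c("sessions.csv", "truth.csv", "meta.yaml")) {
    if (!file.exists(f(x))) stop("missing dataset file: ", x, call. = FALSE)
  }
  meta <- yaml::read_yaml(f("meta.yaml"))
  task <- task_from_config(meta$task)
  sess <- readr::read_csv(f("sessions.csv"), show_col_types = FALSE)
  truth <- readr::read_csv(f("truth.csv"), show_col_types = FALSE)
  count_cols <- paste0("count_", seq_along(task$options))
  .check_schema(sess, c(.session_schema, count_cols), "sessions.csv")
  .check_schema(truth, .truth_schema, "truth.csv")
  structure(list(sessions = sess, truth = truth, task = task, design = NULL),
            class = "synthetic_experiment")
}

.check_schema <- function(df, required, file) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop(sprintf("%s: missing required column(s): %s", file,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}
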