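#' @importFrom Rcpp sourceCpp
#' @importFrom rlang .data %||%
#' @useDynLib socbandit, .registration = TRUE
NULL

.task_option_arrays <- function(task) {
  kind_code <- c(constant = 0L, gaussian = 1L, two_point = 2L)
  kinds <- vapply(task$options, function(o) kind_code[[o$kind]], integer(1))
  g <- function(o, nm1, nm2, nm3) {
    p <- o$pars
    switch(o$kind,
      constant  = c(p[["value"]], 0, 0),
      gaussian  = c(p[["mean"]], p[["sd"]], 0),
      two_point = c(p[["low"]], p[["high"]], p[["p_low"]])
    )
  }
  pm <- vapply(task$options, g, numeric(3))
  list(kind = kinds, p1 = pm[1, ], p2 = pm[2, ], p3 = pm[3, ])
}

.params_to_vectors <- function(agents) {
  if (inherits(agents, "agent_params")) agents <- list(agents)
  if (is.data.frame(agents)) {
    agents <- purrr::pmap(
      agents[intersect(names(agents),
                       c("alpha", "beta", "sigma", "theta", "variant"))],
      agent_params
    )
  }
  stopifnot(all(vapply(agents, inherits, logical(1), what = "agent_params")))
  vcode <- c(asocial = 0L, decision_biasing = 1L, value_shaping = 2L)
  list(
    alpha = vapply(agents, `[[`, numeric(1), "alpha"),
    beta = vapply(agents, `[[`, numeric(1), "beta"),
    sigma = vapply(agents, `[[`, numeric(1), "sigma"),
    theta = vapply(agents, `[[`, numeric(1), "theta"),
    variant = vapply(agents, function(a) vcode[[a$variant]], integer(1))
  )
}

# low-level engine call shared by the simulation front ends; agents may span
# several groups and replicates (group is a 0-based index)
.sim_engine <- function(task, par, group, n_groups, horizon = NULL,
                        last_trial = NULL, exclude_self = TRUE,
                        record = FALSE) {
  opts <- .task_option_arrays(task)
  T <- as.integer(horizon %||% task$horizon)
  n <- length(par$alpha)
  if (is.null(last_trial)) last_trial <- rep(T, n)
  sim_engine_cpp(
    opts$kind, opts$p1, opts$p2, opts$p3, T, task$payoff_scale,
    par$alpha, par$beta, par$sigma, par$theta, par$variant,
    as.integer(group), as.integer(n_groups), as.integer(last_trial),
    exclude_self, as.integer(task$risky_index - 1L),
    as.integer(floor(T / 2)), record
  )
}

#' Run one synchronous group session
#'
#' Simulates a group of learners playing `task` simultaneously. Each agent's
#' choice at trial `t` mixes its softmax preference with the conformist
#' weights of the counts of group members' choices at `t - 1`
#' (decision-biasing), or shapes its values with them (value-shaping).
#' Payoffs are drawn privately from the chosen option only. By default the
#' displayed counts exclude the agent's own previous choice
#' (`exclude_self = TRUE`), so a group of one is informationally asocial.
#'
#' @param task A [bandit_task].
#' @param agents A list of [agent_params] (one per member), a single
#'   `agent_params` (group of one), or a data frame with columns
#'   `alpha, beta, sigma, theta` (and optionally `variant`).
#' @param seed Integer seed; the session is bit-reproducible given
#'   `(task, agents, seed)`.
#' @param exclude_self Should displayed counts exclude the focal agent's own
#'   previous choice?
#' @param horizon Optional override of the task horizon.
#' @return A tibble with one row per agent x trial: `group`, `agent`,
#'   `trial`, `choice`, `payoff` (raw scale), and displayed lagged counts
#'   `count_1 .. count_K` (zero on trial 1).
#' @examples
#' task <- make_preset_task("gaussian_2arm")
#' grp <- replicate(5, agent_params(0.5, 7, 0.3, 2), simplify = FALSE)
#' sess <- run_session(task, grp, seed = 1)
#' prop_risky_second_half(sess, task)
#' @export
run_session <- function(task, agents, seed, exclude_self = TRUE,
                        horizon = NULL) {
  stopifnot(inherits(task, "bandit_task"))
  par <- .params_to_vectors(agents)
  n <- length(par$alpha)
  T <- as.integer(horizon %||% task$horizon)
  if (T < 1) stop("task horizon must be >= 1", call. = FALSE)
  set.seed(seed)
  res <- .sim_engine(task, par, group = rep(0L, n), n_groups = 1L,
                     horizon = T, exclude_self = exclude_self, record = TRUE)
  .session_tibble(res, n, T, length(task$options))
}

.session_tibble <- function(res, n, T, K, group_id = rep(1L, n),
                            agent_id = seq_len(n)) {
  counts <- res$counts
  colnames(counts) <- paste0("count_", seq_len(K))
  out <- tibble::tibble(
    group = rep(group_id, each = T),
    agent = rep(agent_id, each = T),
    trial = rep(seq_len(T), times = n),
    choice = as.integer(t(res$choices)),
    payoff = as.numeric(t(res$payoffs))
  )
  out <- dplyr::bind_cols(out, tibble::as_tibble(counts))
  dplyr::filter(out, !is.na(.data$choice))
}

#' Proportion of risky choices in the second half of a session
#'
#' The mean, over individuals and trials `t > floor(T/2)`, of the indicator
#' that the task's best risky option was chosen (`t > 75` for T = 150,
#' `t > 35` for T = 70).
#'
#' @param session A session tibble from [run_session()].
#' @param task The [bandit_task] the session was played on.
#' @param horizon Optional horizon override (defaults to the task's).
#' @return A single proportion.
#' @export
prop_risky_second_half <- function(session, task, horizon = NULL) {
  stopifnot(inherits(task, "bandit_task"))
  if (nrow(session) == 0) stop("empty session", call. = FALSE)
  T <- horizon %||% max(session$trial)
  half <- floor(T / 2)
  late <- dplyr::filter(session, .data$trial > half)
  mean(late$choice == task$risky_index)
}

#' Sweep learning and social parameters over a grid
#'
#' For every row of the parameter grid, simulates `replicates` independent
#' groups of `n_agents` homogeneous learners and records the mean proportion
#' of risky choice in the second half of the trials.
#'
#' @param task A [bandit_task].
#' @param grid Data frame with columns among `alpha, beta, sigma, theta`
#'   (missing columns are filled with `sigma = 0`, `theta = 0`), e.g. from
#'   [tidyr::expand_grid()].
#' @param n_agents Group size (default 10).
#' @param replicates Groups simulated per grid cell (default 1000).
#' @param seed Integer master seed.
#' @param horizon Optional horizon override.
#' @param variant Model variant for all agents.
#' @param exclude_self Passed to the simulator.
#' @return The grid with columns `prop_risky` (mean across replicates and
#'   members) and `n_groups`, as a tibble.
#' @export
sweep_parameter_grid <- function(task, grid, n_agents = 10, replicates = 1000,
                                 seed = 1, horizon = NULL,
                                 variant = "decision_biasing",
                                 exclude_self = TRUE) {
  stopifnot(inherits(task, "bandit_task"), nrow(grid) >= 1)
  grid <- tibble::as_tibble(grid)
  if (!"sigma" %in% names(grid)) grid$sigma <- 0
  if (!"theta" %in% names(grid)) grid$theta <- 0
  set.seed(seed)
  grid$prop_risky <- purrr::pmap_dbl(
    grid[c("alpha", "beta", "sigma", "theta")],
    function(alpha, beta, sigma, theta) {
      p <- agent_params(alpha, beta, sigma, theta, variant = variant)
      n <- n_agents * replicates
      par <- list(alpha = rep(p$alpha, n), beta = rep(p$beta, n),
                  sigma = rep(p$sigma, n), theta = rep(p$theta, n),
                  variant = rep(c(asocial = 0L, decision_biasing = 1L,
                                  value_shaping = 2L)[[p$variant]], n))
      res <- .sim_engine(task, par,
                         group = rep(seq_len(replicates) - 1L, each = n_agents),
                         n_groups = replicates, horizon = horizon,
                         exclude_self = exclude_self)
      mean(res$prop_target)
    }
  )
  grid$n_groups <- as.integer(replicates)
  class(grid) <- c("sweep_result", class(grid))
  grid
}

#' Heterogeneous-group simulation
#'
#' Simulates sets of group compositions (all of the same size) and reports
#' each member's mean second-half risky proportion across replicates, plus
#' per-composition group means. Compositions vary one focal parameter across
#' members while non-focal parameters stay at the collective-rescue defaults
#' `alpha = 0.5, beta = 7, sigma = 0.3, theta = 2`.
#'
#' @param task A [bandit_task].
#' @param compositions Named list; each element is a data frame of member
#'   parameters (columns `alpha, beta, sigma, theta`) with equal row counts.
#' @param replicates Replications per composition (default 20000; reduce for
#'   interactive use).
#' @param seed Integer master seed.
#' @param exclude_self Passed to the simulator.
#' @return A list with tibbles `members` (composition, member, parameters,
#'   mean performance) and `groups` (composition, group mean), class
#'   `heterogeneous_result`.
#' @export
run_heterogeneous <- function(task, compositions, replicates = 20000,
                              seed = 1, exclude_self = TRUE) {
  stopifnot(inherits(task, "bandit_task"), is.list(compositions))
  sizes <- vapply(compositions, nrow, integer(1))
  if (length(unique(sizes)) != 1) {
    stop("all compositions must share the same group size", call. = FALSE)
  }
  N <- sizes[[1]]
  if (is.null(names(compositions))) {
    names(compositions) <- paste0("composition_", seq_along(compositions))
  }
  set.seed(seed)
  members <- purrr::imap(compositions, function(comp, nm) {
    comp <- tibble::as_tibble(comp)
    if (!"sigma" %in% names(comp)) comp$sigma <- 0
    if (!"theta" %in% names(comp)) comp$theta <- 0
    par <- list(
      alpha = rep(comp$alpha, times = replicates),
      beta = rep(comp$beta, times = replicates),
      sigma = rep(comp$sigma, times = replicates),
      theta = rep(comp$theta, times = replicates),
      variant = rep(1L, N * replicates)
    )
    res <- .sim_engine(task, par,
                       group = rep(seq_len(replicates) - 1L, each = N),
                       n_groups = replicates, exclude_self = exclude_self)
    perf <- matrix(res$prop_target, nrow = N)
    dplyr::mutate(comp, composition = nm, member = dplyr::row_number(),
                  mean_prop_risky = rowMeans(perf), .before = 1)
  })
  members <- dplyr::bind_rows(members)
  groups <- members |>
    dplyr::group_by(.data$composition) |>
    dplyr::summarise(mean_prop_risky = mean(.data$mean_prop_risky),
                     .groups = "drop")
  structure(list(members = members, groups = groups,
                 replicates = replicates),
            class = "heterogeneous_result")
}

#' Compare time horizons
#'
#' Simulates homogeneous groups at each horizon in `horizons` and reports the
#' mean second-half risky proportion per horizon; longer horizons let slow
#' asocial learners approach their asymptotic preference.
#'
#' @param task A [bandit_task].
#' @param params An [agent_params] shared by all members.
#' @param horizons Integer vector of horizons, e.g. `c(150, 1075)`.
#' @param n_agents Group size (1 for asocial learners).
#' @param replicates Groups per horizon.
#' @param seed Integer master seed.
#' @return Tibble with `horizon` and `prop_risky`.
#' @export
compare_horizons <- function(task, params, horizons, n_agents = 1,
                             replicates = 1000, seed = 1) {
  stopifnot(inherits(params, "agent_params"))
  set.seed(seed)
  purrr::map_dfr(horizons, function(T) {
    n <- n_agents * replicates
    vcode <- c(asocial = 0L, decision_biasing = 1L, value_shaping = 2L)
    par <- list(alpha = rep(params$alpha, n), beta = rep(params$beta, n),
                sigma = rep(params$sigma, n), theta = rep(params$theta, n),
                variant = rep(vcode[[params$variant]], n))
    res <- .sim_engine(task, par,
                       group = rep(seq_len(replicates) - 1L, each = n_agents),
                       n_groups = replicates, horizon = T)
    tibble::tibble(horizon = as.integer(T), prop_risky = mean(res$prop_target))
  })
}

# batch of independent asocial learners; returns per-agent proportion of
# risky choice over the last `window` trials (used by long-horizon scans)
.asocial_late_props <- function(task, alpha, beta, n_agents, horizon,
                                window) {
  par <- list(alpha = rep(alpha, n_agents), beta = rep(beta, n_agents),
              sigma = rep(0, n_agents), theta = rep(0, n_agents),
              variant = rep(0L, n_agents))
  opts <- .task_option_arrays(task)
  res <- sim_engine_cpp(
    opts$kind, opts$p1, opts$p2, opts$p3, as.integer(horizon),
    task$payoff_scale, par$alpha, par$beta, par$sigma, par$theta, par$variant,
    seq_len(n_agents) - 1L, n_agents, rep(as.integer(horizon), n_agents),
    TRUE, as.integer(task$risky_index - 1L),
    as.integer(horizon - window), FALSE
  )
  res$prop_target
}

#' Late-trial risky-choice proportion of asocial learners
#'
#' Simulates `n_agents` independent asocial Rescorla-Wagner/softmax learners
#' for `horizon` trials and returns the mean proportion of risky choice over
#' the final `window` trials. At the indifference boundary
#' `alpha * (beta + 1) = 2` on the two-option Gaussian task this converges
#' to one half as the horizon grows.
#'
#' @param task A [bandit_task].
#' @param alpha,beta Learning parameters shared by all learners.
#' @param n_agents Number of independent learners.
#' @param horizon Trial horizon.
#' @param window Number of final trials to average (default `horizon / 10`).
#' @param seed Integer seed.
#' @return Mean late-trial risky proportion across learners.
#' @export
asocial_late_risky <- function(task, alpha, beta, n_agents = 2000,
                               horizon = 5000, window = horizon / 10,
                               seed = 1) {
  set.seed(seed)
  mean(.asocial_late_props(task, alpha, beta, n_agents, horizon, window))
}

#' Locate the asocial choice-shift threshold
#'
#' Scans `alpha` at fixed `beta`, estimates the late-trial risky proportion
#' per value, and linearly interpolates the `alpha` at which the proportion
#' crosses one half. Returns the hot-stove index `alpha * (beta + 1)` at the
#' crossing, expected to sit at 2.
#'
#' @param task A [bandit_task] (two options, positive risk premium).
#' @param alphas Vector of learning rates to scan.
#' @param beta Fixed inverse temperature.
#' @param n_agents Learners per alpha.
#' @param horizon Trial horizon.
#' @param window Late-trial averaging window.
#' @param seed Integer seed.
#' @return List with the interpolated `alpha_cross`, `index_cross`
#'   (= `alpha_cross * (beta + 1)`), and the scan tibble.
#' @export
choice_shift_threshold <- function(task, alphas = seq(0.1, 0.6, by = 0.05),
                                   beta = 4, n_agents = 2000, horizon = 5000,
                                   window = horizon / 10, seed = 1) {
  set.seed(seed)
  scan <- purrr::map_dfr(alphas, function(a) {
    tibble::tibble(
      alpha = a,
      prop_risky = mean(.asocial_late_props(task, a, beta, n_agents,
                                            horizon, window))
    )
  })
  above <- scan$prop_risky > 0.5
  if (all(above) || all(!above)) {
    stop("late-trial proportion does not cross 0.5 on the scanned range",
         call. = FALSE)
  }
  i <- which(above[-length(above)] & !above[-1])[1]  # first downward crossing
  a1 <- scan$alpha[i]; a2 <- scan$alpha[i + 1]
  p1 <- scan$prop_risky[i]; p2 <- scan$prop_risky[i + 1]
  alpha_cross <- a1 + (0.5 - p1) * (a2 - a1) / (p2 - p1)
  list(alpha_cross = alpha_cross,
       index_cross = hot_stove_index(alpha_cross, beta),
       scan = scan)
}
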