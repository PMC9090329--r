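#' MCMC settings
#'
#' @param chains Number of chains (default 4).
#' @param warmup Warmup (adaptation) iterations per chain (default 1000).
#' @param iter Post-warmup draws per chain (default 1000).
#' @param prior_mu_sd Prior s.d. of the global means on the transformed
#'   scales (Normal(0, `prior_mu_sd`), default 2); global scales have a
#'   half-Student-t(4, 0, 1) prior.
#' @return A list of class `mcmc_control`.
#' @export
mcmc_control <- function(chains = 4, warmup = 1000, iter = 1000,
                         prior_mu_sd = 2) {
  stopifnot(chains >= 1, warmup >= 1, iter >= 2)
  structure(list(chains = chains, warmup = warmup, iter = iter,
                 prior_mu_sd = prior_mu_sd), class = "mcmc_control")
}

#' Hierarchical model specification
#'
#' @param variant Model variant: `"asocial"` has no social block
#'   (`mu_logit_sigma`, `mu_theta` absent); `"decision_biasing"` and
#'   `"value_shaping"` carry all four parameter blocks for group-condition
#'   subjects. Individual-condition subjects always have `sigma = 0` and
#'   contribute no information to the social block.
#' @return A list of class `hier_model_spec`.
#' @export
hier_model_spec <- function(variant = c("decision_biasing", "asocial",
                                        "value_shaping")) {
  variant <- match.arg(variant)
  structure(list(variant = variant), class = "hier_model_spec")
}

.global_names <- c("mu_logit_alpha", "mu_log_beta", "mu_logit_sigma",
                   "mu_theta", "v_alpha", "v_beta", "v_sigma", "v_theta")

# flatten a synthetic_experiment (or compatible list) into sampler arrays
.fit_arrays <- function(experiment, spec) {
  sess <- dplyr::arrange(experiment$sessions, .data$subject_id, .data$trial)
  task <- experiment$task
  K <- length(task$options)
  count_cols <- paste0("count_", seq_len(K))
  .check_schema(sess, c(.session_schema, count_cols), "sessions")
  ids <- unique(sess$subject_id)
  n_per <- sess |> dplyr::count(.data$subject_id) |>
    dplyr::arrange(match(.data$subject_id, ids))
  offset <- c(0L, cumsum(n_per$n))
  cond <- sess |>
    dplyr::distinct(.data$subject_id, .data$condition) |>
    dplyr::arrange(match(.data$subject_id, ids))
  vcode <- c(asocial = 0L, decision_biasing = 1L, value_shaping = 2L)
  social <- as.integer(cond$condition == "group" & spec$variant != "asocial")
  sub_variant <- ifelse(social == 1L, vcode[[spec$variant]], 0L)
  list(
    choices = as.integer(sess$choice),
    payoffs = sess$payoff * task$payoff_scale,
    counts = as.matrix(sess[count_cols]),
    offset = offset, social = social, sub_variant = as.integer(sub_variant),
    subject_id = ids, K = K, trial = sess$trial
  )
}

#' Fit the hierarchical learning model by MCMC
#'
#' Fits the non-centred hierarchy
#' `alpha_i = logistic(mu_logit_alpha + v_alpha z_i)`,
#' `beta_i = exp(mu_log_beta + v_beta z_i)`,
#' `sigma_i = logistic(mu_logit_sigma + v_sigma z_i)`,
#' `theta_i = mu_theta + v_theta z_i`, with standard-normal subject effects,
#' Normal(0, 2) priors on the global means and half-Student-t(4, 0, 1)
#' priors on the global scales, using an adaptive random-walk
#' Metropolis-within-Gibbs sampler (scales tuned during warmup only).
#' Individual-condition subjects are fitted with `sigma = 0` and contribute
#' nothing to the social block; an all-individual dataset drops the social
#' block entirely.
#'
#' Convergence is summarised by split-Rhat and effective sample size over
#' the global parameters; the fit is flagged `converged` only when all
#' Rhat < 1.01 and all ESS >= 500. A non-converged fit is still returned,
#' with a diagnostics table.
#'
#' @param experiment A `synthetic_experiment` (or compatible list with
#'   `sessions` and `task`), already passed through the inclusion filter.
#' @param spec A [hier_model_spec].
#' @param control An [mcmc_control].
#' @param seed Integer seed.
#' @return An object of class `socbandit_fit` with elements `globals`
#'   (draws array: iter x chain x parameter), `individual` (tibble of
#'   posterior-mean subject parameters, on the natural and on the sampling
#'   scales), `pointwise` (draws x total-trials
#'   log-likelihood matrix, all chains stacked), `diagnostics`,
#'   `converged`, `spec`, `subject_index`.
#' @export
fit_hierarchical <- function(experiment, spec = hier_model_spec(),
                             control = mcmc_control(), seed = 1) {
  stopifnot(inherits(spec, "hier_model_spec"),
            inherits(control, "mcmc_control"))
  arr <- .fit_arrays(experiment, spec)
  n_subj <- length(arr$subject_id)
  any_social <- any(arr$social == 1L)
  np <- if (any_social) 4L else 2L
  set.seed(seed)
  chains <- vector("list", control$chains)
  for (ch in seq_len(control$chains)) {
    init_mu <- c(stats::rnorm(1, -1, 0.5), stats::rnorm(1, 1, 0.5),
                 stats::rnorm(1, -2, 0.5), stats::rnorm(1, 1, 0.5))
    init_logv <- log(0.5) + stats::rnorm(4, 0, 0.3)
    chains[[ch]] <- fit_hier_chain_cpp(
      arr$choices, arr$payoffs, arr$counts, arr$offset, arr$sub_variant,
      arr$social, control$warmup, control$iter, control$prior_mu_sd,
      init_mu, init_logv, TRUE
    )
  }
  active <- c(seq_len(np), 4L + seq_len(np))
  globals <- array(
    NA_real_, dim = c(control$iter, control$chains, length(active)),
    dimnames = list(NULL, NULL, .global_names[active])
  )
  for (ch in seq_len(control$chains)) {
    globals[, ch, ] <- chains[[ch]]$globals[, active]
  }

  # posterior means of the individual parameters, draws pooled over chains,
  # on both the natural and the sampling (transformed) scales
  ind_nat <- matrix(0, n_subj, 4)
  ind_trans <- matrix(0, n_subj, 4)
  for (ch in seq_len(control$chains)) {
    g <- chains[[ch]]$globals
    z <- chains[[ch]]$z
    for (p in 1:4) {
      x <- sweep(z[, (seq_len(n_subj) - 1) * 4 + p, drop = FALSE] *
                   g[, 4 + p], 1, g[, p], `+`)
      th <- switch(p, stats::plogis(x), exp(x), stats::plogis(x), x)
      if (p >= 3) {
        th[, arr$social == 0L] <- 0
        x[, arr$social == 0L] <- NA_real_
      }
      ind_nat[, p] <- ind_nat[, p] + colMeans(th)
      ind_trans[, p] <- ind_trans[, p] + colMeans(x)
    }
  }
  individual <- tibble::tibble(
    subject_id = arr$subject_id,
    social = arr$social == 1L,
    alpha = ind_nat[, 1] / control$chains,
    beta = ind_nat[, 2] / control$chains,
    sigma = ind_nat[, 3] / control$chains,
    theta = ind_nat[, 4] / control$chains,
    logit_alpha = ind_trans[, 1] / control$chains,
    log_beta = ind_trans[, 2] / control$chains,
    logit_sigma = ind_trans[, 3] / control$chains
  )

  pointwise <- do.call(rbind, lapply(chains, `[[`, "pointwise"))
  diagnostics <- .mcmc_diagnostics(globals)
  converged <- all(diagnostics$rhat < 1.01, na.rm = TRUE) &&
    all(diagnostics$ess >= 500, na.rm = TRUE)

  structure(list(
    globals = globals, individual = individual, pointwise = pointwise,
    diagnostics = diagnostics, converged = converged, spec = spec,
    control = control,
    subject_index = tibble::tibble(subject_id = arr$subject_id[
      findInterval(seq_along(arr$choices) - 1L, arr$offset[-1]) + 1L],
      trial = arr$trial),
    task = experiment$task
  ), class = "socbandit_fit")
}

#' @export
print.socbandit_fit <- function(x, ...) {
  cat(sprintf(
    "<socbandit_fit> %s: %d subjects, %d chains x %d draws, converged: %s\n",
    x$spec$variant, nrow(x$individual), dim(x$globals)[2], dim(x$globals)[1],
    x$converged))
  print(x$diagnostics)
  invisible(x)
}

# split-Rhat and a Geyer-style initial-positive-sequence ESS on an
# iter x chain matrix
.split_rhat <- function(m) {
  m <- as.matrix(m)
  n <- nrow(m)
  half <- floor(n / 2)
  sp <- cbind(m[seq_len(half), , drop = FALSE],
              m[(n - half + 1):n, , drop = FALSE])
  mns <- colMeans(sp)
  vars <- apply(sp, 2, stats::var)
  W <- mean(vars)
  B <- half * stats::var(mns)
  if (W <= 0) return(1)
  sqrt(((half - 1) / half * W + B / half) / W)
}

.ess_basic <- function(m) {
  # pooled over chains after centring each chain
  m <- as.matrix(m)
  n <- nrow(m)
  centred <- sweep(m, 2, colMeans(m))
  total_var <- mean(apply(m, 2, stats::var))
  if (total_var <= 0) return(ncol(m) * n)
  max_lag <- min(n - 1, 500)
  rho <- rep(0, max_lag)
  for (lag in seq_len(max_lag)) {
    acov <- mean(vapply(seq_len(ncol(m)), function(ch) {
      mean(centred[1:(n - lag), ch] * centred[(1 + lag):n, ch])
    }, numeric(1)))
    rho[lag] <- acov / total_var
    if (lag >= 2 && rho[lag] + rho[lag - 1] < 0) {
      rho <- rho[seq_len(lag - 1)]
      break
    }
  }
  ess <- ncol(m) * n / (1 + 2 * sum(pmax(rho, 0)))
  max(ess, 1)
}

.mcmc_diagnostics <- function(globals) {
  pars <- dimnames(globals)[[3]]
  tibble::tibble(
    parameter = pars,
    mean = vapply(pars, function(p) mean(globals[, , p]), numeric(1)),
    sd = vapply(pars, function(p) stats::sd(globals[, , p]), numeric(1)),
    q2.5 = vapply(pars, function(p)
      stats::quantile(globals[, , p], 0.025), numeric(1)),
    q97.5 = vapply(pars, function(p)
      stats::quantile(globals[, , p], 0.975), numeric(1)),
    rhat = vapply(pars, function(p)
      .split_rhat(globals[, , p, drop = TRUE]), numeric(1)),
    ess = vapply(pars, function(p)
      .ess_basic(globals[, , p, drop = TRUE]), numeric(1))
  )
}
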