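#' Per-subject WAIC
#'
#' The widely applicable information criterion per subject, on the deviance
#' scale (lower is better):
#' `WAIC = -2 (lppd - p_waic)` with
#' `lppd = sum_t log mean_d p(choice_t | draw_d)` and
#' `p_waic = sum_t var_d log p(choice_t | draw_d)`,
#' summing over the subject's trials.
#'
#' @param fit A `socbandit_fit` (needs the pointwise log-likelihood matrix
#'   and at least 2 draws).
#' @return Tibble with `subject_id`, `waic`, `lppd`, `p_waic`.
#' @export
compute_waic <- function(fit) {
  stopifnot(inherits(fit, "socbandit_fit"))
  pw <- fit$pointwise
  if (is.null(pw) || nrow(pw) < 2) {
    stop("WAIC needs a pointwise log-likelihood matrix with >= 2 draws",
         call. = FALSE)
  }
  # columnwise log-mean-exp and variance
  mx <- apply(pw, 2, max)
  lppd_t <- mx + log(colMeans(exp(sweep(pw, 2, mx))))
  pwaic_t <- apply(pw, 2, stats::var)
  tibble::tibble(subject_id = fit$subject_index$subject_id,
                 lppd_t = lppd_t, p_waic_t = pwaic_t) |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(lppd = sum(.data$lppd_t),
                     p_waic = sum(.data$p_waic_t), .groups = "drop") |>
    dplyr::mutate(waic = -2 * (.data$lppd - .data$p_waic)) |>
    dplyr::select("subject_id", "waic", "lppd", "p_waic")
}

#' Random-effects Bayesian model selection
#'
#' Treats the model identity as a random effect across subjects. Each
#' subject's model evidence is approximated by `-WAIC/2`; the posterior over
#' population model frequencies is a Dirichlet estimated by the standard
#' variational fixed-point iteration, and each model's exceedance
#' probability (the probability that it is the most frequent model in the
#' population) is computed by Monte-Carlo over that Dirichlet.
#'
#' @param waic_table Tibble with columns `subject_id`, `model`, `waic`
#'   (one row per subject x model), e.g. built from [compute_waic()] calls.
#' @param n_samples Dirichlet Monte-Carlo samples for the exceedance
#'   probability.
#' @param alpha0 Prior Dirichlet count per model (default 1).
#' @return Object of class `model_comparison`: tibble with `model`,
#'   `frequency` (expected population frequency, sums to 1),
#'   `exceedance` (sums to 1), `alpha` (Dirichlet parameters), plus the
#'   attribute `assignments` (per-subject model responsibilities).
#' @export
bayesian_model_selection <- function(waic_table, n_samples = 100000,
                                     alpha0 = 1) {
  .check_schema(waic_table, c("subject_id", "model", "waic"), "waic table")
  wide <- waic_table |>
    dplyr::select("subject_id", "model", "waic") |>
    tidyr::pivot_wider(names_from = "model", values_from = "waic")
  models <- setdiff(names(wide), "subject_id")
  if (anyNA(wide[models])) {
    stop("each subject needs a WAIC for every model", call. = FALSE)
  }
  lme <- -as.matrix(wide[models]) / 2 # subject x model log evidence
  n <- nrow(lme); M <- ncol(lme)
  if (M == 1) {
    out <- tibble::tibble(model = models, frequency = 1, exceedance = 1,
                          alpha = alpha0 + n)
    class(out) <- c("model_comparison", class(out))
    return(out)
  }
  a <- rep(alpha0, M)
  for (it in 1:200) {
    lg <- sweep(lme, 2, digamma(a) - digamma(sum(a)), `+`)
    lg <- lg - apply(lg, 1, max)
    u <- exp(lg)
    u <- u / rowSums(u)
    a_new <- alpha0 + colSums(u)
    if (max(abs(a_new - a)) < 1e-10) { a <- a_new; break }
    a <- a_new
  }
  freq <- as.numeric(a / sum(a))
  a <- as.numeric(a)
  # exceedance by Dirichlet Monte-Carlo (gamma representation)
  g <- matrix(stats::rgamma(n_samples * M, shape = rep(a, each = n_samples)),
              n_samples, M)
  xp <- tabulate(max.col(g), nbins = M) / n_samples
  out <- tibble::tibble(model = models, frequency = freq, exceedance = xp,
                        alpha = a)
  attr(out, "assignments") <- tibble::tibble(subject_id = wide$subject_id) |>
    dplyr::bind_cols(tibble::as_tibble(u, .name_repair = ~models))
  class(out) <- c("model_comparison", class(out))
  out
}

#' Parameter-recovery experiment
#'
#' Generates a synthetic experiment from known globals, refits the
#' generating model by MCMC, and reports (i) the Pearson correlation between
#' true and posterior-mean individual parameter values for each of alpha,
#' beta, sigma, theta — computed on the sampling scales (logit alpha, log
#' beta, logit sigma, theta), where the estimator is stable — and (ii)
#' whether each true global fell inside its 95% posterior credible
#' interval.
#'
#' @param globals True [hier_globals] used to generate.
#' @param design An [experiment_design] (its `globals` are replaced by
#'   `globals`).
#' @param control An [mcmc_control].
#' @param seed Integer seed (generation and fitting).
#' @return List of class `recovery_report`: `correlations` (tibble
#'   parameter/correlation), `coverage` (tibble of globals with CI and
#'   recovered flag), `fit`, `truth`.
#' @export
parameter_recovery <- function(globals, design, control = mcmc_control(),
                               seed = 1) {
  stopifnot(inherits(globals, "hier_globals"))
  design$globals <- globals
  design$seed <- seed
  experiment <- generate_experiment(design)
  experiment <- apply_inclusion_filter(experiment)
  fit <- fit_hierarchical(experiment, hier_model_spec(design$variant),
                          control = control, seed = seed + 1)
  est <- dplyr::inner_join(
    fit$individual,
    dplyr::select(experiment$truth, "subject_id", true_alpha = "alpha",
                  true_beta = "beta", true_sigma = "sigma",
                  true_theta = "theta", "condition"),
    by = "subject_id"
  )
  soc <- dplyr::filter(est, .data$social)
  cors <- tibble::tibble(
    parameter = c("alpha", "beta", "sigma", "theta"),
    correlation = c(
      stats::cor(est$logit_alpha, stats::qlogis(est$true_alpha)),
      stats::cor(est$log_beta, log(est$true_beta)),
      if (nrow(soc) > 2) {
        stats::cor(soc$logit_sigma, stats::qlogis(soc$true_sigma))
      } else NA_real_,
      if (nrow(soc) > 2) stats::cor(soc$theta, soc$true_theta) else NA_real_
    )
  )
  truth_glob <- unlist(globals)[.global_names]
  cover <- fit$diagnostics |>
    dplyr::mutate(truth = truth_glob[.data$parameter],
                  recovered = .data$truth >= .data$q2.5 &
                    .data$truth <= .data$q97.5)
  structure(list(correlations = cors, coverage = cover, fit = fit,
                 truth = experiment$truth),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("<recovery_report>\n")
  print(x$correlations)
  print(dplyr::select(x$coverage, "parameter", "truth", "q2.5", "q97.5",
                      "recovered"))
  invisible(x)
}

#' Posterior predictive group simulation
#'
#' For each replicate, draws one posterior sample of the global parameters,
#' samples a fresh group of individuals from that hierarchy, simulates a
#' session on `task`, and records the per-trial proportion of risky choice.
#' Summaries are the posterior predictive mean and an 80% credible band per
#' trial.
#'
#' @param fit A converged `socbandit_fit` of a social variant.
#' @param task A [bandit_task].
#' @param replicates Number of simulated sessions (default 1000; the full
#'   protocol uses 100000).
#' @param group_size Group size (default 6).
#' @param individual Simulate the individual condition instead (asocial
#'   learners, `sigma = 0`)?
#' @param seed Integer seed.
#' @param band Credible band mass (default 0.8).
#' @return Tibble of class `posthoc_prediction`: `trial`, `mean`, `lower`,
#'   `upper`.
#' @export
posthoc_simulate <- function(fit, task, replicates = 1000, group_size = 6,
                             individual = FALSE, seed = 1, band = 0.8) {
  stopifnot(inherits(fit, "socbandit_fit"), inherits(task, "bandit_task"))
  set.seed(seed)
  g <- fit$globals
  n_draws <- dim(g)[1] * dim(g)[2]
  flat <- matrix(g, n_draws, dim(g)[3])
  colnames(flat) <- dimnames(g)[[3]]
  has_social <- "mu_logit_sigma" %in% colnames(flat) && !individual
  T <- task$horizon
  K <- length(task$options)
  vcode <- c(asocial = 0L, decision_biasing = 1L, value_shaping = 2L)
  variant <- if (has_social) vcode[[fit$spec$variant]] else 0L
  n <- if (individual) 1L else as.integer(group_size)

  draw_idx <- sample.int(n_draws, replicates, replace = TRUE)
  risky_prop <- matrix(NA_real_, replicates, T)
  opts <- .task_option_arrays(task)
  for (r in seq_len(replicates)) {
    d <- flat[draw_idx[r], ]
    gl <- hier_globals(
      mu_logit_alpha = d[["mu_logit_alpha"]], mu_log_beta = d[["mu_log_beta"]],
      mu_logit_sigma = if (has_social) d[["mu_logit_sigma"]] else -20,
      mu_theta = if (has_social) d[["mu_theta"]] else 0,
      v_alpha = d[["v_alpha"]], v_beta = d[["v_beta"]],
      v_sigma = if (has_social) d[["v_sigma"]] else 0,
      v_theta = if (has_social) d[["v_theta"]] else 0
    )
    pars <- draw_individual_params(gl, n, social = has_social)
    res <- sim_engine_cpp(
      opts$kind, opts$p1, opts$p2, opts$p3, T, task$payoff_scale,
      pars$alpha, pars$beta, pars$sigma, pars$theta,
      rep(variant, n), rep(0L, n), 1L, rep(T, n), TRUE,
      as.integer(task$risky_index - 1L), 0L, TRUE
    )
    risky_prop[r, ] <- colMeans(res$choices == task$risky_index)
  }
  lo <- (1 - band) / 2
  out <- tibble::tibble(
    trial = seq_len(T),
    mean = colMeans(risky_prop),
    lower = apply(risky_prop, 2, stats::quantile, probs = lo),
    upper = apply(risky_prop, 2, stats::quantile, probs = 1 - lo)
  )
  class(out) <- c("posthoc_prediction", class(out))
  out
}
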