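# small-but-real MCMC runs: sizes chosen so the whole file stays in tens of
# seconds while still exercising every inference path

test_that("hierarchical fits return draws, diagnostics, and tidiers work", {
  ex <- apply_inclusion_filter(small_experiment(n_groups = 3, size = 4,
                                                seed = 21))
  fit <- fit_hierarchical(ex, hier_model_spec("decision_biasing"),
                          control = mcmc_control(chains = 2, warmup = 200,
                                                 iter = 200), seed = 1)
  expect_s3_class(fit, "socbandit_fit")
  expect_equal(dim(fit$globals), c(200, 2, 8))
  expect_equal(nrow(fit$individual), 12)
  expect_true(all(fit$individual$alpha > 0 & fit$individual$alpha < 1))
  expect_true(all(fit$individual$beta > 0))
  td <- tidy(fit)
  expect_setequal(td$parameter,
                  c("mu_logit_alpha", "mu_log_beta", "mu_logit_sigma",
                    "mu_theta", "v_alpha", "v_beta", "v_sigma", "v_theta"))
  expect_true(all(td$conf.low <= td$estimate & td$estimate <= td$conf.high))
  gl <- glance(fit)
  expect_equal(gl$n_subjects, 12)
  expect_type(gl$converged, "logical")
  expect_equal(nrow(fit$pointwise), 2 * 200)
  expect_equal(ncol(fit$pointwise), 12 * 70)
})

test_that("individual-condition data drop the social block", {
  ex <- apply_inclusion_filter(generate_experiment(
    experiment_design(n_groups = 0, n_individual = 8, seed = 22)))
  fit <- fit_hierarchical(ex, hier_model_spec("decision_biasing"),
                          control = mcmc_control(chains = 2, warmup = 150,
                                                 iter = 150), seed = 2)
  expect_setequal(tidy(fit)$parameter,
                  c("mu_logit_alpha", "mu_log_beta", "v_alpha", "v_beta"))
  expect_true(all(fit$individual$sigma == 0))
})

test_that("a near-zero-data subject shrinks to the population", {
  ex <- apply_inclusion_filter(small_experiment(n_groups = 3, size = 4,
                                                seed = 23))
  # cripple one subject to a single trial (bypassing the inclusion filter,
  # to exercise shrinkage directly)
  ex$sessions <- dplyr::filter(ex$sessions,
                               !(subject_id == 5 & trial > 1))
  fit <- fit_hierarchical(ex, hier_model_spec("decision_biasing"),
                          control = mcmc_control(chains = 2, warmup = 200,
                                                 iter = 200), seed = 3)
  est <- fit$individual
  mu_alpha <- mean(stats::plogis(fit$globals[, , "mu_logit_alpha"]))
  # the one-trial subject's posterior mean hugs the population location
  expect_lt(abs(est$alpha[est$subject_id == 5] - mu_alpha), 0.12)
})

test_that("WAIC is computed per subject and guards its preconditions", {
  ex <- apply_inclusion_filter(small_experiment(n_groups = 2, size = 4,
                                                seed = 24))
  fit <- fit_hierarchical(ex, hier_model_spec("decision_biasing"),
                          control = mcmc_control(chains = 2, warmup = 150,
                                                 iter = 150), seed = 4)
  w <- compute_waic(fit)
  expect_equal(nrow(w), 8)
  expect_true(all(w$p_waic >= 0))
  expect_true(all(is.finite(w$waic)))
  # deviance scale: waic = -2 (lppd - p_waic)
  expect_equal(w$waic, -2 * (w$lppd - w$p_waic))
  # single-draw degenerate input is refused
  broken <- fit
  broken$pointwise <- fit$pointwise[1, , drop = FALSE]
  expect_error(compute_waic(broken), ">= 2 draws")
})

test_that("model selection is symmetric, label-invariant, and decisive", {
  # identical WAICs: frequencies and exceedance split evenly
  tied <- tidyr::expand_grid(subject_id = 1:20,
                             model = c("m1", "m2")) |>
    dplyr::mutate(waic = 100)
  cmp <- bayesian_model_selection(tied, n_samples = 20000)
  expect_equal(cmp$frequency, c(0.5, 0.5), tolerance = 1e-6)
  expect_equal(cmp$exceedance, c(0.5, 0.5), tolerance = 0.02)
  expect_equal(sum(cmp$frequency), 1)
  expect_equal(sum(cmp$exceedance), 1)
  # single model: frequency one
  one <- dplyr::filter(tied, model == "m1")
  expect_equal(bayesian_model_selection(one)$frequency, 1)
  # a clearly better model dominates, and permuting labels permutes results
  set.seed(5)
  tbl <- tidyr::expand_grid(subject_id = 1:20,
                            model = c("good", "bad")) |>
    dplyr::mutate(waic = ifelse(model == "good", 100, 112) + rnorm(40))
  c1 <- bayesian_model_selection(tbl, n_samples = 20000)
  c2 <- bayesian_model_selection(
    dplyr::arrange(tbl, dplyr::desc(model)), n_samples = 20000)
  expect_gt(c1$frequency[c1$model == "good"], 0.9)
  expect_equal(
    c1$frequency[match(c("good", "bad"), c1$model)],
    c2$frequency[match(c("good", "bad"), c2$model)],
    tolerance = 1e-6
  )
})

test_that("the generating model attains the lower WAIC on its own data", {
  ex <- apply_inclusion_filter(generate_experiment(experiment_design(
    task = "exp_1r1s_pos", n_groups = 5, group_sizes = rep(4, 5),
    variant = "decision_biasing", seed = 26)))
  ctrl <- mcmc_control(chains = 2, warmup = 300, iter = 300)
  w_db <- compute_waic(fit_hierarchical(ex, hier_model_spec("decision_biasing"),
                                        control = ctrl, seed = 6))
  w_as <- compute_waic(fit_hierarchical(ex, hier_model_spec("asocial"),
                                        control = ctrl, seed = 6))
  expect_lt(mean(w_db$waic), mean(w_as$waic))
})

test_that("posterior predictive simulation yields coherent bands", {
  ex <- apply_inclusion_filter(small_experiment(n_groups = 3, size = 4,
                                                seed = 27))
  fit <- fit_hierarchical(ex, hier_model_spec("decision_biasing"),
                          control = mcmc_control(chains = 2, warmup = 150,
                                                 iter = 150), seed = 7)
  pred <- posthoc_simulate(fit, ex$task, replicates = 60, group_size = 6,
                           seed = 8)
  expect_equal(nrow(pred), 70)
  expect_true(all(pred$lower <= pred$mean & pred$mean <= pred$upper))
  expect_true(all(pred$mean >= 0 & pred$mean <= 1))
  pred_ind <- posthoc_simulate(fit, ex$task, replicates = 60,
                               individual = TRUE, seed = 8)
  expect_equal(nrow(pred_ind), 70)
})

test_that("sampler diagnostics broadly agree with coda's effective size", {
  skip_if_not_installed("coda")
  ex <- apply_inclusion_filter(small_experiment(n_groups = 2, size = 4,
                                                seed = 28))
  fit <- fit_hierarchical(ex, hier_model_spec("asocial"),
                          control = mcmc_control(chains = 2, warmup = 300,
                                                 iter = 500), seed = 9)
  x <- fit$globals[, , "mu_logit_alpha"]
  ours <- socbandit:::.ess_basic(x)
  coda_ess <- sum(vapply(1:2, function(ch)
    unname(coda::effectiveSize(coda::mcmc(x[, ch]))), numeric(1)))
  expect_gt(ours, 0.25 * coda_ess)
  expect_lt(ours, 4 * coda_ess)
})
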