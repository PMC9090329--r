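test_that("generated parameters respect their supports and target means", {
  set.seed(1)
  g <- example_group_globals()
  pars <- draw_individual_params(g, 2000)
  expect_true(all(pars$alpha > 0 & pars$alpha < 1))
  expect_true(all(pars$sigma > 0 & pars$sigma < 1))
  expect_true(all(pars$beta > 0))
  # sample means converge to the implied means of the transforms (3 s.e.)
  implied <- function(mu, v, trans) {
    z <- stats::qnorm(seq(0.0005, 0.9995, length.out = 4001))
    mean(trans(mu + v * z))
  }
  m_alpha <- implied(g$mu_logit_alpha, g$v_alpha, stats::plogis)
  expect_lt(abs(mean(pars$alpha) - m_alpha),
            3 * stats::sd(pars$alpha) / sqrt(2000))
  m_theta <- g$mu_theta
  expect_lt(abs(mean(pars$theta) - m_theta),
            3 * stats::sd(pars$theta) / sqrt(2000))
  # group-level mean alpha clusters near the human estimate 0.10
  expect_lt(abs(m_alpha - 0.10), 0.05)
  # individual condition: no social parameters
  ind <- draw_individual_params(g, 50, social = FALSE)
  expect_true(all(ind$sigma == 0) && all(ind$theta == 0))
})

test_that("a zero-variance hierarchy collapses to identical subjects", {
  g <- hier_globals(-2, 1.4, -2.4, 1.4, v_alpha = 0, v_beta = 0,
                    v_sigma = 0, v_theta = 0)
  pars <- draw_individual_params(g, 10)
  expect_equal(length(unique(pars$alpha)), 1L)
  expect_equal(pars$beta, rep(exp(1.4), 10))
})

test_that("experiment generation honours the design structure", {
  ex <- small_experiment(n_groups = 3, size = 5, n_individual = 4, seed = 2)
  expect_s3_class(ex, "synthetic_experiment")
  expect_equal(nrow(ex$truth), 19)
  expect_equal(sum(ex$truth$condition == "individual"), 4)
  expect_true(all(ex$truth$sigma[ex$truth$condition == "individual"] == 0))
  expect_equal(nrow(ex$sessions), 19 * 70)
  expect_true(all(ex$sessions$payoff %in% c(50, 550) |
                    abs(ex$sessions$payoff - 150) < 30))
  # 0 groups, only individual subjects
  d0 <- experiment_design(n_groups = 0, n_individual = 3, seed = 3)
  ex0 <- generate_experiment(d0)
  expect_equal(unique(ex0$truth$condition), "individual")
  # reproducibility
  ex2 <- small_experiment(n_groups = 3, size = 5, n_individual = 4, seed = 2)
  expect_identical(ex$sessions, ex2$sessions)
})

test_that("dropout truncates sessions without selecting on parameters", {
  d <- experiment_design(task = "exp_1r1s_pos", n_groups = 40,
                         group_sizes = rep(6, 40), dropout_hazard = 0.02,
                         seed = 4)
  ex <- generate_experiment(d)
  lens <- ex$sessions |> dplyr::count(subject_id)
  expect_true(any(lens$n < 70))
  expect_equal(lens$n, ex$truth$completed_trials)
  filt <- apply_inclusion_filter(ex)
  # hazard-based truncation is independent of behaviour: parameter means
  # before and after filtering agree within 3 standard errors
  for (p in c("alpha", "beta", "sigma", "theta")) {
    se <- stats::sd(ex$truth[[p]]) / sqrt(nrow(filt$truth))
    expect_lt(abs(mean(ex$truth[[p]]) - mean(filt$truth[[p]])), 3 * se)
  }
  # counts after a dropout reflect only members who completed the previous
  # trial (minus the focal agent's own completed choice)
  sess <- ex$sessions
  active_prev <- sess |>
    dplyr::count(group_id, trial, name = "n_active") |>
    dplyr::mutate(trial = trial + 1L)
  joined <- sess |>
    dplyr::filter(trial > 1) |>
    dplyr::left_join(active_prev, by = c("group_id", "trial")) |>
    dplyr::left_join(
      dplyr::transmute(sess, subject_id, trial = trial + 1L, prev = choice),
      by = c("subject_id", "trial")
    )
  counted <- joined$count_1 + joined$count_2
  expect_equal(counted, joined$n_active - !is.na(joined$prev))
})

test_that("the inclusion boundary keeps 35 and drops 34 completed rounds", {
  ex <- small_experiment(n_groups = 2, size = 4, seed = 5)
  # truncate subject 1 at 34 rounds and subject 2 at 35
  ex$sessions <- dplyr::filter(
    ex$sessions,
    !(subject_id == 1 & trial > 34), !(subject_id == 2 & trial > 35)
  )
  filt <- apply_inclusion_filter(ex)
  expect_false(1 %in% filt$truth$subject_id)
  expect_true(2 %in% filt$truth$subject_id)
  expect_equal(attr(filt, "removed_subjects"), 1L)
  # degenerate: everyone truncated early
  ex$sessions <- dplyr::filter(ex$sessions, trial <= 10)
  expect_warning(filt0 <- apply_inclusion_filter(ex), "every subject")
  expect_equal(nrow(filt0$truth), 0)
})

test_that("datasets survive a CSV round-trip with schema validation", {
  ex <- small_experiment(seed = 6)
  dir <- withr::local_tempdir()
  write_dataset(ex, dir)
  back <- read_dataset(dir)
  expect_equal(as.data.frame(back$sessions),
               as.data.frame(ex$sessions), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(back$truth$alpha, ex$truth$alpha, tolerance = 1e-12)
  expect_equal(back$task$expected_values, ex$task$expected_values)
  # extra columns are preserved and harmless
  ex$sessions$note <- "x"
  write_dataset(ex, dir)
  back2 <- read_dataset(dir)
  expect_true("note" %in% names(back2$sessions))
  # a missing required column is reported by name
  sess <- readr::read_csv(file.path(dir, "sessions.csv"),
                          show_col_types = FALSE)
  readr::write_csv(dplyr::select(sess, -payoff),
                   file.path(dir, "sessions.csv"))
  expect_error(read_dataset(dir), "payoff")
})
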