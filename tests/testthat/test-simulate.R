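test_that("sessions are bit-reproducible and schema-complete", {
  task <- gaussian_task()
  grp <- homogeneous_group(5)
  s1 <- run_session(task, grp, seed = 11)
  s2 <- run_session(task, grp, seed = 11)
  s3 <- run_session(task, grp, seed = 12)
  expect_identical(s1, s2)
  expect_false(identical(s1, s3))
  expect_named(s1, c("group", "agent", "trial", "choice", "payoff",
                     "count_1", "count_2"))
  expect_equal(nrow(s1), 5 * 150)
})

test_that("displayed counts are lagged others' choices", {
  task <- gaussian_task()
  s <- run_session(task, homogeneous_group(5), seed = 3)
  # trial 1 rows carry zero counts
  t1 <- dplyr::filter(s, trial == 1)
  expect_true(all(t1$count_1 == 0 & t1$count_2 == 0))
  # later rows: counts sum to the 4 other members (self excluded, no dropout)
  later <- dplyr::filter(s, trial > 1)
  expect_true(all(later$count_1 + later$count_2 == 4))
  # and they equal the others' previous-trial choices, row by row
  prev <- s |>
    dplyr::group_by(trial) |>
    dplyr::summarise(n1 = sum(choice == 1), .groups = "drop")
  joined <- later |>
    dplyr::left_join(
      dplyr::transmute(s, agent, trial = trial + 1L, own_prev = choice),
      by = c("agent", "trial")
    ) |>
    dplyr::left_join(dplyr::mutate(prev, trial = trial + 1L), by = "trial")
  expect_equal(joined$count_1, joined$n1 - (joined$own_prev == 1))
})

test_that("asocial groups equal independent asocial learners", {
  task <- gaussian_task()
  # same members, sigma = 0: a group of 5 and 5 separate singletons consume
  # the same random stream and must produce identical behaviour
  members <- homogeneous_group(5, sigma = 0)
  grouped <- run_session(task, members, seed = 21)
  # the same agents under the asocial variant (counts never consulted)
  asocial <- run_session(task, homogeneous_group(5, sigma = 0,
                                                 variant = "asocial"),
                         seed = 21)
  expect_equal(grouped$choice, asocial$choice)
  expect_equal(grouped$payoff, asocial$payoff)
})

test_that("second-half proportion matches a hand count", {
  task <- gaussian_task()
  s <- toy_session()
  expect_equal(prop_risky_second_half(s, task, horizon = 8), 5 / 8)
  all_risky <- dplyr::mutate(s, choice = 1L)
  expect_equal(prop_risky_second_half(all_risky, task, horizon = 8), 1)
  expect_error(prop_risky_second_half(s[0, ], task), "empty")
})

test_that("strongly hot-stove-prone asocial learners are risk averse", {
  task <- gaussian_task()
  p <- asocial_late_risky(task, alpha = 0.5, beta = 7, n_agents = 1000,
                          horizon = 150, window = 75, seed = 5)
  expect_lt(p, 0.5)
})

test_that("a single-cell sweep composes run_session and the summary", {
  task <- gaussian_task()
  grid <- tibble::tibble(alpha = 0.5, beta = 7, sigma = 0.3, theta = 2)
  sw <- sweep_parameter_grid(task, grid, n_agents = 5, replicates = 1,
                             seed = 31)
  sess <- run_session(task, homogeneous_group(5), seed = 31)
  expect_equal(sw$prop_risky, prop_risky_second_half(sess, task))
})

test_that("social learning enlarges the risk-seeking region of the sweep", {
  task <- gaussian_task()
  grid <- tidyr::expand_grid(alpha = c(0.3, 0.5, 0.7), beta = 7)
  asoc <- sweep_parameter_grid(task, dplyr::mutate(grid, sigma = 0, theta = 0),
                               n_agents = 10, replicates = 60, seed = 41)
  soc <- sweep_parameter_grid(task, dplyr::mutate(grid, sigma = 0.25, theta = 1),
                              n_agents = 10, replicates = 60, seed = 41)
  # all cells sit above the asocial boundary alpha (beta + 1) = 2, so the
  # asocial cells are risk averse and conformist copying lifts every cell
  expect_true(all(asoc$prop_risky < 0.5))
  expect_true(all(soc$prop_risky > asoc$prop_risky))
})

test_that("asocial risk taking declines with the learning rate", {
  task <- gaussian_task()
  grid <- tibble::tibble(alpha = seq(0.1, 0.9, by = 0.2), beta = 7)
  sw <- sweep_parameter_grid(task, grid, n_agents = 1, replicates = 400,
                             seed = 51, variant = "asocial")
  # non-increasing within Monte-Carlo error
  expect_true(all(diff(sw$prop_risky) < 0.03))
  expect_lt(sw$prop_risky[5], sw$prop_risky[1] - 0.1)
})

test_that("heterogeneous runs are exchangeable and composition-tagged", {
  task <- gaussian_task()
  same <- tibble::tibble(alpha = 0.5, beta = 7, sigma = 0.3, theta = 2)[rep(1, 5), ]
  mixed <- tibble::tibble(alpha = c(0.1, 0.3, 0.5, 0.7, 0.9), beta = 7,
                          sigma = 0.3, theta = 2)
  out <- run_heterogeneous(task, list(homog = same, mixed = mixed),
                           replicates = 300, seed = 61)
  expect_setequal(unique(out$members$composition), c("homog", "mixed"))
  # identical members: mean performance equal within Monte-Carlo error
  hom <- dplyr::filter(out$members, composition == "homog")
  expect_lt(diff(range(hom$mean_prop_risky)), 0.08)
  expect_error(
    run_heterogeneous(task, list(a = same, b = mixed[1:3, ])),
    "same group size"
  )
})

test_that("longer horizons move slow asocial learners toward the benchmark", {
  task <- gaussian_task()
  p <- agent_params(0.1, 7, variant = "asocial")  # alpha(beta+1) = 0.8 < 2
  out <- compare_horizons(task, p, horizons = c(150, 1075), n_agents = 1,
                          replicates = 400, seed = 71)
  expect_equal(out$horizon, c(150L, 1075L))
  # below the boundary the asymptotic preference is risk seeking; the longer
  # horizon must get closer to it
  expect_gt(out$prop_risky[2], out$prop_risky[1])
  out2 <- compare_horizons(task, p, horizons = c(150, 1075), n_agents = 1,
                           replicates = 400, seed = 71)
  expect_identical(out, out2)
})
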