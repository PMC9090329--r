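test_that("transition rates follow the social mixture", {
  p0 <- population_params(20, 0.5, 0.2, 0.7, sigma = 0)
  expect_equal(unname(transition_probs(3, 17, p0)), c(0.7, 0.2, 0.2, 0.7))
  # equal densities: social term is one half in every rate
  p1 <- population_params(20, 0.5, 0.2, 0.7, sigma = 0.6, theta = 3)
  tr <- transition_probs(10, 10, p1)
  expect_equal(unname(tr),
               0.4 * c(0.7, 0.2, 0.2, 0.7) + 0.6 * 0.5, tolerance = 1e-12)
  # pure social, linear conformity
  p2 <- population_params(20, 0.5, 0.2, 0.7, sigma = 1, theta = 1)
  expect_equal(unname(transition_probs(5, 15, p2)),
               c(0.75, 0.25, 0.75, 0.25))
  expect_error(transition_probs(0, 0, p0), "positive")
  expect_error(population_params(20, 0.5, 0.8, 0.7), "pl <= ph")
})

test_that("derivatives conserve the population and match hand bookkeeping", {
  p <- population_params(20, 0.5, 0.2, 0.7, sigma = 0)
  d <- ode_rhs(population_state(10, 5, 5), p)
  # hand evaluation: inflows pl*NSm + ph*NSp, outflows ph*(1-e)NR + pl*e*NR
  expect_equal(d[["NR"]], 0.2 * 5 - 0.7 * 5 + 0.7 * 5 - 0.2 * 5)
  expect_equal(d[["NS_minus"]], -0.2 * 5 + 0.7 * 0.5 * 10)
  expect_equal(d[["NS_plus"]], -0.7 * 5 + 0.2 * 0.5 * 10)
  set.seed(8)
  for (i in 1:200) {
    pp <- population_params(20, runif(1), runif(1, 0, 0.5),
                            runif(1, 0.5, 1), runif(1), runif(1, 0, 4))
    st <- c(stats::runif(1, 0, 20), 0, 0)
    rest <- 20 - st[1]
    w <- runif(1)
    st[2] <- rest * w; st[3] <- rest * (1 - w)
    expect_equal(sum(ode_rhs(st, pp)), 0, tolerance = 1e-12)
  }
})

test_that("closed-form asocial equilibrium matches its printed value and zeros", {
  expect_equal(asocial_equilibrium_diff(0.7, 0.2, 0.5, 20), -6.17,
               tolerance = 0.002)
  # neutral curve e = ph/(ph+pl)
  expect_equal(asocial_equilibrium_diff(0.7, 0.2, 0.7 / 0.9, 20), 0,
               tolerance = 1e-12)
  expect_equal(asocial_equilibrium_diff(0.4, 0.4, 0.83, 20), 0)
  expect_error(asocial_equilibrium_diff(0, 0, 0.5, 20), "positive")
  # consistency with the equilibrium ratio form NS:NR
  set.seed(9)
  for (i in 1:100) {
    ph <- runif(1, 0.1, 1); pl <- runif(1, 0.01, ph); e <- runif(1)
    r <- e * pl / ph + (1 - e) * ph / pl
    expect_equal(asocial_equilibrium_diff(ph, pl, e, 20),
                 20 * (1 - r) / (1 + r), tolerance = 1e-9)
  }
})

test_that("integration reaches the closed-form asocial equilibrium", {
  set.seed(10)
  for (i in 1:25) {
    ph <- runif(1, 0.2, 1); pl <- runif(1, 0.05, ph); e <- runif(1)
    p <- population_params(20, e, pl, ph, sigma = 0)
    eq <- integrate_to_equilibrium(p, population_state(10, 5, 5))
    expect_true(attr(eq, "converged"))
    diff_num <- eq[[1]] - eq[[2]] - eq[[3]]
    expect_equal(diff_num, asocial_equilibrium_diff(ph, pl, e, 20),
                 tolerance = 1e-3 * 20)
    expect_equal(sum(eq), 20, tolerance = 1e-6)
    expect_true(all(eq >= 0))
  }
  # starting at the equilibrium returns it unchanged
  p <- population_params(20, 0.6, 0.2, 0.7, sigma = 0)
  eq <- integrate_to_equilibrium(p, population_state(10, 5, 5))
  again <- integrate_to_equilibrium(p, population_state(eq[[1]], eq[[2]],
                                                        eq[[3]]))
  expect_equal(as.numeric(again), as.numeric(eq), tolerance = 1e-6)
  expect_error(integrate_to_equilibrium(p, population_state(1, 1, 1)),
               "sum to the population")
})

test_that("risk seeking never emerges when the risk premium proxy is weak", {
  # e <= 1/2: every social configuration stays risk averse
  for (sg in c(0, 0.3, 0.7)) {
    for (th in c(0, 1, 2)) {
      p <- population_params(20, 0.4, 0.2, 0.7, sigma = sg, theta = th)
      eq <- integrate_to_equilibrium(p, population_state(10, 5, 5))
      expect_true(attr(eq, "converged"))
      expect_lt(eq[[1]], eq[[2]] + eq[[3]])
    }
  }
})

test_that("regime classification splits on the half-population line", {
  expect_equal(classify_regime(c(13, 4, 3), 20), "risk_seeking")
  expect_equal(classify_regime(c(10, 5, 5), 20), "neutral")
  # asocial below the neutral curve: risk averse
  p <- population_params(20, 0.5, 0.2, 0.7, sigma = 0)
  eq <- integrate_to_equilibrium(p, population_state(10, 5, 5))
  expect_equal(classify_regime(eq, 20), "risk_averse")
})

test_that("random-choice social influence dissolves the risky shift", {
  # theta = 0: the shift exists at moderate sigma but vanishes as sigma -> 1
  e <- 0.65
  mid <- integrate_to_equilibrium(
    population_params(20, e, 0.2, 0.7, sigma = 0.5, theta = 0),
    population_state(10, 5, 5))
  hi <- integrate_to_equilibrium(
    population_params(20, e, 0.2, 0.7, sigma = 0.995, theta = 0),
    population_state(10, 5, 5))
  d_mid <- mid[[1]] - mid[[2]] - mid[[3]]
  d_hi <- hi[[1]] - hi[[2]] - hi[[3]]
  expect_lt(abs(d_hi), 0.2)
  expect_lt(abs(d_hi), abs(d_mid))
})

test_that("equilibrium scans count stable states and find monotone growth", {
  # linear conformity: single equilibrium, risky density grows with sigma
  p1 <- population_params(20, 0.65, 0.2, 0.7, theta = 1)
  scan1 <- stable_equilibria_scan(p1, sigma_grid = seq(0, 0.9, by = 0.3))
  expect_true(all(scan1$n_stable == 1))
  nr <- scan1$NR_star[scan1$stable]
  expect_true(all(diff(nr) > 0))
  # sigma = 0 column of any scan: exactly one equilibrium
  p2 <- population_params(20, 0.65, 0.2, 0.7, theta = 2)
  scan0 <- stable_equilibria_scan(p2, sigma_grid = 0)
  expect_equal(unique(scan0$n_stable), 1L)
})
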