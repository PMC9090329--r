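#' Population-dynamics model parameters
#'
#' Parameters of the reduced differential-equation model of collective risky
#' choice. A population of `N` individuals occupies three states: choosing
#' the risky option (`NR`, of whom a fraction `e` holds a positive attitude
#' towards it), and choosing the safe option with a negative (`NS-`) or
#' positive (`NS+`) attitude. `ph` is the per-capita rate of moving towards
#' the preferred option (exploitation), `pl` the rate of moving against the
#' preference (exploration), with `0 <= pl <= ph <= 1`. `sigma` and `theta`
#' add a conformist social term to the transition rates.
#'
#' @param N Population size.
#' @param e Probability that a risky choice leaves a positive attitude
#'   (risk-premium proxy), in \[0, 1\].
#' @param pl,ph Exploration and exploitation rates, `0 <= pl <= ph <= 1`.
#' @param sigma Social influence weight in \[0, 1\].
#' @param theta Conformity exponent.
#' @return Object of class `population_params`.
#' @export
population_params <- function(N, e, pl, ph, sigma = 0, theta = 0) {
  stopifnot(N > 0, e >= 0, e <= 1, sigma >= 0, sigma <= 1, is.finite(theta))
  if (!(pl >= 0 && pl <= ph && ph <= 1)) {
    stop("rates must satisfy 0 <= pl <= ph <= 1", call. = FALSE)
  }
  structure(list(N = N, e = e, pl = pl, ph = ph, sigma = sigma, theta = theta),
            class = "population_params")
}

#' Population state
#'
#' @param NR Density choosing the risky option.
#' @param NS_minus,NS_plus Densities choosing the safe option with negative /
#'   positive attitude.
#' @param e Attitude split of the risky state (`NR+ = e NR`); taken from the
#'   accompanying parameters when used in the integrator.
#' @return Named numeric vector `c(NR, NS_minus, NS_plus)`.
#' @export
population_state <- function(NR, NS_minus, NS_plus) {
  stopifnot(NR >= 0, NS_minus >= 0, NS_plus >= 0)
  c(NR = NR, NS_minus = NS_minus, NS_plus = NS_plus)
}

#' Behavioural transition rates
#'
#' The four per-capita transition rates. Each mixes the asocial baseline
#' (`ph` towards the preferred option, `pl` away from it) with the
#' conformist frequency term `N_i^theta / (NR^theta + NS^theta)`:
#' \deqn{P_{S-} = (1-\sigma) p_h + \sigma N_S^\theta/(N_R^\theta+N_S^\theta)}
#' and analogously for the other three rates.
#'
#' @param NR,NS Current risky and safe densities (`NR + NS > 0`).
#' @param params A [population_params].
#' @return Named vector `c(PS_minus, PR_minus, PS_plus, PR_plus)`.
#' @export
transition_probs <- function(NR, NS, params) {
  stopifnot(inherits(params, "population_params"))
  if (NR + NS <= 0) stop("NR + NS must be positive", call. = FALSE)
  s <- params$sigma
  if (s > 0) {
    fr <- NR^params$theta
    fs <- NS^params$theta
    FS <- fs / (fr + fs)
    FR <- fr / (fr + fs)
  } else {
    FS <- FR <- 0 # unused
  }
  c(
    PS_minus = (1 - s) * params$ph + s * FS,
    PR_minus = (1 - s) * params$pl + s * FR,
    PS_plus  = (1 - s) * params$pl + s * FS,
    PR_plus  = (1 - s) * params$ph + s * FR
  )
}

#' Time derivatives of the population state
#'
#' Inflow/outflow bookkeeping of the three-state system, with `NR+ = e NR`
#' and `NR- = (1 - e) NR` substituted algebraically:
#' \deqn{dN_R/dt = P_{R-} N_{S-} + P_{R+} N_{S+} - P_{S-} (1-e) N_R - P_{S+} e N_R}
#' \deqn{dN_{S-}/dt = -P_{R-} N_{S-} + P_{S-} (1-e) N_R}
#' \deqn{dN_{S+}/dt = -P_{R+} N_{S+} + P_{S+} e N_R}
#' The three derivatives sum to zero (conservation of `N`).
#'
#' @param state Vector `c(NR, NS_minus, NS_plus)`.
#' @param params A [population_params].
#' @return Named derivative vector.
#' @export
ode_rhs <- function(state, params) {
  NR <- state[[1]]; NSm <- state[[2]]; NSp <- state[[3]]
  P <- transition_probs(NR, NSm + NSp, params)
  e <- params$e
  dNR <- P[["PR_minus"]] * NSm + P[["PR_plus"]] * NSp -
    P[["PS_minus"]] * (1 - e) * NR - P[["PS_plus"]] * e * NR
  dNSm <- -P[["PR_minus"]] * NSm + P[["PS_minus"]] * (1 - e) * NR
  dNSp <- -P[["PR_plus"]] * NSp + P[["PS_plus"]] * e * NR
  c(NR = dNR, NS_minus = dNSm, NS_plus = dNSp)
}

#' Integrate the population dynamics to equilibrium
#'
#' Adaptive-step integration (via [deSolve::ode()]) in chunks until the
#' largest absolute derivative drops below `tol`, or `t_max` is reached.
#'
#' @param params A [population_params].
#' @param init Initial state `c(NR, NS_minus, NS_plus)`; must sum to `N`.
#' @param tol Convergence tolerance on `max |d/dt|` (default 1e-8).
#' @param t_max Maximum integration time (default 1e4).
#' @param chunk Integration time per convergence check.
#' @return The terminal state with attributes `converged` (logical) and
#'   `t_end`.
#' @export
integrate_to_equilibrium <- function(params, init, tol = 1e-8, t_max = 1e4,
                                     chunk = 50) {
  stopifnot(inherits(params, "population_params"))
  if (abs(sum(init) - params$N) > 1e-6 * params$N) {
    stop("initial state must sum to the population size N", call. = FALSE)
  }
  rhs <- function(t, y, p) list(ode_rhs(y, params))
  state <- init
  t_now <- 0
  converged <- max(abs(ode_rhs(state, params))) < tol
  while (!converged && t_now < t_max) {
    sol <- deSolve::ode(y = state, times = c(0, chunk), func = rhs,
                        parms = NULL, method = "lsoda",
                        rtol = 1e-10, atol = 1e-10)
    state <- pmax(sol[nrow(sol), -1], 0)
    t_now <- t_now + chunk
    converged <- max(abs(ode_rhs(state, params))) < tol
  }
  structure(state, converged = converged, t_end = t_now)
}

#' Closed-form asocial equilibrium bias
#'
#' The equilibrium difference `NR* - NS*` of the asocial (`sigma = 0`)
#' system:
#' \deqn{-n (p_h - p_l)\{(1-e) p_h - e p_l\} /
#'       [(p_h + p_l)\{(1-e) p_h + e p_l\}]}
#' It vanishes on the neutral curve `e = ph / (ph + pl)` and is consistent
#' with the equilibrium ratio
#' `NS* : NR* = e (pl/ph) + (1-e)(ph/pl) : 1`.
#'
#' @param ph,pl Exploitation and exploration rates (`pl <= ph`,
#'   `pl + ph > 0`).
#' @param e Risk-premium proxy.
#' @param n Population size.
#' @return The density difference `NR* - NS*`.
#' @export
asocial_equilibrium_diff <- function(ph, pl, e, n) {
  if (pl > ph) stop("pl must not exceed ph", call. = FALSE)
  if (ph + pl <= 0) stop("ph + pl must be positive", call. = FALSE)
  -n * (ph - pl) * ((1 - e) * ph - e * pl) /
    ((ph + pl) * ((1 - e) * ph + e * pl))
}

#' Classify the equilibrium regime
#'
#' Risk seeking when `NR* > NS*` beyond tolerance, risk aversion when
#' `NR* < NS*`, neutral within tolerance.
#'
#' @param state Equilibrium state `c(NR, NS_minus, NS_plus)`.
#' @param N Population size.
#' @param tol Neutrality tolerance as a fraction of `N` (default 1e-3).
#' @return One of `"risk_seeking"`, `"risk_averse"`, `"neutral"`.
#' @export
classify_regime <- function(state, N, tol = 1e-3) {
  d <- state[[1]] - (state[[2]] + state[[3]])
  if (abs(d) <= tol * N) "neutral" else if (d > 0) "risk_seeking" else "risk_averse"
}

#' Scan social influence for stable equilibria
#'
#' For each `sigma` in `sigma_grid`, integrates the dynamics from a grid of
#' initial conditions `NR(0)` in `nr0_grid` (the safe remainder split
#' equally between the + and - attitudes), clusters the terminal states with
#' a distinctness tolerance, and confirms local stability by re-integrating
#' from states perturbed by `+-0.5` individuals along `NR`.
#'
#' @param params A [population_params]; its `sigma` entry is overridden by
#'   the grid.
#' @param sigma_grid Vector of social weights to scan.
#' @param nr0_grid Initial risky densities (default `0:N`).
#' @param distinct_tol Equilibria closer than this (in individuals) are
#'   merged (default 0.1).
#' @param tol,t_max Convergence controls for the integrator.
#' @return A tibble of class `bifurcation_scan` with one row per (sigma,
#'   equilibrium): `sigma`, `NR_star`, `stable`, `regime`, `n_stable` (count
#'   of distinct stable equilibria at that sigma), and `converged`.
#' @export
stable_equilibria_scan <- function(params, sigma_grid,
                                   nr0_grid = seq(0, params$N),
                                   distinct_tol = 0.1, tol = 1e-8,
                                   t_max = 1e4) {
  stopifnot(inherits(params, "population_params"))
  rows <- purrr::map_dfr(sigma_grid, function(s) {
    p <- population_params(params$N, params$e, params$pl, params$ph,
                           sigma = s, theta = params$theta)
    ends <- purrr::map(nr0_grid, function(nr0) {
      ns <- (p$N - nr0) / 2
      integrate_to_equilibrium(p, population_state(nr0, ns, ns),
                               tol = tol, t_max = t_max)
    })
    conv <- vapply(ends, function(e) isTRUE(attr(e, "converged")), logical(1))
    nr_star <- vapply(ends, function(e) e[[1]], numeric(1))
    # cluster terminal NR values
    ord <- order(nr_star)
    reps <- list()
    for (i in ord) {
      if (!conv[i]) next
      hit <- FALSE
      for (j in seq_along(reps)) {
        if (abs(nr_star[i] - reps[[j]][[1]]) <= distinct_tol) { hit <- TRUE; break }
      }
      if (!hit) reps <- c(reps, list(ends[[i]]))
    }
    if (length(reps) == 0) {
      return(tibble::tibble(sigma = s, NR_star = NA_real_, stable = NA,
                            regime = NA_character_, n_stable = 0L,
                            converged = FALSE))
    }
    stable <- vapply(reps, function(eq) .is_stable(p, eq, tol, t_max,
                                                   distinct_tol), logical(1))
    keep <- reps[stable]
    n_stable <- length(keep)
    tibble::tibble(
      sigma = s,
      NR_star = vapply(reps, function(e) e[[1]], numeric(1)),
      stable = stable,
      regime = vapply(reps, function(e) classify_regime(e, p$N), character(1)),
      n_stable = as.integer(n_stable),
      converged = TRUE
    )
  })
  class(rows) <- c("bifurcation_scan", class(rows))
  rows
}

# re-integrate from +-0.5-individual perturbations along NR; stable if both
# return to the candidate equilibrium
.is_stable <- function(params, eq, tol, t_max, distinct_tol) {
  NR <- eq[[1]]; NSm <- eq[[2]]; NSp <- eq[[3]]
  ok <- TRUE
  for (d in c(-0.5, 0.5)) {
    nr <- min(max(NR + d, 0), params$N)
    shift <- NR + d - nr # clipped part stays put
    ns_tot <- params$N - nr
    # remove/add the perturbed mass from the safe states proportionally
    if (NSm + NSp > 0) {
      w <- NSm / (NSm + NSp)
    } else {
      w <- 0.5
    }
    st <- population_state(nr, max(ns_tot * w, 0), max(ns_tot * (1 - w), 0))
    end <- integrate_to_equilibrium(params, st, tol = tol, t_max = t_max)
    if (!isTRUE(attr(end, "converged")) ||
        abs(end[[1]] - NR) > max(distinct_tol, 10 * tol)) {
      ok <- FALSE
      break
    }
  }
  ok
}
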