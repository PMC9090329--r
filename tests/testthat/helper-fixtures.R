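# shared fixture builders (everything generated in code)

gaussian_task <- function() make_preset_task("gaussian_2arm")

homogeneous_group <- function(n, alpha = 0.5, beta = 7, sigma = 0.3,
                              theta = 2, variant = "decision_biasing") {
  replicate(n, agent_params(alpha, beta, sigma, theta, variant = variant),
            simplify = FALSE)
}

# a tiny hand-built session table: 2 agents x 8 trials on a 2-option task,
# with 5 choices of option 1 (the risky arm) in the second half (t > 4)
toy_session <- function() {
  choices <- rbind(
    c(2, 2, 1, 2, 1, 1, 2, 1), # agent 1: 3 risky in 2nd half
    c(1, 1, 2, 2, 1, 2, 2, 1)  # agent 2: 2 risky in 2nd half
  )
  tibble::tibble(
    group = 1L, agent = rep(1:2, each = 8L), trial = rep(1:8, 2L),
    choice = as.integer(t(choices)), payoff = 1,
    count_1 = 0L, count_2 = 0L
  )
}

# independent R-level replay of the subject likelihood, built from the
# exported scalar primitives (the C++ path never runs here)
replay_loglik_r <- function(subject_data, params, task) {
  K <- length(task$options)
  sd_ <- dplyr::arrange(subject_data, trial)
  q <- rep(0, K)
  ll <- 0
  for (r in seq_len(nrow(sd_))) {
    counts <- as.numeric(sd_[r, paste0("count_", seq_len(K))])
    first <- sd_$trial[r] == 1
    probs <- if (params$variant == "value_shaping" || first) {
      softmax_probs(q, params$beta)
    } else {
      net_choice_probs(q, counts, params, first_trial = first)
    }
    ch <- sd_$choice[r]
    ll <- ll + log(probs[ch])
    pay <- sd_$payoff[r] * task$payoff_scale
    if (params$variant == "value_shaping" && !first) {
      q <- value_shaping_update(q, pay, ch, counts, params)
    } else {
      q[ch] <- rescorla_wagner_update(q[ch], pay, params$alpha)
    }
  }
  ll
}

small_experiment <- function(n_groups = 2, size = 4, n_individual = 0,
                             seed = 1, ...) {
  generate_experiment(experiment_design(
    task = "exp_1r1s_pos", n_groups = n_groups,
    group_sizes = rep(size, n_groups), n_individual = n_individual,
    seed = seed, ...
  ))
}
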