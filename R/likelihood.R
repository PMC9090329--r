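#' Log-likelihood of one subject's choices
#'
#' Replays a subject's session under the learning model: beliefs are
#' reconstructed from the subject's own observed payoffs (scaled by the
#' task's `payoff_scale`), the choice probability at each trial combines the
#' softmax term with the conformist weights of the displayed lagged counts
#' (decision-biasing) or shapes the values with them (value-shaping), and
#' trial 1 is always asocial. Rows must be ordered by trial.
#'
#' @param subject_data Tibble of one subject's rows (`trial`, `choice`,
#'   `payoff`, `count_1..K`), ordered by trial.
#' @param params An [agent_params].
#' @param task The [bandit_task] played (supplies `payoff_scale` and K).
#' @param pointwise Return the per-trial log-likelihood vector instead of
#'   the sum?
#' @return The summed log-likelihood (or per-trial vector). An error is
#'   raised if any choice probability is non-finite.
#' @export
subject_loglik <- function(subject_data, params, task, pointwise = FALSE) {
  stopifnot(inherits(params, "agent_params"), inherits(task, "bandit_task"))
  K <- length(task$options)
  count_cols <- paste0("count_", seq_len(K))
  .check_schema(subject_data, c("trial", "choice", "payoff", count_cols),
                "subject data")
  subject_data <- dplyr::arrange(subject_data, .data$trial)
  vcode <- c(asocial = 0L, decision_biasing = 1L, value_shaping = 2L)
  pw <- subject_pointwise_cpp(
    as.integer(subject_data$choice),
    subject_data$payoff * task$payoff_scale,
    as.matrix(subject_data[count_cols]),
    params$alpha, params$beta, params$sigma, params$theta,
    vcode[[params$variant]]
  )
  if (pointwise) pw else sum(pw)
}
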