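#' Learner parameters
#'
#' Bundles the four learning parameters: the learning rate `alpha` (weight on
#' the most recent payoff in the Rescorla-Wagner update), the softmax inverse
#' temperature `beta` (exploitation pressure), the copying weight `sigma`
#' (mixture weight on the conformist social term), and the conformity
#' exponent `theta` (nonlinearity of the frequency response; `theta > 1` is
#' conformist, `theta = 0` no social influence, `theta < 0` anti-conformist).
#'
#' `variant` selects how social information enters: `"asocial"` (forces
#' `sigma = 0`), `"decision_biasing"` (social term mixed into the choice
#' probability), or `"value_shaping"` (social term nudges learned values;
#' choice by plain softmax).
#'
#' @param alpha Learning rate in \[0, 1\].
#' @param beta Inverse temperature, `>= 0`.
#' @param sigma Copying weight in \[0, 1\].
#' @param theta Conformity exponent (any real).
#' @param variant Model variant name.
#' @return An object of class `agent_params` (also a plain list).
#' @examples
#' agent_params(0.5, 7, sigma = 0.3, theta = 2)
#' @export
agent_params <- function(alpha, beta, sigma = 0, theta = 0,
                         variant = c("decision_biasing", "asocial",
                                     "value_shaping")) {
  variant <- match.arg(variant)
  if (!is.finite(alpha) || alpha < 0 || alpha > 1) {
    stop("alpha must lie in [0, 1]", call. = FALSE)
  }
  if (!is.finite(beta) || beta < 0) stop("beta must be >= 0", call. = FALSE)
  if (!is.finite(sigma) || sigma < 0 || sigma > 1) {
    stop("sigma must lie in [0, 1]", call. = FALSE)
  }
  if (!is.finite(theta)) stop("theta must be finite", call. = FALSE)
  if (variant == "asocial") sigma <- 0
  structure(list(alpha = alpha, beta = beta, sigma = sigma, theta = theta,
                 variant = variant),
            class = "agent_params")
}

#' @export
print.agent_params <- function(x, ...) {
  cat(sprintf(
    "<agent_params> %s: alpha %.3g, beta %.3g, sigma %.3g, theta %.3g (alpha(beta+1) = %.3g)\n",
    x$variant, x$alpha, x$beta, x$sigma, x$theta, hot_stove_index(x$alpha, x$beta)))
  invisible(x)
}

#' Rescorla-Wagner value update
#'
#' Returns `(1 - alpha) * q + alpha * payoff`. Only the chosen option's value
#' is updated; callers leave unchosen options untouched.
#'
#' @param q Current value estimate.
#' @param payoff Realised payoff.
#' @param alpha Learning rate in \[0, 1\].
#' @return Updated value estimate.
#' @export
rescorla_wagner_update <- function(q, payoff, alpha) {
  if (any(!is.finite(alpha)) || any(alpha < 0) || any(alpha > 1)) {
    stop("alpha must lie in [0, 1]", call. = FALSE)
  }
  (1 - alpha) * q + alpha * payoff
}

#' Softmax choice probabilities
#'
#' Computed in log space with max subtraction, so large `beta * q` values do
#' not overflow. `beta = 0` gives a uniform (random) choice.
#'
#' @param q Numeric vector of value estimates.
#' @param beta Inverse temperature, `>= 0`.
#' @return Probability vector summing to 1.
#' @examples
#' softmax_probs(c(1, 0), 1) # c(e, 1)/(e + 1)
#' @export
softmax_probs <- function(q, beta) {
  if (length(q) == 0) stop("empty value vector", call. = FALSE)
  if (!is.finite(beta) || beta < 0) stop("beta must be >= 0", call. = FALSE)
  z <- beta * q
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

#' Conformist social weights from choice frequencies
#'
#' Each option's weight is `(count + 0.1)^theta` normalised over options. The
#' 0.1 smoothing keeps options chosen by nobody well-defined, and makes them
#' the most attractive under anti-conformity (`theta < 0`). `theta = 0`
#' returns the uniform distribution regardless of the counts.
#'
#' @param counts Non-negative per-option choice counts (previous trial).
#' @param theta Conformity exponent.
#' @param smoothing Additive count smoothing (default 0.1).
#' @return Probability vector summing to 1.
#' @examples
#' conformity_weights(c(9, 0), theta = 1) # c(9.1, 0.1)/9.2
#' @export
conformity_weights <- function(counts, theta, smoothing = 0.1) {
  if (length(counts) == 0) stop("empty counts", call. = FALSE)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  # log-space for numerical robustness at large |theta|
  lw <- theta * log(counts + smoothing)
  lw <- lw - max(lw)
  w <- exp(lw)
  w / sum(w)
}

#' Net choice probabilities under decision-biasing social influence
#'
#' The decision-biasing mixture: `(1 - sigma) * softmax + sigma * conformity`.
#' On the first trial (no social information yet) the softmax term is used
#' alone. With `sigma = 0` this reduces exactly to asocial softmax choice.
#'
#' @param q Value estimates.
#' @param counts Per-option choice counts from the previous trial (ignored
#'   when `first_trial = TRUE`).
#' @param params An [agent_params] object.
#' @param first_trial Logical; is this the first trial of the session?
#' @return Probability vector summing to 1.
#' @export
net_choice_probs <- function(q, counts, params, first_trial = FALSE) {
  stopifnot(inherits(params, "agent_params"))
  a <- softmax_probs(q, params$beta)
  if (first_trial || params$sigma == 0 || params$variant != "decision_biasing") {
    return(a)
  }
  s <- conformity_weights(counts, params$theta)
  (1 - params$sigma) * a + params$sigma * s
}

#' Value-shaping belief update
#'
#' The value-shaping variant applies the Rescorla-Wagner update to the chosen
#' option and then nudges every option's value towards the conformity-weighted
#' choice frequency: each value gains
#' `sigma * (conformity_weight - 1/K)`, a zero-sum social increment across the
#' `K` options. Choice under this variant uses the plain softmax. With
#' `sigma = 0`, or with uniform counts, it reduces to the asocial update.
#'
#' @param q Value-estimate vector (length `K`).
#' @param payoff Realised (scaled) payoff of the chosen option.
#' @param chosen Index of the chosen option.
#' @param counts Per-option counts from the previous trial, or `NULL` on the
#'   first trial (no social increment applied).
#' @param params An [agent_params] object.
#' @return Updated value vector.
#' @export
value_shaping_update <- function(q, payoff, chosen, counts, params) {
  stopifnot(inherits(params, "agent_params"))
  K <- length(q)
  stopifnot(chosen >= 1, chosen <= K)
  q[chosen] <- rescorla_wagner_update(q[chosen], payoff, params$alpha)
  if (!is.null(counts) && params$sigma > 0) {
    w <- conformity_weights(counts, params$theta)
    q <- q + params$sigma * (w - 1 / K)
  }
  q
}

#' Susceptibility to the hot stove effect
#'
#' The product `alpha * (beta + 1)`. In the two-option Gaussian task, values
#' above 2 predict learned risk aversion for asocial learners; values below 2
#' predict eventual risk seeking.
#'
#' @param alpha Learning rate.
#' @param beta Inverse temperature.
#' @return `alpha * (beta + 1)`.
#' @export
hot_stove_index <- function(alpha, beta) {
  alpha * (beta + 1)
}

#' Asocial indifference boundary
#'
#' The inverse temperature at which an asocial learner with learning rate
#' `alpha` is expected to end at indifference between the safe and risky
#' options: `beta = (2 - alpha) / alpha`, i.e. the `alpha * (beta + 1) = 2`
#' contour.
#'
#' @param alpha Learning rate in (0, 1].
#' @return The boundary inverse temperature.
#' @export
asocial_boundary_beta <- function(alpha) {
  if (any(alpha <= 0)) stop("alpha must be > 0", call. = FALSE)
  (2 - alpha) / alpha
}
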