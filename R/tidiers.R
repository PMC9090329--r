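#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a hierarchical fit
#'
#' One row per global parameter: posterior mean, s.d., 95% credible
#' interval, split-Rhat and effective sample size.
#'
#' @param x A `socbandit_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.socbandit_fit <- function(x, ...) {
  dplyr::rename(x$diagnostics, estimate = "mean", std.error = "sd",
                conf.low = "q2.5", conf.high = "q97.5")
}

#' Glance at a hierarchical fit
#'
#' @param x A `socbandit_fit`.
#' @param ... Unused.
#' @return One-row tibble: variant, number of subjects, chains, draws,
#'   worst Rhat, smallest ESS, convergence flag.
#' @export
glance.socbandit_fit <- function(x, ...) {
  tibble::tibble(
    variant = x$spec$variant,
    n_subjects = nrow(x$individual),
    chains = dim(x$globals)[2],
    draws = dim(x$globals)[1],
    max_rhat = max(x$diagnostics$rhat, na.rm = TRUE),
    min_ess = min(x$diagnostics$ess, na.rm = TRUE),
    converged = x$converged
  )
}

#' Tidy a model comparison
#'
#' @param x A `model_comparison`.
#' @param ... Unused.
#' @return Tibble with model, frequency, and exceedance probability.
#' @export
tidy.model_comparison <- function(x, ...) {
  tibble::as_tibble(x)[c("model", "frequency", "exceedance")]
}

#' Tidy a recovery report
#'
#' @param x A `recovery_report`.
#' @param ... Unused.
#' @return The true-vs-recovered correlation table.
#' @export
tidy.recovery_report <- function(x, ...) {
  x$correlations
}
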