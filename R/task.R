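#' Payoff-generating option specifications
#'
#' A `payoff_spec` describes the reward distribution attached to one arm of a
#' bandit task. Three kinds are supported: a constant payoff, a Gaussian
#' payoff, and a two-point gamble paying one of two values.
#'
#' @param value Constant payoff value.
#' @param mean,sd Mean and standard deviation of a Gaussian payoff (`sd >= 0`).
#' @param low,high,p_low The two outcomes of a two-point gamble and the
#'   probability of the low outcome (`p_low` in \[0, 1\]).
#' @param label Optional human-readable arm label.
#' @param risky Logical; whether the arm counts as risky (payoff variance
#'   intended to matter for the learner). Used when summarising risk seeking.
#'
#' @return An object of class `payoff_spec`.
#' @examples
#' payoff_gaussian(1.5, 1)
#' expected_value(payoff_two_point(50, 550, 0.7))
#' @name payoff_spec
NULL

new_payoff_spec <- function(kind, pars, label, risky) {
  structure(
    list(kind = kind, pars = pars, label = label, risky = risky),
    class = "payoff_spec"
  )
}

#' @rdname payoff_spec
#' @export
payoff_constant <- function(value, label = "safe", risky = FALSE) {
  stopifnot(is.numeric(value), length(value) == 1, is.finite(value))
  new_payoff_spec("constant", c(value = value), label, risky)
}

#' @rdname payoff_spec
#' @export
payoff_gaussian <- function(mean, sd, label = NULL, risky = NA) {
  stopifnot(is.finite(mean), is.finite(sd))
  if (sd < 0) stop("Gaussian payoff s.d. must be >= 0", call. = FALSE)
  if (is.na(risky)) risky <- sd >= 0.5 * abs(mean) && sd > 0
  if (is.null(label)) label <- if (risky) "risky" else "safe"
  new_payoff_spec("gaussian", c(mean = mean, sd = sd), label, risky)
}

#' @rdname payoff_spec
#' @export
payoff_two_point <- function(low, high, p_low, label = "risky", risky = TRUE) {
  stopifnot(is.finite(low), is.finite(high), is.finite(p_low))
  if (p_low < 0 || p_low > 1) {
    stop("two-point probability must lie in [0, 1]", call. = FALSE)
  }
  new_payoff_spec("two_point", c(low = low, high = high, p_low = p_low),
                  label, risky)
}

#' @export
print.payoff_spec <- function(x, ...) {
  p <- x$pars
  desc <- switch(x$kind,
    constant  = sprintf("constant %g", p[["value"]]),
    gaussian  = sprintf("Gaussian(mean %g, sd %g)", p[["mean"]], p[["sd"]]),
    two_point = sprintf("two-point {%g w.p. %g; %g w.p. %g}",
                        p[["low"]], p[["p_low"]], p[["high"]], 1 - p[["p_low"]])
  )
  cat(sprintf("<payoff_spec> %s [%s%s]\n", desc, x$label,
              if (x$risky) ", risky" else ""))
  invisible(x)
}

#' Exact expected payoff of an option
#'
#' @param spec A [payoff_spec] object.
#' @return The expectation of the payoff distribution.
#' @examples
#' expected_value(payoff_two_point(50, 220, 0.7)) # 101
#' @export
expected_value <- function(spec) {
  stopifnot(inherits(spec, "payoff_spec"))
  p <- spec$pars
  switch(spec$kind,
    constant  = unname(p[["value"]]),
    gaussian  = unname(p[["mean"]]),
    two_point = unname(p[["low"]] * p[["p_low"]] + p[["high"]] * (1 - p[["p_low"]]))
  )
}

#' Sample payoffs from an option
#'
#' Draws use R's global random number stream, so results are reproducible
#' under `set.seed()`.
#'
#' @param spec A [payoff_spec] object.
#' @param n Number of draws.
#' @return Numeric vector of length `n`.
#' @export
draw_payoff <- function(spec, n = 1) {
  stopifnot(inherits(spec, "payoff_spec"))
  p <- spec$pars
  switch(spec$kind,
    constant  = rep(unname(p[["value"]]), n),
    gaussian  = stats::rnorm(n, p[["mean"]], p[["sd"]]),
    two_point = ifelse(stats::runif(n) < p[["p_low"]],
                       unname(p[["low"]]), unname(p[["high"]]))
  )
}

#' Construct a bandit task
#'
#' A task bundles an ordered list of payoff options with a trial horizon and
#' a payoff scale. The scale divides raw payoffs before they enter the
#' learning model (point-valued experimental tasks use `payoff_scale = 0.01`
#' so that learned values are O(1), commensurate with inverse temperatures in
#' the 3-5 range); recorded session payoffs stay on the raw scale.
#'
#' The declared risk-premium sign must agree with
#' `sign(max risky EV - max safe EV)` and is recomputed internally.
#'
#' @param options List of [payoff_spec] objects (at least 2).
#' @param horizon Number of trials `T >= 1`.
#' @param payoff_scale Multiplier applied to payoffs before learning
#'   (default 1).
#' @param name Optional task name.
#' @return An object of class `bandit_task`.
#' @export
bandit_task <- function(options, horizon, payoff_scale = 1, name = "custom") {
  if (!is.list(options) || length(options) < 2) {
    stop("a task needs at least 2 options", call. = FALSE)
  }
  ok <- vapply(options, inherits, logical(1), what = "payoff_spec")
  if (!all(ok)) stop("all options must be payoff_spec objects", call. = FALSE)
  if (!is.numeric(horizon) || horizon < 1) {
    stop("task horizon must be >= 1", call. = FALSE)
  }
  evs <- vapply(options, expected_value, numeric(1))
  if (!all(is.finite(evs))) stop("option expected values must be finite", call. = FALSE)
  risky <- vapply(options, function(o) isTRUE(o$risky), logical(1))
  if (!any(risky) || !any(!risky)) {
    stop("task needs at least one risky and one safe option", call. = FALSE)
  }
  rp <- max(evs[risky]) - max(evs[!risky])
  # target arm for risk-seeking summaries: the best risky option
  risky_index <- which(risky)[which.max(evs[risky])]
  structure(
    list(
      name = name, options = options, horizon = as.integer(horizon),
      payoff_scale = payoff_scale, expected_values = evs,
      risky = risky, risky_index = risky_index,
      optimal_index = which.max(evs),
      risk_premium = rp, risk_premium_sign = sign(rp)
    ),
    class = "bandit_task"
  )
}

#' @export
print.bandit_task <- function(x, ...) {
  cat(sprintf("<bandit_task> %s: %d options, T = %d, payoff scale %g, RP %s\n",
              x$name, length(x$options), x$horizon, x$payoff_scale,
              if (x$risk_premium_sign > 0) "positive" else if
                (x$risk_premium_sign < 0) "negative" else "zero"))
  for (i in seq_along(x$options)) {
    cat(sprintf("  [%d] EV %.4g  ", i, x$expected_values[i]))
    print(x$options[[i]])
  }
  invisible(x)
}

.task_presets <- c("gaussian_2arm", "exp_1r1s_pos", "exp_1r3s_pos",
                   "exp_2r2s_pos", "exp_1r1s_neg")

#' Preset bandit tasks
#'
#' Returns one of the preset task configurations:
#' \describe{
#'   \item{`gaussian_2arm`}{Safe arm pays 1 constantly; risky arm pays
#'     Gaussian(1.5, 1); T = 150. The canonical hot-stove setup.}
#'   \item{`exp_1r1s_pos`}{Risky 50/550 at 0.7/0.3 (EV 200); safe 150 with
#'     Gaussian noise sd 5; T = 70; positive risk premium.}
#'   \item{`exp_1r3s_pos`}{Risky 50/425 at 0.6/0.4 (EV 200); safes 150, 125,
#'     100 each with sd 5; T = 70.}
#'   \item{`exp_2r2s_pos`}{Optimal risky 50/425 at 0.6/0.4; suboptimal risky
#'     50/238 at 0.6/0.4; safes 150, 125 with sd 5; T = 70.}
#'   \item{`exp_1r1s_neg`}{Risky 50/220 at 0.7/0.3 (EV 101); safe 150 with
#'     sd 5; T = 70; negative risk premium.}
#' }
#' Point-valued experimental tasks carry `payoff_scale = 0.01`.
#'
#' @param name Preset identifier.
#' @param payoff_scale Override the preset's payoff scale.
#' @return A [bandit_task].
#' @examples
#' make_preset_task("gaussian_2arm")
#' @export
make_preset_task <- function(name, payoff_scale = NULL) {
  if (!is.character(name) || length(name) != 1 || !name %in% .task_presets) {
    stop("unknown task preset; valid presets: ",
         paste(.task_presets, collapse = ", "), call. = FALSE)
  }
  scale_exp <- if (is.null(payoff_scale)) 0.01 else payoff_scale
  task <- switch(name,
    gaussian_2arm = bandit_task(
      list(payoff_gaussian(1.5, 1, label = "risky", risky = TRUE),
           payoff_constant(1)),
      horizon = 150,
      payoff_scale = if (is.null(payoff_scale)) 1 else payoff_scale,
      name = name
    ),
    exp_1r1s_pos = bandit_task(
      list(payoff_two_point(50, 550, 0.7),
           payoff_gaussian(150, 5, label = "safe", risky = FALSE)),
      horizon = 70, payoff_scale = scale_exp, name = name
    ),
    exp_1r3s_pos = bandit_task(
      list(payoff_two_point(50, 425, 0.6),
           payoff_gaussian(150, 5, label = "safe150", risky = FALSE),
           payoff_gaussian(125, 5, label = "safe125", risky = FALSE),
           payoff_gaussian(100, 5, label = "safe100", risky = FALSE)),
      horizon = 70, payoff_scale = scale_exp, name = name
    ),
    exp_2r2s_pos = bandit_task(
      list(payoff_two_point(50, 425, 0.6, label = "risky_optimal"),
           payoff_two_point(50, 238, 0.6, label = "risky_suboptimal"),
           payoff_gaussian(150, 5, label = "safe150", risky = FALSE),
           payoff_gaussian(125, 5, label = "safe125", risky = FALSE)),
      horizon = 70, payoff_scale = scale_exp, name = name
    ),
    exp_1r1s_neg = bandit_task(
      list(payoff_two_point(50, 220, 0.7),
           payoff_gaussian(150, 5, label = "safe", risky = FALSE)),
      horizon = 70, payoff_scale = scale_exp, name = name
    )
  )
  task
}

#' Serialise a task to and from a plain config list
#'
#' `task_to_config()` produces a nested list that survives YAML/JSON
#' round-tripping; `task_from_config()` inverts it.
#'
#' @param task A [bandit_task].
#' @param config A list as produced by `task_to_config()`.
#' @return A list, or a [bandit_task].
#' @export
task_to_config <- function(task) {
  stopifnot(inherits(task, "bandit_task"))
  list(
    name = task$name, horizon = task$horizon, payoff_scale = task$payoff_scale,
    options = lapply(task$options, function(o) {
      c(list(kind = o$kind, label = o$label, risky = o$risky), as.list(o$pars))
    })
  )
}

#' @rdname task_to_config
#' @export
task_from_config <- function(config) {
  opts <- lapply(config$options, function(o) {
    switch(o$kind,
      constant  = payoff_constant(o$value, label = o$label,
                                  risky = isTRUE(o$risky)),
      gaussian  = payoff_gaussian(o$mean, o$sd, label = o$label,
                                  risky = isTRUE(o$risky)),
      two_point = payoff_two_point(o$low, o$high, o$p_low, label = o$label,
                                   risky = isTRUE(o$risky)),
      stop("unknown option kind: ", o$kind, call. = FALSE)
    )
  })
  bandit_task(opts, horizon = config$horizon,
              payoff_scale = config$payoff_scale %||% 1,
              name = config$name %||% "custom")
}
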