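#' One-step TD reward-prediction error for tabular values
#'
#' \eqn{\delta_i = R_i + \gamma V(S_{i+1}) - V(S_i)}; at the terminal state
#' (\eqn{i = n}) the \eqn{\gamma V(S_{i+1})} term is dropped.
#'
#' @param V Numeric vector of state values.
#' @param i State index in `1:length(V)`.
#' @param R_i Reward delivered at state `i`.
#' @param gamma Discount factor.
#' @return The TD-RPE, a scalar.
#' @export
td_rpe <- function(V, i, R_i, gamma) {
  n <- length(V)
  if (i < 1L || i > n) stop("state index out of range", call. = FALSE)
  if (i == n) R_i - V[i] else R_i + gamma * V[i + 1L] - V[i]
}

#' TD update of a single state value
#'
#' \eqn{V(S_i) \leftarrow V(S_i) + a\,\delta_i}.
#'
#' @param V Numeric vector of state values.
#' @param i State index.
#' @param delta TD-RPE.
#' @param a Learning rate.
#' @return The updated value vector.
#' @export
update_value <- function(V, i, delta, a) {
  stopifnot(is.finite(delta))
  V[i] <- V[i] + a * delta
  V
}

#' Multiplicative value decay
#'
#' \eqn{V(S_i) \leftarrow (1 - \kappa) V(S_i)} for every state, applied once
#' per within-trial time-step (decay acts only during task trials).
#'
#' @param V Numeric vector of state values.
#' @param kappa Decay rate in `[0, 1)`.
#' @return The decayed value vector.
#' @export
decay_values <- function(V, kappa) {
  stopifnot(kappa >= 0, kappa < 1)
  (1 - kappa) * V
}

#' Run tabular TD learning with value decay (punctate representation)
#'
#' Each within-trial timing is its own orthogonal ("punctate") state. Per
#' trial the runner loops over states \eqn{i = 1, \ldots, n}: it records the
#' pre-update TD-RPE, updates \eqn{V(S_i)}, then decays all state values once.
#' The cue response is recorded as a step-0 channel: an implicit pre-cue
#' state with permanently zero value yields a cue-step RPE of
#' \eqn{\gamma V(S_1)} (or \eqn{V(S_1)} with `cue_response = "value"`),
#' evaluated from the values holding at trial start.
#'
#' @param task A [make_task()] specification.
#' @param a Learning rate (default 0.15).
#' @param kappa Value-decay rate per time-step (default 0).
#' @param cue_response `"discounted"` reports \eqn{\gamma V(S_1)} at step 0;
#'   `"value"` reports \eqn{V(S_1)}. Identical when \eqn{\gamma = 1}.
#' @param seed Optional seed for probabilistic reward schedules.
#' @return A `td_trace`: data frame with columns `trial`, `step`
#'   (0 = cue channel, `1:n` = states), `state`, `delta`, `value`
#'   (pre-update value of the visited state), `reward` (that trial's realized
#'   reward size). Attribute `final_V` holds the value vector after the last
#'   trial.
#' @export
run_punctate <- function(task, a = 0.15, kappa = 0,
                         cue_response = c("discounted", "value"),
                         seed = NULL) {
  stopifnot(inherits(task, "td_task"))
  cue_response <- match.arg(cue_response)
  n <- task$n_states
  gamma <- task$gamma
  rewards <- sample_reward(task, task$n_trials, seed = seed)
  V <- numeric(n)
  n_trials <- task$n_trials
  rows_per <- n + 1L
  delta <- numeric(n_trials * rows_per)
  value <- numeric(n_trials * rows_per)
  r <- 0L
  for (tr in seq_len(n_trials)) {
    # step 0: cue-response channel, from values at trial start
    r <- r + 1L
    delta[r] <- if (cue_response == "discounted") gamma * V[1L] else V[1L]
    value[r] <- 0
    for (i in seq_len(n)) {
      R_i <- if (i == n) rewards[tr] else 0
      d <- td_rpe(V, i, R_i, gamma)
      r <- r + 1L
      delta[r] <- d
      value[r] <- V[i]
      V <- update_value(V, i, d, a)
      V <- decay_values(V, kappa)
    }
  }
  out <- data.frame(
    trial = rep(seq_len(n_trials), each = rows_per),
    step = rep.int(0:n, n_trials),
    state = rep.int(c(NA_integer_, seq_len(n)), n_trials),
    delta = delta,
    value = value,
    reward = rep(rewards, each = rows_per)
  )
  attr(out, "final_V") <- V
  class(out) <- c("td_trace", class(out))
  out
}

#' Steady-state profile of a trace
#'
#' Extracts the per-step TD-RPE (and value) profile from the final trial, or
#' averaged over the last `last_k` trials.
#'
#' @param trace A trace data frame with `trial`, `step`, `delta` columns.
#' @param last_k Number of final trials to average (default 1).
#' @return Data frame with one row per step: `step`, `delta`, plus `value`
#'   if present in the trace.
#' @export
steady_profile <- function(trace, last_k = 1L) {
  trials <- unique(trace$trial)
  keep <- trace$trial > max(trials) - last_k
  tr <- trace[keep, , drop = FALSE]
  out <- aggregate(tr["delta"], by = list(step = tr$step), FUN = mean)
  if ("value" %in% names(tr)) {
    out$value <- aggregate(tr["value"], by = list(step = tr$step), FUN = mean)$value
  }
  out[order(out$step), , drop = FALSE]
}
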