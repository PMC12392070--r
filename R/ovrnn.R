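#' Elementary online value-RNN operations
#'
#' Pure-R reference implementations of the network's building blocks. The
#' trial-scale trainer [run_ovrnn()] uses an equivalent compiled loop; these
#' functions define the semantics and are used to verify it.
#'
#' `rnn_step()` computes \eqn{x(t+1) = f(A x(t) + B o(t))} with the logistic
#' \eqn{f(z) = 1/(1+e^{-z})}; `readout_value()` computes \eqn{v = w^T x};
#' `ovrnn_td_rpe()` computes \eqn{\delta(t) = r(t) + \gamma v(t+1) - v(t)}.
#'
#' @param A Recurrent weight matrix (units x units).
#' @param B Feedforward weight matrix (units x observations).
#' @param x Current activity vector \eqn{x(t)}.
#' @param o Current observation vector \eqn{o(t)}.
#' @return `rnn_step()`: the next activity vector, elementwise in (0, 1).
#' @export
rnn_step <- function(A, B, x, o) {
  stats::plogis(as.numeric(A %*% x + B %*% o))
}

#' @rdname rnn_step
#' @param w Value-weight vector.
#' @export
readout_value <- function(w, x) {
  if (length(w) != length(x)) stop("dimension mismatch", call. = FALSE)
  sum(w * x)
}

#' @rdname rnn_step
#' @param r Reward at time t.
#' @param v_t,v_t1 Values at times t and t+1.
#' @param gamma Discount factor (0.8 in the standard protocol).
#' @export
ovrnn_td_rpe <- function(r, v_t, v_t1, gamma) {
  r + gamma * v_t1 - v_t
}

#' Value-weight plasticity and decay for the online value-RNN
#'
#' `update_value_weights()` applies
#' \eqn{w_j \leftarrow \max(0, w_j + a_{value}\,\delta\,x_j)};
#' `decay_value_weights()` applies \eqn{w_j \leftarrow (1 - dr) w_j}. Unlike
#' the feature-TD module's decay toward a baseline, this decay is toward
#' zero and is applied at every time-step, including inter-trial intervals.
#'
#' @param w Value-weight vector (non-negative).
#' @param delta TD-RPE at time t.
#' @param x Activity vector \eqn{x(t)} used in the update.
#' @param a_value Value learning rate (default 0.03).
#' @param dr Decay rate per time-step (0 or 0.001 in the standard protocol).
#' @return Updated weight vector.
#' @export
update_value_weights <- function(w, delta, x, a_value = 0.03) {
  pmax(0, w + a_value * delta * x)
}

#' @rdname update_value_weights
#' @export
decay_value_weights <- function(w, dr) {
  (1 - dr) * w
}

#' Random-feedback plasticity of recurrent and feedforward weights
#'
#' Gradient-like update in which backpropagation's symmetric feedback is
#' replaced by fixed random feedback gains \eqn{c_i} and the postsynaptic
#' sigmoid-derivative factor \eqn{x_i(1-x_i)} is replaced by the constant
#' 0.25 when \eqn{x_i(t) > 0.5} ("monotonic + saturation"); the two branches
#' coincide at \eqn{x_i = 0.5}, so the rule is continuous. Presynaptic
#' activities are taken at \eqn{t-1}, postsynaptic at \eqn{t}:
#' \deqn{\Delta A_{ij} = a_{RNN}\,\delta(t)\,x_j(t-1)\,\phi(x_i(t))\,c_i,}
#' and analogously for B with \eqn{o_k(t-1)}.
#'
#' @param A,B Weight matrices.
#' @param delta TD-RPE at time t.
#' @param x_prev,o_prev Activities and observations at time t-1.
#' @param x_now Activities at time t.
#' @param c Fixed feedback gains in \[0, 1\] (length = number of units).
#' @param a_RNN Learning rate (default 0.1).
#' @return List with updated `A` and `B`.
#' @export
update_rnn_weights <- function(A, B, delta, x_prev, o_prev, x_now, c,
                               a_RNN = 0.1) {
  post <- ifelse(x_now <= 0.5, x_now * (1 - x_now), 0.25)
  gain <- a_RNN * delta * post * c
  list(A = A + outer(gain, x_prev), B = B + outer(gain, o_prev))
}

#' Train the online value-RNN on a cue-reward association task
#'
#' Simulates continuous learning (across trials and inter-trial intervals)
#' of a 40-unit recurrent network whose representation and value readout are
#' both trained online by the same TD-RPE, with random feedback in place of
#' backpropagation. Initialization: activities uniform \[0, 1\], recurrent
#' and feedforward weights standard normal, value weights zero, feedback
#' gains uniform \[0, 1\].
#'
#' @param cue_type `"fixed"` or `"dynamic"` (see [make_observation_stream()]).
#' @param iti_kind `"short"` or `"long"`.
#' @param dr Value-weight decay per time-step (0 or 0.001).
#' @param n_trials Trials per simulation (default 1000).
#' @param n_reps Independent repetitions (fresh stream and weights).
#' @param n_units Recurrent units (default 40).
#' @param gamma Discount (default 0.8).
#' @param a_RNN,a_value Learning rates (defaults 0.1, 0.03).
#' @param average_last Number of final trials averaged into the reported
#'   trial-aligned profiles (default 100).
#' @param keep_trace Keep the full per-step trace of the first repetition.
#' @param seed Optional seed.
#' @return An `ovrnn_run`: list with `delta_profiles` and `value_profiles`
#'   (`n_reps` x 6 matrices of trial-aligned means at relative steps 0
#'   (pre-cue) through 5 (reward), averaged over the last `average_last`
#'   trials), optionally `trace` (data frame: trial, rel_step, delta, value),
#'   and the call parameters.
#' @export
run_ovrnn <- function(cue_type = c("fixed", "dynamic"),
                      iti_kind = c("short", "long"),
                      dr = 0, n_trials = 1000L, n_reps = 1L,
                      n_units = 40L, gamma = 0.8,
                      a_RNN = 0.1, a_value = 0.03,
                      average_last = 100L, keep_trace = (n_reps == 1L),
                      seed = NULL) {
  cue_type <- match.arg(cue_type)
  iti_kind <- match.arg(iti_kind)
  if (!is.null(seed)) withr::local_seed(seed)
  rel_steps <- 0:5
  delta_profiles <- matrix(NA_real_, n_reps, length(rel_steps))
  value_profiles <- matrix(NA_real_, n_reps, length(rel_steps))
  colnames(delta_profiles) <- colnames(value_profiles) <-
    paste0("rel", rel_steps)
  trace <- NULL
  for (rp in seq_len(n_reps)) {
    stream <- make_observation_stream(cue_type, iti_kind, n_trials)
    # one appended silent step so delta at the final reward step is defined
    obs <- rbind(stream$obs, 0)
    rew <- c(stream$reward, 0)
    A <- matrix(rnorm(n_units * n_units), n_units, n_units)
    B <- matrix(rnorm(n_units * 5L), n_units, 5L)
    x0 <- runif(n_units)
    cgain <- runif(n_units)
    fit <- ovrnn_core(
      A, B, numeric(n_units), cgain, x0, obs, rew,
      gamma, a_value, a_RNN, dr
    )
    idx <- outer(stream$cue_onset - 1L, rel_steps, `+`) # trial x rel_step
    late <- seq.int(max(1L, n_trials - average_last + 1L), n_trials)
    delta_profiles[rp, ] <- colMeans(matrix(fit$delta[idx[late, ]], length(late)))
    value_profiles[rp, ] <- colMeans(matrix(fit$value[idx[late, ]], length(late)))
    if (keep_trace && rp == 1L) {
      trace <- data.frame(
        trial = rep(seq_len(n_trials), times = length(rel_steps)),
        rel_step = rep(rel_steps, each = n_trials),
        delta = fit$delta[as.vector(idx)],
        value = fit$value[as.vector(idx)]
      )
      trace <- trace[order(trace$trial, trace$rel_step), ]
      rownames(trace) <- NULL
    }
  }
  structure(
    list(
      delta_profiles = delta_profiles,
      value_profiles = value_profiles,
      trace = trace,
      cue_type = cue_type, iti_kind = iti_kind, dr = dr,
      n_trials = n_trials, n_reps = n_reps, n_units = n_units,
      gamma = gamma, a_RNN = a_RNN, a_value = a_value,
      average_last = average_last
    ),
    class = "ovrnn_run"
  )
}

#' @export
print.ovrnn_run <- function(x, ...) {
  cat("<ovrnn_run> ", x$cue_type, " cue, ", x$iti_kind, " ITI, dr = ", x$dr,
    ", ", x$n_reps, " rep(s) x ", x$n_trials, " trials\n",
    sep = ""
  )
  cat("  mean TD-RPE profile (pre-cue, cue, ..., reward):\n  ")
  cat(signif(colMeans(x$delta_profiles), 3), "\n")
  invisible(x)
}
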