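#' TD-RPEs of the coupled two-circuit model
#'
#' Circuit M (fast learning, value decay) computes a standard TD-RPE with
#' direct reward input:
#' \eqn{\delta_{Mi} = R_i + \gamma V_M(S_{i+1}) - V_M(S_i)}.
#' Circuit L (slow learning, little or no decay) receives no direct reward;
#' its reinforcement is the upcoming-state value relayed from circuit M
#' (conditioned reinforcement) mixed with its own upcoming value:
#' \eqn{\delta_{Li} = \gamma(0.5 V_L(S_{i+1}) + 0.5 V_M(S_{i+1}))
#'   - \lambda_{cur} V_L(S_i)}.
#' At the terminal state the upcoming-value term is dropped in both.
#' `lambda_cur` is 1 in the original model and 0.5 in the revised model in
#' which the negative current-value input is halved.
#'
#' @param V_M,V_L State-value vectors of the two circuits.
#' @param i State index.
#' @param R_i Reward at state `i` (circuit M only).
#' @param gamma Discount factor (default 1).
#' @param lambda_cur Coefficient of the \eqn{-V_L(S_i)} term (1 or 0.5).
#' @return The circuit's TD-RPE, a scalar.
#' @export
circuit_m_rpe <- function(V_M, i, R_i, gamma = 1) {
  td_rpe(V_M, i, R_i, gamma)
}

#' @rdname circuit_m_rpe
#' @export
circuit_l_rpe <- function(V_L, V_M, i, gamma = 1, lambda_cur = 1) {
  n <- length(V_L)
  if (i < 1L || i > n) stop("state index out of range", call. = FALSE)
  upcoming <- if (i == n) 0 else gamma * (0.5 * V_L[i + 1L] + 0.5 * V_M[i + 1L])
  upcoming - lambda_cur * V_L[i]
}

#' Run the hierarchical two-circuit model across task phases
#'
#' Simulates circuit M (modeling the head-of-caudate / rostromedial-nigra
#' loop: large learning rate, value decay) coupled to circuit L (tail-of-
#' caudate / caudolateral-nigra loop: small learning rate, little or no
#' decay, conditioned reinforcement from M) through an ordered sequence of
#' phases:
#' \describe{
#'   \item{learning}{standard trial loop, reward per the task schedule.}
#'   \item{rest}{no trials; only value decay, applied
#'     `n_states * n_trials` times (the duration-matched equivalent of that
#'     many trials).}
#'   \item{extinction}{trial loop with the reward term set to 0.}
#' }
#' Within each time-step both circuits compute their RPEs from pre-update
#' values, then both update, then both decay (synchronous circuits). Cue
#' responses are recorded at step 0 from values at trial start:
#' \eqn{\gamma V_M(S_1)} for M and
#' \eqn{\gamma(0.5 V_L(S_1) + 0.5 V_M(S_1))} for L (each circuit's own RPE
#' at an implicit zero-valued pre-cue state).
#'
#' @param phases List of `c(phase_name, n_trials)` pairs, e.g.
#'   `list(c("learning", 200), c("rest", 200), c("extinction", 200))`, or a
#'   2-column data frame with columns `phase`, `n_trials`.
#' @param n_states Number of within-trial states (default 5).
#' @param reward_size Reward at the terminal state during learning
#'   (default 1).
#' @param a_M,a_L Learning rates (defaults 0.25 and 0.025).
#' @param kappa_M,kappa_L Decay rates (defaults 0.01 and 0).
#' @param lambda_cur Current-value coefficient in circuit L (default 1).
#' @param gamma Discount factor (default 1).
#' @return A `hier_trace` data frame with columns `phase`, `phase_trial`,
#'   `trial` (cumulative), `step` (0 = cue channel; rest phases carry one
#'   row per decay-equivalent trial with `step = NA`), `delta_M`, `delta_L`,
#'   `V_M`, `V_L` (pre-update values of the visited state; for rest rows the
#'   full-vector maxima). Attributes `final_V_M`/`final_V_L` hold the value
#'   vectors after the last phase.
#' @export
run_hierarchical <- function(phases = list(
                               c("learning", 200),
                               c("rest", 200),
                               c("extinction", 200)
                             ),
                             n_states = 5L, reward_size = 1,
                             a_M = 0.25, a_L = 0.025,
                             kappa_M = 0.01, kappa_L = 0,
                             lambda_cur = 1, gamma = 1) {
  if (is.data.frame(phases)) {
    phases <- lapply(seq_len(nrow(phases)), function(k) {
      c(phases$phase[k], phases$n_trials[k])
    })
  }
  n <- as.integer(n_states)
  V_M <- numeric(n)
  V_L <- numeric(n)
  rows <- list()
  cum_trial <- 0L
  for (ph in phases) {
    phase <- match.arg(ph[[1L]], c("learning", "rest", "extinction"))
    n_trials <- as.integer(ph[[2L]])
    if (phase == "rest") {
      # decay only, n_states applications per duration-matched trial
      for (tr in seq_len(n_trials)) {
        V_M <- V_M * (1 - kappa_M)^n
        V_L <- V_L * (1 - kappa_L)^n
        cum_trial <- cum_trial + 1L
        rows[[length(rows) + 1L]] <- data.frame(
          phase = phase, phase_trial = tr, trial = cum_trial,
          step = NA_integer_, delta_M = NA_real_, delta_L = NA_real_,
          V_M = max(V_M), V_L = max(V_L)
        )
      }
      next
    }
    R_n <- if (phase == "learning") reward_size else 0
    for (tr in seq_len(n_trials)) {
      cum_trial <- cum_trial + 1L
      step <- 0:n
      dM <- numeric(n + 1L)
      dL <- numeric(n + 1L)
      vM <- numeric(n + 1L)
      vL <- numeric(n + 1L)
      dM[1L] <- gamma * V_M[1L]
      dL[1L] <- gamma * (0.5 * V_L[1L] + 0.5 * V_M[1L])
      vM[1L] <- 0
      vL[1L] <- 0
      for (i in seq_len(n)) {
        R_i <- if (i == n) R_n else 0
        d_m <- circuit_m_rpe(V_M, i, R_i, gamma)
        d_l <- circuit_l_rpe(V_L, V_M, i, gamma, lambda_cur)
        dM[i + 1L] <- d_m
        dL[i + 1L] <- d_l
        vM[i + 1L] <- V_M[i]
        vL[i + 1L] <- V_L[i]
        V_M[i] <- V_M[i] + a_M * d_m
        V_L[i] <- V_L[i] + a_L * d_l
        V_M <- V_M * (1 - kappa_M)
        V_L <- V_L * (1 - kappa_L)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        phase = phase, phase_trial = tr, trial = cum_trial,
        step = step, delta_M = dM, delta_L = dL, V_M = vM, V_L = vL
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "final_V_M") <- V_M
  attr(out, "final_V_L") <- V_L
  class(out) <- c("hier_trace", class(out))
  out
}

#' Cue responses of the two circuits at selected trials
#'
#' Convenience accessor: the step-0 (cue channel) RPE of each circuit at the
#' given cumulative trials, or at the first/last trial of a phase.
#'
#' @param trace A `hier_trace` from [run_hierarchical()].
#' @param phase Phase name.
#' @param which `"first"` or `"last"` trial of that phase.
#' @return Named numeric vector with elements `M` and `L`.
#' @export
cue_response <- function(trace, phase, which = c("last", "first")) {
  which <- match.arg(which)
  tr <- trace[trace$phase == phase & !is.na(trace$step) & trace$step == 0L, ]
  if (nrow(tr) == 0L) stop("no such phase in trace", call. = FALSE)
  row <- if (which == "last") tr[which.max(tr$phase_trial), ] else tr[which.min(tr$phase_trial), ]
  c(M = row$delta_M, L = row$delta_L)
}
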