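# Independent brute-force oracles, written from the update equations alone
# (no package runner code reused), for fixed-point and expectile checks.

# deterministic punctate update-then-decay map, iterated to convergence
oracle_punctate_fp <- function(n, r, a, kappa, gamma, tol = 1e-14,
                               max_iter = 1e6) {
  V <- numeric(n)
  for (iter in seq_len(max_iter)) {
    V_old <- V
    for (i in seq_len(n)) {
      d <- if (i == n) r - V[i] else gamma * V[i + 1L] - V[i]
      V[i] <- V[i] + a * d
      V <- (1 - kappa) * V
    }
    if (max(abs(V - V_old)) < tol) {
      return(V)
    }
  }
  stop("oracle did not converge")
}

# deterministic feature-weight map (value = w.x - w0*sum(x); clamped,
# asymmetric-rate update scaled by 1/||x||^2; decay toward w0)
oracle_feature_fp <- function(X, r, a_plus, a_minus, kappa, w0, gamma,
                              tol = 1e-14, max_iter = 1e6) {
  n <- nrow(X)
  w <- rep(w0, ncol(X))
  cs <- rowSums(X)
  val <- function(w, i) sum(w * X[i, ]) - w0 * cs[i]
  for (iter in seq_len(max_iter)) {
    w_old <- w
    for (i in seq_len(n)) {
      d <- if (i == n) r - val(w, i) else gamma * val(w, i + 1L) - val(w, i)
      a_f <- if (d >= 0) a_plus else a_minus
      w <- pmax(0, w + a_f * d * X[i, ] / sum(X[i, ]^2))
      w <- w0 + (1 - kappa) * (w - w0)
    }
    if (max(abs(w - w_old)) < tol) {
      return(w)
    }
  }
  stop("oracle did not converge")
}

# asymmetric fixed point q of a two-point reward distribution:
# a_plus * E[(R - q)+] - a_minus * E[(q - R)+] = 0, solved by root finding
oracle_asym_fixed_point <- function(sizes, probs, a_plus, a_minus) {
  f <- function(q) {
    sum(probs * ifelse(sizes >= q, a_plus * (sizes - q), a_minus * (sizes - q)))
  }
  stats::uniroot(f, range(sizes), tol = 1e-12)$root
}

# step-by-step reference oVRNN built from the exported R primitives,
# mirroring the documented per-step order; used to validate the compiled
# trainer on short streams
ovrnn_reference <- function(A, B, w, cgain, x0, obs, rew, gamma, a_value,
                            a_rnn, dr) {
  T_len <- nrow(obs)
  x <- x0
  x_prev <- NULL
  o_prev <- NULL
  delta <- numeric(T_len - 1L)
  value <- numeric(T_len - 1L)
  for (t in seq_len(T_len - 1L)) {
    x_next <- rnn_step(A, B, x, obs[t, ])
    d <- ovrnn_td_rpe(rew[t], readout_value(w, x), readout_value(w, x_next), gamma)
    delta[t] <- d
    value[t] <- readout_value(w, x)
    w <- decay_value_weights(update_value_weights(w, d, x, a_value), dr)
    if (t > 1L) {
      upd <- update_rnn_weights(A, B, d, x_prev, o_prev, x, cgain, a_rnn)
      A <- upd$A
      B <- upd$B
    }
    x_prev <- x
    o_prev <- obs[t, ]
    x <- x_next
  }
  list(delta = delta, value = value, A = A, B = B, w = w)
}

# shared small tasks
det_task <- function(n_trials = 200L, gamma = 1, n = 5L, r = 1) {
  make_task(n, list(c(r, 1)), n_trials, gamma)
}

prob13_task <- function(n_trials = 200L) {
  make_task(5L, list(c(1, 0.5), c(3, 0.5)), n_trials, 1)
}
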