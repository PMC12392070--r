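#' Build feature vectors for the within-trial states
#'
#' Five representation kinds are supported for the \eqn{n} within-trial
#' states:
#' \describe{
#'   \item{sparse}{`dim`-dimensional (default 100) vectors with exactly
#'     `n_active` (default 10) nonzero entries at pseudorandomly chosen
#'     positions, values drawn uniform on \[0, 1\], then scaled to unit norm.}
#'   \item{dense}{all `dim` entries uniform on \[0, 1\], scaled to unit norm.}
#'   \item{SR}{successor representation, \eqn{x_{i,j} = \gamma^{j-i}} for
#'     \eqn{j \ge i}, else 0 (n-dimensional, upper-triangular).}
#'   \item{PR}{predecessor representation, \eqn{x_{i,j} = \gamma^{i-j}} for
#'     \eqn{j \le i}, else 0 (lower-triangular).}
#'   \item{punctate}{the identity matrix; also the starting point for online
#'     SR learning in [run_navigation()].}
#' }
#' SR/PR vectors are not unit norm; the update rule's \eqn{1/\|x\|^2} scaling
#' handles that.
#'
#' @param kind Representation kind.
#' @param n_states Number of states.
#' @param dim Feature dimension for sparse/dense (default 100).
#' @param n_active Nonzero entries per sparse vector (default 10).
#' @param gamma Discount used to build SR/PR (default 1, independent of the
#'   value-learning discount).
#' @param seed Optional seed for the sparse/dense draws.
#' @return A `feature_set`: list with `kind` and `X`, an `n_states` x m
#'   matrix whose rows are the state feature vectors.
#' @export
make_features <- function(kind = c("sparse", "dense", "SR", "PR", "punctate"),
                          n_states = 5L, dim = 100L, n_active = 10L,
                          gamma = 1, seed = NULL) {
  kind <- match.arg(kind)
  if (!is.null(seed)) withr::local_seed(seed)
  n <- as.integer(n_states)
  X <- switch(kind,
    sparse = {
      stopifnot(n_active <= dim)
      X <- matrix(0, n, dim)
      for (i in seq_len(n)) {
        idx <- sample.int(dim, n_active)
        X[i, idx] <- runif(n_active)
        X[i, ] <- X[i, ] / sqrt(sum(X[i, ]^2))
      }
      X
    },
    dense = {
      X <- matrix(runif(n * dim), n, dim)
      X / sqrt(rowSums(X^2))
    },
    SR = {
      ij <- outer(seq_len(n), seq_len(n), function(i, j) j - i)
      ifelse(ij >= 0, gamma^ij, 0)
    },
    PR = {
      ij <- outer(seq_len(n), seq_len(n), function(i, j) i - j)
      ifelse(ij >= 0, gamma^ij, 0)
    },
    punctate = diag(n)
  )
  structure(list(kind = kind, X = X), class = "feature_set")
}

#' Linear state value with constant-vector subtraction
#'
#' \eqn{V = w \cdot x - w_0 \sum_j x_j}. The weight vector is initialized to
#' the constant baseline \eqn{w_0}, so initial values are 0, and although the
#' stored weights are clamped non-negative the effective weights
#' \eqn{w_j - w_0} can be negative.
#'
#' @param w Weight vector.
#' @param w0 Baseline scalar (default 0.5).
#' @param x Feature vector (same length as `w`).
#' @return Scalar state value.
#' @export
state_value <- function(w, w0, x) {
  if (length(w) != length(x)) stop("dimension mismatch", call. = FALSE)
  sum(w * x) - w0 * sum(x)
}

#' TD update of value weights with non-negativity and asymmetric rates
#'
#' \eqn{w \leftarrow \max(0, w + a_f\,\delta\,x / \|x\|^2)} elementwise,
#' where \eqn{a_f = a_+} if \eqn{\delta \ge 0} and \eqn{a_-} otherwise.
#'
#' @param w Weight vector.
#' @param delta TD-RPE.
#' @param x Feature vector of the visited state.
#' @param a_plus,a_minus Learning rates for non-negative / negative RPE.
#' @return Updated weight vector.
#' @export
update_weights <- function(w, delta, x, a_plus, a_minus = a_plus) {
  nrm2 <- sum(x^2)
  if (nrm2 == 0) stop("zero feature vector", call. = FALSE)
  a_f <- if (delta >= 0) a_plus else a_minus
  pmax(0, w + a_f * delta * x / nrm2)
}

#' Decay value weights toward their baseline
#'
#' \eqn{w_j \leftarrow w_0 + (1 - \kappa)(w_j - w_0)}: two-sided shrinkage
#' toward the initialization \eqn{w_0}, not toward zero.
#'
#' @param w Weight vector.
#' @param w0 Baseline scalar.
#' @param kappa Decay rate in `[0, 1)`.
#' @return Decayed weight vector.
#' @export
decay_weights <- function(w, w0, kappa) {
  stopifnot(kappa >= 0, kappa < 1)
  w0 + (1 - kappa) * (w - w0)
}

#' Run linear-feature TD learning with weight decay
#'
#' Same trial loop as [run_punctate()], but values come from
#' [state_value()] and learning acts on the shared weight vector via
#' [update_weights()] then [decay_weights()], once per within-trial step.
#' The cue response is recorded at step 0 as \eqn{\gamma V(S_1)} from the
#' weights holding at trial start.
#'
#' For sparse/dense representations the feature draw is itself random, so
#' `n_reps` independent repetitions with fresh features can be requested;
#' the returned trace then carries a `rep` column.
#'
#' @param task A [make_task()] specification.
#' @param features A `feature_set` from [make_features()], or a kind string
#'   (`"sparse"`, `"dense"`, ...) to draw features internally (fresh per
#'   repetition for sparse/dense).
#' @param a_plus,a_minus Learning rates (defaults 0.15 and 0.075).
#' @param kappa Weight-decay rate (default 0).
#' @param w0 Baseline weight (default 0.5).
#' @param n_reps Number of repetitions (default 1).
#' @param seed Optional seed covering feature draws and reward draws.
#' @return A `td_trace` data frame with columns `rep`, `trial`, `step`,
#'   `state`, `delta`, `value`, `reward`; attribute `final_w` holds the
#'   weight vector(s) after the last trial (matrix with one row per rep).
#' @export
run_feature_td <- function(task, features = "sparse",
                           a_plus = 0.15, a_minus = 0.075,
                           kappa = 0, w0 = 0.5, n_reps = 1L, seed = NULL) {
  stopifnot(inherits(task, "td_task"))
  if (!is.null(seed)) withr::local_seed(seed)
  fixed_features <- inherits(features, "feature_set")
  kind <- if (fixed_features) features$kind else match.arg(
    features, c("sparse", "dense", "SR", "PR", "punctate")
  )
  reps <- vector("list", n_reps)
  final_w <- NULL
  for (rp in seq_len(n_reps)) {
    fs <- if (fixed_features) features else make_features(kind, task$n_states)
    tr <- feature_td_once(task, fs$X, a_plus, a_minus, kappa, w0)
    final_w <- rbind(final_w, attr(tr, "final_w"))
    tr$rep <- rp
    reps[[rp]] <- tr
  }
  out <- do.call(rbind, reps)
  out <- out[c("rep", setdiff(names(out), "rep"))]
  attr(out, "final_w") <- final_w
  class(out) <- c("td_trace", class(out))
  out
}

# single repetition of the feature-TD trial loop (rewards drawn from the
# current RNG stream)
feature_td_once <- function(task, X, a_plus, a_minus, kappa, w0) {
  n <- task$n_states
  gamma <- task$gamma
  n_trials <- task$n_trials
  rewards <- sample_reward(task, n_trials)
  m <- ncol(X)
  w <- rep(w0, m)
  colsum <- rowSums(X) # per-state sum of features, for the w0 subtraction
  rows_per <- n + 1L
  delta <- numeric(n_trials * rows_per)
  value <- numeric(n_trials * rows_per)
  r <- 0L
  for (tr in seq_len(n_trials)) {
    vals <- as.numeric(X %*% w) - w0 * colsum
    r <- r + 1L
    delta[r] <- gamma * vals[1L]
    value[r] <- 0
    for (i in seq_len(n)) {
      v_i <- sum(w * X[i, ]) - w0 * colsum[i]
      R_i <- if (i == n) rewards[tr] else 0
      d <- if (i == n) {
        R_i - v_i
      } else {
        v_next <- sum(w * X[i + 1L, ]) - w0 * colsum[i + 1L]
        R_i + gamma * v_next - v_i
      }
      r <- r + 1L
      delta[r] <- d
      value[r] <- v_i
      w <- update_weights(w, d, X[i, ], a_plus, a_minus)
      w <- decay_weights(w, w0, kappa)
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
  attr(out, "final_w") <- w
  out
}

#' Feature-level TD error for online successor-representation learning
#'
#' \eqn{\delta^{SR}_i = I_i + \gamma x_{i+1} - x_i}, where \eqn{I_i} is the
#' i-th unit vector; at the terminal state the \eqn{\gamma x_{i+1}} term is
#' dropped, so \eqn{\delta^{SR}_n = I_n - x_n}, which is identically zero
#' because \eqn{x_n} starts (and hence stays) at \eqn{I_n}.
#'
#' @param X n x n feature matrix (rows are state features).
#' @param i State index.
#' @param gamma Discount used for the SR (default 1).
#' @return The n-dimensional feature TD-error vector.
#' @export
sr_feature_td_error <- function(X, i, gamma = 1) {
  n <- nrow(X)
  if (i < 1L || i > n) stop("state index out of range", call. = FALSE)
  I_i <- numeric(n)
  I_i[i] <- 1
  if (i == n) I_i - X[i, ] else I_i + gamma * X[i + 1L, ] - X[i, ]
}

#' Simulated reward navigation with online SR learning
#'
#' A linear-track navigation run abstracted as the cue-reward task: states
#' start with a punctate representation and the successor representation is
#' gradually shaped by feature-level TD ([sr_feature_td_error()], learning
#' rate `a_SR`) while value weights are learned on the evolving features
#' with weight decay. The headline readout is the TD-RPE between the
#' "post-start" state \eqn{S_2} and the "pre-goal" state \eqn{S_4},
#' session-averaged; full traces and per-session feature matrices are also
#' returned.
#'
#' @param reward_size Reward at the goal (1 or 0.5 in the standard protocol).
#' @param n_trials Total trials (default 360 = 9 sessions x 40 trials).
#' @param session_length Trials per session (default 40).
#' @param a_SR Feature learning rate (default 0.001); 0 freezes the punctate
#'   representation.
#' @param a_plus,a_minus Value learning rates (defaults 0.15, 0.075).
#' @param kappa Weight-decay rate (default 0.01).
#' @param w0 Baseline weight (default 0.5).
#' @param n_states Number of states (default 5).
#' @param gamma Value-learning discount (default 1; the SR target also uses 1).
#' @param order Within-time-step interleaving: `"features_first"` (default)
#'   updates the visited state's feature vector before the value step;
#'   `"value_first"` does the reverse.
#' @return List with `trace` (a `td_trace` with a `session` column),
#'   `session_profiles` (session x step matrix of mean TD-RPE),
#'   `session_features` (list of feature matrices at each session end), and
#'   `sr_distance` (Frobenius distance from each session-end feature matrix
#'   to the exact SR).
#' @export
run_navigation <- function(reward_size = 1, n_trials = 360L,
                           session_length = 40L, a_SR = 0.001,
                           a_plus = 0.15, a_minus = 0.075, kappa = 0.01,
                           w0 = 0.5, n_states = 5L, gamma = 1,
                           order = c("features_first", "value_first")) {
  order <- match.arg(order)
  n <- as.integer(n_states)
  X <- diag(n)
  SR <- make_features("SR", n, gamma = 1)$X
  w <- rep(w0, n)
  n_sessions <- n_trials %/% session_length
  rows_per <- n + 1L
  delta <- numeric(n_trials * rows_per)
  value <- numeric(n_trials * rows_per)
  session_features <- vector("list", n_sessions)
  sr_distance <- numeric(n_sessions)
  r <- 0L
  sv <- function(i) sum(w * X[i, ]) - w0 * sum(X[i, ])
  for (tr in seq_len(n_trials)) {
    r <- r + 1L
    delta[r] <- gamma * sv(1L)
    value[r] <- 0
    for (i in seq_len(n)) {
      value_step <- function() {
        v_i <- sv(i)
        R_i <- if (i == n) reward_size else 0
        d <- if (i == n) R_i - v_i else R_i + gamma * sv(i + 1L) - v_i
        r <<- r + 1L
        delta[r] <<- d
        value[r] <<- v_i
        w <<- update_weights(w, d, X[i, ], a_plus, a_minus)
        w <<- decay_weights(w, w0, kappa)
      }
      if (order == "features_first") {
        X[i, ] <- X[i, ] + a_SR * sr_feature_td_error(X, i, gamma = 1)
        value_step()
      } else {
        value_step()
        X[i, ] <- X[i, ] + a_SR * sr_feature_td_error(X, i, gamma = 1)
      }
    }
    if (tr %% session_length == 0L) {
      s <- tr %/% session_length
      session_features[[s]] <- X
      sr_distance[s] <- sqrt(sum((X - SR)^2))
    }
  }
  trace <- data.frame(
    trial = rep(seq_len(n_trials), each = rows_per),
    step = rep.int(0:n, n_trials),
    state = rep.int(c(NA_integer_, seq_len(n)), n_trials),
    delta = delta,
    value = value,
    reward = reward_size
  )
  trace$session <- (trace$trial - 1L) %/% session_length + 1L
  class(trace) <- c("td_trace", class(trace))
  session_profiles <- t(vapply(
    seq_len(n_sessions),
    function(s) {
      tr <- trace[trace$session == s, ]
      vapply(0:n, function(st) mean(tr$delta[tr$step == st]), numeric(1))
    },
    numeric(rows_per)
  ))
  colnames(session_profiles) <- paste0("step", 0:n)
  list(
    trace = trace,
    session_profiles = session_profiles,
    session_features = session_features,
    sr_distance = sr_distance
  )
}
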