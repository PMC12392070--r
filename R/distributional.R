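#' Reward-prediction errors of the distributional RL algorithms
#'
#' Two schemes for computing TD-RPE from the D1-pathway and D2-pathway value
#' vectors \eqn{V_1} and \eqn{V_2}:
#' \describe{
#'   \item{integRPE}{one unified RPE from the summed values,
#'     \eqn{\delta_i = R_i + \gamma(V_1(S_{i+1}) + V_2(S_{i+1}))
#'       - (V_1(S_i) + V_2(S_i))}, used to update both pathways.}
#'   \item{segreRPE}{per-pathway RPEs,
#'     \eqn{\delta_{ji} = R_i + \gamma V_j(S_{i+1}) - V_j(S_i)}, each used
#'     only for its own pathway.}
#' }
#' At the terminal state the upcoming-value term is dropped in both.
#'
#' @param V1,V2 Pathway value vectors.
#' @param i State index.
#' @param R_i Reward at state `i`.
#' @param gamma Discount factor (default 1).
#' @return The RPE, a scalar.
#' @export
integ_rpe <- function(V1, V2, i, R_i, gamma = 1) {
  n <- length(V1)
  if (i < 1L || i > n) stop("state index out of range", call. = FALSE)
  upcoming <- if (i == n) 0 else gamma * (V1[i + 1L] + V2[i + 1L])
  R_i + upcoming - (V1[i] + V2[i])
}

#' @rdname integ_rpe
#' @param pathway 1 (D1) or 2 (D2).
#' @export
segre_rpe <- function(V1, V2, i, R_i, pathway = 1L, gamma = 1) {
  V <- if (pathway == 1L) V1 else if (pathway == 2L) V2 else {
    stop("pathway must be 1 or 2", call. = FALSE)
  }
  td_rpe(V, i, R_i, gamma)
}

#' Asymmetric value update and joint decay
#'
#' `asym_update()` applies \eqn{V(S_i) \leftarrow V(S_i) + a_+ \delta} if
#' \eqn{\delta \ge 0} and with \eqn{a_-} otherwise. `decay_dist_values()`
#' multiplies every entry of both pathway vectors by \eqn{(1 - \kappa)}.
#'
#' @param V Value vector.
#' @param i State index.
#' @param delta The RPE driving the update.
#' @param a_plus,a_minus Learning rates for non-negative / negative RPE.
#' @return `asym_update()`: the updated vector; `decay_dist_values()`: a
#'   list with decayed `V1` and `V2`.
#' @export
asym_update <- function(V, i, delta, a_plus, a_minus) {
  stopifnot(is.finite(delta))
  V[i] <- V[i] + (if (delta >= 0) a_plus else a_minus) * delta
  V
}

#' @rdname asym_update
#' @param V1,V2 Pathway value vectors.
#' @param kappa Decay rate in `[0, 1)`.
#' @export
decay_dist_values <- function(V1, V2, kappa) {
  stopifnot(kappa >= 0, kappa < 1)
  list(V1 = (1 - kappa) * V1, V2 = (1 - kappa) * V2)
}

#' Run a distributional RL algorithm on a cue-reward task
#'
#' Trial loop as in [run_punctate()] on the two pathway value vectors, with
#' the RPE rule selected by `algorithm`, asymmetric learning rates
#' `(a1_plus, a1_minus, a2_plus, a2_minus)`, and optional value decay
#' applied to all entries of both vectors at every within-trial time-step.
#' All `n_reps` repetitions are simulated in lock-step (vectorized over the
#' repetition dimension) with independent reward draws.
#'
#' @param algorithm `"integRPE"` or `"segreRPE"`.
#' @param task A [make_task()] specification.
#' @param kappa Decay rate (0 or 0.01 in the standard protocol).
#' @param rates Learning-rate quadruple, default `c(0.15, 0.05, 0.05, 0.15)`
#'   so D1 is positively and D2 negatively biased.
#' @param n_reps Number of repetitions (default 100).
#' @param snapshot_trials Trials at which to record the within-trial record
#'   (default: the last trial). Each snapshot stores the pre-update values
#'   of the visited states, the RPE(s), and the realized reward.
#' @param seed Optional seed.
#' @return A `dist_run`: list with `snapshots` (one per requested trial:
#'   `visited_V1`/`visited_V2` (n x n_reps), `delta` (unified, n x n_reps)
#'   or `delta1`/`delta2`, `reward` (length n_reps)), `final_V1`/`final_V2`
#'   (post-run value functions, n x n_reps), and the call parameters.
#' @export
run_distributional <- function(algorithm = c("integRPE", "segreRPE"),
                               task, kappa = 0,
                               rates = c(0.15, 0.05, 0.05, 0.15),
                               n_reps = 100L, snapshot_trials = NULL,
                               seed = NULL) {
  algorithm <- match.arg(algorithm)
  stopifnot(inherits(task, "td_task"), length(rates) == 4L, all(rates > 0))
  if (!is.null(seed)) withr::local_seed(seed)
  n <- task$n_states
  gamma <- task$gamma
  n_trials <- task$n_trials
  if (is.null(snapshot_trials)) snapshot_trials <- n_trials
  stopifnot(all(snapshot_trials >= 1), all(snapshot_trials <= n_trials))
  a1p <- rates[1L]; a1m <- rates[2L]; a2p <- rates[3L]; a2m <- rates[4L]
  R <- as.integer(n_reps)
  V1 <- matrix(0, n, R)
  V2 <- matrix(0, n, R)
  snapshots <- stats::setNames(
    vector("list", length(snapshot_trials)), as.character(snapshot_trials)
  )
  for (tr in seq_len(n_trials)) {
    rew <- sample_reward(task, R)
    snap <- tr %in% snapshot_trials
    if (snap) {
      vis1 <- matrix(NA_real_, n, R); vis2 <- matrix(NA_real_, n, R)
      if (algorithm == "integRPE") {
        dl <- matrix(NA_real_, n, R)
      } else {
        dl1 <- matrix(NA_real_, n, R); dl2 <- matrix(NA_real_, n, R)
      }
    }
    for (i in seq_len(n)) {
      R_i <- if (i == n) rew else numeric(R)
      if (snap) {
        vis1[i, ] <- V1[i, ]
        vis2[i, ] <- V2[i, ]
      }
      if (algorithm == "integRPE") {
        upcoming <- if (i == n) 0 else gamma * (V1[i + 1L, ] + V2[i + 1L, ])
        d <- R_i + upcoming - (V1[i, ] + V2[i, ])
        if (snap) dl[i, ] <- d
        V1[i, ] <- V1[i, ] + ifelse(d >= 0, a1p, a1m) * d
        V2[i, ] <- V2[i, ] + ifelse(d >= 0, a2p, a2m) * d
      } else {
        up1 <- if (i == n) 0 else gamma * V1[i + 1L, ]
        up2 <- if (i == n) 0 else gamma * V2[i + 1L, ]
        d1 <- R_i + up1 - V1[i, ]
        d2 <- R_i + up2 - V2[i, ]
        if (snap) {
          dl1[i, ] <- d1
          dl2[i, ] <- d2
        }
        V1[i, ] <- V1[i, ] + ifelse(d1 >= 0, a1p, a1m) * d1
        V2[i, ] <- V2[i, ] + ifelse(d2 >= 0, a2p, a2m) * d2
      }
      if (kappa > 0) {
        V1 <- (1 - kappa) * V1
        V2 <- (1 - kappa) * V2
      }
    }
    if (snap) {
      snapshots[[as.character(tr)]] <- c(
        list(trial = tr, visited_V1 = vis1, visited_V2 = vis2, reward = rew),
        if (algorithm == "integRPE") list(delta = dl) else {
          list(delta1 = dl1, delta2 = dl2)
        }
      )
    }
  }
  structure(
    list(
      algorithm = algorithm, task = task, kappa = kappa, rates = rates,
      n_reps = R, snapshots = snapshots, final_V1 = V1, final_V2 = V2
    ),
    class = "dist_run"
  )
}

#' @export
print.dist_run <- function(x, ...) {
  cat("<dist_run> ", x$algorithm, ", kappa = ", x$kappa, ", ", x$n_reps,
    " reps x ", x$task$n_trials, " trials\n",
    sep = ""
  )
  cat("  mean terminal V1 =", signif(mean(x$final_V1[x$task$n_states, ]), 4),
    " V2 =", signif(mean(x$final_V2[x$task$n_states, ]), 4), "\n"
  )
  invisible(x)
}

#' Long-format trace of a distributional run's snapshots
#'
#' @param run A `dist_run`.
#' @return Data frame with columns `algorithm`, `repetition`,
#'   `trial_snapshot`, `step`, `V1`, `V2`, `reward`, and `delta` (unified)
#'   or `delta1`/`delta2` (segregated).
#' @export
dist_run_trace <- function(run) {
  stopifnot(inherits(run, "dist_run"))
  do.call(rbind, lapply(run$snapshots, function(s) {
    n <- nrow(s$visited_V1)
    base <- data.frame(
      algorithm = run$algorithm,
      repetition = rep(seq_len(run$n_reps), each = n),
      trial_snapshot = s$trial,
      step = rep.int(seq_len(n), run$n_reps),
      V1 = as.vector(s$visited_V1),
      V2 = as.vector(s$visited_V2),
      reward = rep(s$reward, each = n)
    )
    if (!is.null(s$delta)) {
      base$delta <- as.vector(s$delta)
    } else {
      base$delta1 <- as.vector(s$delta1)
      base$delta2 <- as.vector(s$delta2)
    }
    base
  }))
}

#' Strength of reward-distribution coding
#'
#' Quantifies how well the (D1 value, D2 value) population geometry
#' separates a "fixed" reward condition (always the distribution mean) from
#' a "variable" two-point condition. Gaussian noise of SD `noise_sd` is
#' added to all values; for each time-step, the i-th paired simulations of
#' the two conditions give a difference vector in the (D1, D2) plane, and
#' the score is the mean (and SD) cosine similarity over all unordered
#' pairs of the `n_reps` difference vectors (`n_reps * (n_reps - 1) / 2`
#' pairs). Zero-length difference vectors are excluded and counted.
#'
#' @param fixed,variable `dist_run`s of the two conditions with equal
#'   `n_reps` (paired by repetition index).
#' @param noise_sd Noise SD (0.05 or 0.07 in the standard protocol).
#' @param snapshot Which snapshot trial to use (default: the last recorded).
#' @param seed Optional seed for the noise draws.
#' @return Data frame with one row per time-step: `step`, `cos_mean`,
#'   `cos_sd`, `n_pairs`, `n_excluded`.
#' @export
distribution_coding_score <- function(fixed, variable, noise_sd,
                                      snapshot = NULL, seed = NULL) {
  stopifnot(inherits(fixed, "dist_run"), inherits(variable, "dist_run"))
  stopifnot(fixed$n_reps == variable$n_reps)
  if (!is.null(seed)) withr::local_seed(seed)
  sf <- last_snapshot(fixed, snapshot)
  sv <- last_snapshot(variable, snapshot)
  n <- nrow(sf$visited_V1)
  R <- ncol(sf$visited_V1)
  noisy <- function(m) m + matrix(rnorm(length(m), sd = noise_sd), nrow(m))
  f1 <- noisy(sf$visited_V1); f2 <- noisy(sf$visited_V2)
  v1 <- noisy(sv$visited_V1); v2 <- noisy(sv$visited_V2)
  out <- lapply(seq_len(n), function(i) {
    D <- cbind(f1[i, ] - v1[i, ], f2[i, ] - v2[i, ])
    len <- sqrt(rowSums(D^2))
    keep <- len > 0
    U <- D[keep, , drop = FALSE] / len[keep]
    C <- U %*% t(U)
    cs <- C[upper.tri(C)]
    data.frame(
      step = i, cos_mean = mean(cs), cos_sd = stats::sd(cs),
      n_pairs = length(cs), n_excluded = sum(!keep)
    )
  })
  do.call(rbind, out)
}

#' Strength of reward-mean coding
#'
#' For three reward conditions (in the standard protocol: always 0, {1, 3}
#' equiprobable, always 2, i.e. reward means 0, 2, 2), Gaussian noise is
#' added to the D1 and D2 values, which are then z-normalized across the
#' three conditions separately for D1 and D2 within each simulation and
#' time-step. The score per time-step is the \eqn{R^2} of a regression of
#' the reward mean on the normalized (D1, D2) pair, pooled over simulations
#' and conditions (`method = "multiple"`), or the average of the two
#' univariate \eqn{R^2}s (`method = "average_univariate"`). Simulations
#' with zero variance across conditions are dropped and counted.
#'
#' @param runs List of three `dist_run`s, paired by repetition index.
#' @param noise_sd Noise SD.
#' @param method `"multiple"` (default) or `"average_univariate"`.
#' @param snapshot Which snapshot trial to use (default: the last recorded).
#' @param seed Optional seed for the noise draws.
#' @return Data frame with one row per time-step: `step`, `r2`, `n_dropped`.
#' @export
mean_coding_score <- function(runs, noise_sd,
                              method = c("multiple", "average_univariate"),
                              snapshot = NULL, seed = NULL) {
  method <- match.arg(method)
  stopifnot(length(runs) == 3L, all(vapply(runs, inherits, TRUE, "dist_run")))
  if (!is.null(seed)) withr::local_seed(seed)
  reward_mean <- vapply(runs, function(r) {
    sum(r$task$reward_schedule$size * r$task$reward_schedule$prob)
  }, numeric(1))
  snaps <- lapply(runs, last_snapshot, snapshot)
  n <- nrow(snaps[[1L]]$visited_V1)
  R <- ncol(snaps[[1L]]$visited_V1)
  noisy <- function(m) m + matrix(rnorm(length(m), sd = noise_sd), nrow(m))
  V1 <- lapply(snaps, function(s) noisy(s$visited_V1)) # list over conditions
  V2 <- lapply(snaps, function(s) noisy(s$visited_V2))
  znorm3 <- function(lst, i) {
    # sims x 3 matrix of one pathway's values at step i, z-scored per row
    m <- cbind(lst[[1L]][i, ], lst[[2L]][i, ], lst[[3L]][i, ])
    mu <- rowMeans(m)
    sdv <- apply(m, 1L, stats::sd)
    sweep(sweep(m, 1L, mu), 1L, sdv, "/")
  }
  out <- lapply(seq_len(n), function(i) {
    z1 <- znorm3(V1, i)
    z2 <- znorm3(V2, i)
    ok <- stats::complete.cases(z1) & stats::complete.cases(z2) &
      apply(is.finite(z1), 1L, all) & apply(is.finite(z2), 1L, all)
    y <- rep(reward_mean, each = sum(ok))
    x1 <- as.vector(z1[ok, ])
    x2 <- as.vector(z2[ok, ])
    r2 <- if (method == "multiple") {
      summary(stats::lm(y ~ x1 + x2))$r.squared
    } else {
      (stats::cor(y, x1)^2 + stats::cor(y, x2)^2) / 2
    }
    data.frame(step = i, r2 = r2, n_dropped = sum(!ok))
  })
  do.call(rbind, out)
}

last_snapshot <- function(run, snapshot = NULL) {
  if (is.null(snapshot)) {
    run$snapshots[[length(run$snapshots)]]
  } else {
    s <- run$snapshots[[as.character(snapshot)]]
    if (is.null(s)) stop("no snapshot at trial ", snapshot, call. = FALSE)
    s
  }
}
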