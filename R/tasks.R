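#' Define a cue-delay-reward Pavlovian task
#'
#' Builds the trial structure shared by all model runners: within each trial
#' the agent enters state \eqn{S_1} upon cue and transitions deterministically
#' through \eqn{S_2, \ldots, S_n}, receiving reward only at the final state
#' \eqn{S_n}. The reward can be deterministic (a single size with probability
#' 1) or drawn from a discrete schedule each trial.
#'
#' @param n_states Number of within-trial states \eqn{n \ge 1}. The cue state
#'   is \eqn{S_1} and the reward state is \eqn{S_n}; for `n_states = 1` they
#'   coincide.
#' @param reward_schedule Reward schedule at \eqn{S_n}: a two-column
#'   `data.frame`/matrix with columns `size` and `prob`, or a list of
#'   `c(size, prob)` pairs. Probabilities must sum to 1.
#' @param n_trials Number of trials.
#' @param gamma Time discount factor \eqn{\gamma \in [0, 1]}.
#'
#' @return An object of class `td_task`.
#' @examples
#' # deterministic task: reward of size 1 after a 4-step delay
#' make_task(5, list(c(1, 1)), 200, 1)
#' # probabilistic task: reward 1 or 3 with equal probabilities
#' make_task(5, list(c(1, 0.5), c(3, 0.5)), 200, 1)
#' @export
make_task <- function(n_states, reward_schedule, n_trials = 200L, gamma = 1) {
  schedule <- as_reward_schedule(reward_schedule)
  stopifnot(
    length(n_states) == 1L, n_states >= 1, n_states == as.integer(n_states),
    length(n_trials) == 1L, n_trials >= 1,
    length(gamma) == 1L, gamma >= 0, gamma <= 1
  )
  if (abs(sum(schedule$prob) - 1) > 1e-8) {
    stop("reward schedule probabilities must sum to 1", call. = FALSE)
  }
  if (any(schedule$prob < 0)) {
    stop("reward schedule probabilities must be non-negative", call. = FALSE)
  }
  structure(
    list(
      n_states = as.integer(n_states),
      reward_schedule = schedule,
      n_trials = as.integer(n_trials),
      gamma = as.numeric(gamma)
    ),
    class = "td_task"
  )
}

as_reward_schedule <- function(x) {
  if (is.data.frame(x) || is.matrix(x)) {
    x <- as.data.frame(x)
    if (ncol(x) != 2L) stop("reward schedule needs columns size, prob", call. = FALSE)
    names(x) <- c("size", "prob")
  } else if (is.list(x)) {
    if (!all(vapply(x, length, 1L) == 2L)) {
      stop("reward schedule pairs must be (size, prob)", call. = FALSE)
    }
    x <- data.frame(
      size = vapply(x, `[`, numeric(1), 1L),
      prob = vapply(x, `[`, numeric(1), 2L)
    )
  } else if (is.numeric(x) && length(x) == 2L) {
    x <- data.frame(size = x[1L], prob = x[2L])
  } else {
    stop("cannot interpret reward schedule", call. = FALSE)
  }
  x
}

#' @export
print.td_task <- function(x, ...) {
  cat("<td_task> ", x$n_states, " states, ", x$n_trials, " trials, gamma = ",
    x$gamma, "\n",
    sep = ""
  )
  cat("  reward at S_n:",
    paste0(x$reward_schedule$size, " (p=", x$reward_schedule$prob, ")",
      collapse = ", "
    ), "\n"
  )
  invisible(x)
}

#' Draw per-trial rewards from a task's schedule
#'
#' @param task A `td_task`.
#' @param n Number of draws (one per trial).
#' @param seed Optional integer seed; when supplied the draw is made with a
#'   locally seeded RNG so global RNG state is untouched.
#' @return Numeric vector of `n` reward sizes.
#' @export
sample_reward <- function(task, n = 1L, seed = NULL) {
  stopifnot(inherits(task, "td_task"))
  if (!is.null(seed)) withr::local_seed(seed)
  sizes <- task$reward_schedule$size
  probs <- task$reward_schedule$prob
  if (length(sizes) == 1L) {
    return(rep(sizes, n))
  }
  sizes[sample.int(length(sizes), n, replace = TRUE, prob = probs)]
}

#' Generate the observation stream for the online value-RNN task
#'
#' Concatenates `n_trials` trials into a single time series of 5-dimensional
#' binary observations. A trial consists of an inter-trial interval (ITI)
#' with all units silent, 4 cue time-steps, and a reward time-step. With a
#' `fixed` cue, observation unit 1 is active for the four consecutive cue
#' steps; with a `dynamic` cue, units 1-4 fire sequentially, one per step.
#' Unit 5 fires only at the reward step.
#'
#' The ITI is the number of silent steps strictly between a reward step and
#' the next cue-onset step (exclusive-exclusive count), drawn uniformly per
#' trial from {4,5,6,7} (`short`) or {7,9,11,13} (`long`). The first trial is
#' preceded by an ITI drawn the same way.
#'
#' @param cue_type `"fixed"` or `"dynamic"`.
#' @param iti_kind `"short"` or `"long"`.
#' @param n_trials Number of trials.
#' @param seed Optional integer seed for the ITI draws.
#' @return An object of class `observation_stream` with elements
#'   `obs` (T x 5 binary matrix), `reward` (length-T 0/1 vector),
#'   `trial` (length-T trial index, 0 during the leading ITI of trial 1;
#'   ITI steps are attributed to the upcoming trial), `cue_onset` and
#'   `reward_step` (per-trial step indices), `iti` (per-trial draw), and the
#'   generating arguments.
#' @export
make_observation_stream <- function(cue_type = c("fixed", "dynamic"),
                                    iti_kind = c("short", "long"),
                                    n_trials = 1000L,
                                    seed = NULL) {
  cue_type <- match.arg(cue_type)
  iti_kind <- match.arg(iti_kind)
  stopifnot(n_trials >= 1)
  if (!is.null(seed)) withr::local_seed(seed)
  iti_choices <- switch(iti_kind,
    short = c(4L, 5L, 6L, 7L),
    long = c(7L, 9L, 11L, 13L)
  )
  iti <- iti_choices[sample.int(4L, n_trials, replace = TRUE)]
  total <- sum(iti) + 5L * n_trials
  obs <- matrix(0, nrow = total, ncol = 5L)
  reward <- numeric(total)
  trial <- integer(total)
  cue_onset <- integer(n_trials)
  reward_step <- integer(n_trials)
  t <- 0L
  for (k in seq_len(n_trials)) {
    if (iti[k] > 0L) trial[(t + 1L):(t + iti[k])] <- k
    t <- t + iti[k] # silent ITI steps
    cue_onset[k] <- t + 1L
    if (cue_type == "fixed") {
      obs[t + 1:4, 1L] <- 1
    } else {
      obs[cbind(t + 1:4, 1:4)] <- 1
    }
    obs[t + 5L, 5L] <- 1
    reward[t + 5L] <- 1
    trial[(t + 1L):(t + 5L)] <- k
    reward_step[k] <- t + 5L
    t <- t + 5L
  }
  structure(
    list(
      obs = obs, reward = reward, trial = trial,
      cue_onset = cue_onset, reward_step = reward_step, iti = iti,
      cue_type = cue_type, iti_kind = iti_kind, n_trials = as.integer(n_trials)
    ),
    class = "observation_stream"
  )
}

#' @export
print.observation_stream <- function(x, ...) {
  cat("<observation_stream> ", x$n_trials, " trials (", x$cue_type, " cue, ",
    x$iti_kind, " ITI), ", nrow(x$obs), " time-steps\n",
    sep = ""
  )
  invisible(x)
}

#' @export
as.data.frame.observation_stream <- function(x, ...) {
  d <- as.data.frame(x$obs)
  names(d) <- paste0("o", 1:5)
  cbind(t = seq_len(nrow(x$obs)), d, trial_index = x$trial)
}

#' Serialize / restore a task specification
#'
#' Tasks round-trip losslessly through YAML (or JSON via file extension
#' `.json`), so experiment configurations can be kept as plain-text files.
#'
#' @param task A `td_task`.
#' @param path File path ending in `.yaml`/`.yml` or `.json`.
#' @return `write_task_config` returns `path` invisibly; `read_task_config`
#'   returns the restored `td_task`.
#' @export
write_task_config <- function(task, path) {
  stopifnot(inherits(task, "td_task"))
  x <- list(
    n_states = task$n_states,
    reward_schedule = list(
      size = task$reward_schedule$size,
      prob = task$reward_schedule$prob
    ),
    n_trials = task$n_trials,
    gamma = task$gamma
  )
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}

#' @rdname write_task_config
#' @export
read_task_config <- function(path) {
  x <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  make_task(
    n_states = x$n_states,
    reward_schedule = data.frame(
      size = unlist(x$reward_schedule$size),
      prob = unlist(x$reward_schedule$prob)
    ),
    n_trials = x$n_trials,
    gamma = x$gamma
  )
}
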