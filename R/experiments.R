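#' Named experiment presets
#'
#' Each preset bundles the default parameters of one of the package's
#' standard experiments. Every default equals the protocol
#' value documented in the corresponding runner; presets are plain lists,
#' so any field can be overridden through [run_experiment()].
#'
#' Available ids:
#' \describe{
#'   \item{punctate_decay_sweep}{tabular TD, decay rate 0 / 0.01 / 0.02.}
#'   \item{discounting_vs_decay}{tabular TD: no decay, decay 0.01, and
#'     discounting (gamma 0.75) without decay.}
#'   \item{feature_decay_sweep}{sparse/dense/SR/PR features under the same
#'     decay sweep; 100 repetitions for the random representations.}
#'   \item{navigation_sr}{online SR learning during simulated navigation,
#'     reward 1 and 0.5.}
#'   \item{ovrnn_conditions}{online value-RNN, 2 cue types x 2 ITI lengths
#'     x decay 0 / 0.001, 100 repetitions.}
#'   \item{hierarchical_retention}{two-circuit model through learning, rest
#'     and extinction, original and revised (halved current-value) variants.}
#'   \item{distributional_values}{integRPE / segreRPE value trajectories on
#'     probabilistic and deterministic tasks, snapshots at trials 200 and
#'     2000.}
#'   \item{coding_strength}{distribution- and mean-coding scores, 1000
#'     simulations x 3 reward conditions x noise SD 0.05 / 0.07.}
#'   \item{cue_value_delay_sweep}{cue response versus cue-reward delay
#'     (1-10 steps) per representation, decay 0.01 / 0.02.}
#'   \item{incomplete_learning}{dense features, symmetric learning rate
#'     0.15 / 0.015 / 0.005, probabilistic reward 0.5 / 1.5, 100 trials.}
#' }
#'
#' @return Named list of preset configurations.
#' @export
experiment_presets <- function() {
  list(
    punctate_decay_sweep = list(
      n_states = 5L, reward = 1, n_trials = 200L, gamma = 1,
      a = 0.15, kappa = c(0, 0.01, 0.02)
    ),
    discounting_vs_decay = list(
      n_states = 5L, reward = 1, n_trials = 200L, a = 0.15,
      cases = list(
        no_decay = list(kappa = 0, gamma = 1),
        decay = list(kappa = 0.01, gamma = 1),
        discounting = list(kappa = 0, gamma = 0.75)
      )
    ),
    feature_decay_sweep = list(
      n_states = 5L, reward = 1, n_trials = 200L, gamma = 1,
      a_plus = 0.15, a_minus = 0.075, w0 = 0.5,
      kappa = c(0, 0.01, 0.02),
      kinds = c("sparse", "dense", "SR", "PR"), n_reps = 100L
    ),
    navigation_sr = list(
      reward_sizes = c(1, 0.5), n_trials = 360L, session_length = 40L,
      a_SR = 0.001, a_plus = 0.15, a_minus = 0.075, kappa = 0.01, w0 = 0.5
    ),
    ovrnn_conditions = list(
      cue_types = c("fixed", "dynamic"), iti_kinds = c("short", "long"),
      dr = c(0, 0.001), n_trials = 1000L, n_reps = 100L, n_units = 40L,
      gamma = 0.8, a_RNN = 0.1, a_value = 0.03, average_last = 100L
    ),
    hierarchical_retention = list(
      n_states = 5L, reward = 1,
      phases = list(c("learning", 200), c("rest", 200), c("extinction", 200)),
      a_M = 0.25, a_L = 0.025, kappa_M = 0.01, kappa_L = 0,
      lambda_cur = c(1, 0.5), gamma = 1
    ),
    distributional_values = list(
      n_states = 5L, gamma = 1, n_trials = 2000L,
      snapshot_trials = c(200L, 2000L), n_reps = 100L,
      rates = c(0.15, 0.05, 0.05, 0.15),
      tasks = list(
        variable13 = list(c(1, 0.5), c(3, 0.5)),
        variable04 = list(c(0, 0.5), c(4, 0.5)),
        fixed2 = list(c(2, 1))
      ),
      cases = list(
        integ_nodecay = list(algorithm = "integRPE", kappa = 0),
        integ_decay = list(algorithm = "integRPE", kappa = 0.01),
        segre_nodecay = list(algorithm = "segreRPE", kappa = 0),
        segre_decay = list(algorithm = "segreRPE", kappa = 0.01)
      )
    ),
    coding_strength = list(
      n_states = 5L, gamma = 1, n_trials = 200L, n_sims = 1000L,
      rates = c(0.15, 0.05, 0.05, 0.15), noise_sd = c(0.05, 0.07),
      conditions = list(
        always0 = list(c(0, 1)),
        variable13 = list(c(1, 0.5), c(3, 0.5)),
        always2 = list(c(2, 1))
      ),
      algorithms = list(
        integ_decay = list(algorithm = "integRPE", kappa = 0.01),
        segre_nodecay = list(algorithm = "segreRPE", kappa = 0)
      )
    ),
    cue_value_delay_sweep = list(
      delays = 1:10, reward = 1, n_trials = 200L, gamma = 1,
      a = 0.15, a_plus = 0.15, a_minus = 0.075, w0 = 0.5,
      kappa = c(0.01, 0.02),
      kinds = c("punctate", "sparse", "dense", "SR", "PR"), n_reps = 100L
    ),
    incomplete_learning = list(
      n_states = 5L, n_trials = 100L, gamma = 1, w0 = 0.5, kappa = 0,
      reward_schedule = list(c(0.5, 0.5), c(1.5, 0.5)),
      learning_rates = c(0.15, 0.015, 0.005), n_reps = 100L
    )
  )
}

#' Run a configured experiment and write its artifacts
#'
#' Resolves a preset id (or a full configuration list with an `experiment`
#' field naming the preset), applies overrides, runs the corresponding
#' simulations, and writes long-format CSV tables plus a JSON sidecar
#' holding the resolved configuration, the seed, and the package version.
#' Given the same configuration and seed the outputs are byte-identical.
#'
#' @param experiment Preset id (see [experiment_presets()]) or a config
#'   list with an `experiment` element.
#' @param overrides Named list of parameter overrides.
#' @param seed Integer seed governing all randomness in the experiment.
#' @param out_dir Output directory (created if needed); `NULL` skips
#'   writing and just returns the tables.
#' @return Invisibly, a list with `tables` (named list of data frames),
#'   `config`, and `files` (paths written, or `NULL`).
#' @export
run_experiment <- function(experiment, overrides = list(), seed = 1L,
                           out_dir = NULL) {
  presets <- experiment_presets()
  if (is.list(experiment)) {
    id <- experiment$experiment
    inline <- experiment[setdiff(names(experiment), "experiment")]
    inline[names(overrides)] <- overrides
    overrides <- inline
  } else {
    id <- experiment
  }
  if (is.null(id) || !id %in% names(presets)) {
    stop("unknown experiment id: ", deparse(id), call. = FALSE)
  }
  # shallow merge: an override replaces the preset field wholesale
  config <- presets[[id]]
  config[names(overrides)] <- overrides
  validate_config(config)
  handler <- experiment_handlers()[[id]]
  tables <- withr::with_seed(seed, handler(config))
  files <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- character(0)
    for (nm in names(tables)) {
      f <- file.path(out_dir, paste0(nm, ".csv"))
      utils::write.csv(tables[[nm]], f, row.names = FALSE)
      files <- c(files, f)
    }
    sidecar <- file.path(out_dir, "config.json")
    jsonlite::write_json(
      list(
        experiment = id, config = config, seed = seed,
        package_version = as.character(utils::packageVersion("decaytd"))
      ),
      sidecar,
      auto_unbox = TRUE, digits = NA, pretty = TRUE, force = TRUE
    )
    files <- c(files, sidecar)
  }
  invisible(list(tables = tables, config = config, files = files))
}

validate_config <- function(config) {
  for (nm in intersect(names(config), c("kappa", "kappa_M", "kappa_L", "dr"))) {
    v <- config[[nm]]
    if (any(v < 0) || any(v >= 1)) {
      stop("invalid parameter ", nm, ": decay rates must lie in [0, 1)",
        call. = FALSE
      )
    }
  }
  invisible(config)
}

#' Per-time-step summary of a trace
#'
#' Aggregates a long-format trace over repetitions (and trials, if several
#' are present) at each within-trial step, reporting the mean with SD or
#' SEM, optionally split by realized reward size.
#'
#' @param trace Data frame with columns `step`, `delta` (and optionally
#'   `value`, `rep`, `reward`).
#' @param stat `"mean_sd"` or `"mean_sem"`.
#' @param by_reward Split by the `reward` column.
#' @return Data frame with columns `step` (, `reward`), `n`, `delta_mean`,
#'   `delta_spread` (SD or SEM), and the analogous `value_*` columns when a
#'   `value` column is present.
#' @export
summarize_trace <- function(trace, stat = c("mean_sd", "mean_sem"),
                            by_reward = FALSE) {
  stat <- match.arg(stat)
  if (nrow(trace) == 0L) stop("empty trace", call. = FALSE)
  groups <- list(step = trace$step)
  if (by_reward) groups$reward <- trace$reward
  spread <- function(x) {
    s <- stats::sd(x)
    if (stat == "mean_sem") s / sqrt(length(x)) else s
  }
  out <- aggregate(trace["delta"], by = groups, FUN = mean)
  names(out)[names(out) == "delta"] <- "delta_mean"
  out$delta_spread <- aggregate(trace["delta"], by = groups, FUN = spread)$delta
  out$n <- aggregate(trace["delta"], by = groups, FUN = length)$delta
  if ("value" %in% names(trace)) {
    out$value_mean <- aggregate(trace["value"], by = groups, FUN = mean)$value
    out$value_spread <- aggregate(trace["value"], by = groups, FUN = spread)$value
  }
  ord <- if (by_reward) order(out$reward, out$step) else order(out$step)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# --- preset handlers ------------------------------------------------------

experiment_handlers <- function() {
  list(
    punctate_decay_sweep = function(cfg) {
      task <- make_task(cfg$n_states, list(c(cfg$reward, 1)), cfg$n_trials, cfg$gamma)
      tabs <- lapply(cfg$kappa, function(k) {
        prof <- steady_profile(run_punctate(task, a = cfg$a, kappa = k))
        cbind(kappa = k, prof)
      })
      list(steady_profiles = do.call(rbind, tabs))
    },
    discounting_vs_decay = function(cfg) {
      tabs <- lapply(names(cfg$cases), function(nm) {
        cs <- cfg$cases[[nm]]
        task <- make_task(cfg$n_states, list(c(cfg$reward, 1)), cfg$n_trials, cs$gamma)
        prof <- steady_profile(run_punctate(task, a = cfg$a, kappa = cs$kappa))
        cbind(case = nm, kappa = cs$kappa, gamma = cs$gamma, prof)
      })
      list(steady_profiles = do.call(rbind, tabs))
    },
    feature_decay_sweep = function(cfg) {
      task <- make_task(cfg$n_states, list(c(cfg$reward, 1)), cfg$n_trials, cfg$gamma)
      tabs <- list()
      for (kind in cfg$kinds) {
        reps <- if (kind %in% c("sparse", "dense")) cfg$n_reps else 1L
        for (k in cfg$kappa) {
          tr <- run_feature_td(task, kind,
            a_plus = cfg$a_plus, a_minus = cfg$a_minus,
            kappa = k, w0 = cfg$w0, n_reps = reps
          )
          fin <- tr[tr$trial == cfg$n_trials, ]
          sm <- summarize_trace(fin)
          tabs[[paste(kind, k, sep = "_")]] <- cbind(kind = kind, kappa = k, sm)
        }
      }
      list(steady_profiles = do.call(rbind, tabs))
    },
    navigation_sr = function(cfg) {
      profs <- list()
      dists <- list()
      for (rs in cfg$reward_sizes) {
        nav <- run_navigation(
          reward_size = rs, n_trials = cfg$n_trials,
          session_length = cfg$session_length, a_SR = cfg$a_SR,
          a_plus = cfg$a_plus, a_minus = cfg$a_minus, kappa = cfg$kappa,
          w0 = cfg$w0
        )
        sp <- as.data.frame(nav$session_profiles)
        sp$session <- seq_len(nrow(sp))
        sp$reward_size <- rs
        profs[[as.character(rs)]] <- sp
        dists[[as.character(rs)]] <- data.frame(
          reward_size = rs, session = seq_along(nav$sr_distance),
          sr_distance = nav$sr_distance
        )
      }
      list(
        session_profiles = do.call(rbind, profs),
        sr_distance = do.call(rbind, dists)
      )
    },
    ovrnn_conditions = function(cfg) {
      tabs <- list()
      for (dr in cfg$dr) {
        for (ct in cfg$cue_types) {
          for (ik in cfg$iti_kinds) {
            run <- run_ovrnn(ct, ik,
              dr = dr, n_trials = cfg$n_trials,
              n_reps = cfg$n_reps, n_units = cfg$n_units, gamma = cfg$gamma,
              a_RNN = cfg$a_RNN, a_value = cfg$a_value,
              average_last = cfg$average_last, keep_trace = FALSE
            )
            long <- data.frame(
              dr = dr, cue_type = ct, iti_kind = ik,
              rep = rep(seq_len(cfg$n_reps), times = 6L),
              rel_step = rep(0:5, each = cfg$n_reps),
              delta = as.vector(run$delta_profiles),
              value = as.vector(run$value_profiles)
            )
            sm <- summarize_trace(
              data.frame(step = long$rel_step, delta = long$delta, value = long$value),
              stat = "mean_sem"
            )
            tabs[[paste(dr, ct, ik, sep = "_")]] <-
              cbind(dr = dr, cue_type = ct, iti_kind = ik, sm)
          }
        }
      }
      list(condition_profiles = do.call(rbind, tabs))
    },
    hierarchical_retention = function(cfg) {
      tabs <- lapply(cfg$lambda_cur, function(lc) {
        tr <- run_hierarchical(
          phases = cfg$phases, n_states = cfg$n_states,
          reward_size = cfg$reward, a_M = cfg$a_M, a_L = cfg$a_L,
          kappa_M = cfg$kappa_M, kappa_L = cfg$kappa_L,
          lambda_cur = lc, gamma = cfg$gamma
        )
        cbind(lambda_cur = lc, tr)
      })
      list(trace = do.call(rbind, tabs))
    },
    distributional_values = function(cfg) {
      tabs <- list()
      for (tn in names(cfg$tasks)) {
        task <- make_task(cfg$n_states, cfg$tasks[[tn]], cfg$n_trials, cfg$gamma)
        for (cn in names(cfg$cases)) {
          cs <- cfg$cases[[cn]]
          run <- run_distributional(cs$algorithm, task,
            kappa = cs$kappa,
            rates = cfg$rates, n_reps = cfg$n_reps,
            snapshot_trials = cfg$snapshot_trials
          )
          tabs[[paste(tn, cn, sep = "_")]] <-
            cbind(task = tn, case = cn, kappa = cs$kappa, dist_run_trace(run))
        }
      }
      list(snapshots = do.call(rbind, tabs))
    },
    coding_strength = function(cfg) {
      runs <- list()
      for (an in names(cfg$algorithms)) {
        alg <- cfg$algorithms[[an]]
        runs[[an]] <- lapply(cfg$conditions, function(sch) {
          task <- make_task(cfg$n_states, sch, cfg$n_trials, cfg$gamma)
          run_distributional(alg$algorithm, task,
            kappa = alg$kappa,
            rates = cfg$rates, n_reps = cfg$n_sims
          )
        })
      }
      dist_tab <- list()
      mean_tab <- list()
      for (an in names(runs)) {
        for (ns in cfg$noise_sd) {
          dc <- distribution_coding_score(
            runs[[an]]$always2, runs[[an]]$variable13, ns
          )
          mc <- mean_coding_score(
            runs[[an]][c("always0", "variable13", "always2")], ns
          )
          dist_tab[[paste(an, ns)]] <- cbind(algorithm = an, noise_sd = ns, dc)
          mean_tab[[paste(an, ns)]] <- cbind(algorithm = an, noise_sd = ns, mc)
        }
      }
      list(
        distribution_coding = do.call(rbind, dist_tab),
        mean_coding = do.call(rbind, mean_tab)
      )
    },
    cue_value_delay_sweep = function(cfg) {
      tabs <- list()
      for (k in cfg$kappa) {
        for (kind in cfg$kinds) {
          for (d in cfg$delays) {
            task <- make_task(d, list(c(cfg$reward, 1)), cfg$n_trials, cfg$gamma)
            cue <- if (kind == "punctate") {
              tr <- run_punctate(task, a = cfg$a, kappa = k)
              list(mean = tr$delta[tr$trial == cfg$n_trials & tr$step == 0L], sd = 0)
            } else {
              reps <- if (kind %in% c("sparse", "dense")) cfg$n_reps else 1L
              tr <- run_feature_td(task, kind,
                a_plus = cfg$a_plus,
                a_minus = cfg$a_minus, kappa = k, w0 = cfg$w0, n_reps = reps
              )
              x <- tr$delta[tr$trial == cfg$n_trials & tr$step == 0L]
              list(mean = mean(x), sd = if (length(x) > 1L) stats::sd(x) else 0)
            }
            tabs[[paste(k, kind, d)]] <- data.frame(
              kappa = k, kind = kind, delay = d,
              cue_value = cue$mean, cue_value_sd = cue$sd
            )
          }
        }
      }
      list(cue_value_vs_delay = do.call(rbind, tabs))
    },
    incomplete_learning = function(cfg) {
      task <- make_task(cfg$n_states, cfg$reward_schedule, cfg$n_trials, cfg$gamma)
      tabs <- lapply(cfg$learning_rates, function(a) {
        tr <- run_feature_td(task, "dense",
          a_plus = a, a_minus = a,
          kappa = cfg$kappa, w0 = cfg$w0, n_reps = cfg$n_reps
        )
        fin <- tr[tr$trial == cfg$n_trials, ]
        cbind(a = a, summarize_trace(fin, by_reward = TRUE))
      })
      list(final_trial_profiles = do.call(rbind, tabs))
    }
  )
}
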