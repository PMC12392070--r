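test_that("feature constructors obey the representation invariants", {
  sr <- make_features("SR", 5)$X
  expect_equal(sr[1, ], rep(1, 5))
  expect_equal(sr[5, ], c(0, 0, 0, 0, 1))
  expect_true(all(sr[lower.tri(sr)] == 0))
  pr <- make_features("PR", 5)$X
  expect_equal(pr[1, ], c(1, 0, 0, 0, 0))
  expect_equal(pr[5, ], rep(1, 5))
  # discounted occupancies for gamma < 1
  sr9 <- make_features("SR", 5, gamma = 0.9)$X
  expect_equal(sr9[1, ], 0.9^(0:4))

  sp <- make_features("sparse", 5, seed = 5)$X
  expect_equal(rowSums(sp != 0), rep(10, 5))
  expect_equal(sqrt(rowSums(sp^2)), rep(1, 5))
  dn <- make_features("dense", 5, seed = 5)$X
  expect_true(all(dn > 0))
  expect_equal(sqrt(rowSums(dn^2)), rep(1, 5))
  expect_equal(make_features("punctate", 4)$X, diag(4))
})

test_that("state value, weight update and weight decay follow their formulas", {
  # initialization w = w0 gives zero values for any feature vector
  x <- runif(10)
  expect_equal(state_value(rep(0.5, 10), 0.5, x), 0)
  expect_equal(state_value(c(1, 0.5), 0.5, c(1, 0)), 0.5)
  expect_equal(
    state_value(c(1, 0.5), 0.5, 3 * c(0.2, 0.7)),
    3 * state_value(c(1, 0.5), 0.5, c(0.2, 0.7))
  )
  expect_error(state_value(c(1, 0.5), 0.5, c(1, 0, 0)), "mismatch")

  expect_equal(update_weights(c(0.5, 0.5), 0.2, c(1, 0), 0.15), c(0.53, 0.5))
  expect_equal(update_weights(c(0.5, 0.5), 0, c(1, 0), 0.15), c(0.5, 0.5))
  expect_equal(update_weights(c(0, 0), -1, c(1, 1), 0.15, 0.075), c(0, 0))
  # the 1/||x||^2 scaling matters for non-unit-norm features
  expect_equal(update_weights(c(0, 0), 1, c(2, 0), 0.15), c(0.075, 0))
  expect_error(update_weights(c(0, 0), 1, c(0, 0), 0.15), "zero feature")

  expect_equal(decay_weights(0.5, 0.5, 0.01), 0.5) # baseline is the attractor
  expect_equal(decay_weights(0.7, 0.5, 0.01), 0.698)
  expect_equal(decay_weights(0.3, 0.5, 0.01), 0.302) # moves UP toward w0
})

test_that("weights stay non-negative through arbitrary update/decay runs", {
  withr::with_seed(8, {
    w <- runif(20)
    X <- matrix(runif(100), 5)
    for (k in 1:500) {
      i <- sample(5, 1)
      w <- update_weights(w, rnorm(1, sd = 2), X[i, ], 0.15, 0.075)
      w <- decay_weights(w, 0.5, 0.01)
      expect_true(all(w >= 0))
    }
  })
})

test_that("without decay, feature TD recovers the tabular values", {
  # linearly independent features: steady values must match tabular TD
  task <- det_task(3000)
  for (kind in c("SR", "PR")) {
    tr <- run_feature_td(task, make_features(kind, 5), kappa = 0)
    fin <- tr[tr$trial == 3000 & tr$step >= 1, ]
    expect_equal(fin$value, rep(1, 5), tolerance = 1e-4)
    expect_true(all(abs(fin$delta) < 1e-4))
  }
})

test_that("feature-TD steady state matches the brute-force fixed point", {
  task <- det_task(3000)
  for (kind in c("SR", "PR")) {
    X <- make_features(kind, 5)$X
    w_fp <- oracle_feature_fp(X, 1, 0.15, 0.075, 0.01, 0.5, 1)
    tr <- run_feature_td(task, make_features(kind, 5), kappa = 0.01)
    expect_lt(max(abs(attr(tr, "final_w") - w_fp)), 1e-8)
  }
})

test_that("ramping under decay depends on the representation", {
  task <- det_task(200)
  mid <- function(trace) {
    fin <- trace[trace$trial == 200, ]
    mean(fin$delta[fin$step %in% 2:4])
  }
  sr <- run_feature_td(task, make_features("SR", 5), kappa = 0.01)
  pr <- run_feature_td(task, make_features("PR", 5), kappa = 0.01)
  sp <- run_feature_td(task, "sparse", kappa = 0.01, n_reps = 50, seed = 31)
  dn <- run_feature_td(task, "dense", kappa = 0.01, n_reps = 50, seed = 32)
  expect_gt(mid(sp), mid(dn))
  expect_gt(mid(dn), mid(sr))
  expect_lt(abs(mid(sr)), 0.02) # SR: no intermediate ramp
  # SR keeps a sustained response at reward
  fin_sr <- sr[sr$trial == 200, ]
  expect_gt(fin_sr$delta[fin_sr$step == 5], 0.1)
  # PR ramps DOWN across the intermediate states
  fin_pr <- pr[pr$trial == 200, ]
  dpr <- fin_pr$delta[fin_pr$step %in% 2:4]
  expect_true(all(diff(dpr) < 0))
})

test_that("SR feature TD errors vanish exactly at the SR fixed point", {
  X0 <- diag(5)
  expect_equal(sr_feature_td_error(X0, 1, 1), c(0, 1, 0, 0, 0))
  expect_equal(sr_feature_td_error(X0, 5, 1), numeric(5)) # always zero
  SR <- make_features("SR", 5)$X
  for (i in 1:5) expect_equal(sr_feature_td_error(SR, i, 1), numeric(5))
})

test_that("navigation ramps fade as the representation approaches the SR", {
  nav <- run_navigation(reward_size = 1)
  ramp <- rowMeans(nav$session_profiles[, c("step2", "step3", "step4")])
  expect_length(ramp, 9)
  expect_true(all(diff(ramp) < 0)) # monotone shrinkage across sessions
  expect_true(all(diff(nav$sr_distance) <= 0)) # converging toward exact SR
  # early trials: ramp concentrated at reward-proximal steps
  tr <- nav$trace
  early <- vapply(
    2:4, function(s) mean(tr$delta[tr$trial %in% 2:9 & tr$step == s]),
    numeric(1)
  )
  expect_true(all(diff(early) > 0))
  expect_gt(early[3], 3 * early[1])
  # frozen features (a_SR = 0) keep the ramp across all sessions
  nav0 <- run_navigation(reward_size = 1, a_SR = 0)
  ramp0 <- rowMeans(nav0$session_profiles[, c("step2", "step3", "step4")])
  expect_gt(min(ramp0), 0.8 * ramp0[1])
})

test_that("incomplete learning leaves positive cue and reward responses", {
  task <- make_task(5, list(c(0.5, 0.5), c(1.5, 0.5)), 100, 1)
  withr::with_seed(33, {
    fast <- run_feature_td(task, "dense", a_plus = 0.15, a_minus = 0.15, n_reps = 50)
    slow <- run_feature_td(task, "dense", a_plus = 0.005, a_minus = 0.005, n_reps = 50)
  })
  cue <- function(tr) mean(tr$delta[tr$trial == 100 & tr$step == 0])
  expect_gt(cue(fast), 0.9) # learning almost complete
  expect_lt(cue(slow), 0.5) # learning still incomplete
  fin <- slow[slow$trial == 100 & slow$step == 5, ]
  for (r in c(0.5, 1.5)) expect_gt(mean(fin$delta[fin$reward == r]), 0)
})
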