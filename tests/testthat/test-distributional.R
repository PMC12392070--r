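test_that("integrated and segregated RPEs follow their formulas", {
  V0 <- numeric(5)
  expect_equal(integ_rpe(V0, V0, 5, 2), 2)
  # only the sum of the two pathway values matters
  V1 <- rep(1.5, 5)
  V2 <- rep(0.5, 5)
  for (i in 1:5) expect_equal(integ_rpe(V1, V2, i, if (i == 5) 2 else 0), 0)
  withr::with_seed(51, {
    A <- runif(5)
    B <- runif(5)
    h <- rnorm(5)
    for (i in 1:5) {
      expect_equal(
        integ_rpe(A + h, B - h, i, 1),
        integ_rpe(A, B, i, 1)
      ) # shift invariance
      expect_equal(integ_rpe(A, B, i, 1), integ_rpe(B, A, i, 1)) # symmetry
    }
  })
  # segregation: pathway 1 ignores pathway 2 entirely
  Vf <- rep(2, 5)
  for (i in 1:5) {
    expect_equal(segre_rpe(Vf, runif(5), i, if (i == 5) 2 else 0, 1), 0)
  }
  expect_equal(segre_rpe(V0, rep(1.5, 5), 5, 3, 2), 1.5)
  expect_equal(segre_rpe(Vf, Vf, 3, 0, 1), segre_rpe(Vf, Vf, 3, 0, 2))
})

test_that("asymmetric update and joint decay follow their formulas", {
  V <- numeric(3)
  expect_equal(asym_update(V, 2, 1, 0.15, 0.05)[2], 0.15)
  expect_equal(asym_update(V, 2, -1, 0.15, 0.05)[2], -0.05)
  expect_equal(asym_update(V, 2, 0, 0.15, 0.05), V)
  d <- decay_dist_values(c(2, 1), c(-1, 3), 0.01)
  expect_equal(d$V1, c(1.98, 0.99))
  expect_equal(d$V2, c(-0.99, 2.97))
})

test_that("segregated learning recovers the asymmetric fixed points", {
  # two-point {1,3} task: expectile-like fixed points from a root solver
  q1 <- oracle_asym_fixed_point(c(1, 3), c(0.5, 0.5), 0.15, 0.05)
  q2 <- oracle_asym_fixed_point(c(1, 3), c(0.5, 0.5), 0.05, 0.15)
  expect_equal(q1, 2.5, tolerance = 1e-9)
  expect_equal(q2, 1.5, tolerance = 1e-9)
  snaps <- seq(1100, 2000, by = 20)
  run <- run_distributional("segreRPE", prob13_task(2000),
    kappa = 0,
    n_reps = 60, snapshot_trials = snaps, seed = 52
  )
  term_V1 <- vapply(run$snapshots, function(s) mean(s$visited_V1[5, ]), 1)
  term_V2 <- vapply(run$snapshots, function(s) mean(s$visited_V2[5, ]), 1)
  expect_equal(mean(term_V1), q1, tolerance = 0.05)
  expect_equal(mean(term_V2), q2, tolerance = 0.05)
  # a different two-point distribution and rate quadruple
  q <- oracle_asym_fixed_point(c(0, 4), c(0.5, 0.5), 0.12, 0.04)
  t04 <- make_task(5, list(c(0, 0.5), c(4, 0.5)), 2000, 1)
  r04 <- run_distributional("segreRPE", t04,
    kappa = 0, rates = c(0.12, 0.04, 0.04, 0.12),
    n_reps = 60, snapshot_trials = snaps, seed = 53
  )
  expect_equal(
    mean(vapply(r04$snapshots, function(s) mean(s$visited_V1[5, ]), 1)),
    q, tolerance = 0.1
  )
})

test_that("deterministic reward drives both pathways to the same value", {
  t2 <- make_task(5, list(c(2, 1)), 200, 1)
  run <- run_distributional("segreRPE", t2, kappa = 0, n_reps = 20, seed = 54)
  expect_equal(as.vector(run$final_V1), rep(2, 100), tolerance = 1e-2)
  expect_equal(as.vector(run$final_V2), rep(2, 100), tolerance = 1e-2)
  # decay breaks the common fixed point
  t2l <- make_task(5, list(c(2, 1)), 2000, 1)
  rd <- run_distributional("segreRPE", t2l, kappa = 0.01, n_reps = 20, seed = 55)
  expect_gt(
    mean(rd$final_V1[5, ]) - mean(rd$final_V2[5, ]), 0.2
  )
})

test_that("integrated RPE grows pathway values unboundedly unless decayed", {
  run <- run_distributional("integRPE", prob13_task(2000),
    kappa = 0,
    n_reps = 30, snapshot_trials = c(200, 2000), seed = 56
  )
  s200 <- run$snapshots[["200"]]
  s2000 <- run$snapshots[["2000"]]
  expect_gt(max(abs(s2000$visited_V1)), max(abs(s200$visited_V1)))
  expect_gt(max(abs(s2000$visited_V2)), max(abs(s200$visited_V2)))
  # D1 drifts positive, D2 negative, while the sum stays near the mean reward
  expect_gt(mean(s2000$visited_V1), 0)
  expect_lt(mean(s2000$visited_V2), 0)
  sums <- s2000$visited_V1 + s2000$visited_V2
  expect_true(all(abs(sums) < 4))
  withdecay <- run_distributional("integRPE", prob13_task(2000),
    kappa = 0.01,
    n_reps = 30, snapshot_trials = c(200, 2000), seed = 57
  )
  expect_lt(
    max(abs(withdecay$snapshots[["2000"]]$visited_V1)),
    1.25 * max(abs(withdecay$snapshots[["200"]]$visited_V1))
  )
})

test_that("RPE patterns: ramp with integrated+decay, abrupt with segregated", {
  run_i <- run_distributional("integRPE", prob13_task(200),
    kappa = 0.01,
    n_reps = 100, seed = 58
  )
  di <- rowMeans(run_i$snapshots[[1]]$delta)
  expect_true(all(diff(di[2:5]) > 0)) # ramping toward reward
  expect_true(all(di[2:5] > 0))
  run_s <- run_distributional("segreRPE", prob13_task(200),
    kappa = 0,
    n_reps = 100, seed = 59
  )
  d1 <- rowMeans(run_s$snapshots[[1]]$delta1)
  expect_true(all(abs(d1[2:4]) < 0.1)) # near-zero intermediate RPE
  # and far smaller than the intermediate ramp of the decayed integrated RPE
  expect_lt(max(abs(d1[2:4])), 0.5 * min(di[2:4]))
})

test_that("distribution coding separates the algorithms", {
  t2 <- make_task(5, list(c(2, 1)), 200, 1)
  t13 <- prob13_task(200)
  withr::with_seed(60, {
    seg_f <- run_distributional("segreRPE", t2, 0, n_reps = 200)
    seg_v <- run_distributional("segreRPE", t13, 0, n_reps = 200)
    int_f <- run_distributional("integRPE", t2, 0.01, n_reps = 200)
    int_v <- run_distributional("integRPE", t13, 0.01, n_reps = 200)
  })
  ds <- distribution_coding_score(seg_f, seg_v, 0.05, seed = 61)
  di <- distribution_coding_score(int_f, int_v, 0.05, seed = 62)
  expect_equal(ds$n_pairs, rep(choose(200, 2), 5))
  expect_true(all(ds$cos_mean[1:4] > di$cos_mean[1:4]))
  expect_gt(ds$cos_mean[1], 0.8)
  expect_lt(abs(di$cos_mean[1]), 0.2)
})

test_that("coding score geometry behaves on degenerate inputs", {
  # identical difference vectors give cosine 1 with zero spread
  base <- run_distributional("segreRPE", make_task(2, list(c(1, 1)), 5, 1),
    n_reps = 10, seed = 63
  )
  shifted <- base
  shifted$snapshots[[1]]$visited_V1 <- base$snapshots[[1]]$visited_V1 + 1
  shifted$snapshots[[1]]$visited_V2 <- base$snapshots[[1]]$visited_V2 + 2
  out <- distribution_coding_score(shifted, base, noise_sd = 0)
  expect_equal(out$cos_mean, rep(1, 2))
  expect_equal(out$cos_sd, rep(0, 2))
  # isotropic random difference vectors have mean similarity near zero
  iso <- base
  withr::with_seed(64, {
    iso$snapshots[[1]]$visited_V1 <-
      base$snapshots[[1]]$visited_V1 + matrix(rnorm(20, sd = 100), 2)
    iso$snapshots[[1]]$visited_V2 <-
      base$snapshots[[1]]$visited_V2 + matrix(rnorm(20, sd = 100), 2)
  })
  out_iso <- distribution_coding_score(iso, base, noise_sd = 0, seed = 65)
  expect_lt(abs(mean(out_iso$cos_mean)), 0.25)
})

test_that("mean coding scores behave at the limits", {
  conds <- list(
    list(c(0, 1)), list(c(1, 0.5), c(3, 0.5)), list(c(2, 1))
  )
  withr::with_seed(66, {
    runs <- lapply(conds, function(s) {
      run_distributional("integRPE", make_task(5, s, 200, 1), 0.01, n_reps = 100)
    })
  })
  # values exactly proportional to the reward mean + vanishing noise: R2 -> 1
  ideal <- runs
  means <- c(0, 2, 2)
  for (k in 1:3) {
    v <- runs[[k]]$snapshots[[1]]$visited_V1
    ideal[[k]]$snapshots[[1]]$visited_V1 <- matrix(means[k], nrow(v), ncol(v))
    ideal[[k]]$snapshots[[1]]$visited_V2 <- matrix(0.5 * means[k], nrow(v), ncol(v))
  }
  low <- mean_coding_score(ideal, noise_sd = 1e-6, seed = 67)
  expect_true(all(low$r2 > 0.99))
  # values independent of condition carry no mean information
  null_runs <- runs
  for (k in 1:3) {
    null_runs[[k]]$snapshots[[1]]$visited_V1 <- runs[[1]]$snapshots[[1]]$visited_V1
    null_runs[[k]]$snapshots[[1]]$visited_V2 <- runs[[1]]$snapshots[[1]]$visited_V2
  }
  null <- mean_coding_score(null_runs, noise_sd = 0.05, seed = 68)
  expect_true(all(null$r2 < 0.05))
  # the averaged-univariate estimator is available and bounded by 1
  avg <- mean_coding_score(runs, 0.05, method = "average_univariate", seed = 69)
  expect_true(all(avg$r2 >= 0 & avg$r2 <= 1))
})

test_that("runs are reproducible and traces well-formed", {
  r1 <- run_distributional("integRPE", prob13_task(50), 0.01, n_reps = 5, seed = 70)
  r2 <- run_distributional("integRPE", prob13_task(50), 0.01, n_reps = 5, seed = 70)
  expect_identical(r1$final_V1, r2$final_V1)
  tr <- dist_run_trace(r1)
  expect_named(tr, c(
    "algorithm", "repetition", "trial_snapshot", "step",
    "V1", "V2", "reward", "delta"
  ))
  expect_equal(nrow(tr), 5 * 5)
  tr_s <- dist_run_trace(
    run_distributional("segreRPE", prob13_task(50), 0, n_reps = 5, seed = 71)
  )
  expect_true(all(c("delta1", "delta2") %in% names(tr_s)))
})
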