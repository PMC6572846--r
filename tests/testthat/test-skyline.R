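test_that("per-column clock rate rescales the per-site rate", {
  expect_equal(clock_rate(0.74e-9, 14494268, 7834), 1.369129e-6,
               tolerance = 1e-6)
  expect_equal(clock_rate(0.74e-9, 14494268, 7252), 1.479007e-6,
               tolerance = 1e-6)
  expect_equal(clock_rate(1e-9, 5000, 5000), 1e-9)
  expect_error(clock_rate(1e-9, 5000, 0), "positive")
})

test_that("clock calibration divides heights by the per-column rate", {
  tree <- ape::read.tree(text = "(A:0.001369,B:0.001369);")
  cal <- calibrate_tree(tree, clock_model(per_column_rate = 1.369e-6))
  expect_equal(max(node_times(cal)), 0.001369 / 1.369e-6)
  zero <- ape::read.tree(text = "(A:0,B:0);")
  expect_error(calibrate_tree(zero, clock_model(per_column_rate = 1e-6)),
               "zero height")
  skew <- ape::read.tree(text = "(A:1,B:2);")
  expect_error(calibrate_tree(skew, clock_model(per_column_rate = 1e-6)),
               "ultrametric")
})

test_that("calibrated TMRCA recovers simulation truth end to end", {
  set.seed(51)
  reps <- 60
  ratio <- numeric(reps)
  for (i in seq_len(reps)) {
    g <- simulate_genealogy(demographic_model(200), 50)
    mat <- drop_mutations(g, 5000)
    # matched clock: one mutation per column over the total length,
    # 1 year per generation
    clock <- clock_model(per_column_rate = 1 / sum(g$edge.length))
    cal <- calibrate_tree(upgma(p_distance(mat)), clock)
    ratio[i] <- max(node_times(cal)) / max(node_times(g))
  }
  expect_lt(abs(mean(ratio) - 1), 0.25)
})

test_that("coalescent intervals enumerate lineage counts and lengths", {
  two <- ape::read.tree(text = "(A:1,B:1);")
  ci <- coalescent_intervals(two)
  expect_equal(ci$k, 2L)
  expect_equal(ci$w, 1)
  three <- ape::read.tree(text = "((A:1,B:1):2,C:3);")
  ci3 <- coalescent_intervals(three)
  expect_equal(ci3$k, c(3L, 2L))
  expect_equal(ci3$w, c(1, 2))
  expect_equal(sum(ci3$w), 3)
})

test_that("classical skyline applies the method-of-moments formula", {
  two <- ape::read.tree(text = "(A:0.7,B:0.7);")
  est <- classical_skyline(two)
  expect_equal(est$N, 0.7)  # k(k-1)/2 = 1
  three <- ape::read.tree(text = "((A:1,B:1):2,C:3);")
  est3 <- classical_skyline(three)
  expect_equal(est3$N, c(3 * 2 * 1 / 2, 2 * 1 * 2 / 2))
  # time-unit equivariance
  scaled <- three
  scaled$edge.length <- scaled$edge.length * 10
  expect_equal(classical_skyline(scaled)$N, est3$N * 10)
})

test_that("classical skyline recovers constant population size", {
  set.seed(52)
  hms <- replicate(200, {
    g <- simulate_genealogy(demographic_model(10000), 200)
    ci <- coalescent_intervals(g)
    est <- classical_skyline(ci)
    # time-weighted harmonic mean of the skyline trajectory: an unbiased
    # summary, since it equals TMRCA / (2 (1 - 1/n))
    sum(ci$w) / sum(ci$w / est$N)
  })
  expect_lt(abs(mean(hms) - 10000) / 10000, 0.15)
})

test_that("classical skyline agrees with the reference implementation", {
  g <- simulate_genealogy(demographic_model(2000), 40, seed = 57)
  mine <- classical_skyline(g)
  ref <- ape::skyline(g)
  expect_equal(mine$N, as.numeric(ref$population.size), tolerance = 1e-9)
  expect_equal(mine$t_end, as.numeric(ref$time), tolerance = 1e-9)
})

test_that("single-group generalized skyline equals the constant-size MLE", {
  g <- simulate_genealogy(demographic_model(800), 30, seed = 53)
  ci <- coalescent_intervals(g)
  mle <- sum(ci$k * (ci$k - 1) * ci$w / 2) / (30 - 1)
  est <- generalized_skyline(ci, eps = Inf)
  expect_equal(nrow(est), 1L)
  expect_equal(est$N, mle)
})

test_that("AICc selects parsimonious groupings on constant-size data", {
  set.seed(54)
  picks <- replicate(100, {
    g <- simulate_genealogy(demographic_model(1000), 100)
    attr(generalized_skyline(g), "n_groups")
  })
  expect_gte(mean(picks == 1), 0.8)
})

test_that("AICc detects a strong two-epoch size change", {
  shift <- demographic_model(10000, data.frame(time = 500,
                                               size_factor = 0.1))
  set.seed(55)
  picks <- replicate(100, {
    g <- simulate_genealogy(shift, 100)
    attr(generalized_skyline(g), "n_groups")
  })
  expect_gte(mean(picks >= 2), 0.8)
})

test_that("detection rule flags bottleneck-and-recovery step functions", {
  rule <- detection_rule()
  # the three-epoch trajectory of the packaged model, in years at 25 y/gen
  true_traj <- make_skyline(t_start = c(0, 2000, 3000, 14500),
                            t_end = c(2000, 3000, 14500, 50000),
                            N = c(10000, 1120, 4009.6, 689.65))
  expect_true(detect_change(true_traj, rule))
  flat <- make_skyline(0, 50000, 5000)
  expect_false(detect_change(flat, rule))
  no_recovery <- make_skyline(t_start = c(0, 3000),
                              t_end = c(3000, 50000),
                              N = c(1120, 4009.6))
  expect_false(detect_change(no_recovery, rule))
  short <- make_skyline(0, 5000, 1000)
  expect_error(detect_change(short, rule), "outside")
  expect_error(detection_rule(fold = 1), "fold")
  expect_error(detection_rule(post = c(0, 2500)), "ordered")
})

test_that("effective sample size matches analytic expectations", {
  set.seed(56)
  iid <- rnorm(1e4)
  expect_lt(abs(ess(iid) - 1e4) / 1e4, 0.1)
  rho <- 0.9
  ar <- as.numeric(stats::arima.sim(list(ar = rho), 1e4))
  target <- 1e4 * (1 - rho) / (1 + rho)
  expect_lt(abs(ess(ar) - target) / target, 0.25)
  expect_warning(out <- ess(rep(1, 100)), "constant")
  expect_equal(out, 0)
  expect_error(ess(1:5), "at least 10")
})
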