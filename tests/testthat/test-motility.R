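test_that("MSD matches analytic values on degenerate tracks", {
  still <- make_track(rep(0, 20), rep(0, 20))
  msd <- msd_curve(still)
  expect_true(all(msd$msd == 0))

  # straight line, 1 um per 30-s frame: MSD(k) = k^2
  line <- make_track(0:120, rep(0, 121))
  msd <- msd_curve(line, max_lag = 3600)
  k <- msd$lag_s / 30
  expect_equal(msd$msd, k^2, tolerance = 1e-12)
})

test_that("MSD equals the brute-force double loop on random tracks", {
  set.seed(33)
  for (i in 1:50) {
    tr <- random_track(sample(10:80, 1))
    kmax <- nrow(tr) - 1
    msd <- msd_curve(tr, max_lag = kmax * 30)
    expect_equal(msd$msd, brute_force_msd(tr$x_um, tr$y_um, kmax),
                 tolerance = 1e-12)
  }
})

test_that("trajectory validation catches malformed input", {
  expect_error(msd_curve(make_track(1, 1)), "fewer than 2 frames")
  dup <- make_track(c(0, 1, 2), c(0, 0, 0))
  dup$frame[2] <- 0
  expect_error(msd_curve(dup), "duplicate frames")
  uneven <- make_track(c(0, 1, 2), c(0, 0, 0))
  uneven$time_s <- c(0, 30, 90)
  expect_error(msd_curve(uneven), "non-uniform")
})

test_that("log-log slope has its analytic limits and zero-MSD rule", {
  line <- make_track(0:120, rep(0, 121))
  msd <- msd_curve(line, max_lag = 900)
  expect_equal(loglog_slope(msd), 2, tolerance = 1e-9)
  # with 30-s frames, lags strictly below 150 s are {30, 60, 90, 120}
  expect_equal(sum(msd$lag_s > 0 & msd$lag_s < 150), 4)

  still <- make_track(rep(0, 20), rep(0, 20))
  expect_equal(loglog_slope(msd_curve(still)), 0)

  short <- make_track(c(0, 1), c(0, 0))
  expect_error(loglog_slope(msd_curve(short, max_lag = 30)),
               "insufficient lags")
})

test_that("Brownian tracks have unit mean slope", {
  pars <- motility_params(fraction_non_migrating = 1,
                          non_migrating_diffusivity = 0.01,
                          confinement_radius = Inf)
  sim <- simulate_trajectories(pars, 500, seed = 8)
  mot <- analyze_trajectories(sim$tracks)
  expect_gt(mean(mot$records$slope), 0.9)
  expect_lt(mean(mot$records$slope), 1.1)
})

test_that("classification threshold and tie-break behave as documented", {
  expect_identical(classify_motility(0.3), "non_migrating")
  expect_identical(classify_motility(1.2), "migrating")
  expect_identical(classify_motility(0.5), "migrating")
})

test_that("total displacement is path length, not net displacement", {
  line <- make_track(0:120, rep(0, 121))
  expect_equal(total_displacement(line), 120)
  still <- make_track(rep(0, 10), rep(0, 10))
  expect_equal(total_displacement(still), 0)
  outback <- make_track(c(0:5, 4:0), rep(0, 11))
  expect_equal(total_displacement(outback), 10)
})

test_that("slope is invariant to spatial scaling, rotation and translation", {
  set.seed(44)
  tr <- random_track(60)
  base <- loglog_slope(msd_curve(tr))
  for (s in c(0.1, 3, 250)) {
    sc <- tr; sc$x_um <- s * sc$x_um; sc$y_um <- s * sc$y_um
    expect_equal(loglog_slope(msd_curve(sc)), base, tolerance = 1e-12)
  }
  th <- 0.7
  rot <- tr
  rot$x_um <- cos(th) * tr$x_um - sin(th) * tr$y_um + 50
  rot$y_um <- sin(th) * tr$x_um + cos(th) * tr$y_um - 20
  expect_equal(loglog_slope(msd_curve(rot)), base, tolerance = 1e-12)
  expect_identical(classify_motility(loglog_slope(msd_curve(rot))),
                   classify_motility(base))
})

test_that("latent motility classes are recovered from well-separated mixtures", {
  sim <- simulate_trajectories(motility_params(fraction_non_migrating = 0.4),
                               400, seed = 15)
  mot <- analyze_trajectories(sim$tracks)
  truth <- sim$latent$class[match(mot$records$cell_id, sim$latent$cell_id)]
  expect_gte(mean(mot$records$class == truth), 0.95)
})

test_that("population summary reports fraction, Wilson CI and class contrasts", {
  sim <- simulate_trajectories(motility_params(fraction_non_migrating = 0),
                               30, seed = 2)
  mot <- analyze_trajectories(sim$tracks)
  pop <- population_summary(mot$records)
  expect_equal(pop$fraction_non_migrating, 0)
  expect_true(all(pop$ci >= 0 & pop$ci <= 1))

  # recovery of the mixture weight across seeded replicates
  errs <- vapply(1:20, function(s) {
    sm <- simulate_trajectories(motility_params(fraction_non_migrating = 0.3),
                                600, seed = 100 + s)
    m <- analyze_trajectories(sm$tracks)
    abs(population_summary(m$records)$fraction_non_migrating - 0.3)
  }, numeric(1))
  expect_lt(mean(errs), 0.05)

  # well-separated displacement distributions are highly significant
  sim <- simulate_trajectories(motility_params(fraction_non_migrating = 0.5),
                               200, seed = 77)
  mot <- analyze_trajectories(sim$tracks)
  cg <- compare_groups(mot$records$total_displacement, mot$records$class,
                       method = "mann_whitney")
  expect_lt(cg$p_value, 0.0005)
})

test_that("group comparisons behave across methods", {
  set.seed(6)
  # identical groups: permutation p is essentially 1
  v <- rep(rnorm(10), 2)
  g <- rep(c("a", "b"), each = 10)
  r <- rep(1:10, 2)
  cg <- compare_groups(v, g, replicate = r, method = "replicate_permutation",
                       n_perm = 1000, seed = 1)
  expect_gte(cg$p_value, 0.95)

  # 10-sigma separation is decisively detected by the t test
  x <- rnorm(30); y <- rnorm(30) + 10
  cg <- compare_groups(c(x, y), rep(c("a", "b"), each = 30),
                       method = "student_t")
  expect_lt(cg$p_value, 1e-6)

  expect_error(compare_groups(1:4, c("a", "a", "a", "b")), "degenerate")
  expect_error(compare_groups(1:4, rep("a", 4)), "exactly 2 groups")
  expect_error(compare_groups(1:4, rep(c("a", "b"), 2),
                              method = "replicate_permutation"),
               "replicate labels")
})

test_that("permutation p-values are uniform under an exchangeable null", {
  p_vals <- vapply(1:200, function(run) {
    set.seed(10000 + run)
    v <- rnorm(20)
    g <- rep(c("a", "b"), each = 10)
    r <- 1:20
    compare_groups(v, g, replicate = r, method = "replicate_permutation",
                   n_perm = 800, seed = run)$p_value
  }, numeric(1))
  ks <- suppressWarnings(ks.test(p_vals, "punif"))
  expect_gt(ks$p.value, 0.01)
})
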