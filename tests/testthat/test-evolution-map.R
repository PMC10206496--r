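test_that("iteration follows the clamped map and its analytic limits", {
  # zero profile: frequencies never move
  flat <- frequency_map(bias_profile(0, 0))
  expect_equal(iterate_map(flat, 0.3, 10), rep(0.3, 11))

  # uniformly positive bias drives fixation of the focal type
  up <- frequency_map(bias_profile(0.2, 0))        # B = 0.2 f(1-f)
  tr <- iterate_map(up, 0.1, 1000)
  expect_equal(tr[length(tr)], 1, tolerance = 1e-6)
  expect_true(all(tr >= 0 & tr <= 1))

  # sign-changing profile with interior zero at 0.5 converges there
  # B(f) = 0.2 f(1-f)(0.5-f) -> a = 0.1, b = -0.2
  coex <- frequency_map(bias_profile(0.1, -0.2))
  tr <- iterate_map(coex, 0.1, 1000)
  expect_equal(tr[length(tr)], 0.5, tolerance = 1e-6)

  expect_error(iterate_map(up, 1.1, 5), "\\[0, 1\\]")
})

test_that("iteration preserves ordering of initial conditions between fixed points", {
  map <- frequency_map(bias_profile(0.1, -0.2))
  starts <- seq(0.05, 0.45, by = 0.1)
  for (g in c(1, 5, 20)) {
    ends <- vapply(starts, function(f0) iterate_map(map, f0, g)[g + 1],
                   numeric(1))
    expect_true(all(diff(ends) >= 0))
  }
})

test_that("fixed points and stability match the analytic criterion", {
  # interior coexistence point: B = c f(1-f)(0.5-f), c = 0.2
  fps <- find_fixed_points(frequency_map(bias_profile(0.1, -0.2)))
  mid <- fps[abs(fps$location - 0.5) < 1e-12, ]
  expect_equal(nrow(mid), 1)
  expect_equal(mid$multiplier, 1 - 0.25 * 0.2, tolerance = 1e-12)
  expect_identical(mid$stability, "stable")
  expect_equal(c(mid$basin_lo, mid$basin_hi), c(0, 1))

  # monotone cheater profile: no interior point, 1 stable, 0 unstable
  fps <- find_fixed_points(frequency_map(bias_profile(0.2, 0)))
  expect_equal(fps$location, c(0, 1))
  expect_identical(fps$stability, c("unstable", "stable"))

  # degenerate zero profile: endpoints reported neutral
  fps <- find_fixed_points(frequency_map(bias_profile(0, 0)))
  expect_true(all(fps$stability == "neutral"))
  expect_true(attr(fps, "degenerate"))
})

test_that("analytic fixed points agree with grid-scan and iteration oracles", {
  set.seed(21)
  n_checked <- 0
  for (i in 1:100) {
    prof <- bias_profile(runif(1, -0.5, 0.5), runif(1, -0.5, 0.5))
    map <- frequency_map(prof)
    fps <- find_fixed_points(map)
    interior <- fps$location[fps$location > 0 & fps$location < 1]
    scanned <- scan_fixed_points(prof)
    expect_equal(length(interior), length(scanned))
    if (length(interior) > 0)
      expect_lt(max(abs(sort(interior) - sort(scanned))), 1e-9)
    # empirical stability of clearly hyperbolic interior points
    for (j in seq_along(interior)) {
      row <- fps[fps$location == interior[j], ]
      if (row$stability == "neutral" || abs(abs(row$multiplier) - 1) < 1e-3)
        next
      expect_identical(empirical_stability(map, row$location), row$stability)
      n_checked <- n_checked + 1
    }
  }
  expect_gt(n_checked, 10)  # the draw must actually exercise the comparison
})

test_that("behavior classification follows the sign of the corrected bias", {
  grid <- seq(0.1, 0.9, by = 0.1)
  cheat <- classify_behavior(bias_profile(0.2, 0), grid)
  expect_true(all(cheat$behavior == "cheater"))

  neutral <- classify_behavior(bias_profile(0, 0), grid)
  expect_true(all(neutral$behavior == "neutral"))

  # sign-changing profile: under-represented at low f, over at high f
  mix <- classify_behavior(bias_profile(-0.1, 0.2), grid)
  expect_true(all(mix$behavior[grid < 0.5] == "cooperator"))
  expect_true(all(mix$behavior[grid > 0.5] == "cheater"))

  # neutral band driven by confidence bounds covering zero
  b <- predict(bias_profile(0.05, 0), grid)
  cls <- classify_behavior(bias_profile(0.05, 0), grid,
                           lower = b - 0.2, upper = b + 0.2)
  expect_true(all(cls$behavior == "neutral"))
})
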