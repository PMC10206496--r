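count_row <- function(n_focal, n_partner, compartment, sample_id = "s1",
                      replicate = 1L) {
  data.frame(sample_id = sample_id, replicate = replicate,
             compartment = compartment, n_focal = n_focal,
             n_partner = n_partner, stage_focal = NA, stage_partner = NA,
             stringsAsFactors = FALSE)
}

test_that("fractions and raw biases follow their definitions", {
  expect_equal(mix_fraction(600, 400), 0.6)
  expect_equal(mix_fraction(0, 5000), 0)
  expect_equal(mix_fraction(1, 1), 0.5)
  expect_error(mix_fraction(0, 0, sample_id = "empty"), "empty")

  counts <- rbind(count_row(2500, 7500, "initial"),   # f = 0.25
                  count_row(4000, 6000, "spores"))    # fS = 0.40
  b <- compute_bias(counts, "spores")
  expect_equal(b$raw_bias, 0.15)
  expect_equal(b$f, 0.25)

  counts <- rbind(count_row(500, 500, "initial"), count_row(700, 300, "loners"))
  b <- compute_bias(counts, "loners")
  expect_equal(b$raw_bias, 0.2)
  expect_equal(b$compartment, "loners")

  same <- rbind(count_row(500, 500, "initial"), count_row(500, 500, "spores"))
  expect_equal(compute_bias(same, "spores")$raw_bias, 0)

  # missing initial partner
  orphan <- count_row(10, 10, "spores", sample_id = "sX")
  expect_error(compute_bias(rbind(count_row(5, 5, "initial"), orphan)),
               "pairing error")
})

test_that("bias is antisymmetric under focal/partner swap and bounded", {
  set.seed(1)
  for (i in 1:25) {
    n_i <- sample(50:5000, 1); n_o <- sample(50:5000, 1)
    k_i <- rbinom(1, n_i, runif(1, 0.05, 0.95))
    k_o <- rbinom(1, n_o, runif(1))
    counts <- rbind(count_row(k_i, n_i - k_i, "initial"),
                    count_row(k_o, n_o - k_o, "spores"))
    swapped <- counts
    swapped$n_focal <- counts$n_partner
    swapped$n_partner <- counts$n_focal
    b <- compute_bias(counts, "spores")
    bs <- compute_bias(swapped, "spores")
    expect_equal(bs$raw_bias, -b$raw_bias, tolerance = 1e-12)
    expect_gte(b$raw_bias, -b$f)
    expect_lte(b$raw_bias, 1 - b$f)
  }
})

test_that("constrained cubic fit recovers exact profiles and honours constraints", {
  f <- seq(0.1, 0.9, by = 0.1)
  p <- fit_constrained_cubic(f, f * (1 - f) * (1 - 2 * f))
  expect_equal(p$a, 1, tolerance = 1e-10)
  expect_equal(p$b, -2, tolerance = 1e-10)
  expect_lte(p$rss, 1e-10)
  expect_equal(predict(p, 0), 0)
  expect_equal(predict(p, 1), 0)

  p0 <- fit_constrained_cubic(f, rep(0, length(f)))
  expect_equal(p0$a, 0)
  expect_equal(p0$b, 0)

  expect_error(fit_constrained_cubic(c(0.5, 0.5, 0, 1), c(1, 1, 0, 0)),
               "insufficient data")
})

test_that("least-squares fit agrees with an independent grid search", {
  set.seed(7)
  for (i in 1:5) {
    a0 <- runif(1, -1, 1); b0 <- runif(1, -1, 1)
    f <- runif(12, 0.05, 0.95)
    bias <- f * (1 - f) * (a0 + b0 * f) + rnorm(12, sd = 0.01)
    p <- fit_constrained_cubic(f, bias)
    g <- grid_fit_cubic(f, bias, round(p$a, 1), round(p$b, 1))
    rss_at <- function(a, b) sum((bias - f * (1 - f) * (a + b * f))^2)
    # the analytic solution is at least as good as the best of 10^6 grid
    # candidates, and the grid argmin sits in the same (quantised) RSS valley
    expect_lte(p$rss, rss_at(g["a"], g["b"]) + 1e-12)
    # quantisation bound: ||theta_grid - theta_ls|| <= step *
    # sqrt(cond(X'X) / 2); the correlated basis makes the valley elongated
    X <- cbind(f * (1 - f), f^2 * (1 - f))
    ev <- eigen(crossprod(X), only.values = TRUE)$values
    bound <- 1e-3 * sqrt(max(ev) / min(ev) / 2) + 1e-9
    expect_lt(abs(p$a - g["a"]), bound)
    expect_lt(abs(p$b - g["b"]), bound)
  }
})

test_that("label-bias correction subtracts the profile at the measured f", {
  L <- bias_profile(a = 0.16, b = 0)           # L(0.5) = 0.04
  tbl <- data.frame(f = 0.5, raw_bias = 0.10)
  expect_equal(correct_bias(tbl, L)$corrected_bias, 0.06)
  zero <- bias_profile(0, 0)
  expect_equal(correct_bias(tbl, zero)$corrected_bias, tbl$raw_bias)
})

test_that("correction recovers zero true bias end-to-end", {
  # isogenic co-cultures measured with a known admissible label bias
  L <- bias_profile(a = 0.3, b = 0)            # L(f) = 0.3 f(1-f)
  validate_label_bias(L)
  freqs <- seq(0.1, 0.9, by = 0.1)
  rows <- lapply(seq_along(freqs), function(i) {
    rbind(
      sample_mix_counts(freqs[i], 1e4, seed = 1000 + i,
                        sample_id = sprintf("f%02d", i),
                        compartment = "initial"),
      sample_mix_counts(freqs[i], 1e4, label_bias = L, seed = 2000 + i,
                        sample_id = sprintf("f%02d", i),
                        compartment = "spores")
    )
  })
  counts <- do.call(rbind, rows)
  corrected <- compute_bias(counts, "spores", label_bias = L)
  expect_true(all(abs(corrected$corrected_bias) < 0.02))
})

test_that("unbiasedness of the correction over replicated experiments", {
  L <- bias_profile(a = 0.25, b = -0.2)
  validate_label_bias(L)
  set.seed(0)
  seeds <- sample.int(1e6, 200)
  resid <- vapply(seq_along(seeds), function(i) {
    f <- 0.5
    ini <- sample_mix_counts(f, 5000, seed = seeds[i], compartment = "initial")
    spo <- sample_mix_counts(f, 5000, label_bias = L,
                             seed = seeds[i] + 1e6, compartment = "spores")
    b <- compute_bias(rbind(ini, spo), "spores", label_bias = L)
    b$corrected_bias
  }, numeric(1))
  expect_lt(abs(mean(resid)), 2 * sd(resid) / sqrt(length(resid)))
})

test_that("label swap check accepts mirrored profiles and rejects others", {
  p <- bias_profile(a = 0.4, b = -0.5)
  # exact mirror: B_BA(f) = -B_AB(1-f) -> a' = -(a+b), b' = b
  mirror <- bias_profile(a = -(p$a + p$b), b = p$b)
  expect_true(label_swap_check(p, mirror, tolerance = 1e-12))
  expect_false(label_swap_check(p, p, tolerance = 0.01))
  expect_gt(attr(label_swap_check(p, p, tolerance = 0.01), "max_deviation"), 0.01)
})

test_that("independently fitted label-swapped experiments mirror each other", {
  # true bias of A over B at frequency f of A
  truth <- bias_profile(a = 0.2, b = -0.15)
  validate_label_bias(truth)
  freqs <- seq(0.1, 0.9, by = 0.1)
  fit_experiment <- function(profile, seed_base) {
    rows <- lapply(seq_along(freqs), function(i) rbind(
      sample_mix_counts(freqs[i], 1e4, seed = seed_base + i,
                        sample_id = sprintf("f%02d", i), compartment = "initial"),
      sample_mix_counts(freqs[i], 1e4, label_bias = profile,
                        seed = seed_base + 100 + i,
                        sample_id = sprintf("f%02d", i), compartment = "spores")
    ))
    b <- compute_bias(do.call(rbind, rows), "spores")
    fit_constrained_cubic(b$f, b$raw_bias)
  }
  swapped_truth <- bias_profile(a = -(truth$a + truth$b), b = truth$b)
  p_ab <- fit_experiment(truth, 3000)
  p_ba <- fit_experiment(swapped_truth, 4000)
  expect_true(label_swap_check(p_ab, p_ba, tolerance = 0.03))
})

test_that("bias association reports Pearson r with bootstrap interval", {
  x <- seq(-0.2, 0.2, length.out = 10)
  res <- bias_association(x, -2 * x, n_boot = 200, seed = 1)
  expect_equal(res$r, -1, tolerance = 1e-12)

  set.seed(5)
  res0 <- bias_association(rnorm(1000), rnorm(1000), n_boot = 200, seed = 2)
  expect_lt(abs(res0$r), 0.1)
  expect_true(res0$ci[1] <= res0$r && res0$r <= res0$ci[2])

  expect_error(bias_association(c(1, 1, 1), c(1, 2, 3)), "degenerate")
  expect_error(bias_association(c(1, 2), c(1, 2)), "at least 3")
})

test_that("go-or-grow sweep yields negatively correlated spore and loner biases", {
  phis <- seq(0.1, 0.9, length.out = 20)
  sims <- lapply(seq_along(phis), function(i) {
    pars <- go_or_grow_params(
      0.5, 1e4,
      focal = motility_params(fraction_non_migrating = phis[i]),
      partner = motility_params(fraction_non_migrating = 0.1),
      loner_prob_non_migrating = 0.8, loner_prob_migrating = 0.1,
      seed = 500 + i)
    b_s <- compute_bias(simulate_chimera(pars)$counts, "spores")$raw_bias
    b_l <- compute_bias(simulate_chimera(pars)$counts, "loners")$raw_bias
    c(spore = b_s, loner = b_l)
  })
  m <- do.call(rbind, sims)
  res <- bias_association(m[, "loner"], m[, "spore"], n_boot = 200, seed = 3)
  expect_lt(res$r, 0)
})
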