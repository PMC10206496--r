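# Independent oracles and fixture builders used across the suite.

# O(n^2) double-loop time-averaged MSD, deliberately naive.
brute_force_msd <- function(x, y, kmax) {
  n <- length(x)
  vapply(seq_len(kmax), function(k) {
    acc <- 0
    for (i in seq_len(n - k))
      acc <- acc + (x[i + k] - x[i])^2 + (y[i + k] - y[i])^2
    acc / (n - k)
  }, numeric(1))
}

# random planar track in the canonical trajectory dialect
random_track <- function(n_frames, dt = 30, cell_id = "cell", sd = 2) {
  data.frame(
    cell_id = cell_id,
    frame = 0:(n_frames - 1),
    time_s = (0:(n_frames - 1)) * dt,
    x_um = cumsum(rnorm(n_frames, sd = sd)),
    y_um = cumsum(rnorm(n_frames, sd = sd)),
    stringsAsFactors = FALSE
  )
}

make_track <- function(x, y, dt = 30, cell_id = "cell") {
  data.frame(cell_id = cell_id, frame = seq_along(x) - 1,
             time_s = (seq_along(x) - 1) * dt, x_um = x, y_um = y,
             stringsAsFactors = FALSE)
}

# grid-search least squares for the constrained cubic, independent of lm
grid_fit_cubic <- function(f, bias, centre_a, centre_b, half = 0.5,
                           step = 1e-3) {
  a_grid <- seq(centre_a - half, centre_a + half, by = step)
  b_grid <- seq(centre_b - half, centre_b + half, by = step)
  x1 <- f * (1 - f); x2 <- f^2 * (1 - f)
  s11 <- sum(x1^2); s22 <- sum(x2^2); s12 <- sum(x1 * x2)
  s1y <- sum(x1 * bias); s2y <- sum(x2 * bias)
  A <- matrix(rep(a_grid, times = length(b_grid)), ncol = length(b_grid))
  B <- matrix(rep(b_grid, each = length(a_grid)), ncol = length(b_grid))
  rss <- A^2 * s11 + B^2 * s22 + 2 * A * B * s12 - 2 * A * s1y - 2 * B * s2y
  i <- which.min(rss)
  c(a = A[i], b = B[i])
}

# brute-force interior fixed points of f' = f + B(f): sign changes of B on a
# dense grid, refined by uniroot
scan_fixed_points <- function(profile, n_grid = 1e5) {
  f <- seq(0, 1, length.out = n_grid)
  Bf <- predict(profile, f)
  interior <- which(diff(sign(Bf[-c(1, n_grid)])) != 0) + 1
  vapply(interior, function(i) {
    stats::uniroot(function(z) predict(profile, z),
                   c(f[i], f[i + 1]), tol = 1e-12)$root
  }, numeric(1))
}

# empirical stability: does iteration started just off the fixed point
# return to it or escape?
empirical_stability <- function(map, fstar, delta = 1e-3, n_iter = 1000) {
  verdict <- function(f0) {
    f <- iterate_map(map, clamp(f0), n_iter)
    abs(f[length(f)] - fstar) < delta / 2
  }
  below <- if (fstar - delta >= 0) verdict(fstar - delta) else TRUE
  above <- if (fstar + delta <= 1) verdict(fstar + delta) else TRUE
  if (below && above) "stable" else "unstable"
}
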