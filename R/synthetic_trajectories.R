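#' Parameters of the two-class motility mixture
#'
#' Describes a population in which a fraction of cells is near-stationary
#' ("non-migrating") while the rest crawl persistently ("migrating"), the
#' bimodal motility structure seen in vegetative amoebae. Defaults reproduce
#' the sampling design of the motility assay: positions recorded every 30 s
#' over 1 h.
#'
#' @param fraction_non_migrating probability that a cell belongs to the
#'   non-migrating class, in `[0, 1]`; varies with nominal growth phase.
#' @param migrating_speed crawling speed of migrating cells (um/s, > 0).
#' @param persistence_time directional persistence time of migrating cells
#'   (s, > 0; `Inf` gives straight ballistic tracks).
#' @param non_migrating_diffusivity diffusivity of the non-migrating jitter
#'   (um^2/s, >= 0; 0 gives perfectly stationary cells).
#' @param confinement_radius per-coordinate stationary spread of the
#'   non-migrating jitter (um). Non-migrating cells barely move, so their
#'   jitter is modelled as position fluctuations confined around an anchor
#'   point (Ornstein-Uhlenbeck process with relaxation time
#'   radius^2 / diffusivity), giving a near-flat MSD at the sampled lags.
#'   `Inf` removes the confinement and yields a pure Brownian walk.
#' @param frame_interval imaging interval (s, default 30).
#' @param duration track duration (s, default 3600).
#' @return an object of class `motility_params`.
#' @export
motility_params <- function(fraction_non_migrating = 0.3,
                            migrating_speed = 0.1,
                            persistence_time = 300,
                            non_migrating_diffusivity = 0.01,
                            confinement_radius = 0.5,
                            frame_interval = 30,
                            duration = 3600) {
  p <- list(fraction_non_migrating = fraction_non_migrating,
            migrating_speed = migrating_speed,
            persistence_time = persistence_time,
            non_migrating_diffusivity = non_migrating_diffusivity,
            confinement_radius = confinement_radius,
            frame_interval = frame_interval,
            duration = duration)
  validate_motility_params(p)
  structure(p, class = "motility_params")
}

validate_motility_params <- function(p) {
  if (p$fraction_non_migrating < 0 || p$fraction_non_migrating > 1)
    stop("fraction_non_migrating must lie in [0, 1]")
  if (p$migrating_speed <= 0) stop("migrating_speed must be positive")
  if (p$persistence_time <= 0) stop("persistence_time must be positive")
  if (p$non_migrating_diffusivity < 0)
    stop("non_migrating_diffusivity must be non-negative")
  if (p$confinement_radius <= 0) stop("confinement_radius must be positive")
  if (p$frame_interval <= 0) stop("frame_interval must be positive")
  if (p$duration <= 0) stop("duration must be positive")
  invisible(TRUE)
}

#' Simulate two-class single-cell trajectories
#'
#' Each cell is assigned to the non-migrating class with probability
#' `fraction_non_migrating`. Migrating cells follow a persistent random walk:
#' constant speed with a heading angle that diffuses with angular variance
#' `2 * dt / persistence_time` per step, so direction decorrelates over the
#' persistence time (short-lag MSD ~ ballistic, long-lag ~ diffusive).
#' Non-migrating cells jitter around their anchor point (see
#' [motility_params]). Latent class labels are retained so classifier
#' recovery can be tested.
#'
#' @param params a [motility_params] object.
#' @param n_cells number of cells (>= 1).
#' @param seed integer seed; output is bit-reproducible given the seed.
#' @param cell_prefix prefix used to build cell ids.
#' @return a list of class `trajectory_sim` with elements
#'   \describe{
#'     \item{tracks}{data.frame `cell_id, frame, time_s, x_um, y_um`, one row
#'       per cell per frame, frames 0-based.}
#'     \item{latent}{data.frame `cell_id, class` with the latent class of
#'       every cell (`migrating` / `non_migrating`).}
#'     \item{params, seed}{the inputs, for provenance.}
#'   }
#' @export
simulate_trajectories <- function(params, n_cells, seed, cell_prefix = "cell") {
  stopifnot(inherits(params, "motility_params"), n_cells >= 1)
  validate_motility_params(params)
  set.seed(seed)
  dt <- params$frame_interval
  n_steps <- as.integer(round(params$duration / dt))
  if (n_steps < 1) stop("duration must cover at least one frame interval")

  classes <- ifelse(stats::runif(n_cells) < params$fraction_non_migrating,
                    "non_migrating", "migrating")
  X <- matrix(0, n_cells, n_steps + 1)
  Y <- matrix(0, n_cells, n_steps + 1)

  mig <- which(classes == "migrating")
  if (length(mig) > 0) {
    m <- length(mig)
    sd_ang <- if (is.finite(params$persistence_time))
      sqrt(2 * dt / params$persistence_time) else 0
    theta0 <- stats::runif(m, 0, 2 * pi)
    dtheta <- matrix(stats::rnorm(m * n_steps, sd = sd_ang), m, n_steps)
    # heading during step j: initial heading plus accumulated turns
    theta <- theta0 + t(apply(dtheta, 1, cumsum))
    step <- params$migrating_speed * dt
    X[mig, -1] <- t(apply(step * cos(theta), 1, cumsum))
    Y[mig, -1] <- t(apply(step * sin(theta), 1, cumsum))
  }

  nm <- which(classes == "non_migrating")
  if (length(nm) > 0 && params$non_migrating_diffusivity > 0) {
    k <- length(nm)
    D <- params$non_migrating_diffusivity
    r <- params$confinement_radius
    if (is.infinite(r)) {
      sd_step <- sqrt(2 * D * dt)
      X[nm, -1] <- t(apply(matrix(stats::rnorm(k * n_steps, sd = sd_step),
                                  k, n_steps), 1, cumsum))
      Y[nm, -1] <- t(apply(matrix(stats::rnorm(k * n_steps, sd = sd_step),
                                  k, n_steps), 1, cumsum))
    } else {
      # exact OU transition around the anchor (origin)
      tau <- r^2 / D
      rho <- exp(-dt / tau)
      sd_st <- r * sqrt(1 - rho^2)
      for (j in seq_len(n_steps)) {
        X[nm, j + 1] <- X[nm, j] * rho + stats::rnorm(k, sd = sd_st)
        Y[nm, j + 1] <- Y[nm, j] * rho + stats::rnorm(k, sd = sd_st)
      }
    }
  }

  ids <- sprintf("%s_%05d", cell_prefix, seq_len(n_cells))
  frames <- 0:n_steps
  tracks <- data.frame(
    cell_id = rep(ids, each = n_steps + 1),
    frame = rep(frames, times = n_cells),
    time_s = rep(frames * dt, times = n_cells),
    x_um = as.vector(t(X)),
    y_um = as.vector(t(Y)),
    stringsAsFactors = FALSE
  )
  structure(
    list(tracks = tracks,
         latent = data.frame(cell_id = ids, class = classes,
                             stringsAsFactors = FALSE),
         params = params, seed = as.integer(seed)),
    class = "trajectory_sim"
  )
}
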