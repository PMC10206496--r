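#' Validate and normalise a trajectory table
#'
#' Accepts a table of tracked cell positions and maps it onto the canonical
#' columns `cell_id, frame, time_s, x_um, y_um`. Extra columns are tolerated
#' and dropped; a `mapping` translates tracker-exported dialects (e.g.
#' `list(cell_id = "particle", x_um = "x", y_um = "y")`).
#'
#' @param tracks data.frame of positions.
#' @param mapping optional named list mapping canonical column names to the
#'   column names present in `tracks`.
#' @return data.frame with the five canonical columns, ordered by cell and
#'   frame.
#' @export
as_trajectories <- function(tracks, mapping = NULL) {
  canon <- c("cell_id", "frame", "time_s", "x_um", "y_um")
  if (!is.null(mapping)) {
    for (nm in names(mapping)) {
      if (!mapping[[nm]] %in% names(tracks))
        stop(sprintf("mapped column '%s' not found in trajectory table",
                     mapping[[nm]]))
      names(tracks)[names(tracks) == mapping[[nm]]] <- nm
    }
  }
  miss <- setdiff(canon, names(tracks))
  if (length(miss) > 0)
    stop("trajectory table lacks columns: ", paste(miss, collapse = ", "))
  tracks <- tracks[canon]
  tracks[order(tracks$cell_id, tracks$frame), , drop = FALSE]
}

validate_trajectory <- function(traj, rel_tol = 1e-6) {
  if (nrow(traj) < 2)
    stop(sprintf("insufficient trajectory: cell '%s' has fewer than 2 frames",
                 traj$cell_id[1]))
  if (anyDuplicated(traj$frame))
    stop(sprintf("duplicate frames in trajectory of cell '%s'",
                 traj$cell_id[1]))
  dtimes <- diff(traj$time_s)
  dt <- dtimes[1]
  if (dt <= 0 || any(abs(dtimes - dt) > rel_tol * dt))
    stop(sprintf("non-uniform frame interval in trajectory of cell '%s'",
                 traj$cell_id[1]))
  dt
}

#' Per-cell time-averaged mean squared displacement
#'
#' For each integer lag k, the MSD is the mean squared Euclidean
#' displacement over frame pairs (i, i + k). Overlapping pairs (the standard
#' time-averaged per-trajectory estimator) are the default; non-overlapping
#' pairs are available for comparison.
#'
#' @param traj single-cell trajectory (canonical columns, see
#'   [as_trajectories]).
#' @param max_lag largest lag (s) to include; defaults to a quarter of the
#'   track duration (estimator variance control).
#' @param overlapping use overlapping displacement pairs (default) or
#'   disjoint pairs.
#' @return data.frame `lag_s, msd` (um^2); lag 0 is not included.
#' @export
msd_curve <- function(traj, max_lag = NULL, overlapping = TRUE) {
  dt <- validate_trajectory(traj)
  n <- nrow(traj)
  duration <- traj$time_s[n] - traj$time_s[1]
  if (is.null(max_lag)) max_lag <- duration / 4
  if (max_lag < dt) stop("max_lag must cover at least one frame interval")
  kmax <- min(n - 1, floor(max_lag / dt + 1e-9))
  x <- traj$x_um; y <- traj$y_um
  msd <- vapply(seq_len(kmax), function(k) {
    if (overlapping) {
      i <- seq_len(n - k)
    } else {
      i <- seq(1, n - k, by = k)
    }
    mean((x[i + k] - x[i])^2 + (y[i + k] - y[i])^2)
  }, numeric(1))
  data.frame(lag_s = seq_len(kmax) * dt, msd = msd)
}

#' Short-lag log-log slope of an MSD curve
#'
#' Ordinary least-squares slope of log(MSD) versus log(lag) over lags
#' strictly below `lag_cutoff` (lag 0 excluded); with 30-s frames and the
#' default 150-s cutoff this uses lags \{30, 60, 90, 120\} s. A slope near 2
#' indicates ballistic crawling, near 1 diffusion, near 0 a stationary cell.
#' Trajectories with a zero MSD among the usable lags barely moved at all
#' and are assigned slope 0 rather than failing on log(0).
#'
#' @param msd data.frame `lag_s, msd` from [msd_curve].
#' @param lag_cutoff upper lag bound in seconds (exclusive; default 150).
#' @return the slope (dimensionless).
#' @export
loglog_slope <- function(msd, lag_cutoff = 150) {
  use <- msd$lag_s > 0 & msd$lag_s < lag_cutoff
  if (sum(use) < 2)
    stop("insufficient lags: need at least 2 usable lags below the cutoff")
  m <- msd$msd[use]
  if (any(m == 0)) return(0)
  lt <- log(msd$lag_s[use])
  lm_fit <- stats::lm.fit(cbind(1, lt), log(m))
  unname(lm_fit$coefficients[2])
}

#' Classify a cell by its MSD slope
#'
#' Cells are partitioned into the two modes of the slope distribution at a
#' threshold (default 0.5): `non_migrating` below the threshold, `migrating`
#' at or above it (ties go to migrating).
#'
#' @param slope numeric vector of log-log MSD slopes.
#' @param threshold classification threshold (default 0.5).
#' @return character vector of `"migrating"` / `"non_migrating"`.
#' @export
classify_motility <- function(slope, threshold = 0.5) {
  ifelse(slope < threshold, "non_migrating", "migrating")
}

#' Total displacement along a trajectory
#'
#' Sum of Euclidean step lengths between successive frames (path length, not
#' net displacement).
#'
#' @param traj single-cell trajectory (canonical columns).
#' @return total displacement in um.
#' @export
total_displacement <- function(traj) {
  validate_trajectory(traj)
  sum(sqrt(diff(traj$x_um)^2 + diff(traj$y_um)^2))
}

#' Per-cell motility records for a trajectory table
#'
#' Runs the full single-cell pipeline — time-averaged MSD, short-lag log-log
#' slope, bimodal classification, total displacement — for every cell in a
#' trajectory table.
#'
#' @param tracks trajectory table (any dialect [as_trajectories] accepts).
#' @param lag_cutoff slope fit window upper bound in s (exclusive).
#' @param threshold classification threshold on the slope.
#' @param max_lag largest lag stored in the MSD curves (s); default a quarter
#'   of the track duration. The fit window is independent of this cap.
#' @param overlapping overlapping displacement pairs in the MSD (default).
#' @param mapping optional column mapping, see [as_trajectories].
#' @return list with
#'   \describe{
#'     \item{records}{data.frame `cell_id, slope, class, total_displacement,
#'       n_frames`.}
#'     \item{msd}{long data.frame `cell_id, lag_s, msd`.}
#'   }
#' @export
analyze_trajectories <- function(tracks, lag_cutoff = 150, threshold = 0.5,
                                 max_lag = NULL, overlapping = TRUE,
                                 mapping = NULL) {
  tracks <- as_trajectories(tracks, mapping = mapping)
  per_cell <- split(tracks, tracks$cell_id)
  msd_list <- vector("list", length(per_cell))
  records <- data.frame(
    cell_id = names(per_cell),
    slope = NA_real_, class = NA_character_,
    total_displacement = NA_real_,
    n_frames = vapply(per_cell, nrow, integer(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  # fit window must be covered even when the stored curve is capped shorter
  for (i in seq_along(per_cell)) {
    traj <- per_cell[[i]]
    dt <- validate_trajectory(traj)
    cap <- max_lag %||% ((traj$time_s[nrow(traj)] - traj$time_s[1]) / 4)
    msd <- msd_curve(traj, max_lag = max(cap, lag_cutoff),
                     overlapping = overlapping)
    records$slope[i] <- loglog_slope(msd, lag_cutoff = lag_cutoff)
    records$total_displacement[i] <- total_displacement(traj)
    keep <- msd$lag_s <= cap + 1e-9
    msd_list[[i]] <- data.frame(cell_id = records$cell_id[i],
                                msd[keep, , drop = FALSE],
                                stringsAsFactors = FALSE)
  }
  records$class <- classify_motility(records$slope, threshold = threshold)
  list(records = records,
       msd = do.call(rbind, c(msd_list, list(make.row.names = FALSE))))
}

#' Population-level motility summary
#'
#' Fraction of non-migrating cells with a Wilson binomial confidence
#' interval, plus per-class displacement summaries.
#'
#' @param records `records` data.frame from [analyze_trajectories].
#' @param conf confidence level for the Wilson interval.
#' @return list with `n`, `n_non_migrating`, `fraction_non_migrating`,
#'   `ci` (Wilson bounds), and `by_class` (per-class n, mean / median / sd of
#'   total displacement).
#' @export
population_summary <- function(records, conf = 0.95) {
  stopifnot(nrow(records) >= 1)
  n <- nrow(records)
  k <- sum(records$class == "non_migrating")
  by_class <- do.call(rbind, lapply(split(records, records$class), function(d)
    data.frame(class = d$class[1], n = nrow(d),
               mean_displacement = mean(d$total_displacement),
               median_displacement = stats::median(d$total_displacement),
               sd_displacement = stats::sd(d$total_displacement),
               stringsAsFactors = FALSE)))
  row.names(by_class) <- NULL
  list(n = n, n_non_migrating = k, fraction_non_migrating = k / n,
       ci = wilson_ci(k, n, conf = conf), by_class = by_class)
}

#' Two-group comparison with parametric, rank or replicate-permutation tests
#'
#' Thin contracts over the two-sample Student t test and Mann-Whitney U
#' test, plus a replicate-stratified permutation test for designs where
#' replicates, not cells, are the exchangeable units: the test statistic is
#' the difference between group means of replicate means, and group labels
#' are permuted at the replicate level.
#'
#' @param values numeric measurements.
#' @param group group label per measurement (exactly 2 groups).
#' @param replicate replicate label per measurement (required for the
#'   permutation method).
#' @param method `"student_t"`, `"mann_whitney"` or
#'   `"replicate_permutation"`.
#' @param n_perm number of label permutations (default 5000).
#' @param seed seed for the permutation draw.
#' @return list with `method`, `statistic`, `p_value`, `estimate`
#'   (difference of group means, first minus second group level), and `n`
#'   per group.
#' @export
compare_groups <- function(values, group, replicate = NULL,
                           method = c("student_t", "mann_whitney",
                                      "replicate_permutation"),
                           n_perm = 5000, seed = NULL) {
  method <- match.arg(method)
  stopifnot(length(values) == length(group))
  group <- as.character(group)
  lev <- unique(group)
  if (length(lev) != 2) stop("exactly 2 groups are required")
  v1 <- values[group == lev[1]]
  v2 <- values[group == lev[2]]
  if (length(v1) < 2 || length(v2) < 2)
    stop("degenerate groups: each group needs at least 2 values")
  est <- mean(v1) - mean(v2)
  ns <- stats::setNames(c(length(v1), length(v2)), lev)

  if (method == "student_t") {
    ht <- stats::t.test(v1, v2)
    return(list(method = method, statistic = unname(ht$statistic),
                p_value = ht$p.value, estimate = est, n = ns))
  }
  if (method == "mann_whitney") {
    ht <- stats::wilcox.test(v1, v2, exact = FALSE)
    return(list(method = method, statistic = unname(ht$statistic),
                p_value = ht$p.value, estimate = est, n = ns))
  }
  # replicate-stratified permutation
  if (is.null(replicate))
    stop("replicate labels are required for the permutation method")
  stopifnot(length(replicate) == length(values))
  rep_means <- tapply(values, list(group, as.character(replicate)), mean)
  rm_group <- rep(rownames(rep_means), times = ncol(rep_means))
  rm_value <- as.vector(rep_means)
  keep <- !is.na(rm_value)
  rm_group <- rm_group[keep]; rm_value <- rm_value[keep]
  if (sum(rm_group == lev[1]) < 1 || sum(rm_group == lev[2]) < 1)
    stop("degenerate groups: each group needs at least one replicate")
  obs <- mean(rm_value[rm_group == lev[1]]) -
    mean(rm_value[rm_group == lev[2]])
  if (!is.null(seed)) set.seed(seed)
  n1 <- sum(rm_group == lev[1])
  perm <- vapply(seq_len(n_perm), function(i) {
    idx <- sample.int(length(rm_value), n1)
    mean(rm_value[idx]) - mean(rm_value[-idx])
  }, numeric(1))
  p <- (1 + sum(abs(perm) >= abs(obs) - 1e-12)) / (n_perm + 1)
  list(method = method, statistic = obs, p_value = p, estimate = est, n = ns)
}
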