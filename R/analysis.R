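#' Mean distance of the wheeled robot from the light
#'
#' Time-average, over a window, of the minimal-image Euclidean distance
#' from the robot center to the light in the periodic arena.
#'
#' @param traj Trajectory data frame with columns `t`, `x`, `y` (as
#'   produced by [run_experiment()]).
#' @param window `c(from, to)` in time-units; `NULL` uses the whole
#'   trajectory.
#' @param light Light position.
#' @param width Arena period.
#' @return Mean distance (arena units).
#' @export
mean_distance_to_light <- function(traj, window = NULL, light = c(0, 0),
                                   width = 4) {
  keep <- if (is.null(window)) rep(TRUE, nrow(traj)) else
    traj$t >= window[1] & traj$t <= window[2]
  if (!any(keep)) stop("empty evaluation window")
  dx <- min_image(traj$x[keep] - light[1], width)
  dy <- min_image(traj$y[keep] - light[2], width)
  mean(sqrt(dx^2 + dy^2))
}

#' Lattice region-ID sequence of a sensorimotor trajectory
#'
#' Subdivides the normalized sensorimotor space into
#' `bins_per_dim^D` hypercubes (half-open bins, top bin closed so 1.0
#' falls in the last bin) and recodes the trajectory as the sequence of
#' hypercubes visited, numbered in order of first visitation starting
#' at 0.
#'
#' @param sm Matrix (or data frame) of normalized sensorimotor states, one
#'   row per time point.
#' @param bins_per_dim Bins per dimension.
#' @return Integer vector of region IDs (`0 .. K-1`), one per row.
#' @export
region_id_sequence <- function(sm, bins_per_dim = 10) {
  sm <- as.matrix(sm)
  B <- pmin(pmax(floor(sm * bins_per_dim), 0), bins_per_dim - 1)
  key <- as.vector(B %*% bins_per_dim^(seq_len(ncol(sm)) - 1))
  match(key, unique(key)) - 1L
}

#' Two-dimensional PCA projection of pooled sensorimotor states
#'
#' Centers the pooled states and projects them onto their top two
#' principal components, reporting explained-variance ratios.  Fitting on
#' the pooled states places trajectories from different trials into one
#' common projection space.
#'
#' @param states Matrix of states (one row per time point), or a list of
#'   such matrices which are pooled by row-binding.
#' @return A list with `scores` (n x 2 matrix), `var_explained`
#'   (per-component variance ratios), `rotation` and `center`.
#' @export
pca_projection <- function(states) {
  if (is.list(states) && !is.data.frame(states)) states <- do.call(rbind, states)
  states <- as.matrix(states)
  if (nrow(states) < 2) stop("need at least two states")
  if (all(apply(states, 2, stats::sd) == 0)) stop("zero-variance input")
  pr <- stats::prcomp(states, center = TRUE, scale. = FALSE)
  scores <- pr$x[, seq_len(min(2, ncol(pr$x))), drop = FALSE]
  if (ncol(scores) < 2) scores <- cbind(scores, 0)
  colnames(scores) <- c("PC1", "PC2")
  list(scores = scores,
       var_explained = pr$sdev^2 / sum(pr$sdev^2),
       rotation = pr$rotation, center = pr$center)
}

#' Amplitude, period and mean of an oscillatory signal
#'
#' The amplitude is half the 5–95% interquantile span; the period is the
#' mean interval between rising crossings of the signal mean (crossing
#' times linearly interpolated).  With fewer than two crossings the
#' period is reported as `NA`.
#'
#' @param t Time stamps.
#' @param x Signal values.
#' @param window Optional `c(from, to)` restriction.
#' @return A list with `mean`, `amplitude`, `period`.
#' @export
oscillation_stats <- function(t, x, window = NULL) {
  if (!is.null(window)) {
    keep <- t >= window[1] & t <= window[2]
    t <- t[keep]; x <- x[keep]
  }
  if (!length(x)) stop("empty window")
  m <- mean(x)
  q <- stats::quantile(x, c(0.05, 0.95), names = FALSE)
  s <- x - m
  i <- which(s[-length(s)] < 0 & s[-1] >= 0)
  period <- NA_real_
  if (length(i) >= 2) {
    tc <- t[i] + (t[i + 1] - t[i]) * (-s[i]) / (s[i + 1] - s[i])
    period <- mean(diff(tc))
  }
  list(mean = m, amplitude = (q[2] - q[1]) / 2, period = period)
}

#' Fraction of states that recur within the window
#'
#' For each state in the window, checks whether the nearest other
#' in-window state at temporal distance of at least `guard` lies within
#' `delta` in normalized sensorimotor space; returns the fraction that do
#' (over the states that have at least one such temporally distant
#' companion).  An exactly repeating trajectory scores 1; a non-recurrent
#' wander scores near 0 for small `delta`.
#'
#' @param t Time stamps.
#' @param states Matrix of normalized sensorimotor states (rows align
#'   with `t`).
#' @param delta Recurrence radius.
#' @param guard Temporal guard in time-units: states closer in time than
#'   this are not counted as revisits.
#' @param window Optional `c(from, to)` restriction.
#' @return Fraction in \[0, 1\] (`NA` if no state has an admissible
#'   companion).
#' @export
recurrence_fraction <- function(t, states, delta, guard = 1, window = NULL) {
  stopifnot(delta > 0)
  states <- as.matrix(states)
  if (!is.null(window)) {
    keep <- t >= window[1] & t <= window[2]
    t <- t[keep]; states <- states[keep, , drop = FALSE]
  }
  n <- length(t)
  if (n < 2) return(NA_real_)
  DM <- as.matrix(stats::dist(states))
  hits <- 0L; tot <- 0L
  for (i in seq_len(n)) {
    adm <- which(abs(t - t[i]) >= guard)
    if (!length(adm)) next
    tot <- tot + 1L
    if (min(DM[i, adm]) <= delta) hits <- hits + 1L
  }
  if (tot == 0L) return(NA_real_)
  hits / tot
}
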