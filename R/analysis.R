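# Trajectory statistics: horizontal speed, angular velocity of the flight
# tangent, approach angle to a landmark, and per-condition speed
# histograms.

# First derivative by central differences, one-sided at the endpoints.
central_diff <- function(x, dt) {
  n <- length(x)
  if (n < 2L) stop("need at least 2 samples to differentiate")
  d <- numeric(n)
  d[1] <- (x[2] - x[1]) / dt
  d[n] <- (x[n] - x[n - 1]) / dt
  if (n > 2L) {
    d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (2 * dt)
  }
  d
}

traj_matrix <- function(traj) {
  if (is.data.frame(traj)) {
    as.matrix(traj[, c("x", "y", "z")])
  } else {
    m <- as.matrix(traj)
    m[, 1:3, drop = FALSE]
  }
}

# centred moving average with the window truncated at the series ends;
# window must be odd, 1 = no smoothing
smooth_positions <- function(pos, window) {
  window <- as.integer(window)
  if (window <= 1L) return(pos)
  if (window %% 2L == 0L) stop("smooth_window must be odd")
  half <- window %/% 2L
  n <- nrow(pos)
  out <- pos
  for (i in seq_len(n)) {
    lo <- max(1L, i - half)
    hi <- min(n, i + half)
    out[i, ] <- colMeans(pos[lo:hi, , drop = FALSE])
  }
  out
}

#' Horizontal flight speed
#'
#' The first derivative of position in the XY plane: central differences
#' of `x` and `y` (one-sided at the endpoints), then the Euclidean norm.
#' Purely vertical motion yields zero.
#'
#' @param traj trajectory: a data frame with `x, y, z` columns (one target,
#'   frames in order) or a matrix whose first three columns are positions.
#' @param dt frame interval in seconds.
#' @param smooth_window optional odd moving-average window (frames) applied
#'   to the positions before differentiating; 1 (default) disables
#'   smoothing. Differentiation amplifies per-frame estimation noise, so a
#'   window spanning 50-100 ms is useful on tracked (as opposed to
#'   ground-truth) trajectories.
#' @return numeric vector of speeds (m/s), one per frame.
#' @export
horizontal_speed <- function(traj, dt, smooth_window = 1L) {
  pos <- smooth_positions(traj_matrix(traj), smooth_window)
  if (nrow(pos) < 2L) stop("horizontal speed needs at least 2 frames")
  vx <- central_diff(pos[, 1], dt)
  vy <- central_diff(pos[, 2], dt)
  sqrt(vx^2 + vy^2)
}

#' Angular velocity of the flight tangent
#'
#' Rate of change of the unit tangent to the three-dimensional trajectory,
#' in rad/s. Straight flight gives zero; a horizontal circle of radius `r`
#' flown at speed `v` gives `v / r`; saccades appear as sharp local peaks.
#' Frames where the speed is (numerically) zero are returned as `NA`.
#'
#' @param traj trajectory (see [horizontal_speed]); at least 3 frames.
#' @param dt frame interval in seconds.
#' @param speed_tol speeds below this (m/s) are treated as stationary.
#' @param smooth_window optional odd moving-average window on positions
#'   (see [horizontal_speed]).
#' @return numeric vector (rad/s), `NA` where undefined.
#' @export
angular_velocity <- function(traj, dt, speed_tol = 1e-9,
                             smooth_window = 1L) {
  pos <- smooth_positions(traj_matrix(traj), smooth_window)
  n <- nrow(pos)
  if (n < 3L) stop("angular velocity needs at least 3 frames")
  vel <- apply(pos, 2, central_diff, dt = dt)
  speed <- sqrt(rowSums(vel^2))
  ok <- speed > speed_tol
  tang <- vel / ifelse(ok, speed, NA_real_)
  dtang <- apply(tang, 2, function(col) {
    # differentiate where defined; NA propagates
    d <- rep(NA_real_, n)
    d[1] <- (col[2] - col[1]) / dt
    d[n] <- (col[n] - col[n - 1]) / dt
    if (n > 2L) d[2:(n - 1)] <- (col[3:n] - col[1:(n - 2)]) / (2 * dt)
    d
  })
  out <- sqrt(rowSums(dtang^2))
  out[!ok] <- NA_real_
  out
}

#' Landmark scene
#'
#' A vertical post in the arena, described by its horizontal position and
#' radius.
#'
#' @param post_position `c(x, y)` of the post axis (m).
#' @param post_radius post radius (m), >= 0.
#' @return list of class `landmark_scene`.
#' @export
landmark_scene <- function(post_position, post_radius = 0) {
  stopifnot(length(post_position) == 2L, post_radius >= 0)
  structure(list(post_position = as.numeric(post_position),
                 post_radius = post_radius),
            class = "landmark_scene")
}

wrap_pi <- function(a) {
  a <- (a + pi) %% (2 * pi) - pi
  a[a == -pi] <- pi
  a
}

#' Approach angle to a landmark
#'
#' The difference between the bearing to the post and the direction of
#' flight, both measured in the horizontal plane:
#' `psi = 0` means flying directly toward the post, `|psi| = pi` directly
#' away, and positive `psi` means the post lies to the left of the
#' heading. Frames with zero horizontal speed are `NA`.
#'
#' @param traj trajectory (see [horizontal_speed]).
#' @param scene a [landmark_scene].
#' @param dt frame interval in seconds.
#' @param speed_tol horizontal speeds below this are treated as undefined.
#' @return numeric vector of angles in `(-pi, pi]`, `NA` where undefined.
#' @export
approach_angle <- function(traj, scene, dt, speed_tol = 1e-9) {
  pos <- traj_matrix(traj)
  if (nrow(pos) < 2L) stop("approach angle needs at least 2 frames")
  vx <- central_diff(pos[, 1], dt)
  vy <- central_diff(pos[, 2], dt)
  dx <- scene$post_position[1] - pos[, 1]
  dy <- scene$post_position[2] - pos[, 2]
  if (any(dx == 0 & dy == 0)) {
    stop("trajectory passes through the post centre; bearing undefined")
  }
  heading <- atan2(vy, vx)
  bearing <- atan2(dy, dx)
  psi <- wrap_pi(bearing - heading)
  psi[sqrt(vx^2 + vy^2) <= speed_tol] <- NA_real_
  psi
}

#' Per-condition speed histograms
#'
#' Computes horizontal speeds for every trajectory, excludes frames closer
#' than `margin` to any arena wall, floor or ceiling, and returns one
#' unit-area histogram per condition together with the mean and standard
#' deviation of the retained speeds.
#'
#' @param trajectories data frame with `target_id, frame, x, y, z` (e.g.
#'   from [track_features]).
#' @param conditions vector of condition labels, one per row of
#'   `trajectories`.
#' @param arena arena dimensions `c(x, y, z)` (m), centred on the origin.
#' @param dt frame interval in seconds.
#' @param margin minimum distance to the nearest arena surface (m,
#'   default 0.05).
#' @param breaks histogram breakpoints (m/s) passed to [graphics::hist];
#'   default 30 equal bins over the pooled retained speeds.
#' @return named list per condition: `breaks`, `density` (integrates to
#'   1), `mean`, `sd`, `n`. Conditions with no retained frames report
#'   `n = 0` and empty histograms.
#' @export
speed_histogram <- function(trajectories, conditions, arena, dt,
                            margin = 0.05, breaks = NULL) {
  stopifnot(length(conditions) == nrow(trajectories))
  half <- arena / 2
  speeds <- rep(NA_real_, nrow(trajectories))
  for (id in unique(trajectories$target_id)) {
    sel <- which(trajectories$target_id == id)
    sel <- sel[order(trajectories$frame[sel])]
    if (length(sel) >= 2L) {
      speeds[sel] <- horizontal_speed(trajectories[sel, ], dt)
    }
  }
  pos <- as.matrix(trajectories[, c("x", "y", "z")])
  wall_dist <- pmin(half[1] - abs(pos[, 1]),
                    half[2] - abs(pos[, 2]),
                    half[3] - abs(pos[, 3]))
  keep <- !is.na(speeds) & wall_dist > margin
  if (is.null(breaks)) {
    if (any(keep)) {
      rng <- range(speeds[keep])
      if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5) * max(rng[1], 1e-6)
      breaks <- seq(rng[1], rng[2], length.out = 31L)
    } else {
      breaks <- seq(0, 1, length.out = 31L)
    }
  }
  out <- list()
  for (cond in unique(conditions)) {
    sel <- keep & conditions == cond
    s <- speeds[sel]
    if (length(s) == 0L) {
      out[[as.character(cond)]] <- list(breaks = breaks,
                                        density = numeric(0),
                                        mean = NA_real_, sd = NA_real_,
                                        n = 0L)
      next
    }
    hh <- graphics::hist(s, breaks = breaks, plot = FALSE)
    out[[as.character(cond)]] <- list(
      breaks = hh$breaks, density = hh$density,
      mean = mean(s), sd = stats::sd(s), n = length(s)
    )
  }
  out
}
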