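# Per-target extended Kalman filter: constant-velocity process model and a
# projective multi-camera observation model. The state is
# s = (x, y, z, vx, vy, vz) in metres and metres per second; observations
# are concatenated distortion-corrected image points (u_i, v_i) from the
# contributing cameras.

#' Constant-velocity process model
#'
#' Transition `A = [I, dt I; 0, I]` with additive Gaussian process noise of
#' covariance `Q = diag(q_pos, q_pos, q_pos, q_vel, q_vel, q_vel)`.
#' Manoeuvring (deviation from constant velocity) is absorbed into `Q`; the
#' defaults are 100 mm^2 (1e-4 m^2) on the position entries and
#' 0.25 m^2 s^-2 on the velocity entries, which work well for fruit-fly
#' flight observed at around 100 frames per second.
#'
#' @param dt time step in seconds.
#' @param q_pos process variance of each position component (m^2).
#' @param q_vel process variance of each velocity component (m^2 s^-2).
#' @return list of class `process_model` with `dt`, `A`, `Q`.
#' @export
process_model <- function(dt, q_pos = 1e-4, q_vel = 0.25) {
  stopifnot(dt > 0, q_pos >= 0, q_vel >= 0)
  A <- diag(6)
  A[1:3, 4:6] <- dt * diag(3)
  Q <- diag(c(rep(q_pos, 3), rep(q_vel, 3)))
  structure(list(dt = dt, A = A, Q = Q), class = "process_model")
}

#' Multi-camera observation model
#'
#' @param cameras list of [camera_model]s (the rig).
#' @param r_px observation variance per image coordinate in px^2 (default
#'   1, i.e. one-pixel standard deviation on detected image positions).
#' @return list of class `observation_model`.
#' @export
observation_model <- function(cameras, r_px = 1) {
  stopifnot(length(cameras) >= 1L, r_px > 0)
  structure(list(cameras = cameras, r_px = r_px),
            class = "observation_model")
}

#' Create a new tracked-target model
#'
#' A target carries its state estimate, covariance and bookkeeping:
#' `Gamma = {s_hat, P}` plus identity, birth frame and the number of frames
#' since the last observation. New targets start with zero velocity and a
#' relatively high error estimate.
#'
#' @param id unique integer identity.
#' @param position length-3 initial position (m).
#' @param birth_frame frame index of creation.
#' @param pos_var initial position variance per axis (m^2).
#' @param vel_var initial velocity variance per axis (m^2 s^-2).
#' @return list of class `target_model`.
#' @export
new_target <- function(id, position, birth_frame = NA_integer_,
                       pos_var = 0.01, vel_var = 1) {
  stopifnot(length(position) == 3L, all(is.finite(position)))
  structure(
    list(id = as.integer(id),
         state = c(as.numeric(position), 0, 0, 0),
         P = diag(c(rep(pos_var, 3), rep(vel_var, 3))),
         frames_since_observation = 0L,
         birth_frame = as.integer(birth_frame)),
    class = "target_model"
  )
}

#' EKF prediction step
#'
#' `s <- A s`; `P <- A P A' + Q`. Identity and bookkeeping are preserved.
#'
#' @param target a [target_model].
#' @param process a [process_model].
#' @return the predicted `target_model`.
#' @export
ekf_predict <- function(target, process) {
  target$state <- drop(process$A %*% target$state)
  target$P <- process$A %*% target$P %*% t(process$A) + process$Q
  target$P <- (target$P + t(target$P)) / 2
  target
}

#' Nonlinear observation function
#'
#' Concatenates the projections of the state's position through each listed
#' camera: `h(s) = (u_1, v_1, ..., u_n, v_n)`.
#'
#' @param state length-6 state vector (or length-3 position).
#' @param cameras list of [camera_model]s.
#' @return numeric vector of length `2 * length(cameras)`.
#' @export
observation_function <- function(state, cameras) {
  pos <- state[1:3]
  unlist(lapply(cameras, function(cam) unname(project(cam, pos))),
         use.names = FALSE)
}

#' Jacobian of the observation function
#'
#' Analytic derivative of the dehomogenized projection with respect to the
#' position components; the velocity columns are zero because cameras
#' observe position only. For camera matrix rows `p1, p2, p3` and
#' homogeneous point `X`, with `num_u = p1 . X`, `num_v = p2 . X`,
#' `den = p3 . X`:
#' `d u / d pos = (p1[1:3] den - num_u p3[1:3]) / den^2` and analogously
#' for `v`.
#'
#' @param state length-6 state vector (or length-3 position).
#' @param cameras list of [camera_model]s.
#' @return `2n x 6` matrix.
#' @export
observation_jacobian <- function(state, cameras) {
  pos <- state[1:3]
  X <- c(pos, 1)
  H <- matrix(0, 2L * length(cameras), 6L)
  for (i in seq_along(cameras)) {
    P <- cameras[[i]]$P
    num_u <- sum(P[1, ] * X)
    num_v <- sum(P[2, ] * X)
    den <- sum(P[3, ] * X)
    if (abs(den) <= 1e-12 * max(1, abs(num_u), abs(num_v))) {
      stop("degenerate projection in Jacobian for camera ", cameras[[i]]$id)
    }
    H[2L * i - 1L, 1:3] <- (P[1, 1:3] * den - num_u * P[3, 1:3]) / den^2
    H[2L * i, 1:3] <- (P[2, 1:3] * den - num_v * P[3, 1:3]) / den^2
  }
  H
}

#' EKF update step
#'
#' Standard extended Kalman filter measurement update using the stacked
#' observation function and Jacobian of the contributing cameras only, with
#' block-diagonal `R = r_px * I`. The covariance is updated in Joseph form
#' and symmetrized for numerical positive-semidefiniteness. With an empty
#' observation the posterior is simply the prior (the missing-data rule)
#' and the frames-since-observation counter is incremented.
#'
#' @param target a [target_model], already predicted for this frame.
#' @param observed list of `list(camera_index = i, point = c(u, v))`; may be
#'   empty. `camera_index` indexes `obs_model$cameras`.
#' @param obs_model an [observation_model].
#' @return the updated `target_model`.
#' @export
ekf_update <- function(target, observed, obs_model) {
  if (length(observed) == 0L) {
    target$frames_since_observation <- target$frames_since_observation + 1L
    return(target)
  }
  idx <- vapply(observed, function(o) as.integer(o$camera_index), integer(1))
  if (anyDuplicated(idx)) {
    stop("a camera may contribute at most one observation per update")
  }
  cams <- obs_model$cameras[idx]
  y <- unlist(lapply(observed, function(o) as.numeric(o$point[1:2])),
              use.names = FALSE)
  h <- observation_function(target$state, cams)
  H <- observation_jacobian(target$state, cams)
  m <- length(y)
  R <- diag(obs_model$r_px, m)
  S <- H %*% target$P %*% t(H) + R
  S <- (S + t(S)) / 2
  K <- tryCatch(
    target$P %*% t(H) %*% solve(S),
    error = function(e) stop(
      "singular innovation covariance for target ", target$id,
      " (", conditionMessage(e), ")"
    )
  )
  target$state <- target$state + drop(K %*% (y - h))
  IKH <- diag(6) - K %*% H
  Pn <- IKH %*% target$P %*% t(IKH) + K %*% R %*% t(K)
  target$P <- (Pn + t(Pn)) / 2
  target$frames_since_observation <- 0L
  target
}
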