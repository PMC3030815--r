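# Synthetic fixtures with ground truth: calibrated camera rigs viewing an
# arena, flight-like trajectories (straight segments punctuated by
# saccades), noisy/cluttered 2D observations, and rendered blob images.
#
# All randomness is driven by the seed in the simulation config; each
# generator derives its own stream (seed + fixed offset) so that, e.g.,
# trajectories are identical whether or not frames are rendered afterwards.

#' Simulation configuration
#'
#' Defaults emulate a small fruit-fly rig: five cameras around a
#' 0.3 x 0.3 x 1.5 m arena filmed at 100 frames per second, flight speed
#' regulated near 0.15 m/s, one-pixel detection noise.
#'
#' @param n_cameras number of cameras (>= 2).
#' @param arena arena dimensions `c(x, y, z)` in metres, centred on the
#'   origin, z up.
#' @param n_targets number of simultaneous targets.
#' @param frame_rate frames per second.
#' @param n_frames number of frames to simulate.
#' @param speed mean flight speed set point (m/s).
#' @param saccade_rate mean saccades per second (Poisson).
#' @param pixel_noise_sigma isotropic Gaussian noise on detections (px).
#' @param miss_rate per-camera per-frame probability of a missed detection.
#' @param clutter_rate mean false-positive detections per camera per frame
#'   (Poisson).
#' @param image_size `c(width, height)` of each camera in px.
#' @param seed integer seed; all simulator outputs are reproducible
#'   functions of it.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_cameras = 5L, arena = c(0.3, 0.3, 1.5),
                       n_targets = 1L, frame_rate = 100, n_frames = 200L,
                       speed = 0.15, saccade_rate = 0.5,
                       pixel_noise_sigma = 1, miss_rate = 0,
                       clutter_rate = 0, image_size = c(640L, 480L),
                       seed = 1L) {
  stopifnot(n_cameras >= 2L, length(arena) == 3L, all(arena > 0),
            n_targets >= 1L, frame_rate > 0, n_frames >= 1L,
            speed > 0, saccade_rate >= 0, pixel_noise_sigma >= 0,
            miss_rate >= 0, miss_rate <= 1, clutter_rate >= 0,
            length(image_size) == 2L)
  structure(
    list(n_cameras = as.integer(n_cameras), arena = as.numeric(arena),
         n_targets = as.integer(n_targets), frame_rate = frame_rate,
         n_frames = as.integer(n_frames), speed = speed,
         saccade_rate = saccade_rate,
         pixel_noise_sigma = pixel_noise_sigma, miss_rate = miss_rate,
         clutter_rate = clutter_rate,
         image_size = as.numeric(image_size), seed = as.integer(seed)),
    class = "sim_config"
  )
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

arena_corners <- function(arena) {
  h <- arena / 2
  as.matrix(expand.grid(x = c(-h[1], h[1]), y = c(-h[2], h[2]),
                        z = c(-h[3], h[3])))
}

#' Build a synthetic calibrated camera rig
#'
#' Places `n_cameras` on a ring around the arena centre (alternating
#' above/below the mid-plane so camera centres are not coplanar), aimed at
#' the centre, with the focal length chosen so every arena corner projects
#' at least `margin` px inside every image. Deterministic: no randomness.
#'
#' @param config a [sim_config].
#' @param margin minimum distance of projected arena corners from the
#'   image border (px).
#' @return named list of [camera_model]s (`cam1`, `cam2`, ...).
#' @export
make_rig <- function(config, margin = 10) {
  n <- config$n_cameras
  arena <- config$arena
  corners <- arena_corners(arena)
  radius <- 1.4 * sqrt(sum((arena / 2)^2))
  w <- config$image_size[1]
  h <- config$image_size[2]
  cx <- (w - 1) / 2
  cy <- (h - 1) / 2
  cams <- vector("list", n)
  for (i in seq_len(n)) {
    ang <- 2 * pi * (i - 1) / n + pi / (2 * n)
    elev <- 0.35 * radius * (if (i %% 2 == 0) 1 else -1) * (1 + 0.1 * i / n)
    C <- c(radius * cos(ang), radius * sin(ang), elev)
    f <- C / sqrt(sum(C^2))          # from centre toward camera
    fwd <- -f                        # camera looks at the arena centre
    up <- if (abs(fwd[3]) > 0.99) c(0, 1, 0) else c(0, 0, 1)
    right <- cross3(fwd, up)
    right <- right / sqrt(sum(right^2))
    down <- cross3(fwd, right)
    R <- rbind(right, down, fwd)
    Xc <- t(R %*% (t(corners) - C))  # corners in camera coordinates
    if (any(Xc[, 3] <= 0)) stop("arena not fully in front of camera ", i)
    xn <- abs(Xc[, 1] / Xc[, 3])
    yn <- abs(Xc[, 2] / Xc[, 3])
    focal <- min((cx - margin) / max(xn), (cy - margin) / max(yn))
    if (focal <= 0) stop("cannot cover the arena from camera ", i)
    K <- matrix(c(focal, 0, cx, 0, focal, cy, 0, 0, 1), 3, 3, byrow = TRUE)
    P <- K %*% cbind(R, -R %*% C)
    cams[[i]] <- camera_model(paste0("cam", i), P,
                              image_size = config$image_size)
  }
  names(cams) <- vapply(cams, function(cm) cm$id, character(1))
  # coverage check: every corner inside every image
  for (cm in cams) {
    uv <- project(cm, corners)
    if (any(uv[, 1] < 0 | uv[, 1] > w - 1 | uv[, 2] < 0 | uv[, 2] > h - 1)) {
      stop("rig construction failed: arena corner outside image of ", cm$id)
    }
  }
  cams
}

rotate_about_axis <- function(v, axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  v * cos(angle) + cross3(a, v) * sin(angle) +
    a * sum(a * v) * (1 - cos(angle))
}

#' Simulate flight-like ground-truth trajectories
#'
#' Each target flies piecewise-smoothly: constant-velocity segments whose
#' speed is drawn near the configured set point, punctuated at
#' Poisson-distributed times by saccades — brief, rapid turns of 90-150
#' degrees spread over 2-5 frames, mostly about the vertical axis. Targets
#' are confined to the arena by reflecting the offending velocity
#' component at the walls.
#'
#' @param config a [sim_config].
#' @return list with `states`: a list (one per target) of
#'   `n_frames x 6` matrices, columns `x, y, z, vx, vy, vz`.
#' @export
make_trajectory <- function(config) {
  set.seed(config$seed + 1L)
  dt <- 1 / config$frame_rate
  half <- config$arena / 2
  p_saccade <- config$saccade_rate * dt
  states <- vector("list", config$n_targets)
  for (k in seq_len(config$n_targets)) {
    pos <- stats::runif(3, -0.6 * half, 0.6 * half)
    hd <- stats::rnorm(3)
    hd[3] <- hd[3] * 0.3          # mostly horizontal flight
    hd <- hd / sqrt(sum(hd^2))
    speed <- abs(stats::rnorm(1, config$speed, 0.05 * config$speed))
    S <- matrix(0, config$n_frames, 6,
                dimnames = list(NULL, c("x", "y", "z", "vx", "vy", "vz")))
    saccade_left <- 0L
    saccade_step <- 0
    saccade_axis <- c(0, 0, 1)
    for (t in seq_len(config$n_frames)) {
      if (saccade_left > 0L) {
        hd <- rotate_about_axis(hd, saccade_axis, saccade_step)
        hd <- hd / sqrt(sum(hd^2))
        saccade_left <- saccade_left - 1L
        if (saccade_left == 0L) {
          speed <- abs(stats::rnorm(1, config$speed, 0.05 * config$speed))
        }
      } else if (stats::runif(1) < p_saccade) {
        total <- stats::runif(1, 90, 150) * pi / 180 *
          sample(c(-1, 1), 1)
        nsteps <- sample(2:5, 1)
        axis <- c(stats::rnorm(2, 0, 0.2), 1)
        saccade_axis <- axis / sqrt(sum(axis^2))
        saccade_step <- total / nsteps
        saccade_left <- nsteps
      }
      vel <- speed * hd
      nxt <- pos + vel * dt
      for (ax in 1:3) {                 # reflective confinement
        if (abs(nxt[ax]) > 0.95 * half[ax]) {
          hd[ax] <- -hd[ax]
          vel <- speed * hd
          nxt <- pos + vel * dt
        }
      }
      pos <- nxt
      S[t, ] <- c(pos, vel)
    }
    states[[k]] <- S
  }
  list(states = states)
}

# Blob-statistic sampler shared by true detections and clutter so that
# area gating is a meaningful discriminator test.
sample_blob_stats <- function(n) {
  data.frame(alpha = stats::rlnorm(n, log(20), 0.3),
             beta = stats::runif(n, 0.3, 0.9),
             theta = stats::runif(n, 0, pi),
             epsilon = stats::runif(n, 0, 0.8))
}

#' Generate noisy 2D observations of ground-truth states
#'
#' Projects every true target position into every camera, adds isotropic
#' Gaussian pixel noise, drops detections with the configured miss
#' probability, and appends Poisson-distributed uniform clutter with blob
#' statistics drawn from the same distribution as true detections.
#' Detections falling outside the image are dropped (a physical miss).
#'
#' @param states list of per-target `n_frames x 6` state matrices, as from
#'   [make_trajectory].
#' @param rig named list of [camera_model]s from [make_rig].
#' @param config a [sim_config].
#' @return list with `features` (a feature data frame, see
#'   [extract_features]) and `provenance` (aligned row for row:
#'   `frame, camera_id, index, target` where `index` is the feature's row
#'   within its camera and frame and `target` is the originating target or
#'   `NA` for clutter).
#' @export
sim_observe <- function(states, rig, config) {
  set.seed(config$seed + 2L)
  w <- config$image_size[1]
  h <- config$image_size[2]
  feats <- list()
  prov <- list()
  for (t in seq_len(config$n_frames)) {
    for (ci in seq_along(rig)) {
      cam <- rig[[ci]]
      rows <- list()
      src <- integer(0)
      for (k in seq_along(states)) {
        uv <- tryCatch(project(cam, states[[k]][t, 1:3]),
                       error = function(e) NULL)
        if (is.null(uv)) next
        if (stats::runif(1) < config$miss_rate) next
        uv <- uv + stats::rnorm(2, 0, config$pixel_noise_sigma)
        if (uv[1] < 0 || uv[1] > w - 1 || uv[2] < 0 || uv[2] > h - 1) next
        rows[[length(rows) + 1L]] <- uv
        src <- c(src, k)
      }
      n_clutter <- stats::rpois(1, config$clutter_rate)
      if (n_clutter > 0L) {
        for (j in seq_len(n_clutter)) {
          rows[[length(rows) + 1L]] <- c(stats::runif(1, 0, w - 1),
                                         stats::runif(1, 0, h - 1))
          src <- c(src, NA_integer_)
        }
      }
      if (length(rows) == 0L) next
      uvm <- do.call(rbind, rows)
      stats_df <- sample_blob_stats(nrow(uvm))
      feats[[length(feats) + 1L]] <- data.frame(
        frame = t, camera_id = cam$id, u = uvm[, 1], v = uvm[, 2],
        alpha = stats_df$alpha, beta = stats_df$beta,
        theta = stats_df$theta, epsilon = stats_df$epsilon,
        stringsAsFactors = FALSE
      )
      prov[[length(prov) + 1L]] <- data.frame(
        frame = t, camera_id = cam$id, index = seq_len(nrow(uvm)),
        target = src, stringsAsFactors = FALSE
      )
    }
  }
  empty_f <- data.frame(frame = integer(0), camera_id = character(0),
                        u = numeric(0), v = numeric(0), alpha = numeric(0),
                        beta = numeric(0), theta = numeric(0),
                        epsilon = numeric(0), stringsAsFactors = FALSE)
  empty_p <- data.frame(frame = integer(0), camera_id = character(0),
                        index = integer(0), target = integer(0),
                        stringsAsFactors = FALSE)
  list(features = if (length(feats) > 0L) do.call(rbind, feats) else empty_f,
       provenance = if (length(prov) > 0L) do.call(rbind, prov) else empty_p)
}

sim_background <- function(width, height, cam_index) {
  r <- matrix(seq_len(height), height, width)
  c <- matrix(seq_len(width), height, width, byrow = TRUE)
  0.4 + 0.05 * sin(2 * pi * r / 17 + cam_index) * cos(2 * pi * c / 23)
}

#' Render grayscale frames of the simulated scene
#'
#' Draws each target as a Gaussian blob at its projected image position on
#' a static textured background, optionally elongated along the projected
#' velocity direction (emulating a body axis). Returns the true background
#' per camera so feature extraction can be tested against a perfect
#' background model.
#'
#' @param states list of per-target state matrices from [make_trajectory].
#' @param rig named list of [camera_model]s.
#' @param config a [sim_config] (its `image_size` sets the frame size).
#' @param sigma_blob isotropic blob standard deviation (px).
#' @param amplitude peak luminance increment of a blob (frame units).
#' @param elongation ratio of the major to minor blob axis; 1 renders
#'   round blobs, > 1 stretches the blob along the projected velocity.
#' @return list with `frames` (list over cameras of lists over frames of
#'   matrices) and `backgrounds` (list over cameras of matrices).
#' @export
render_frames <- function(states, rig, config, sigma_blob = 2,
                          amplitude = 0.4, elongation = 1) {
  set.seed(config$seed + 3L)
  w <- as.integer(config$image_size[1])
  h <- as.integer(config$image_size[2])
  backgrounds <- lapply(seq_along(rig), function(ci) sim_background(w, h, ci))
  frames <- vector("list", length(rig))
  sig_major <- sigma_blob * elongation
  roi <- ceiling(4 * sig_major)
  for (ci in seq_along(rig)) {
    cam <- rig[[ci]]
    frames[[ci]] <- vector("list", config$n_frames)
    for (t in seq_len(config$n_frames)) {
      img <- backgrounds[[ci]]
      for (k in seq_along(states)) {
        st <- states[[k]][t, ]
        uv <- tryCatch(project(cam, st[1:3]), error = function(e) NULL)
        if (is.null(uv)) next
        if (uv[1] < -roi || uv[1] > w - 1 + roi ||
            uv[2] < -roi || uv[2] > h - 1 + roi) next
        if (elongation > 1) {
          dp <- tryCatch(
            project(cam, st[1:3] + 1e-3 * st[4:6]) - uv,
            error = function(e) c(1, 0))
          phi <- atan2(dp[2], dp[1])
        } else {
          phi <- 0
        }
        Rm <- matrix(c(cos(phi), -sin(phi), sin(phi), cos(phi)), 2, 2,
                     byrow = TRUE)
        Sinv <- Rm %*% diag(1 / c(sig_major^2, sigma_blob^2)) %*% t(Rm)
        c0 <- max(1L, floor(uv[1]) + 1L - roi)
        c1 <- min(w, floor(uv[1]) + 1L + roi)
        r0 <- max(1L, floor(uv[2]) + 1L - roi)
        r1 <- min(h, floor(uv[2]) + 1L + roi)
        if (c0 > c1 || r0 > r1) next
        uu <- matrix((c0:c1) - 1, r1 - r0 + 1L, c1 - c0 + 1L, byrow = TRUE)
        vv <- matrix((r0:r1) - 1, r1 - r0 + 1L, c1 - c0 + 1L)
        du <- uu - uv[1]
        dv <- vv - uv[2]
        q <- Sinv[1, 1] * du^2 + 2 * Sinv[1, 2] * du * dv +
          Sinv[2, 2] * dv^2
        img[r0:r1, c0:c1] <- img[r0:r1, c0:c1] + amplitude * exp(-q / 2)
      }
      frames[[ci]][[t]] <- img
    }
  }
  names(frames) <- names(rig)
  names(backgrounds) <- names(rig)
  list(frames = frames, backgrounds = backgrounds)
}

#' Simulate a complete dataset
#'
#' Convenience wrapper: builds the rig, simulates trajectories, and
#' generates noisy observations, all deterministically from the config
#' seed.
#'
#' @param config a [sim_config].
#' @return list with `rig`, `truth` (from [make_trajectory]) and
#'   `observations` (from [sim_observe]).
#' @export
simulate_dataset <- function(config) {
  rig <- make_rig(config)
  truth <- make_trajectory(config)
  obs <- sim_observe(truth$states, rig, config)
  list(rig = rig, truth = truth, observations = obs, config = config)
}
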