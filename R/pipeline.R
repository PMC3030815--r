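# Per-frame orchestration of the tracker: predict -> associate -> resolve
# shared assignments -> EKF update -> spawn new targets -> retire, plus
# trajectory assembly and file-level entry points.

#' Full tracker configuration
#'
#' Bundles the process, observation and gating parameters of the tracker.
#'
#' @param dt frame interval in seconds (1 / frame rate).
#' @param q_pos,q_vel process noise variances, see [process_model].
#' @param r_px observation variance (px^2), see [observation_model].
#' @param init_pos_var,init_vel_var initial covariance diagonal for newly
#'   born targets (m^2 and m^2 s^-2).
#' @param ... gating and track-management settings passed to
#'   [gating_params].
#' @return list of class `tracker_config`.
#' @export
tracker_config <- function(dt = 0.01, q_pos = 1e-4, q_vel = 0.25, r_px = 1,
                           init_pos_var = 0.01, init_vel_var = 1, ...) {
  structure(
    list(dt = dt, q_pos = q_pos, q_vel = q_vel, r_px = r_px,
         init_pos_var = init_pos_var, init_vel_var = init_vel_var,
         gating = gating_params(...)),
    class = "tracker_config"
  )
}

#' Read a tracker configuration from a key = value text file
#'
#' Lines of the form `name = value`; `#` starts a comment. Unknown keys are
#' an error. Missing keys take the [tracker_config] defaults.
#'
#' @param path file path.
#' @return a `tracker_config`.
#' @export
read_tracker_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- list()
  for (l in lines) {
    parts <- strsplit(l, "=", fixed = TRUE)[[1]]
    if (length(parts) != 2L) stop("malformed config line: ", l)
    kv[[trimws(parts[1])]] <- as.numeric(trimws(parts[2]))
  }
  allowed <- c("dt", "q_pos", "q_vel", "r_px", "init_pos_var",
               "init_vel_var", "max_pixel_dist", "min_area",
               "max_reproj_error_birth", "max_covariance_trace_death",
               "max_frames_unobserved", "max_birth_combinations")
  unknown <- setdiff(names(kv), allowed)
  if (length(unknown) > 0L) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  }
  do.call(tracker_config, kv)
}

#' Write a tracker configuration to a key = value text file
#'
#' @param config a [tracker_config].
#' @param path file path.
#' @export
write_tracker_config <- function(config, path) {
  flat <- c(config[c("dt", "q_pos", "q_vel", "r_px", "init_pos_var",
                     "init_vel_var")],
            config$gating[c("max_pixel_dist", "min_area",
                            "max_reproj_error_birth",
                            "max_covariance_trace_death",
                            "max_frames_unobserved",
                            "max_birth_combinations")])
  writeLines(sprintf("%s = %.17g", names(flat), as.numeric(flat)), path)
  invisible(path)
}

#' Create a tracker state
#'
#' @param cameras list of [camera_model]s (the rig).
#' @param config a [tracker_config].
#' @return list of class `tracker_state` holding the live targets, the
#'   models and accumulated per-frame records.
#' @export
tracker_state <- function(cameras, config = tracker_config()) {
  structure(
    list(cameras = cameras,
         config = config,
         process = process_model(config$dt, config$q_pos, config$q_vel),
         obs_model = observation_model(cameras, config$r_px),
         targets = list(),
         next_id = 1L,
         records = list(),
         n_births = 0L,
         n_deaths = 0L),
    class = "tracker_state"
  )
}

#' Advance the tracker by one frame
#'
#' Executes, in order: EKF predict for all live targets; NNSF association;
#' merge prevention; EKF update per target (an empty assignment carries the
#' prior forward); birth of new targets from unclaimed detections by
#' triangulation hypothesis testing; retirement of targets whose error
#' estimate exceeded its threshold. Deterministic given its inputs.
#'
#' @param state a [tracker_state].
#' @param features_by_camera list aligned with `state$cameras` of feature
#'   data frames for this frame (NULL or zero rows = no detections).
#' @param frame_index integer frame counter.
#' @return the advanced `tracker_state`; `state$events` holds the birth and
#'   death ids of this frame.
#' @export
track_step <- function(state, features_by_camera, frame_index) {
  cams <- state$cameras
  n_cam <- length(cams)
  if (length(features_by_camera) != n_cam) {
    stop("frame ", frame_index, ": expected ", n_cam,
         " per-camera feature lists, got ", length(features_by_camera))
  }
  gp <- state$config$gating
  # 1. predict
  state$targets <- lapply(state$targets, ekf_predict, process = state$process)
  # 2. associate, 3. resolve shared assignments
  assignments <- associate(state$targets, features_by_camera, cams, gp)
  assignments <- resolve_shared(state$targets, assignments,
                                features_by_camera, cams)
  # 4. update
  ncams_used <- integer(length(state$targets))
  for (k in seq_along(state$targets)) {
    d <- assignments[[k]]
    obs <- lapply(which(!is.na(d)), function(i) {
      f <- features_by_camera[[i]][d[i], ]
      list(camera_index = i, point = c(f$u, f$v))
    })
    ncams_used[k] <- length(obs)
    state$targets[[k]] <- ekf_update(state$targets[[k]], obs,
                                     state$obs_model)
  }
  # 5. spawn from unclaimed features
  claimed <- lapply(seq_len(n_cam), function(i) {
    idx <- unlist(lapply(assignments, function(d) d[i]), use.names = FALSE)
    idx[!is.na(idx)]
  })
  unclaimed <- lapply(seq_len(n_cam), function(i) {
    f <- features_by_camera[[i]]
    if (is.null(f) || nrow(f) == 0L) return(f)
    keep <- setdiff(seq_len(nrow(f)), claimed[[i]])
    f[keep, , drop = FALSE]
  })
  born <- spawn_targets(unclaimed, cams, gp, state$next_id,
                        birth_frame = frame_index,
                        pos_var = state$config$init_pos_var,
                        vel_var = state$config$init_vel_var)
  birth_ids <- vapply(born$targets, function(tg) tg$id, integer(1))
  if (length(born$targets) > 0L) {
    state$next_id <- state$next_id + length(born$targets)
    ncams_born <- vapply(born$targets, function(tg) {
      sum(born$used$target_id == tg$id)
    }, integer(1))
    state$targets <- c(state$targets, born$targets)
    ncams_used <- c(ncams_used, ncams_born)
    state$n_births <- state$n_births + length(born$targets)
  }
  # record posterior states before retirement so death frames are kept
  recs <- lapply(seq_along(state$targets), function(k) {
    tg <- state$targets[[k]]
    data.frame(target_id = tg$id, frame = frame_index,
               x = tg$state[1], y = tg$state[2], z = tg$state[3],
               vx = tg$state[4], vy = tg$state[5], vz = tg$state[6],
               ptrace = sum(diag(tg$P)[1:3]), ncams = ncams_used[k])
  })
  # 6. retire
  ret <- retire_targets(state$targets, gp)
  death_ids <- vapply(ret$retired, function(tg) tg$id, integer(1))
  state$targets <- ret$kept
  state$n_deaths <- state$n_deaths + length(ret$retired)
  state$records[[length(state$records) + 1L]] <-
    if (length(recs) > 0L) do.call(rbind, recs) else NULL
  state$events <- list(births = birth_ids, deaths = death_ids,
                       frame = frame_index)
  # diagnostic: resolved assignment vectors of the pre-existing targets
  state$last_assignments <- assignments
  state
}

#' Track a feature table into 3D trajectories
#'
#' Streams a feature table (one row per detection, as produced by
#' [extract_features] or the simulator) frame by frame through
#' [track_step] and assembles one trajectory per target identity.
#'
#' @param features data frame with columns
#'   `frame, camera_id, u, v, alpha, beta, theta, epsilon`.
#' @param cameras named list of [camera_model]s; `camera_id` values in
#'   `features` must match the names.
#' @param config a [tracker_config].
#' @param frames optional integer vector of frames to process (default:
#'   every frame from the minimum to the maximum present).
#' @return list with `trajectories` (data frame `target_id, frame, x, y, z,
#'   vx, vy, vz, ptrace, ncams`, ordered by target then frame) and `log`
#'   (frame, feature, birth and death counts).
#' @export
track_features <- function(features, cameras, config = tracker_config(),
                           frames = NULL) {
  cam_ids <- vapply(cameras, function(cm) cm$id, character(1))
  if (nrow(features) > 0) {
    unknown <- setdiff(unique(features$camera_id), cam_ids)
    if (length(unknown) > 0L) {
      stop("feature table references unknown cameras: ",
           paste(unknown, collapse = ", "))
    }
  }
  if (is.null(frames)) {
    frames <- if (nrow(features) == 0L) integer(0) else
      seq(min(features$frame), max(features$frame))
  }
  state <- tracker_state(cameras, config)
  for (fr in frames) {
    fsub <- features[features$frame == fr, , drop = FALSE]
    by_cam <- lapply(cam_ids, function(cid) {
      fsub[fsub$camera_id == cid, , drop = FALSE]
    })
    state <- track_step(state, by_cam, fr)
  }
  recs <- state$records[!vapply(state$records, is.null, logical(1))]
  traj <- if (length(recs) > 0L) {
    out <- do.call(rbind, recs)
    out <- out[order(out$target_id, out$frame), , drop = FALSE]
    rownames(out) <- NULL
    out
  } else {
    data.frame(target_id = integer(0), frame = integer(0), x = numeric(0),
               y = numeric(0), z = numeric(0), vx = numeric(0),
               vy = numeric(0), vz = numeric(0), ptrace = numeric(0),
               ncams = integer(0))
  }
  list(trajectories = traj,
       log = list(n_frames = length(frames), n_features = nrow(features),
                  n_births = state$n_births, n_deaths = state$n_deaths))
}

#' Run the tracker from files
#'
#' Reads a feature CSV and a camera file, runs [track_features] and writes
#' the trajectory table.
#'
#' @param features_file CSV of 2D features.
#' @param camera_file plain-text camera file, see [read_cameras].
#' @param out_file output trajectory CSV.
#' @param config_file optional key = value tracker configuration file.
#' @return (invisibly) the [track_features] result.
#' @export
track_files <- function(features_file, camera_file, out_file,
                        config_file = NULL) {
  cameras <- read_cameras(camera_file)
  features <- read_features(features_file)
  config <- if (is.null(config_file)) tracker_config() else
    read_tracker_config(config_file)
  res <- track_features(features, cameras, config)
  write_trajectories(res$trajectories, out_file)
  invisible(res)
}

#' Write a trajectory table to CSV
#'
#' @param trajectories data frame from [track_features].
#' @param path output path.
#' @export
write_trajectories <- function(trajectories, path) {
  utils::write.csv(trajectories, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a trajectory table from CSV
#'
#' @param path CSV written by [write_trajectories].
#' @return data frame.
#' @export
read_trajectories <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
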