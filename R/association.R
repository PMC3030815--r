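# Nearest-neighbour standard filter (NNSF) data association: cheap gates
# (image distance, blob area), a ray-to-prior Mahalanobis likelihood term,
# independent per-target per-camera argmax assignment, merge prevention for
# targets sharing identical observation sets, and track birth/death.

#' Gating and track-management parameters
#'
#' @param max_pixel_dist gate radius in px on the image distance between a
#'   detection and the projected prior position (inclusive).
#' @param min_area area gate: a detection's `alpha` must be strictly
#'   greater than this value.
#' @param max_reproj_error_birth maximum mean reprojection error in px for
#'   a triangulated birth hypothesis to be accepted.
#' @param max_covariance_trace_death a target is retired when the trace of
#'   the positional 3x3 covariance block exceeds this value (m^2).
#' @param max_frames_unobserved a target is also retired after more than
#'   this many consecutive frames without any observation.
#' @param max_birth_combinations cap on triangulation hypotheses evaluated
#'   per frame; excess hypotheses are deferred to the next frame.
#' @return list of class `gating_params`.
#' @export
gating_params <- function(max_pixel_dist = 20, min_area = 1,
                          max_reproj_error_birth = 3,
                          max_covariance_trace_death = 0.1,
                          max_frames_unobserved = 10L,
                          max_birth_combinations = 10000L) {
  stopifnot(max_pixel_dist > 0, min_area >= 0, max_reproj_error_birth > 0,
            max_covariance_trace_death > 0, max_frames_unobserved >= 1)
  structure(
    list(max_pixel_dist = max_pixel_dist, min_area = min_area,
         max_reproj_error_birth = max_reproj_error_birth,
         max_covariance_trace_death = max_covariance_trace_death,
         max_frames_unobserved = as.integer(max_frames_unobserved),
         max_birth_combinations = as.integer(max_birth_combinations)),
    class = "gating_params"
  )
}

#' Image-distance gate
#'
#' Indicator: 1 if the Euclidean pixel distance between a detection and the
#' projection of the predicted target position is at most
#' `max_pixel_dist` (inclusive at the boundary), else 0.
#'
#' @param feature_uv detection `c(u, v)` in the distortion-corrected frame.
#' @param predicted_pixel projected prior `c(u, v)` in the same frame.
#' @param params a [gating_params].
#' @return 0 or 1.
#' @export
pixel_gate <- function(feature_uv, predicted_pixel, params) {
  d <- sqrt(sum((as.numeric(feature_uv[1:2]) -
                   as.numeric(predicted_pixel[1:2]))^2))
  as.integer(d <= params$max_pixel_dist)
}

#' Blob-area gate
#'
#' Indicator: 1 iff the detection's area statistic `alpha` is strictly
#' greater than `min_area`.
#'
#' @param alpha detection area statistic (px^2-scaled difference mass).
#' @param params a [gating_params].
#' @return 0 or 1.
#' @export
area_gate <- function(alpha, params) {
  as.integer(alpha > params$min_area)
}

#' Mahalanobis distance
#'
#' `sqrt((a - mean)' cov^-1 (a - mean))` for a positive-definite 3x3
#' covariance.
#'
#' @param a length-3 point.
#' @param mean length-3 expected value.
#' @param cov 3x3 positive-definite covariance matrix.
#' @return non-negative scalar; 0 iff `a == mean`.
#' @export
mahalanobis_distance <- function(a, mean, cov) {
  d <- as.numeric(a) - as.numeric(mean)
  q <- tryCatch(drop(t(d) %*% solve(cov, d)),
                error = function(e) stop("singular covariance matrix"))
  sqrt(max(q, 0))
}

#' Closest point on a ray under a Mahalanobis metric
#'
#' For the parametrized line `L(s) = origin + s * direction`, returns the
#' point minimizing the Mahalanobis distance to `mean` under `cov`. The
#' minimizer is the closed-form zero of the derivative,
#' `s* = d' cov^-1 (mean - origin) / (d' cov^-1 d)`. With `cov = I` this is
#' the orthogonal projection of `mean` onto the ray.
#'
#' @param ray a `ray` (list with `origin`, unit `direction`).
#' @param mean length-3 expected position.
#' @param cov 3x3 symmetric positive-definite covariance.
#' @return length-3 point on the ray.
#' @export
closest_point_on_ray <- function(ray, mean, cov) {
  W <- tryCatch(solve(cov), error = function(e) stop("singular covariance"))
  d <- ray$direction
  denom <- drop(t(d) %*% W %*% d)
  if (denom <= 0) stop("covariance is not positive-definite along the ray")
  s <- drop(t(d) %*% W %*% (as.numeric(mean) - ray$origin)) / denom
  ray$origin + s * d
}

#' Likelihood score of a detection for a target
#'
#' The product of the image-distance gate, the area gate and a Gaussian
#' kernel `exp(-d_mahal^2 / 2)` of the Mahalanobis distance from the prior
#' mean to the closest point on the detection's back-projected ray, under
#' the prior's positional covariance. If either gate is zero the expensive
#' ray term is never evaluated (short-circuit), and the score is 0.
#'
#' @param feature one-row data frame (or list) with `u`, `v`, `alpha`.
#' @param target a predicted (prior) [target_model].
#' @param camera the [camera_model] that produced the detection.
#' @param params a [gating_params].
#' @param instrumentation optional environment; if supplied, its
#'   `ray_evals` counter is incremented each time the ray term is computed.
#' @return non-negative score; higher is more likely.
#' @export
feature_likelihood <- function(feature, target, camera, params,
                               instrumentation = NULL) {
  predicted_pixel <- tryCatch(project(camera, target$state[1:3]),
                              error = function(e) NULL)
  if (is.null(predicted_pixel)) return(0)
  g1 <- pixel_gate(c(feature$u, feature$v), predicted_pixel, params)
  if (g1 == 0) return(0)
  g2 <- area_gate(feature$alpha, params)
  if (g2 == 0) return(0)
  if (!is.null(instrumentation)) {
    instrumentation$ray_evals <-
      (instrumentation$ray_evals %||% 0L) + 1L
  }
  ray <- ray_from_pixel(camera, c(feature$u, feature$v))
  mean3 <- target$state[1:3]
  cov3 <- target$P[1:3, 1:3]
  a <- closest_point_on_ray(ray, mean3, cov3)
  dm <- mahalanobis_distance(a, mean3, cov3)
  exp(-0.5 * dm^2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' NNSF assignment of detections to targets
#'
#' Independently for each target and each camera, assigns the feature index
#' maximizing [feature_likelihood] provided the score is positive; ties are
#' broken toward the lowest feature index. The result is one assignment
#' vector per target: length `n_cameras`, entries `NA` (no contribution)
#' or the row index into that camera's feature table.
#'
#' @param targets list of predicted (prior) [target_model]s.
#' @param features_by_camera list (aligned with `cameras`) of per-camera
#'   feature data frames.
#' @param cameras list of [camera_model]s.
#' @param params a [gating_params].
#' @return list of integer vectors (one per target, `NA` = null).
#' @export
associate <- function(targets, features_by_camera, cameras, params) {
  n_cam <- length(cameras)
  lapply(targets, function(tg) {
    d <- rep(NA_integer_, n_cam)
    for (i in seq_len(n_cam)) {
      feats <- features_by_camera[[i]]
      if (is.null(feats) || nrow(feats) == 0L) next
      scores <- vapply(seq_len(nrow(feats)), function(j) {
        feature_likelihood(feats[j, ], tg, cameras[[i]], params)
      }, numeric(1))
      if (any(scores > 0)) {
        d[i] <- which.max(scores)
      }
    }
    d
  })
}

#' Merge prevention for identical assignment sets
#'
#' When two or more targets are assigned the exact same non-empty set of
#' feature points, only the target whose predicted observation is closest
#' (summed image distance between projected prior positions and the
#' assigned detections) keeps the assignment; the others are stripped to
#' all-null vectors and will be updated without any observation. Exact
#' distance ties go to the lowest target id.
#'
#' @param targets list of predicted [target_model]s.
#' @param assignments list of assignment vectors from [associate].
#' @param features_by_camera per-camera feature data frames.
#' @param cameras list of [camera_model]s.
#' @return the resolved list of assignment vectors.
#' @export
resolve_shared <- function(targets, assignments, features_by_camera,
                           cameras) {
  if (length(targets) < 2L) return(assignments)
  keys <- vapply(assignments, function(d) {
    used <- which(!is.na(d))
    if (length(used) == 0L) return("")
    paste(used, d[used], sep = ":", collapse = ",")
  }, character(1))
  for (key in unique(keys[nzchar(keys)])) {
    members <- which(keys == key)
    if (length(members) < 2L) next
    dists <- vapply(members, function(m) {
      d <- assignments[[m]]
      total <- 0
      for (i in which(!is.na(d))) {
        pred <- tryCatch(project(cameras[[i]], targets[[m]]$state[1:3]),
                         error = function(e) c(Inf, Inf))
        f <- features_by_camera[[i]][d[i], ]
        total <- total + sqrt(sum((pred - c(f$u, f$v))^2))
      }
      total
    }, numeric(1))
    ids <- vapply(members, function(m) targets[[m]]$id, integer(1))
    keep <- members[order(dists, ids)][1]
    for (m in setdiff(members, keep)) {
      assignments[[m]] <- rep(NA_integer_, length(assignments[[m]]))
    }
  }
  assignments
}

# Enumerate birth hypotheses: all combinations of >= 2 cameras, one
# unclaimed feature per chosen camera. Returns a list of hypotheses, each
# list(cams = integer camera indices, feats = integer feature indices).
enumerate_birth_hypotheses <- function(counts, max_combinations) {
  n <- length(counts)
  with_feats <- which(counts > 0L)
  hypotheses <- list()
  overflow <- FALSE
  if (length(with_feats) < 2L) {
    return(list(hypotheses = hypotheses, overflow = FALSE))
  }
  for (k in rev(seq(2L, length(with_feats)))) {
    combos <- utils::combn(with_feats, k, simplify = FALSE)
    for (cams in combos) {
      grid <- expand.grid(lapply(counts[cams], seq_len),
                          KEEP.OUT.ATTRS = FALSE)
      for (r in seq_len(nrow(grid))) {
        if (length(hypotheses) >= max_combinations) {
          overflow <- TRUE
          break
        }
        hypotheses[[length(hypotheses) + 1L]] <-
          list(cams = cams, feats = as.integer(grid[r, ]))
      }
      if (overflow) break
    }
    if (overflow) break
  }
  list(hypotheses = hypotheses, overflow = overflow)
}

#' Initiate new targets from unclaimed detections
#'
#' Unguided hypothesis testing: every combination of 2, 3, ..., n cameras
#' with one unclaimed feature per chosen camera is triangulated. Among
#' hypotheses whose mean reprojection error is below
#' `max_reproj_error_birth`, the one using the greatest number of cameras
#' (ties: lowest error) seeds a new target at the triangulated position
#' with zero velocity and a relatively high error estimate; its features
#' are removed and the search repeats until no valid hypothesis remains.
#' The number of hypotheses evaluated per frame is capped at
#' `max_birth_combinations`; excess detections wait for the next frame.
#'
#' @param features_by_camera per-camera data frames of unclaimed features.
#' @param cameras list of [camera_model]s.
#' @param params a [gating_params].
#' @param next_id integer id for the first new target.
#' @param birth_frame frame index recorded on new targets.
#' @param pos_var,vel_var initial covariance diagonal for new targets.
#' @return list with `targets` (possibly empty list of new
#'   [target_model]s), `used` (data frame `camera_index, feature_index,
#'   target_id`), and `overflow` flag.
#' @export
spawn_targets <- function(features_by_camera, cameras, params, next_id,
                          birth_frame = NA_integer_, pos_var = 0.01,
                          vel_var = 1) {
  n <- length(cameras)
  counts <- vapply(features_by_camera, function(f) {
    if (is.null(f)) 0L else nrow(f)
  }, integer(1))
  enum <- enumerate_birth_hypotheses(counts, params$max_birth_combinations)
  hyps <- enum$hypotheses
  used <- data.frame(camera_index = integer(0), feature_index = integer(0),
                     target_id = integer(0))
  new_targets <- list()
  if (length(hyps) == 0L) {
    return(list(targets = new_targets, used = used,
                overflow = enum$overflow))
  }
  evals <- lapply(hyps, function(h) {
    obs <- lapply(seq_along(h$cams), function(j) {
      f <- features_by_camera[[h$cams[j]]][h$feats[j], ]
      list(camera = cameras[[h$cams[j]]], point = c(f$u, f$v))
    })
    tryCatch(triangulate(obs), error = function(e) NULL)
  })
  valid <- vapply(evals, function(e) {
    !is.null(e) && e$reproj_error_px < params$max_reproj_error_birth
  }, logical(1))
  claimed <- matrix(FALSE, n, max(c(counts, 1L)))
  repeat {
    alive <- which(valid)
    if (length(alive) == 0L) break
    ncams <- vapply(hyps[alive], function(h) length(h$cams), integer(1))
    errs <- vapply(evals[alive], function(e) e$reproj_error_px, numeric(1))
    best <- alive[order(-ncams, errs)][1]
    h <- hyps[[best]]
    tg <- new_target(next_id, evals[[best]]$point, birth_frame,
                     pos_var = pos_var, vel_var = vel_var)
    new_targets[[length(new_targets) + 1L]] <- tg
    used <- rbind(used, data.frame(camera_index = h$cams,
                                   feature_index = h$feats,
                                   target_id = next_id))
    next_id <- next_id + 1L
    for (j in seq_along(h$cams)) claimed[h$cams[j], h$feats[j]] <- TRUE
    valid <- valid & vapply(hyps, function(hh) {
      !any(claimed[cbind(hh$cams, hh$feats)])
    }, logical(1))
  }
  list(targets = new_targets, used = used, overflow = enum$overflow)
}

#' Retire targets with excessive uncertainty
#'
#' A target is removed when the trace of its positional covariance block
#' exceeds `max_covariance_trace_death`, or when it has gone more than
#' `max_frames_unobserved` consecutive frames without an observation.
#' Retirement is permanent: a re-detected animal starts a new identity.
#'
#' @param targets list of [target_model]s, updated for this frame.
#' @param params a [gating_params].
#' @return list with `kept` and `retired` target lists.
#' @export
retire_targets <- function(targets, params) {
  dead <- vapply(targets, function(tg) {
    ptrace <- sum(diag(tg$P)[1:3])
    ptrace > params$max_covariance_trace_death ||
      tg$frames_since_observation > params$max_frames_unobserved
  }, logical(1))
  list(kept = targets[!dead], retired = targets[dead])
}
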