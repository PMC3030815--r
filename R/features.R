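# 2D feature extraction: running-Gaussian background subtraction and
# image-moment statistics of difference blobs.
#
# Frames are numeric matrices indexed [row, col]; pixel (u, v) = (0, 0) is
# the centre of the top-left pixel, so matrix element [r, c] sits at
# (u, v) = (c - 1, r - 1).

#' Initialize a running-Gaussian background model
#'
#' Maintains per-pixel estimates of the background luminance mean and
#' variance, updated slowly so that targets moving through the scene do not
#' contaminate the background.
#'
#' @param frame an initial frame (numeric matrix) used to seed the mean.
#' @param update_interval frames between updates; the model is refreshed
#'   only on frames whose index is a multiple of this interval (default 500).
#' @param learning_rate exponential forgetting factor in (0, 1].
#' @return list of class `background_model` with `mean`, `variance`,
#'   `update_interval`, `learning_rate`.
#' @export
background_model <- function(frame, update_interval = 500L,
                             learning_rate = 0.5) {
  frame <- as.matrix(frame)
  stopifnot(learning_rate > 0, learning_rate <= 1, update_interval >= 1)
  structure(
    list(mean = frame, variance = matrix(0, nrow(frame), ncol(frame)),
         update_interval = as.integer(update_interval),
         learning_rate = learning_rate),
    class = "background_model"
  )
}

#' Update the background model with a new frame
#'
#' Exponential update `mean <- (1 - lambda) mean + lambda frame`, and the
#' variance analogously on the squared residual about the updated mean.
#' When `frame_index` is supplied, the update is applied only when
#' `frame_index %% update_interval == 0`; otherwise the model is returned
#' unchanged.
#'
#' @param bg a [background_model].
#' @param frame numeric matrix, same shape as the model.
#' @param frame_index optional frame counter implementing the interval rule;
#'   `NULL` forces an update.
#' @return the updated `background_model`.
#' @export
update_background <- function(bg, frame, frame_index = NULL) {
  frame <- as.matrix(frame)
  if (!all(dim(frame) == dim(bg$mean))) {
    stop("frame shape does not match background model")
  }
  if (!is.null(frame_index) && (frame_index %% bg$update_interval) != 0) {
    return(bg)
  }
  lam <- bg$learning_rate
  bg$mean <- (1 - lam) * bg$mean + lam * frame
  resid2 <- (frame - bg$mean)^2
  bg$variance <- (1 - lam) * bg$variance + lam * resid2
  bg
}

#' Feature-extraction parameters
#'
#' @param detect_threshold absolute-difference threshold for candidate
#'   pixels (luminance units of the frames).
#' @param clear_fraction pixels below this fraction of the blob peak are
#'   zeroed before moment analysis, suppressing spurious moment arms
#'   (default 0.3).
#' @param roi_radius half-size in px of the square analysis window centred
#'   on the blob peak.
#' @param max_features_per_camera at most this many features are returned
#'   per frame, brightest (largest peak difference) first.
#' @param threshold_mode `"absolute"` (default) thresholds the difference
#'   image at `detect_threshold`; `"sigma"` uses a per-pixel threshold of
#'   `k_sigma` background standard deviations (floored at
#'   `detect_threshold`).
#' @param k_sigma multiplier for `threshold_mode = "sigma"`.
#' @return list of class `extraction_params`.
#' @export
extraction_params <- function(detect_threshold, clear_fraction = 0.3,
                              roi_radius = 10L, max_features_per_camera = 10L,
                              threshold_mode = c("absolute", "sigma"),
                              k_sigma = 5) {
  stopifnot(detect_threshold > 0, clear_fraction > 0, clear_fraction < 1,
            roi_radius >= 1)
  structure(
    list(detect_threshold = detect_threshold,
         clear_fraction = clear_fraction,
         roi_radius = as.integer(roi_radius),
         max_features_per_camera = as.integer(max_features_per_camera),
         threshold_mode = match.arg(threshold_mode),
         k_sigma = k_sigma),
    class = "extraction_params"
  )
}

# 8-connected component labelling of a logical matrix; returns an integer
# matrix of labels (0 = background). Iterative flood fill, no recursion.
label_components <- function(mask) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  labels <- matrix(0L, nr, nc)
  next_label <- 0L
  idx <- which(mask)
  for (start in idx) {
    if (labels[start] != 0L) next
    next_label <- next_label + 1L
    stack <- start
    labels[start] <- next_label
    while (length(stack) > 0L) {
      cur <- stack[length(stack)]
      stack <- stack[-length(stack)]
      r <- ((cur - 1L) %% nr) + 1L
      c <- ((cur - 1L) %/% nr) + 1L
      for (dc in -1:1) {
        cc <- c + dc
        if (cc < 1L || cc > nc) next
        for (dr in -1:1) {
          rr <- r + dr
          if (rr < 1L || rr > nr) next
          nb <- (cc - 1L) * nr + rr
          if (mask[nb] && labels[nb] == 0L) {
            labels[nb] <- next_label
            stack <- c(stack, nb)
          }
        }
      }
    }
  }
  labels
}

#' Image-moment statistics of a difference patch
#'
#' Computes the 0th moment (total difference mass `alpha`), the 1st-moment
#' centre, and from the central second moments the principal-axis slope
#' angle `theta` in `[0, pi)` and an eccentricity
#' `epsilon = sqrt(1 - lambda2 / lambda1)` from the eigenvalues
#' `lambda1 >= lambda2` of the normalized second-moment matrix. A patch
#' with no spatial extent (single pixel, or degenerate mass) returns
#' `theta = 0`, `epsilon = 0`.
#'
#' @param patch non-negative numeric matrix, not all zero.
#' @param origin `(u, v)` of the patch's top-left pixel in image
#'   coordinates (default `c(0, 0)`).
#' @return list with `alpha`, `centre` (length-2 `(u, v)`), `theta`,
#'   `epsilon`.
#' @export
moment_statistics <- function(patch, origin = c(0, 0)) {
  patch <- as.matrix(patch)
  if (any(patch < 0)) stop("patch must be non-negative")
  alpha <- sum(patch)
  if (alpha <= 0) stop("patch is all zero; moments undefined")
  nr <- nrow(patch)
  nc <- ncol(patch)
  u <- origin[1] + (col(patch) - 1)
  v <- origin[2] + (row(patch) - 1)
  cu <- sum(patch * u) / alpha
  cv <- sum(patch * v) / alpha
  mu20 <- sum(patch * (u - cu)^2) / alpha
  mu02 <- sum(patch * (v - cv)^2) / alpha
  mu11 <- sum(patch * (u - cu) * (v - cv)) / alpha
  M <- matrix(c(mu20, mu11, mu11, mu02), 2, 2)
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  lam1 <- max(ev[1], 0)
  lam2 <- max(ev[2], 0)
  if (lam1 < 1e-12) {
    theta <- 0
    epsilon <- 0
  } else {
    if (abs(mu20 - mu02) < 1e-15 && abs(mu11) < 1e-15) {
      theta <- 0   # isotropic: orientation undefined, report 0
    } else {
      theta <- 0.5 * atan2(2 * mu11, mu20 - mu02)
      if (theta < 0) theta <- theta + pi
      if (theta >= pi) theta <- theta - pi
    }
    epsilon <- sqrt(max(0, 1 - lam2 / lam1))
  }
  list(alpha = alpha, centre = c(u = cu, v = cv), theta = theta,
       epsilon = epsilon)
}

#' Extract 2D features from a frame by background subtraction
#'
#' Forms the absolute difference between the frame and the background mean,
#' thresholds it, and for each 8-connected suprathreshold region analyses a
#' square window around the region's peak: pixels below
#' `clear_fraction * beta` (where `beta` is the peak absolute difference)
#' are zeroed and image moments of the remaining difference mass give the
#' sub-pixel centre, total mass `alpha`, orientation `theta` and
#' eccentricity `epsilon`. Centres are distortion-corrected when the camera
#' carries a distortion model.
#'
#' @param frame numeric matrix.
#' @param bg a [background_model] with matching shape.
#' @param params an [extraction_params].
#' @param camera optional [camera_model] used for undistortion and the
#'   `camera_id` column.
#' @param frame_index frame counter stored in the output.
#' @return data frame with columns
#'   `frame, camera_id, u, v, alpha, beta, theta, epsilon`, at most
#'   `max_features_per_camera` rows, sorted by `beta` decreasing. Zero rows
#'   is a valid result.
#' @export
extract_features <- function(frame, bg, params, camera = NULL,
                             frame_index = NA_integer_) {
  frame <- as.matrix(frame)
  if (!all(dim(frame) == dim(bg$mean))) {
    stop("frame shape does not match background model")
  }
  diffim <- abs(frame - bg$mean)
  if (params$threshold_mode == "sigma") {
    thr <- pmax(params$k_sigma * sqrt(bg$variance), params$detect_threshold)
    mask <- diffim > thr
  } else {
    mask <- diffim > params$detect_threshold
  }
  cam_id <- if (is.null(camera)) NA_character_ else camera$id
  empty <- data.frame(
    frame = integer(0), camera_id = character(0), u = numeric(0),
    v = numeric(0), alpha = numeric(0), beta = numeric(0),
    theta = numeric(0), epsilon = numeric(0), stringsAsFactors = FALSE
  )
  if (!any(mask)) return(empty)
  labels <- label_components(mask)
  nlab <- max(labels)
  nr <- nrow(frame)
  nc <- ncol(frame)
  feats <- vector("list", nlab)
  for (k in seq_len(nlab)) {
    comp <- which(labels == k)
    peak <- comp[which.max(diffim[comp])]
    beta <- diffim[peak]
    pr <- ((peak - 1L) %% nr) + 1L
    pc <- ((peak - 1L) %/% nr) + 1L
    r0 <- max(1L, pr - params$roi_radius)
    r1 <- min(nr, pr + params$roi_radius)
    c0 <- max(1L, pc - params$roi_radius)
    c1 <- min(nc, pc + params$roi_radius)
    patch <- diffim[r0:r1, c0:c1, drop = FALSE]
    patch[patch < params$clear_fraction * beta] <- 0
    if (sum(patch) <= 0) next
    m <- moment_statistics(patch, origin = c(c0 - 1, r0 - 1))
    uv <- m$centre
    if (!is.null(camera) && !is.null(camera$distortion)) {
      uv <- undistort_point(camera, uv)
    }
    feats[[k]] <- data.frame(
      frame = frame_index, camera_id = cam_id, u = uv[1], v = uv[2],
      alpha = m$alpha, beta = beta, theta = m$theta, epsilon = m$epsilon,
      stringsAsFactors = FALSE
    )
  }
  feats <- feats[!vapply(feats, is.null, logical(1))]
  if (length(feats) == 0L) return(empty)
  out <- do.call(rbind, feats)
  out <- out[order(-out$beta), , drop = FALSE]
  if (nrow(out) > params$max_features_per_camera) {
    out <- out[seq_len(params$max_features_per_camera), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Read a grayscale frame from PNG or TIFF
#'
#' Multi-channel images are averaged to a single luminance channel. Values
#' are returned in `[0, 1]` as read by the underlying decoder.
#'
#' @param path image file (`.png`, `.tif`, `.tiff`).
#' @return numeric matrix.
#' @export
read_frame <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported frame format: ", ext)
  )
  if (length(dim(img)) == 3L) {
    img <- apply(img[, , seq_len(min(3L, dim(img)[3])), drop = FALSE],
                 c(1, 2), mean)
  }
  img
}

#' Write a grayscale frame to PNG or TIFF
#'
#' @param frame numeric matrix; values are clamped to `[0, 1]`.
#' @param path output path (`.png`, `.tif`, `.tiff`).
#' @export
write_frame <- function(frame, path) {
  frame <- pmin(pmax(as.matrix(frame), 0), 1)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(frame, path),
    tif = ,
    tiff = tiff::writeTIFF(frame, path),
    stop("unsupported frame format: ", ext)
  )
  invisible(path)
}

#' Read a feature table from CSV
#'
#' @param path CSV with header `frame,camera_id,u,v,alpha,beta,theta,epsilon`.
#' @return data frame of features.
#' @export
read_features <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("frame", "camera_id", "u", "v", "alpha", "beta", "theta",
              "epsilon")
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0L) {
    stop("feature table ", path, " lacks columns: ",
         paste(missing, collapse = ", "))
  }
  df$camera_id <- as.character(df$camera_id)
  df[needed]
}

#' Write a feature table to CSV
#'
#' @param features data frame as produced by [extract_features].
#' @param path output CSV path.
#' @export
write_features <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
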