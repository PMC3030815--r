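# Projective camera geometry: pinhole model, radial distortion, rays,
# linear triangulation and DLT calibration.

#' Construct a pinhole camera model
#'
#' A camera is described by a 3x4 projection matrix `P` mapping homogeneous
#' world points (metres) to homogeneous pixel coordinates, optionally with a
#' two-term radial distortion model `r_d = r (1 + k1 r^2 + k2 r^4)` about a
#' distortion centre `(cx, cy)`.
#'
#' Pixel convention: `(0, 0)` is the centre of the top-left pixel, `u`
#' increases rightward and `v` downward, with continuous sub-pixel
#' coordinates.
#'
#' @param id camera label (coerced to character).
#' @param P numeric 3x4 projection matrix of rank 3.
#' @param distortion `NULL` for a pure pinhole camera, or a list/vector with
#'   elements `k1`, `k2`, `cx`, `cy`.
#' @param image_size optional integer `c(width, height)` in pixels.
#' @return An object of class `camera_model`.
#' @export
camera_model <- function(id, P, distortion = NULL, image_size = NULL) {
  P <- as.matrix(P)
  if (!all(dim(P) == c(3L, 4L))) {
    stop("P must be a 3x4 matrix")
  }
  if (!all(is.finite(P))) {
    stop("P must be finite")
  }
  if (qr(P)$rank < 3L) {
    stop("P must have rank 3")
  }
  if (!is.null(distortion)) {
    distortion <- as.list(distortion)
    for (nm in c("k1", "k2", "cx", "cy")) {
      if (is.null(distortion[[nm]])) {
        stop("distortion must supply k1, k2, cx, cy")
      }
    }
    distortion <- list(
      k1 = as.numeric(distortion$k1), k2 = as.numeric(distortion$k2),
      cx = as.numeric(distortion$cx), cy = as.numeric(distortion$cy)
    )
  }
  if (!is.null(image_size)) {
    image_size <- as.numeric(image_size)
    stopifnot(length(image_size) == 2L, all(image_size > 0))
  }
  structure(
    list(id = as.character(id), P = P, distortion = distortion,
         image_size = image_size),
    class = "camera_model"
  )
}

#' @export
print.camera_model <- function(x, ...) {
  cat("<camera_model>", x$id, "\n")
  cat("  P:\n")
  print(unname(x$P))
  if (!is.null(x$distortion)) {
    cat(sprintf("  distortion: k1=%g k2=%g centre=(%g, %g)\n",
                x$distortion$k1, x$distortion$k2,
                x$distortion$cx, x$distortion$cy))
  }
  if (!is.null(x$image_size)) {
    cat(sprintf("  image size: %g x %g px\n",
                x$image_size[1], x$image_size[2]))
  }
  invisible(x)
}

#' Camera centre
#'
#' The camera centre `C` is the (dehomogenized) right null vector of `P`,
#' i.e. the unique point with `P \%*\% c(C, 1) = 0`.
#'
#' @param camera a [camera_model].
#' @return numeric length-3 centre in world coordinates (m).
#' @export
camera_centre <- function(camera) {
  sv <- svd(camera$P, nu = 0, nv = 4)
  v <- sv$v[, 4]
  if (abs(v[4]) < 1e-12 * max(abs(v))) {
    stop("camera centre at infinity")
  }
  v[1:3] / v[4]
}

#' Project a 3D point into a camera
#'
#' Dehomogenizes `P \%*\% (x, y, z, 1)`. With a distortion model present the
#' returned coordinates are in the ideal (distortion-corrected) pixel frame;
#' applying distortion is a separate step ([distort_point]).
#'
#' @param camera a [camera_model].
#' @param point numeric length-3 vector, or an n x 3 matrix of points.
#' @return numeric `c(u, v)`, or an n x 2 matrix.
#' @export
project <- function(camera, point) {
  if (is.matrix(point)) {
    stopifnot(ncol(point) == 3L)
    Xh <- cbind(point, 1)
    x <- Xh %*% t(camera$P)
    w <- x[, 3]
    if (any(abs(w) <= 1e-12 * pmax(1, abs(x[, 1]), abs(x[, 2])))) {
      stop("degenerate projection: point on the principal plane of camera ",
           camera$id)
    }
    return(cbind(u = x[, 1] / w, v = x[, 2] / w))
  }
  stopifnot(length(point) == 3L)
  x <- drop(camera$P %*% c(point, 1))
  if (abs(x[3]) <= 1e-12 * max(1, abs(x[1]), abs(x[2]))) {
    stop("degenerate projection: point on the principal plane of camera ",
         camera$id)
  }
  c(u = x[1] / x[3], v = x[2] / x[3])
}

#' Apply the radial distortion model
#'
#' Maps ideal (distortion-corrected) pixel coordinates to raw distorted ones
#' using `r_d = r (1 + k1 r^2 + k2 r^4)` about the distortion centre.
#' Cameras without a distortion model use the identity.
#'
#' @param camera a [camera_model].
#' @param point numeric `c(u, v)` or n x 2 matrix of ideal coordinates.
#' @return distorted coordinates, same shape as `point`.
#' @export
distort_point <- function(camera, point) {
  d <- camera$distortion
  if (is.null(d)) return(point)
  pt <- if (is.matrix(point)) point else matrix(point, ncol = 2)
  du <- pt[, 1] - d$cx
  dv <- pt[, 2] - d$cy
  r2 <- du^2 + dv^2
  s <- 1 + d$k1 * r2 + d$k2 * r2^2
  out <- cbind(d$cx + du * s, d$cy + dv * s)
  if (is.matrix(point)) out else drop(out)
}

#' Invert the radial distortion model
#'
#' Recovers ideal pixel coordinates from raw ones by fixed-point iteration
#' on the undistorted radius (`r <- r_d / (1 + k1 r^2 + k2 r^4)`),
#' tolerance 1e-8 px, at most 20 iterations. With `k1 = k2 = 0` the result
#' equals the input.
#'
#' @param camera a [camera_model] (no distortion model means identity).
#' @param raw numeric `c(u, v)` or n x 2 matrix of raw coordinates.
#' @param tol convergence tolerance in pixels.
#' @param max_iter maximum fixed-point iterations.
#' @return undistorted coordinates, same shape as `raw`.
#' @export
undistort_point <- function(camera, raw, tol = 1e-8, max_iter = 20L) {
  d <- camera$distortion
  if (is.null(d) || (d$k1 == 0 && d$k2 == 0)) return(raw)
  pt <- if (is.matrix(raw)) raw else matrix(raw, ncol = 2)
  du <- pt[, 1] - d$cx
  dv <- pt[, 2] - d$cy
  rd <- sqrt(du^2 + dv^2)
  r <- rd
  converged <- rd == 0
  for (i in seq_len(max_iter)) {
    s <- 1 + d$k1 * r^2 + d$k2 * r^4
    r_new <- rd / s
    converged <- converged | abs(r_new - r) < tol
    r <- r_new
    if (all(converged)) break
  }
  if (!all(converged)) {
    stop(sprintf(
      "undistortion did not converge within %d iterations (max residual %.3g px)",
      max_iter, max(abs(rd / (1 + d$k1 * r^2 + d$k2 * r^4) - r))
    ))
  }
  scale <- ifelse(rd > 0, r / rd, 1)
  out <- cbind(d$cx + du * scale, d$cy + dv * scale)
  if (is.matrix(raw)) out else drop(out)
}

#' Back-project a pixel to a 3D ray
#'
#' Returns the half-line from the camera centre through the given
#' (distortion-corrected) pixel: for every `s > 0`,
#' `project(camera, origin + s * direction)` equals `pixel`.
#'
#' @param camera a [camera_model].
#' @param pixel numeric `c(u, v)`, distortion-corrected.
#' @return A list of class `ray` with `origin` (camera centre, m) and unit
#'   `direction`.
#' @export
ray_from_pixel <- function(camera, pixel) {
  M <- camera$P[, 1:3]
  if (rcond(M) < 1e-14) {
    stop("left 3x3 block of P is rank-deficient; cannot back-project")
  }
  centre <- drop(-solve(M, camera$P[, 4]))
  dir <- drop(solve(M, c(pixel[1], pixel[2], 1)))
  n <- sqrt(sum(dir^2))
  if (n == 0) stop("degenerate back-projection")
  structure(list(origin = centre, direction = dir / n), class = "ray")
}

#' Triangulate a 3D point from multi-camera observations
#'
#' Linear (DLT-style) triangulation: stacks the cross-product constraints
#' `u (p3 . X) - (p1 . X) = 0`, `v (p3 . X) - (p2 . X) = 0` for every
#' camera and takes the right singular vector of the smallest singular
#' value. No iterative refinement.
#'
#' @param observations list of `list(camera = <camera_model>,
#'   point = c(u, v))`, pixels distortion-corrected; at least two distinct
#'   cameras with non-parallel rays.
#' @return list with `point` (length-3, m) and `reproj_error_px`, the mean
#'   Euclidean reprojection error over the contributing cameras.
#' @export
triangulate <- function(observations) {
  if (length(observations) < 2L) {
    stop("triangulation requires at least 2 camera observations")
  }
  ids <- vapply(observations, function(o) o$camera$id, character(1))
  if (length(unique(ids)) < 2L) {
    stop("triangulation requires observations from at least 2 distinct cameras")
  }
  rays <- lapply(observations, function(o) ray_from_pixel(o$camera, o$point))
  max_angle <- 0
  for (i in seq_along(rays)) {
    for (j in seq_len(i - 1L)) {
      cosang <- abs(sum(rays[[i]]$direction * rays[[j]]$direction))
      max_angle <- max(max_angle, acos(min(1, cosang)))
    }
  }
  if (max_angle < 1e-10) {
    stop("degenerate configuration: all back-projected rays are parallel")
  }
  A <- do.call(rbind, lapply(observations, function(o) {
    P <- o$camera$P
    u <- o$point[1]
    v <- o$point[2]
    rbind(u * P[3, ] - P[1, ], v * P[3, ] - P[2, ])
  }))
  sv <- svd(A, nu = 0, nv = 4)
  X <- sv$v[, 4]
  if (abs(X[4]) < 1e-12 * max(abs(X))) {
    stop("triangulated point at infinity (near-parallel rays)")
  }
  pt <- X[1:3] / X[4]
  errs <- vapply(observations, function(o) {
    uv <- project(o$camera, pt)
    sqrt(sum((uv - o$point)^2))
  }, numeric(1))
  list(point = pt, reproj_error_px = mean(errs))
}

#' Estimate a camera projection matrix by DLT
#'
#' Direct linear transformation: given >= 6 non-coplanar 3D-2D
#' correspondences, finds the 3x4 matrix minimizing the algebraic error of
#' the homogeneous projection constraints, with Hartley normalization of
#' both point sets. The result is scaled to unit Frobenius norm.
#'
#' @param points3d n x 3 matrix of world points (m).
#' @param points2d n x 2 matrix of matching (distortion-corrected) pixels.
#' @param id label for the returned camera.
#' @param image_size optional `c(width, height)` passed through.
#' @return A [camera_model] (no distortion model).
#' @export
dlt_calibrate <- function(points3d, points2d, id = "dlt", image_size = NULL) {
  points3d <- as.matrix(points3d)
  points2d <- as.matrix(points2d)
  n <- nrow(points3d)
  if (nrow(points2d) != n) stop("correspondence count mismatch")
  if (n < 6L) stop("DLT calibration requires at least 6 correspondences")
  ctr3 <- colMeans(points3d)
  X0 <- sweep(points3d, 2, ctr3)
  svX <- svd(X0, nu = 0, nv = 0)
  if (svX$d[3] < 1e-10 * max(svX$d[1], 1)) {
    stop("degenerate correspondences: 3D points are coplanar")
  }
  # Hartley normalization
  s3 <- sqrt(3) / mean(sqrt(rowSums(X0^2)))
  T3 <- diag(c(s3, s3, s3, 1))
  T3[1:3, 4] <- -s3 * ctr3
  ctr2 <- colMeans(points2d)
  U0 <- sweep(points2d, 2, ctr2)
  s2 <- sqrt(2) / mean(sqrt(rowSums(U0^2)))
  T2 <- diag(c(s2, s2, 1))
  T2[1:2, 3] <- -s2 * ctr2
  Xn <- cbind(s3 * X0, 1)
  Un <- s2 * U0
  A <- matrix(0, 2L * n, 12L)
  for (i in seq_len(n)) {
    X <- Xn[i, ]
    u <- Un[i, 1]
    v <- Un[i, 2]
    A[2L * i - 1L, ] <- c(X, rep(0, 4), -u * X)
    A[2L * i, ] <- c(rep(0, 4), X, -v * X)
  }
  sv <- svd(A, nu = 0, nv = 12)
  Pn <- matrix(sv$v[, 12], 3, 4, byrow = TRUE)
  P <- solve(T2) %*% Pn %*% T3
  P <- P / sqrt(sum(P^2))
  # fix the overall sign so that points project with positive depth
  w <- drop(P %*% c(points3d[1, ], 1))[3]
  if (w < 0) P <- -P
  camera_model(id, P, image_size = image_size)
}

#' Read camera models from a plain-text file
#'
#' One camera per block: a `camera <id>` line, three whitespace-separated
#' rows of the projection matrix, then optional `distortion k1 k2 cx cy`
#' and `image_size w h` lines. Blocks are separated by blank lines.
#'
#' @param path file path.
#' @return named list of [camera_model]s (names are camera ids).
#' @export
read_cameras <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[!grepl("^#", lines)]
  starts <- grep("^camera\\s+", lines)
  if (length(starts) == 0L) stop("no 'camera <id>' blocks found in ", path)
  bounds <- c(starts, length(lines) + 1L)
  cams <- vector("list", length(starts))
  for (k in seq_along(starts)) {
    blk <- lines[starts[k]:(bounds[k + 1L] - 1L)]
    blk <- blk[nzchar(blk)]
    id <- sub("^camera\\s+", "", blk[1])
    rows <- lapply(blk[2:4], function(l) as.numeric(strsplit(l, "\\s+")[[1]]))
    if (any(vapply(rows, length, integer(1)) != 4L)) {
      stop("malformed projection matrix for camera ", id, " in ", path)
    }
    P <- do.call(rbind, rows)
    distortion <- NULL
    image_size <- NULL
    for (l in blk[-(1:4)]) {
      if (grepl("^distortion\\s+", l)) {
        vals <- as.numeric(strsplit(sub("^distortion\\s+", "", l), "\\s+")[[1]])
        if (length(vals) != 4L) stop("malformed distortion line for camera ", id)
        distortion <- list(k1 = vals[1], k2 = vals[2], cx = vals[3], cy = vals[4])
      } else if (grepl("^image_size\\s+", l)) {
        image_size <- as.numeric(strsplit(sub("^image_size\\s+", "", l), "\\s+")[[1]])
      } else {
        stop("unrecognized line in camera block '", id, "': ", l)
      }
    }
    cams[[k]] <- camera_model(id, P, distortion, image_size)
  }
  names(cams) <- vapply(cams, function(c) c$id, character(1))
  cams
}

#' Write camera models to a plain-text file
#'
#' Inverse of [read_cameras]; numeric values are written with 17 significant
#' digits so that a read/write cycle preserves them exactly.
#'
#' @param cameras list of [camera_model]s.
#' @param path file path.
#' @export
write_cameras <- function(cameras, path) {
  fmt <- function(x) paste(sprintf("%.17g", x), collapse = " ")
  out <- character(0)
  for (cam in cameras) {
    out <- c(out, paste("camera", cam$id),
             apply(cam$P, 1, fmt))
    if (!is.null(cam$distortion)) {
      d <- cam$distortion
      out <- c(out, paste("distortion", fmt(c(d$k1, d$k2, d$cx, d$cy))))
    }
    if (!is.null(cam$image_size)) {
      out <- c(out, paste("image_size", fmt(cam$image_size)))
    }
    out <- c(out, "")
  }
  writeLines(out, path)
  invisible(path)
}
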