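# Shared fixtures: hand-built cameras and independent mini-oracles used
# across test files.

# canonical camera P = [I | 0]: world units project to (x/z, y/z)
canonical_camera <- function(id = "canon") {
  camera_model(id, cbind(diag(3), 0))
}

# simple calibrated camera: focal f px, principal point (cx, cy), world
# frame equal to camera frame (looking along +z)
focal_camera <- function(f = 100, cx = 320, cy = 240, id = "focal") {
  K <- matrix(c(f, 0, cx, 0, f, cy, 0, 0, 1), 3, 3, byrow = TRUE)
  camera_model(id, K %*% cbind(diag(3), 0))
}

# random full-rank projection matrix built as K [R | t] with the camera
# looking at the origin from a random position; returns the camera_model
random_camera <- function(id = "rand", f = 800, cx = 320, cy = 240) {
  repeat {
    C <- stats::rnorm(3, 0, 2)
    if (sqrt(sum(C^2)) > 0.5) break
  }
  fwd <- -C / sqrt(sum(C^2))
  up <- if (abs(fwd[3]) > 0.99) c(0, 1, 0) else c(0, 0, 1)
  right <- c(fwd[2] * up[3] - fwd[3] * up[2],
             fwd[3] * up[1] - fwd[1] * up[3],
             fwd[1] * up[2] - fwd[2] * up[1])
  right <- right / sqrt(sum(right^2))
  down <- c(fwd[2] * right[3] - fwd[3] * right[2],
            fwd[3] * right[1] - fwd[1] * right[3],
            fwd[1] * right[2] - fwd[2] * right[1])
  K <- matrix(c(f, 0, cx, 0, f, cy, 0, 0, 1), 3, 3, byrow = TRUE)
  R <- rbind(right, down, fwd)
  camera_model(id, K %*% cbind(R, -R %*% C))
}

# independent projection oracle: direct homogeneous 4-vector product
oracle_project <- function(P, X) {
  x <- drop(P %*% c(X, 1))
  c(x[1] / x[3], x[2] / x[3])
}

# independent camera-centre oracle via pseudo-inverse of P
oracle_centre <- function(P) {
  sv <- svd(P, nu = 0, nv = 4)
  v <- sv$v[, 4]
  v[1:3] / v[4]
}

# render a (possibly anisotropic) Gaussian blob sampled at pixel centres
# onto a constant background; centre in (u, v), cov 2x2 in px^2
render_blob <- function(width, height, centre, cov, amplitude,
                        background = 0) {
  uu <- matrix(0:(width - 1), height, width, byrow = TRUE)
  vv <- matrix(0:(height - 1), height, width)
  S <- solve(cov)
  du <- uu - centre[1]
  dv <- vv - centre[2]
  q <- S[1, 1] * du^2 + 2 * S[1, 2] * du * dv + S[2, 2] * dv^2
  background + amplitude * exp(-q / 2)
}

# a small rig from the simulator defaults (deterministic)
small_rig <- function(n_cameras = 4, ...) {
  make_rig(sim_config(n_cameras = n_cameras, ...))
}
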