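# Background model and blob feature extraction via image moments.

test_that("background update follows the exponential recursion", {
  set.seed(31)
  f0 <- matrix(stats::runif(40), 5, 8)
  f1 <- matrix(stats::runif(40), 5, 8)
  f2 <- matrix(stats::runif(40), 5, 8)
  bg <- background_model(f0, update_interval = 1, learning_rate = 0.1)
  bg <- update_background(bg, f1)
  bg <- update_background(bg, f2)
  # hand-computed two-step closed form
  lam <- 0.1
  m1 <- (1 - lam) * f0 + lam * f1
  v1 <- lam * (f1 - m1)^2
  m2 <- (1 - lam) * m1 + lam * f2
  v2 <- (1 - lam) * v1 + lam * (f2 - m2)^2
  expect_equal(bg$mean, m2, tolerance = 1e-12)
  expect_equal(bg$variance, v2, tolerance = 1e-12)
})

test_that("background update fixed points and interval rule hold", {
  f <- matrix(0.5, 6, 6)
  bg <- background_model(matrix(0.9, 6, 6), update_interval = 1,
                         learning_rate = 0.3)
  for (i in 1:200) bg <- update_background(bg, f)
  expect_equal(bg$mean, f, tolerance = 1e-9)
  expect_lt(max(bg$variance), 1e-9)

  # learning rate 1: mean snaps to the latest frame
  bg1 <- background_model(matrix(0, 3, 3), update_interval = 1,
                          learning_rate = 1)
  bg1 <- update_background(bg1, f[1:3, 1:3])
  expect_identical(bg1$mean, f[1:3, 1:3])
  expect_equal(max(bg1$variance), 0)

  # off-interval frames leave the model untouched
  bg500 <- background_model(matrix(0, 3, 3), update_interval = 500)
  same <- update_background(bg500, f[1:3, 1:3], frame_index = 123)
  expect_identical(same$mean, bg500$mean)
  hit <- update_background(bg500, f[1:3, 1:3], frame_index = 1000)
  expect_false(identical(hit$mean, bg500$mean))

  expect_error(update_background(bg500, f), "shape")
})

test_that("moment statistics match hand computations", {
  # single nonzero pixel
  p <- matrix(0, 5, 5)
  p[3, 4] <- 2.5
  m <- moment_statistics(p, origin = c(10, 20))
  expect_equal(m$alpha, 2.5)
  expect_equal(unname(m$centre), c(13, 22))
  expect_equal(m$epsilon, 0)

  # two equal pixels 10 px apart horizontally: midpoint centre, theta 0
  p2 <- matrix(0, 3, 12)
  p2[2, 1] <- 1
  p2[2, 11] <- 1
  m2 <- moment_statistics(p2)
  expect_equal(unname(m2$centre), c(5, 1))
  expect_equal(m2$theta, 0)
  expect_gt(m2$epsilon, 0.9)

  # symmetric round blob: eccentricity ~ 0
  blob <- render_blob(21, 21, c(10, 10), diag(c(4, 4)), 1)
  m3 <- moment_statistics(blob)
  expect_lt(m3$epsilon, 1e-6)

  expect_error(moment_statistics(matrix(0, 3, 3)), "all zero")
})

test_that("a frame identical to the background yields no features", {
  set.seed(32)
  bgimg <- matrix(stats::runif(100 * 120, 0.3, 0.5), 100, 120)
  bg <- background_model(bgimg)
  params <- extraction_params(detect_threshold = 0.1)
  out <- extract_features(bgimg, bg, params)
  expect_equal(nrow(out), 0)
})

test_that("a rendered Gaussian blob is recovered with sub-0.1 px error", {
  bgimg <- matrix(0.4, 100, 120)
  bg <- background_model(bgimg)
  frame <- render_blob(120, 100, c(57.3, 41.8), diag(c(4, 4)), 0.5,
                       background = 0.4)
  params <- extraction_params(detect_threshold = 0.1, roi_radius = 8)
  out <- extract_features(frame, bg, params, frame_index = 7L)
  expect_equal(nrow(out), 1)
  expect_lt(abs(out$u - 57.3), 0.1)
  expect_lt(abs(out$v - 41.8), 0.1)
  expect_equal(out$frame, 7L)
  # beta is the brightest sampled pixel; the true centre is off-pixel
  expect_equal(out$beta, max(abs(frame - bgimg)))
})

test_that("an elongated blob reports its orientation and eccentricity", {
  ang <- 30 * pi / 180
  R <- matrix(c(cos(ang), -sin(ang), sin(ang), cos(ang)), 2, 2, byrow = TRUE)
  cov <- R %*% diag(c(16, 2.25)) %*% t(R)
  frame <- render_blob(120, 100, c(60, 50), cov, 0.5, background = 0.4)
  bg <- background_model(matrix(0.4, 100, 120))
  params <- extraction_params(detect_threshold = 0.05, roi_radius = 14)
  out <- extract_features(frame, bg, params)
  expect_equal(nrow(out), 1)
  expect_lt(abs(out$theta - ang), 2 * pi / 180)
  # baseline: a round blob of the same scale
  round_out <- extract_features(
    render_blob(120, 100, c(60, 50), diag(c(9, 9)), 0.5, background = 0.4),
    bg, params
  )
  expect_gt(out$epsilon, round_out$epsilon + 0.3)
})

test_that("feature centroids are translation-equivariant and alpha invariant", {
  bg <- background_model(matrix(0.4, 100, 120))
  params <- extraction_params(detect_threshold = 0.1, roi_radius = 8)
  f1 <- render_blob(120, 100, c(40.6, 30.2), diag(c(4, 4)), 0.5,
                    background = 0.4)
  f2 <- render_blob(120, 100, c(40.6 + 25, 30.2 + 13), diag(c(4, 4)), 0.5,
                    background = 0.4)
  o1 <- extract_features(f1, bg, params)
  o2 <- extract_features(f2, bg, params)
  expect_equal(o2$u - o1$u, 25, tolerance = 1e-6)
  expect_equal(o2$v - o1$v, 13, tolerance = 1e-6)
  expect_equal(o2$alpha, o1$alpha, tolerance = 1e-6)
})

test_that("rotating a patch by 90 degrees shifts theta by pi/2 mod pi", {
  ang <- 25 * pi / 180
  R <- matrix(c(cos(ang), -sin(ang), sin(ang), cos(ang)), 2, 2, byrow = TRUE)
  cov <- R %*% diag(c(16, 2.25)) %*% t(R)
  patch <- render_blob(41, 41, c(20, 20), cov, 1)
  m <- moment_statistics(patch)
  rotated <- t(patch)[, nrow(patch):1]   # 90-degree rotation
  m90 <- moment_statistics(rotated)
  diff <- (m90$theta - m$theta) %% pi
  expect_equal(min(abs(diff - pi / 2), abs(diff - pi / 2 - pi),
                   abs(diff - pi / 2 + pi)), 0, tolerance = 0.02)
})

test_that("extraction caps the feature count and sorts by peak brightness", {
  bgimg <- matrix(0.4, 80, 160)
  bg <- background_model(bgimg)
  frame <- bgimg
  centres <- list(c(20, 20), c(60, 20), c(100, 20), c(140, 20))
  amps <- c(0.2, 0.5, 0.35, 0.28)
  for (i in seq_along(centres)) {
    frame <- frame + render_blob(160, 80, c(centres[[i]][1], centres[[i]][2]),
                                 diag(c(3, 3)), amps[i])
  }
  params <- extraction_params(detect_threshold = 0.1, roi_radius = 6,
                              max_features_per_camera = 3)
  out <- extract_features(frame, bg, params)
  expect_equal(nrow(out), 3)
  expect_equal(out$beta, sort(out$beta, decreasing = TRUE))
  expect_equal(sort(round(out$u / 10) * 10), c(60, 100, 140))
})

test_that("extraction undistorts centres when the camera has distortion", {
  bgimg <- matrix(0.4, 100, 120)
  bg <- background_model(bgimg)
  frame <- render_blob(120, 100, c(90, 70), diag(c(4, 4)), 0.5,
                       background = 0.4)
  params <- extraction_params(detect_threshold = 0.1, roi_radius = 8)
  cam <- camera_model("d", focal_camera()$P,
                      distortion = list(k1 = 2e-5, k2 = 0, cx = 59.5,
                                        cy = 49.5))
  plain <- extract_features(frame, bg, params)
  corr <- extract_features(frame, bg, params, camera = cam)
  expect_equal(unname(undistort_point(cam, c(plain$u, plain$v))),
               c(corr$u, corr$v), tolerance = 1e-9)
})

test_that("frame and feature-table files round-trip", {
  set.seed(33)
  img <- matrix(stats::runif(48), 6, 8)
  p <- tempfile(fileext = ".png")
  write_frame(img, p)
  back <- read_frame(p)
  expect_lt(max(abs(back - img)), 1 / 255)   # 8-bit quantization
  pt <- tempfile(fileext = ".tif")
  write_frame(img, pt)
  expect_lt(max(abs(read_frame(pt) - img)), 1 / 255)

  feats <- data.frame(frame = c(1L, 1L, 2L), camera_id = c("a", "b", "a"),
                      u = c(1.5, 2.25, 3), v = c(4, 5, 6),
                      alpha = c(10, 20, 30), beta = c(0.5, 0.6, 0.7),
                      theta = c(0, 1, 2), epsilon = c(0.1, 0.2, 0.3),
                      stringsAsFactors = FALSE)
  fp <- tempfile(fileext = ".csv")
  write_features(feats, fp)
  expect_equal(read_features(fp), feats)
})
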