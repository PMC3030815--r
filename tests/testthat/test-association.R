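# NNSF data association: gates, ray likelihood, assignment, merge
# prevention, birth and death.

test_that("the image-distance gate is inclusive at its boundary", {
  gp <- gating_params(max_pixel_dist = 20)
  expect_equal(pixel_gate(c(10, 10), c(10, 10), gp), 1L)
  expect_equal(pixel_gate(c(0, 0), c(20, 0), gp), 1L)          # exactly at
  expect_equal(pixel_gate(c(0, 0), c(20 + 1e-9, 0), gp), 0L)   # just beyond
})

test_that("the area gate is strict", {
  gp <- gating_params(min_area = 5)
  expect_equal(area_gate(5, gp), 0L)       # equal does not pass
  expect_equal(area_gate(10, gp), 1L)
  gp0 <- gating_params(min_area = 0)
  expect_equal(area_gate(1e-9, gp0), 1L)
})

test_that("Mahalanobis distance matches hand evaluations", {
  expect_equal(mahalanobis_distance(c(1, 2, 3), c(1, 2, 3), diag(3)), 0)
  expect_equal(mahalanobis_distance(c(3, 4, 0), c(0, 0, 0), diag(3)), 5)
  expect_equal(
    mahalanobis_distance(c(2, 0, 0), c(0, 0, 0), diag(c(4, 1, 1))), 1)
  expect_error(mahalanobis_distance(c(1, 0, 0), c(0, 0, 0),
                                    matrix(0, 3, 3)), "singular")
})

test_that("closest ray point reduces to orthogonal projection for cov = I", {
  r <- structure(list(origin = c(0, 0, 0), direction = c(1, 0, 0)),
                 class = "ray")
  got <- closest_point_on_ray(r, c(3, 4, 5), diag(3))
  expect_equal(got, c(3, 0, 0))
  # a mean on the ray is returned unchanged
  expect_equal(closest_point_on_ray(r, c(2, 0, 0), diag(c(1, 4, 9))),
               c(2, 0, 0))
})

test_that("closest ray point matches a 1-D numerical minimization oracle", {
  set.seed(51)
  for (i in 1:25) {
    d <- stats::rnorm(3)
    d <- d / sqrt(sum(d^2))
    r <- structure(list(origin = stats::rnorm(3), direction = d),
                   class = "ray")
    A <- matrix(stats::rnorm(9), 3, 3)
    cov <- A %*% t(A) + diag(3) * 0.5
    mean3 <- stats::rnorm(3)
    got <- closest_point_on_ray(r, mean3, cov)
    f <- function(s) {
      p <- r$origin + s * d - mean3
      drop(t(p) %*% solve(cov, p))
    }
    opt <- stats::optimize(f, c(-100, 100), tol = 1e-12)
    expect_equal(got, r$origin + opt$minimum * d, tolerance = 1e-6)
    expect_lte(f(sum((got - r$origin) * d)), opt$objective + 1e-8)
  }
})

test_that("likelihood short-circuits failed gates and ranks by ray distance", {
  set.seed(52)
  rig <- small_rig(3)
  cam <- rig[[1]]
  gp <- gating_params(max_pixel_dist = 20, min_area = 1)
  tg <- new_target(1L, c(0, 0, 0), pos_var = 0.01)
  pred <- project(cam, tg$state[1:3])

  counter <- new.env()
  counter$ray_evals <- 0L
  far <- data.frame(u = pred[1] + 100, v = pred[2], alpha = 50)
  expect_equal(feature_likelihood(far, tg, cam, gp,
                                  instrumentation = counter), 0)
  expect_equal(counter$ray_evals, 0L)       # expensive term never evaluated

  small <- data.frame(u = pred[1], v = pred[2], alpha = 0.5)
  expect_equal(feature_likelihood(small, tg, cam, gp,
                                  instrumentation = counter), 0)
  expect_equal(counter$ray_evals, 0L)

  # a ray through the prior mean attains the maximal score exp(0) = 1
  exact <- data.frame(u = pred[1], v = pred[2], alpha = 50)
  expect_equal(feature_likelihood(exact, tg, cam, gp,
                                  instrumentation = counter), 1)
  expect_equal(counter$ray_evals, 1L)

  # monotone: smaller ray-Mahalanobis distance scores strictly higher
  near <- data.frame(u = pred[1] + 2, v = pred[2], alpha = 50)
  farther <- data.frame(u = pred[1] + 6, v = pred[2], alpha = 50)
  s_near <- feature_likelihood(near, tg, cam, gp)
  s_far <- feature_likelihood(farther, tg, cam, gp)
  expect_gt(s_near, s_far)
  expect_gt(s_far, 0)
})

test_that("NNSF assignment equals the exhaustive argmax oracle", {
  set.seed(53)
  rig <- small_rig(4)
  gp <- gating_params(max_pixel_dist = 20, min_area = 1)
  for (rep in 1:200) {
    inst <- random_instance(rig, gp)
    got <- associate(inst$targets, inst$feats, rig, gp)
    want <- oracle_assign(inst$targets, inst$feats, rig, gp)
    expect_identical(got, want)
  }
})

test_that("assignment is equivariant under feature permutations", {
  set.seed(54)
  rig <- small_rig(4)
  gp <- gating_params()
  inst <- random_instance(rig, gp)
  perms <- lapply(inst$feats, function(f) sample(seq_len(max(1, nrow(f)))))
  permuted <- mapply(function(f, p) {
    if (nrow(f) == 0) f else f[p, , drop = FALSE]
  }, inst$feats, perms, SIMPLIFY = FALSE)
  a1 <- associate(inst$targets, inst$feats, rig, gp)
  a2 <- associate(inst$targets, permuted, rig, gp)
  for (k in seq_along(a1)) {
    for (i in seq_along(rig)) {
      j1 <- a1[[k]][i]
      j2 <- a2[[k]][i]
      expect_equal(is.na(j1), is.na(j2))
      if (!is.na(j1)) {
        # the chosen physical feature is the same one
        expect_equal(which(perms[[i]] == j1), as.integer(j2))
      }
    }
  }
})

test_that("merge prevention strips the farther of two matching targets", {
  set.seed(55)
  rig <- small_rig(3)
  gp <- gating_params()
  X <- c(0.02, 0.01, 0)
  tgA <- new_target(1L, X)                       # right on the features
  tgB <- new_target(2L, X + c(0.004, 0, 0))      # slightly off
  feats <- lapply(rig, function(cm) {
    uv <- project(cm, X)
    data.frame(u = uv[1], v = uv[2], alpha = 10)
  })
  asg <- associate(list(tgA, tgB), feats, rig, gp)
  expect_identical(asg[[1]], asg[[2]])           # both claim the same set
  res <- resolve_shared(list(tgA, tgB), asg, feats, rig)
  expect_false(any(is.na(res[[1]])))
  expect_true(all(is.na(res[[2]])))

  # different assignment sets are untouched
  asg2 <- list(c(1L, NA, 1L), c(NA, 1L, 1L))
  expect_identical(resolve_shared(list(tgA, tgB), asg2, feats, rig), asg2)

  # an exact tie goes to the lower target id
  tgC <- new_target(3L, X)
  asg3 <- associate(list(tgA, tgC), feats, rig, gp)
  res3 <- resolve_shared(list(tgA, tgC), asg3, feats, rig)
  expect_false(any(is.na(res3[[1]])))
  expect_true(all(is.na(res3[[2]])))
})

test_that("consistent unclaimed features in several cameras spawn one target", {
  set.seed(56)
  rig <- small_rig(4)
  gp <- gating_params(max_reproj_error_birth = 3)
  X <- c(0.03, -0.02, 0.1)
  feats <- lapply(seq_along(rig), function(i) {
    if (i == 4) return(data.frame(u = numeric(0), v = numeric(0),
                                  alpha = numeric(0)))
    uv <- project(rig[[i]], X)
    data.frame(u = uv[1], v = uv[2], alpha = 10)
  })
  out <- spawn_targets(feats, rig, gp, next_id = 7L, birth_frame = 3L)
  expect_length(out$targets, 1)
  tg <- out$targets[[1]]
  expect_equal(tg$id, 7L)
  expect_equal(tg$state[1:3], X, tolerance = 1e-6)
  expect_equal(tg$state[4:6], c(0, 0, 0))        # zero-velocity start
  expect_equal(tg$birth_frame, 3L)
  expect_equal(sort(out$used$camera_index), 1:3)
})

test_that("features in a single camera cannot create a target", {
  rig <- small_rig(4)
  gp <- gating_params()
  feats <- lapply(seq_along(rig), function(i) {
    if (i != 2) return(data.frame(u = numeric(0), v = numeric(0),
                                  alpha = numeric(0)))
    data.frame(u = c(100, 200), v = c(100, 200), alpha = c(10, 10))
  })
  out <- spawn_targets(feats, rig, gp, next_id = 1L)
  expect_length(out$targets, 0)
})

test_that("birth enumerates every camera combination and prefers the largest", {
  set.seed(57)
  for (n in c(3, 4, 5)) {
    rig <- small_rig(n)
    counts <- rep(1L, n)
    enum <- mvtrack:::enumerate_birth_hypotheses(counts, 100000L)
    expect_length(enum$hypotheses, 2^n - n - 1)   # all subsets of size >= 2
    X <- c(0.01, 0.02, -0.05)
    feats <- lapply(rig, function(cm) {
      uv <- project(cm, X)
      data.frame(u = uv[1], v = uv[2], alpha = 10)
    })
    out <- spawn_targets(feats, rig, gating_params(), next_id = 1L)
    expect_length(out$targets, 1)
    expect_equal(nrow(out$used), n)               # the n-camera hypothesis won
  }
})

test_that("two crossing-consistent feature sets spawn two disjoint targets", {
  set.seed(58)
  rig <- small_rig(4)
  gp <- gating_params(max_reproj_error_birth = 2)
  XA <- c(-0.08, 0, 0.2)
  XB <- c(0.08, 0.05, -0.3)
  feats <- lapply(rig, function(cm) {
    rbind(
      data.frame(u = project(cm, XA)[1], v = project(cm, XA)[2], alpha = 10),
      data.frame(u = project(cm, XB)[1], v = project(cm, XB)[2], alpha = 10)
    )
  })
  out <- spawn_targets(feats, rig, gp, next_id = 1L)
  expect_length(out$targets, 2)
  pts <- t(vapply(out$targets, function(tg) tg$state[1:3], numeric(3)))
  d_match <- min(sqrt(rowSums(sweep(pts, 2, XA)^2)))
  expect_lt(d_match, 1e-6)
  # no feature is used by both targets
  expect_false(any(duplicated(out$used[c("camera_index", "feature_index")])))
})

test_that("targets retire exactly when their error estimate crosses threshold", {
  pm <- process_model(0.01)
  gp <- gating_params(max_covariance_trace_death = 0.05,
                      max_frames_unobserved = 1000L)
  tg <- new_target(1L, c(0, 0, 0), pos_var = 0.01, vel_var = 1)
  # independent closed-form iteration of the positional trace under A, Q
  P <- tg$P
  crossing <- NA_integer_
  for (t in 1:200) {
    P <- pm$A %*% P %*% t(pm$A) + pm$Q
    if (sum(diag(P)[1:3]) > gp$max_covariance_trace_death) {
      crossing <- t
      break
    }
  }
  expect_false(is.na(crossing))
  # run the live target unobserved and find its actual retirement frame
  got <- NA_integer_
  for (t in 1:200) {
    tg <- ekf_predict(tg, pm)
    tg$frames_since_observation <- tg$frames_since_observation + 1L
    ret <- retire_targets(list(tg), gp)
    if (length(ret$retired) == 1) {
      got <- t
      break
    }
  }
  expect_equal(got, crossing)

  # a continuously observed target is kept; an infinite threshold retires none
  rig <- small_rig(3)
  om <- observation_model(rig)
  tg2 <- new_target(2L, c(0, 0, 0))
  for (t in 1:50) {
    tg2 <- ekf_predict(tg2, pm)
    obs <- lapply(seq_along(rig), function(ci) {
      list(camera_index = ci, point = project(rig[[ci]], c(0, 0, 0)))
    })
    tg2 <- ekf_update(tg2, obs, om)
  }
  expect_length(retire_targets(list(tg2), gp)$kept, 1)
  gp_inf <- gating_params(max_covariance_trace_death = Inf,
                          max_frames_unobserved = .Machine$integer.max)
  tg3 <- new_target(3L, c(0, 0, 0), pos_var = 1e6)
  expect_length(retire_targets(list(tg3), gp_inf)$retired, 0)
})
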