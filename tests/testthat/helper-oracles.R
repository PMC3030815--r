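# Independent mini-oracle for NNSF association: exhaustive per-target
# per-camera argmax with all geometry recomputed from scratch, plus a
# random-instance generator. Kept separate from the package code paths.

oracle_assign <- function(targets, features_by_camera, cameras, gp) {
  lapply(targets, function(tg) {
    mean3 <- tg$state[1:3]
    cov3 <- tg$P[1:3, 1:3]
    d <- rep(NA_integer_, length(cameras))
    for (i in seq_along(cameras)) {
      P <- cameras[[i]]$P
      feats <- features_by_camera[[i]]
      if (is.null(feats) || nrow(feats) == 0) next
      xh <- drop(P %*% c(mean3, 1))
      pred <- xh[1:2] / xh[3]
      best <- 0
      besti <- NA_integer_
      for (j in seq_len(nrow(feats))) {
        uv <- c(feats$u[j], feats$v[j])
        if (sqrt(sum((uv - pred)^2)) > gp$max_pixel_dist) next
        if (!(feats$alpha[j] > gp$min_area)) next
        M <- P[, 1:3]
        orig <- -solve(M, P[, 4])
        dir <- solve(M, c(uv, 1))
        dir <- dir / sqrt(sum(dir^2))
        W <- solve(cov3)
        s <- drop(t(dir) %*% W %*% (mean3 - orig)) /
          drop(t(dir) %*% W %*% dir)
        a <- orig + s * dir
        dm2 <- drop(t(a - mean3) %*% W %*% (a - mean3))
        score <- exp(-dm2 / 2)
        if (score > best) {
          best <- score
          besti <- j
        }
      }
      if (!is.na(besti)) d[i] <- besti
    }
    d
  })
}

random_instance <- function(rig, gp) {
  n_targets <- sample(1:3, 1)
  targets <- lapply(seq_len(n_targets), function(k) {
    new_target(k, stats::runif(3, -0.1, 0.1), pos_var = 0.02)
  })
  feats <- lapply(seq_along(rig), function(i) {
    m <- sample(0:5, 1)
    if (m == 0) return(data.frame(u = numeric(0), v = numeric(0),
                                  alpha = numeric(0)))
    base <- targets[[sample(n_targets, 1)]]$state[1:3]
    uv0 <- tryCatch(project(rig[[i]], base), error = function(e) c(320, 240))
    data.frame(u = uv0[1] + stats::rnorm(m, 0, 15),
               v = uv0[2] + stats::rnorm(m, 0, 15),
               alpha = stats::runif(m, 0, 10))
  })
  list(targets = targets, feats = feats)
}
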