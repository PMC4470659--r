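test_that("noiseless prediction is exact linear extrapolation", {
  p <- list(X = matrix(c(1, 2, 3, 0, 0, 0), 1, 6), O = matrix(NA_real_, 1, 2),
            w = 1, missing = FALSE)
  q <- predict_location(p, sigma = 0)
  expect_equal(q$X[1, 1:3], c(2, 4, 6))
  expect_equal(q$X[1, 4:6], c(1, 2, 3))
  # stationary particle stays put
  s <- list(X = matrix(c(5, 5, 5, 5, 5, 5), 1, 6), O = matrix(NA_real_, 1, 2),
            w = 1, missing = FALSE)
  expect_equal(predict_location(s, 0)$X[1, 1:3], c(5, 5, 5))
})

test_that("transition noise has the configured first two moments", {
  n <- 1e5
  p <- list(X = matrix(rep(c(1, 2, 3, 0, 0, 0), each = n), n, 6),
            O = matrix(NA_real_, n, 2), w = rep(1 / n, n),
            missing = rep(FALSE, n))
  q <- predict_location(p, sigma = 2, seed = 99)
  dev <- sweep(q$X[, 1:3], 2, c(2, 4, 6))
  expect_lt(max(abs(colMeans(dev))), 3 * 2 / sqrt(n))
  expect_close(diag(cov(dev)), rep(4, 3), 4 * 0.05)
})

test_that("occupancy scores match a brute-force pixel-set oracle", {
  cam <- plane_camera(64L, 64L)
  set.seed(40)
  for (i in 1:50) {
    ng <- sample(10:60, 1)
    gate <- cbind(matrix(runif(2 * ng, 5, 20), ng, 2), 0)
    nb <- sample(3:25, 1)
    rows <- sample(5:25, nb, replace = TRUE)
    cols <- sample(5:25, nb, replace = TRUE)
    dup <- duplicated(cbind(rows, cols))
    rows <- rows[!dup]; cols <- cols[!dup]
    ms <- list(list(as_measurement(rows, cols, 64L)))
    got <- pot_associate(c(0, 0, 0), ms, list(cam), eta_c = -1,
                         gate_points = gate)
    gpix <- unique(paste(round(gate[, 2]) + 1, round(gate[, 1]) + 1))
    bpix <- paste(rows, cols)
    eta_brute <- length(intersect(gpix, bpix)) / length(bpix)
    eta_got <- if (nrow(got[[1]])) got[[1]]$eta[1] else 0
    expect_equal(eta_got, eta_brute)
  }
})

test_that("occupancy extremes behave as set containment dictates", {
  cam <- plane_camera()
  rows <- c(10L, 10L, 11L); cols <- c(10L, 11L, 10L)
  ms <- list(list(as_measurement(rows, cols, 64L)))
  gate_exact <- cbind(cols - 1, rows - 1, 0)
  got <- pot_associate(c(0, 0, 0), ms, list(cam), eta_c = 0.99,
                       gate_points = gate_exact)
  expect_equal(got[[1]]$eta, 1)
  gate_far <- cbind(matrix(50, 5, 2), 0)
  far <- pot_associate(c(0, 0, 0), ms, list(cam), eta_c = 0,
                       gate_points = gate_far)
  expect_equal(nrow(far[[1]]), 0)
  expect_true(attr(far, "missing"))
})

test_that("MMP enumeration is the capped per-view Cartesian product", {
  mk <- function(n) data.frame(meas = seq_len(n), eta = seq(1, 0.5,
                                                            length.out = n))
  expect_length(enumerate_mmps(list(mk(1), mk(1), mk(1))), 1)
  # two candidates in camera 1 only: exactly two MMPs sharing views 2 and 3
  two <- enumerate_mmps(list(mk(2), mk(1), mk(1)))
  expect_length(two, 2)
  expect_equal(sort(vapply(two, function(m) m$meas[1], 1L)), 1:2)
  expect_equal(unique(lapply(two, function(m) m$meas[2:3]))[[1]], c(1L, 1L))
  all12 <- enumerate_mmps(list(mk(2), mk(3), mk(2)))
  expect_length(all12, 12)
  expect_equal(length(unique(lapply(all12, `[[`, "meas"))), 12)
  # a view without candidates kills the particle
  expect_length(enumerate_mmps(list(mk(2), mk(0), mk(1))), 0)
  # cap bounds the product
  expect_length(enumerate_mmps(list(mk(5), mk(5), mk(5)), cap_per_view = 3),
                27)
})

test_that("orientation from exact ellipse axes is near-perfect", {
  cams <- toy_cameras()
  set.seed(41)
  eps <- replicate(200, {
    d <- rnorm(3); d <- d / sqrt(sum(d^2))
    p <- 180 + runif(3, -60, 60)
    mm <- lapply(cams, exact_segment_measurement, p_center = p,
                 direction = d, half_len = 1.365)
    ori <- compute_orientation(mm, cams, gamma_min = 1.3, ref_dir = d)
    1 - sum(ori$dir * d)
  })
  expect_lt(mean(eps), 1e-9)
})

test_that("a vertical fly seen by two side cameras resolves to the z axis", {
  ctr <- c(180, 180, 180)
  cams <- list(
    make_lookat_camera(ctr + c(900, 0, 0), ctr, up = c(0, 0, 1),
                       focal_px = 2000, image_size = c(512, 512), id = 1),
    make_lookat_camera(ctr + c(0, 900, 0), ctr, up = c(0, 0, 1),
                       focal_px = 2000, image_size = c(512, 512), id = 2))
  mm <- lapply(cams, exact_segment_measurement, p_center = ctr,
               direction = c(0, 0, 1), half_len = 1.365)
  ori <- compute_orientation(mm, cams, ref_dir = c(0, 0, 1))
  expect_close(abs(ori$dir), c(0, 0, 1), 1e-9)
  expect_close(abs(ori$phi), pi / 2, 1e-6)
})

test_that("orientation is unrecoverable below the axis-ratio threshold", {
  cams <- toy_cameras()
  mm <- lapply(cams, exact_segment_measurement, p_center = c(180, 180, 180),
               direction = c(1, 0, 0), half_len = 1.365, gamma = 1.1)
  expect_null(compute_orientation(mm, cams))
})

test_that("orientation likelihood evaluates its closed forms", {
  o <- c(0.3, 0.2)
  expect_equal(orientation_likelihood(o, o, mode = "literal"), exp(-1))
  expect_equal(orientation_likelihood(o, o, mode = "consistency"), 1)
  opp <- dir_to_angles(-drop(angles_to_dir(0.3, 0.2)))
  expect_equal(orientation_likelihood(c(opp$theta, opp$phi), o,
                                      mode = "consistency"), exp(-2))
  expect_equal(orientation_likelihood(NULL, o), 1)  # unset is neutral
})

test_that("blob NCC equals the textbook normalized cross-correlation", {
  set.seed(42)
  for (i in 1:10) {
    I1 <- runif(25, 0, 255); I2 <- 0.8 * I1 + rnorm(25, 0, 10)
    mk <- function(I) list(u = rep(0:4, 5), v = rep(0:4, each = 5), I = I)
    got <- ncc_blobs(mk(I1), mk(I2))
    ref <- sum((I1 - mean(I1)) * (I2 - mean(I2))) /
      sqrt(sum((I1 - mean(I1))^2) * sum((I2 - mean(I2))^2))
    expect_close(got, ref, 1e-12)
  }
  # identical patches correlate perfectly
  p <- list(u = 0:4, v = rep(0L, 5), I = c(1, 5, 2, 8, 3))
  expect_equal(ncc_blobs(p, p), 1)
})

test_that("appearance likelihood multiplies per-view factors", {
  p <- list(u = 0:4, v = rep(0L, 5), I = c(1, 5, 2, 8, 3))
  ms <- lapply(1:3, function(v) list(list(blob = p)))
  mmp <- list(meas = c(1L, 1L, 1L), eta = c(1, 1, 1))
  expect_close(appearance_likelihood(mmp, ms, list(p, p, p)), exp(3), 1e-12)
  # no stored appearance: neutral
  expect_equal(appearance_likelihood(mmp, ms, list(NULL, NULL, NULL)), 1)
})

test_that("MMP selection agrees with a brute-force weight maximization", {
  cams <- toy_cameras()
  set.seed(43)
  p <- c(180, 180, 180)
  for (rep_ in 1:5) {
    # three candidate measurements per view with random axes and patches
    ms <- lapply(cams, function(cam) lapply(1:3, function(i) {
      d <- rnorm(3); d <- d / sqrt(sum(d^2))
      m <- exact_segment_measurement(cam, p + rnorm(3), d, 1.365)
      m$blob <- list(u = 0:8, v = rep(0L, 9), I = runif(9, 0, 255))
      m
    }))
    app <- lapply(1:3, function(v) ms[[v]][[sample(3, 1)]]$blob)
    mmps <- enumerate_mmps(lapply(1:3, function(v)
      data.frame(meas = 1:3, eta = runif(3, 0.3, 1))))
    o_prev <- c(0.1, 0.1)
    got <- weigh_and_select(mmps, ms, cams, app, o_prev = o_prev,
                            ref_dir = drop(angles_to_dir(0.1, 0.1)))
    brute <- -Inf; bi <- NULL
    for (m in mmps) {
      ori <- compute_orientation(lapply(1:3, function(v) ms[[v]][[m$meas[v]]]),
                                 cams, 1.3, drop(angles_to_dir(0.1, 0.1)))
      pol <- orientation_likelihood(if (is.null(ori)) NULL else ori$dir,
                                    o_prev)
      pal <- appearance_likelihood(m, ms, app)
      if (pol * pal > brute) { brute <- pol * pal; bi <- m }
    }
    expect_equal(got$mmp$meas, bi$meas)
    expect_close(got$weight, brute, 1e-12)
  }
})

test_that("state expectation is the weighted particle mean", {
  p <- list(X = rbind(c(0, 0, 0, 0, 0, 0), c(2, 2, 2, 1, 1, 1)),
            O = matrix(NA_real_, 2, 2), w = c(0.5, 0.5),
            missing = c(FALSE, FALSE))
  est <- estimate_state(p)
  expect_equal(est$location, c(1, 1, 1))
  p$w <- c(1, 0)
  expect_equal(estimate_state(p)$location, c(0, 0, 0))
  # random weighted sets against direct arithmetic
  set.seed(44)
  X <- matrix(rnorm(60), 10, 6)
  w <- runif(10); w <- w / sum(w)
  q <- list(X = X, O = cbind(runif(10, -pi, pi), runif(10, -1, 1)),
            w = w, missing = rep(FALSE, 10))
  est <- estimate_state(q)
  expect_close(est$location, colSums(X[, 1:3] * w), 1e-12)
  dm <- colSums(angles_to_dir(q$O[, 1], q$O[, 2]) * w)
  ang <- dir_to_angles(dm / sqrt(sum(dm^2)))
  expect_close(est$theta, ang$theta, 1e-12)
  # all-missing fails
  p$missing <- c(TRUE, TRUE)
  expect_error(estimate_state(p), "missing")
})

test_that("systematic resampling reproduces weights in expectation", {
  one <- list(X = matrix(1:6, 1, 6), O = matrix(0.5, 1, 2), w = 1,
              missing = FALSE)
  r <- resample_particles(one, 50, seed = 1)
  expect_equal(nrow(r$X), 50)
  expect_true(all(r$X[, 1] == 1))
  two <- list(X = rbind(rep(0, 6), rep(1, 6)), O = matrix(0, 2, 2),
              w = c(0.5, 0.5), missing = c(FALSE, FALSE))
  r2 <- resample_particles(two, 200, seed = 2)
  expect_equal(sum(r2$X[, 1] == 0), 100)   # systematic: exact split
  # skewed weights: multiplicity concentrates near 180/200
  set.seed(3)
  counts <- replicate(2000, {
    r <- resample_particles(list(X = rbind(rep(0, 6), rep(1, 6)),
                                 O = matrix(0, 2, 2), w = c(0.9, 0.1),
                                 missing = c(FALSE, FALSE)), 200)
    sum(r$X[, 1] == 0)
  })
  expect_lt(abs(mean(counts) - 180), 3 * sd(counts) / sqrt(2000) + 1e-9)
  expect_error(resample_particles(list(X = matrix(0, 1, 6),
                                       O = matrix(0, 1, 2), w = 0,
                                       missing = TRUE), 10),
               "degenerate")
})

test_that("single-target closed loop stays within half a body length", {
  z <- arena_rig()
  truth <- simulate_swarm(1, 25, z$arena, seed = 15)
  res <- run_closed_loop(truth, z$cams, z$rc, z$cfg)
  tb <- res$tracks$trajectories
  expect_gte(nrow(tb), 20)
  errs <- vapply(seq_len(nrow(tb)), function(r) {
    t <- tb$frame[r]
    sqrt(sum((truth$pos[t, 1, ] - c(tb$x_mm[r], tb$y_mm[r], tb$z_mm[r]))^2))
  }, 1.0)
  expect_lt(median(errs), 2.73 / 2)
  expect_lt(mean(errs > 2.73 / 2), 0.2)
})

test_that("tracking is reproducible for identical inputs and seed", {
  z <- arena_rig()
  truth <- simulate_swarm(2, 10, z$arena, seed = 16)
  a <- run_closed_loop(truth, z$cams, z$rc, z$cfg)
  b <- run_closed_loop(truth, z$cams, z$rc, z$cfg)
  expect_identical(a$tracks$trajectories, b$tracks$trajectories)
})

test_that("tracks terminate after repeated failures when a target vanishes", {
  z <- arena_rig()
  cfg <- z$cfg
  truth <- simulate_swarm(1, 30, z$arena, seed = 17)
  # the fly disappears after frame 12: serve empty frames afterwards
  src <- function(t) {
    if (t <= 12) render_frame(truth$pos[t, , , drop = TRUE],
                              cbind(truth$theta[t, ], truth$phi[t, ]),
                              z$cams, z$rc, frame = t)$images
    else render_frame(NULL, NULL, z$cams, z$rc, frame = t)$images
  }
  tk <- track_swarm(src, 30, z$cams, z$bgs, cfg, z$arena)
  expect_lte(max(tk$trajectories$frame), 12 + cfg$max_failures)
})

test_that("well-separated simultaneous appearances each seed one track", {
  z <- arena_rig()
  set.seed(18)
  pos <- as.matrix(expand.grid(c(100, 260), c(100, 260), c(100, 260)))[1:8, ]
  pos <- pos + matrix(runif(24, -10, 10), 8, 3)
  o <- cbind(runif(8, -pi, pi), asin(runif(8, -1, 1)))
  fr <- render_frame(pos, o, z$cams, z$rc, frame = 3)
  meas <- lapply(seq_along(z$cams), function(v)
    detect(fr$images[[v]], z$bgs[[v]], z$cfg, view = v))
  used <- lapply(meas, function(m) logical(length(m)))
  nt <- initiate_tracks(meas, used, z$cams, z$cfg, 1L, 1L, z$arena)
  expect_equal(length(nt), 8)
  got <- t(vapply(nt, function(tr) tr$state[1:3], c(0, 0, 0)))
  d <- vapply(seq_len(8), function(i)
    min(sqrt(rowSums(sweep(got, 2, pos[i, ])^2))), 1.0)
  expect_lt(max(d), 1)
  # clutter in a single view does not seed a track
  only1 <- list(meas[[1]], list(), list())
  nt0 <- initiate_tracks(only1, lapply(only1, function(m) logical(length(m))),
                         z$cams, z$cfg, 1L, 1L, z$arena)
  expect_length(nt0, 0)
})
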