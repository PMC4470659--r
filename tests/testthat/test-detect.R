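test_that("background model computes per-pixel moments with a sigma floor", {
  frames <- replicate(5, matrix(200, 4, 4), simplify = FALSE)
  bg <- fit_background(frames, sigma_floor = 1)
  expect_equal(bg$mu, matrix(200, 4, 4))
  expect_equal(bg$sigma, matrix(1, 4, 4))
  # two-frame population formula
  bg2 <- fit_background(list(matrix(100, 2, 2), matrix(200, 2, 2)))
  expect_equal(bg2$mu[1, 1], 150)
  expect_equal(bg2$sigma[1, 1], 50)
  expect_error(fit_background(frames[1]), "at least 2")
  expect_error(fit_background(list(matrix(0, 2, 2), matrix(0, 3, 3))),
               "mismatched")
})

test_that("estimated background moments converge on the generator values", {
  set.seed(30)
  frames <- lapply(1:100, function(i) matrix(rnorm(400, 180, 6), 20, 20))
  bg <- fit_background(frames, sigma_floor = 0.1)
  se_mu <- 6 / sqrt(100)
  expect_lt(abs(mean(bg$mu) - 180), 3 * se_mu / sqrt(400) * 20)
  expect_lt(abs(mean(bg$sigma) - 6), 0.5)
})

test_that("foreground segmentation is one-sided at the z-score threshold", {
  bg <- structure(list(mu = matrix(200, 1, 3), sigma = matrix(10, 1, 3),
                       n = 2), class = "background_model")
  img <- matrix(c(200, 170, 250), 1, 3)
  mask <- segment_foreground(img, bg, c1 = 1.5)
  expect_equal(as.vector(mask), c(FALSE, TRUE, FALSE))
  expect_error(segment_foreground(matrix(0, 2, 2), bg), "shape")
})

test_that("blob extraction respects connectivity and minimum area", {
  mask <- matrix(FALSE, 5, 5)
  mask[2, 2] <- TRUE; mask[3, 3] <- TRUE   # diagonal pair
  img <- matrix(100, 5, 5)
  expect_length(extract_blobs(mask, img, connectivity = 8L, min_area = 1L), 1)
  expect_length(extract_blobs(mask, img, connectivity = 4L, min_area = 1L), 2)
  expect_length(extract_blobs(mask, img, connectivity = 8L, min_area = 3L), 0)
  expect_length(extract_blobs(matrix(FALSE, 5, 5), img), 0)
})

test_that("wing removal keeps the dark body core of a mixed blob", {
  # 4 body pixels at 10, 12 wing pixels at 120: mu_b = 92.5, sigma_b ~ 47.6;
  # body scores ~ -1.73 (kept), wing scores ~ +0.58 (removed)
  b <- list(lin = 1:16, row = rep(1:4, 4), col = rep(1:4, each = 4),
            u = rep(0:3, each = 4), v = rep(0:3, 4),
            I = c(rep(10, 4), rep(120, 12)))
  rb <- remove_wing_pixels(b, c2 = 1.5)
  expect_equal(length(rb$lin), 4)
  expect_true(all(rb$I == 10))
  # uniform blob is degenerate
  b$I <- rep(50, 16)
  expect_null(remove_wing_pixels(b, 1.5))
})

test_that("wing removal output is always a subset and monotone in c2", {
  set.seed(31)
  for (i in 1:20) {
    n <- sample(5:40, 1)
    b <- list(lin = seq_len(n), row = seq_len(n), col = rep(1L, n),
              u = rep(0L, n), v = seq_len(n) - 1L,
              I = runif(n, 0, 255))
    r1 <- remove_wing_pixels(b, 1.0)
    r2 <- remove_wing_pixels(b, 1.5)
    if (!is.null(r2)) {
      expect_true(all(r2$lin %in% b$lin))
      expect_true(all(r2$lin %in% r1$lin))  # raising c2 never adds pixels
    }
  }
})

test_that("raising the segmentation threshold never adds foreground", {
  set.seed(32)
  bg <- fit_background(lapply(1:5, function(i) matrix(rnorm(100, 200, 2),
                                                      10, 10)))
  img <- matrix(rnorm(100, 195, 10), 10, 10)
  m1 <- segment_foreground(img, bg, 1.0)
  m2 <- segment_foreground(img, bg, 1.5)
  expect_true(all(m1[m2]))
})

test_that("weighted ellipse fit reduces to plain moments for equal weights", {
  H <- 10L
  b <- as_measurement(rows = c(2L, 2L, 3L, 3L), cols = c(2L, 3L, 2L, 3L),
                      H = H, I = rep(100, 4))$blob
  bg <- structure(list(mu = matrix(200, H, H), sigma = matrix(10, H, H)),
                  class = "background_model")
  e <- fit_ellipse_weighted(b, bg)
  expect_close(e$center, c(1.5, 1.5), 1e-12)
  expect_close(e$cov, diag(2) * 0.25, 1e-12)
  expect_equal(e$gamma, 1)
  # matches unweighted moments exactly when weights are uniform
  pts <- cbind(b$u, b$v)
  expect_close(e$cov, crossprod(sweep(pts, 2, colMeans(pts))) / 4, 1e-12)
})

test_that("ellipse centre stays inside the blob bounding box, gamma >= 1", {
  set.seed(33)
  H <- 30L
  bg <- structure(list(mu = matrix(200, H, H), sigma = matrix(5, H, H)),
                  class = "background_model")
  for (i in 1:15) {
    n <- sample(4:20, 1)
    rows <- sample(5:25, n, replace = TRUE)
    cols <- sample(5:25, n, replace = TRUE)
    b <- as_measurement(rows, cols, H, I = runif(n, 10, 150))$blob
    e <- fit_ellipse_weighted(b, bg)
    if (is.null(e)) next
    expect_gte(e$gamma, 1)
    expect_gte(e$center[1], min(b$u)); expect_lte(e$center[1], max(b$u))
    expect_gte(e$center[2], min(b$v)); expect_lte(e$center[2], max(b$v))
  }
})

test_that("detection recovers rendered ellipses with sub-pixel accuracy", {
  z <- zoom_rig()
  set.seed(34)
  ang_errs <- c(); ctr_errs <- c(); kept <- c()
  for (i in 1:8) {
    pos <- matrix(180 + runif(3, -30, 30), 1)
    th <- runif(1, -pi, pi); ph <- asin(runif(1, -1, 1))
    fr <- render_frame(pos, matrix(c(th, ph), 1), z$cams, z$rc,
                       frame = 40 + i, keep_body_pixels = TRUE)
    for (v in seq_along(z$cams)) {
      ms <- detect(fr$images[[v]], z$bgs[[v]], z$cfg, view = v)
      if (length(ms) != 1) next
      gt <- fr$gt2d[fr$gt2d$view == v, ]
      ctr_errs <- c(ctr_errs, sqrt(sum((ms[[1]]$ellipse$center -
                                          c(gt$u, gt$v_px))^2)))
      # refined blob must sit inside the true body pixel support and keep
      # most of the body core
      gtpx <- fr$body_pixels[[v]][[1]]
      core <- gtpx$lin[gtpx$alpha >= 0.5]
      expect_true(all(ms[[1]]$blob$lin %in% gtpx$lin))
      kept <- c(kept, mean(core %in% ms[[1]]$blob$lin))
      if (ms[[1]]$ellipse$gamma >= 1.3 && gt$gamma >= 1.3) {
        # major-axis direction against the projected ground-truth axis
        ep <- project_points(z$cams[[v]], rbind(
          pos[1, ] + drop(angles_to_dir(th, ph)) * 1.3,
          pos[1, ] - drop(angles_to_dir(th, ph)) * 1.3))
        true_ang <- atan2(ep[1, 2] - ep[2, 2], ep[1, 1] - ep[2, 1])
        d_ang <- abs(((ms[[1]]$ellipse$angle - true_ang + pi / 2) %% pi) -
                       pi / 2)
        ang_errs <- c(ang_errs, d_ang * 180 / pi)
      }
    }
  }
  expect_lt(median(ctr_errs), 0.5)
  expect_gt(mean(kept), 0.5)
  expect_lt(median(ang_errs), 5)
})

test_that("sub-pixel translations shift the fitted centre consistently", {
  z <- zoom_rig()
  base <- c(180, 180, 180)
  # a world offset along the first camera's u axis of known pixel size
  cam <- z$cams[[1]]
  o <- matrix(c(0.5, 0.15), 1)
  shift_mm <- c(0, 0.1, 0)
  f1 <- render_frame(matrix(base, 1), o, z$cams, z$rc, frame = 60)
  f2 <- render_frame(matrix(base + shift_mm, 1), o, z$cams, z$rc, frame = 60)
  m1 <- detect(f1$images[[1]], z$bgs[[1]], z$cfg)
  m2 <- detect(f2$images[[1]], z$bgs[[1]], z$cfg)
  expect_equal(length(m1), 1); expect_equal(length(m2), 1)
  gt_shift <- project_points(cam, base + shift_mm) - project_points(cam, base)
  got_shift <- m2[[1]]$ellipse$center - m1[[1]]$ellipse$center
  expect_lt(sqrt(sum((got_shift - gt_shift)^2)), 0.3)
})

test_that("the measurement table carries the serialization schema", {
  z <- zoom_rig()
  fr <- render_frame(matrix(c(180, 180, 180), 1), matrix(c(0.2, 0.4), 1),
                     z$cams, z$rc, frame = 70)
  ms <- detect(fr$images[[1]], z$bgs[[1]], z$cfg, view = 1L, frame = 70L)
  tb <- measurement_table(ms)
  expect_equal(names(tb), c("frame", "view", "blob_id", "n_pixels", "cx",
                            "cy", "cov_xx", "cov_xy", "cov_yy", "gamma"))
  expect_equal(nrow(tb), length(ms))
  expect_equal(nrow(measurement_table(list())), 0)
})
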