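straight_track <- function(n = 20, d = 4, fps = 100) {
  data.frame(track_id = 1L, frame = seq_len(n),
             x_mm = seq_len(n) * d, y_mm = 0, z_mm = 0,
             theta_deg = 0, phi_deg = 0)
}

test_that("kinematics of uniform straight motion", {
  k <- kinematics(straight_track(), fps = 100)
  expect_close(k$speed, rep(400, nrow(k)), 1e-9)
  expect_close(k$accel, rep(0, nrow(k)), 1e-6)
  expect_close(k$ang_vel, rep(0, nrow(k)), 1e-6)
  expect_equal(nrow(k), 18)     # interior frames only
  expect_equal(nrow(kinematics(straight_track(2))), 0)
})

test_that("kinematics of uniform circular motion recover the angular rate", {
  fps <- 100; r <- 50; omega <- 2   # rad/s
  t <- seq_len(400) / fps
  tr <- data.frame(track_id = 1L, frame = seq_along(t),
                   x_mm = r * cos(omega * t), y_mm = r * sin(omega * t),
                   z_mm = 0)
  k <- kinematics(tr, fps = fps)
  expect_lt(abs(mean(k$speed) - r * omega) / (r * omega), 0.01)
  expect_lt(abs(median(k$ang_vel) - omega * 180 / pi) / (omega * 180 / pi),
            0.02)
  # centripetal acceleration r * omega^2
  expect_lt(abs(median(k$accel) - r * omega^2) / (r * omega^2), 0.02)
})

test_that("kinematics track the simulator's internal velocities", {
  truth <- simulate_swarm(5, 60, seed = 60)
  k <- kinematics(as.data.frame(truth), fps = 100)
  gt_speed <- mean(apply(truth$pos, 2,
                         function(p) sqrt(rowSums(diff(p)^2)))) * 100
  expect_lt(abs(mean(k$speed) - gt_speed) / gt_speed, 0.05)
})

test_that("z-scores standardize exactly", {
  z <- zscores(c(1, 2, 3))
  expect_equal(z$mu, 2)
  expect_equal(z$z[2], 0)
  expect_equal(z$z[1], -z$z[3])
  set.seed(61)
  x <- rnorm(500, 40, 7)
  z2 <- zscores(x)
  expect_lt(abs(mean(z2$z)), 1e-12)
  expect_lt(abs(sd(z2$z) - 1), 1e-12)
  expect_gt(suppressWarnings(ks.test(z2$z, "pnorm")$p.value), 0.01)
  expect_error(zscores(rep(5, 10)), "variance")
})

test_that("polarisation hits its closed-form extremes", {
  same <- matrix(rep(c(100, 0, 0), 10), 10, 3, byrow = TRUE)
  expect_equal(polarisation(same), 1)
  opp <- rbind(c(100, 0, 0), c(-100, 0, 0))
  expect_equal(polarisation(opp), 0)
  set.seed(62)
  iso <- matrix(rnorm(3e4), 1e4, 3)
  expect_lt(polarisation(iso), 0.02)
  # invariant under global rotation
  R <- swarmtrack:::orientation_rotation(0.7, 0.3)
  v <- matrix(rnorm(30), 10, 3)
  expect_close(polarisation(v %*% t(R)), polarisation(v), 1e-12)
  expect_true(is.na(polarisation(matrix(0, 3, 3))))
})

test_that("NND matches brute force and applies the wall margin to focals", {
  two <- rbind(c(100, 100, 100), c(107, 100, 100))
  r <- nnd(two)
  expect_equal(r$nnd, c(7, 7))
  expect_true(all(r$included))
  # focal fly 10 mm from a wall is excluded but still serves as neighbour
  pair <- rbind(c(10, 180, 180), c(40, 180, 180))
  r2 <- nnd(pair)
  expect_false(r2$included[1])
  expect_true(r2$included[2])
  expect_equal(r2$nnd[2], 30)
  set.seed(63)
  P <- matrix(runif(600, 0, 360), 200, 3)
  r3 <- nnd(P)
  brute <- vapply(1:200, function(i)
    min(sqrt(colSums((t(P[-i, , drop = FALSE]) - P[i, ])^2))), 1.0)
  expect_close(r3$nnd, brute, 1e-12)
  wall <- pmin(apply(P, 1, min), apply(360 - P, 1, min))
  expect_identical(r3$included, wall >= 20)
  expect_equal(nrow(nnd(matrix(1, 1, 3))), 0)
})

test_that("power-law fit recovers noiseless parameters to 1e-6", {
  x <- seq(1e-6, 2e-5, length.out = 40)
  y <- 50 * x^(-0.5) + 15
  f <- fit_power_law(x, y)
  expect_close(coef(f), c(A = 50, B = 0.5, C = 15), 1e-5)
  expect_close(predict(f, x), y, 1e-4)
  expect_error(fit_power_law(x, rep(20, 40)), "unidentifiable")
  expect_error(fit_power_law(x[1:3], y[1:3]), "at least 4")
})

test_that("power-law fit with noise brackets the asymptote", {
  set.seed(64)
  n <- 500
  x <- 10^runif(n, -6, -4.5)
  y0 <- 50 * x^(-0.5) + 15.11
  y <- y0 * (1 + rnorm(n, 0, 0.05))
  f <- fit_power_law(x, y)
  cf <- coef(f)
  expect_lt(abs(cf[["C"]] - 15.11), 2 * f$se[["C"]] + 1)
})

test_that("identical samples compare as indistinguishable from the null", {
  set.seed(65)
  s <- rweibull(200, 3, 30)
  r <- compare_to_random(s, s)
  expect_lt(abs(r$t), 1e-9)
  expect_gt(r$p, 0.99)
  # the Poisson-null intensity estimate inverts the Weibull scale
  lam <- 2e-5
  big <- rweibull(5e4, 3, (4 / 3 * pi * lam)^(-1 / 3))
  r2 <- compare_to_random(big, big)
  expect_lt(abs(r2$lambda_hat - lam) / lam, 0.05)
})

test_that("acceleration direction maps point where the kinematics say", {
  # fly 1 accelerates straight toward its only neighbour (along +x)
  n <- 9
  tr <- rbind(
    data.frame(track_id = 1L, frame = 1:n,
               x_mm = 100 + 0.5 * (1:n)^2, y_mm = 100, z_mm = 100),
    data.frame(track_id = 2L, frame = 1:n, x_mm = 200, y_mm = 100,
               z_mm = 100))
  m <- acceleration_direction_map(tr, bins = c(8L, 4L))
  expect_equal(sum(m$density * (360 / 8) * (180 / 4)), 1, tolerance = 1e-9)
  az_ctr <- findInterval(0, m$azimuth_breaks)
  el_ctr <- findInterval(0, m$elevation_breaks)
  expect_equal(which(m$density == max(m$density), arr.ind = TRUE)[1, ],
               c(row = az_ctr, col = el_ctr))
  # accelerating away: mass at |azimuth| = 180, elevation 0
  tr2 <- tr
  tr2$x_mm[tr2$track_id == 1L] <- 100 - 0.5 * (1:n)^2
  m2 <- acceleration_direction_map(tr2, bins = c(8L, 4L))
  hot <- which(m2$density == max(m2$density), arr.ind = TRUE)[1, ]
  expect_true(hot[1] %in% c(1L, 8L))
  expect_equal(hot[[2]], el_ctr)
})

test_that("a repulsion rule leaves its signature in the acceleration map", {
  l <- 2.73
  truth <- simulate_swarm(30, 250, seed = 66,
                          repulsion_radius = 6 * l,
                          repulsion_strength = 600,
                          cohesion_radius = 120, cohesion_strength = 150)
  tr <- as.data.frame(truth)
  near <- acceleration_direction_map(tr, nnd_range = c(0, 6 * l),
                                     bins = c(12L, 6L))
  far <- acceleration_direction_map(tr, nnd_range = c(8 * l, Inf),
                                    bins = c(12L, 6L))
  expect_gt(near$n, 50); expect_gt(far$n, 50)
  toward <- function(m) {
    az <- findInterval(0, m$azimuth_breaks); el <- findInterval(0,
                                                                m$elevation_breaks)
    m$density[az, el] / mean(m$density[m$density > 0])
  }
  # close encounters: acceleration mass moves away from the neighbour
  expect_lt(toward(near), toward(far))
})
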