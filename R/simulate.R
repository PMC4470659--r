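#' Simulate ground-truthed swarm trajectories
#'
#' A correlated-random-walk behavioural model for flying fruit flies in the
#' cubic arena: each fly carries a heading and a speed; the heading diffuses
#' slowly and is occasionally redrawn through large rapid turns (saccades),
#' the hallmark of fruit fly flight; speeds fluctuate around a mean
#' (400 mm/s by default, matching observed swarm kinematics at 100 fps).
#' Walls reflect. Optional pairwise social forces (short-range repulsion,
#' mid-range cohesion) let tests construct swarms with a known interaction
#' rule; both default to off, giving independent flies.
#'
#' The body orientation of a flying fly is taken to be its velocity
#' direction.
#'
#' @param n_flies number of flies (>= 1).
#' @param n_frames number of frames.
#' @param arena an \code{\link{arena_config}}.
#' @param fps frame rate (frames/s), default 100.
#' @param mean_speed,speed_sd mean and standard deviation of flight speed
#'   (mm/s).
#' @param turn_sd per-frame heading diffusion scale (radians/frame).
#' @param saccade_prob per-frame probability of a saccade (large turn).
#' @param saccade_sd angular scale of a saccade (radians).
#' @param repulsion_radius,repulsion_strength social repulsion: within
#'   \code{repulsion_radius} mm, a fly's velocity is biased away from the
#'   neighbour with weight \code{repulsion_strength} (mm/s at zero
#'   distance, decaying linearly to the radius). 0 disables.
#' @param cohesion_radius,cohesion_strength social cohesion: velocity bias
#'   (mm/s) toward the centroid of neighbours within \code{cohesion_radius}
#'   mm. 0 disables.
#' @param center_pull velocity bias (mm/s) toward the arena centre,
#'   emulating swarming around a fixed marker; keeps an interacting swarm
#'   off the walls. 0 (default) disables.
#' @param landing_prob probability that a wall contact becomes a landing
#'   (fly stops, flagged not flying); a landed fly relaunches with
#'   probability \code{relaunch_prob} per frame.
#' @param relaunch_prob see \code{landing_prob}.
#' @param seed RNG seed; the simulation is deterministic per seed.
#' @return object of class \code{"swarm_truth"}: list with \code{pos}
#'   (array frames x flies x 3, mm), \code{theta}, \code{phi} (matrices,
#'   radians), \code{alive} (logical matrix, TRUE while flying),
#'   \code{arena}, \code{fps} and the parameters used.
#' @export
simulate_swarm <- function(n_flies, n_frames, arena = arena_config(),
                           fps = 100, mean_speed = 400, speed_sd = 100,
                           turn_sd = 0.12, saccade_prob = 0.03,
                           saccade_sd = 1.2,
                           repulsion_radius = 0, repulsion_strength = 0,
                           cohesion_radius = 0, cohesion_strength = 0,
                           center_pull = 0,
                           landing_prob = 0, relaunch_prob = 0.02,
                           seed = 1L) {
  if (n_flies < 1) stop("n_flies must be >= 1")
  if (n_frames < 1) stop("n_frames must be >= 1")
  if (mean_speed < 0 || speed_sd < 0) stop("speeds must be non-negative")
  if (turn_sd < 0 || saccade_sd < 0 || saccade_prob < 0 || saccade_prob > 1)
    stop("invalid turn/saccade parameters")
  set.seed(seed)
  side <- arena$side
  eps <- 1e-6
  pos <- array(NA_real_, c(n_frames, n_flies, 3))
  theta <- matrix(NA_real_, n_frames, n_flies)
  phi <- matrix(NA_real_, n_frames, n_flies)
  alive <- matrix(TRUE, n_frames, n_flies)

  x <- matrix(runif(3 * n_flies, 0.1 * side, 0.9 * side), n_flies, 3)
  h <- matrix(rnorm(3 * n_flies), n_flies, 3)
  h <- h / sqrt(rowSums(h^2))
  spd <- pmax(1, rnorm(n_flies, mean_speed, speed_sd))
  landed <- rep(FALSE, n_flies)

  for (t in seq_len(n_frames)) {
    if (t > 1L) {
      # relaunch landed flies
      if (any(landed)) {
        re <- landed & (runif(n_flies) < relaunch_prob)
        if (any(re)) {
          landed[re] <- FALSE
          hr <- matrix(rnorm(3 * sum(re)), ncol = 3)
          h[re, ] <- hr / sqrt(rowSums(hr^2))
        }
      }
      fly <- !landed
      # heading update: saccade or diffusion
      sac <- fly & (runif(n_flies) < saccade_prob)
      dif <- fly & !sac
      if (any(dif)) {
        pert <- matrix(rnorm(3 * sum(dif), 0, turn_sd), ncol = 3)
        hn <- h[dif, , drop = FALSE] + pert
        h[dif, ] <- hn / sqrt(rowSums(hn^2))
      }
      if (any(sac)) {
        pert <- matrix(rnorm(3 * sum(sac), 0, saccade_sd), ncol = 3)
        hn <- h[sac, , drop = FALSE] + pert
        h[sac, ] <- hn / sqrt(rowSums(hn^2))
      }
      spd <- pmax(1, spd + 0.2 * (mean_speed - spd) +
                    rnorm(n_flies, 0, speed_sd * 0.45))
      v <- h * spd
      # pairwise social forces and the marker pull
      if ((repulsion_strength > 0 && repulsion_radius > 0) ||
          (cohesion_strength > 0 && cohesion_radius > 0) ||
          center_pull > 0) {
        v <- v + social_force(x, repulsion_radius, repulsion_strength,
                              cohesion_radius, cohesion_strength)
        if (center_pull > 0) {
          to_ctr <- sweep(-x, 2, side / 2, "+")       # centre - x
          dd <- pmax(sqrt(rowSums(to_ctr^2)), 1e-9)
          v <- v + center_pull * to_ctr / dd
        }
        spd2 <- sqrt(rowSums(v^2))
        h <- v / pmax(spd2, 1e-9)
        v <- h * spd            # forces steer, speed magnitude is kept
      }
      v[landed, ] <- 0
      xn <- x + v / fps
      # reflective walls (possibly landing)
      for (k in 1:3) {
        lo <- xn[, k] < 0
        hi <- xn[, k] > side
        if (any(lo | hi)) {
          contact <- (lo | hi) & !landed
          land <- contact & (runif(n_flies) < landing_prob)
          xn[lo, k] <- -xn[lo, k]
          xn[hi, k] <- 2 * side - xn[hi, k]
          h[lo & !land, k] <- abs(h[lo & !land, k])
          h[hi & !land, k] <- -abs(h[hi & !land, k])
          if (any(land)) {
            landed[land] <- TRUE
            xn[land, ] <- pmin(pmax(xn[land, , drop = FALSE], eps), side - eps)
          }
        }
      }
      x <- pmin(pmax(xn, eps), side - eps)
    }
    pos[t, , ] <- x
    ang <- dir_to_angles(h)
    theta[t, ] <- ang$theta
    phi[t, ] <- ang$phi
    alive[t, ] <- !landed
  }
  structure(list(pos = pos, theta = theta, phi = phi, alive = alive,
                 arena = arena, fps = fps, seed = seed,
                 params = list(mean_speed = mean_speed, speed_sd = speed_sd,
                               turn_sd = turn_sd, saccade_prob = saccade_prob,
                               saccade_sd = saccade_sd,
                               repulsion_radius = repulsion_radius,
                               repulsion_strength = repulsion_strength,
                               cohesion_radius = cohesion_radius,
                               cohesion_strength = cohesion_strength),
                 kind = "swarm"),
            class = "swarm_truth")
}

# summed pairwise velocity bias: repulsion inside r_rep, cohesion toward the
# centroid of neighbours inside r_coh
social_force <- function(x, r_rep, k_rep, r_coh, k_coh) {
  n <- nrow(x)
  f <- matrix(0, n, 3)
  if (n < 2L) return(f)
  d <- as.matrix(stats::dist(x))
  diag(d) <- Inf
  for (i in seq_len(n)) {
    if (k_rep > 0 && r_rep > 0) {
      j <- which(d[i, ] < r_rep)
      if (length(j)) {
        sep <- sweep(-x[j, , drop = FALSE], 2, x[i, ], "+")  # x_i - x_j
        w <- k_rep * (1 - d[i, j] / r_rep) / pmax(d[i, j], 1e-9)
        f[i, ] <- f[i, ] + colSums(sep * w)
      }
    }
    if (k_coh > 0 && r_coh > 0) {
      j <- which(d[i, ] < r_coh)
      if (length(j)) {
        ctr <- colMeans(x[j, , drop = FALSE])
        dd <- sqrt(sum((ctr - x[i, ])^2))
        if (dd > 1e-9) f[i, ] <- f[i, ] + k_coh * (ctr - x[i, ]) / dd
      }
    }
  }
  f
}

#' Simulate non-interacting random particles (Brownian null model)
#'
#' Physical random particles moving in the confined arena volume: uniform
#' initial positions, i.i.d. Gaussian displacements each step, reflective
#' walls. This is the social-force-free null model against which the spatial
#' structure of real swarms is compared.
#'
#' @param n_particles number of particles (>= 2).
#' @param arena an \code{\link{arena_config}}.
#' @param n_steps number of steps (default 3000, as in the null simulations).
#' @param step_sd per-axis displacement standard deviation per step (mm);
#'   default 4 mm, the displacement scale of a fly flying 400 mm/s filmed at
#'   100 fps.
#' @param seed RNG seed.
#' @return a \code{"swarm_truth"} object (see \code{\link{simulate_swarm}}).
#' @export
simulate_random_particles <- function(n_particles, arena = arena_config(),
                                      n_steps = 3000L, step_sd = 4,
                                      seed = 1L) {
  if (n_particles < 2) stop("n_particles must be >= 2")
  if (step_sd < 0) stop("step_sd must be non-negative")
  set.seed(seed)
  side <- arena$side
  eps <- 1e-6
  pos <- array(NA_real_, c(n_steps, n_particles, 3))
  theta <- matrix(0, n_steps, n_particles)
  phi <- matrix(0, n_steps, n_particles)
  x <- matrix(runif(3 * n_particles, 0, side), n_particles, 3)
  for (t in seq_len(n_steps)) {
    if (t > 1L) {
      stp <- matrix(rnorm(3 * n_particles, 0, step_sd), n_particles, 3)
      xn <- x + stp
      xn <- reflect_into(xn, side)
      if (step_sd > 0) {
        ang <- dir_to_angles_safe(xn - x)
        theta[t, ] <- ang$theta
        phi[t, ] <- ang$phi
      }
      x <- pmin(pmax(xn, eps), side - eps)
    }
    pos[t, , ] <- x
  }
  structure(list(pos = pos, theta = theta, phi = phi,
                 alive = matrix(TRUE, n_steps, n_particles),
                 arena = arena, fps = NA_real_, seed = seed,
                 params = list(step_sd = step_sd), kind = "random_particles"),
            class = "swarm_truth")
}

# reflect coordinates into [0, side] (handles multiple bounces)
reflect_into <- function(x, side) {
  x <- x %% (2 * side)
  over <- x > side
  x[over] <- 2 * side - x[over]
  x
}

dir_to_angles_safe <- function(d) {
  n <- sqrt(rowSums(d^2))
  zero <- n < 1e-12
  d[zero, ] <- matrix(rep(c(1, 0, 0), each = sum(zero)), ncol = 3)
  dir_to_angles(d)
}

#' Flatten ground truth to a trajectory table
#'
#' @param x a \code{"swarm_truth"}.
#' @param ... unused.
#' @return data frame with columns \code{track_id, frame, x_mm, y_mm, z_mm,
#'   theta_deg, phi_deg, flying} (one row per fly per frame) -- the same
#'   schema the tracker emits.
#' @export
as.data.frame.swarm_truth <- function(x, ...) {
  nf <- dim(x$pos)[1]; nb <- dim(x$pos)[2]
  data.frame(
    track_id = rep(seq_len(nb), each = nf),
    frame = rep(seq_len(nf), nb),
    x_mm = as.vector(x$pos[, , 1]),
    y_mm = as.vector(x$pos[, , 2]),
    z_mm = as.vector(x$pos[, , 3]),
    theta_deg = as.vector(x$theta) * 180 / pi,
    phi_deg = as.vector(x$phi) * 180 / pi,
    flying = as.vector(x$alive))
}

#' @export
print.swarm_truth <- function(x, ...) {
  cat(sprintf("<swarm_truth: %s, %d frames x %d individuals, arena %g mm>\n",
              x$kind, dim(x$pos)[1], dim(x$pos)[2], x$arena$side))
  invisible(x)
}
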