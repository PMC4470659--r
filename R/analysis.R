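#' Per-track kinematics from a trajectory table
#'
#' Central-difference velocity and acceleration (scaled by the frame rate)
#' and angular velocity, the angle between consecutive velocity vectors
#' times the frame rate, in degrees per second. Angular velocity is defined
#' on the velocity direction (flight heading), which is where saccades show;
#' set \code{on = "orientation"} to use the body axis instead. Records exist
#' only for interior frames of each track.
#'
#' @param trajectory data frame with columns \code{track_id, frame, x_mm,
#'   y_mm, z_mm} (and \code{theta_deg, phi_deg} for the orientation
#'   variant). Frames within a track must be consecutive.
#' @param fps frame rate (default 100).
#' @param min_length drop tracks shorter than this many frames (default 3).
#' @param on "velocity" (default) or "orientation".
#' @param smooth optional Savitzky-Golay position smoothing window (odd,
#'   >= 5) applied before differentiation; 0 (default) disables.
#' @return data frame: track_id, frame, vx, vy, vz (mm/s), speed (mm/s),
#'   ax, ay, az (mm/s^2), accel (mm/s^2), ang_vel (degrees/s).
#' @export
kinematics <- function(trajectory, fps = 100, min_length = 3L,
                       on = c("velocity", "orientation"), smooth = 0L) {
  on <- match.arg(on)
  out <- list()
  for (id in unique(trajectory$track_id)) {
    tr <- trajectory[trajectory$track_id == id, , drop = FALSE]
    tr <- tr[order(tr$frame), , drop = FALSE]
    n <- nrow(tr)
    if (n < max(3L, min_length)) next
    P <- as.matrix(tr[, c("x_mm", "y_mm", "z_mm")])
    if (smooth >= 5L) P <- apply(P, 2, sg_smooth, window = smooth)
    i <- 2:(n - 1L)
    V <- (P[i + 1L, , drop = FALSE] - P[i - 1L, , drop = FALSE]) * (fps / 2)
    A <- (P[i + 1L, , drop = FALSE] - 2 * P[i, , drop = FALSE] +
            P[i - 1L, , drop = FALSE]) * fps^2
    speed <- sqrt(rowSums(V^2))
    if (on == "velocity") {
      D <- V
    } else {
      D <- angles_to_dir(tr$theta_deg * pi / 180, tr$phi_deg * pi / 180)[i, ,
                                                                         drop = FALSE]
    }
    av <- rep(NA_real_, length(i))
    if (length(i) >= 2L) {
      d1 <- D[-nrow(D), , drop = FALSE]
      d2 <- D[-1L, , drop = FALSE]
      cc <- rowSums(d1 * d2) /
        pmax(sqrt(rowSums(d1^2) * rowSums(d2^2)), 1e-12)
      dang <- acos(pmin(1, pmax(-1, cc))) * 180 / pi * fps
      av <- c(dang, dang[length(dang)])   # carry last interval forward
    }
    out[[length(out) + 1L]] <- data.frame(
      track_id = id, frame = tr$frame[i],
      vx = V[, 1], vy = V[, 2], vz = V[, 3], speed = speed,
      ax = A[, 1], ay = A[, 2], az = A[, 3], accel = sqrt(rowSums(A^2)),
      ang_vel = av)
  }
  if (!length(out))
    return(data.frame(track_id = integer(), frame = integer(), vx = numeric(),
                      vy = numeric(), vz = numeric(), speed = numeric(),
                      ax = numeric(), ay = numeric(), az = numeric(),
                      accel = numeric(), ang_vel = numeric()))
  do.call(rbind, out)
}

# Savitzky-Golay quadratic smoothing via running least squares
sg_smooth <- function(x, window = 5L) {
  h <- (window - 1L) %/% 2L
  n <- length(x)
  out <- x
  for (k in seq_len(n)) {
    lo <- max(1L, k - h); hi <- min(n, k + h)
    t <- (lo:hi) - k
    fit <- stats::lm.fit(cbind(1, t, t^2), x[lo:hi])
    out[k] <- fit$coefficients[1]
  }
  out
}

#' Standard scores of a series
#'
#' @param x numeric vector (>= 2 values, positive spread).
#' @return list with \code{z} (standardized series), \code{mu}, \code{sigma}
#'   (sample standard deviation).
#' @export
zscores <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2L) stop("need at least 2 samples")
  mu <- mean(x)
  sigma <- stats::sd(x)
  if (sigma <= 0) stop("zero variance: z-scores undefined")
  list(z = (x - mu) / sigma, mu = mu, sigma = sigma)
}

#' Polarisation order parameter of a group
#'
#' The norm of the mean unit-velocity vector,
#' \code{Phi = |sum_i v_i / |v_i|| / N}: 0 for disordered motion, 1 for a
#' fully aligned group. Zero-speed individuals are excluded.
#'
#' @param velocities n x 3 matrix of velocities at one instant (mm/s).
#' @param min_speed exclusion threshold (mm/s).
#' @return Phi in [0, 1]; NA if no individual moves.
#' @export
polarisation <- function(velocities, min_speed = 1e-9) {
  velocities <- rbind3(velocities)
  sp <- sqrt(rowSums(velocities^2))
  keep <- sp > min_speed
  if (!any(keep)) return(NA_real_)
  u <- velocities[keep, , drop = FALSE] / sp[keep]
  sqrt(sum(colMeans(u)^2))
}

#' Nearest-neighbour distances at one instant
#'
#' Per fly, the minimum Euclidean distance to any other fly. Edge effects
#' are controlled by the wall margin: a focal fly closer than \code{margin}
#' to any arena wall is flagged excluded (landed and wall-hugging flies bias
#' the statistics), but still serves as a neighbour for interior flies; set
#' \code{gate_neighbours = TRUE} to drop wall-adjacent flies from the
#' neighbour set too.
#'
#' @param positions n x 3 matrix (mm).
#' @param arena an \code{\link{arena_config}} (supplies the margin).
#' @param margin wall margin (mm); defaults to \code{arena$margin}.
#' @param gate_neighbours also exclude wall-adjacent flies as neighbours.
#' @return data frame: fly, nnd (mm), wall_dist (mm), included.
#' @export
nnd <- function(positions, arena = arena_config(), margin = arena$margin,
                gate_neighbours = FALSE) {
  positions <- rbind3(positions)
  n <- nrow(positions)
  if (n < 2L)
    return(data.frame(fly = integer(), nnd = numeric(),
                      wall_dist = numeric(), included = logical()))
  wall <- pmin(apply(positions, 1, min),
               apply(arena$side - positions, 1, min))
  D <- as.matrix(stats::dist(positions))
  diag(D) <- Inf
  if (gate_neighbours) D[, wall < margin] <- Inf
  nn <- apply(D, 1, min)
  data.frame(fly = seq_len(n), nnd = nn, wall_dist = wall,
             included = wall >= margin & is.finite(nn))
}

#' Per-frame NND summary over a trajectory table
#'
#' @param trajectory trajectory data frame (tracker output schema).
#' @param arena an \code{\link{arena_config}}.
#' @param min_flies minimum simultaneous flies for a frame to count.
#' @return data frame: frame, n_flies, density (flies/mm^3 over the arena
#'   volume), mean_nnd over included flies.
#' @export
nnd_by_frame <- function(trajectory, arena = arena_config(), min_flies = 2L) {
  out <- list()
  for (t in sort(unique(trajectory$frame))) {
    rows <- trajectory[trajectory$frame == t, , drop = FALSE]
    if (nrow(rows) < min_flies) next
    r <- nnd(as.matrix(rows[, c("x_mm", "y_mm", "z_mm")]), arena)
    inc <- r$included
    if (!any(inc)) next
    out[[length(out) + 1L]] <- data.frame(
      frame = t, n_flies = nrow(rows),
      density = nrow(rows) / arena$side^3,
      mean_nnd = mean(r$nnd[inc]))
  }
  if (!length(out))
    return(data.frame(frame = integer(), n_flies = integer(),
                      density = numeric(), mean_nnd = numeric()))
  do.call(rbind, out)
}

#' Fit the decaying power law between density and average NND
#'
#' Nonlinear least squares for \code{y = A * x^(-B) + C} with multi-start
#' initialization (Levenberg-Marquardt). \code{C} is the asymptotic average
#' nearest-neighbour distance at high density -- the exclusive distance a
#' fly keeps from its neighbours.
#'
#' @param x population densities (flies/mm^3 or any consistent unit).
#' @param y average NNDs (mm).
#' @param n_starts number of random multi-starts.
#' @return object of class \code{"powerlaw_fit"}: coefficients A, B, C with
#'   standard errors, fitted values, residuals and the underlying
#'   \code{nls}-like fit.
#' @export
fit_power_law <- function(x, y, n_starts = 20L) {
  ok <- is.finite(x) & is.finite(y) & x > 0
  x <- x[ok]; y <- y[ok]
  if (length(x) < 4L) stop("need at least 4 points")
  if (max(x) / min(x) <= 2) stop("density range too narrow (< 2x)")
  if (stats::sd(y) < 1e-12)
    stop("constant response: decay rate unidentifiable")
  dat <- data.frame(x = x, y = y)
  set.seed(20121L)
  starts <- c(list(list(A = diff(range(y)) * stats::median(x)^0.5, B = 0.5,
                        C = min(y))),
              lapply(seq_len(n_starts - 1L), function(i)
                list(A = stats::runif(1, 0.1, 10) * diff(range(y)),
                     B = stats::runif(1, 0.1, 1.5),
                     C = stats::runif(1, 0, max(min(y), 1e-3)))))
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ A * x^(-B) + C, data = dat, start = st,
                        lower = c(A = 0, B = 1e-6, C = 0),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) stop("power-law fit failed to converge from all starts")
  fit <- best$fit
  sm <- summary(fit)
  co <- sm$coefficients
  structure(list(coefficients = co[, "Estimate"],
                 se = co[, "Std. Error"],
                 fitted = stats::fitted(fit),
                 residuals = stats::residuals(fit),
                 rss = best$rss, n = length(x), fit = fit,
                 data = dat),
            class = "powerlaw_fit")
}

#' @export
print.powerlaw_fit <- function(x, ...) {
  cat("Decaying power-law fit: y = A * x^(-B) + C\n")
  cf <- x$coefficients; se <- x$se
  for (k in names(cf))
    cat(sprintf("  %s = %.4g +/- %.3g\n", k, cf[[k]], se[[k]]))
  cat(sprintf("  n = %d, RSS = %.4g\n", x$n, x$rss))
  invisible(x)
}

#' @export
summary.powerlaw_fit <- function(object, ...) summary(object$fit, ...)

#' @export
coef.powerlaw_fit <- function(object, ...) object$coefficients

#' @export
predict.powerlaw_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$data$x else
    if (is.data.frame(newdata)) newdata$x else newdata
  cf <- object$coefficients
  cf[["A"]] * x^(-cf[["B"]]) + cf[["C"]]
}

#' @export
residuals.powerlaw_fit <- function(object, ...) object$residuals

# minimal rotation taking +x to the unit vector n (Rodrigues)
rotation_x_to <- function(n) {
  n <- n / sqrt(sum(n^2))
  v <- cross3(c(1, 0, 0), n)
  s <- sqrt(sum(v^2))
  c_ <- n[1]
  if (s < 1e-12) {
    if (c_ > 0) return(diag(3))
    return(diag(c(-1, -1, 1)))   # opposite direction: flip about z
  }
  K <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + K + K %*% K * ((1 - c_) / s^2)
}

#' Acceleration-direction map relative to the nearest neighbour
#'
#' For every included (fly, frame) record, the world frame is rotated by the
#' minimal rotation taking +x to the unit vector pointing at the fly's
#' nearest neighbour; the fly's acceleration is expressed in that frame and
#' binned by azimuth (-180..180 deg) and elevation (-90..90 deg). The centre
#' bin (0, 0) is acceleration straight towards the neighbour. The histogram
#' is normalized to a probability density over the angle rectangle; set
#' \code{solid_angle = TRUE} to weight each count by 1/cos(elevation) so the
#' density is per unit solid angle instead.
#'
#' @param trajectory trajectory table.
#' @param arena an \code{\link{arena_config}}.
#' @param fps frame rate.
#' @param nnd_range inclusion window on the NND, in mm (e.g.
#'   \code{c(0, 6 * 2.73)} for the short-range regime).
#' @param bins \code{c(n_azimuth, n_elevation)}.
#' @param solid_angle apply solid-angle weighting.
#' @return list with \code{density} (matrix azimuth x elevation, integrates
#'   to 1 over the angle rectangle in degrees), \code{azimuth_breaks},
#'   \code{elevation_breaks}, \code{n} (records used).
#' @export
acceleration_direction_map <- function(trajectory, arena = arena_config(),
                                       fps = 100,
                                       nnd_range = c(0, Inf),
                                       bins = c(36L, 18L),
                                       solid_angle = FALSE) {
  kin <- kinematics(trajectory, fps = fps)
  az_br <- seq(-180, 180, length.out = bins[1] + 1L)
  el_br <- seq(-90, 90, length.out = bins[2] + 1L)
  counts <- matrix(0, bins[1], bins[2])
  n_used <- 0L
  for (t in sort(unique(kin$frame))) {
    rows <- trajectory[trajectory$frame == t, , drop = FALSE]
    if (nrow(rows) < 2L) next
    P <- as.matrix(rows[, c("x_mm", "y_mm", "z_mm")])
    r <- nnd(P, arena)
    D <- as.matrix(stats::dist(P)); diag(D) <- Inf
    krows <- kin[kin$frame == t, , drop = FALSE]
    for (i in seq_len(nrow(rows))) {
      if (!r$included[i]) next
      if (r$nnd[i] < nnd_range[1] || r$nnd[i] > nnd_range[2]) next
      k <- krows[krows$track_id == rows$track_id[i], , drop = FALSE]
      if (!nrow(k)) next
      a <- c(k$ax[1], k$ay[1], k$az[1])
      if (sum(a^2) < 1e-12) next
      j <- which.min(D[i, ])
      nvec <- P[j, ] - P[i, ]
      R <- rotation_x_to(nvec)
      al <- drop(t(R) %*% a)
      ang <- dir_to_angles(al)
      azi <- ang$theta * 180 / pi
      ele <- ang$phi * 180 / pi
      bi <- min(bins[1], max(1L, findInterval(azi, az_br, all.inside = TRUE)))
      bj <- min(bins[2], max(1L, findInterval(ele, el_br, all.inside = TRUE)))
      wgt <- if (solid_angle) 1 / max(cos(ang$phi), 0.05) else 1
      counts[bi, bj] <- counts[bi, bj] + wgt
      n_used <- n_used + 1L
    }
  }
  total <- sum(counts)
  cell <- diff(az_br)[1] * diff(el_br)[1]
  dens <- if (total > 0) counts / (total * cell) else counts
  list(density = dens, azimuth_breaks = az_br, elevation_breaks = el_br,
       n = n_used)
}

#' Compare an NND sample against the random-particle null
#'
#' For homogeneous random (Poisson) particles at intensity \code{lambda} the
#' NND follows a Weibull distribution with shape 3 and scale
#' \code{(4/3 pi lambda)^(-1/3)}; the closed-form maximum-likelihood
#' estimate of \code{lambda} from the null sample is reported together with
#' a Welch two-sample t-test between the real and simulated samples and the
#' shift direction.
#'
#' @param real_nnd NND sample from tracked flies (mm).
#' @param null_nnd NND sample from a matched random-particle simulation (mm).
#' @return list with \code{lambda_hat} (per mm^3), \code{scale_hat} (mm),
#'   \code{t} (Welch statistic), \code{p}, \code{mean_real},
#'   \code{mean_null}, \code{left_shifted} (real mean below null mean).
#' @export
compare_to_random <- function(real_nnd, null_nnd) {
  real_nnd <- real_nnd[is.finite(real_nnd) & real_nnd > 0]
  null_nnd <- null_nnd[is.finite(null_nnd) & null_nnd > 0]
  if (length(real_nnd) < 30L || length(null_nnd) < 30L)
    stop("need at least 30 NNDs in each sample")
  # Weibull(shape 3) MLE: scale^3 = mean(r^3); lambda from 4/3 pi lambda s^3 = 1
  s3 <- mean(null_nnd^3)
  lambda_hat <- 1 / (4 / 3 * pi * s3)
  tt <- stats::t.test(real_nnd, null_nnd)
  list(lambda_hat = lambda_hat, scale_hat = s3^(1 / 3),
       t = unname(tt$statistic), p = tt$p.value,
       mean_real = mean(real_nnd), mean_null = mean(null_nnd),
       left_shifted = mean(real_nnd) < mean(null_nnd))
}

#' Pool NNDs of a trajectory table
#'
#' All per-frame, per-fly NNDs of included (interior) flies, pooled.
#'
#' @param trajectory trajectory table.
#' @param arena an \code{\link{arena_config}}.
#' @param frames optional frame subset.
#' @return numeric vector of NNDs (mm).
#' @export
pool_nnds <- function(trajectory, arena = arena_config(), frames = NULL) {
  if (is.null(frames)) frames <- sort(unique(trajectory$frame))
  out <- numeric(0)
  for (t in frames) {
    rows <- trajectory[trajectory$frame == t, , drop = FALSE]
    if (nrow(rows) < 2L) next
    r <- nnd(as.matrix(rows[, c("x_mm", "y_mm", "z_mm")]), arena)
    out <- c(out, r$nnd[r$included])
  }
  out
}
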