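#' Two-camera rig at body-resolving pixel scale
#'
#' A zoomed pair of near-orthogonal cameras used by the orientation
#' benchmark: the field of view spans only the central portion of the arena
#' so a fly's body covers 10-14 pixels, proportionally matching the full
#' experimental rig where the 2040-pixel sensor spans the 360 mm arena.
#'
#' @param arena an \code{\link{arena_config}}.
#' @param image_size image size (px).
#' @param fov_mm field-of-view span at the arena centre (mm).
#' @param distance_mm camera distance (mm).
#' @return list of two \code{camera_model}s.
#' @export
orientation_test_rig <- function(arena = arena_config(),
                                 image_size = c(512L, 512L), fov_mm = 120,
                                 distance_mm = 900) {
  ctr <- rep(arena$side / 2, 3)
  axes <- list(c(1, 0.12, 0.07), c(0.07, 1, 0.12))
  focal <- min(image_size) * distance_mm / fov_mm
  lapply(1:2, function(v) {
    a <- axes[[v]] / sqrt(sum(axes[[v]]^2))
    make_lookat_camera(ctr + distance_mm * a, ctr, up = c(0, 0, 1),
                       focal_px = focal, image_size = image_size, id = v)
  })
}

#' Orientation-reconstruction error benchmark
#'
#' Renders flies with random body axes as pixelated back-lit silhouettes
#' into two near-orthogonal cameras at body-resolving scale, runs the full
#' detection chain, keeps the cases where the fitted ellipses reach the
#' axis-ratio threshold \code{gamma >= gamma_min} in both views, and
#' reconstructs each orientation by intersecting the two back-projected
#' major-axis planes. The error is \code{epsilon = 1 - cos(alpha)} with
#' \code{alpha} the angle between reconstructed and true axis.
#'
#' Flies are placed a few per frame on a jittered grid (with a minimum
#' projected separation so silhouettes never merge) inside the central
#' region covered by the zoomed rig.
#'
#' @param n_flies number of flies to render (>= 1).
#' @param gamma_min axis-ratio threshold (default 1.3).
#' @param cameras two-camera rig (default \code{\link{orientation_test_rig}}).
#' @param rc render configuration.
#' @param cfg run configuration.
#' @param seed RNG seed.
#' @param flies_per_frame flies per rendered frame.
#' @return data frame with one row per rendered fly: \code{theta},
#'   \code{phi} (true, radians), \code{gamma1}, \code{gamma2} (fitted axis
#'   ratios, NA when undetected), \code{eligible} (both gammas >=
#'   \code{gamma_min}), \code{eps} (1 - cos(alpha), NA when not
#'   reconstructable). Attribute \code{"mean_eps"} is the mean over eligible
#'   cases.
#' @export
orientation_benchmark <- function(n_flies = 500L, gamma_min = 1.3,
                                  cameras = orientation_test_rig(),
                                  rc = render_config(),
                                  cfg = run_config(), seed = 1L,
                                  flies_per_frame = 10L) {
  rc$seed <- as.integer(seed)      # rendering noise follows the same seed
  arena_ctr <- 180
  half <- 40                       # placement cube half-side (mm)
  rows <- list()
  n_done <- 0L
  frame_id <- 0L
  bg_frames <- lapply(1:12, function(t)
    render_frame(NULL, NULL, cameras, rc, frame = 900000L + t)$images)
  bgs <- lapply(seq_along(cameras), function(v)
    fit_background(lapply(bg_frames, `[[`, v), cfg$sigma_floor))
  while (n_done < n_flies) {
    frame_id <- frame_id + 1L
    # renders reseed the global RNG, so poses get their own seed stream
    set.seed(derive_seed(seed, frame_id, 7L))
    k <- min(flies_per_frame, n_flies - n_done)
    # rejection-sample positions with a minimum projected separation
    pos <- matrix(NA_real_, 0, 3)
    guard <- 0L
    while (nrow(pos) < k && guard < 1000L) {
      guard <- guard + 1L
      p <- arena_ctr + stats::runif(3, -half, half)
      ok <- TRUE
      if (nrow(pos)) for (cam in cameras) {
        d <- sqrt(rowSums(sweep(project_points(cam, pos), 2,
                                project_points(cam, p))^2))
        if (min(d) < 25) { ok <- FALSE; break }
      }
      if (ok) pos <- rbind(pos, p)
    }
    k <- nrow(pos)
    th <- stats::runif(k, -pi, pi)
    ph <- asin(stats::runif(k, -1, 1))
    fr <- render_frame(pos, cbind(th, ph), cameras, rc, frame = frame_id)
    meas <- lapply(seq_along(cameras), function(v)
      detect(fr$images[[v]], bgs[[v]], cfg, view = v, frame = frame_id))
    for (f in seq_len(k)) {
      g <- rep(NA_real_, 2)
      mm <- vector("list", 2)
      for (v in 1:2) {
        gtv <- fr$gt2d[fr$gt2d$view == v & fr$gt2d$fly == f, ]
        if (!length(meas[[v]])) next
        dd <- vapply(meas[[v]], function(m)
          sqrt(sum((m$ellipse$center - c(gtv$u, gtv$v_px))^2)), 1.0)
        j <- which.min(dd)
        if (dd[j] < 1.5) { g[v] <- meas[[v]][[j]]$ellipse$gamma; mm[[v]] <- meas[[v]][[j]] }
      }
      eligible <- !anyNA(g) && all(g >= gamma_min)
      eps <- NA_real_
      if (eligible) {
        truth_dir <- drop(angles_to_dir(th[f], ph[f]))
        ori <- compute_orientation(mm, cameras, gamma_min = gamma_min,
                                   ref_dir = truth_dir)
        if (!is.null(ori)) eps <- 1 - sum(ori$dir * truth_dir)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        theta = th[f], phi = ph[f], gamma1 = g[1], gamma2 = g[2],
        eligible = eligible && !is.na(eps), eps = eps)
    }
    n_done <- n_done + k
  }
  out <- do.call(rbind, rows)
  attr(out, "mean_eps") <- mean(out$eps[out$eligible], na.rm = TRUE)
  out
}
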