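#' Rendering configuration for synthetic back-lit views
#'
#' Emulates the back-lit imaging geometry: a bright, nearly uniform
#' background (diffused planar illumination), dark body silhouettes, and
#' semi-transparent wings at an intermediate grey level. Intensities are
#' 8-bit grey levels. The background pixel noise is sub-quantization by
#' default (back-lit LED panels behind a diffuser are very stable), so the
#' background-model sigma floor dominates during detection.
#'
#' @param background_mean background grey level (default 200).
#' @param noise_sd background pixel noise standard deviation in grey levels
#'   (default 0.5).
#' @param body_level body silhouette grey level (default 60).
#' @param wing_level wing grey level (default 140); must satisfy
#'   body < wing < background.
#' @param wings render wings (default TRUE).
#' @param wing_jitter resample the wing stroke smear every frame (default
#'   TRUE); at 100 fps wing positions are inconsistent between frames, which
#'   the wing-removal step relies on.
#' @param wing_length wing length from hinge to tip (mm, default 2.5).
#' @param wing_alpha maximal wing opacity (0..1). Wings beat faster than the
#'   exposure time, so each wing is rendered as the faint motion-blurred
#'   shell swept during one exposure rather than a sharp membrane.
#' @param body_points surface samples per fly when rasterizing the body.
#' @param wing_points samples per wing smear.
#' @param level_noise_sd grey-level jitter on body/wing pixels.
#' @param seed base RNG seed; renders are bit-identical per seed.
#' @return object of class \code{"render_config"}.
#' @export
render_config <- function(background_mean = 200, noise_sd = 0.5,
                          body_level = 60, wing_level = 150,
                          wings = TRUE, wing_jitter = TRUE,
                          wing_length = 2.5, wing_alpha = 0.6,
                          body_points = 2000L, wing_points = 900L,
                          level_noise_sd = 2, seed = 1L) {
  if (!(body_level < wing_level && wing_level < background_mean))
    stop("intensity ordering violated: need body < wing < background")
  if (noise_sd <= 0) stop("noise_sd must be positive")
  if (wing_alpha <= 0 || wing_alpha > 1) stop("wing_alpha must be in (0, 1]")
  structure(list(background_mean = background_mean, noise_sd = noise_sd,
                 body_level = body_level, wing_level = wing_level,
                 wings = wings, wing_jitter = wing_jitter,
                 wing_length = wing_length, wing_alpha = wing_alpha,
                 body_points = as.integer(body_points),
                 wing_points = as.integer(wing_points),
                 level_noise_sd = level_noise_sd, seed = as.integer(seed)),
            class = "render_config")
}

# deterministic seed stream per (frame, view); view 0 seeds 3D wing geometry
derive_seed <- function(seed, frame, view = 0L) {
  as.integer((as.double(seed + 1L) * 1000003 + frame * 131 + view) %% 2147483629)
}

# sunflower lattice on the unit disk
disk_lattice <- function(n) {
  i <- seq_len(n)
  r <- sqrt((i - 0.5) / n)
  th <- pi * (3 - sqrt(5)) * (i - 1)
  cbind(r * cos(th), r * sin(th))
}

#' Render one synthetic frame in every camera view
#'
#' Draws each flying fly by projecting a dense sampling of its generative
#' body surface (body grey level) and, optionally, two planar wing ellipses
#' at the wing grey level with a per-frame random stroke angle. Surfaces
#' attenuate light by their pixel coverage, so wings never overdraw bodies.
#' Landed (non-flying) flies are rendered at their resting position with
#' folded wings (no wing smear). Flies projecting outside an image are
#' clipped silently and flagged in the returned 2D ground truth.
#'
#' @param positions n x 3 matrix of fly positions (mm); may have 0 rows.
#' @param orientations n x 2 matrix (theta, phi) in radians.
#' @param cameras list of \code{camera_model}s.
#' @param rc a \code{\link{render_config}}.
#' @param frame frame index (drives the deterministic noise/jitter streams).
#' @param body_length body length (mm).
#' @param profile body profile function.
#' @param alive logical vector (default all TRUE).
#' @param keep_body_pixels store each fly's rendered body pixel set in the
#'   ground truth (needed by detector-oracle tests).
#' @return list with \code{images} (list per view of integer H x W matrices,
#'   grey 0..255) and \code{gt2d} (data frame: view, fly, u, v sub-pixel
#'   projected body centroid, gamma of the projected body point cloud,
#'   visible flag) plus, if requested, \code{body_pixels[[view]][[fly]]}:
#'   a list with the body's touched pixels (\code{lin}, linear indices) and
#'   their coverage fractions (\code{alpha}; pixels with \code{alpha >= 0.5}
#'   are the body core).
#' @export
render_frame <- function(positions, orientations, cameras, rc,
                         frame = 1L, body_length = 2.73,
                         profile = spindle_profile(body_length),
                         alive = NULL, keep_body_pixels = FALSE) {
  positions <- if (is.null(positions) || NROW(positions) == 0)
    matrix(0, 0, 3) else rbind3(positions)
  n <- nrow(positions)
  if (n > 0 && is.null(dim(orientations)))
    orientations <- matrix(orientations, ncol = 2)
  if (is.null(alive)) alive <- rep(TRUE, n)

  # 3D wing geometry is shared across views: seed it once per frame. Each
  # wing is the motion-blurred shell swept during one exposure: span
  # directions fan fore-aft over the stroke arc with elevation scatter, so
  # the smear is a curved 3D surface that never projects to a sliver.
  # Landed flies fold their wings: no wing smear is drawn for them.
  wing_sets <- vector("list", n)
  if (rc$wings && n > 0) {
    set.seed(derive_seed(rc$seed, if (rc$wing_jitter) frame else 0L, 0L))
    for (f in seq_len(n)) {
      if (!alive[f]) next
      R <- orientation_rotation(orientations[f, 1], orientations[f, 2])
      d <- R[, 1]; lat <- R[, 2]; dors <- R[, 3]
      attach_pt <- positions[f, ] + d * (body_length / 6) # 1/3 from the head
      pts <- lapply(1:2, function(k) {
        s <- if (k == 1) 1 else -1
        m <- rc$wing_points
        stroke <- stats::runif(m, -15, 85) * pi / 180   # fore-aft sweep
        elev <- stats::runif(m, -30, 30) * pi / 180     # stroke-plane scatter
        dir <- outer(cos(elev) * cos(stroke), s * lat) -
          outer(cos(elev) * sin(stroke), d) + outer(sin(elev), dors)
        r <- sqrt(stats::runif(m)) * rc$wing_length
        w <- dir * r + matrix(stats::rnorm(3 * m, 0, 0.08), m, 3)
        sweep(w, 2, attach_pt, "+")
      })
      wing_sets[[f]] <- rbind(pts[[1]], pts[[2]])
    }
  }
  body_sets <- vector("list", n)
  for (f in seq_len(n))
    body_sets[[f]] <- generative_shape_points(
      positions[f, ], orientations[f, ], body_length, profile, rc$body_points)

  images <- vector("list", length(cameras))
  gt <- list()
  body_px <- if (keep_body_pixels) vector("list", length(cameras)) else NULL
  for (v in seq_along(cameras)) {
    cam <- cameras[[v]]
    H <- cam$image_size[1]; W <- cam$image_size[2]
    set.seed(derive_seed(rc$seed, frame, v))
    img <- matrix(stats::rnorm(H * W, rc$background_mean, rc$noise_sd), H, W)
    if (keep_body_pixels) body_px[[v]] <- vector("list", n)
    for (f in seq_len(n)) {
      # wings first (semi-transparent), body second (opaque core); each
      # surface attenuates the incoming light by its pixel coverage, which
      # emulates the optical blur of a silhouette a few pixels across
      if (rc$wings && !is.null(wing_sets[[f]])) {
        cv <- coverage_map(cam, wing_sets[[f]], H, W)
        if (length(cv$lin)) {
          a <- rc$wing_alpha * cv$alpha
          img[cv$lin] <- img[cv$lin] * (1 - a) + rc$wing_level * a +
            stats::rnorm(length(a), 0, rc$level_noise_sd * a)
        }
      }
      uv <- project_points(cam, body_sets[[f]])
      cv <- coverage_uv(uv, H, W)
      if (length(cv$lin)) {
        a <- cv$alpha
        img[cv$lin] <- img[cv$lin] * (1 - a) + rc$body_level * a +
          stats::rnorm(length(a), 0, rc$level_noise_sd * a)
      }
      if (keep_body_pixels)
        body_px[[v]][[f]] <- list(lin = cv$lin, alpha = cv$alpha)
      ctr <- colMeans(uv)
      gamma <- if (nrow(uv) >= 3) {
        ev <- eigen(stats::cov(uv), symmetric = TRUE, only.values = TRUE)$values
        sqrt(max(ev[1], 0) / max(ev[2], 1e-12))
      } else NA_real_
      gt[[length(gt) + 1L]] <- data.frame(
        view = v, fly = f, u = ctr[1], v_px = ctr[2], gamma = gamma,
        visible = length(cv$lin) > 0 &&
          ctr[1] >= 0 && ctr[1] <= W - 1 && ctr[2] >= 0 && ctr[2] <= H - 1)
    }
    img <- round(img)
    img[img < 0] <- 0L; img[img > 255] <- 255L
    storage.mode(img) <- "integer"
    images[[v]] <- img
  }
  out <- list(images = images,
              gt2d = if (length(gt)) do.call(rbind, gt) else
                data.frame(view = integer(), fly = integer(), u = numeric(),
                           v_px = numeric(), gamma = numeric(),
                           visible = logical()))
  if (keep_body_pixels) out$body_pixels <- body_px
  out
}

# project, round to integer pixels, clip, return unique linear indices
raster_points <- function(cam, pts, H, W) {
  raster_uv(project_points(cam, pts), H, W)
}

raster_uv <- function(uv, H, W) {
  col <- as.integer(round(uv[, 1])) + 1L
  row <- as.integer(round(uv[, 2])) + 1L
  ok <- col >= 1L & col <= W & row >= 1L & row <= H
  unique(row[ok] + (col[ok] - 1L) * H)
}

# per-pixel coverage of a projected surface point cloud: sample counts per
# pixel normalized by the core (dense) count, capped at 1. Pixels fully
# inside the silhouette reach alpha = 1; boundary pixels get fractional
# coverage, emulating a point-spread blur.
coverage_map <- function(cam, pts, H, W) {
  coverage_uv(project_points(cam, pts), H, W)
}

coverage_uv <- function(uv, H, W) {
  col <- as.integer(round(uv[, 1])) + 1L
  row <- as.integer(round(uv[, 2])) + 1L
  ok <- col >= 1L & col <= W & row >= 1L & row <= H
  if (!any(ok)) return(list(lin = integer(), alpha = numeric()))
  lin <- row[ok] + (col[ok] - 1L) * H
  tb <- table(lin)
  cnt <- as.numeric(tb)
  ref <- max(3, stats::quantile(cnt, 0.8))
  list(lin = as.integer(names(tb)), alpha = pmin(1, cnt / ref))
}

#' Render a ground-truth sequence into multi-view image stacks
#'
#' Convenience wrapper around \code{\link{render_frame}} for whole
#' \code{"swarm_truth"} objects. For long sequences prefer calling
#' \code{render_frame} per frame and discarding images as you go (the
#' closed-loop tracker driver does this).
#'
#' @param truth a \code{"swarm_truth"}.
#' @param cameras list of \code{camera_model}s.
#' @param rc a \code{\link{render_config}}.
#' @param frames frame indices to render (default: all).
#' @param dir if non-NULL, write 8-bit grayscale PNGs as
#'   \code{cam<v>/frame<t>.png} under this directory instead of keeping
#'   images in memory.
#' @param ... passed to \code{render_frame}.
#' @return list of per-frame \code{render_frame} results (images replaced by
#'   file paths when \code{dir} is given).
#' @export
render_views <- function(truth, cameras, rc, frames = NULL, dir = NULL, ...) {
  if (is.null(frames)) frames <- seq_len(dim(truth$pos)[1])
  if (!is.null(dir))
    for (v in seq_along(cameras))
      dir.create(file.path(dir, sprintf("cam%d", v)), recursive = TRUE,
                 showWarnings = FALSE)
  out <- vector("list", length(frames))
  for (k in seq_along(frames)) {
    t <- frames[k]
    fr <- render_frame(truth$pos[t, , , drop = TRUE],
                       cbind(truth$theta[t, ], truth$phi[t, ]),
                       cameras, rc, frame = t, alive = truth$alive[t, ], ...)
    if (!is.null(dir)) {
      paths <- character(length(cameras))
      for (v in seq_along(cameras)) {
        paths[v] <- file.path(dir, sprintf("cam%d", v),
                              sprintf("frame%06d.png", t))
        png::writePNG(fr$images[[v]] / 255, paths[v])
      }
      fr$images <- paths
    }
    out[[k]] <- fr
  }
  names(out) <- as.character(frames)
  out
}
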