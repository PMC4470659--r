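# Shared fixtures, built lazily and cached for the whole test run.
.fx <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fx[[name]])) .fx[[name]] <- build()
  .fx[[name]]
}

# zoomed two-camera rig (flies ~12 px long) with trained background models
zoom_rig <- function() fixture("zoom_rig", function() {
  cams <- orientation_test_rig()
  rc <- render_config()
  cfg <- run_config()
  bg_frames <- lapply(1:10, function(t)
    render_frame(NULL, NULL, cams, rc, frame = 900000L + t)$images)
  bgs <- lapply(seq_along(cams), function(v)
    fit_background(lapply(bg_frames, `[[`, v), cfg$sigma_floor))
  list(cams = cams, rc = rc, cfg = cfg, bgs = bgs)
})

# full-arena three-camera rig with trained background models
arena_rig <- function() fixture("arena_rig", function() {
  arena <- arena_config()
  cams <- default_camera_rig(arena)
  rc <- render_config()
  cfg <- run_config()
  bg_frames <- lapply(1:15, function(t)
    render_frame(NULL, NULL, cams, rc, frame = 800000L + t)$images)
  bgs <- lapply(seq_along(cams), function(v)
    fit_background(lapply(bg_frames, `[[`, v), cfg$sigma_floor))
  list(arena = arena, cams = cams, rc = rc, cfg = cfg, bgs = bgs)
})

# three simple synthetic cameras around the arena centre (no rendering)
toy_cameras <- function(image_size = c(512L, 512L)) {
  ctr <- c(180, 180, 180)
  lapply(1:3, function(v) {
    a <- list(c(1, 0.1, 0.05), c(0.05, 1, 0.1), c(0.1, 0.05, 1))[[v]]
    a <- a / sqrt(sum(a^2))
    make_lookat_camera(ctr + 900 * a, ctr, up = if (v == 3) c(1, 0, 0)
                       else c(0, 0, 1),
                       focal_px = 2000, image_size = image_size, id = v)
  })
}

# a flat-plane camera: world (x, y, z ~ 0) maps to pixel (x, y) exactly
plane_camera <- function(H = 64L, W = 64L) {
  P <- rbind(c(10, 0, 0, 0),
             c(0, 10, 0, 0),
             c(0, 0, 1, 10))
  camera_model(P, image_size = c(H, W), id = 1L)
}

# wrap a set of pixel (row, col) indices as a minimal measurement list
as_measurement <- function(rows, cols, H, I = NULL, view = 1L) {
  lin <- rows + (cols - 1L) * H
  if (is.null(I)) I <- rep(50, length(lin))
  list(blob = list(lin = lin, row = rows, col = cols,
                   u = cols - 1L, v = rows - 1L, I = I),
       ellipse = NULL, view = view, frame = 1L, n_pixels = length(lin))
}

# exact ellipse measurement from a projected 3D segment (noise-free axes)
exact_segment_measurement <- function(cam, p_center, direction, half_len,
                                      gamma = 3) {
  ep <- project_points(cam, rbind(p_center + direction * half_len,
                                  p_center - direction * half_len))
  ctr <- colMeans(ep)
  d <- ep[1, ] - ctr
  ang <- atan2(d[2], d[1])
  a <- sqrt(sum(d^2))
  list(blob = NULL,
       ellipse = structure(list(center = ctr, cov = NULL,
                                semi_major = a, semi_minor = a / gamma,
                                angle = ang, gamma = gamma),
                           class = "ellipse_fit"),
       view = cam$id, frame = 1L, n_pixels = 0L)
}

expect_close <- function(actual, expected, tol = 1e-9) {
  expect_lt(max(abs(actual - expected)), tol)
}
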