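#' Pinhole camera model
#'
#' Constructs a finite projective (pinhole) camera from its 3x4 projection
#' matrix. The matrix maps homogeneous world coordinates in millimetres to
#' homogeneous pixel coordinates. Pixel coordinates are 0-based and
#' real-valued (sub-pixel): \code{u} runs along image columns, \code{v} along
#' rows.
#'
#' @param P numeric 3x4 projection matrix of full rank (rank 3).
#' @param image_size integer vector \code{c(height, width)} in pixels.
#' @param id small integer camera identifier.
#' @return an object of class \code{"camera_model"} with elements \code{P},
#'   \code{image_size}, \code{id} and the precomputed camera centre
#'   \code{center} (world mm).
#' @export
camera_model <- function(P, image_size, id = 1L) {
  P <- as.matrix(P)
  if (!all(dim(P) == c(3L, 4L))) stop("P must be a 3x4 matrix")
  if (!all(is.finite(P))) stop("P must be finite")
  if (qr(P)$rank < 3L) stop("P must have rank 3")
  image_size <- as.integer(image_size)
  if (length(image_size) != 2L || any(image_size < 1L))
    stop("image_size must be c(height, width), both positive")
  M <- P[, 1:3]
  if (abs(det(M)) < 1e-12)
    stop("camera is not finite (left 3x3 block of P is singular)")
  center <- drop(-solve(M, P[, 4]))
  structure(list(P = P, image_size = image_size, id = as.integer(id),
                 center = center, M = M),
            class = "camera_model")
}

#' @export
print.camera_model <- function(x, ...) {
  cat(sprintf("<camera_model #%d>  image %d x %d px, centre (%.1f, %.1f, %.1f) mm\n",
              x$id, x$image_size[1], x$image_size[2],
              x$center[1], x$center[2], x$center[3]))
  invisible(x)
}

#' Project world points into a camera
#'
#' Applies the projective mapping \code{P [x y z 1]'} and dehomogenizes.
#'
#' @param camera a \code{camera_model}.
#' @param pts numeric vector of length 3 or an n x 3 matrix of world points (mm).
#' @return an n x 2 matrix of pixel coordinates \code{(u, v)} (0-based,
#'   sub-pixel real).
#' @export
project_points <- function(camera, pts) {
  pts <- rbind3(pts)
  if (!all(is.finite(pts))) stop("points must be finite")
  h <- cbind(pts, 1) %*% t(camera$P)
  w <- h[, 3]
  if (any(abs(w) < 1e-12))
    stop("degenerate projection: point on the camera's principal plane")
  cbind(u = h[, 1] / w, v = h[, 2] / w)
}

# coerce a length-3 vector or n x 3 matrix to n x 3 matrix
rbind3 <- function(pts) {
  if (is.null(dim(pts))) {
    if (length(pts) != 3L) stop("expected a 3-vector or n x 3 matrix")
    matrix(pts, nrow = 1L)
  } else {
    pts <- as.matrix(pts)
    if (ncol(pts) != 3L) stop("expected a 3-vector or n x 3 matrix")
    pts
  }
}

#' Triangulate a world point from two or more views
#'
#' Linear (DLT) triangulation: the homogeneous least-squares solution of the
#' stacked equations \code{u p3' - p1'} and \code{v p3' - p2'} over all views,
#' solved by SVD. Deterministic, no initialization.
#'
#' @param cameras list of \code{camera_model}s (length >= 2).
#' @param uv an n x 2 matrix of observed pixel coordinates, row i from
#'   \code{cameras[[i]]}.
#' @return world point as a length-3 numeric vector (mm).
#' @export
triangulate <- function(cameras, uv) {
  uv <- as.matrix(uv)
  n <- length(cameras)
  if (n < 2L) stop("triangulation needs at least 2 views")
  if (nrow(uv) != n) stop("one pixel observation per camera required")
  A <- matrix(0, 2L * n, 4L)
  for (i in seq_len(n)) {
    P <- cameras[[i]]$P
    A[2L * i - 1L, ] <- uv[i, 1] * P[3, ] - P[1, ]
    A[2L * i,      ] <- uv[i, 2] * P[3, ] - P[2, ]
  }
  sv <- svd(A)
  # rank-deficiency: identical cameras / parallel rays leave >1 vanishing
  # singular value
  if (sv$d[3] < 1e-9 * sv$d[1])
    stop("untriangulatable: viewing rays are parallel or cameras coincide")
  X <- sv$v[, 4]
  if (abs(X[4]) < 1e-12 * max(abs(X)))
    stop("untriangulatable: point at infinity")
  X[1:3] / X[4]
}

#' Back-project a pixel to its viewing ray direction
#'
#' @param camera a \code{camera_model}.
#' @param uv pixel coordinates, length-2 vector or n x 2 matrix.
#' @return n x 3 matrix of (unnormalized) ray directions; the ray is
#'   \code{center + t * direction}, t > 0 in front of the camera.
#' @export
backproject_ray <- function(camera, uv) {
  if (is.null(dim(uv))) uv <- matrix(uv, nrow = 1L)
  t(solve(camera$M, t(cbind(uv, 1))))
}

#' Plane spanned by the viewing rays of a pixel segment
#'
#' The projection rays of two distinct pixels pass through the camera centre;
#' together they span a plane in the world frame. Used to reconstruct the
#' body axis: the plane of a fitted ellipse's major-axis endpoints contains
#' the fly's centre-axis.
#'
#' @param camera a \code{camera_model}.
#' @param endpoints 2 x 2 matrix, one pixel \code{(u, v)} per row.
#' @return object of class \code{"plane3d"}: list with unit \code{normal} and
#'   scalar \code{offset} such that the plane is \code{normal . x == offset}.
#' @export
backproject_segment_plane <- function(camera, endpoints) {
  endpoints <- as.matrix(endpoints)
  if (!all(dim(endpoints) == c(2L, 2L))) stop("endpoints must be 2 x 2 (u, v)")
  if (sqrt(sum((endpoints[1, ] - endpoints[2, ])^2)) < 1e-9)
    stop("degenerate: coincident endpoints")
  rays <- backproject_ray(camera, endpoints)
  n <- cross3(rays[1, ], rays[2, ])
  nn <- sqrt(sum(n^2))
  if (nn < 1e-12) stop("degenerate: rays are parallel")
  n <- n / nn
  structure(list(normal = n, offset = sum(n * camera$center)),
            class = "plane3d")
}

#' Direction of the intersection line of two planes
#'
#' @param a,b \code{plane3d} objects with unit normals.
#' @param tol smallest acceptable sine of the angle between the normals.
#' @return unit 3-vector along the cross line; its sign is arbitrary (the
#'   tracker disambiguates head/tail separately).
#' @export
intersect_planes <- function(a, b, tol = 1e-6) {
  d <- cross3(a$normal, b$normal)
  nd <- sqrt(sum(d^2))
  if (nd < tol)
    stop("near-parallel planes: line direction unrecoverable")
  d / nd
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Build a camera looking at a target point
#'
#' Convenience constructor for synthetic rigs: a distortion-free pinhole
#' camera at \code{position} whose optical axis points at \code{target}, with
#' square pixels, focal length in pixels, and principal point at the image
#' centre.
#'
#' @param position,target world points (mm).
#' @param up approximate up direction (world); must not be parallel to the
#'   optical axis.
#' @param focal_px focal length in pixels.
#' @param image_size \code{c(height, width)} px.
#' @param id camera id.
#' @return a \code{camera_model}.
#' @export
make_lookat_camera <- function(position, target, up = c(0, 0, 1),
                               focal_px, image_size, id = 1L) {
  zc <- target - position
  zc <- zc / sqrt(sum(zc^2))
  xc <- cross3(zc, up)             # image u axis: right-handed with up
  nx <- sqrt(sum(xc^2))
  if (nx < 1e-9) stop("up direction parallel to the optical axis")
  xc <- xc / nx
  yc <- cross3(zc, xc)             # image v axis (down in world terms)
  R <- rbind(xc, yc, zc)
  K <- matrix(c(focal_px, 0, (image_size[2] - 1) / 2,
                0, focal_px, (image_size[1] - 1) / 2,
                0, 0, 1), 3L, 3L, byrow = TRUE)
  P <- K %*% cbind(R, -R %*% position)
  camera_model(P, image_size, id = id)
}

#' Default three-camera rig for the cubic flight arena
#'
#' Three near-orthogonal cameras placed about 900 mm from the arena centre,
#' looking at it. Their viewing axes are deliberately tilted a few degrees off
#' the world axes so that no world direction is degenerate in two views at
#' once. The focal length is chosen so the field of view at the arena centre
#' spans \code{fov_mm}.
#'
#' @param arena an \code{\link{arena_config}}.
#' @param image_size \code{c(height, width)} px; default 1536 x 1536.
#' @param fov_mm field-of-view span at the arena centre (mm); the default
#'   (1.85 x the arena side) is wide enough that even the arena corners on
#'   the near side of each camera stay in frame.
#' @param distance_mm camera distance from the arena centre (mm).
#' @param n_cameras 2 or 3.
#' @return list of \code{camera_model}s.
#' @export
default_camera_rig <- function(arena, image_size = c(1536L, 1536L),
                               fov_mm = 1.85 * arena$side,
                               distance_mm = 900, n_cameras = 3L) {
  ctr <- rep(arena$side / 2, 3)
  axes <- list(c(1, 0.12, 0.07), c(0.07, 1, 0.12), c(0.12, 0.07, 1))
  ups <- list(c(0, 0, 1), c(0, 0, 1), c(1, 0, 0))
  focal <- min(image_size) * distance_mm / fov_mm
  lapply(seq_len(n_cameras), function(v) {
    a <- axes[[v]] / sqrt(sum(axes[[v]]^2))
    make_lookat_camera(position = ctr + distance_mm * a, target = ctr,
                       up = ups[[v]], focal_px = focal,
                       image_size = image_size, id = v)
  })
}

#' Read / write a plain-text calibration file
#'
#' One camera per block: a line \code{camera <id> <height> <width>} followed
#' by the 12 entries of P in row-major order on the next three lines (4 per
#' line). Blank lines and lines starting with \code{#} are ignored.
#'
#' @param path file path.
#' @return \code{read_calibration}: list of \code{camera_model}s.
#' @export
read_calibration <- function(path) {
  ln <- readLines(path)
  ln <- trimws(ln)
  ln <- ln[nzchar(ln) & !startsWith(ln, "#")]
  cams <- list()
  i <- 1L
  while (i <= length(ln)) {
    hd <- strsplit(ln[i], "\\s+")[[1]]
    if (hd[1] != "camera" || length(hd) != 4L)
      stop(sprintf("calibration parse error at line '%s'", ln[i]))
    if (i + 3L > length(ln)) stop("truncated calibration file")
    rows <- lapply(ln[(i + 1L):(i + 3L)], function(s)
      as.numeric(strsplit(s, "\\s+")[[1]]))
    if (any(vapply(rows, length, 1L) != 4L))
      stop("each projection-matrix row must have 4 entries")
    P <- do.call(rbind, rows)
    cams[[length(cams) + 1L]] <-
      camera_model(P, image_size = as.integer(hd[3:4]), id = as.integer(hd[2]))
    i <- i + 4L
  }
  if (!length(cams)) stop("no cameras found in calibration file")
  cams
}

#' @rdname read_calibration
#' @param cameras list of \code{camera_model}s.
#' @export
write_calibration <- function(cameras, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (cam in cameras) {
    writeLines(sprintf("camera %d %d %d", cam$id,
                       cam$image_size[1], cam$image_size[2]), con)
    for (r in 1:3)
      writeLines(paste(formatC(cam$P[r, ], format = "g", digits = 17),
                       collapse = " "), con)
  }
  invisible(path)
}
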