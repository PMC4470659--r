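#' Fit the per-pixel Gaussian background model
#'
#' Computes the per-pixel mean and (population) standard deviation of
#' intensity over a training sequence from the back-lit camera. The standard
#' deviation is clamped from below by \code{sigma_floor} so that the
#' normalized residual used for segmentation is always defined, also for
#' pixels whose intensity never varies.
#'
#' @param frames list of grayscale image matrices (identical dimensions).
#' @param sigma_floor minimal sigma in grey levels (default 1).
#' @return object of class \code{"background_model"}: list with matrices
#'   \code{mu}, \code{sigma} and the training frame count \code{n}.
#' @export
fit_background <- function(frames, sigma_floor = 1) {
  if (length(frames) < 2L) stop("need at least 2 training frames")
  d <- dim(frames[[1]])
  s <- matrix(0, d[1], d[2]); s2 <- matrix(0, d[1], d[2])
  for (f in frames) {
    if (!identical(dim(f), d)) stop("training frames have mismatched shapes")
    s <- s + f
    s2 <- s2 + as.numeric(f)^2
  }
  n <- length(frames)
  mu <- s / n
  v <- s2 / n - mu^2
  v[v < 0] <- 0
  sigma <- sqrt(v)
  sigma[sigma < sigma_floor] <- sigma_floor
  structure(list(mu = mu, sigma = sigma, n = n), class = "background_model")
}

#' Segment dark foreground pixels against the background model
#'
#' A pixel is foreground iff its normalized residual
#' \code{(I - mu) / sigma} falls below \code{-c1}. The test is one-sided:
#' back-lit flies are darker than the background, so bright outliers are
#' never foreground.
#'
#' @param image grayscale matrix.
#' @param bg a \code{\link{fit_background}} model.
#' @param c1 z-score threshold (default 1.5).
#' @return logical matrix mask.
#' @export
segment_foreground <- function(image, bg, c1 = 1.5) {
  if (!identical(dim(image), dim(bg$mu)))
    stop("image shape does not match background model")
  (image - bg$mu) / bg$sigma < -c1
}

#' Extract connected foreground blobs
#'
#' Labels connected components of the mask (4- or 8-connectivity) by
#' union-find over the foreground pixels only, and keeps components of at
#' least \code{min_area} pixels. Each blob carries its pixel locations and
#' intensities.
#'
#' @param mask logical matrix from \code{\link{segment_foreground}}.
#' @param image the intensity image the mask came from.
#' @param connectivity 4 or 8 (default 8).
#' @param min_area minimal blob area in pixels (default 3).
#' @return list of blobs; each is a list with \code{lin} (linear pixel
#'   indices), \code{row}, \code{col} (1-based), \code{u}, \code{v}
#'   (0-based pixel coordinates) and \code{I} (intensities).
#' @export
extract_blobs <- function(mask, image, connectivity = 8L, min_area = 3L) {
  if (!identical(dim(mask), dim(image))) stop("mask/image shape mismatch")
  H <- nrow(mask); W <- ncol(mask)
  idx <- which(mask)
  n <- length(idx)
  if (!n) return(list())
  pos <- integer(H * W)
  pos[idx] <- seq_len(n)
  row <- (idx - 1L) %% H + 1L
  col <- (idx - 1L) %/% H + 1L
  offs <- if (connectivity == 8L)
    list(c(-1L, -1L), c(0L, -1L), c(1L, -1L), c(-1L, 0L))
  else list(c(0L, -1L), c(-1L, 0L))
  # union-find over half the neighbourhood (the rest is symmetric)
  parent <- seq_len(n)
  find <- function(a) {
    while (parent[a] != a) {
      parent[a] <<- parent[parent[a]]
      a <- parent[a]
    }
    a
  }
  for (o in offs) {
    ok <- row + o[1] >= 1L & row + o[1] <= H & col + o[2] >= 1L & col + o[2] <= W
    nb <- idx[ok] + o[1] + o[2] * H
    j <- pos[nb]
    hit <- j > 0L
    a_all <- which(ok)[hit]
    b_all <- j[hit]
    for (k in seq_along(a_all)) {
      ra <- find(a_all[k]); rb <- find(b_all[k])
      if (ra != rb) parent[ra] <- rb
    }
  }
  root <- vapply(seq_len(n), find, 1L)
  comp <- split(seq_len(n), root)
  out <- list()
  for (cp in comp) {
    if (length(cp) < min_area) next
    li <- idx[cp]
    out[[length(out) + 1L]] <- list(
      lin = li, row = row[cp], col = col[cp],
      u = col[cp] - 1L, v = row[cp] - 1L,
      I = as.numeric(image[li]))
  }
  out
}

#' Remove wing pixels from a blob
#'
#' Wings are semi-transparent under back-lighting, so their pixels are
#' brighter than body pixels. A local Gaussian model is fitted from all
#' pixels of the blob (mean \code{mu_b}, population sd \code{sigma_b}); a
#' pixel is kept iff \code{(I - mu_b) / sigma_b < -c2}. The surviving
#' pixels are the fly's body.
#'
#' @param blob a blob from \code{\link{extract_blobs}}.
#' @param c2 z-score threshold (default 1.5).
#' @return the refined blob (subset of the input pixels), or \code{NULL} if
#'   the refinement is degenerate (near-uniform intensity or nothing kept).
#' @export
remove_wing_pixels <- function(blob, c2 = 1.5) {
  if (!length(blob$I)) return(NULL)
  mu_b <- mean(blob$I)
  sigma_b <- sqrt(mean((blob$I - mu_b)^2))
  if (sigma_b < 1e-9) return(NULL)   # uniform blob: nothing distinguishable
  keep <- (blob$I - mu_b) / sigma_b < -c2
  if (!any(keep)) return(NULL)
  list(lin = blob$lin[keep], row = blob$row[keep], col = blob$col[keep],
       u = blob$u[keep], v = blob$v[keep], I = blob$I[keep])
}

#' Intensity-weighted sub-pixel ellipse fit
#'
#' Fits a 2D Gaussian to the refined blob's pixel locations with weights
#' \code{w(i) = |I(i) - mu(i)| / sigma(i)} taken against the background
#' model, giving a sub-pixel centre and a covariance whose eigenstructure
#' defines the ellipse: semi-axes are \code{axis_scale * sqrt(eigenvalue)}
#' and the axis ratio is \code{gamma = major / minor >= 1}.
#'
#' @param blob refined blob.
#' @param bg background model (for the weights).
#' @param axis_scale semi-axis scale factor (default 2, approximately the
#'   95\% mass contour of the fitted Gaussian).
#' @return object of class \code{"ellipse_fit"}: list with \code{center}
#'   (u, v), \code{cov} (2x2), \code{semi_major}, \code{semi_minor},
#'   \code{angle} (major-axis direction from +u, radians in (-pi/2, pi/2]),
#'   \code{gamma}; or \code{NULL} when degenerate (<3 pixels or collinear).
#' @export
fit_ellipse_weighted <- function(blob, bg, axis_scale = 2) {
  if (length(blob$lin) < 3L) return(NULL)
  w <- abs(blob$I - bg$mu[blob$lin]) / bg$sigma[blob$lin]
  W_ <- sum(w)
  if (W_ <= 0) return(NULL)
  pts <- cbind(blob$u, blob$v)
  ctr <- colSums(pts * w) / W_
  dx <- sweep(pts, 2, ctr)
  S <- crossprod(dx * sqrt(w)) / W_
  ev <- eigen(S, symmetric = TRUE)
  if (ev$values[2] < 1e-9) return(NULL)   # collinear pixels
  major_dir <- ev$vectors[, 1]
  ang <- atan2(major_dir[2], major_dir[1])
  if (ang <= -pi / 2) ang <- ang + pi
  if (ang > pi / 2) ang <- ang - pi
  structure(list(center = ctr, cov = S,
                 semi_major = axis_scale * sqrt(ev$values[1]),
                 semi_minor = axis_scale * sqrt(ev$values[2]),
                 angle = ang,
                 gamma = sqrt(ev$values[1] / ev$values[2])),
            class = "ellipse_fit")
}

#' Major-axis endpoints of a fitted ellipse
#'
#' @param e an \code{"ellipse_fit"}.
#' @return 2 x 2 matrix of pixel coordinates (u, v), one endpoint per row.
#' @export
ellipse_major_endpoints <- function(e) {
  d <- c(cos(e$angle), sin(e$angle)) * e$semi_major
  rbind(e$center + d, e$center - d)
}

#' Detect measurements in one frame of one view
#'
#' Composition of the full detection chain: foreground segmentation,
#' connected-component blob extraction, wing-pixel removal and weighted
#' ellipse fitting. Blobs that become degenerate at any stage are dropped.
#'
#' @param image grayscale matrix.
#' @param bg background model for this view.
#' @param config a \code{\link{run_config}}.
#' @param view,frame indices recorded on each measurement.
#' @return list of measurements; each is a list with \code{blob} (refined,
#'   wing-free pixels), \code{ellipse}, \code{view}, \code{frame},
#'   \code{n_pixels}.
#' @export
detect <- function(image, bg, config = run_config(), view = 1L, frame = 1L) {
  mask <- segment_foreground(image, bg, config$c1)
  blobs <- extract_blobs(mask, image, config$connectivity, config$min_area)
  out <- list()
  for (b in blobs) {
    rb <- remove_wing_pixels(b, config$c2)
    if (is.null(rb)) next
    e <- fit_ellipse_weighted(rb, bg, config$axis_scale)
    if (is.null(e)) next
    out[[length(out) + 1L]] <- list(blob = rb, ellipse = e,
                                    view = as.integer(view),
                                    frame = as.integer(frame),
                                    n_pixels = length(rb$lin))
  }
  out
}

#' Tabulate a list of measurements
#'
#' @param measurements list of measurements from \code{\link{detect}}.
#' @return data frame with one row per measurement: frame, view, blob_id,
#'   n_pixels, cx, cy, cov_xx, cov_xy, cov_yy, gamma.
#' @export
measurement_table <- function(measurements) {
  if (!length(measurements))
    return(data.frame(frame = integer(), view = integer(), blob_id = integer(),
                      n_pixels = integer(), cx = numeric(), cy = numeric(),
                      cov_xx = numeric(), cov_xy = numeric(),
                      cov_yy = numeric(), gamma = numeric()))
  do.call(rbind, lapply(seq_along(measurements), function(i) {
    m <- measurements[[i]]
    data.frame(frame = m$frame, view = m$view, blob_id = i,
               n_pixels = m$n_pixels,
               cx = m$ellipse$center[1], cy = m$ellipse$center[2],
               cov_xx = m$ellipse$cov[1, 1], cov_xy = m$ellipse$cov[1, 2],
               cov_yy = m$ellipse$cov[2, 2], gamma = m$ellipse$gamma)
  }))
}
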