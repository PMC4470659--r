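#' Create a particle set
#'
#' A particle is one sampled target hypothesis: a location state
#' \code{X = (x, y, z, x-, y-, z-)} (current and previous-moment location,
#' mm), an orientation state \code{O = (theta, phi)} (radians; unset until
#' computed from an associated measurement tuple), and a weight. Particles
#' whose cross-view association fails are flagged missing and carry weight 0.
#'
#' @param location length-3 current location (mm).
#' @param previous length-3 previous-moment location; defaults to
#'   \code{location} (stationary bootstrap).
#' @param n number of particles.
#' @param spread isotropic positional scatter (mm) applied to the current
#'   location block.
#' @return a list with \code{X} (n x 6), \code{O} (n x 2, NA = unset),
#'   \code{w} (weights, sum 1), \code{missing} (logical).
#' @export
make_particles <- function(location, previous = location, n = 200L,
                           spread = 0.5) {
  X <- cbind(matrix(rep(location, each = n), n, 3) +
               matrix(stats::rnorm(3 * n, 0, spread), n, 3),
             matrix(rep(previous, each = n), n, 3))
  list(X = X, O = matrix(NA_real_, n, 2), w = rep(1 / n, n),
       missing = rep(FALSE, n))
}

#' Predict particle locations by first-order linear extrapolation
#'
#' The dynamic model: the next location is the linear extrapolation of the
#' last two, \code{x_t = 2 x_{t-1} - x_{t-2}}, plus Gaussian transition
#' noise. The previous-location block becomes the old current location and
#' the orientation state is reset to unset (it is recomputed from the
#' measurements each frame).
#'
#' @param particles a particle set (see \code{\link{make_particles}}).
#' @param sigma transition-noise scale: a scalar (isotropic sd, mm) or a
#'   3 x 3 covariance matrix.
#' @param seed optional RNG seed for reproducibility.
#' @return the predicted particle set.
#' @export
predict_location <- function(particles, sigma, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(particles$X)
  cur <- particles$X[, 1:3, drop = FALSE]
  prev <- particles$X[, 4:6, drop = FALSE]
  noise <- if (is.matrix(sigma)) {
    if (!all(dim(sigma) == c(3, 3))) stop("sigma must be scalar or 3x3")
    matrix(stats::rnorm(3 * n), n, 3) %*% chol(sigma + diag(1e-12, 3))
  } else if (sigma > 0) {
    matrix(stats::rnorm(3 * n, 0, sigma), n, 3)
  } else matrix(0, n, 3)
  particles$X <- cbind(2 * cur - prev + noise, cur)
  particles$O[] <- NA_real_
  particles$missing[] <- FALSE
  particles
}

# ---------------------------------------------------------------------------
# frame preparation: per view, a pixel -> measurement lookup for the POT

prepare_views <- function(measurements_by_view, cameras) {
  lapply(seq_along(cameras), function(v) {
    cam <- cameras[[v]]
    H <- cam$image_size[1]; W <- cam$image_size[2]
    ms <- measurements_by_view[[v]]
    blobmap <- integer(H * W)
    sizes <- integer(length(ms))
    for (i in seq_along(ms)) {
      blobmap[ms[[i]]$blob$lin] <- i
      sizes[i] <- length(ms[[i]]$blob$lin)
    }
    list(cam = cam, H = H, W = W, measurements = ms,
         blobmap = blobmap, sizes = sizes)
  })
}

# batch pixels-occupancy test: locations (n x 3) all share the gate template
# (n_g x 3, centred at the origin); returns per view a matrix with columns
# (particle, measurement, eta) for all eta > eta_c
pot_batch <- function(locations, gate_template, views, eta_c) {
  np <- nrow(locations)
  ng <- nrow(gate_template)
  pts <- gate_template[rep(seq_len(ng), np), , drop = FALSE] +
    locations[rep(seq_len(np), each = ng), , drop = FALSE]
  pid <- rep(seq_len(np), each = ng)
  lapply(views, function(vw) {
    uv <- project_points(vw$cam, pts)
    col <- as.integer(round(uv[, 1])) + 1L
    row <- as.integer(round(uv[, 2])) + 1L
    ok <- col >= 1L & col <= vw$W & row >= 1L & row <= vw$H
    if (!any(ok) || !length(vw$sizes))
      return(matrix(0, 0, 3, dimnames = list(NULL, c("particle", "meas", "eta"))))
    lin <- row[ok] + (col[ok] - 1L) * vw$H
    p <- pid[ok]
    key <- (p - 1) * (vw$H * vw$W) + lin       # dedupe per particle
    dup <- duplicated(key)
    lin <- lin[!dup]; p <- p[!dup]
    m <- vw$blobmap[lin]
    hit <- m > 0L
    if (!any(hit))
      return(matrix(0, 0, 3, dimnames = list(NULL, c("particle", "meas", "eta"))))
    p <- p[hit]; m <- m[hit]
    nm <- length(vw$sizes)
    pk <- (p - 1L) * nm + m
    cnt <- tabulate(pk, nbins = np * nm)
    nz <- which(cnt > 0L)
    pp <- (nz - 1L) %/% nm + 1L
    mm <- (nz - 1L) %% nm + 1L
    eta <- cnt[nz] / vw$sizes[mm]
    keep <- eta > eta_c
    cbind(particle = pp[keep], meas = mm[keep], eta = eta[keep])
  })
}

#' Pixels-occupancy association for one target hypothesis
#'
#' Projects discrete 3D gate-surface points into every camera view,
#' rasterizes them to integer pixels (with deduplication), and scores each
#' measurement by the occupancy ratio \code{eta}: the fraction of the
#' measurement's blob pixels covered by the projected gate. Measurements
#' with \code{eta > eta_c} in their view are associated. The association
#' fails (missing particle) if any view contributes no measurement.
#'
#' During tracking the gate is a sphere of diameter equal to the body
#' length, centred on the hypothesised location (no orientation is available
#' before association); validation passes a generative body shape instead.
#'
#' @param location length-3 hypothesised location (mm).
#' @param measurements_by_view list (one per camera) of measurement lists
#'   from \code{\link{detect}}.
#' @param cameras list of \code{camera_model}s.
#' @param eta_c occupancy threshold in [0, 1].
#' @param gate_points n x 3 matrix of gate surface points centred at the
#'   origin (world mm offsets); default: Fibonacci sphere of diameter
#'   \code{body_length}.
#' @param body_length sphere gate diameter (mm) when \code{gate_points} is
#'   NULL.
#' @param n_gate number of sphere gate points.
#' @return list per view of data frames \code{(meas, eta)} sorted by
#'   decreasing eta; attribute \code{"missing"} is TRUE when some view has
#'   no association.
#' @export
pot_associate <- function(location, measurements_by_view, cameras, eta_c,
                          gate_points = NULL, body_length = 2.73,
                          n_gate = 200L) {
  if (is.null(gate_points))
    gate_points <- fibonacci_sphere_points(n_gate, diameter = body_length)
  views <- prepare_views(measurements_by_view, cameras)
  res <- pot_batch(matrix(location, 1, 3), gate_points, views, eta_c)
  out <- lapply(res, function(r) {
    r <- r[r[, "particle"] == 1L, , drop = FALSE]
    r <- r[order(-r[, "eta"]), , drop = FALSE]
    data.frame(meas = as.integer(r[, "meas"]), eta = r[, "eta"])
  })
  attr(out, "missing") <- any(vapply(out, nrow, 1L) == 0L)
  out
}

#' Enumerate matched measurement tuples (MMPs)
#'
#' An MMP holds exactly one associated measurement per camera view. When a
#' view has several associated measurements the Cartesian product over views
#' is enumerated, keeping at most \code{cap_per_view} of the highest-eta
#' candidates per view to bound the product in clutter.
#'
#' @param assoc list per view of data frames \code{(meas, eta)} (as from
#'   \code{\link{pot_associate}}).
#' @param cap_per_view per-view candidate cap (default 3).
#' @return list of MMPs, each a list with integer vector \code{meas} and
#'   numeric vector \code{eta} (one entry per view); empty if any view has
#'   no candidate.
#' @export
enumerate_mmps <- function(assoc, cap_per_view = 3L) {
  nv <- length(assoc)
  lens <- integer(nv)
  for (v in seq_len(nv)) {
    a <- assoc[[v]]
    if (!nrow(a)) return(list())
    o <- order(-a$eta)
    assoc[[v]] <- a[o[seq_len(min(length(o), cap_per_view))], , drop = FALSE]
    lens[v] <- nrow(assoc[[v]])
  }
  idx <- as.matrix(expand.grid(lapply(lens, seq_len)))
  lapply(seq_len(nrow(idx)), function(r) {
    list(meas = vapply(seq_len(nv), function(v) assoc[[v]]$meas[idx[r, v]], 1L),
         eta = vapply(seq_len(nv), function(v) assoc[[v]]$eta[idx[r, v]], 1.0))
  })
}

#' Reconstruct the body-axis orientation from an MMP
#'
#' Chooses the two views whose fitted ellipses have the largest axis ratio
#' gamma; if both reach \code{gamma_min}, back-projects each ellipse's
#' major-axis endpoints to a plane through the camera centre and intersects
#' the two planes. The intersection line carries the body axis; its sign is
#' chosen to maximize the dot product with \code{ref_dir} (previous
#' orientation, else flight direction, else the +x hemisphere).
#'
#' When fewer than two views reach \code{gamma_min}, or the planes are
#' near-parallel, the orientation is unrecoverable and \code{NULL} is
#' returned (the tracker then carries the previous orientation).
#'
#' @param mmp_meas list of measurements, one per view (each with an
#'   \code{ellipse}).
#' @param cameras list of \code{camera_model}s (same order).
#' @param gamma_min minimal axis ratio (default 1.3).
#' @param ref_dir length-3 reference direction for the head/tail sign, or
#'   NULL.
#' @return list with \code{dir} (unit 3-vector), \code{theta}, \code{phi}
#'   (radians) and \code{views} (the two view indices used), or NULL.
#' @export
compute_orientation <- function(mmp_meas, cameras, gamma_min = 1.3,
                                ref_dir = NULL) {
  gam <- vapply(mmp_meas, function(m) m$ellipse$gamma, 1.0)
  o <- order(-gam)[1:2]
  if (gam[o[2]] < gamma_min) return(NULL)
  pl <- lapply(o, function(v)
    backproject_segment_plane(cameras[[v]],
                              ellipse_major_endpoints(mmp_meas[[v]]$ellipse)))
  d <- tryCatch(intersect_planes(pl[[1]], pl[[2]]), error = function(e) NULL)
  if (is.null(d)) return(NULL)
  if (!is.null(ref_dir) && sum(d * ref_dir) < 0) d <- -d
  if (is.null(ref_dir) && d[1] < 0) d <- -d
  ang <- dir_to_angles(d)
  list(dir = d, theta = ang$theta, phi = ang$phi, views = o)
}

#' Orientation likelihood between consecutive moments
#'
#' With \code{c} the cosine of the angle between the direction vectors of
#' the two orientations: mode \code{"consistency"} (default) returns
#' \code{exp(c - 1)}, maximal (1) for temporally consistent orientations;
#' mode \code{"literal"} returns \code{exp(-c)}. If either orientation is
#' unset the likelihood is neutral (1).
#'
#' @param o_t,o_prev orientations: \code{c(theta, phi)} (radians), a length-3
#'   direction, or NULL (unset).
#' @param mode "consistency" or "literal".
#' @return positive scalar.
#' @export
orientation_likelihood <- function(o_t, o_prev,
                                   mode = c("consistency", "literal")) {
  mode <- match.arg(mode)
  d1 <- orient_dir(o_t); d2 <- orient_dir(o_prev)
  if (is.null(d1) || is.null(d2)) return(1)
  cc <- sum(d1 * d2) / sqrt(sum(d1^2) * sum(d2^2))
  if (mode == "literal") exp(-cc) else exp(cc - 1)
}

orient_dir <- function(o) {
  if (is.null(o) || anyNA(o)) return(NULL)
  if (length(o) == 3L) o else drop(angles_to_dir(o[1], o[2]))
}

#' Normalized cross-correlation of two blob patches
#'
#' Patches are aligned on their rounded pixel centroids; the correlation is
#' computed over the intersected support with intensity normalization
#' (Pearson correlation of the overlapping intensities). Degenerate overlap
#' (fewer than 2 common pixels, or zero variance) yields 0.
#'
#' @param a,b blobs (pixel coordinate vectors \code{u}, \code{v} and
#'   intensities \code{I}).
#' @return correlation in [-1, 1].
#' @export
ncc_blobs <- function(a, b) {
  ka <- blob_relkeys(a); kb <- blob_relkeys(b)
  common <- intersect(ka$key, kb$key)
  if (length(common) < 2L) return(0)
  ia <- a$I[match(common, ka$key)]
  ib <- b$I[match(common, kb$key)]
  if (stats::sd(ia) < 1e-12 || stats::sd(ib) < 1e-12) return(0)
  stats::cor(ia, ib)
}

blob_relkeys <- function(b) {
  du <- b$u - round(mean(b$u))
  dv <- b$v - round(mean(b$v))
  list(key = (du + 4096) * 8192 + (dv + 4096))
}

#' Appearance likelihood of an MMP against the stored appearance
#'
#' Product over views of \code{exp(eta * ncc)} where \code{ncc} is the
#' normalized cross-correlation between the measurement's blob and the
#' target's stored appearance blob in that view. A view without stored
#' appearance contributes the neutral factor 1.
#'
#' @param mmp an MMP (from \code{\link{enumerate_mmps}}).
#' @param measurements_by_view per-view measurement lists.
#' @param appearance per-view list of stored blobs (NULL when absent).
#' @return positive scalar.
#' @export
appearance_likelihood <- function(mmp, measurements_by_view, appearance) {
  p <- 1
  for (v in seq_along(mmp$meas)) {
    app <- if (v <= length(appearance)) appearance[[v]] else NULL
    ncc <- if (is.null(app)) 0 else
      ncc_blobs(measurements_by_view[[v]][[mmp$meas[v]]]$blob, app)
    p <- p * exp(mmp$eta[v] * ncc)
  }
  p
}

#' Weigh candidate MMPs and select the best for one particle
#'
#' For each MMP the orientation is computed, then the particle weight
#' \code{w = p_ol * p_al} (orientation likelihood times appearance
#' likelihood); the MMP with the highest weight is selected and the particle
#' adopts its orientation and weight. If every MMP's orientation is
#' unrecoverable the weight reduces to the appearance likelihood and the
#' orientation is carried over.
#'
#' @param mmps list of MMPs.
#' @param measurements_by_view per-view measurement lists.
#' @param cameras camera list.
#' @param appearance stored appearance (per view).
#' @param o_prev previous orientation \code{c(theta, phi)} or NULL.
#' @param gamma_min minimal axis ratio for orientation reconstruction.
#' @param ol_mode orientation-likelihood mode.
#' @param ref_dir head/tail disambiguation reference.
#' @return list with \code{mmp} (the selected MMP), \code{weight},
#'   \code{orientation} (list or NULL); or NULL when \code{mmps} is empty.
#' @export
weigh_and_select <- function(mmps, measurements_by_view, cameras, appearance,
                             o_prev = NULL, gamma_min = 1.3,
                             ol_mode = "consistency", ref_dir = NULL) {
  if (!length(mmps)) return(NULL)
  best <- NULL
  for (mmp in mmps) {
    ori <- compute_orientation(lapply(seq_along(mmp$meas), function(v)
      measurements_by_view[[v]][[mmp$meas[v]]]), cameras, gamma_min, ref_dir)
    p_ol <- orientation_likelihood(
      if (is.null(ori)) NULL else ori$dir,
      if (is.null(o_prev)) NULL else o_prev, mode = ol_mode)
    p_al <- appearance_likelihood(mmp, measurements_by_view, appearance)
    w <- p_ol * p_al
    if (is.null(best) || w > best$weight)
      best <- list(mmp = mmp, weight = w, orientation = ori)
  }
  best
}

#' Posterior state expectation over a particle set
#'
#' The estimated motion state is the weighted expectation over the
#' non-missing particles: the location is the weighted arithmetic mean; the
#' orientation is the weighted mean of the particle direction vectors,
#' renormalized and converted back to angles (particles with unset
#' orientation are excluded from the orientation average).
#'
#' @param particles a particle set with normalized weights.
#' @return list with \code{location} (x, y, z), \code{previous},
#'   \code{theta}, \code{phi} (NA when no particle carries an orientation).
#' @export
estimate_state <- function(particles) {
  ok <- !particles$missing & particles$w > 0
  if (!any(ok)) stop("all particles missing: tracker step failed")
  w <- particles$w[ok] / sum(particles$w[ok])
  X <- particles$X[ok, , drop = FALSE]
  loc <- colSums(X[, 1:3, drop = FALSE] * w)
  prev <- colSums(X[, 4:6, drop = FALSE] * w)
  O <- particles$O[ok, , drop = FALSE]
  hasO <- !is.na(O[, 1])
  theta <- NA_real_; phi <- NA_real_
  if (any(hasO)) {
    d <- angles_to_dir(O[hasO, 1], O[hasO, 2])
    dm <- colSums(d * (w[hasO] / sum(w[hasO])))
    nm <- sqrt(sum(dm^2))
    if (nm > 1e-9) {
      ang <- dir_to_angles(dm)
      theta <- ang$theta; phi <- ang$phi
    }
  }
  list(location = loc, previous = prev, theta = theta, phi = phi)
}

#' Systematic resampling of a particle set
#'
#' Draws an equally-weighted set of \code{n_out} particles whose expected
#' parent multiplicities are proportional to the parent weights
#' (low-variance systematic scheme).
#'
#' @param particles particle set with normalized weights.
#' @param n_out output set size.
#' @param seed optional RNG seed.
#' @return resampled particle set with uniform weights.
#' @export
resample_particles <- function(particles, n_out = nrow(particles$X),
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  w <- particles$w
  s <- sum(w)
  if (!is.finite(s) || s <= 0) stop("degenerate weights: cannot resample")
  w <- w / s
  u <- (stats::runif(1) + seq_len(n_out) - 1) / n_out
  parent <- findInterval(u, cumsum(w)) + 1L
  parent[parent > length(w)] <- length(w)
  list(X = particles$X[parent, , drop = FALSE],
       O = particles$O[parent, , drop = FALSE],
       w = rep(1 / n_out, n_out),
       missing = rep(FALSE, n_out))
}
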