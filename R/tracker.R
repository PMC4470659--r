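#' Advance one track by one frame
#'
#' One full tracking step for a single target: systematic resampling of the
#' particle set, location prediction by linear extrapolation, cross-view
#' pixels-occupancy association of every particle (sphere gate, with the
#' association threshold schedule), MMP enumeration, orientation computation
#' and likelihood weighting, posterior state expectation, then validation
#' with the generative shape, location correction and appearance update.
#' Association or validation failures increment the track's consecutive
#' failure counter; the caller closes the track when the counter reaches its
#' limit.
#'
#' @param track a track object (see \code{\link{initiate_tracks}}).
#' @param views prepared view structures (internal, from the driver).
#' @param measurements_by_view per-view measurement lists for this frame.
#' @param cameras camera list.
#' @param cfg a \code{\link{run_config}}.
#' @param frame frame index.
#' @param gate_template sphere gate points centred at the origin.
#' @return the updated track; \code{track$last_row} holds this frame's
#'   trajectory record.
#' @export
step_tracker <- function(track, views, measurements_by_view, cameras, cfg,
                         frame, gate_template = NULL) {
  if (is.null(gate_template))
    gate_template <- fibonacci_sphere_points(cfg$gate_points,
                                             diameter = cfg$body_length)
  nv <- length(cameras)
  pts <- resample_particles(track$particles, cfg$n_particles)
  pts <- predict_location(pts, cfg$transition_sigma)
  eta_c <- if (track$age < cfg$eta_c_switch_frame) cfg$eta_c_initial
           else cfg$eta_c_later
  res <- pot_batch(pts$X[, 1:3, drop = FALSE], gate_template, views, eta_c)

  np <- nrow(pts$X)
  cand <- lapply(seq_len(np), function(i) vector("list", nv))
  for (v in seq_len(nv)) {
    r <- res[[v]]
    if (!nrow(r)) next
    sp <- split(seq_len(nrow(r)), r[, "particle"])
    for (pn in names(sp)) {
      p <- as.integer(pn)
      rows <- sp[[pn]]
      o <- rows[order(-r[rows, "eta"])]
      o <- o[seq_len(min(length(o), cfg$mmp_cap_per_view))]
      cand[[p]][[v]] <- cbind(meas = r[o, "meas"], eta = r[o, "eta"])
    }
  }

  o_prev <- if (!is.na(track$theta)) c(track$theta, track$phi) else NULL
  ref_dir <- if (!is.null(o_prev)) drop(angles_to_dir(o_prev[1], o_prev[2]))
  else {
    vel <- track$state[1:3] - track$state[4:6]
    if (sum(vel^2) > 1e-12) vel / sqrt(sum(vel^2)) else NULL
  }

  ncc_cache <- new.env(parent = emptyenv())
  mmp_cache <- new.env(parent = emptyenv())
  get_ncc <- function(v, m) {
    key <- paste0(v, "_", m)
    val <- ncc_cache[[key]]
    if (is.null(val)) {
      app <- if (v <= length(track$appearance)) track$appearance[[v]] else NULL
      val <- if (is.null(app)) 0 else
        ncc_blobs(measurements_by_view[[v]][[m]]$blob, app)
      ncc_cache[[key]] <- val
    }
    val
  }
  get_ori <- function(meas_ids) {
    key <- paste(meas_ids, collapse = ",")
    val <- mmp_cache[[key]]
    if (is.null(val)) {
      ori <- compute_orientation(lapply(seq_len(nv), function(v)
        measurements_by_view[[v]][[meas_ids[v]]]), cameras,
        cfg$gamma_min, ref_dir)
      p_ol <- orientation_likelihood(if (is.null(ori)) NULL else ori$dir,
                                     if (is.null(o_prev)) NULL else o_prev,
                                     mode = cfg$ol_mode)
      val <- list(ori = ori, p_ol = p_ol)
      mmp_cache[[key]] <- val
    }
    val
  }

  sel_mmp <- NULL; sel_w <- -Inf
  for (p in seq_len(np)) {
    cv <- cand[[p]]
    if (any(vapply(cv, is.null, TRUE))) {
      pts$missing[p] <- TRUE
      pts$w[p] <- 0
      next
    }
    lens <- vapply(cv, nrow, 1L)
    combos <- as.matrix(expand.grid(lapply(lens, seq_len)))
    bw <- -Inf; bori <- NULL; bm <- NULL
    for (r in seq_len(nrow(combos))) {
      ids <- vapply(seq_len(nv), function(v) cv[[v]][combos[r, v], "meas"], 1.0)
      etas <- vapply(seq_len(nv), function(v) cv[[v]][combos[r, v], "eta"], 1.0)
      oi <- get_ori(ids)
      p_al <- exp(sum(etas * vapply(seq_len(nv), function(v)
        get_ncc(v, ids[v]), 1.0)))
      w <- oi$p_ol * p_al
      if (w > bw) { bw <- w; bori <- oi$ori; bm <- ids }
    }
    pts$w[p] <- bw
    if (!is.null(bori)) pts$O[p, ] <- c(bori$theta, bori$phi)
    else if (!is.null(o_prev)) pts$O[p, ] <- o_prev
    if (bw > sel_w) { sel_w <- bw; sel_mmp <- bm }
  }

  track$age <- track$age + 1L
  wsum <- sum(pts$w[!pts$missing])
  if (all(pts$missing) || !is.finite(wsum) || wsum <= 0) {
    # association failed: coast on the prediction
    pts$w <- rep(1 / np, np)
    pts$missing[] <- FALSE
    track$particles <- pts
    loc <- colMeans(pts$X[, 1:3, drop = FALSE])
    prev <- colMeans(pts$X[, 4:6, drop = FALSE])
    track$state <- c(loc, prev)
    track$fail_count <- track$fail_count + 1L
    track$selected_mmp <- NULL
    track$last_row <- track_row(track, frame, loc, 0L, FALSE, FALSE)
    return(track)
  }
  pts$w <- pts$w / wsum
  pts$w[pts$missing] <- 0
  est <- estimate_state(pts)
  if (is.na(est$theta) && !is.null(o_prev)) {
    est$theta <- o_prev[1]; est$phi <- o_prev[2]
  }

  val <- validate_state(est$location, c(est$theta, est$phi),
                        measurements_by_view, cameras,
                        eta_c = cfg$eta_c_validation,
                        body_length = cfg$body_length,
                        n_points = cfg$shape_points)
  corrected <- FALSE
  if (val$success) {
    cor_ <- correct_location(est$location, val$mmp, measurements_by_view,
                             cameras, cfg$body_length)
    if (cor_$corrected) {
      shift <- cor_$location - est$location
      pts$X[, 1:3] <- sweep(pts$X[, 1:3, drop = FALSE], 2, shift, "+")
      est$location <- cor_$location
      corrected <- TRUE
    }
    track <- update_appearance(track, val$mmp, measurements_by_view, frame)
    track$fail_count <- 0L
    track$selected_mmp <- val$mmp
  } else {
    track$fail_count <- track$fail_count + 1L
    track$selected_mmp <- sel_mmp
  }
  track$particles <- pts
  track$state <- c(est$location, est$previous)
  if (!is.na(est$theta)) { track$theta <- est$theta; track$phi <- est$phi }
  track$last_row <- track_row(track, frame, est$location,
                              if (!is.null(track$selected_mmp)) nv else 0L,
                              val$success, corrected)
  track
}

track_row <- function(track, frame, loc, n_views, validated, corrected) {
  data.frame(track_id = track$id, frame = as.integer(frame),
             x_mm = loc[1], y_mm = loc[2], z_mm = loc[3],
             theta_deg = if (is.na(track$theta)) NA_real_ else
               track$theta * 180 / pi,
             phi_deg = if (is.na(track$phi)) NA_real_ else
               track$phi * 180 / pi,
             n_valid_views = as.integer(n_views),
             validated = validated, corrected = corrected)
}

#' Initiate tracks from unassociated measurements
#'
#' Greedy cross-view matching of leftover measurements: every pair of
#' unassociated ellipse centres from the first two views is triangulated;
#' pairs whose two-view reprojection error stays below the pixel tolerance
#' are completed by the nearest unassociated measurement in each remaining
#' view (also within tolerance). Complete tuples are accepted greedily by
#' total reprojection error, each seeding one new track whose particles
#' start around the triangulated point with a stationary motion prior.
#'
#' @param measurements_by_view per-view measurement lists.
#' @param used_by_view per-view logical vectors flagging measurements
#'   already claimed by active tracks this frame.
#' @param cameras camera list.
#' @param cfg a \code{\link{run_config}}.
#' @param frame frame index.
#' @param next_id first identity to assign.
#' @param arena an \code{\link{arena_config}} (candidates outside the arena
#'   are rejected).
#' @return list of new track objects (possibly empty).
#' @export
initiate_tracks <- function(measurements_by_view, used_by_view, cameras, cfg,
                            frame, next_id, arena = arena_config()) {
  nv <- length(cameras)
  un <- lapply(seq_len(nv), function(v) which(!used_by_view[[v]]))
  if (any(vapply(un, length, 1L) == 0L)) return(list())
  ctr <- lapply(seq_len(nv), function(v)
    t(vapply(measurements_by_view[[v]], function(m) m$ellipse$center, c(0, 0))))
  tol <- cfg$init_reproj_tol_px
  cands <- list()
  for (i in un[[1]]) for (j in un[[2]]) {
    uv2 <- rbind(ctr[[1]][i, ], ctr[[2]][j, ])
    p3 <- tryCatch(triangulate(cameras[1:2], uv2), error = function(e) NULL)
    if (is.null(p3)) next
    if (any(p3 < -5) || any(p3 > arena$side + 5)) next
    e2 <- vapply(1:2, function(v)
      sqrt(sum((project_points(cameras[[v]], p3) - uv2[v, ])^2)), 1.0)
    if (max(e2) > tol) next
    ids <- c(i, j, rep(NA_integer_, nv - 2L))
    errs <- e2
    ok <- TRUE
    if (nv > 2L) for (v in 3:nv) {
      pr <- project_points(cameras[[v]], p3)
      dd <- sqrt(rowSums(sweep(ctr[[v]][un[[v]], , drop = FALSE], 2, pr)^2))
      k <- which.min(dd)
      if (!length(k) || dd[k] > 3 * tol) { ok <- FALSE; break }
      ids[v] <- un[[v]][k]
      errs <- c(errs, dd[k])
    }
    if (!ok) next
    uv <- t(vapply(seq_len(nv), function(v) ctr[[v]][ids[v], ], c(0, 0)))
    pt <- tryCatch(triangulate(cameras, uv), error = function(e) NULL)
    if (is.null(pt)) next
    rerr <- mean(vapply(seq_len(nv), function(v)
      sqrt(sum((project_points(cameras[[v]], pt) - uv[v, ])^2)), 1.0))
    if (rerr > tol) next
    cands[[length(cands) + 1L]] <- list(ids = ids, pt = pt, err = rerr)
  }
  if (!length(cands)) return(list())
  cands <- cands[order(vapply(cands, function(c_) c_$err, 1.0))]
  taken <- lapply(seq_len(nv), function(v) logical(length(measurements_by_view[[v]])))
  out <- list()
  for (c_ in cands) {
    if (any(vapply(seq_len(nv), function(v) taken[[v]][c_$ids[v]], TRUE))) next
    for (v in seq_len(nv)) taken[[v]][c_$ids[v]] <- TRUE
    tr <- list(id = next_id, status = "active", age = 0L, fail_count = 0L,
               particles = make_particles(c_$pt, n = cfg$n_particles,
                                          spread = cfg$body_length / 5),
               state = c(c_$pt, c_$pt), theta = NA_real_, phi = NA_real_,
               appearance = lapply(seq_len(nv), function(v)
                 measurements_by_view[[v]][[c_$ids[v]]]$blob),
               appearance_stamp = as.integer(frame),
               selected_mmp = c_$ids, born = as.integer(frame))
    tr$last_row <- track_row(tr, frame, c_$pt, nv, FALSE, FALSE)
    out[[length(out) + 1L]] <- tr
    next_id <- next_id + 1L
  }
  out
}

#' Track a swarm through a multi-view image sequence
#'
#' The full multi-target driver: per frame it detects measurements in every
#' view, advances every active track by one particle-filter step, closes
#' tracks after \code{max_failures} consecutive failures, and initiates new
#' tracks from measurements no active track claimed. Identities are not
#' maintained across disappearances: a fly that lands or is lost re-enters
#' as a new identity.
#'
#' @param frame_source either a function \code{function(t)} returning the
#'   list of per-view grayscale image matrices for frame \code{t}, or a list
#'   of such lists.
#' @param n_frames number of frames to process.
#' @param cameras camera list.
#' @param bg_models per-view background models (\code{\link{fit_background}}).
#' @param cfg a \code{\link{run_config}}.
#' @param arena an \code{\link{arena_config}}.
#' @param verbose print per-frame progress.
#' @return object of class \code{"swarm_tracks"}: list with
#'   \code{trajectories} (data frame: track_id, frame, x_mm, y_mm, z_mm,
#'   theta_deg, phi_deg, n_valid_views, validated, corrected), \code{config},
#'   and \code{n_tracks}.
#' @export
track_swarm <- function(frame_source, n_frames, cameras, bg_models,
                        cfg = run_config(), arena = arena_config(),
                        verbose = FALSE) {
  get_frame <- if (is.function(frame_source)) frame_source
  else function(t) frame_source[[t]]
  gate_template <- fibonacci_sphere_points(cfg$gate_points,
                                           diameter = cfg$body_length)
  tracks <- list()
  next_id <- 1L
  rows <- vector("list", n_frames)
  for (t in seq_len(n_frames)) {
    imgs <- get_frame(t)
    set.seed(derive_seed(cfg$seed, t, 997L))
    meas <- lapply(seq_along(cameras), function(v)
      detect(imgs[[v]], bg_models[[v]], cfg, view = v, frame = t))
    views <- prepare_views(meas, cameras)
    used <- lapply(meas, function(m) logical(length(m)))
    frame_rows <- list()
    for (k in seq_along(tracks)) {
      if (tracks[[k]]$status != "active") next
      tr <- step_tracker(tracks[[k]], views, meas, cameras, cfg, t,
                         gate_template)
      if (!is.null(tr$selected_mmp))
        for (v in seq_along(used)) used[[v]][tr$selected_mmp[v]] <- TRUE
      if (tr$fail_count >= cfg$max_failures) tr$status <- "closed"
      frame_rows[[length(frame_rows) + 1L]] <- tr$last_row
      tracks[[k]] <- tr
    }
    new_tracks <- initiate_tracks(meas, used, cameras, cfg, t, next_id, arena)
    for (tr in new_tracks) {
      tracks[[length(tracks) + 1L]] <- tr
      frame_rows[[length(frame_rows) + 1L]] <- tr$last_row
      next_id <- next_id + 1L
    }
    rows[[t]] <- if (length(frame_rows)) do.call(rbind, frame_rows) else NULL
    if (verbose)
      message(sprintf("frame %d: %d measurements/view, %d active tracks",
                      t, round(mean(lengths(meas))),
                      sum(vapply(tracks, function(x) x$status == "active", TRUE))))
  }
  traj <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(traj)) traj <- track_row(list(id = integer(), theta = NA,
                                            phi = NA), integer(), rep(NA_real_, 3),
                                       integer(), logical(), logical())[0, ]
  structure(list(trajectories = traj, config = cfg,
                 n_tracks = next_id - 1L), class = "swarm_tracks")
}

#' @export
print.swarm_tracks <- function(x, ...) {
  cat(sprintf("<swarm_tracks: %d tracks, %d state records, frames %s..%s>\n",
              x$n_tracks, nrow(x$trajectories),
              min(x$trajectories$frame), max(x$trajectories$frame)))
  invisible(x)
}

#' Run the full synthetic closed loop: simulate, render, track
#'
#' Renders a ground-truth swarm frame by frame (streaming, nothing kept in
#' memory), trains the background model on fly-free renders, and runs the
#' tracker. The working tool for end-to-end evaluation without real videos.
#'
#' @param truth a \code{"swarm_truth"}.
#' @param cameras camera list (default rig if NULL).
#' @param rc render configuration.
#' @param cfg run configuration.
#' @param n_bg_frames background training frames (rendered fly-free).
#' @param verbose progress output.
#' @return list with \code{tracks} (a \code{"swarm_tracks"}), \code{truth},
#'   \code{cameras}, \code{bg_models}.
#' @export
run_closed_loop <- function(truth, cameras = NULL, rc = render_config(),
                            cfg = run_config(), n_bg_frames = 20L,
                            verbose = FALSE) {
  if (is.null(cameras)) cameras <- default_camera_rig(truth$arena)
  bg_frames <- lapply(seq_len(n_bg_frames), function(t)
    render_frame(NULL, NULL, cameras, rc, frame = 100000L + t)$images)
  bg_models <- lapply(seq_along(cameras), function(v)
    fit_background(lapply(bg_frames, `[[`, v), cfg$sigma_floor))
  n_frames <- dim(truth$pos)[1]
  src <- function(t)
    render_frame(truth$pos[t, , , drop = TRUE],
                 cbind(truth$theta[t, ], truth$phi[t, ]),
                 cameras, rc, frame = t, alive = truth$alive[t, ],
                 body_length = cfg$body_length)$images
  tk <- track_swarm(src, n_frames, cameras, bg_models, cfg, truth$arena,
                    verbose = verbose)
  list(tracks = tk, truth = truth, cameras = cameras, bg_models = bg_models)
}

#' Match estimated trajectories against ground truth
#'
#' Per-frame greedy nearest matching of estimated states to true fly
#' positions within \code{max_dist}. Reports the coverage (fraction of true
#' (fly, frame) records matched by some estimate) and identity switches (a
#' track whose matched true fly changes between consecutive matched frames).
#'
#' @param tracks a \code{"swarm_tracks"} or its trajectory data frame.
#' @param truth a \code{"swarm_truth"}.
#' @param max_dist matching radius (mm); default one body length, 2.73.
#' @return list with \code{coverage}, \code{n_switches},
#'   \code{track_seconds} (total tracked time, s), \code{switch_rate_per_10s}
#'   and the per-record match table.
#' @export
match_tracks_to_truth <- function(tracks, truth, max_dist = 2.73) {
  traj <- if (inherits(tracks, "swarm_tracks")) tracks$trajectories else tracks
  nf <- dim(truth$pos)[1]; nb <- dim(truth$pos)[2]
  matched <- matrix(FALSE, nf, nb)
  assign_rows <- vector("list", nf)
  for (t in unique(traj$frame)) {
    est <- traj[traj$frame == t, , drop = FALSE]
    gt <- matrix(truth$pos[t, , ], nb, 3)
    D <- outer(seq_len(nrow(est)), seq_len(nb), Vectorize(function(i, j)
      sqrt(sum((c(est$x_mm[i], est$y_mm[i], est$z_mm[i]) - gt[j, ])^2))))
    # greedy assignment by increasing distance
    pairs <- which(D <= max_dist, arr.ind = TRUE)
    if (nrow(pairs)) {
      pairs <- pairs[order(D[pairs]), , drop = FALSE]
      eu <- logical(nrow(est)); gu <- logical(nb)
      keep <- integer(0)
      for (r in seq_len(nrow(pairs))) {
        i <- pairs[r, 1]; j <- pairs[r, 2]
        if (!eu[i] && !gu[j]) {
          eu[i] <- TRUE; gu[j] <- TRUE
          matched[t, j] <- TRUE
          keep <- c(keep, r)
        }
      }
      pr <- pairs[keep, , drop = FALSE]
      assign_rows[[t]] <- data.frame(frame = t,
                                     track_id = est$track_id[pr[, 1]],
                                     fly = pr[, 2],
                                     dist = D[pr])
    }
  }
  amap <- do.call(rbind, assign_rows[!vapply(assign_rows, is.null, TRUE)])
  n_switch <- 0L
  if (!is.null(amap)) for (id in unique(amap$track_id)) {
    fl <- amap$fly[amap$track_id == id][order(amap$frame[amap$track_id == id])]
    n_switch <- n_switch + sum(diff(fl) != 0)
  }
  fps <- if (is.na(truth$fps)) 100 else truth$fps
  track_seconds <- nrow(traj) / fps
  list(coverage = mean(matched), n_switches = n_switch,
       track_seconds = track_seconds,
       switch_rate_per_10s = n_switch / (track_seconds / 10),
       matches = amap)
}
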