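#' Validate an estimated state with the generative shape
#'
#' Re-runs the pixels-occupancy association, but with gate points sampled
#' from the generative body shape posed at the estimated state instead of a
#' sphere, and a restrictive threshold (\code{eta_c = 0.8}). Validation
#' succeeds iff every camera view contributes at least one measurement with
#' \code{eta > eta_c}; where several qualify the highest-eta one is kept
#' (ties broken by the smaller centre distance to the state's projection),
#' forming exactly one validated MMP.
#'
#' @param location estimated location (x, y, z mm).
#' @param orientation estimated orientation \code{c(theta, phi)} (radians);
#'   validation requires a complete state.
#' @param measurements_by_view per-view measurement lists.
#' @param cameras camera list.
#' @param eta_c occupancy threshold (default 0.8).
#' @param body_length centre-axis length (mm).
#' @param profile body profile function.
#' @param n_points shape surface samples (default 400; denser than the
#'   tracking sphere because the restrictive threshold demands accurate
#'   silhouette coverage).
#' @return list with \code{success}, and on success \code{mmp} (integer
#'   measurement index per view) and \code{eta} per view.
#' @export
validate_state <- function(location, orientation, measurements_by_view,
                           cameras, eta_c = 0.8, body_length = 2.73,
                           profile = spindle_profile(body_length),
                           n_points = 400L) {
  if (anyNA(orientation)) return(list(success = FALSE, reason = "no orientation"))
  gate <- generative_shape_points(c(0, 0, 0), orientation, body_length,
                                  profile, n_points)
  assoc <- pot_associate(location, measurements_by_view, cameras, eta_c,
                         gate_points = gate)
  nv <- length(assoc)
  mmp <- integer(nv); eta <- numeric(nv)
  for (v in seq_len(nv)) {
    a <- assoc[[v]]
    if (!nrow(a)) return(list(success = FALSE, reason = "view without match"))
    if (nrow(a) > 1L) {
      top <- a[a$eta == max(a$eta), , drop = FALSE]
      if (nrow(top) > 1L) {
        proj <- project_points(cameras[[v]], location)
        dd <- vapply(top$meas, function(i) {
          ctr <- measurements_by_view[[v]][[i]]$ellipse$center
          sum((ctr - proj)^2)
        }, 1.0)
        top <- top[which.min(dd), , drop = FALSE]
      }
      a <- top
    }
    mmp[v] <- a$meas[1]; eta[v] <- a$eta[1]
  }
  list(success = TRUE, mmp = mmp, eta = eta)
}

#' Correct a validated location against the triangulated candidate
#'
#' Triangulates the validated MMP's ellipse centres into a candidate 3D
#' location. If the candidate lies farther than one body length from the
#' estimated location, the location is replaced by the midpoint of the two;
#' otherwise it is left unchanged.
#'
#' @param location estimated location (mm).
#' @param mmp integer measurement index per view.
#' @param measurements_by_view per-view measurement lists.
#' @param cameras camera list.
#' @param body_length correction distance threshold (mm).
#' @return list with \code{location}, \code{corrected} flag and
#'   \code{candidate}.
#' @export
correct_location <- function(location, mmp, measurements_by_view, cameras,
                             body_length = 2.73) {
  uv <- t(vapply(seq_along(cameras), function(v)
    measurements_by_view[[v]][[mmp[v]]]$ellipse$center, c(0, 0)))
  cand <- tryCatch(triangulate(cameras, uv), error = function(e) NULL)
  if (is.null(cand))
    return(list(location = location, corrected = FALSE, candidate = NULL))
  if (sqrt(sum((location - cand)^2)) > body_length)
    list(location = (location + cand) / 2, corrected = TRUE, candidate = cand)
  else
    list(location = location, corrected = FALSE, candidate = cand)
}

#' Store a validated MMP as the target's appearance
#'
#' The appearance of a target is the validated MMP's per-view blobs together
#' with a time stamp; it is the reference for the appearance likelihood in
#' subsequent frames.
#'
#' @param track a track object (list).
#' @param mmp integer measurement index per view.
#' @param measurements_by_view per-view measurement lists.
#' @param frame current frame index.
#' @return the track with updated \code{appearance} and
#'   \code{appearance_stamp}.
#' @export
update_appearance <- function(track, mmp, measurements_by_view, frame) {
  track$appearance <- lapply(seq_along(mmp), function(v)
    measurements_by_view[[v]][[mmp[v]]]$blob)
  track$appearance_stamp <- as.integer(frame)
  track
}
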