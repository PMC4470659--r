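#' Orientation angles and direction vectors
#'
#' The body orientation is a directed axis described by two angles: the
#' azimuth \code{theta}, measured from the world x-axis in the horizontal
#' (x-y) plane, and the elevation \code{phi}, measured from the horizontal
#' plane towards +z. Internally all angles are radians; trajectory tables use
#' degrees.
#'
#' \code{angles_to_dir} returns the unit direction
#' \code{(cos(phi) cos(theta), cos(phi) sin(theta), sin(phi))}. The
#' alternative \code{convention = "polar"} treats \code{phi} as a polar angle
#' from +z, i.e. \code{(sin(phi) cos(theta), sin(phi) sin(theta), cos(phi))}.
#'
#' @param theta,phi angles in radians (vectors allowed).
#' @param convention \code{"elevation"} (default) or \code{"polar"}.
#' @return \code{angles_to_dir}: n x 3 matrix of unit vectors.
#' @export
angles_to_dir <- function(theta, phi, convention = c("elevation", "polar")) {
  convention <- match.arg(convention)
  if (convention == "elevation")
    cbind(cos(phi) * cos(theta), cos(phi) * sin(theta), sin(phi))
  else
    cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' @rdname angles_to_dir
#' @param d unit 3-vector or n x 3 matrix of directions.
#' @return \code{dir_to_angles}: list with \code{theta} in (-pi, pi] and
#'   \code{phi} in [-pi/2, pi/2] (elevation) or [0, pi] (polar).
#' @export
dir_to_angles <- function(d, convention = c("elevation", "polar")) {
  convention <- match.arg(convention)
  d <- rbind3(d)
  n <- sqrt(rowSums(d^2))
  if (any(n < 1e-12)) stop("zero direction vector")
  d <- d / n
  if (convention == "elevation")
    list(theta = atan2(d[, 2], d[, 1]), phi = asin(pmin(1, pmax(-1, d[, 3]))))
  else
    list(theta = atan2(d[, 2], d[, 1]), phi = acos(pmin(1, pmax(-1, d[, 3]))))
}
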