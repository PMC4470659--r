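#' Cubic flight arena configuration
#'
#' @param side inner side length in mm (default 360, the Lucite cube used for
#'   the fly experiments).
#' @param margin wall margin in mm used by the analyses to discard flies close
#'   to a wall (default 20).
#' @return object of class \code{"arena_config"}. The arena occupies
#'   \code{[0, side]^3} in world coordinates.
#' @export
arena_config <- function(side = 360, margin = 20) {
  if (!is.numeric(side) || side <= 0) stop("arena side must be positive")
  if (margin < 0 || margin >= side / 2) stop("margin must lie in [0, side/2)")
  structure(list(side = side, margin = margin), class = "arena_config")
}

#' Evenly distributed points on a sphere (Fibonacci lattice)
#'
#' Deterministic quasi-uniform sampling of a sphere surface, used as the
#' spherical association gate: latitudes are equally spaced in z and
#' longitudes advance by the golden angle.
#'
#' @param n number of points.
#' @param center sphere centre (length-3, mm); default origin.
#' @param diameter sphere diameter (mm); default 1.
#' @return n x 3 matrix of points on the sphere surface.
#' @export
fibonacci_sphere_points <- function(n, center = c(0, 0, 0), diameter = 1) {
  i <- seq_len(n)
  z <- 1 - (2 * i - 1) / n
  r <- sqrt(pmax(0, 1 - z^2))
  ga <- pi * (3 - sqrt(5))
  th <- ga * (i - 1)
  p <- cbind(r * cos(th), r * sin(th), z) * (diameter / 2)
  sweep(p, 2, center, "+")
}

#' Spindle profile curve for the generative body shape
#'
#' Radius of the body surface of revolution as a function of the normalized
#' position \code{u} along the centre-axis (0 = tail, 1 = head):
#' \code{rho(u) = r_max * sin(pi * u)}, an elongated spindle with aspect
#' ratio \code{body_length / (2 r_max)}. With the default
#' \code{r_max = body_length / 6} the aspect ratio is 3:1, matching a fruit
#' fly silhouette. Any replacement profile function \code{u -> radius (mm)}
#' with \code{rho(0) = rho(1) = 0} can be injected wherever a profile is
#' accepted.
#'
#' @param body_length centre-axis length in mm.
#' @param r_max maximal radius in mm.
#' @return function mapping u in [0,1] to radius (mm).
#' @export
spindle_profile <- function(body_length = 2.73, r_max = body_length / 6) {
  force(r_max)
  function(u) r_max * sin(pi * u)
}

# rotation taking the +x axis to direction (theta, phi): Rz(theta) %*% Ry(-phi)
orientation_rotation <- function(theta, phi) {
  ct <- cos(theta); st <- sin(theta); cp <- cos(phi); sp <- sin(phi)
  Ry <- matrix(c(cp, 0, -sp, 0, 1, 0, sp, 0, cp), 3, 3, byrow = TRUE)
  Rz <- matrix(c(ct, -st, 0, st, ct, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  Rz %*% Ry
}

#' Sample the surface of the generative body shape
#'
#' The fly body is modelled as a surface of revolution: a profile curve
#' revolved around the directed centre-axis of length \code{body_length},
#' centred on \code{position} and pointing along \code{orientation}. Points
#' are placed deterministically on a Fibonacci-style lattice over the
#' (axis position, revolution angle) parameter rectangle, so the same state
#' always yields the same point set, and rotating/translating the state
#' applies the same rigid motion to the points.
#'
#' @param position body centre, length-3 (mm).
#' @param orientation either \code{c(theta, phi)} in radians or a length-3
#'   direction vector.
#' @param body_length centre-axis length in mm (default 2.73, the average
#'   fruit fly body length).
#' @param profile profile function u -> radius (mm); default
#'   \code{\link{spindle_profile}(body_length)}.
#' @param n_samples number of surface points (default 400).
#' @return n x 3 matrix of world points (mm) on the body surface.
#' @export
generative_shape_points <- function(position, orientation,
                                    body_length = 2.73,
                                    profile = spindle_profile(body_length),
                                    n_samples = 400L) {
  if (body_length <= 0) stop("degenerate: body length must be positive")
  if (length(orientation) == 3L) {
    ang <- dir_to_angles(orientation)
    theta <- ang$theta; phi <- ang$phi
  } else {
    theta <- orientation[1]; phi <- orientation[2]
  }
  i <- seq_len(n_samples)
  u <- (i - 0.5) / n_samples
  ga <- pi * (3 - sqrt(5))
  psi <- ga * (i - 1)
  r <- profile(u)
  # canonical shape: axis along +x, centred at the origin
  pts <- cbind((u - 0.5) * body_length, r * cos(psi), r * sin(psi))
  pts <- pts %*% t(orientation_rotation(theta, phi))
  sweep(pts, 2, position, "+")
}
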