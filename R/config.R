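#' Run configuration
#'
#' All tunable constants of the pipeline with their defaults. Detection:
#' \code{c1}, \code{c2} are the background- and wing-removal z-score
#' thresholds (both 1.5); \code{sigma_floor} the background-sigma floor in
#' grey levels; \code{connectivity}/\code{min_area} govern blob extraction;
#' \code{axis_scale} converts covariance eigenvalues to ellipse semi-axes
#' (semi-axis = axis_scale * sqrt(eigenvalue)). Tracking: \code{n_particles}
#' particles per target; the association (pixels-occupancy) threshold
#' \code{eta_c} starts at \code{eta_c_initial} for the first
#' \code{eta_c_switch_frame} frames of a track and then relaxes to
#' \code{eta_c_later}; validation re-runs the occupancy test at
#' \code{eta_c_validation} with the generative shape; \code{gamma_min} is the
#' minimal ellipse axis ratio for orientation reconstruction;
#' \code{transition_sigma} (mm) scales the isotropic transition noise of the
#' linear-extrapolation dynamic model; tracks close after
#' \code{max_failures} consecutive association/validation failures.
#' \code{ol_mode} selects the orientation-likelihood form: "consistency"
#' (exp(cos - 1), rewards temporal alignment; default) or "literal"
#' (exp(-cos)).
#'
#' @param ... overrides of any default, by name. Unknown names and
#'   out-of-range values raise an error naming the key.
#' @return object of class \code{"run_config"} (a named list).
#' @export
run_config <- function(...) {
  cfg <- list(
    # detection
    c1 = 1.5, c2 = 1.5, sigma_floor = 1,
    connectivity = 8L, min_area = 3L, axis_scale = 2,
    # body model
    body_length = 2.73, gamma_min = 1.3,
    # tracking
    n_particles = 200L,
    eta_c_initial = 0.5, eta_c_later = 0.25, eta_c_switch_frame = 30L,
    eta_c_validation = 0.8,
    gate_points = 200L, shape_points = 400L,
    mmp_cap_per_view = 3L, max_failures = 5L,
    transition_sigma = 2,
    init_reproj_tol_px = 2,
    ol_mode = "consistency", angle_convention = "elevation",
    # rig / timing
    fps = 100, arena_side = 360, wall_margin = 20,
    seed = 1L)
  ov <- list(...)
  if (length(ov)) {
    if (is.null(names(ov)) || any(!nzchar(names(ov))))
      stop("config overrides must be named")
    bad <- setdiff(names(ov), names(cfg))
    if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
    cfg[names(ov)] <- ov
  }
  validate_run_config(cfg)
  structure(cfg, class = "run_config")
}

validate_run_config <- function(cfg) {
  chk <- function(key, ok) if (!isTRUE(ok))
    stop(sprintf("config key '%s' out of range (value: %s)", key,
                 paste(format(cfg[[key]]), collapse = ", ")))
  chk("c1", is.numeric(cfg$c1) && cfg$c1 > 0)
  chk("c2", is.numeric(cfg$c2) && cfg$c2 > 0)
  chk("sigma_floor", cfg$sigma_floor > 0)
  chk("connectivity", cfg$connectivity %in% c(4L, 8L))
  chk("min_area", cfg$min_area >= 1)
  chk("axis_scale", cfg$axis_scale > 0)
  chk("body_length", cfg$body_length > 0)
  chk("gamma_min", cfg$gamma_min >= 1)
  chk("n_particles", cfg$n_particles >= 1)
  for (k in c("eta_c_initial", "eta_c_later", "eta_c_validation"))
    chk(k, cfg[[k]] >= 0 && cfg[[k]] <= 1)
  chk("eta_c_switch_frame", cfg$eta_c_switch_frame >= 0)
  chk("gate_points", cfg$gate_points >= 4)
  chk("shape_points", cfg$shape_points >= 4)
  chk("mmp_cap_per_view", cfg$mmp_cap_per_view >= 1)
  chk("max_failures", cfg$max_failures >= 1)
  chk("transition_sigma", cfg$transition_sigma >= 0)
  chk("init_reproj_tol_px", cfg$init_reproj_tol_px > 0)
  chk("ol_mode", cfg$ol_mode %in% c("consistency", "literal"))
  chk("angle_convention", cfg$angle_convention %in% c("elevation", "polar"))
  chk("fps", cfg$fps > 0)
  chk("arena_side", cfg$arena_side > 0)
  chk("wall_margin", cfg$wall_margin >= 0 && cfg$wall_margin < cfg$arena_side / 2)
  invisible(cfg)
}

#' Load a run configuration from a YAML file
#'
#' Defaults are merged with the overrides found in the file; an empty file
#' yields the full default configuration.
#'
#' @param path YAML file path.
#' @return a \code{\link{run_config}}.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ov <- yaml::read_yaml(path)
  if (is.null(ov)) ov <- list()
  do.call(run_config, ov)
}

#' Serialize the effective configuration next to an output artifact
#'
#' @param cfg a \code{run_config}.
#' @param path output file (YAML).
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  for (k in names(x))
    cat(sprintf("  %-20s %s\n", k, paste(format(x[[k]]), collapse = ", ")))
  invisible(x)
}
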