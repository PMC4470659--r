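#' Read synchronized multi-view frame sequences
#'
#' Expects one directory per view (\code{cam1}, \code{cam2}, ...) containing
#' numbered grayscale images (\code{frame000001.png} or any
#' lexicographically ordered naming). Frames are yielded synchronized across
#' views; a missing frame raises an error naming the view and index.
#'
#' @param root directory holding the per-view subdirectories.
#' @param views view ids (default: all \code{cam*} subdirectories).
#' @param frames frame index range as \code{c(first, last)} or NULL for all.
#' @return list with \code{n_frames}, \code{views}, and \code{get(t)}
#'   returning the list of per-view image matrices (grey 0..255) for frame
#'   \code{t} (1-based within the selected range).
#' @export
read_frames <- function(root, views = NULL, frames = NULL) {
  if (is.null(views)) {
    dirs <- list.dirs(root, recursive = FALSE, full.names = FALSE)
    views <- sort(as.integer(sub("^cam", "", dirs[grepl("^cam[0-9]+$", dirs)])))
  }
  if (!length(views)) stop("no camera directories found under ", root)
  files <- lapply(views, function(v) {
    fs <- sort(list.files(file.path(root, sprintf("cam%d", v)),
                          pattern = "\\.(png|PNG)$", full.names = TRUE))
    if (!length(fs)) stop(sprintf("view %d: no frames found", v))
    fs
  })
  n_all <- vapply(files, length, 1L)
  n <- min(n_all)
  if (any(n_all != n_all[1]))
    stop(sprintf("frame count mismatch across views: %s",
                 paste(n_all, collapse = ", ")))
  idx <- if (is.null(frames)) seq_len(n) else seq(frames[1], frames[2])
  if (any(idx < 1L | idx > n)) stop("frame range out of bounds")
  get <- function(t) {
    if (t < 1L || t > length(idx)) stop("frame index out of range")
    lapply(seq_along(views), function(k) {
      f <- files[[k]][idx[t]]
      if (!file.exists(f))
        stop(sprintf("missing frame %d in view %d", idx[t], views[k]))
      img <- png::readPNG(f)
      if (length(dim(img)) == 3L) img <- img[, , 1]
      round(img * 255)
    })
  }
  # probe the first frame for shape consistency
  probe <- get(1L)
  shp <- dim(probe[[1]])
  for (k in seq_along(probe))
    if (!identical(dim(probe[[k]]), shp))
      stop(sprintf("image shape mismatch in view %d", views[k]))
  list(n_frames = length(idx), views = views, get = get)
}

#' Write / read a trajectory table
#'
#' Plain CSV with the tracker schema (mm and degrees).
#'
#' @param trajectory data frame (or a \code{"swarm_tracks"} object).
#' @param path CSV path.
#' @export
write_trajectories <- function(trajectory, path) {
  if (inherits(trajectory, "swarm_tracks")) trajectory <- trajectory$trajectories
  utils::write.csv(trajectory, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectories
#' @export
read_trajectories <- function(path) {
  utils::read.csv(path)
}
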