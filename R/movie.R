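#' Construct a calibrated movie
#'
#' A movie is a `(Y, X, T)` array of 2D frames plus a calibration. The
#' `kind` records how pixel values are to be interpreted: `"probability"`
#' (foreground probabilities in \[0, 1\]), `"intensity"` (raw values),
#' `"binary"` (0/1 masks) or `"labels"` (non-negative integer cell labels,
#' 0 = background).
#'
#' @param frames a `(Y, X)` matrix or `(Y, X, T)` array, or a list of equal
#'   sized matrices (ordered frames).
#' @param calibration a [calibration()] object.
#' @param kind one of `"probability"`, `"intensity"`, `"binary"`, `"labels"`.
#' @return An object of class `morphodyn_movie`: a `(Y, X, T)` array with
#'   `calibration` and `kind` attributes.
#' @export
movie <- function(frames, calibration,
                  kind = c("probability", "intensity", "binary", "labels")) {
  kind <- match.arg(kind)
  if (is.list(frames)) {
    shapes <- vapply(frames, dim, integer(2))
    if (ncol(shapes) > 1 && any(shapes != shapes[, 1]))
      stop("all frames must share one shape")
    frames <- array(unlist(frames, use.names = FALSE),
                    dim = c(shapes[1, 1], shapes[2, 1], length(frames)))
  }
  if (is.matrix(frames)) frames <- array(frames, dim = c(dim(frames), 1))
  if (length(dim(frames)) != 3 || dim(frames)[3] < 1)
    stop("frames must form a (Y, X, T) array with T >= 1")
  stopifnot(inherits(calibration, "morphodyn_calibration"))
  if (kind == "probability") {
    rng <- range(frames, finite = TRUE)
    if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9)
      stop("probability movies must have values in [0, 1]")
  }
  if (kind %in% c("binary", "labels")) {
    storage.mode(frames) <- "integer"
    if (any(frames < 0)) stop("labels/binary movies must be non-negative")
  } else {
    storage.mode(frames) <- "double"
  }
  structure(frames, calibration = calibration, kind = kind,
            class = "morphodyn_movie")
}

#' @export
print.morphodyn_movie <- function(x, ...) {
  d <- dim(x)
  cal <- attr(x, "calibration")
  cat(sprintf("morphodyn movie [%s]: %d x %d px, %d frame(s), %g um/px, %g s/frame\n",
              attr(x, "kind"), d[1], d[2], d[3],
              cal$pixel_size_um, cal$frame_interval_s))
  invisible(x)
}

n_frames <- function(m) dim(m)[3]

get_frame <- function(m, t) {
  f <- m[, , t, drop = TRUE]
  if (!is.matrix(f)) f <- matrix(f, dim(m)[1], dim(m)[2])
  f
}

movie_cal <- function(m) attr(m, "calibration")

#' Extract a binary frame as a logical matrix
#' @noRd
get_mask <- function(m, t) get_frame(m, t) > 0

#' One cell's binary movie
#'
#' @param frames binary frames as for [movie()].
#' @param calibration a [calibration()] object.
#' @param cell_id integer cell identifier.
#' @return A `morphodyn_movie` of kind `"binary"` with a `cell_id` attribute
#'   and class `morphodyn_cell_movie`.
#' @export
cell_movie <- function(frames, calibration, cell_id = 1L) {
  m <- movie(frames, calibration, kind = "binary")
  attr(m, "cell_id") <- as.integer(cell_id)
  class(m) <- c("morphodyn_cell_movie", class(m))
  m
}
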