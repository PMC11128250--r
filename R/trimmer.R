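#' Create a trimmer configuration
#'
#' A configuration names the engaged trimmers and their lateral offsets from
#' the beamlet central axis. At most one X trimmer (X1 or X2) and one Y
#' trimmer (Y1 or Y2) may be engaged simultaneously; engaging both trimmers
#' of the same axis is a hardware impossibility and is rejected. Offsets are
#' measured from the beamlet axis toward the field interior: X2/Y2 collimate
#' from the positive-coordinate side, X1/Y1 from the negative side.
#'
#' @param x One of `"X1"`, `"X2"`, `"Out"`.
#' @param y One of `"Y1"`, `"Y2"`, `"Out"`.
#' @param x_offset Offset in mm of the engaged X trimmer (>= 1); must be
#'   absent (`NULL`) when `x == "Out"`.
#' @param y_offset Offset in mm of the engaged Y trimmer; same rules.
#' @return An object of class `trimmer_config`.
#' @export
#' @examples
#' trimmer_config("X2", "Out", x_offset = 1)
#' trimmer_config()  # uncollimated
trimmer_config <- function(x = "Out", y = "Out", x_offset = NULL, y_offset = NULL) {
  if (!is.character(x) || length(x) != 1L || !(x %in% c("X1", "X2", "Out")))
    stop("x trimmer must be one of X1, X2, Out (got ", deparse(x),
         "); engaging two trimmers of the same axis is not allowed")
  if (!is.character(y) || length(y) != 1L || !(y %in% c("Y1", "Y2", "Out")))
    stop("y trimmer must be one of Y1, Y2, Out (got ", deparse(y),
         "); engaging two trimmers of the same axis is not allowed")
  if (x == "Out" && !is.null(x_offset)) stop("x_offset given but X trimmer is Out")
  if (y == "Out" && !is.null(y_offset)) stop("y_offset given but Y trimmer is Out")
  if (x != "Out") {
    if (is.null(x_offset) || !is.numeric(x_offset) || length(x_offset) != 1L)
      stop("engaged X trimmer requires a numeric x_offset")
    if (x_offset < 1) stop("trimmer offset below the 1 mm minimum: ", x_offset)
  }
  if (y != "Out") {
    if (is.null(y_offset) || !is.numeric(y_offset) || length(y_offset) != 1L)
      stop("engaged Y trimmer requires a numeric y_offset")
    if (y_offset < 1) stop("trimmer offset below the 1 mm minimum: ", y_offset)
  }
  structure(list(x = x, y = y,
                 x_offset = if (x == "Out") NULL else x_offset,
                 y_offset = if (y == "Out") NULL else y_offset),
            class = "trimmer_config")
}

#' @export
print.trimmer_config <- function(x, ...) {
  cat("<trimmer_config>", config_label(x), "\n")
  invisible(x)
}

#' Canonical label of a trimmer configuration
#'
#' @param config A `trimmer_config`.
#' @return A string such as `"X2@1/Y1@2"` or `"Out/Out"`.
#' @export
config_label <- function(config) {
  lab <- function(t, o) if (t == "Out") "Out" else sprintf("%s@%g", t, o)
  paste(lab(config$x, config$x_offset), lab(config$y, config$y_offset), sep = "/")
}

#' Number of engaged trimmers in a configuration
#' @param config A `trimmer_config`.
#' @return 0, 1 or 2.
#' @export
n_engaged <- function(config) {
  (config$x != "Out") + (config$y != "Out")
}

#' Base trimmer configurations of the beamlet library
#'
#' Enumerates the nine unique base configurations simulated per energy:
#' all combinations of X offset and Y offset drawn from \{1 mm, 2 mm, Out\},
#' using the X2/Y2 (positive-side) convention for engaged trimmers. The
#' ninth configuration (Out/Out) is the uncollimated beamlet. Opposing-
#' trimmer variants are obtained afterwards by symmetry expansion.
#'
#' @return A list of nine `trimmer_config` objects in table order
#'   (X offsets 1,1,2,2,Out,Out,1,2,Out crossed with Y offsets
#'   1,2,1,2,1,2,Out,Out,Out).
#' @export
base_trimmer_configs <- function() {
  xo <- list(1, 1, 2, 2, NULL, NULL, 1, 2, NULL)
  yo <- list(1, 2, 1, 2, 1, 2, NULL, NULL, NULL)
  lapply(seq_along(xo), function(i) {
    trimmer_config(x = if (is.null(xo[[i]])) "Out" else "X2",
                   y = if (is.null(yo[[i]])) "Out" else "Y2",
                   x_offset = xo[[i]], y_offset = yo[[i]])
  })
}

# Mirror a configuration across x = 0 (swaps X1 and X2) or y = 0.
flip_config <- function(config, axis = c("x", "y")) {
  axis <- match.arg(axis)
  sw <- function(t) switch(t, X1 = "X2", X2 = "X1", Y1 = "Y2", Y2 = "Y1", Out = "Out")
  if (axis == "x")
    trimmer_config(sw(config$x), config$y, config$x_offset, config$y_offset)
  else
    trimmer_config(config$x, sw(config$y), config$x_offset, config$y_offset)
}
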