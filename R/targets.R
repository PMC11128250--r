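#' Rasterize a circular target
#'
#' Builds a planar circular target mask on a node-centered isotropic grid.
#' A node is inside the target iff its center lies within `diameter/2` of
#' the target center, which sits at the grid coordinate origin.
#'
#' @param diameter Target diameter in mm (> 0).
#' @param spacing Grid spacing in mm (default 0.5, the analysis resolution).
#' @param padding Clearance in mm between the target and the grid boundary
#'   (default 40; must exceed the widest rind evaluated).
#' @return An object of class `target_geometry`: `mask` (logical matrix
#'   indexed \[x, y\]), `x`/`y` node coordinates (mm), `spacing`,
#'   `shape_label`, `area` (mm^2).
#' @export
#' @examples
#' tg <- make_circle_target(30)
#' tg$area / (pi * 15^2)
make_circle_target <- function(diameter, spacing = 0.5, padding = 40) {
  if (!is.numeric(diameter) || diameter <= 0) stop("diameter must be > 0")
  if (!is.numeric(spacing) || spacing <= 0) stop("spacing must be > 0")
  r <- diameter / 2
  hw <- r + padding
  ax <- seq(-hw, hw, by = spacing)
  mask <- outer(ax^2, ax^2, `+`) <= r^2
  label <- if (abs(diameter / 10 - round(diameter / 10)) < 1e-9)
    paste0("circle", diameter / 10) else sprintf("circle_%gmm", diameter)
  new_target(mask, ax, ax, spacing, label)
}

#' Rasterize a kidney-bean test target
#'
#' Concave crescent target in the spirit of the planning-QA bean shapes:
#' the set difference of an outer ellipse (semi-axes 45 x 25 mm for the
#' large variant) and an inner ellipse (40 x 22 mm) displaced 15 mm along
#' the minor axis; the small variant is the same shape scaled by 0.4. The
#' shape is symmetric about its transverse midline (x = 0) and concave on
#' the displaced side.
#'
#' @param size `"large"` or `"small"`.
#' @param spacing Grid spacing in mm (default 0.5).
#' @param padding Clearance to the grid boundary in mm (default 40).
#' @return A `target_geometry`.
#' @export
#' @examples
#' tg <- make_kidney_bean_target("large")
#' tg$area
make_kidney_bean_target <- function(size = c("large", "small"), spacing = 0.5,
                                    padding = 40) {
  size <- match.arg(size)
  if (!is.numeric(spacing) || spacing <= 0) stop("spacing must be > 0")
  sc <- if (size == "large") 1 else 0.4
  a1 <- 45 * sc; b1 <- 25 * sc        # outer ellipse semi-axes (x, y)
  a2 <- 40 * sc; b2 <- 22 * sc        # inner (subtracted) ellipse
  dy <- -15 * sc                      # inner ellipse shift along minor axis
  hwx <- a1 + padding
  hwy <- b1 + padding
  x <- seq(-hwx, hwx, by = spacing)
  y <- seq(-hwy, hwy, by = spacing)
  outer_e <- outer((x / a1)^2, (y / b1)^2, `+`) <= 1
  inner_e <- outer((x / a2)^2, ((y - dy) / b2)^2, `+`) <= 1
  mask <- outer_e & !inner_e
  new_target(mask, x, y, spacing, paste0("kidney_", size))
}

new_target <- function(mask, x, y, spacing, label) {
  if (!any(mask)) stop("target mask is empty")
  if (any(mask[1, ]) || any(mask[nrow(mask), ]) ||
      any(mask[, 1]) || any(mask[, ncol(mask)]))
    stop("target touches the grid boundary; increase padding")
  structure(list(mask = mask, x = x, y = y, spacing = spacing,
                 shape_label = label, area = sum(mask) * spacing^2),
            class = "target_geometry")
}

#' @export
print.target_geometry <- function(x, ...) {
  cat(sprintf("<target_geometry> %s: %.1f mm^2 on %d x %d grid @ %g mm\n",
              x$shape_label, x$area, length(x$x), length(x$y), x$spacing))
  invisible(x)
}

#' Build a named standard target
#'
#' Dispatch helper covering the five evaluated shapes.
#'
#' @param shape One of `"circle3"`, `"circle5"`, `"circle8"`,
#'   `"kidney_small"`, `"kidney_large"`.
#' @param spacing,padding Passed through to the shape generator.
#' @return A `target_geometry`.
#' @export
make_target <- function(shape, spacing = 0.5, padding = 40) {
  switch(shape,
         circle3 = make_circle_target(30, spacing, padding),
         circle5 = make_circle_target(50, spacing, padding),
         circle8 = make_circle_target(80, spacing, padding),
         kidney_small = make_kidney_bean_target("small", spacing, padding),
         kidney_large = make_kidney_bean_target("large", spacing, padding),
         stop("unknown shape: ", shape))
}

#' Peripheral rind region around a target
#'
#' The rind of width w is the set of grid nodes outside the target whose
#' Euclidean distance to the target is at most w: the morphological
#' dilation of the target by an isotropic disk, minus the target itself.
#' Used as the normal-tissue evaluation region.
#'
#' @param target A `target_geometry`.
#' @param width Rind width in mm (> 0); 10 and 30 are the standard widths.
#' @return An object of class `rind_region`: `mask` (logical matrix on the
#'   target grid), `width`, `parent` (the target), `area` (mm^2).
#' @export
#' @examples
#' tg <- make_circle_target(30)
#' rind <- make_rind(tg, 10)
#' rind$area / (pi * (25^2 - 15^2))
make_rind <- function(target, width) {
  stopifnot(inherits(target, "target_geometry"))
  if (!is.numeric(width) || width <= 0) stop("width must be > 0")
  d <- EBImage::distmap(1 - target$mask) * target$spacing
  mask <- d > 0 & d <= width
  if (any(mask[1, ]) || any(mask[nrow(mask), ]) ||
      any(mask[, 1]) || any(mask[, ncol(mask)]))
    stop("rind touches the grid boundary; rebuild the target with larger padding")
  structure(list(mask = mask, width = width, parent = target,
                 area = sum(mask) * target$spacing^2),
            class = "rind_region")
}

#' @export
print.rind_region <- function(x, ...) {
  cat(sprintf("<rind_region> %g mm around %s: %.1f mm^2\n",
              x$width, x$parent$shape_label, x$area))
  invisible(x)
}

# Centroid of a target mask (mm), snapped to the nearest grid node.
target_centroid <- function(target) {
  idx <- which(target$mask, arr.ind = TRUE)
  cx <- mean(target$x[idx[, 1]])
  cy <- mean(target$y[idx[, 2]])
  c(target$x[which.min(abs(target$x - cx))],
    target$y[which.min(abs(target$y - cy))])
}

#' Export a mask as run-length-encoded text or portable graymap
#'
#' @param mask A `target_geometry` or `rind_region`.
#' @param path Output path.
#' @param format `"rle"` (run-length text) or `"pgm"` (plain P2 graymap).
#' @return The path, invisibly.
#' @export
export_mask <- function(mask, path, format = c("rle", "pgm")) {
  format <- match.arg(format)
  m <- mask$mask
  if (format == "rle") {
    r <- rle(as.integer(m))
    writeLines(c(sprintf("# mask %d x %d spacing %g", nrow(m), ncol(m),
                         if (!is.null(mask$spacing)) mask$spacing else mask$parent$spacing),
                 paste(r$lengths, r$values, sep = "x", collapse = " ")), path)
  } else {
    writeLines(c("P2", sprintf("%d %d", nrow(m), ncol(m)), "1",
                 apply(matrix(as.integer(m), nrow(m)), 2, paste, collapse = " ")), path)
  }
  invisible(path)
}
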