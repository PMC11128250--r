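#' Place a rectangular spot map over a target
#'
#' Lays a rectangular scanning lattice of the given in-plane spacing over
#' the target bounding box expanded by a margin. The lattice is aligned so
#' that one node coincides with the target centroid (snapped to the
#' analysis grid), making spot positions reproducible for a given target.
#'
#' @param target A `target_geometry`.
#' @param spacing In-plane spot spacing in mm (2.5 is the standard value;
#'   1 for the small bean target).
#' @param margin Expansion of the bounding box in mm (default 10), so that
#'   candidate spots outside the target remain available to the optimizer.
#' @return An object of class `spot_map`: `positions` (n x 2 matrix of mm
#'   coordinates), `spacing`, `energy` (NA until attached to a beam).
#' @export
#' @examples
#' sm <- place_spots(make_circle_target(30), spacing = 2.5)
#' nrow(sm$positions)
place_spots <- function(target, spacing = 2.5, margin = 10) {
  stopifnot(inherits(target, "target_geometry"))
  if (!is.numeric(spacing) || spacing <= 0) stop("spacing must be > 0")
  if (!any(target$mask)) stop("target mask is empty")
  ctr <- target_centroid(target)
  idx <- which(target$mask, arr.ind = TRUE)
  bx <- range(target$x[idx[, 1]]) + c(-margin, margin)
  by <- range(target$y[idx[, 2]]) + c(-margin, margin)
  gx <- ctr[1] + spacing * (ceiling((bx[1] - ctr[1]) / spacing):floor((bx[2] - ctr[1]) / spacing))
  gy <- ctr[2] + spacing * (ceiling((by[1] - ctr[2]) / spacing):floor((by[2] - ctr[2]) / spacing))
  pos <- cbind(x = rep(gx, times = length(gy)), y = rep(gy, each = length(gx)))
  structure(list(positions = pos, spacing = spacing, energy = NA_real_),
            class = "spot_map")
}

#' @export
print.spot_map <- function(x, ...) {
  cat(sprintf("<spot_map> %d spots @ %g mm spacing\n", nrow(x$positions), x$spacing))
  invisible(x)
}

# Sample a kernel at tensor positions (xq, yq) in the kernel frame,
# zero outside its support.
sample_kernel <- function(kernel, xq, yq) {
  v <- bilinear_grid(kernel$x, kernel$y, kernel$grid, xq, yq)
  v[xq < kernel$x[1] | xq > kernel$x[length(kernel$x)], ] <- 0
  v[, yq < kernel$y[1] | yq > kernel$y[length(kernel$y)]] <- 0
  v
}

#' Dose ratio (conformity score) of a beamlet at a spot position
#'
#' The per-spot conformity criterion: DR = 100 * Din / Dout, where Din is
#' the beamlet dose integrated over target nodes of the analysis grid and
#' Dout the dose integrated over non-target nodes, with the kernel shifted
#' to the spot position. A beamlet depositing no dose outside the target
#' returns `Inf` (it trivially passes any selection threshold and is never
#' a candidate for collimation).
#'
#' @param kernel A `beamlet_kernel`.
#' @param position Length-2 numeric, spot (x, y) in mm.
#' @param target A `target_geometry` providing the analysis grid and mask.
#' @return DR in percent (possibly `Inf`).
#' @export
dose_ratio <- function(kernel, position, target) {
  stopifnot(inherits(kernel, "beamlet_kernel"), inherits(target, "target_geometry"))
  v <- sample_kernel(kernel, target$x - position[1], target$y - position[2])
  din <- sum(v[target$mask])
  dout <- sum(v) - din
  if (dout == 0) return(Inf)
  100 * din / dout
}

# DR of every distinct library configuration at every spot.
# Returns list(dr = matrix [n_config x n_spots], labels, engaged, offsets).
# Uses kernels resampled to the analysis grid and exact node alignment
# (spot positions sit on the analysis lattice), so values agree with
# dose_ratio() to floating-point accuracy.
dr_matrix <- function(spot_map, library, target) {
  cfgs <- library_configs(library, include_uncollimated = TRUE)
  h <- target$spacing
  ups <- lapply(cfgs, kernel_on_spacing, spacing = h)
  kx <- ups[[1]]$x; ky <- ups[[1]]$y
  nk <- length(kx) * length(ky)
  K <- vapply(ups, function(u) as.vector(u$grid), numeric(nk))
  pos <- spot_map$positions
  nx <- length(target$x); ny <- length(target$y)
  dr <- matrix(NA_real_, ncol(K), nrow(pos))
  for (s in seq_len(nrow(pos))) {
    ix <- round((pos[s, 1] + kx - target$x[1]) / h) + 1L
    jy <- round((pos[s, 2] + ky - target$y[1]) / h) + 1L
    okx <- ix >= 1L & ix <= nx
    oky <- jy >= 1L & jy <= ny
    m <- matrix(FALSE, length(kx), length(ky))
    m[okx, oky] <- target$mask[ix[okx], jy[oky], drop = FALSE]
    sel <- as.vector(outer(okx, oky))
    din <- crossprod(K, as.numeric(m))
    tot <- crossprod(K, as.numeric(sel))
    dout <- tot - din
    dr[, s] <- ifelse(dout == 0, Inf, 100 * din / dout)
  }
  engaged <- vapply(cfgs, function(k) n_engaged(k$config), numeric(1))
  offsets <- vapply(cfgs, function(k) {
    sum(c(k$config$x_offset, k$config$y_offset))
  }, numeric(1))
  list(dr = dr, labels = names(cfgs), engaged = engaged, offsets = offsets)
}

#' Select candidate spots by dose-ratio threshold
#'
#' Keeps a spot iff the best dose ratio attainable under the selection
#' policy meets the threshold: for uncollimated planning the uncollimated
#' kernel's DR, for collimated planning the maximum DR over all library
#' configurations. Kept spots carry their uncollimated DR and (initially
#' uncollimated) configuration; `assign_collimation()` decides which spots
#' actually receive trimmed beamlets.
#'
#' @param spot_map A `spot_map`.
#' @param library A `kernel_library`.
#' @param target A `target_geometry`.
#' @param dr_thresh Selection threshold in percent (>= 0). Values around
#'   30 (uncollimated) and 16 (collimated) reproduce matched target
#'   coverage between the two plan types.
#' @param policy `"uncollimated"` or `"best"` (maximum over library).
#' @return A data.frame of class `candidate_spots` with columns `x`, `y`,
#'   `dr_uncoll`, `dr`, `config`, `t_x1`, `t_x2`, `t_y1`, `t_y2` (mm, NA
#'   when parked Out). The full DR matrix is attached as attribute
#'   `"dr_matrix"` for reuse by `assign_collimation()`.
#' @export
select_spots <- function(spot_map, library, target, dr_thresh,
                         policy = c("uncollimated", "best")) {
  policy <- match.arg(policy)
  if (!is.numeric(dr_thresh) || dr_thresh < 0) stop("dr_thresh must be >= 0")
  dm <- dr_matrix(spot_map, library, target)
  iu <- match("Out/Out", dm$labels)
  score <- if (policy == "uncollimated") dm$dr[iu, ] else apply(dm$dr, 2, max)
  keep <- score >= dr_thresh
  pos <- spot_map$positions[keep, , drop = FALSE]
  out <- data.frame(x = pos[, 1], y = pos[, 2],
                    dr_uncoll = dm$dr[iu, keep],
                    dr = dm$dr[iu, keep],
                    config = rep("Out/Out", sum(keep)),
                    t_x1 = rep(NA_real_, sum(keep)),
                    t_x2 = rep(NA_real_, sum(keep)),
                    t_y1 = rep(NA_real_, sum(keep)),
                    t_y2 = rep(NA_real_, sum(keep)),
                    stringsAsFactors = FALSE)
  attr(out, "dr_matrix") <- list(dr = dm$dr[, keep, drop = FALSE],
                                 labels = dm$labels, engaged = dm$engaged,
                                 offsets = dm$offsets)
  class(out) <- c("candidate_spots", "data.frame")
  out
}

#' Assign collimated configurations by the collimation-level threshold
#'
#' A spot is assigned a collimated configuration iff its uncollimated DR is
#' below the collimation level `t_coll`; interior spots with high (or
#' infinite) uncollimated DR stay uncollimated. The assigned configuration
#' is the library entry maximizing the spot's DR, with ties broken in favor
#' of fewer engaged trimmers, then smaller total offset, then label order.
#' Increasing `t_coll` therefore monotonically increases the number of
#' trimmed beamlets, concentrating collimation at the target edge.
#'
#' @param candidates A `candidate_spots` data.frame from `select_spots()`.
#' @param library A `kernel_library`.
#' @param target A `target_geometry`.
#' @param t_coll Collimation level in percent, in \[0, 100\].
#' @return The candidates with updated `dr`, `config` and trimmer
#'   coordinate columns.
#' @export
assign_collimation <- function(candidates, library, target, t_coll) {
  stopifnot(inherits(candidates, "candidate_spots"))
  if (!is.numeric(t_coll) || t_coll < 0 || t_coll > 100)
    stop("t_coll must be in [0, 100]")
  if (nrow(candidates) == 0L) return(candidates)
  dm <- attr(candidates, "dr_matrix")
  if (is.null(dm) || ncol(dm$dr) != nrow(candidates)) {
    sm <- structure(list(positions = cbind(candidates$x, candidates$y),
                         spacing = NA_real_, energy = NA_real_),
                    class = "spot_map")
    dm <- dr_matrix(sm, library, target)
  }
  ord <- order(dm$engaged, dm$offsets, dm$labels)
  for (s in seq_len(nrow(candidates))) {
    if (is.finite(candidates$dr_uncoll[s]) && candidates$dr_uncoll[s] < t_coll) {
      drs <- dm$dr[ord, s]
      best <- ord[which.max(drs)]   # first max in tie-break order
      candidates$config[s] <- dm$labels[best]
      candidates$dr[s] <- dm$dr[best, s]
    } else {
      candidates$config[s] <- "Out/Out"
      candidates$dr[s] <- candidates$dr_uncoll[s]
    }
    cfg <- parse_config_label(candidates$config[s])
    tp <- trimmer_positions_for_spot(c(candidates$x[s], candidates$y[s]), cfg)
    candidates$t_x1[s] <- tp["t_x1"]; candidates$t_x2[s] <- tp["t_x2"]
    candidates$t_y1[s] <- tp["t_y1"]; candidates$t_y2[s] <- tp["t_y2"]
  }
  candidates
}

# Inverse of config_label().
parse_config_label <- function(label) {
  parts <- strsplit(label, "/", fixed = TRUE)[[1]]
  if (length(parts) != 2L) stop("malformed configuration label: ", label)
  p <- lapply(parts, function(s) {
    if (s == "Out") return(list(t = "Out", o = NULL))
    m <- regmatches(s, regexec("^([XY][12])@([0-9.]+)$", s))[[1]]
    if (length(m) != 3L) stop("malformed configuration label: ", label)
    list(t = m[2], o = as.numeric(m[3]))
  })
  trimmer_config(p[[1]]$t, p[[2]]$t, p[[1]]$o, p[[2]]$o)
}

#' Physical trimmer positions for one spot
#'
#' Converts a spot position plus trimmer configuration into the four
#' physical trimmer edge coordinates. The engaged trimmer edge sits at the
#' spot coordinate plus the offset on the positive side (X2/Y2) or minus
#' the offset on the negative side (X1/Y1); parked trimmers are reported
#' as NA (the `Out` token in delivery files). Offsets below the 1 mm
#' delivery-robustness minimum are rejected.
#'
#' @param spot Length-2 numeric spot position (x, y) in mm.
#' @param config A `trimmer_config`.
#' @return Named numeric vector `t_x1`, `t_x2`, `t_y1`, `t_y2` (mm; NA for
#'   parked trimmers).
#' @export
#' @examples
#' trimmer_positions_for_spot(c(10, 0), trimmer_config("X2", "Out", x_offset = 1))
trimmer_positions_for_spot <- function(spot, config) {
  stopifnot(is.numeric(spot), length(spot) == 2L, inherits(config, "trimmer_config"))
  out <- c(t_x1 = NA_real_, t_x2 = NA_real_, t_y1 = NA_real_, t_y2 = NA_real_)
  if (config$x != "Out") {
    if (config$x_offset < 1) stop("trimmer offset below the 1 mm minimum")
    if (config$x == "X2") out["t_x2"] <- spot[1] + config$x_offset
    else out["t_x1"] <- spot[1] - config$x_offset
  }
  if (config$y != "Out") {
    if (config$y_offset < 1) stop("trimmer offset below the 1 mm minimum")
    if (config$y == "Y2") out["t_y2"] <- spot[2] + config$y_offset
    else out["t_y1"] <- spot[2] - config$y_offset
  }
  out
}
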