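#' Dose-area percentile
#'
#' Dose received by at least q% of the masked area: the value of the
#' sorted (descending) dose-area curve at area fraction q/100, linearly
#' interpolated between nodes. D98 and D2 summarize target coverage and
#' hot spots; D50 is the median.
#'
#' @param dose A `dose_distribution` or a numeric matrix.
#' @param mask Logical matrix selecting the evaluated area.
#' @param q Area percentage in (0, 100).
#' @return Dose in Gy.
#' @export
#' @examples
#' d <- matrix(5, 10, 10)
#' dose_area_percentile(d, matrix(TRUE, 10, 10), 98)
dose_area_percentile <- function(dose, mask, q) {
  g <- if (inherits(dose, "dose_distribution")) dose$grid else dose
  stopifnot(is.matrix(g), is.logical(mask), all(dim(g) == dim(mask)))
  if (!any(mask)) stop("empty mask")
  if (!is.numeric(q) || q <= 0 || q >= 100) stop("q must be in (0, 100)")
  sorted_area_percentile(g[mask], q)
}

#' Collimation-induced rind mean-dose reduction
#'
#' Difference in mean dose over a peripheral rind between an uncollimated
#' and a collimated plan, expressed as a percentage of the prescription
#' dose. Positive values mean the collimated plan spares the rind.
#'
#' @param dose_uncoll,dose_coll `dose_distribution`s on the rind's lattice.
#' @param rind A `rind_region`.
#' @param prescription Prescription dose in Gy (default 5).
#' @return Reduction in percent of prescription.
#' @export
rind_mean_dose_reduction <- function(dose_uncoll, dose_coll, rind, prescription = 5) {
  stopifnot(inherits(rind, "rind_region"))
  gu <- if (inherits(dose_uncoll, "dose_distribution")) dose_uncoll$grid else dose_uncoll
  gc <- if (inherits(dose_coll, "dose_distribution")) dose_coll$grid else dose_coll
  if (!all(dim(gu) == dim(rind$mask)) || !all(dim(gc) == dim(rind$mask)))
    stop("doses and rind are not on the same lattice")
  100 * (mean(gu[rind$mask]) - mean(gc[rind$mask])) / prescription
}

#' Fit a depth trend to rind dose-reduction data
#'
#' Least-squares linear or quadratic fit of dose reduction versus depth.
#' Non-range-shifted plans show a linearly decreasing reduction with
#' depth; range-shifted plans behave nonlinearly and are better captured
#' by the quadratic. The smallest real root of the fit beyond the last
#' data point -- the extrapolated depth at which the collimation benefit
#' vanishes -- is reported when it exists.
#'
#' @param series A data.frame (or 2-column matrix) with columns `depth`
#'   (cm) and `reduction` (percent of prescription).
#' @param kind `"linear"` (>= 3 points) or `"poly2"` (>= 4 points).
#' @return A list of class `trend_fit`: `kind`, `coefficients`,
#'   `slope_pct_per_cm` (linear only), `zero_crossing_depth` (cm or NA),
#'   `model` (the underlying `lm`).
#' @export
#' @examples
#' fit_depth_trend(data.frame(depth = c(5, 10, 15), reduction = c(40, 30, 20)))
fit_depth_trend <- function(series, kind = c("linear", "poly2")) {
  kind <- match.arg(kind)
  series <- as.data.frame(series)
  names(series)[1:2] <- c("depth", "reduction")
  need <- if (kind == "linear") 3L else 4L
  if (nrow(series) < need)
    stop("need at least ", need, " points for a ", kind, " fit")
  fit <- if (kind == "linear") stats::lm(reduction ~ depth, data = series)
  else stats::lm(reduction ~ depth + I(depth^2), data = series)
  cf <- stats::coef(fit)
  dmax <- max(series$depth)
  roots <- if (kind == "linear") {
    if (abs(cf[2]) > 0) -cf[1] / cf[2] else numeric(0)
  } else {
    a <- cf[3]; b <- cf[2]; c0 <- cf[1]
    disc <- b^2 - 4 * a * c0
    if (abs(a) < 1e-12) { if (abs(b) > 0) -c0 / b else numeric(0) }
    else if (disc < 0) numeric(0)
    else (-b + c(-1, 1) * sqrt(disc)) / (2 * a)
  }
  roots <- roots[is.finite(roots) & roots > dmax]
  structure(list(kind = kind, coefficients = unname(cf),
                 slope_pct_per_cm = if (kind == "linear") unname(cf[2]) else NA_real_,
                 zero_crossing_depth = if (length(roots)) min(roots) else NA_real_,
                 model = fit),
            class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf("<trend_fit> %s: coefficients %s", x$kind,
              paste(sprintf("%.4g", x$coefficients), collapse = ", ")))
  if (x$kind == "linear") cat(sprintf("; slope %.3f %%/cm", x$slope_pct_per_cm))
  if (is.finite(x$zero_crossing_depth))
    cat(sprintf("; zero crossing %.1f cm", x$zero_crossing_depth))
  cat("\n")
  invisible(x)
}

# Sample a dose image at all grid nodes shifted by (ox, oy); NA outside.
shift_sample <- function(dose, ox, oy) {
  x <- dose$x; y <- dose$y; g <- dose$grid
  h <- dose$spacing
  sx <- ox / h; sy <- oy / h
  i0 <- floor(sx); fx <- sx - i0
  j0 <- floor(sy); fy <- sy - j0
  nx <- length(x); ny <- length(y)
  pick <- function(di, dj) {
    ii <- seq_len(nx) + i0 + di
    jj <- seq_len(ny) + j0 + dj
    okx <- ii >= 1L & ii <= nx
    oky <- jj >= 1L & jj <= ny
    m <- matrix(NA_real_, nx, ny)
    m[okx, oky] <- g[ii[okx], jj[oky], drop = FALSE]
    m
  }
  # zero-weight terms contribute nothing even when their shifted index is
  # off-grid (exact-lattice offsets at the boundary must stay valid)
  term <- function(m, wgt) if (wgt == 0) 0 else m * wgt
  term(pick(0, 0), (1 - fx) * (1 - fy)) + term(pick(1, 0), fx * (1 - fy)) +
    term(pick(0, 1), (1 - fx) * fy) + term(pick(1, 1), fx * fy)
}

#' 2D gamma analysis between two dose distributions
#'
#' Global-normalization gamma index: for each reference node above the
#' dose threshold, the minimum over search offsets of
#' sqrt(dose_diff^2 / dD^2 + dist^2 / dta^2), with dD the dose criterion
#' as a percentage of the reference maximum. The search covers offsets up
#' to `search_factor * dta` on a `dta/10` sub-grid, with the evaluated
#' dose interpolated bilinearly. In relative mode the evaluated dose is
#' first rescaled to the reference by the least-squares factor over
#' above-threshold nodes (the film-style renormalization).
#'
#' @param reference,evaluated `dose_distribution`s on identical lattices
#'   (use `resample_dose()` first if needed).
#' @param dose_criterion Dose-difference criterion in percent (e.g. 3).
#' @param dta Distance-to-agreement criterion in mm (e.g. 2).
#' @param threshold Low-dose threshold in percent of the reference maximum
#'   (default 10); nodes below it are excluded from the pass rate.
#' @param mode `"absolute"` or `"relative"`.
#' @param search_factor Search radius as a multiple of dta (default 3).
#' @return A list of class `gamma_result`: `pass_rate` (%), `gamma_map`
#'   (matrix, NA below threshold), criteria echo fields.
#' @export
gamma_pass_rate <- function(reference, evaluated, dose_criterion = 3, dta = 2,
                            threshold = 10, mode = c("absolute", "relative"),
                            search_factor = 3) {
  mode <- match.arg(mode)
  stopifnot(inherits(reference, "dose_distribution"),
            inherits(evaluated, "dose_distribution"))
  if (!isTRUE(all.equal(reference$x, evaluated$x)) ||
      !isTRUE(all.equal(reference$y, evaluated$y)))
    stop("reference and evaluated must share a lattice; resample_dose() first")
  rmax <- max(reference$grid)
  above <- reference$grid >= threshold / 100 * rmax
  if (!any(above)) stop("no reference node above the dose threshold")
  ev <- evaluated
  if (mode == "relative") {
    denom <- sum(evaluated$grid[above]^2)
    if (denom == 0) stop("evaluated dose is zero over the evaluated region")
    f <- sum(reference$grid[above] * evaluated$grid[above]) / denom
    ev$grid <- evaluated$grid * f
  }
  dd <- dose_criterion / 100 * rmax
  step <- dta / 10
  nmax <- floor(search_factor * dta / step)
  offs <- expand.grid(i = -nmax:nmax, j = -nmax:nmax)
  r2 <- (offs$i^2 + offs$j^2) * step^2
  keep <- r2 <= (search_factor * dta)^2
  offs <- offs[keep, ]; r2 <- r2[keep]
  ord <- order(r2)
  offs <- offs[ord, ]; r2 <- r2[ord]
  gsq <- matrix(Inf, nrow(reference$grid), ncol(reference$grid))
  for (k in seq_len(nrow(offs))) {
    dist_term <- r2[k] / dta^2
    if (dist_term >= max(gsq[above])) break
    es <- shift_sample(ev, offs$i[k] * step, offs$j[k] * step)
    cand <- ((es - reference$grid) / dd)^2 + dist_term
    upd <- !is.na(cand) & cand < gsq
    gsq[upd] <- cand[upd]
  }
  gmap <- sqrt(gsq)
  gmap[!above] <- NA_real_
  structure(list(pass_rate = 100 * mean(gmap[above] <= 1),
                 gamma_map = gmap, dose_criterion = dose_criterion,
                 dta = dta, threshold = threshold, mode = mode),
            class = "gamma_result")
}

#' @export
print.gamma_result <- function(x, ...) {
  cat(sprintf("<gamma_result> %g%%/%g mm (%s, %g%% threshold): pass rate %.1f%%\n",
              x$dose_criterion, x$dta, x$mode, x$threshold, x$pass_rate))
  invisible(x)
}

#' Rigid registration of two planar dose distributions
#'
#' Finds the translation and rotation that best aligns a measured dose to
#' a simulated one by maximizing normalized cross-correlation: a coarse
#' deterministic grid search over +/-10 mm and +/-5 degrees followed by
#' local simplex refinement. The returned transform (dx, dy, theta) maps
#' simulated-frame coordinates into the measured image: the measured dose
#' sampled at R(theta) r + (dx, dy) matches the simulated dose at r.
#'
#' @param measured,simulated `dose_distribution`s with overlapping fields
#'   of view.
#' @param coarse_step Coarse translation step in mm (default 2).
#' @return A list of class `rigid_transform`: `dx`, `dy` (mm),
#'   `rotation` (degrees), `ncc`.
#' @export
rigid_register <- function(measured, simulated, coarse_step = 2) {
  stopifnot(inherits(measured, "dose_distribution"),
            inherits(simulated, "dose_distribution"))
  if (stats::sd(measured$grid) == 0 || stats::sd(simulated$grid) == 0)
    stop("degenerate (constant) dose image")
  sx <- rep(simulated$x, times = length(simulated$y))
  sy <- rep(simulated$y, each = length(simulated$x))
  sg <- as.vector(simulated$grid)
  ncc <- function(p) {
    th <- p[3] * pi / 180
    qx <- cos(th) * sx - sin(th) * sy + p[1]
    qy <- sin(th) * sx + cos(th) * sy + p[2]
    inside <- qx >= measured$x[1] & qx <= measured$x[length(measured$x)] &
      qy >= measured$y[1] & qy <= measured$y[length(measured$y)]
    if (sum(inside) < 16) return(-Inf)
    mv <- sample_points(measured$x, measured$y, measured$grid, qx[inside], qy[inside])
    if (stats::sd(mv) == 0 || stats::sd(sg[inside]) == 0) return(-Inf)
    stats::cor(mv, sg[inside])
  }
  grid <- expand.grid(dx = seq(-10, 10, by = coarse_step),
                      dy = seq(-10, 10, by = coarse_step),
                      th = seq(-5, 5, by = 1))
  vals <- apply(grid, 1, ncc)
  p0 <- as.numeric(grid[which.max(vals), ])
  fit <- stats::optim(p0, function(p) -ncc(p), method = "Nelder-Mead",
                      control = list(reltol = 1e-10, maxit = 500))
  structure(list(dx = fit$par[1], dy = fit$par[2], rotation = fit$par[3],
                 ncc = -fit$value),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform> dx %.2f mm, dy %.2f mm, rotation %.2f deg (NCC %.4f)\n",
              x$dx, x$dy, x$rotation, x$ncc))
  invisible(x)
}

#' Chamber-averaged central-axis dose
#'
#' Area-weighted mean dose over a disk of the given diameter centered at
#' the coordinate origin, emulating the lateral averaging of a
#' plane-parallel reference chamber (vendor-nominal 10 mm diameter by
#' default; the exact footprint is configurable).
#'
#' @param dose A `dose_distribution`.
#' @param footprint_diameter Disk diameter in mm (default 10).
#' @return Mean dose in Gy.
#' @export
central_axis_dose <- function(dose, footprint_diameter = 10) {
  stopifnot(inherits(dose, "dose_distribution"))
  r <- footprint_diameter / 2
  if (r > min(abs(range(dose$x))) || r > min(abs(range(dose$y))))
    stop("chamber footprint exceeds the dose grid")
  disk <- outer(dose$x^2, dose$y^2, `+`) <= r^2
  mean(dose$grid[disk])
}
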