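# Shared lazily-built fixtures. Expensive objects (kernel libraries, fitted
# plans) are constructed once per test run and memoized here; everything is
# generated in code, nothing is read from disk.

.fixtures <- new.env(parent = emptyenv())

fx <- function(name, expr) {
  if (!exists(name, envir = .fixtures, inherits = FALSE))
    assign(name, force(expr), envir = .fixtures)
  get(name, envir = .fixtures, inherits = FALSE)
}

beam78 <- function() beam_from_table(78.3, range_shifted = FALSE)

lib78 <- function() fx("lib78", build_kernel_library(beam78(), tsd = 5))

# small, fast planning scenario: 20 mm circle with just enough padding for
# the 30 mm optimization rind
small_target <- function() fx("small_target", make_circle_target(20, padding = 35))

small_plan <- function() fx("small_plan", {
  dc_plan(small_target(), beam78(), tsd = 5, library = lib78(),
          collimated = TRUE, t_coll = 40)
})

small_plan_uncoll <- function() fx("small_plan_uncoll", {
  dc_plan(small_target(), beam78(), tsd = 5, library = lib78(),
          collimated = FALSE)
})

# hand-rolled target on an arbitrary grid (bypasses the generators; used for
# half-plane / sentinel constructions)
raw_target <- function(mask, x, y, spacing = x[2] - x[1], label = "raw") {
  structure(list(mask = mask, x = x, y = y, spacing = spacing,
                 shape_label = label, area = sum(mask) * spacing^2),
            class = "target_geometry")
}

# candidate-spot data.frame in the shape select_spots() produces
raw_candidates <- function(x, y, config = "Out/Out") {
  out <- data.frame(x = x, y = y, dr_uncoll = NA_real_, dr = NA_real_,
                    config = rep_len(config, length(x)),
                    t_x1 = NA_real_, t_x2 = NA_real_,
                    t_y1 = NA_real_, t_y2 = NA_real_)
  class(out) <- c("candidate_spots", "data.frame")
  out
}

# scalar bilinear interpolation, independent of the package internals;
# returns 0 outside the grid (test oracle building block)
oracle_bilinear <- function(x, y, grid, px, py) {
  if (px < x[1] || px > x[length(x)] || py < y[1] || py > y[length(y)]) return(0)
  h <- x[2] - x[1]
  i <- min(floor((px - x[1]) / h), length(x) - 2)
  j <- min(floor((py - y[1]) / h), length(y) - 2)
  fx_ <- (px - x[1]) / h - i
  fy_ <- (py - y[1]) / h - j
  grid[i + 1, j + 1] * (1 - fx_) * (1 - fy_) + grid[i + 2, j + 1] * fx_ * (1 - fy_) +
    grid[i + 1, j + 2] * (1 - fx_) * fy_ + grid[i + 2, j + 2] * fx_ * fy_
}

# smooth synthetic planar dose: anisotropic Gaussian blob mixture, evaluable
# at arbitrary (possibly transformed) coordinates for registration oracles
blob_dose_fun <- function(px, py) {
  2.0 * exp(-((px - 5)^2 / 200 + (py + 3)^2 / 120)) +
    1.2 * exp(-((px + 15)^2 / 90 + (py - 10)^2 / 260)) +
    0.8 * exp(-((px - 20)^2 / 150 + (py - 18)^2 / 80))
}

blob_dose <- function(spacing = 1, transform = function(px, py) list(px, py)) {
  ax <- seq(-50, 50, by = spacing)
  px <- rep(ax, times = length(ax)); py <- rep(ax, each = length(ax))
  q <- transform(px, py)
  dose_distribution(matrix(blob_dose_fun(q[[1]], q[[2]]), length(ax)), ax, ax)
}
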