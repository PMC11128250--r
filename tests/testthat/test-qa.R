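test_that("dose-area percentiles interpolate the sorted curve and are monotone", {
  m <- matrix(TRUE, 10, 10)
  expect_equal(dose_area_percentile(matrix(5, 10, 10), m, 98), 5)
  expect_equal(dose_area_percentile(matrix(5, 10, 10), m, 2), 5)
  half <- matrix(c(rep(0, 50), rep(10, 50)), 10, 10)
  s <- sort(as.numeric(half), decreasing = TRUE)
  oracle <- approx(seq_along(s) / length(s), s, xout = 0.5, rule = 2)$y
  expect_equal(dose_area_percentile(half, m, 50), oracle)
  set.seed(3)
  r <- matrix(runif(100), 10, 10)
  qs <- c(2, 25, 50, 75, 98)
  vals <- vapply(qs, dose_area_percentile, numeric(1), dose = r, mask = m)
  expect_true(all(diff(vals) <= 0))
  expect_error(dose_area_percentile(r, matrix(FALSE, 10, 10), 50), "empty")
})

test_that("rind mean-dose reduction matches hand arithmetic and is sign-correct", {
  rind <- structure(list(mask = matrix(c(TRUE, FALSE, TRUE, FALSE, FALSE,
                                         FALSE, TRUE, FALSE, TRUE), 3, 3),
                         width = 10, parent = NULL, area = 1),
                    class = "rind_region")
  du <- matrix(1:9 / 2, 3, 3)
  dc <- du * 0.6
  # hand-computed: masked (corner) nodes carry 0.5, 1.5, 3.5, 4.5 Gy, mean
  # 2.5 Gy uncollimated and 1.5 Gy collimated -> 20% of a 5 Gy prescription
  expect_equal(rind_mean_dose_reduction(du, dc, rind, prescription = 5),
               100 * (2.5 - 1.5) / 5)
  expect_equal(rind_mean_dose_reduction(du, du, rind), 0)
  expect_gte(rind_mean_dose_reduction(du, pmin(dc, du), rind), 0)
  expect_error(rind_mean_dose_reduction(matrix(0, 2, 2), dc, rind), "lattice")
})

test_that("depth-trend fits recover exact lines, roots, and noisy slopes", {
  exact <- fit_depth_trend(data.frame(depth = c(5, 10, 15),
                                      reduction = c(40, 30, 20)))
  expect_equal(exact$slope_pct_per_cm, -2, tolerance = 1e-12)
  expect_equal(exact$zero_crossing_depth, 25, tolerance = 1e-9)
  expect_error(fit_depth_trend(data.frame(depth = 1:2, reduction = 1:2)), "3 points")
  quad <- fit_depth_trend(data.frame(depth = c(2, 5, 10, 15),
                                     reduction = 50 - 0.1 * c(2, 5, 10, 15)^2),
                          kind = "poly2")
  expect_equal(quad$zero_crossing_depth, sqrt(500), tolerance = 1e-6)
  set.seed(5)
  d <- seq(4, 22, by = 2)
  y <- 45 - 1.8 * d + rnorm(length(d), sd = 1.5)
  noisy <- fit_depth_trend(data.frame(depth = d, reduction = y))
  se <- summary(noisy$model)$coefficients["depth", "Std. Error"]
  expect_lt(abs(noisy$slope_pct_per_cm - (-1.8)), 2 * se)
})

test_that("gamma is zero for identical doses and 2/3 under a uniform 2% scaling", {
  d <- blob_dose(spacing = 1)
  g <- gamma_pass_rate(d, d, 3, 2)
  expect_equal(g$pass_rate, 100)
  expect_lt(max(g$gamma_map, na.rm = TRUE), 1e-9)
  ax <- seq(-10, 10, by = 0.5)
  uni <- dose_distribution(matrix(2, length(ax), length(ax)), ax, ax)
  sc <- uni; sc$grid <- sc$grid * 1.02
  g2 <- gamma_pass_rate(uni, sc, 3, 2)
  expect_equal(g2$pass_rate, 100)
  expect_equal(max(g2$gamma_map, na.rm = TRUE), 2 / 3, tolerance = 1e-9)
})

test_that("gamma equals an exhaustive brute-force oracle on seeded 11x11 grids", {
  set.seed(123)
  ax <- seq(0, 5, by = 0.5)
  for (rep in 1:3) {
    base <- matrix(runif(121, 0.5, 2), 11, 11)
    ref <- dose_distribution(base, ax, ax)
    ev <- dose_distribution(pmax(base + matrix(rnorm(121, sd = 0.05), 11, 11), 0),
                            ax, ax)
    res <- gamma_pass_rate(ref, ev, 3, 2, threshold = 10)
    # independent oracle: per-node scalar loop over the same offset lattice
    dd <- 0.03 * max(ref$grid)
    step <- 0.2
    offs <- expand.grid(ox = seq(-6, 6, by = step), oy = seq(-6, 6, by = step))
    offs <- offs[offs$ox^2 + offs$oy^2 <= 36 + 1e-12, ]
    above <- ref$grid >= 0.1 * max(ref$grid)
    gmap <- matrix(NA_real_, 11, 11)
    for (i in 1:11) for (j in 1:11) {
      if (!above[i, j]) next
      best <- Inf
      for (k in seq_len(nrow(offs))) {
        px <- ax[i] + offs$ox[k]; py <- ax[j] + offs$oy[k]
        if (px < 0 || px > 5 || py < 0 || py > 5) next
        e <- oracle_bilinear(ax, ax, ev$grid, px, py)
        best <- min(best, ((e - ref$grid[i, j]) / dd)^2 +
                      (offs$ox[k]^2 + offs$oy[k]^2) / 4)
      }
      gmap[i, j] <- sqrt(best)
    }
    expect_equal(res$pass_rate, 100 * mean(gmap[above] <= 1))
    expect_equal(res$gamma_map, gmap, tolerance = 1e-9)
  }
})

test_that("looser gamma criteria never produce lower pass rates", {
  set.seed(9)
  ax <- seq(-8, 8, by = 0.5)
  base <- outer(dnorm(ax, sd = 5), dnorm(ax, sd = 5))
  ref <- dose_distribution(base / max(base), ax, ax)
  ev <- ref
  ev$grid <- pmax(ref$grid * (1 + 0.04 * sin(outer(ax, ax, `+`))), 0)
  p33 <- gamma_pass_rate(ref, ev, 3, 3)$pass_rate
  p32 <- gamma_pass_rate(ref, ev, 3, 2)$pass_rate
  p22 <- gamma_pass_rate(ref, ev, 2, 2)$pass_rate
  expect_gte(p33, p32)
  expect_gte(p32, p22)
})

test_that("relative-mode gamma absorbs a global scale difference", {
  d <- blob_dose(spacing = 1)
  ev <- d; ev$grid <- d$grid * 1.30
  expect_lt(gamma_pass_rate(d, ev, 2, 2)$pass_rate, 100)
  expect_equal(gamma_pass_rate(d, ev, 2, 2, mode = "relative")$pass_rate, 100)
})

test_that("rigid registration recovers identity, shifts and rotations", {
  sim <- blob_dose(spacing = 1)
  t_id <- rigid_register(sim, sim)
  expect_lt(abs(t_id$dx), 0.05)
  expect_lt(abs(t_id$dy), 0.05)
  expect_lt(abs(t_id$rotation), 0.05)
  meas <- blob_dose(spacing = 1,
                    transform = function(px, py) list(px - 3.8, py + 2.0))
  t_sh <- rigid_register(meas, sim)
  expect_lt(abs(t_sh$dx - 3.8), 0.25)
  expect_lt(abs(t_sh$dy - (-2.0)), 0.25)
  th <- 2 * pi / 180
  rot <- blob_dose(spacing = 1, transform = function(px, py)
    list(cos(th) * px + sin(th) * py, -sin(th) * px + cos(th) * py))
  t_rot <- rigid_register(rot, sim)
  expect_lt(abs(t_rot$rotation - 2), 0.25)
  flat <- dose_distribution(matrix(1, 11, 11), 0:10, 0:10)
  expect_error(rigid_register(flat, sim), "constant")
})

test_that("central-axis chamber dose averages a centered disk", {
  ax <- seq(-20, 20, by = 0.5)
  n <- length(ax)
  expect_equal(central_axis_dose(dose_distribution(matrix(3, n, n), ax, ax), 10), 3)
  grad <- dose_distribution(matrix(2 + 0.01 * ax, n, n), ax, ax)
  expect_equal(central_axis_dose(grad, 10), 2, tolerance = 1e-12)
  set.seed(21)
  r <- dose_distribution(matrix(runif(n * n), n, n), ax, ax)
  disk <- outer(ax^2, ax^2, `+`) <= 25
  expect_equal(central_axis_dose(r, 10), mean(r$grid[disk]))
  expect_error(central_axis_dose(r, 60), "exceeds")
})
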