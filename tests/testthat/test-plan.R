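test_that("spot lattice has the requested spacing and contains the centroid", {
  tg <- make_circle_target(80)
  sm <- place_spots(tg, 2.5)
  expect_true(all(abs(diff(sort(unique(sm$positions[, 1]))) - 2.5) < 1e-9))
  expect_true(all(abs(diff(sort(unique(sm$positions[, 2]))) - 2.5) < 1e-9))
  ctr <- dcpt:::target_centroid(tg)
  expect_true(any(sm$positions[, 1] == ctr[1] & sm$positions[, 2] == ctr[2]))
  ks <- make_kidney_bean_target("small")
  expect_gt(nrow(place_spots(ks, 1)$positions), nrow(place_spots(ks, 2.5)$positions))
  empty <- tg
  empty$mask[] <- FALSE
  expect_error(place_spots(empty, 2.5), "empty")
})

test_that("dose ratio is 100% on a half-plane, tiny far away, peaked at the center", {
  k <- make_uncollimated_kernel(beam78())
  ax <- seq(-60.25, 60.25, by = 0.5)   # no node at x = 0: exact half split
  half <- raw_target(matrix(rep(ax < 0, times = length(ax)), length(ax)), ax, ax)
  expect_equal(dose_ratio(k, c(0, 0), half), 100, tolerance = 0.01)
  tg3 <- make_circle_target(30)
  expect_lt(dose_ratio(k, c(10 * core_sigma(beam78()) + 15, 0), tg3), 0.1)
  tg8 <- make_circle_target(80)
  expect_gt(dose_ratio(k, c(0, 0), tg8), dose_ratio(k, c(40, 0), tg8))
})

test_that("dose ratio equals a brute-force double sum over grid nodes", {
  b <- beam_spec(100, sigma_air = 3, depth = 5)
  k <- make_uncollimated_kernel(b, grid_half_width = 18)
  tg <- make_circle_target(10, spacing = 1, padding = 12)
  for (pos in list(c(0, 0), c(4, -3), c(7, 7))) {
    din <- dout <- 0
    for (i in seq_along(tg$x)) for (j in seq_along(tg$y)) {
      v <- oracle_bilinear(k$x, k$y, k$grid, tg$x[i] - pos[1], tg$y[j] - pos[2])
      if (tg$mask[i, j]) din <- din + v else dout <- dout + v
    }
    expect_equal(dose_ratio(k, pos, tg), 100 * din / dout, tolerance = 1e-9)
  }
})

test_that("spot selection is vacuous at 0, empty above the attainable maximum,
           and monotone in the threshold with new spots outside the target", {
  tg <- make_circle_target(30)
  sm <- place_spots(tg, 2.5)
  lib <- lib78()
  all_kept <- select_spots(sm, lib, tg, 0)
  expect_equal(nrow(all_kept), nrow(sm$positions))
  expect_equal(nrow(select_spots(sm, lib, tg, 1e6)), 0L)
  s30 <- select_spots(sm, lib, tg, 30)
  s16 <- select_spots(sm, lib, tg, 16)
  expect_gte(nrow(s16), nrow(s30))
  extra <- setdiff(paste(s16$x, s16$y), paste(s30$x, s30$y))
  expect_gt(length(extra), 0L)
  inside <- vapply(strsplit(extra, " "), function(p) {
    tg$mask[match(as.numeric(p[1]), tg$x), match(as.numeric(p[2]), tg$y)]
  }, logical(1))
  expect_true(all(!inside))
})

test_that("collimation assignment is monotone in the collimation level", {
  tg <- make_circle_target(30)
  sm <- place_spots(tg, 2.5)
  lib <- lib78()
  cand <- select_spots(sm, lib, tg, 16, policy = "best")
  counts <- vapply(c(0, 20, 40, 65, 70, 100), function(tc) {
    sum(assign_collimation(cand, lib, tg, tc)$config != "Out/Out")
  }, numeric(1))
  expect_equal(counts[1], 0)
  expect_true(all(diff(counts) >= 0))
  expect_gt(counts[6], 0)
  # every emitted configuration is a member of the expanded library
  a70 <- assign_collimation(cand, lib, tg, 70)
  expect_true(all(a70$config %in% c("Out/Out", names(lib$entries))))
})

test_that("spots with the infinite dose-ratio sentinel are never collimated", {
  # target covering the whole grid: no dose falls outside, DR = Inf
  ax <- seq(-20, 20, by = 0.5)
  full <- raw_target(matrix(TRUE, length(ax), length(ax)), ax, ax)
  k <- make_uncollimated_kernel(beam_spec(100, 2, 5), grid_half_width = 15)
  expect_identical(dose_ratio(k, c(0, 0), full), Inf)
  lib <- lib78()
  sm <- structure(list(positions = cbind(0, 0), spacing = 2.5, energy = NA_real_),
                  class = "spot_map")
  cand <- select_spots(sm, lib, full, 0, policy = "best")
  out <- assign_collimation(cand, lib, full, 100)
  expect_identical(out$config, "Out/Out")
})

test_that("trimmer coordinates follow the sign convention and the 1 mm floor", {
  tp <- trimmer_positions_for_spot(c(10, 0), trimmer_config("X2", "Out", x_offset = 1))
  expect_equal(unname(tp["t_x2"]), 11)
  expect_true(all(is.na(tp[c("t_x1", "t_y1", "t_y2")])))
  tp2 <- trimmer_positions_for_spot(c(-3, 4), trimmer_config("X1", "Y2", 2, 1))
  expect_equal(unname(tp2["t_x1"]), -5)
  expect_equal(unname(tp2["t_y2"]), 5)
  expect_error(trimmer_config("X2", "Out", x_offset = 0.5), "1 mm minimum")
  expect_error(trimmer_config("X1", "X2", 1, 1), "X1, X2, Out|Y1, Y2, Out")
})
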