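test_that("beam table lookup returns the tabulated sigma and depth", {
  b <- beam_from_table(78.3, FALSE)
  expect_equal(b$sigma_air, 6.6)
  expect_equal(b$depth, 5)
  b2 <- beam_from_table(184.6, FALSE)
  expect_equal(b2$sigma_air, 3.4)
  expect_equal(b2$depth, 22.5)
  expect_error(beam_from_table(100, FALSE), "valid rows")
  expect_error(beam_from_table(78.3, TRUE), "valid rows")
})

test_that("uncollimated kernel is centro-symmetric, peak-normalized at the origin", {
  k <- make_uncollimated_kernel(beam78())
  n <- length(k$x)
  expect_identical(k$grid, k$grid[n:1, n:1])
  expect_equal(which(k$grid == max(k$grid)), (n^2 + 1) / 2)
  expect_equal(max(k$grid), k$params$peak_calibration)
  expect_true(all(k$grid >= 0))
  expect_error(make_uncollimated_kernel(beam78(), grid_half_width = 10),
               "below 5 core sigmas")
})

test_that("moment analysis on a wide grid recovers the mixture sigma within 2%", {
  p <- beam_model_params()
  for (e in c(78.3, 184.6)) {
    b <- beam_from_table(e, FALSE)
    s <- core_sigma(b, p)
    k <- make_uncollimated_kernel(b, grid_half_width = ceiling(9 * s), params = p)
    # brute-force second moment of the gridded kernel along x
    mom <- sqrt(sum(k$grid * k$x^2) / sum(k$grid))
    s_eff <- s * sqrt(p$core_weight + p$halo_weight * p$halo_ratio^2)
    expect_lt(abs(mom - s_eff) / s_eff, 0.02)
  }
})

test_that("Out/Out collimation is the identity and engaged edges land at the offset", {
  k <- make_uncollimated_kernel(beam78())
  expect_identical(collimate_kernel(k, trimmer_config()), k)
  kc <- collimate_kernel(k, trimmer_config("X2", "Out", x_offset = 1))
  se <- edge_spread_sigma(k$beam, k$tsd, k$params)
  j0 <- which.min(abs(k$y))
  ratio <- kc$grid[, j0] / k$grid[, j0]
  # 50%-of-local-uncollimated crossing of the X profile
  i <- max(which(ratio >= 0.5))
  x50 <- k$x[i] + (0.5 - ratio[i]) / (ratio[i + 1] - ratio[i]) * (k$x[i + 1] - k$x[i])
  expect_lt(abs(x50 - 1), se)
})

test_that("collimation never increases dose and engagement shrinks the integral", {
  k <- make_uncollimated_kernel(beam78())
  lib <- lib78()
  for (entry in lib$entries) {
    expect_true(all(entry$grid <= k$grid + 1e-12))
    expect_gt(kernel_integral(entry), 0)
  }
  two <- library_kernel(lib, "X2@1/Y2@1")
  one_x <- library_kernel(lib, "X2@1/Out")
  one_y <- library_kernel(lib, "Out/Y2@1")
  expect_lt(kernel_integral(two), kernel_integral(one_x))
  expect_lt(kernel_integral(two), kernel_integral(one_y))
})

test_that("edge-spread sigma rises with TSD for RS beams and is nearly flat for NRS", {
  b_rs <- beam_from_table(109.3, TRUE)
  b_nrs <- beam_from_table(78.3, FALSE)
  se_rs <- sapply(c(5, 10, 15), edge_spread_sigma, beam = b_rs)
  se_nrs <- sapply(c(5, 10, 15), edge_spread_sigma, beam = b_nrs)
  expect_true(all(diff(se_rs) > 0))
  expect_lt((max(se_nrs) - min(se_nrs)) / min(se_nrs), 0.05)
})

test_that("symmetry expansion yields 32 trimmed entries closed under flips", {
  lib <- lib78()
  expect_length(lib$entries, 32L)
  expect_identical(config_label(lib$uncollimated$config), "Out/Out")
  k <- lib$entries[[5]]
  expect_identical(dcpt:::flip_kernel(dcpt:::flip_kernel(k, "x"), "x")$grid, k$grid)
  # an X1 entry is the mirrored X2 base kernel
  x1 <- library_kernel(lib, "X1@2/Out")
  x2 <- library_kernel(lib, "X2@2/Out")
  expect_identical(x1$grid, x2$grid[rev(seq_len(nrow(x2$grid))), ])
  # flipping any entry lands on another entry with the flipped label
  for (entry in lib$entries) {
    fl <- dcpt:::flip_kernel(entry, "y")
    mate <- library_kernel(lib, config_label(fl$config))
    expect_identical(fl$grid, mate$grid)
  }
})

test_that("expansion refuses an incomplete base set, naming the gaps", {
  base <- lapply(base_trimmer_configs()[-3],
                 function(cfg) collimate_kernel(make_uncollimated_kernel(beam78()), cfg))
  expect_error(expand_library(base, beam78()), "X2@2/Y2@1")
})
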