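test_that("influence matrix entries are nonnegative kernel samples with exact
           column integrals and shift equivariance", {
  lib <- lib78()
  k <- kernel_on_spacing(lib$uncollimated, 0.5)
  # evaluation nodes laid exactly on the shifted kernel lattice
  spot <- c(2.5, -5)
  nodes <- as.matrix(expand.grid(x = k$x + spot[1], y = k$y + spot[2]))
  A <- build_influence_matrix(raw_candidates(spot[1], spot[2]), lib, nodes)
  expect_true(all(A >= 0))
  expect_equal(sum(A[, 1]) * 0.5^2, sum(k$grid) * 0.5^2, tolerance = 1e-12)
  # translating the spot by one lattice step permutes its column
  ax <- seq(-10, 10, by = 0.5)
  g <- as.matrix(expand.grid(x = ax, y = ax))
  A1 <- build_influence_matrix(raw_candidates(0, 0), lib, g)
  A2 <- build_influence_matrix(raw_candidates(0.5, 0), lib, g)
  m1 <- matrix(A1[, 1], length(ax))
  m2 <- matrix(A2[, 1], length(ax))
  expect_equal(m2[-1, ], m1[-length(ax), ], tolerance = 1e-12)
})

test_that("kernel_on_spacing agrees with the kernel at shared nodes", {
  k <- lib78()$uncollimated
  u <- kernel_on_spacing(k, 0.5)
  shared <- match(k$x, u$x)
  expect_equal(u$grid[shared, shared], k$grid, tolerance = 1e-12)
})

test_that("a one-spot one-node system solves exactly to Rx over influence", {
  w <- optimize_weights(matrix(2e-9, 1, 1), objective_spec(prescription = 5),
                        regions = "target")
  expect_equal(as.numeric(w), 5 / 2e-9, tolerance = 1e-12)
})

test_that("unconstrained-feasible systems match the normal-equations oracle", {
  set.seed(42)
  for (rep in 1:5) {
    A <- matrix(runif(15, 0.5, 1.5), 5, 3) + diag(3, 5, 3)  # well-conditioned
    obj <- objective_spec(prescription = 5, rind_weight = 0)
    w <- optimize_weights(A, obj, regions = rep("target", 5))
    oracle <- solve(crossprod(A), crossprod(A, rep(5, 5)))
    expect_true(all(oracle > 0))  # interior optimum, constraint inactive
    expect_equal(as.numeric(w), as.numeric(oracle), tolerance = 1e-8)
    expect_true(all(w >= 0))
  }
})

test_that("the active-set solver agrees with an independent NNLS implementation", {
  skip_if_not_installed("pracma")
  set.seed(7)
  for (rep in 1:5) {
    A <- matrix(runif(60), 12, 5)
    b <- runif(12, -0.2, 1)          # sign-mixed: some weights pinned at zero
    w <- nnls_qc(crossprod(A), crossprod(A, b))
    ref <- pracma::lsqnonneg(A, b)$x
    expect_equal(as.numeric(w), as.numeric(ref), tolerance = 1e-6)
  }
})

test_that("optimized weights beat the zero vector and random nonnegative vectors", {
  set.seed(11)
  A <- matrix(runif(200, 0, 1e-9), 20, 10)
  regions <- rep(c("target", "rind"), each = 10)
  obj <- objective_spec()
  w <- optimize_weights(A, obj, regions)
  f_opt <- objective_value(A, w, obj, regions)
  expect_lte(f_opt, objective_value(A, numeric(10), obj, regions))
  for (i in 1:100) {
    r <- runif(10, 0, 2) * mean(w[w > 0])
    expect_lte(f_opt, objective_value(A, r, obj, regions) + 1e-15)
  }
})

test_that("dose computation is linear, zero at zero weights, and superposes", {
  pl <- small_plan()
  d1 <- pl$dose
  d2 <- compute_dose(pl, weights = 2 * pl$weights)
  expect_equal(d2$grid, 2 * d1$grid, tolerance = 1e-12)
  d0 <- compute_dose(pl, weights = 0 * pl$weights)
  expect_true(all(d0$grid == 0))
  idx <- order(pl$weights, decreasing = TRUE)[1:3]
  singles <- lapply(idx, function(i) {
    w <- 0 * pl$weights; w[i] <- pl$weights[i]
    compute_dose(pl, weights = w)$grid
  })
  w3 <- 0 * pl$weights; w3[idx] <- pl$weights[idx]
  expect_equal(compute_dose(pl, weights = w3)$grid, Reduce(`+`, singles),
               tolerance = 1e-12)
})

test_that("plan criteria flag the 3% window and paired 1% agreement", {
  tg <- make_circle_target(30)
  uni <- function(v) dose_distribution(matrix(v, length(tg$x), length(tg$y)),
                                       tg$x, tg$y)
  ok <- verify_plan_criteria(uni(5), tg)
  expect_true(ok$within_3pct)
  expect_equal(ok$d98, 5)
  expect_equal(ok$d2, 5)
  expect_false(verify_plan_criteria(uni(4.5), tg)$within_3pct)
  paired <- verify_plan_criteria(uni(5), tg, paired = uni(5))
  expect_true(paired$paired_within_1pct)
  expect_false(verify_plan_criteria(uni(5), tg, paired = uni(4.8))$paired_within_1pct)
})

test_that("fitted plans expose the usual accessor methods coherently", {
  pl <- small_plan()
  expect_s3_class(pl, "dc_plan")
  expect_length(coef(pl), nrow(pl$spots))
  expect_true(all(coef(pl) >= 0))
  expect_identical(fitted(pl), pl$dose)
  res <- residuals(pl)
  expect_length(res, sum(pl$target$mask))
  expect_lt(max(abs(res)), 0.2)          # near-uniform coverage
  d2mm <- predict(pl, spacing = 2)
  expect_equal(d2mm$spacing, 2)
  s <- summary(pl)
  expect_gt(s$total_protons, 0)
  expect_true(s$within_3pct)
})
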