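#' Optimization objective specification
#'
#' Quadratic target-deviation penalty plus a one-sided quadratic overdose
#' penalty on the 30 mm rind. Penalties are normalized per node so the
#' weights are comparable across targets of different size.
#'
#' @param prescription Prescribed uniform target dose in Gy (default 5).
#' @param target_weight Penalty weight on squared target deviation
#'   (default 1).
#' @param rind_weight Penalty weight on squared rind overdose, relative to
#'   the target weight (default 0.05).
#' @param rind_limit Rind dose above which the one-sided penalty applies
#'   (Gy, default 0: any rind dose is penalized).
#' @param sample_stride Node stride (in analysis-grid nodes) used to sample
#'   the influence matrix during optimization; default 2, i.e. an effective
#'   1 mm lattice on the 0.5 mm analysis grid. Reporting always uses the
#'   full grid.
#' @return A list of class `objective_spec`.
#' @export
objective_spec <- function(prescription = 5, target_weight = 1,
                           rind_weight = 0.05, rind_limit = 0,
                           sample_stride = 2) {
  if (!is.numeric(prescription) || prescription <= 0)
    stop("prescription must be > 0")
  stopifnot(target_weight >= 0, rind_weight >= 0, rind_limit >= 0,
            sample_stride >= 1)
  structure(list(prescription = prescription, target_weight = target_weight,
                 rind_weight = rind_weight, rind_limit = rind_limit,
                 sample_stride = as.integer(sample_stride)),
            class = "objective_spec")
}

# Sampled evaluation nodes: every `stride`-th analysis-grid node inside the
# target and inside the rind. Returns coords plus region labels.
sample_eval_nodes <- function(target, rind, stride) {
  nx <- length(target$x); ny <- length(target$y)
  si <- seq(1L, nx, by = stride); sj <- seq(1L, ny, by = stride)
  sub_t <- target$mask[si, sj, drop = FALSE]
  sub_r <- rind$mask[si, sj, drop = FALSE]
  it <- which(sub_t, arr.ind = TRUE)
  ir <- which(sub_r, arr.ind = TRUE)
  list(
    xy = rbind(cbind(target$x[si[it[, 1]]], target$y[sj[it[, 2]]]),
               cbind(target$x[si[ir[, 1]]], target$y[sj[ir[, 2]]])),
    region = c(rep("target", nrow(it)), rep("rind", nrow(ir)))
  )
}

#' Build the beamlet influence matrix
#'
#' Entry (i, j) is the dose per proton delivered at evaluation node i by
#' spot j's configured, shifted beamlet kernel; nodes outside a kernel's
#' support receive zero. Kernels are resampled once per configuration to
#' the analysis spacing, so influence values are consistent with
#' `compute_dose()`.
#'
#' @param spots A `candidate_spots` data.frame (columns `x`, `y`, `config`).
#' @param library A `kernel_library`.
#' @param eval_nodes An n x 2 matrix of node coordinates in mm.
#' @param spacing Analysis spacing the kernels are resampled to (mm).
#' @return A dense numeric matrix (nodes x spots), all entries >= 0.
#' @export
build_influence_matrix <- function(spots, library, eval_nodes, spacing = 0.5) {
  stopifnot(is.data.frame(spots), is.matrix(eval_nodes), ncol(eval_nodes) == 2)
  cfgs <- unique(spots$config)
  ups <- lapply(cfgs, function(lb) kernel_on_spacing(library_kernel(library, lb), spacing))
  names(ups) <- cfgs
  n <- nrow(eval_nodes); m <- nrow(spots)
  A <- matrix(0, n, m)
  for (j in seq_len(m)) {
    u <- ups[[spots$config[j]]]
    A[, j] <- sample_points(u$x, u$y, u$grid,
                            eval_nodes[, 1] - spots$x[j],
                            eval_nodes[, 2] - spots$y[j])
  }
  A
}

# Bilinear sample of a regular grid at arbitrary point pairs, zero outside.
sample_points <- function(x, y, grid, px, py) {
  hx <- x[2] - x[1]; hy <- y[2] - y[1]
  inside <- px >= x[1] & px <= x[length(x)] & py >= y[1] & py <= y[length(y)]
  v <- numeric(length(px))
  if (!any(inside)) return(v)
  ix <- (px[inside] - x[1]) / hx
  iy <- (py[inside] - y[1]) / hy
  i0 <- pmin(floor(ix), length(x) - 2); fx <- ix - i0
  j0 <- pmin(floor(iy), length(y) - 2); fy <- iy - j0
  n <- length(x)
  idx <- i0 + 1 + j0 * n
  v[inside] <- grid[idx] * (1 - fx) * (1 - fy) + grid[idx + 1] * fx * (1 - fy) +
    grid[idx + n] * (1 - fx) * fy + grid[idx + n + 1] * fx * fy
  v
}

#' Nonnegative least squares on normal equations
#'
#' Active-set Lawson-Hanson solver for min ||A w - b||^2 s.t. w >= 0,
#' posed on the normal equations Q = A'A, c = A'b. Pivoting is
#' deterministic (largest positive gradient first, first index on ties)
#' and the solve is warm-started from the positive part of the
#' unconstrained solution, which for well-conditioned planning systems
#' reduces the number of active-set iterations substantially.
#'
#' @param Q Symmetric positive semi-definite matrix (n x n).
#' @param c Right-hand side vector A'b.
#' @param tol Convergence tolerance on the projected gradient; default
#'   1e-10 relative to the largest gradient entry.
#' @return Nonnegative weight vector of length n.
#' @export
nnls_qc <- function(Q, c, tol = NULL) {
  n <- length(c)
  if (is.null(tol)) tol <- 1e-10 * max(abs(c), .Machine$double.xmin)
  if (all(c <= tol)) return(numeric(n))
  solveP <- function(p) {
    Qp <- Q[p, p, drop = FALSE]
    ch <- tryCatch(chol(Qp), error = function(e) NULL)
    if (is.null(ch))
      ch <- chol(Qp + diag(1e-12 * max(diag(Qp)), sum(p)))
    backsolve(ch, forwardsolve(t(ch), c[p]))
  }
  w <- numeric(n)
  P <- rep(FALSE, n)
  z0 <- tryCatch(solveP(rep(TRUE, n)), error = function(e) NULL)
  if (!is.null(z0)) P <- z0 > 0
  iter <- 0L
  repeat {
    iter <- iter + 1L
    if (iter > 10L * n) stop("nnls_qc failed to converge")
    if (any(P)) {
      z <- solveP(P)
      inner <- 0L
      while (any(z <= 0) && inner < 10L * n) {
        inner <- inner + 1L
        ip <- which(P)
        neg <- which(z <= 0)
        alpha <- min(w[ip][neg] / (w[ip][neg] - z[neg]))
        wp <- w[ip] + alpha * (z - w[ip])
        wp[neg[w[ip][neg] / (w[ip][neg] - z[neg]) <= alpha + 1e-15]] <- 0
        w[] <- 0; w[ip] <- wp
        P[ip[wp <= 0]] <- FALSE
        if (!any(P)) break
        z <- solveP(P)
      }
      w[] <- 0
      if (any(P)) w[which(P)] <- z
    }
    g <- c - as.vector(Q %*% w)
    cand <- which(!P & g > tol)
    if (!length(cand)) break
    P[cand[which.max(g[cand])]] <- TRUE
  }
  w
}

#' Optimize spot weights to a uniform prescription
#'
#' Minimizes target_weight * mean_target (D_i - Rx)^2 + rind_weight *
#' mean_rind max(D_i - rind_limit, 0)^2 over nonnegative weights, where
#' D = A w. With the default rind_limit of 0 the one-sided penalty is a
#' plain quadratic (doses are nonnegative); for positive limits the active
#' rind set is re-estimated in an outer loop. Deterministic for fixed
#' inputs.
#'
#' @param matrix Influence matrix (nodes x spots).
#' @param objective An `objective_spec`.
#' @param regions Character vector per row of `matrix`: `"target"` or
#'   `"rind"`.
#' @return Nonnegative weight vector (protons per spot), with the achieved
#'   objective value as attribute `"objective_value"`.
#' @export
optimize_weights <- function(matrix, objective = objective_spec(), regions) {
  stopifnot(is.matrix(matrix), nrow(matrix) == length(regions))
  if (nrow(matrix) == 0L || ncol(matrix) == 0L) stop("empty influence matrix")
  ti <- regions == "target"
  if (!any(ti)) stop("no target nodes among evaluation nodes")
  if (all(matrix == 0)) stop("all-zero influence matrix: no spot reaches any node")
  At <- matrix[ti, , drop = FALSE]
  Ar <- matrix[!ti, , drop = FALSE]
  nt <- nrow(At); nr <- max(1L, nrow(Ar))
  wt <- objective$target_weight / nt
  wr <- objective$rind_weight / nr
  Qt <- crossprod(At); ct <- colSums(At) * objective$prescription
  active <- rep(TRUE, nrow(Ar))   # rind_limit = 0: every rind node active
  for (pass in 1:10) {
    Qr <- if (any(active)) crossprod(Ar[active, , drop = FALSE]) else 0 * Qt
    cr <- if (any(active) && objective$rind_limit > 0)
      colSums(Ar[active, , drop = FALSE]) * objective$rind_limit else numeric(ncol(At))
    w <- nnls_qc(wt * Qt + wr * Qr, wt * ct + wr * cr)
    if (objective$rind_limit == 0 || nrow(Ar) == 0L) break
    newact <- as.vector(Ar %*% w) > objective$rind_limit
    if (identical(newact, active)) break
    active <- newact
  }
  attr(w, "objective_value") <- objective_value(matrix, w, objective, regions)
  w
}

#' Objective value of a weight vector
#'
#' @inheritParams optimize_weights
#' @param weights Nonnegative weight vector.
#' @return Scalar penalized objective value.
#' @export
objective_value <- function(matrix, weights, objective, regions) {
  d <- as.vector(matrix %*% weights)
  ti <- regions == "target"
  val <- objective$target_weight * mean((d[ti] - objective$prescription)^2)
  if (any(!ti))
    val <- val + objective$rind_weight * mean(pmax(d[!ti] - objective$rind_limit, 0)^2)
  val
}
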