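#' Protons-per-MU conversion factor
#'
#' Relates the Monte Carlo-style dose calibration (Gy per proton) to the
#' machine meterset calibration (Gy per MU) under reference conditions:
#' factor = (Gy/MU) / (Gy/proton) protons per MU.
#'
#' @param dose_per_proton Dose per proton at the reference point (Gy).
#' @param dose_per_mu Measured dose per MU at the same point (Gy).
#' @param energy Beam energy the factor applies to (MeV, optional).
#' @param reference_conditions Label of the reference setup.
#' @return A list of class `conversion_factor` with `protons_per_mu`.
#' @export
#' @examples
#' protons_per_mu(1e-9, 1e-2)$protons_per_mu
protons_per_mu <- function(dose_per_proton, dose_per_mu, energy = NA_real_,
                           reference_conditions = "reference") {
  if (!is.numeric(dose_per_proton) || dose_per_proton <= 0)
    stop("dose_per_proton must be > 0")
  if (!is.numeric(dose_per_mu) || dose_per_mu <= 0)
    stop("dose_per_mu must be > 0")
  structure(list(protons_per_mu = dose_per_mu / dose_per_proton,
                 energy = energy, reference_conditions = reference_conditions),
            class = "conversion_factor")
}

#' @export
print.conversion_factor <- function(x, ...) {
  cat(sprintf("<conversion_factor> %.4e protons/MU (%s)\n",
              x$protons_per_mu, x$reference_conditions))
  invisible(x)
}

fmt_trim <- function(v) ifelse(is.na(v), "Out", sprintf("%.3f", v))

#' Write an extended PLD delivery file
#'
#' Serializes a plan as a layered delivery description: a version line, a
#' beam header, one layer block for the single energy layer, and one
#' element line per spot carrying the spot coordinates, the meterset in MU
#' (optimized protons divided by the protons/MU factor) and -- the
#' extension over the legacy dialect -- the four trimmer coordinates
#' appended to the element line (`Out` for parked trimmers). Coordinates
#' are isocenter-plane mm with 3 decimals; MU uses 6 significant digits.
#'
#' @param x A `dc_plan` or a `pld_file` (from `read_pld()`).
#' @param conversion A `conversion_factor` (`dc_plan` method only).
#' @param path Output file path.
#' @param ... Unused.
#' @return The path, invisibly.
#' @export
write_pld <- function(x, ...) UseMethod("write_pld")

#' @rdname write_pld
#' @export
write_pld.dc_plan <- function(x, conversion, path, ...) {
  stopifnot(inherits(conversion, "conversion_factor"))
  if (any(x$weights < 0)) stop("negative spot weight")
  mu <- x$weights / conversion$protons_per_mu
  pld <- structure(list(energy = x$beam$energy, tsd = x$tsd,
                        rs = x$beam$range_shifted,
                        reference = conversion$reference_conditions,
                        elements = data.frame(
                          x = x$spots$x, y = x$spots$y, mu = mu,
                          t_x1 = x$spots$t_x1, t_x2 = x$spots$t_x2,
                          t_y1 = x$spots$t_y1, t_y2 = x$spots$t_y2)),
                   class = "pld_file")
  write_pld(pld, path = path)
}

#' @rdname write_pld
#' @export
write_pld.pld_file <- function(x, path, ...) {
  e <- x$elements
  if (any(e$mu < 0)) stop("negative MU")
  lines <- c(
    "pld,1",
    sprintf("beam,%.1f,%g,%s,%s", x$energy, x$tsd,
            if (x$rs) "RS" else "NRS", x$reference),
    sprintf("layer,%.1f,%d", x$energy, nrow(e)),
    sprintf("spot,%.3f,%.3f,%.6g,%s,%s,%s,%s",
            e$x, e$y, e$mu,
            fmt_trim(e$t_x1), fmt_trim(e$t_x2),
            fmt_trim(e$t_y1), fmt_trim(e$t_y2))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read an extended PLD delivery file
#'
#' Strict parser for the dialect written by `write_pld()`. Element lines
#' must carry all four trimmer fields; legacy element lines without them
#' are rejected as a dialect error rather than silently accepted. Negative
#' metersets and malformed lines raise errors naming the offending line.
#'
#' @param path File path.
#' @return An object of class `pld_file`: `energy`, `tsd`, `rs`,
#'   `reference`, `elements` (data.frame with `x`, `y`, `mu`, `t_x1`,
#'   `t_x2`, `t_y1`, `t_y2`; NA encodes a parked trimmer).
#' @export
read_pld <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3L || lines[1] != "pld,1")
    stop("not a PLD file (missing 'pld,1' version line)")
  bh <- strsplit(lines[2], ",", fixed = TRUE)[[1]]
  if (length(bh) != 5L || bh[1] != "beam")
    stop("line 2: malformed beam header")
  lh <- strsplit(lines[3], ",", fixed = TRUE)[[1]]
  if (length(lh) != 3L || lh[1] != "layer")
    stop("line 3: malformed layer header")
  n <- as.integer(lh[3])
  el <- lines[-(1:3)]
  if (length(el) != n)
    stop("layer declares ", n, " elements but file has ", length(el))
  parse_trim <- function(s, ln) {
    if (s == "Out") return(NA_real_)
    v <- suppressWarnings(as.numeric(s))
    if (is.na(v)) stop("line ", ln, ": bad trimmer coordinate '", s, "'")
    v
  }
  rows <- lapply(seq_along(el), function(i) {
    ln <- i + 3L
    f <- strsplit(el[i], ",", fixed = TRUE)[[1]]
    if (length(f) == 4L && f[1] == "spot")
      stop("line ", ln, ": legacy element without trimmer fields (dialect error)")
    if (length(f) != 8L || f[1] != "spot")
      stop("line ", ln, ": malformed element line")
    num <- suppressWarnings(as.numeric(f[2:4]))
    if (any(is.na(num))) stop("line ", ln, ": non-numeric spot fields")
    if (num[3] < 0) stop("line ", ln, ": negative MU")
    c(num, vapply(f[5:8], parse_trim, numeric(1), ln = ln))
  })
  m <- do.call(rbind, rows)
  structure(list(energy = as.numeric(bh[2]), tsd = as.numeric(bh[3]),
                 rs = bh[4] == "RS", reference = bh[5],
                 elements = data.frame(x = m[, 1], y = m[, 2], mu = m[, 3],
                                       t_x1 = m[, 4], t_x2 = m[, 5],
                                       t_y1 = m[, 6], t_y2 = m[, 7])),
            class = "pld_file")
}

#' @export
print.pld_file <- function(x, ...) {
  cat(sprintf("<pld_file> %.1f MeV %s, TSD %g cm, %d elements, total %.4g MU\n",
              x$energy, if (x$rs) "RS" else "NRS", x$tsd,
              nrow(x$elements), sum(x$elements$mu)))
  invisible(x)
}
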