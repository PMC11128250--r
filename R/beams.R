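#' Machine beam table for the evaluated treatment depths
#'
#' Returns the table of monoenergetic beams evaluated by the planning study:
#' treatment depth in water, range-shifter presence, nominal beam energy and
#' spot sigma in air at isocenter. One row per (energy, range-shifter) pair.
#'
#' @return A data.frame with columns `depth` (cm), `rs` (logical,
#'   range-shifted), `energy` (MeV) and `sigma_air` (mm).
#' @export
#' @examples
#' beam_table()
beam_table <- function() {
  data.frame(
    depth     = c(2, 3, 5, 5, 10, 10, 13.5, 15, 17.5, 22.5),
    rs        = c(TRUE, TRUE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, FALSE, FALSE),
    energy    = c(86.9, 94.8, 109.3, 78.3, 140.5, 116.0, 159.7, 146.1, 159.7, 184.6),
    sigma_air = c(7.6, 7.0, 6.2, 6.6, 4.9, 5.0, 4.3, 4.2, 3.8, 3.4)
  )
}

#' Construct a beam specification from the machine beam table
#'
#' Looks up the beam table row for a given nominal energy and range-shifter
#' flag and returns the corresponding beam specification.
#'
#' @param energy Nominal beam energy in MeV. Must match a beam-table row.
#' @param range_shifted Logical; `TRUE` for range-shifted (RS) beams.
#' @param measurement_depth Depth in cm of the planar dose evaluation plane.
#'   Defaults to the treatment (Bragg) depth of the table row.
#' @return An object of class `beam_spec` with fields `energy`, `sigma_air`
#'   (mm), `depth` (cm), `range_shifted` and `measurement_depth` (cm).
#' @export
#' @examples
#' beam_from_table(78.3, range_shifted = FALSE)
beam_from_table <- function(energy, range_shifted = FALSE, measurement_depth = NULL) {
  tab <- beam_table()
  hit <- which(abs(tab$energy - energy) < 1e-6 & tab$rs == range_shifted)
  if (length(hit) != 1L) {
    rows <- paste(sprintf("%.1f MeV (%s)", tab$energy, ifelse(tab$rs, "RS", "NRS")),
                  collapse = ", ")
    stop("no beam-table row for ", energy, " MeV (",
         if (range_shifted) "RS" else "NRS", "); valid rows: ", rows)
  }
  beam_spec(energy = tab$energy[hit], sigma_air = tab$sigma_air[hit],
            depth = tab$depth[hit], range_shifted = range_shifted,
            measurement_depth = measurement_depth)
}

#' Create a beam specification
#'
#' Low-level constructor; `beam_from_table()` is the usual entry point.
#'
#' @param energy Beam energy (MeV).
#' @param sigma_air Spot sigma in air at isocenter (mm), > 0.
#' @param depth Treatment depth in water (cm), > 0.
#' @param range_shifted Logical range-shifter flag.
#' @param measurement_depth Evaluation plane depth (cm); defaults to `depth`.
#' @return A `beam_spec` object.
#' @export
beam_spec <- function(energy, sigma_air, depth, range_shifted = FALSE,
                      measurement_depth = NULL) {
  stopifnot(is.numeric(energy), length(energy) == 1L)
  if (!is.numeric(sigma_air) || sigma_air <= 0) stop("sigma_air must be > 0")
  if (!is.numeric(depth) || depth <= 0) stop("depth must be > 0")
  if (is.null(measurement_depth)) measurement_depth <- depth
  if (measurement_depth <= 0) stop("measurement_depth must be > 0")
  structure(list(energy = energy, sigma_air = sigma_air, depth = depth,
                 range_shifted = isTRUE(range_shifted),
                 measurement_depth = measurement_depth),
            class = "beam_spec")
}

#' @export
print.beam_spec <- function(x, ...) {
  cat(sprintf("<beam_spec> %.1f MeV %s, sigma_air %.1f mm, depth %.1f cm (plane %.1f cm)\n",
              x$energy, if (x$range_shifted) "RS" else "NRS",
              x$sigma_air, x$depth, x$measurement_depth))
  invisible(x)
}

#' Lateral beam-model parameters
#'
#' Parameters of the analytic lateral beamlet model: a double-Gaussian
#' fluence kernel (narrow core plus light broad halo), quadrature in-water
#' broadening of the spot sigma, and a geometric-plus-scatter edge-spread
#' model for the trimmer penumbra.
#'
#' @param core_weight Integral weight of the core Gaussian (default 0.95).
#' @param halo_weight Integral weight of the halo Gaussian (default 0.05).
#' @param halo_ratio Halo sigma as a multiple of the core sigma (default 3).
#' @param k_water In-water broadening coefficient (mm of sigma per cm of
#'   depth, default 0.35).
#' @param theta_nrs Effective angular spread without range shifter (rad,
#'   default 0.002).
#' @param theta_rs Effective angular spread with range shifter (rad,
#'   default 0.012).
#' @param peak_calibration Dose per proton at the uncollimated kernel peak
#'   (Gy/proton, default 1e-9).
#' @return A list of class `beam_model_params`.
#' @export
beam_model_params <- function(core_weight = 0.95, halo_weight = 0.05,
                              halo_ratio = 3, k_water = 0.35,
                              theta_nrs = 0.002, theta_rs = 0.012,
                              peak_calibration = 1e-9) {
  stopifnot(core_weight > 0, halo_weight >= 0, halo_ratio >= 1,
            k_water >= 0, theta_nrs >= 0, theta_rs >= 0, peak_calibration > 0)
  structure(list(core_weight = core_weight, halo_weight = halo_weight,
                 halo_ratio = halo_ratio, k_water = k_water,
                 theta_nrs = theta_nrs, theta_rs = theta_rs,
                 peak_calibration = peak_calibration),
            class = "beam_model_params")
}

#' In-water broadened core sigma of a beam
#'
#' Effective core sigma at the evaluation plane: the in-air sigma broadened
#' in quadrature by multiple Coulomb scattering, sigma(d) =
#' sqrt(sigma_air^2 + (k d)^2) with d the plane depth in cm.
#'
#' @param beam A `beam_spec`.
#' @param params A `beam_model_params` list.
#' @return Core sigma in mm.
#' @export
core_sigma <- function(beam, params = beam_model_params()) {
  sqrt(beam$sigma_air^2 + (params$k_water * beam$measurement_depth)^2)
}

#' Trimmer edge-spread sigma
#'
#' Penumbral blur of a trimmer edge at the evaluation plane. Combines the
#' geometric penumbra of the beam's angular spread projected over the
#' trimmer-to-surface distance plus the in-water depth with the in-water
#' scattering term: sigma_edge = sqrt((theta (TSD + d) * 10)^2 + (k d)^2),
#' distances in cm, result in mm. The angular spread is much larger for
#' range-shifted beams, which is what makes their penumbra (and hence the
#' achievable collimation benefit) strongly TSD-dependent.
#'
#' @param beam A `beam_spec`.
#' @param tsd Trimmer-to-surface distance (cm).
#' @param params A `beam_model_params` list.
#' @return Edge-spread sigma in mm.
#' @export
edge_spread_sigma <- function(beam, tsd, params = beam_model_params()) {
  stopifnot(is.numeric(tsd), tsd >= 0)
  theta <- if (beam$range_shifted) params$theta_rs else params$theta_nrs
  d <- beam$measurement_depth
  sqrt((theta * (tsd + d) * 10)^2 + (params$k_water * d)^2)
}
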