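#' Write a planar dose grid as delimited text
#'
#' Tab-separated dose matrix preceded by commented header lines carrying
#' the spatial metadata (origin, spacing, depth).
#'
#' @param dose A `dose_distribution`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_dose_table <- function(dose, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# origin %.6g %.6g", dose$x[1], dose$y[1]),
               sprintf("# spacing %.6g", dose$spacing),
               sprintf("# depth %.6g", dose$depth)), con)
  utils::write.table(dose$grid, con, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a planar dose grid written by `write_dose_table()`
#'
#' @param path File path.
#' @return A `dose_distribution`.
#' @export
read_dose_table <- function(path) {
  hdr <- readLines(path, n = 3)
  if (!all(startsWith(hdr, "# "))) stop("missing dose-table header")
  origin <- as.numeric(strsplit(hdr[1], " ")[[1]][3:4])
  spacing <- as.numeric(strsplit(hdr[2], " ")[[1]][3])
  depth <- as.numeric(strsplit(hdr[3], " ")[[1]][3])
  g <- as.matrix(utils::read.table(path, sep = "\t", skip = 3))
  dimnames(g) <- NULL
  dose_distribution(g, origin[1] + spacing * (seq_len(nrow(g)) - 1),
                    origin[2] + spacing * (seq_len(ncol(g)) - 1), depth)
}

#' Export a plan as a plain-text spot table
#'
#' One row per spot: position, configuration label, the four trimmer
#' coordinates and the optimized weight, preceded by a commented header
#' echoing the planning parameters.
#'
#' @param plan A `dc_plan`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_plan_table <- function(plan, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# target %s", plan$target$shape_label),
    sprintf("# beam %.1f MeV %s depth %g cm", plan$beam$energy,
            if (plan$beam$range_shifted) "RS" else "NRS", plan$beam$depth),
    sprintf("# tsd %g cm", plan$tsd),
    sprintf("# dr_thresh %g t_coll %g prescription %g",
            plan$dr_thresh, plan$t_coll, plan$objective$prescription)), con)
  df <- plan$spots[, c("x", "y", "config", "t_x1", "t_x2", "t_y1", "t_y2")]
  df$weight <- plan$weights
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

pipeline_defaults <- function() {
  list(shape = "kidney_large", depth = 5, range_shifted = FALSE, tsd = 5,
       spot_spacing = NULL, dr_thresh_uncollimated = 30,
       dr_thresh_collimated = 16, t_coll = 40, prescription = 5,
       dose_per_mu = 1e-2, outdir = tempfile("dcpt_run_"), seed = 1,
       qa_spacing = 2)
}

#' Run the end-to-end planning and QA pipeline
#'
#' Orchestrates the full chain for one target/beam scenario: kernel
#' library generation, target and rind rasterization, spot selection,
#' collimation assignment, weight optimization for the matched
#' uncollimated/collimated plan pair, plan-criteria verification, rind
#' dose-reduction summary, a gamma QA self-check of the dose reconstructed
#' from the emitted delivery file against the planned dose, and PLD
#' emission. Fully deterministic for a fixed configuration.
#'
#' @param config A named list (or path to a YAML file) overriding the
#'   defaults: `shape`, `depth` (cm), `range_shifted`, `tsd` (cm),
#'   `spot_spacing` (mm or NULL for the shape default),
#'   `dr_thresh_uncollimated`, `dr_thresh_collimated`, `t_coll`,
#'   `prescription` (Gy), `dose_per_mu` (Gy/MU), `outdir`, `seed`,
#'   `qa_spacing` (mm lattice for the gamma self-check).
#' @param quiet Suppress stage logging (default FALSE).
#' @return A list of class `pipeline_bundle`: the plan pair, criteria,
#'   rind summary data.frame, gamma QA result, conversion factor and the
#'   paths of all written artifacts. Errors if the paired plan criteria
#'   fail after auto-tuning.
#' @export
run_pipeline <- function(config = list(), quiet = FALSE) {
  if (is.character(config)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading a config file requires the yaml package")
    config <- yaml::read_yaml(config)
  }
  cfg <- utils::modifyList(pipeline_defaults(), config)
  log_stage <- function(...) if (!quiet)
    message(format(Sys.time(), "[%H:%M:%S] "), sprintf(...))
  log_stage("config: %s depth %g cm %s TSD %g cm Tcoll %g%% seed %d",
            cfg$shape, cfg$depth, if (cfg$range_shifted) "RS" else "NRS",
            cfg$tsd, cfg$t_coll, cfg$seed)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)

  tab <- beam_table()
  row <- which(abs(tab$depth - cfg$depth) < 1e-9 & tab$rs == cfg$range_shifted)
  if (length(row) != 1L)
    stop("no beam-table row at depth ", cfg$depth, " cm (",
         if (cfg$range_shifted) "RS" else "NRS", ")")
  beam <- beam_from_table(tab$energy[row], cfg$range_shifted)

  log_stage("library: generating kernels at %.1f MeV", beam$energy)
  library <- build_kernel_library(beam, cfg$tsd)

  log_stage("target: %s", cfg$shape)
  target <- make_target(cfg$shape)
  rind10 <- make_rind(target, 10)
  rind30 <- make_rind(target, 30)

  log_stage("planning: paired uncollimated/collimated optimization")
  obj <- objective_spec(prescription = cfg$prescription)
  pair <- dc_plan_pair(target, beam, tsd = cfg$tsd, library = library,
                       dr_thresh_uncollimated = cfg$dr_thresh_uncollimated,
                       dr_thresh_collimated = cfg$dr_thresh_collimated,
                       t_coll = cfg$t_coll, objective = obj,
                       spot_spacing = cfg$spot_spacing)
  if (!pair$uncollimated$criteria$within_3pct ||
      !pair$collimated$criteria$within_3pct ||
      !pair$criteria$paired_within_1pct)
    stop("plan criteria not met after auto-tuning: ",
         sprintf("uncoll D98 %.3f D2 %.3f; coll D98 %.3f D2 %.3f",
                 pair$uncollimated$criteria$d98, pair$uncollimated$criteria$d2,
                 pair$collimated$criteria$d98, pair$collimated$criteria$d2))

  log_stage("metrics: rind dose reductions")
  rind_summary <- do.call(rbind, lapply(list(rind10, rind30), function(r) {
    data.frame(rind_width = r$width,
               mean_uncoll_pct = 100 * mean(pair$uncollimated$dose$grid[r$mask]) / cfg$prescription,
               mean_coll_pct = 100 * mean(pair$collimated$dose$grid[r$mask]) / cfg$prescription,
               reduction_pct = rind_mean_dose_reduction(
                 pair$uncollimated$dose, pair$collimated$dose, r, cfg$prescription))
  }))

  log_stage("delivery: PLD emission and round-trip QA")
  conv <- protons_per_mu(pair$collimated$params$peak_calibration, cfg$dose_per_mu,
                         energy = beam$energy, reference_conditions = "synthetic")
  paths <- list(
    pld_uncollimated = file.path(cfg$outdir, "uncollimated.pld"),
    pld_collimated = file.path(cfg$outdir, "collimated.pld"),
    plan_uncollimated = file.path(cfg$outdir, "plan_uncollimated.tsv"),
    plan_collimated = file.path(cfg$outdir, "plan_collimated.tsv"),
    dose_uncollimated = file.path(cfg$outdir, "dose_uncollimated.tsv"),
    dose_collimated = file.path(cfg$outdir, "dose_collimated.tsv"),
    criteria = file.path(cfg$outdir, "criteria.txt"),
    rind_summary = file.path(cfg$outdir, "rind_summary.tsv")
  )
  write_pld(pair$uncollimated, conv, paths$pld_uncollimated)
  write_pld(pair$collimated, conv, paths$pld_collimated)
  write_plan_table(pair$uncollimated, paths$plan_uncollimated)
  write_plan_table(pair$collimated, paths$plan_collimated)
  write_dose_table(pair$uncollimated$dose, paths$dose_uncollimated)
  write_dose_table(pair$collimated$dose, paths$dose_collimated)
  utils::write.table(rind_summary, paths$rind_summary, sep = "\t", row.names = FALSE)

  # QA self-check: dose rebuilt from the emitted PLD (MU quantized to the
  # file precision) compared to the planned dose
  pld <- read_pld(paths$pld_collimated)
  w_rt <- pld$elements$mu * conv$protons_per_mu
  dose_rt <- compute_dose(pair$collimated$spots, library, target, weights = w_rt)
  gamma <- gamma_pass_rate(resample_dose(pair$collimated$dose, cfg$qa_spacing),
                           resample_dose(dose_rt, cfg$qa_spacing),
                           dose_criterion = 3, dta = 2, threshold = 10)

  crit_lines <- utils::capture.output({
    print(pair$uncollimated$criteria)
    print(pair$collimated$criteria)
    print(pair$criteria)
    print(gamma)
  })
  writeLines(crit_lines, paths$criteria)
  log_stage("done: artifacts in %s", cfg$outdir)

  structure(list(config = cfg, beam = beam, target = target, pair = pair,
                 rind_summary = rind_summary, gamma = gamma,
                 conversion = conv, paths = paths),
            class = "pipeline_bundle")
}

#' @export
print.pipeline_bundle <- function(x, ...) {
  cat(sprintf("<pipeline_bundle> %s, %.1f MeV %s, TSD %g cm\n",
              x$config$shape, x$beam$energy,
              if (x$beam$range_shifted) "RS" else "NRS", x$config$tsd))
  print(x$pair$criteria)
  print(x$rind_summary)
  invisible(x)
}
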