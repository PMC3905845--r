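# Orchestration: run configuration, stage execution, run reports and the
# command-line entry point `halodyn {simulate|foci|frap|nandb|hydro}`.

#' Read a run configuration
#'
#' YAML (or JSON) file holding the subcommand parameters, input/output paths
#' and physical calibrations. Values given in \code{overrides} (e.g. parsed
#' CLI flags) replace file values.
#'
#' @param path config file path (NULL for overrides only).
#' @param overrides named list of overriding values.
#' @return named list.
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  cfg <- if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    yaml::read_yaml(path)
  } else list()
  for (nm in names(overrides)) cfg[[nm]] <- overrides[[nm]]
  cfg
}

.require_fields <- function(cfg, fields, stage) {
  miss <- setdiff(fields, names(cfg))
  if (length(miss)) {
    stop("stage '", stage, "' requires config fields: ",
         paste(miss, collapse = ", "), " (no silent defaults for calibrations)")
  }
}

.stage_simulate <- function(cfg, out_dir) {
  preset <- cfg$preset %||% "foci"
  sc_args <- cfg[intersect(names(cfg), names(formals(sim_config)))]
  sc <- do.call(sim_config, sc_args)
  seed <- cfg$rng_seed %||% sc$rng_seed
  if (preset == "foci") {
    geom <- make_cell_geometry(sc, n_cells = cfg$n_cells %||% 20, seed = seed)
    sim <- simulate_timelapse(geom, sc, n_frames = 1, seed = seed)
    write_stack(file.path(out_dir, "field.tif"), sim$stack)
    utils::write.csv(sim$truth, file.path(out_dir, "truth_cells.csv"),
                     row.names = FALSE)
    utils::write.csv(sim$foci, file.path(out_dir, "truth_foci.csv"),
                     row.names = FALSE)
    list(n_cells = nrow(sim$truth), n_foci = sum(sim$truth$n_foci))
  } else if (preset == "frap") {
    sim <- simulate_frap_traces(k_values = cfg$k_values %||% 1.15,
                                amplitudes = cfg$amplitudes %||% 0.35,
                                immobile_fraction = cfg$immobile_fraction %||% 0.65,
                                noise_sd = cfg$noise_sd %||% 0.03,
                                n_traces = cfg$n_traces %||% 17,
                                config = sc, seed = seed)
    for (i in seq_along(sim$traces)) {
      write_frap_csv(file.path(out_dir, sprintf("trace_%03d.csv", i)),
                     sim$traces[[i]])
    }
    jsonlite::write_json(sim$truth, file.path(out_dir, "truth_frap.json"),
                         auto_unbox = TRUE, digits = NA)
    list(n_traces = length(sim$traces))
  } else if (preset == "nandb") {
    sim <- simulate_nandb_stack(n_true = cfg$n_true %||% 27,
                                epsilon_true = cfg$epsilon_true %||% 0.2,
                                n_frames = cfg$n_frames %||% 100,
                                config = sc, seed = seed)
    write_stack(file.path(out_dir, "nandb_stack.tif"), sim$stack)
    jsonlite::write_json(list(epsilon_true = sim$truth$epsilon_true,
                              background = sim$truth$background,
                              seed = sim$truth$seed),
                         file.path(out_dir, "truth_nandb.json"),
                         auto_unbox = TRUE, digits = NA)
    list(n_frames = dim(sim$stack)[3])
  } else stop("unknown simulate preset: ", preset)
}

.stage_foci <- function(cfg, out_dir) {
  .require_fields(cfg, c("input", "pixel_size_um", "quality"), "foci")
  stack <- read_stack(cfg$input, cfg$pixel_size_um,
                      cfg$frame_interval_s %||% 1)
  img <- max_project(stack)
  labels <- segment_cells(img, pixel_size_um = cfg$pixel_size_um,
                          smooth_width_um = cfg$smooth_um %||% 1.5,
                          background_sphere_um = cfg$bg_sphere_um %||% 1.0,
                          seed_diameter_um = cfg$seed_um %||% 2.0)
  foci <- detect_foci(img, labels, pixel_size_um = cfg$pixel_size_um,
                      spot_diameter_um = cfg$spot_um %||% 0.75,
                      quality_threshold = cfg$quality)
  cells <- per_cell_metrics(img, labels, foci,
                            pixel_size_um = cfg$pixel_size_um)
  utils::write.csv(cells, file.path(out_dir, "cells.csv"), row.names = FALSE)
  utils::write.csv(foci, file.path(out_dir, "foci.csv"), row.names = FALSE)
  if (nrow(cells) > 0) {
    s <- population_summary(cells)
    jsonlite::write_json(unclass(s), file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    list(n_cells = s$n_cells, mean_foci_per_cell = s$mean_foci_per_cell)
  } else list(n_cells = 0)
}

.stage_frap <- function(cfg, out_dir) {
  .require_fields(cfg, c("input", "area_um2"), "frap")
  paths <- cfg$input
  traces <- lapply(paths, function(pth) {
    df <- read_frap_csv(pth)
    normalize_trace(df$time_s, df$roi, df$background,
                    n_prebleach = cfg$n_prebleach %||% 50,
                    bleach_area_um2 = cfg$area_um2)
  })
  avg <- average_traces(traces)
  fit <- fit_recovery(avg, model = cfg$model %||% "mono",
                      beta = cfg$beta %||% 1,
                      bootstrap = cfg$bootstrap %||% 0)
  out <- unclass(fit)
  out$k_ci <- as.vector(t(fit$k_ci))
  jsonlite::write_json(out, file.path(out_dir, "frap_fit.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  list(model = fit$model, k = fit$k, D = fit$D)
}

.stage_nandb <- function(cfg, out_dir) {
  .require_fields(cfg, c("input", "pixel_size_um", "frame_interval_s"), "nandb")
  stack <- read_stack(cfg$input, cfg$pixel_size_um, cfg$frame_interval_s)
  mf <- motion_filter(stack, max_shift_px = cfg$max_shift %||% 1)
  if (!mf$pass) {
    stop(sprintf("stack rejected by motion filter: shift %.2f px", mf$shift_norm))
  }
  mom <- pixel_moments(stack)
  nbm <- nb_maps(mom$mean_map, mom$variance_map,
                 background = cfg$background %||% 0)
  for (nm in c("mean_map", "variance_map", "apparent_number",
               "apparent_brightness", "molecular_number",
               "molecular_brightness")) {
    m <- nbm[[nm]]
    m[is.na(m)] <- -1  # sentinel for invalid pixels in float output
    write_stack(file.path(out_dir, paste0(nm, ".tif")), m, format = "float32")
  }
  res <- list(n_valid = sum(nbm$valid_mask),
              mean_eps = mean(nbm$molecular_brightness[nbm$valid_mask]))
  if (!is.null(cfg$roi)) {
    rois <- get_frame(read_stack(cfg$roi, cfg$pixel_size_um,
                                 cfg$frame_interval_s), 1)
    st <- roi_stats(nbm, round(rois), reference_roi = cfg$reference %||% 1)
    utils::write.csv(st, file.path(out_dir, "roi_stats.csv"),
                     row.names = FALSE)
    res$n_rois <- nrow(st)
  }
  res
}

.stage_hydro <- function(cfg, out_dir) {
  .require_fields(cfg, c("monomer_mass", "measured_mass"), "hydro")
  olig <- oligomer_ratio(cfg$measured_mass, cfg$monomer_mass)
  vbar <- cfg$vbar %||% 0.73
  out <- list(oligomer = olig)
  if (!is.null(cfg$f_ratio)) {
    out$hydrodynamic_radius_nm <-
      hydrodynamic_radius(cfg$measured_mass, cfg$f_ratio, vbar)
  }
  if (!is.null(cfg$s_obs)) {
    .require_fields(cfg, c("buffer_viscosity", "buffer_density"), "hydro")
    out$s20w <- s20w_correct(cfg$s_obs, vbar,
                             cfg$buffer_viscosity, cfg$buffer_density)
  }
  if (!is.null(cfg$mass_ratio)) {
    out$size_scaling_factor <- size_scaling_factor(cfg$mass_ratio)
  }
  jsonlite::write_json(out, file.path(out_dir, "hydro.json"),
                       auto_unbox = TRUE, digits = NA)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run one or more pipeline stages
#'
#' Executes the stages named in \code{config$stages} (or the single
#' \code{config$stage}) in order, writing each stage's tables/maps and a
#' machine-readable JSON run report (package version, seed, parameters,
#' per-stage status). A stage failure is recorded with a FAILED marker and
#' the error message; earlier outputs are retained.
#'
#' @param config named list, see \code{\link{read_run_config}}.
#' @param out_dir output directory (created if absent).
#' @return the run report, invisibly; its \code{ok} field is FALSE if any
#'   stage failed.
#' @export
run_pipeline <- function(config, out_dir = config$out_dir %||% ".") {
  stages <- config$stages %||% config$stage
  if (is.null(stages) || length(stages) == 0) {
    stop("usage error: config must name at least one stage ",
         "(simulate, foci, frap, nandb, hydro)")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  runners <- list(simulate = .stage_simulate, foci = .stage_foci,
                  frap = .stage_frap, nandb = .stage_nandb,
                  hydro = .stage_hydro)
  report <- list(package = "halodyn",
                 version = as.character(utils::packageVersion("halodyn")),
                 seed = config$rng_seed %||% NA,
                 parameters = config, stages = list(), ok = TRUE)
  for (st in stages) {
    if (!st %in% names(runners)) stop("unknown stage: ", st)
    res <- tryCatch(
      list(status = "OK", result = runners[[st]](config, out_dir)),
      error = function(e) list(status = "FAILED",
                               error = conditionMessage(e)))
    report$stages[[st]] <- res
    if (res$status == "FAILED") report$ok <- FALSE
  }
  jsonlite::write_json(report, file.path(out_dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       force = TRUE)
  invisible(report)
}

# Parse "--flag value" pairs into a named list, with numeric coercion.
.parse_flags <- function(args) {
  out <- list()
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a)
    key <- gsub("-", "_", substring(a, 3))
    if (i == length(args) || startsWith(args[i + 1], "--")) {
      out[[key]] <- TRUE
      i <- i + 1
    } else {
      v <- args[i + 1]
      num <- suppressWarnings(as.numeric(v))
      out[[key]] <- if (!is.na(num)) num else v
      i <- i + 2
    }
  }
  out
}

#' Command-line entry point
#'
#' \code{halodyn <subcommand> [--config run.yaml] [--flag value ...]} where
#' subcommand is one of simulate, foci, frap, nandb, hydro. Flags override
#' config-file values; \code{--out-dir} sets the output directory.
#'
#' @param argv character vector of command-line arguments.
#' @return exit status (0 on success), invisibly.
#' @export
halodyn_main <- function(argv = commandArgs(trailingOnly = TRUE)) {
  if (length(argv) == 0) {
    message("usage: halodyn {simulate|foci|frap|nandb|hydro} [--config file] [--flags]")
    return(invisible(2L))
  }
  sub <- argv[1]
  flags <- .parse_flags(argv[-1])
  cfg_path <- flags$config
  flags$config <- NULL
  cfg <- read_run_config(cfg_path, overrides = flags)
  cfg$stage <- sub
  report <- tryCatch(run_pipeline(cfg, out_dir = cfg$out_dir %||% "."),
                     error = function(e) {
                       message("error: ", conditionMessage(e))
                       NULL
                     })
  if (is.null(report)) return(invisible(2L))
  invisible(if (report$ok) 0L else 1L)
}
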