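#' Default pipeline run configuration
#'
#' Parameter bundle for [run_pipeline()]: output directory, seed, stage
#' parameter lists (`scene`, `sensor` override the respective constructors),
#' segmentation method and optional fixed threshold, baseline environment
#' tag, CWSI method (with wet/dry references for the empirical method),
#' fused-map target dimensions, EWMA settings and cycle length.
#'
#' @param seed Integer seed recorded in every artifact.
#' @param out_dir Output directory for stage artifacts.
#' @return A run-configuration list.
#' @export
default_run_config <- function(seed = 1L, out_dir = "cwsimap-run") {
  list(
    seed = as.integer(seed),
    out_dir = out_dir,
    scene = list(),                 # overrides for scene_params()
    # 73 x 36 cells of 20 mm cover 1460 x 720 mm of the 1500 x 750 mm bench,
    # registering the fused thermal map to the image within one cell
    sensor = list(grid_nx = 73L, grid_ny = 36L),
    segmentation = list(method = "otsu", threshold = NULL),
    ltm_target_dims = c(620L, 1280L),
    nwsb = list(env_tag = "protected", days = 30, a = 2.54, b = -1.71,
                noise_sd = 0.3),
    cwsi = list(method = "nwsb", denominator = "range",
                t_wet = NULL, t_dry = NULL),
    monitor = list(days = 15, lambda = 0.2, L = 3, stress_gain = 3),
    stages = c("scene", "segment", "thermal", "nwsb", "cwsi", "monitor")
  )
}

pipeline_stages <- c("scene", "segment", "thermal", "nwsb", "cwsi", "monitor")

# Fail fast, naming the stage whose inputs are missing, before any work runs.
preflight_check <- function(config, stages) {
  bad <- setdiff(stages, pipeline_stages)
  if (length(bad))
    stop("unknown stage(s): ", paste(bad, collapse = ", "), call. = FALSE)
  if ("segment" %in% stages && !("scene" %in% stages))
    stop("pre-flight: stage `segment` needs stage `scene` in the same run",
         call. = FALSE)
  if ("thermal" %in% stages && !all(c("scene", "segment") %in% stages))
    stop("pre-flight: stage `thermal` needs stages `scene` and `segment`",
         call. = FALSE)
  if ("cwsi" %in% stages) {
    if (!("thermal" %in% stages))
      stop("pre-flight: stage `cwsi` needs stage `thermal`", call. = FALSE)
    if (identical(config$cwsi$method, "nwsb") && !("nwsb" %in% stages))
      stop("pre-flight: stage `cwsi` with method \"nwsb\" needs stage `nwsb` ",
           "(no baseline model available)", call. = FALSE)
    if (identical(config$cwsi$method, "empirical") &&
        (is.null(config$cwsi$t_wet) || is.null(config$cwsi$t_dry)))
      stop("pre-flight: stage `cwsi` with method \"empirical\" needs ",
           "`cwsi$t_wet` and `cwsi$t_dry` in the config", call. = FALSE)
  }
  invisible(TRUE)
}

# Proportionally rescale a column layout to a new raster width.
scale_layout <- function(layout, from_w, to_w) {
  bounds <- cumsum(vapply(layout, length, integer(1)))
  new_bounds <- round(bounds / from_w * to_w)
  starts <- c(1L, utils::head(new_bounds, -1) + 1L)
  stats::setNames(Map(function(s, e) seq.int(s, e), starts, new_bounds),
                  names(layout))
}

#' Run the water-stress detection pipeline
#'
#' Executes the staged workflow on a synthetic bench: scene generation,
#' ExG segmentation (scored against the ground-truth mask), infrared scan
#' and leaf-temperature-map fusion (validated against the true temperature
#' field), baseline parameterization, CWSI mapping with per-treatment
#' summaries, and EWMA cycle monitoring.  Every stage writes its artifacts
#' into `config$out_dir` and a manifest records the seed, the parameter
#' echo and the file list.  Reruns with the same configuration produce
#' identical artifacts.
#'
#' @param config A configuration list from [default_run_config()] or
#'   [read_run_config()].
#' @param stages Subset of stages to run, in pipeline order; dependencies
#'   are validated before anything runs.
#' @return The manifest list, invisibly; artifacts on disk under
#'   `config$out_dir`.
#' @export
run_pipeline <- function(config = default_run_config(),
                         stages = config$stages) {
  stages <- intersect(pipeline_stages, stages)
  preflight_check(config, stages)
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  seeds <- derive_seeds(config$seed, 6L)
  files <- character(0)
  done <- character(0)
  state <- new.env(parent = emptyenv())

  run_stage <- function(name, fun) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fun(), error = function(e)
      stop(sprintf("stage `%s` failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    message(sprintf("[cwsimap] stage %-8s done in %.2f s", name,
                    proc.time()[["elapsed"]] - t0))
    done <<- c(done, name)
    res
  }

  if ("scene" %in% stages) run_stage("scene", function() {
    params <- do.call(scene_params, config$scene)
    state$scene <- generate_canopy_scene(params, seed = seeds[[1]])
    files <<- c(files, write_scene(state$scene, out))
  })

  if ("segment" %in% stages) run_stage("segment", function() {
    sc <- state$scene
    exg <- excess_green(sc$rgb)
    t0 <- proc.time()[["elapsed"]]
    mask <- if (identical(config$segmentation$method, "fixed"))
      segment_exg(exg, "fixed", config$segmentation$threshold)
    else segment_exg(exg, "otsu")
    elapsed <- proc.time()[["elapsed"]] - t0
    met <- segmentation_metrics(confusion(mask, sc$truth_mask),
                                processing_time = elapsed)
    state$mask <- mask
    p1 <- file.path(out, "plant_mask.png")
    write_mask_png(mask, p1)
    p2 <- file.path(out, "segmentation_metrics.json")
    write_report_json(c(unclass(met),
                        list(threshold = attr(mask, "threshold"))), p2)
    files <<- c(files, p1, p2)
  })

  if ("thermal" %in% stages) run_stage("thermal", function() {
    sc <- state$scene
    spec <- do.call(sensor_spec, config$sensor)
    grid <- simulate_ir_scan(sc, spec, seed = seeds[[2]])
    state$grid <- grid
    target <- as.integer(config$ltm_target_dims)
    ltm <- build_ltm(grid, state$mask, target_dims = target)
    state$ltm <- ltm
    reference <- resize_bilinear(sc$true_temp, target)
    report <- validate_against_reference(ltm, reference)
    p1 <- file.path(out, "thermal_grid.csv"); write_thermal_grid(grid, p1)
    p23 <- write_ltm(ltm, file.path(out, "ltm.csv"), file.path(out, "ltm.png"))
    p4 <- file.path(out, "ltm_validation.json")
    write_report_json(list(general_mean_error = report$general_mean_error,
                           mean_standard_error = report$mean_standard_error,
                           mean_difference_c = report$mean_difference_c,
                           n = report$n, n_excluded = report$n_excluded), p4)
    files <<- c(files, p1, p23, p4)
  })

  if ("nwsb" %in% stages) run_stage("nwsb", function() {
    env <- generate_environment_series(days = config$nwsb$days,
                                       seed = seeds[[3]])
    obs <- generate_nwsb_observations(env, a = config$nwsb$a,
                                      b = config$nwsb$b,
                                      noise_sd = config$nwsb$noise_sd,
                                      seed = seeds[[4]])
    model <- fit_nwsb(obs$dt, obs$vpd, env_tag = config$nwsb$env_tag)
    state$model <- model
    p1 <- file.path(out, "environment.csv"); write_series_csv(env, p1)
    p2 <- file.path(out, "nwsb_observations.csv"); write_series_csv(obs, p2)
    p3 <- file.path(out, "nwsb_model.json")
    write_report_json(list(a = model$a, b = model$b, n = model$n,
                           se_a = model$se_a, se_b = model$se_b,
                           r_squared = model$r_squared,
                           env_tag = model$env_tag,
                           diagnostics = model$diagnostics), p3)
    files <<- c(files, p1, p2, p3)
  })

  if ("cwsi" %in% stages) run_stage("cwsi", function() {
    sc <- state$scene
    smap <- if (identical(config$cwsi$method, "empirical")) {
      refs <- reference_temperatures(config$cwsi$t_wet, config$cwsi$t_dry)
      stress_map(state$ltm, method = "empirical", refs = refs)
    } else {
      stress_map(state$ltm, method = "nwsb", model = state$model,
                 denominator = config$cwsi$denominator)
    }
    state$smap <- smap
    layout <- scale_layout(sc$treatment_layout, ncol(sc$truth_mask),
                           ncol(smap$cwsi))
    summ <- treatment_summary(smap, layout)
    p12 <- write_stress_map(smap, file.path(out, "stress_map.csv"),
                            file.path(out, "stress_map.png"))
    p3 <- file.path(out, "treatment_summary.csv")
    utils::write.csv(summ, p3, row.names = FALSE)
    files <<- c(files, p12, p3)
  })

  if ("monitor" %in% stages) run_stage("monitor", function() {
    cyc <- simulate_stress_cycle(days = config$monitor$days,
                                 model = state$model,
                                 stress_gain = config$monitor$stress_gain,
                                 seed = seeds[[6]])
    cw <- data.frame(day = cyc$daily$day, treatment = cyc$daily$treatment,
                     value = cyc$daily$cwsi)
    vw <- data.frame(day = cyc$daily$day, treatment = cyc$daily$treatment,
                     value = cyc$daily$vwc)
    rep <- joint_cycle_report(cw, vw, lambda = config$monitor$lambda,
                              L = config$monitor$L)
    p1 <- file.path(out, "cycle_daily.csv")
    utils::write.csv(cyc$daily, p1, row.names = FALSE)
    p2 <- file.path(out, "moisture_readings.csv")
    write_series_csv(cyc$moisture$readings, p2)
    p3 <- file.path(out, "irrigation_events.csv")
    write_series_csv(cyc$moisture$events, p3)
    charts <- lapply(rep$charts, function(ch)
      list(z = ch$z, ucl = ch$ucl, lcl = ch$lcl, center = ch$center,
           sigma = ch$sigma, lambda = ch$lambda, L = ch$L,
           violations = ch$violations))
    p4 <- file.path(out, "ewma_charts.json")
    write_report_json(list(charts = charts,
                           correlations = rep$correlations,
                           stable = rep$stable), p4)
    files <<- c(files, p1, p2, p3, p4)
  })

  manifest <- list(package = "cwsimap",
                   version = as.character(utils::packageVersion("cwsimap")),
                   seed = config$seed,
                   stages = done,
                   files = basename(unname(files)),
                   config = config[setdiff(names(config), "out_dir")])
  write_report_json(manifest, file.path(out, "manifest.json"))
  invisible(manifest)
}
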