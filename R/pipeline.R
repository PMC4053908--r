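# Pipeline orchestration: simulate -> route -> classify -> ratios -> expose
# -> compare, with every inter-stage hand-off going through the on-disk
# formats so a stage can be rerun from files alone.

#' Pipeline configuration
#'
#' @param scenario a [scenario_config()] describing the synthetic world.
#' @param out_dir output directory (created if missing).
#' @param seed run seed; overrides the scenario seed so one flag controls
#'   all randomness.
#' @param n_perm permutations for the Fisher-Pitman test in the compare
#'   stage.
#' @param stages subset of the six stage names to execute, in pipeline
#'   order.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(scenario = scenario_config(),
                            out_dir = tempfile("no2commute_run_"),
                            seed = NULL, n_perm = 999,
                            stages = c("simulate", "route", "classify",
                                       "ratios", "expose", "compare")) {
  if (!is.null(seed)) scenario$seed <- as.integer(seed)
  structure(list(scenario = scenario, out_dir = out_dir,
                 seed = scenario$seed, n_perm = n_perm, stages = stages),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a JSON or YAML file
#'
#' Recognised top-level keys: any [scenario_config()] argument, plus
#' `out_dir`, `seed`, `n_perm`, `stages`. `diurnal_profile` may be a mapping
#' with `main` and `side` lists.
#'
#' @param path config file ending in .json, .yaml or .yml.
#' @param out_dir optional override of the configured output directory.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path, out_dir = NULL) {
  abort_if(!file.exists(path), paste("config file not found:", path))
  cfg <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configs requires the yaml package", call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  sc_args <- cfg[intersect(names(cfg), names(formals(scenario_config)))]
  if (!is.null(sc_args$mode_shares)) {
    sc_args$mode_shares <- unlist(sc_args$mode_shares)
  }
  if (!is.null(sc_args$diurnal_profile)) {
    sc_args$diurnal_profile <- lapply(sc_args$diurnal_profile, unlist)
  }
  scenario <- do.call(scenario_config, sc_args)
  pipeline_config(
    scenario = scenario,
    out_dir = out_dir %||% cfg$out_dir %||% tempfile("no2commute_run_"),
    seed = cfg$seed, n_perm = cfg$n_perm %||% 999,
    stages = cfg$stages %||% c("simulate", "route", "classify", "ratios",
                               "expose", "compare"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Rebuild minimal subjects from a parsed legs GeoJSON
#'
#' Groups legs and waits by subject and trip index; enough structure for the
#' exposure engine (geometry, mode, class, clock time, duration).
#' @param parsed result of [read_legs_geojson()].
#' @return list of subject-like lists.
#' @export
subjects_from_legs <- function(parsed) {
  ids <- sort(unique(vapply(parsed$legs, `[[`, numeric(1), "subject_id")))
  lapply(ids, function(sid) {
    legs <- Filter(function(l) l$subject_id == sid, parsed$legs)
    waits <- Filter(function(w) w$subject_id == sid, parsed$waits)
    trips_idx <- sort(unique(vapply(legs, `[[`, numeric(1), "trip")))
    trips <- lapply(trips_idx, function(ti) {
      tl <- Filter(function(l) l$trip == ti, legs)
      tw <- Filter(function(w) w$trip == ti, waits)
      dir <- tl[[1L]]$direction %||% "out"
      list(direction = dir, start_min = tl[[1L]]$start_min,
           legs = tl, waits = tw)
    })
    make_subject(id = sid, home = NA_integer_, work = NA_integer_,
                 home_xy = c(NA, NA), work_xy = c(NA, NA), trips = trips)
  })
}

#' Run the full simulation and comparison pipeline
#'
#' Executes, in order: `simulate` (network, rasters, station series,
#' population), `route` (trip completion, inclusion filters, legs GeoJSON),
#' `classify` (main/side per leg and wait), `ratios` (temporal adjustment
#' factors from the station CSV), `expose` (per-subject and per-leg exposure
#' from the classified legs, ratio CSV and grid files) and `compare`
#' (pairwise model statistics). All randomness derives from the single run
#' seed; two runs with the same seed produce byte-identical outputs. Any
#' stage failure aborts with the stage name and cause.
#'
#' @param config a [pipeline_config()].
#' @return list with `status` (0 on success), `out_dir`, `outputs` (file
#'   paths) and `manifest` (path to the JSON manifest).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$out_dir, ...)
  sc <- config$scenario
  env <- new.env(parent = emptyenv())
  outputs <- character(0)

  stage <- function(name, fun) {
    if (!name %in% config$stages) return(invisible(NULL))
    tryCatch(fun(), error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  stage("simulate", function() {
    env$network <- generate_network(sc)
    env$grids <- generate_rasters(sc, env$network)
    env$stations <- generate_station_series(sc)
    env$population <- generate_population(sc, env$network)
    write_network_geojson(env$network, out("network.geojson"))
    grid_files <- vapply(env$grids, function(g) {
      f <- out(sprintf("grid_%s.asc", g$model_name))
      write_ascii_grid(g, f)
      f
    }, character(1))
    write_station_csv(env$stations, out("stations.csv"), seed = sc$seed)
    truth <- list(
      seed = sc$seed,
      background_level = sc$background_level,
      road_increment = sc$road_increment,
      decay_length = sc$decay_length,
      model_bias = as.list(stats::setNames(sc$model_bias,
                                           names(env$grids))),
      true_ratio_main = sc$diurnal_profile$main /
        mean(sc$diurnal_profile$main),
      true_ratio_side = sc$diurnal_profile$side /
        mean(sc$diurnal_profile$side))
    jsonlite::write_json(truth, out("ground_truth.json"), auto_unbox = TRUE,
                         digits = NA)
    outputs <<- c(outputs, out("network.geojson"), grid_files,
                  out("stations.csv"), out("ground_truth.json"))
  })

  stage("route", function() {
    pop <- lapply(env$population, complete_trips)
    flt <- filter_subjects(pop, sc$domain_extent)
    env$subjects <- flt$subjects
    write_legs_geojson(env$subjects, out("legs.geojson"))
    routed <- vapply(env$subjects, function(s) {
      sum(vapply(s$trips[[1L]]$legs, `[[`, numeric(1), "length_m"))
    }, numeric(1))
    reported <- vapply(env$subjects, `[[`, numeric(1), "reported_distance_m")
    summ <- list(n_subjects = length(env$subjects),
                 rejections = as.list(flt$rejections),
                 distance_r_squared = if (length(routed) >= 3 &&
                                          stats::var(reported) > 0) {
                   distance_agreement(reported, routed)
                 } else NA)
    jsonlite::write_json(summ, out("route_summary.json"), auto_unbox = TRUE,
                         digits = NA)
    outputs <<- c(outputs, out("legs.geojson"), out("route_summary.json"))
  })

  stage("classify", function() {
    network <- read_network_geojson(out("network.geojson"))
    env$subjects <- classify_population(env$subjects, network)
    write_legs_geojson(env$subjects, out("legs_classified.geojson"))
    outputs <<- c(outputs, out("legs_classified.geojson"))
  })

  stage("ratios", function() {
    stations <- read_station_csv(out("stations.csv"))
    rt <- compute_hourly_ratios(stations$street, stations$background)
    write_ratio_csv(rt, out("ratios.csv"), seed = sc$seed)
    outputs <<- c(outputs, out("ratios.csv"))
  })

  stage("expose", function() {
    grid_files <- Sys.glob(out("grid_*.asc"))
    abort_if(length(grid_files) == 0L, "no grid files found")
    grids <- lapply(grid_files, function(f) {
      read_ascii_grid(f, model_name = sub("^grid_", "",
                                          sub("\\.asc$", "", basename(f))))
    })
    ratios <- read_ratio_csv(out("ratios.csv"))
    subjects <- subjects_from_legs(
      read_legs_geojson(out("legs_classified.geojson")))
    expo <- compute_exposure(subjects, ratios, grids)
    legs <- compute_leg_exposure(subjects, ratios, grids)
    write_csv_stamped(expo, out("exposure.csv"), seed = sc$seed)
    write_csv_stamped(legs, out("leg_exposure.csv"), seed = sc$seed)
    outputs <<- c(outputs, out("exposure.csv"), out("leg_exposure.csv"))
  })

  stage("compare", function() {
    expo <- read_csv_stamped(out("exposure.csv"))
    cmp <- compare_models(expo, n_perm = config$n_perm, seed = sc$seed)
    write_csv_stamped(as.data.frame(cmp), out("comparison.csv"),
                      seed = sc$seed)
    outputs <<- c(outputs, out("comparison.csv"))
  })

  manifest <- out("manifest.json")
  write_manifest(manifest, seed = sc$seed, files = outputs,
                 extra = list(stages = config$stages))
  list(status = 0L, out_dir = config$out_dir, outputs = outputs,
       manifest = manifest)
}
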