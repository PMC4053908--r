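#' Scenario configuration for the synthetic commuter-exposure world
#'
#' Bundles every tunable parameter of the synthetic data generator: the spatial
#' domain, the raster resolutions of the emulated air pollution models, the
#' latent NO2 concentration field (suburban background level plus an
#' exponentially decaying road-proximity increment), the commuter population,
#' and the diurnal profiles driving the monitoring-station time series.
#'
#' Defaults follow the study setting the generator emulates: a 23.5 ug/m3
#' annual-mean suburban background, model grids of 25, 50 and 100 m, a
#' commuter sample of 258 subjects, and main travel mode shares of roughly
#' 27% walking, 30% bicycle, 9% motorized and 32% public transport
#' (renormalised over the four modelled modes).
#'
#' @param domain_extent numeric rectangle `c(xmin, ymin, xmax, ymax)` in
#'   metres. Both side lengths must be multiples of every grid size.
#' @param grid_sizes raster cell sizes in metres, one emulated model per size.
#' @param background_level annual-mean background NO2, ug/m3.
#' @param road_increment additional NO2 at a main-road centreline, ug/m3.
#' @param side_increment_factor fraction of `road_increment` applying at
#'   side-street centrelines (side streets carry less traffic, so their
#'   proximity increment is smaller; this contrast is what a high-resolution
#'   raster resolves and a coarse one averages away).
#' @param decay_length e-folding distance of the road increment, metres.
#' @param n_subjects number of commuters to generate.
#' @param mode_shares named fractions per travel mode
#'   (walking, bicycle, motorized, public); must sum to 1.
#' @param diurnal_profile list with elements `main` and `side`, each 24
#'   dimensionless hour-of-day multipliers (hour 0 first). Need not average
#'   to 1; ratios are normalised by the weekday mean when derived.
#' @param noise_sd Gaussian noise SD of the 30-min station values, ug/m3.
#' @param seed integer seed making every generated artefact reproducible.
#' @param n_blocks number of street blocks per axis of the synthetic grid
#'   network.
#' @param p_side probability that a given grid line is a side street (0 gives
#'   an all-main network).
#' @param model_bias additive per-model offset in ug/m3, recycled to one value
#'   per grid size; zero keeps resolution the only inter-model difference.
#' @param n_weekdays number of weekdays in the station series (a working year
#'   has about 261).
#' @param uneven_fraction fraction of subjects reporting an uneven trip count
#'   (one direction missing); these are completed later by trip duplication.
#' @param quad_step quadrature step in metres for cell-averaging the latent
#'   field; must divide every grid size so that coarse cells are exact means
#'   of the fine cells they contain.
#'
#' @return an object of class `scenario_config` (a validated list).
#' @export
#' @examples
#' cfg <- scenario_config(n_subjects = 20, seed = 1)
#' cfg$grid_sizes
scenario_config <- function(domain_extent = c(0, 0, 1200, 1200),
                            grid_sizes = c(25, 50, 100),
                            background_level = 23.5,
                            road_increment = 30,
                            side_increment_factor = 0.5,
                            decay_length = 60,
                            n_subjects = 258,
                            mode_shares = c(walking = 27, bicycle = 30,
                                            motorized = 9, public = 32) / 98,
                            diurnal_profile = default_diurnal_profile(),
                            noise_sd = 2.35,
                            seed = 1L,
                            n_blocks = 6L,
                            p_side = 0.5,
                            model_bias = 0,
                            n_weekdays = 261L,
                            uneven_fraction = 0,
                            quad_step = 5) {
  stopifnot(is.numeric(domain_extent), length(domain_extent) == 4L)
  width <- domain_extent[3L] - domain_extent[1L]
  height <- domain_extent[4L] - domain_extent[2L]
  if (width <= 0 || height <= 0) {
    stop("domain_extent is degenerate: xmax/ymax must exceed xmin/ymin",
         call. = FALSE)
  }
  if (any(grid_sizes <= 0)) stop("grid_sizes must be strictly positive",
                                 call. = FALSE)
  for (g in grid_sizes) {
    if (abs(width / g - round(width / g)) > 1e-9 ||
        abs(height / g - round(height / g)) > 1e-9) {
      stop(sprintf("grid size %g does not divide the domain extent %g x %g",
                   g, width, height), call. = FALSE)
    }
    if (abs(g / quad_step - round(g / quad_step)) > 1e-9) {
      stop(sprintf("quad_step %g must divide grid size %g", quad_step, g),
           call. = FALSE)
    }
  }
  if (background_level <= 0) stop("background_level must be > 0", call. = FALSE)
  if (road_increment < 0) stop("road_increment must be >= 0", call. = FALSE)
  if (side_increment_factor < 0 || side_increment_factor > 1) {
    stop("side_increment_factor must lie in [0, 1]", call. = FALSE)
  }
  if (decay_length <= 0) stop("decay_length must be > 0", call. = FALSE)
  if (n_subjects < 1) stop("n_subjects must be >= 1", call. = FALSE)
  modes <- c("walking", "bicycle", "motorized", "public")
  if (!all(modes %in% names(mode_shares))) {
    stop("mode_shares must name walking, bicycle, motorized and public",
         call. = FALSE)
  }
  mode_shares <- mode_shares[modes]
  if (any(mode_shares < 0) || abs(sum(mode_shares) - 1) > 1e-9) {
    stop("mode_shares must be non-negative and sum to 1 (tolerance 1e-9)",
         call. = FALSE)
  }
  if (!is.list(diurnal_profile) ||
      !all(c("main", "side") %in% names(diurnal_profile)) ||
      length(diurnal_profile$main) != 24L ||
      length(diurnal_profile$side) != 24L) {
    stop("diurnal_profile must list 24 multipliers for both main and side",
         call. = FALSE)
  }
  if (any(unlist(diurnal_profile) <= 0)) {
    stop("diurnal_profile multipliers must be strictly positive", call. = FALSE)
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (n_blocks < 1) stop("n_blocks must be >= 1", call. = FALSE)
  if (p_side < 0 || p_side > 1) stop("p_side must lie in [0, 1]", call. = FALSE)
  if (uneven_fraction < 0 || uneven_fraction > 1) {
    stop("uneven_fraction must lie in [0, 1]", call. = FALSE)
  }
  model_bias <- rep_len(as.numeric(model_bias), length(grid_sizes))

  structure(list(
    domain_extent = as.numeric(domain_extent),
    grid_sizes = as.numeric(grid_sizes),
    background_level = background_level,
    road_increment = road_increment,
    side_increment_factor = side_increment_factor,
    decay_length = decay_length,
    n_subjects = as.integer(n_subjects),
    mode_shares = mode_shares,
    diurnal_profile = lapply(diurnal_profile[c("main", "side")], as.numeric),
    noise_sd = noise_sd,
    seed = as.integer(seed),
    n_blocks = as.integer(n_blocks),
    p_side = p_side,
    model_bias = model_bias,
    n_weekdays = as.integer(n_weekdays),
    uneven_fraction = uneven_fraction,
    quad_step = quad_step
  ), class = "scenario_config")
}

#' Default weekday diurnal NO2 profiles by road class
#'
#' Hour-of-day multipliers with a morning (7-9) and late-afternoon (17-19)
#' rush-hour peak and a night-time trough; the street (main) profile is more
#' peaked than the urban background (side) profile, mirroring the stronger
#' traffic signal at kerbside monitors.
#'
#' @return list with numeric elements `main` and `side`, 24 values each.
#' @export
default_diurnal_profile <- function() {
  list(
    main = c(0.65, 0.60, 0.58, 0.60, 0.70, 0.90, 1.20, 1.45, 1.40, 1.20,
             1.05, 1.00, 1.00, 1.00, 1.05, 1.15, 1.30, 1.45, 1.40, 1.20,
             1.05, 0.95, 0.85, 0.72),
    side = c(0.78, 0.74, 0.72, 0.74, 0.80, 0.92, 1.08, 1.24, 1.20, 1.10,
             1.02, 1.00, 1.00, 1.00, 1.02, 1.08, 1.16, 1.26, 1.22, 1.12,
             1.02, 0.95, 0.88, 0.81)
  )
}

#' @export
print.scenario_config <- function(x, ...) {
  ext <- x$domain_extent
  cat("<scenario_config>\n")
  cat(sprintf("  domain: [%g, %g] x [%g, %g] m\n", ext[1], ext[3], ext[2], ext[4]))
  cat(sprintf("  grids: %s m; background %g ug/m3; road increment %g ug/m3\n",
              paste(x$grid_sizes, collapse = "/"), x$background_level,
              x$road_increment))
  cat(sprintf("  subjects: %d; seed %d\n", x$n_subjects, x$seed))
  invisible(x)
}
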