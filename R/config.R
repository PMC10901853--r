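# Run configuration: a single YAML document holding the world generator,
# forcings and every module parameter block, fully resolvable so a run is
# replayable from its emitted config.

#' Default run configuration
#'
#' The complete nested configuration with every default. Unknown keys in a
#' user file are rejected against this structure; an annotated template
#' ships at `system.file("extdata", "demo_config.yml", package =
#' "vegcarb")`.
#'
#' @return Nested named list.
#' @export
default_run_config <- function() {
  list(
    world = list(
      generator = "supercontinent",  # supercontinent | dispersed | file
      n_lat = 40, n_lon = 48,
      land_fraction = 0.3, center_lat = 0, n_blocks = 4,
      seed = 1, basalt_fraction = 0.2,
      path = NULL),
    forcing = list(time_Ma = 0, o2_mixing_ratio = 0.21,
                   degassing_rel = 1.0),
    photosynthesis = list(npp_max = 3200, a = 0.015, h = 12,
                          k_co2 = 0.5, o2_sensitivity = 0.3,
                          runoff_half = 30),
    weathering = list(npp_slope = 5e-4, f_minbiota = 0.32, r = 0.25,
                      act_energy_granite = 63000,
                      act_energy_basalt = 50000),
    climate = list(t_eq = 27, dt_pole = 45, interior_cooling = 0.8,
                   interior_cooling_max = 8, interior_efold = 3,
                   d_arid = 6, runoff_floor = 20, hydro_sens = 0.03,
                   polar_amp_max = 2),
    coupler = list(dt_init = 1e5, dt_min = 1e3, dt_max = 1e6,
                   step_shrink = 0.5, step_grow = 1.2,
                   stab_threshold = 0.02, steady_tol = 1e-3,
                   max_steps = 400, co2_bounds = c(0.05, 20),
                   climate_sensitivity = 5, t_ref = 14,
                   seed_biomass = 2.5e4, veg_tol = 0.01),
    ensemble = list(n_members = 5, degassing_range = c(0.75, 1.25),
                    lithology_shift = c(-0.2, 0.2), rng_seed = 1),
    compare = list(world_b = NULL),
    output_dir = "vegcarb_out",
    rng_seed = 1,
    verbosity = 1)
}

check_unknown_keys <- function(cfg, ref, path = "") {
  if (!is.list(cfg)) return(invisible(NULL))
  for (nm in names(cfg)) {
    here <- if (path == "") nm else paste0(path, ".", nm)
    if (!nm %in% names(ref))
      stop("unknown configuration key `", here, "`", call. = FALSE)
    if (is.list(ref[[nm]]) && !is.null(names(ref[[nm]])))
      check_unknown_keys(cfg[[nm]], ref[[nm]], here)
  }
  invisible(NULL)
}

merge_config <- function(defaults, cfg) {
  for (nm in names(cfg)) {
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]])) &&
        is.list(cfg[[nm]])) {
      defaults[[nm]] <- merge_config(defaults[[nm]], cfg[[nm]])
    } else {
      defaults[[nm]] <- cfg[[nm]]
    }
  }
  defaults
}

#' Read, validate and resolve a run configuration
#'
#' Parses a YAML configuration, rejects unknown keys (with the dotted path
#' of the offending key), merges the defaults, and eagerly constructs
#' every parameter block so that invalid values (for example a negative
#' `runoff_half`) fail here, before any computation.
#'
#' @param path YAML file path.
#' @return The resolved configuration list, with the constructed parameter
#'   objects attached as attribute `"built"`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("config must be a YAML mapping", call. = FALSE)
  defaults <- default_run_config()
  ref <- defaults
  ref$compare$world_b <- defaults$world   # world_b shares the world schema
  check_unknown_keys(cfg, ref)
  resolved <- merge_config(defaults, cfg)
  if (!is.null(resolved$compare$world_b))
    resolved$compare$world_b <- merge_config(defaults$world,
                                             resolved$compare$world_b)
  attr(resolved, "built") <- build_from_config(resolved)
  resolved
}

build_params_from_config <- function(cfg) {
  photo <- do.call(photosynthesis_params, cfg$photosynthesis)
  weath <- do.call(weathering_params, cfg$weathering)
  climate <- do.call(climate_params, cfg$climate)
  default_params(photo = photo, weathering = weath, climate = climate)
}

build_coupler_from_config <- function(cfg) {
  cc <- cfg$coupler
  coupler_config(dt_init = cc$dt_init, dt_min = cc$dt_min,
                 dt_max = cc$dt_max, step_shrink = cc$step_shrink,
                 step_grow = cc$step_grow,
                 stab_threshold = cc$stab_threshold,
                 steady_tol = cc$steady_tol, max_steps = cc$max_steps,
                 co2_bounds = unlist(cc$co2_bounds),
                 climate_sensitivity = cc$climate_sensitivity,
                 t_ref = cc$t_ref, seed_biomass = cc$seed_biomass,
                 veg_tol = cc$veg_tol)
}

build_world_from_config <- function(wcfg) {
  gen <- match.arg(wcfg$generator, c("supercontinent", "dispersed", "file"))
  if (gen == "file") {
    if (is.null(wcfg$path))
      stop("world.generator = file requires world.path", call. = FALSE)
    return(load_climate(wcfg$path)$grid)
  }
  grid <- make_grid(wcfg$n_lat, wcfg$n_lon)
  if (gen == "supercontinent") {
    make_supercontinent(grid, wcfg$land_fraction, wcfg$center_lat,
                        seed = wcfg$seed,
                        basalt_fraction = wcfg$basalt_fraction)
  } else {
    make_dispersed(grid, wcfg$land_fraction, wcfg$n_blocks,
                   seed = wcfg$seed,
                   basalt_fraction = wcfg$basalt_fraction)
  }
}

build_from_config <- function(cfg) {
  list(params = build_params_from_config(cfg),
       config = build_coupler_from_config(cfg),
       forcing = do.call(forcing_state, cfg$forcing),
       world = build_world_from_config(cfg$world))
}
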