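#' Photosynthesis parameters for the vegetation kernel
#'
#' Collects the scalar constants of the multiplicative-limitation
#' productivity kernel: the productivity ceiling, the leaf-respiration
#' coefficients, and the half-saturation constants of the CO2 and water
#' responses. The leaf-respiration rate `s` is derived from the daylight
#' hours `h` and the coefficient `a` as `s = (24/h) * a`, so with the
#' default 12 h day and `a = 0.015`, `s = 0.03`.
#'
#' @param npp_max Productivity ceiling, gC m^-2 yr^-1. The default 3200 is
#'   the value at which the biotic weathering enhancement reaches exactly
#'   six times its bare-ground value at present-day CO2.
#' @param a Dimensionless leaf-respiration coefficient.
#' @param h Daylight hours used for the respiration scaling; the model
#'   assumes a seasonless 12 h day at all latitudes.
#' @param k_co2 CO2 half-saturation of the productivity response, in units
#'   of relative CO2; the response is normalised to 1 at `rco2 = 1`.
#' @param o2_sensitivity Slope of the photorespiration penalty per unit
#'   relative deviation of the O2 mixing ratio from 0.21.
#' @param runoff_half Runoff half-saturation of the water limitation,
#'   mm yr^-1.
#' @return An object of class `photosynthesis_params`.
#' @seealso [leaf_respiration_rate()], [npp_cell()]
#' @export
#' @examples
#' p <- photosynthesis_params()
#' p$s  # 0.03
photosynthesis_params <- function(npp_max = 3200, a = 0.015, h = 12,
                                  k_co2 = 0.5, o2_sensitivity = 0.3,
                                  runoff_half = 30) {
  if (!is.numeric(npp_max) || npp_max <= 0)
    stop("`npp_max` must be a positive number", call. = FALSE)
  if (!is.numeric(runoff_half) || runoff_half <= 0)
    stop("`runoff_half` must be a positive number", call. = FALSE)
  if (!is.numeric(k_co2) || k_co2 <= 0)
    stop("`k_co2` must be a positive number", call. = FALSE)
  structure(
    list(npp_max = npp_max, a = a, h = h,
         s = leaf_respiration_rate(h, a),
         k_co2 = k_co2, o2_sensitivity = o2_sensitivity,
         runoff_half = runoff_half),
    class = "photosynthesis_params")
}

#' Temperature-response parameters of one plant functional type
#'
#' Each functional type responds to annual-mean temperature through a
#' trapezoidal ramp: zero at or below `t_min`, rising linearly to 1 at
#' `t_opt_lo`, flat across the optimum plateau, falling to zero at `t_max`.
#'
#' @param name One of `"tropical"`, `"temperate"`, `"boreal"`.
#' @param t_min,t_opt_lo,t_opt_hi,t_max Ramp thresholds in degrees C,
#'   strictly ordered `t_min < t_opt_lo <= t_opt_hi < t_max`.
#' @return An object of class `pft_params`.
#' @export
pft_params <- function(name, t_min, t_opt_lo, t_opt_hi, t_max) {
  name <- match.arg(name, c("tropical", "temperate", "boreal"))
  if (!(t_min < t_opt_lo && t_opt_lo <= t_opt_hi && t_opt_hi < t_max))
    stop("PFT thresholds must satisfy t_min < t_opt_lo <= t_opt_hi < t_max",
         call. = FALSE)
  structure(list(name = name, t_min = t_min, t_opt_lo = t_opt_lo,
                 t_opt_hi = t_opt_hi, t_max = t_max),
            class = "pft_params")
}

#' Default tropical, temperate and boreal functional types
#'
#' Temperature ramps follow the LPJ-heritage bioclimatic limits commonly
#' used for broad functional types. The list order (tropical, temperate,
#' boreal) is also the tie-breaking priority when types produce equal NPP.
#'
#' @return Named list of three [pft_params()] objects.
#' @export
default_pfts <- function() {
  list(
    tropical  = pft_params("tropical",   2, 25, 30, 55),
    temperate = pft_params("temperate", -4, 15, 25, 38),
    boreal    = pft_params("boreal",    -4, 10, 25, 38)
  )
}

#' Weathering and burial parameters
#'
#' Constants of the biotic weathering enhancement and of the per-cell
#' silicate/carbonate weathering kinetics. The enhancement factor applied
#' to every land cell is `npp_slope * NPP + f_minbiota * rco2^r`, so a bare
#' cell retains the abiotic pH-driven term `f_minbiota * rco2^r`.
#'
#' The kinetic rate constants `k_sil_granite`, `k_sil_basalt`, `k_carb`,
#' `k_locb` and `k_mocb` are placeholders until [calibrate_reference()]
#' rescales them so that a chosen reference world at relative CO2 of 1
#' balances the reference degassing flux; only their ratios (e.g. basalt
#' weathering twice as fast as granite at the reference temperature) carry
#' meaning before calibration.
#'
#' @param npp_slope Slope of the enhancement in NPP, (gC m^-2 yr^-1)^-1.
#' @param f_minbiota Abiotic minimum enhancement at `rco2 = 1`.
#' @param r Exponent of the abiotic CO2 dependence, in \[0.25, 0.5\];
#'   0.25 is the conservative choice.
#' @param k_sil_granite,k_sil_basalt Silicate rate constants per lithology
#'   (mol C yr^-1 per m^2 per mm yr^-1 of runoff, before calibration).
#' @param act_energy_granite,act_energy_basalt Arrhenius activation
#'   energies, J mol^-1.
#' @param k_carb Carbonate rate constant (same kinetic units).
#' @param k_locb Land organic-carbon burial flux at unit relative
#'   vegetation, mol C yr^-1.
#' @param k_mocb Marine organic-carbon burial flux, mol C yr^-1 (held
#'   constant).
#' @return An object of class `weathering_params`.
#' @export
#' @examples
#' biotic_enhancement(0, 1, weathering_params())   # 0.32
weathering_params <- function(npp_slope = 5e-4, f_minbiota = 0.32, r = 0.25,
                              k_sil_granite = 1e-9, k_sil_basalt = 2e-9,
                              act_energy_granite = 63000,
                              act_energy_basalt = 50000,
                              k_carb = 1e-9,
                              k_locb = 8e11, k_mocb = 8e11) {
  if (npp_slope <= 0) stop("`npp_slope` must be positive", call. = FALSE)
  if (f_minbiota <= 0 || f_minbiota >= 1)
    stop("`f_minbiota` must be in (0, 1)", call. = FALSE)
  if (r < 0.25 || r > 0.5)
    stop("`r` must lie in [0.25, 0.5]", call. = FALSE)
  ks <- c(k_sil_granite, k_sil_basalt, k_carb, k_locb, k_mocb)
  if (any(!is.finite(ks)) || any(ks <= 0))
    stop("all rate constants must be positive", call. = FALSE)
  structure(
    list(npp_slope = npp_slope, f_minbiota = f_minbiota, r = r,
         k_sil_granite = k_sil_granite, k_sil_basalt = k_sil_basalt,
         act_energy_granite = act_energy_granite,
         act_energy_basalt = act_energy_basalt,
         k_carb = k_carb, k_locb = k_locb, k_mocb = k_mocb),
    class = "weathering_params")
}

#' Shape constants of the synthetic climate generator
#'
#' All tunables of [synth_climate()] in one place: the zonal temperature
#' profile, the continental-interior cooling, the zonal runoff profile with
#' its subtropical dry belts, the coastal-moisture decay, and the response
#' of the hydrological cycle and high latitudes to a global temperature
#' offset.
#'
#' @param t_eq Equatorial annual-mean temperature at zero offset, degrees C.
#' @param dt_pole Equator-to-pole temperature drop (applied as
#'   `dt_pole * sin(lat)^2`), degrees C.
#' @param interior_cooling Continentality cooling per cell of
#'   distance-to-coast beyond the coast itself, degrees C per cell.
#' @param interior_cooling_max Cap on the continentality cooling, degrees C.
#' @param runoff_lat_knots,runoff_knot_values Knots (absolute latitude,
#'   degrees) and values (mm yr^-1) of the piecewise-linear zonal runoff
#'   profile: a wet equatorial band, dry subtropical belts near 15-35
#'   degrees, a wet mid-latitude band, dry poles.
#' @param interior_efold E-folding distance (cells) of the exponential decay
#'   of runoff with distance to coast.
#' @param d_arid Distance-to-coast (cells) at and beyond which moisture
#'   transport fails entirely and runoff is zero: the arid interior belt.
#' @param runoff_floor Runoff below this value (mm yr^-1) is treated as
#'   zero (effectively arid).
#' @param hydro_sens Fractional change of runoff per degree C of global
#'   temperature offset (warming-enhanced hydrology).
#' @param polar_amp_max Amplification of the global offset at the poles;
#'   amplification rises linearly from 1 at the equator to this value.
#' @return An object of class `climate_params`.
#' @export
climate_params <- function(t_eq = 27, dt_pole = 45,
                           interior_cooling = 0.8, interior_cooling_max = 8,
                           runoff_lat_knots = c(0, 12, 20, 30, 45, 60, 90),
                           runoff_knot_values = c(1500, 900, 150, 150, 700,
                                                  450, 100),
                           interior_efold = 3, d_arid = 6,
                           runoff_floor = 20, hydro_sens = 0.03,
                           polar_amp_max = 2) {
  if (length(runoff_lat_knots) != length(runoff_knot_values))
    stop("runoff knot vectors must have equal length", call. = FALSE)
  if (is.unsorted(runoff_lat_knots, strictly = TRUE))
    stop("`runoff_lat_knots` must be strictly increasing", call. = FALSE)
  if (any(runoff_knot_values < 0))
    stop("runoff knot values must be non-negative", call. = FALSE)
  if (interior_efold <= 0 || d_arid < 2)
    stop("`interior_efold` must be positive and `d_arid` >= 2",
         call. = FALSE)
  structure(
    list(t_eq = t_eq, dt_pole = dt_pole,
         interior_cooling = interior_cooling,
         interior_cooling_max = interior_cooling_max,
         runoff_lat_knots = runoff_lat_knots,
         runoff_knot_values = runoff_knot_values,
         interior_efold = interior_efold, d_arid = d_arid,
         runoff_floor = runoff_floor, hydro_sens = hydro_sens,
         polar_amp_max = polar_amp_max),
    class = "climate_params")
}

#' Coupler and carbon-reservoir configuration
#'
#' Settings of the adaptive explicit integration of the lumped
#' atmosphere-ocean carbon reservoir and of the CO2-to-climate mapping.
#'
#' @param dt_init Initial timestep, yr (default 1e5, i.e. ~100 kyr).
#' @param dt_min,dt_max Bounds on the adaptive timestep, yr.
#' @param step_shrink Factor applied to `dt` when a step is rejected.
#' @param step_grow Factor applied to `dt` after an accepted step.
#' @param stab_threshold Maximum accepted relative change of relative CO2
#'   in one step; larger proposed changes shrink `dt` and retry.
#' @param steady_tol Steady state is declared when the absolute carbon
#'   tendency falls below `steady_tol * f_degas_ref`.
#' @param max_steps Maximum number of accepted coupler steps.
#' @param max_retries Maximum timestep rejections within a single step.
#' @param co2_bounds Two-sided bounds on relative CO2; exceedance is
#'   classified as a runaway failure.
#' @param climate_sensitivity Warming per CO2 doubling, degrees C.
#' @param t_ref Global average surface temperature at relative CO2 of 1,
#'   degrees C.
#' @param c_ref Reference atmosphere-ocean carbon inventory, mol C;
#'   relative CO2 is inventory / `c_ref`.
#' @param f_degas_ref Reference degassing flux, mol C yr^-1.
#' @param sink_shares Named shares (silicate, land_burial, marine_burial)
#'   of the reference degassing flux balanced by each sink at calibration.
#' @param f_carb_ref Reference global carbonate-weathering flux used to
#'   scale the (carbon-neutral) carbonate rate constant, mol C yr^-1.
#' @param seed_biomass Uniform biomass seed for every vegetation spin-up,
#'   gC m^-2.
#' @param veg_tol Relative tolerance of the vegetation fixed-point
#'   iteration (the "<1 percent" rule).
#' @param veg_max_iter Iteration cap of the vegetation spin-up.
#' @return An object of class `coupler_config`.
#' @export
coupler_config <- function(dt_init = 1e5, dt_min = 1e3, dt_max = 1e6,
                           step_shrink = 0.5, step_grow = 1.2,
                           stab_threshold = 0.02, steady_tol = 1e-3,
                           max_steps = 400, max_retries = 40,
                           co2_bounds = c(0.05, 20),
                           climate_sensitivity = 5, t_ref = 14,
                           c_ref = 3.2e18, f_degas_ref = 8e12,
                           sink_shares = c(silicate = 0.8,
                                           land_burial = 0.1,
                                           marine_burial = 0.1),
                           f_carb_ref = 1.2e13,
                           seed_biomass = 2.5e4, veg_tol = 0.01,
                           veg_max_iter = 2000) {
  if (!(dt_min <= dt_init && dt_init <= dt_max))
    stop("need dt_min <= dt_init <= dt_max", call. = FALSE)
  if (steady_tol <= 0) stop("`steady_tol` must be positive", call. = FALSE)
  if (step_shrink <= 0 || step_shrink >= 1)
    stop("`step_shrink` must be in (0, 1)", call. = FALSE)
  if (step_grow < 1) stop("`step_grow` must be >= 1", call. = FALSE)
  if (length(co2_bounds) != 2 || co2_bounds[1] <= 0 ||
      co2_bounds[1] >= co2_bounds[2])
    stop("`co2_bounds` must be positive and increasing", call. = FALSE)
  shares <- sink_shares[c("silicate", "land_burial", "marine_burial")]
  if (any(is.na(shares)) || abs(sum(shares) - 1) > 1e-10)
    stop("`sink_shares` must name silicate, land_burial, marine_burial ",
         "and sum to 1", call. = FALSE)
  structure(
    list(dt_init = dt_init, dt_min = dt_min, dt_max = dt_max,
         step_shrink = step_shrink, step_grow = step_grow,
         stab_threshold = stab_threshold, steady_tol = steady_tol,
         max_steps = max_steps, max_retries = max_retries,
         co2_bounds = co2_bounds,
         climate_sensitivity = climate_sensitivity, t_ref = t_ref,
         c_ref = c_ref, f_degas_ref = f_degas_ref,
         sink_shares = shares, f_carb_ref = f_carb_ref,
         seed_biomass = seed_biomass, veg_tol = veg_tol,
         veg_max_iter = veg_max_iter),
    class = "coupler_config")
}

#' Scalar forcings of a model epoch
#'
#' @param time_Ma Time before present, Myr (controls solar luminosity).
#' @param o2_mixing_ratio Atmospheric O2 mixing ratio, in \[0.05, 0.40\].
#' @param degassing_rel Degassing flux relative to the reference flux.
#' @return An object of class `forcing_state`.
#' @export
forcing_state <- function(time_Ma = 0, o2_mixing_ratio = 0.21,
                          degassing_rel = 1) {
  if (time_Ma < 0) stop("`time_Ma` must be >= 0", call. = FALSE)
  if (o2_mixing_ratio < 0.05 || o2_mixing_ratio > 0.40)
    stop("`o2_mixing_ratio` must lie in [0.05, 0.40]", call. = FALSE)
  if (degassing_rel <= 0)
    stop("`degassing_rel` must be positive", call. = FALSE)
  structure(list(time_Ma = time_Ma, o2_mixing_ratio = o2_mixing_ratio,
                 degassing_rel = degassing_rel),
            class = "forcing_state")
}

#' Bundle of all module parameter blocks with their defaults
#'
#' @param photo [photosynthesis_params()] block.
#' @param pfts List of functional types, see [default_pfts()].
#' @param weathering [weathering_params()] block.
#' @param climate [climate_params()] block.
#' @return Named list with classes preserved.
#' @export
default_params <- function(photo = photosynthesis_params(),
                           pfts = default_pfts(),
                           weathering = weathering_params(),
                           climate = climate_params()) {
  stopifnot(inherits(photo, "photosynthesis_params"),
            inherits(weathering, "weathering_params"),
            inherits(climate, "climate_params"))
  list(photo = photo, pfts = pfts, weathering = weathering,
       climate = climate)
}
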