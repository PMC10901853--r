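# Lumped atmosphere-ocean carbon reservoir, CO2-to-climate mapping, the
# calibration that closes the reference budget, and the adaptive coupling
# loop that spins vegetation to steady state inside every carbon step.

#' Global average surface temperature from relative CO2
#'
#' Logarithmic climate sensitivity:
#' `gast = t_ref + climate_sensitivity * log2(rco2)`.
#'
#' @param rco2 Relative atmospheric CO2 (> 0, vectorised).
#' @param config A [coupler_config()].
#' @return Temperature in degrees C.
#' @export
#' @examples
#' gast_from_rco2(2, coupler_config())  # 14 + 5
gast_from_rco2 <- function(rco2, config = coupler_config()) {
  if (any(rco2 <= 0)) stop("`rco2` must be positive", call. = FALSE)
  config$t_ref + config$climate_sensitivity * log2(rco2)
}

#' Carbon reservoir state
#'
#' A single lumped atmosphere-ocean inventory; relative CO2 is the
#' inventory divided by the reference inventory, and the global average
#' surface temperature follows [gast_from_rco2()].
#'
#' @param rco2 Initial relative CO2 (> 0).
#' @param config A [coupler_config()].
#' @return An object of class `carbon_state` with `atm_ocean_C` (mol C),
#'   `rco2` and `gast` (degrees C).
#' @export
carbon_state <- function(rco2 = 1, config = coupler_config()) {
  if (rco2 <= 0) stop("`rco2` must be positive", call. = FALSE)
  structure(list(atm_ocean_C = rco2 * config$c_ref, rco2 = rco2,
                 gast = gast_from_rco2(rco2, config)),
            class = "carbon_state")
}

set_inventory <- function(state, inventory, config) {
  state$atm_ocean_C <- inventory
  state$rco2 <- inventory / config$c_ref
  state$gast <- gast_from_rco2(state$rco2, config)
  state
}

#' Net carbon tendency of the atmosphere-ocean reservoir
#'
#' Mass balance `dC/dt = degassing - silicate weathering - land burial -
#' marine burial`. Carbonate weathering is carbon-neutral on this
#' timescale (the weathered carbonate is returned as deposition) and so
#' does not appear.
#'
#' @param state A `carbon_state`.
#' @param weathering A `weathering_state` with burial terms filled in.
#' @param forcing A [forcing_state()].
#' @param config A [coupler_config()].
#' @return Tendency in mol C yr^-1.
#' @export
carbon_tendency <- function(state, weathering, forcing,
                            config = coupler_config()) {
  stopifnot(inherits(weathering, "weathering_state"))
  sinks <- weathering$total_sil + weathering$burial_land +
    weathering$burial_marine
  if (!is.finite(sinks))
    stop("weathering state is missing burial terms ",
         "(no vegetation baseline?)", call. = FALSE)
  forcing$degassing_rel * config$f_degas_ref - sinks
}

# One full diagnosis of the coupled system at the current carbon state:
# climate -> vegetation spin-up -> weathering and burial -> tendency.
coupled_fields <- function(state, forcing, world, model) {
  config <- model$config
  climate <- synth_climate(world, forcing,
                           gast_offset = state$gast - config$t_ref,
                           params = model$params$climate)
  veg <- grow_vegetation(climate, forcing, state$rco2, world,
                         pfts = model$params$pfts,
                         params = model$params$photo,
                         seed_biomass = config$seed_biomass,
                         tol = config$veg_tol,
                         max_iter = config$veg_max_iter)
  weath <- global_weathering(climate, veg, world, state$rco2,
                             params = model$params$weathering,
                             baseline_total = model$baseline_total)
  veg$v_rel <- weath$v_rel
  hab <- habitable_area(veg, world)
  list(climate = climate, veg = veg, weath = weath, habitable = hab,
       tendency = carbon_tendency(state, weath, forcing, config))
}

#' Calibrate the weathering and burial constants on a reference world
#'
#' Scales the silicate rate constants (preserving the basalt/granite
#' ratio), the land and marine burial constants and the carbonate rate
#' constant so that, at relative CO2 of 1 on the given world and forcing,
#' the carbon sinks exactly balance the reference degassing flux with the
#' configured sink shares (by default silicate 80 percent, land burial 10,
#' marine burial 10). The reference world's steady-state global biomass
#' becomes the baseline of the relative-vegetation scalar, so the
#' calibrated world sits at `v_rel = 1` and is a fixed point of the
#' coupled system. Calibration is idempotent.
#'
#' @param world A `world_grid` with land.
#' @param forcing The reference [forcing_state()] (normally
#'   `degassing_rel = 1`).
#' @param params A [default_params()] bundle.
#' @param config A [coupler_config()].
#' @return An object of class `vc_model`: the calibrated `params`, the
#'   `config`, the vegetation `baseline_total` (gC) and a `reference`
#'   list of diagnostic fluxes.
#' @export
#' @examples
#' w <- make_supercontinent(make_grid(16, 20), 0.3, 0, seed = 2)
#' m <- calibrate_reference(w, forcing_state())
#' m$reference$tendency  # ~0
calibrate_reference <- function(world, forcing = forcing_state(),
                                params = default_params(),
                                config = coupler_config()) {
  stopifnot(inherits(world, "world_grid"))
  state <- carbon_state(1, config)
  climate <- synth_climate(world, forcing, gast_offset = 0,
                           params = params$climate)
  veg <- grow_vegetation(climate, forcing, 1, world,
                         pfts = params$pfts, params = params$photo,
                         seed_biomass = config$seed_biomass,
                         tol = config$veg_tol,
                         max_iter = config$veg_max_iter)
  if (!any(veg$habitable))
    stop("reference world supports no vegetation; cannot calibrate",
         call. = FALSE)
  baseline_total <- total_biomass(veg, world)

  raw <- global_weathering(climate, veg, world, 1,
                           params = params$weathering)
  if (raw$total_sil <= 0)
    stop("reference world has zero weatherable silicate flux", call. = FALSE)
  f_bal <- forcing$degassing_rel * config$f_degas_ref
  shares <- config$sink_shares
  sil_scale <- shares[["silicate"]] * f_bal / raw$total_sil
  params$weathering$k_sil_granite <- params$weathering$k_sil_granite * sil_scale
  params$weathering$k_sil_basalt <- params$weathering$k_sil_basalt * sil_scale
  params$weathering$k_carb <- params$weathering$k_carb *
    config$f_carb_ref / raw$total_carb
  params$weathering$k_locb <- shares[["land_burial"]] * f_bal  # v_rel = 1
  params$weathering$k_mocb <- shares[["marine_burial"]] * f_bal

  model <- structure(
    list(params = params, config = config,
         baseline_total = baseline_total, forcing_ref = forcing,
         reference = NULL),
    class = "vc_model")
  ref <- coupled_fields(state, forcing, world, model)
  model$reference <- list(
    total_sil = ref$weath$total_sil, total_carb = ref$weath$total_carb,
    burial_land = ref$weath$burial_land,
    burial_marine = ref$weath$burial_marine,
    v_rel = ref$veg$v_rel, habitable_fraction = ref$habitable$fraction,
    tendency = ref$tendency,
    k_sil_granite = params$weathering$k_sil_granite,
    k_sil_basalt = params$weathering$k_sil_basalt,
    k_locb = params$weathering$k_locb)
  model
}

#' @export
print.vc_model <- function(x, ...) {
  cat(sprintf(
    "<vc_model: baseline biomass %.3g gC, k_sil_granite %.3g, residual %.2g>\n",
    x$baseline_total, x$params$weathering$k_sil_granite,
    x$reference$tendency / x$config$f_degas_ref))
  invisible(x)
}

#' One adaptive coupled timestep
#'
#' Diagnoses the coupled system at the current state (climate from the
#' CO2-implied temperature offset, vegetation re-seeded and spun to steady
#' state, weathering and burial fluxes), then advances the carbon
#' inventory by an explicit Euler step. A step whose relative CO2 change
#' exceeds `stab_threshold` is rejected: `dt` shrinks and the Euler update
#' is retried (the vegetation spin-up is not repeated, since the
#' pre-step state is unchanged). Accepted steps grow `dt` up to `dt_max`.
#'
#' @param state A `carbon_state`.
#' @param forcing A [forcing_state()].
#' @param world A `world_grid`.
#' @param model A calibrated `vc_model` from [calibrate_reference()].
#' @param dt Proposed timestep, yr (default `config$dt_init`).
#' @return List: updated `state`, `veg`, `weath`, `habitable`, `tendency`,
#'   `dt_used`, `dt_next`, `n_retries` and `status` (`"ok"`,
#'   `"runaway_hot"`, `"runaway_cold"` or `"extinction"`).
#' @export
step_coupled <- function(state, forcing, world, model,
                         dt = model$config$dt_init) {
  stopifnot(inherits(state, "carbon_state"), inherits(model, "vc_model"))
  if (!any(world$land_mask)) stop("world has no land", call. = FALSE)
  config <- model$config
  fields <- coupled_fields(state, forcing, world, model)

  status <- "ok"
  if (fields$habitable$fraction <= 0 &&
      abs(fields$tendency) > config$steady_tol * config$f_degas_ref)
    status <- "extinction"

  dt <- min(max(dt, config$dt_min), config$dt_max)
  n_retries <- 0L
  repeat {
    inv_new <- state$atm_ocean_C + dt * fields$tendency
    rel_change <- abs(inv_new - state$atm_ocean_C) / state$atm_ocean_C
    if (inv_new > 0 && rel_change <= config$stab_threshold) break
    if (dt <= config$dt_min || n_retries >= config$max_retries) {
      inv_new <- max(inv_new, state$atm_ocean_C * 0.5)
      break
    }
    dt <- max(dt * config$step_shrink, config$dt_min)
    n_retries <- n_retries + 1L
  }
  new_state <- set_inventory(state, inv_new, config)
  if (new_state$rco2 > config$co2_bounds[2]) status <- "runaway_hot"
  if (new_state$rco2 < config$co2_bounds[1]) status <- "runaway_cold"

  list(state = new_state, veg = fields$veg, weath = fields$weath,
       habitable = fields$habitable, tendency = fields$tendency,
       dt_used = dt, dt_next = min(dt * config$step_grow, config$dt_max),
       n_retries = n_retries, status = status)
}

#' Run the coupled system to steady state
#'
#' Iterates [step_coupled()] until the absolute carbon tendency falls
#' below `steady_tol` of the reference degassing flux, the step budget is
#' exhausted, or a failure mode (runaway CO2 or vegetation extinction) is
#' detected. Failures are recorded as data, not raised.
#'
#' @param state Initial `carbon_state` (default: relative CO2 of 1).
#' @param forcing A [forcing_state()].
#' @param world A `world_grid`.
#' @param model A calibrated `vc_model`.
#' @return An object of class `vc_run`: `success`, `failure_mode`
#'   (`"none"`, `"runaway_hot"`, `"runaway_cold"`, `"extinction"` or
#'   `"no_convergence"`), a `trajectory` data frame (time, relative CO2,
#'   temperature, relative vegetation, habitable fraction and area,
#'   global fluxes, timestep, spin-up iterations, retries), a `steady`
#'   summary list, and the final `veg`, `weath` and `state`.
#' @export
#' @examples
#' \donttest{
#' w <- make_supercontinent(make_grid(16, 20), 0.3, 0, seed = 2)
#' m <- calibrate_reference(w, forcing_state())
#' r <- run_to_steady(carbon_state(1, m$config), forcing_state(), w, m)
#' r$steady$rco2  # 1 (the calibration fixed point)
#' }
run_to_steady <- function(state = NULL, forcing = forcing_state(),
                          world, model) {
  stopifnot(inherits(model, "vc_model"))
  config <- model$config
  if (is.null(state)) state <- carbon_state(1, config)
  dt <- config$dt_init
  rows <- vector("list", config$max_steps + 1L)
  time_yr <- 0
  failure <- "no_convergence"
  last <- NULL
  n_rows <- 0L

  for (k in seq_len(config$max_steps)) {
    stepped <- step_coupled(state, forcing, world, model, dt = dt)
    n_rows <- n_rows + 1L
    rows[[n_rows]] <- data.frame(
      time_yr = time_yr, rco2 = state$rco2, gast_C = state$gast,
      v_rel = stepped$weath$v_rel,
      habitable_fraction = stepped$habitable$fraction,
      habitable_area_m2 = stepped$habitable$area_m2,
      F_sil = stepped$weath$total_sil, F_carb = stepped$weath$total_carb,
      F_locb = stepped$weath$burial_land,
      F_mocb = stepped$weath$burial_marine,
      tendency = stepped$tendency, dt_yr = stepped$dt_used,
      veg_iterations = stepped$veg$iterations_to_converge,
      n_retries = stepped$n_retries)
    last <- stepped
    if (abs(stepped$tendency) < config$steady_tol * config$f_degas_ref) {
      failure <- "none"
      break
    }
    if (stepped$status != "ok") {
      failure <- stepped$status
      state <- stepped$state
      break
    }
    time_yr <- time_yr + stepped$dt_used
    state <- stepped$state
    dt <- stepped$dt_next
  }

  trajectory <- do.call(rbind, rows[seq_len(n_rows)])
  steady <- if (failure == "none") {
    fin <- trajectory[nrow(trajectory), ]
    list(rco2 = fin$rco2, gast = fin$gast_C, v_rel = fin$v_rel,
         habitable_fraction = fin$habitable_fraction,
         habitable_area_m2 = fin$habitable_area_m2,
         F_sil = fin$F_sil, n_steps = nrow(trajectory))
  } else {
    list(rco2 = NA_real_, gast = NA_real_, v_rel = NA_real_,
         habitable_fraction = NA_real_, habitable_area_m2 = NA_real_,
         F_sil = NA_real_, n_steps = nrow(trajectory))
  }
  structure(
    list(success = failure == "none", failure_mode = failure,
         trajectory = trajectory, steady = steady,
         final_veg = last$veg, final_weath = last$weath,
         final_state = if (failure == "none") state else last$state),
    class = "vc_run")
}

#' @export
print.vc_run <- function(x, ...) {
  if (x$success) {
    cat(sprintf(
      "<vc_run: steady rco2 %.4f, gast %.2f C, habitable %.1f%%, %d steps>\n",
      x$steady$rco2, x$steady$gast, 100 * x$steady$habitable_fraction,
      x$steady$n_steps))
  } else {
    cat(sprintf("<vc_run: FAILED (%s) after %d steps>\n",
                x$failure_mode, nrow(x$trajectory)))
  }
  invisible(x)
}

#' Run a sequence of forcing epochs
#'
#' Convenience forcing-history runner: each row of `forcings` (columns
#' `time_Ma`, `o2_mixing_ratio`, `degassing_rel`) is run to steady state,
#' carrying the carbon state forward between epochs. Intended for
#' synthetic demonstration scenarios.
#'
#' @param forcings Data frame of epochs.
#' @param world A `world_grid`.
#' @param model A calibrated `vc_model`.
#' @return List of `vc_run` objects, one per epoch, plus a `summary`
#'   data frame.
#' @export
run_history <- function(forcings, world, model) {
  need <- c("time_Ma", "o2_mixing_ratio", "degassing_rel")
  if (!all(need %in% names(forcings)))
    stop("`forcings` needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  state <- carbon_state(1, model$config)
  runs <- vector("list", nrow(forcings))
  for (i in seq_len(nrow(forcings))) {
    f <- forcing_state(forcings$time_Ma[i], forcings$o2_mixing_ratio[i],
                       forcings$degassing_rel[i])
    runs[[i]] <- run_to_steady(state, f, world, model)
    if (runs[[i]]$success) state <- runs[[i]]$final_state
  }
  summary <- data.frame(
    time_Ma = forcings$time_Ma,
    success = vapply(runs, function(r) r$success, TRUE),
    rco2 = vapply(runs, function(r) r$steady$rco2, 1),
    gast_C = vapply(runs, function(r) r$steady$gast, 1),
    habitable_fraction =
      vapply(runs, function(r) r$steady$habitable_fraction, 1))
  list(runs = runs, summary = summary)
}
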