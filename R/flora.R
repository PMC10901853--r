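# Gridded vegetation kernel: per-cell NPP for three functional types,
# oxygen-dependent turnover, and steady-state biomass by fixed-point
# iteration from a uniform seed.

#' Relative insolation at a latitude and geological time
#'
#' Cosine-of-latitude weighting of incoming light, normalised to 1 at the
#' equator at present, multiplied by the relative solar luminosity
#' `L(t) = 1 / (1 + 0.4 t / 4570)` with `t` in Myr before present -- about
#' a 5 percent reduction in the early Phanerozoic.
#'
#' @param lat Latitude in degrees (vectorised; |lat| <= 90).
#' @param time_Ma Time before present, Myr (>= 0).
#' @return Dimensionless factor in \[0, 1\].
#' @export
#' @examples
#' insolation_factor(0, 0)     # 1
#' insolation_factor(0, 541)   # ~0.955
insolation_factor <- function(lat, time_Ma = 0) {
  if (any(abs(lat) > 90)) stop("|lat| must be <= 90", call. = FALSE)
  if (any(time_Ma < 0)) stop("`time_Ma` must be >= 0", call. = FALSE)
  cos(deg2rad(lat)) / (1 + 0.4 * time_Ma / 4570)
}

#' Leaf respiration rate from daylight hours
#'
#' `s = (24 / h) * a`: the respiratory cost per unit photosynthesis rises
#' as the day shortens.
#'
#' @param h Daylight hours, in (0, 24\].
#' @param a Dimensionless leaf-respiration coefficient (>= 0).
#' @return The dimensionless rate `s`.
#' @export
#' @examples
#' leaf_respiration_rate(12, 0.015)  # 0.03
leaf_respiration_rate <- function(h, a) {
  if (!is.numeric(h) || any(h <= 0) || any(h > 24))
    stop("`h` must lie in (0, 24]", call. = FALSE)
  if (any(a < 0)) stop("`a` must be >= 0", call. = FALSE)
  (24 / h) * a
}

#' Oxygen-dependent biomass turnover fraction
#'
#' Annual fractional biomass loss rises linearly with atmospheric oxygen
#' (fire probability), clamped between 8 and 20 percent:
#' `min(max(0.0092 * (100 * o2 - 10), 0.08), 0.2)`. At present-day oxygen
#' (0.21) the value is 0.1012; the upper clamp (double that) binds from an
#' O2 mixing ratio of about 0.317.
#'
#' @param o2_mixing_ratio Atmospheric O2 mixing ratio (>= 0, vectorised).
#' @return Turnover in yr^-1, within \[0.08, 0.2\].
#' @export
#' @examples
#' turnover_fraction(0.35)  # 0.20
#' turnover_fraction(0.21)  # 0.1012
turnover_fraction <- function(o2_mixing_ratio) {
  if (any(o2_mixing_ratio < 0))
    stop("`o2_mixing_ratio` must be >= 0", call. = FALSE)
  pmin(pmax(0.0092 * (100 * o2_mixing_ratio - 10), 0.08), 0.2)
}

# Trapezoidal temperature response of one functional type.
pft_temperature_response <- function(temperature, pft) {
  up <- (temperature - pft$t_min) / (pft$t_opt_lo - pft$t_min)
  down <- (pft$t_max - temperature) / (pft$t_max - pft$t_opt_hi)
  g <- pmax(pmin(1, pmin(up, down)), 0)
  g[temperature <= pft$t_min | temperature >= pft$t_max] <- 0
  g
}

#' Net primary productivity of one functional type in one cell
#'
#' Multiplicative-limitation kernel
#' `NPP = min(npp_max, npp_max * g_T * g_W * g_L * g_C * g_O * (1 - s))`
#' where `g_T` is the trapezoidal temperature ramp of the functional type,
#' `g_W = runoff / (runoff + runoff_half)` the water limitation,
#' `g_L` the relative insolation, `g_C = rco2 (1 + k_co2) / (rco2 + k_co2)`
#' a saturating CO2 response normalised to 1 at `rco2 = 1`,
#' `g_O = clamp(1 - o2_sensitivity (O2mr - 0.21)/0.21, 0, 1.1)` a
#' photorespiration penalty equal to 1 at present-day oxygen, and `s` the
#' leaf respiration rate. Productivity is zero wherever the habitability
#' rule fails: zero runoff, annual temperature below -10 degrees C, or
#' temperature outside the functional type's window.
#'
#' All climate arguments are vectorised (matrices pass through).
#'
#' @param temperature Annual-mean temperature, degrees C.
#' @param runoff Runoff, mm yr^-1 (>= 0).
#' @param insolation_rel Relative insolation, dimensionless.
#' @param rco2 Relative atmospheric CO2 (> 0).
#' @param o2_mixing_ratio Atmospheric O2 mixing ratio.
#' @param pft A [pft_params()] object.
#' @param params A [photosynthesis_params()] block.
#' @return NPP in gC m^-2 yr^-1, same shape as the climate inputs.
#' @export
npp_cell <- function(temperature, runoff, insolation_rel, rco2,
                     o2_mixing_ratio, pft, params = photosynthesis_params()) {
  stopifnot(inherits(pft, "pft_params"),
            inherits(params, "photosynthesis_params"))
  if (any(rco2 <= 0)) stop("`rco2` must be positive", call. = FALSE)
  g_t <- pft_temperature_response(temperature, pft)
  g_w <- runoff / (runoff + params$runoff_half)
  g_l <- insolation_rel
  g_c <- rco2 * (1 + params$k_co2) / (rco2 + params$k_co2)
  g_o <- pmin(pmax(1 - params$o2_sensitivity *
                     (o2_mixing_ratio - 0.21) / 0.21, 0), 1.1)
  npp <- params$npp_max * g_t * g_w * g_l * g_c * g_o * (1 - params$s)
  npp[npp > params$npp_max] <- params$npp_max   # ceiling, shape-preserving
  npp[runoff <= 0 | temperature < -10] <- 0
  npp
}

#' Per-cell NPP and dominant functional type over a climate grid
#'
#' Evaluates [npp_cell()] for every functional type on every land cell and
#' keeps the most productive type. Ties are broken by list order
#' (tropical > temperate > boreal with [default_pfts()]). Ocean cells get
#' zero NPP and no type.
#'
#' @param climate A `climate_field`.
#' @param forcing A [forcing_state()].
#' @param rco2 Relative atmospheric CO2.
#' @param grid The matching `world_grid`.
#' @param pfts Named list of [pft_params()].
#' @param params A [photosynthesis_params()] block.
#' @return List with `npp` (matrix, gC m^-2 yr^-1) and `dominant_pft`
#'   (integer matrix: 0 = none, then the index into `pfts`; the `levels`
#'   attribute carries the type names).
#' @export
npp_grid <- function(climate, forcing, rco2, grid, pfts = default_pfts(),
                     params = photosynthesis_params()) {
  stopifnot(inherits(climate, "climate_field"),
            inherits(grid, "world_grid"))
  if (!all(dim(climate$temperature) == c(grid$n_lat, grid$n_lon)))
    stop("climate and grid shapes do not match", call. = FALSE)
  per_type <- lapply(pfts, function(pft)
    npp_cell(climate$temperature, climate$runoff, climate$insolation_rel,
             rco2, forcing$o2_mixing_ratio, pft, params))
  npp <- per_type[[1]]
  dominant <- matrix(1L, grid$n_lat, grid$n_lon)
  for (k in seq_along(per_type)[-1]) {
    better <- per_type[[k]] > npp   # strict: ties keep the earlier type
    dominant[better] <- k
    npp[better] <- per_type[[k]][better]
  }
  dominant[npp <= 0] <- 0L
  npp[!grid$land_mask] <- 0
  dominant[!grid$land_mask] <- 0L
  storage.mode(dominant) <- "integer"
  attr(dominant, "levels") <- names(pfts)
  list(npp = npp, dominant_pft = dominant)
}

#' Spin biomass to steady state from a uniform seed
#'
#' Iterates the yearly update `B <- B + NPP - turnover * B` in every
#' colonisable cell, starting from the uniform seed (default 2.5e4
#' gC m^-2, the present-day average). Cells with zero NPP are set to zero
#' immediately and flagged uninhabitable. Because the update is linear,
#' the remaining distance to the fixed point `NPP / turnover` equals the
#' last per-cell change divided by the turnover; iteration stops when that
#' estimated distance falls below `tol` of the standing biomass in every
#' colonised cell and in the global total, which guarantees the returned
#' biomass agrees with the closed form within ~`tol` everywhere.
#'
#' @param npp Matrix (or vector) of NPP, gC m^-2 yr^-1.
#' @param o2_mixing_ratio O2 mixing ratio (sets the turnover fraction).
#' @param seed_biomass Uniform starting biomass, gC m^-2 (> 0).
#' @param tol Relative convergence tolerance (default 0.01, the
#'   "<1 percent" rule).
#' @param max_iter Iteration cap; exceeding it is an error with
#'   diagnostics.
#' @return An object of class `vegetation_state`: `npp`, `biomass`,
#'   `turnover` (scalar yr^-1, spatially uniform), `habitable` (logical),
#'   `dominant_pft` (`NULL` here; filled by [grow_vegetation()]),
#'   `v_rel` (`NA` until referenced against a baseline) and
#'   `iterations_to_converge`.
#' @export
#' @examples
#' st <- spin_to_steady_biomass(matrix(1000, 2, 2), 0.21)
#' st$biomass[1, 1] / (1000 / st$turnover)  # ~1
spin_to_steady_biomass <- function(npp, o2_mixing_ratio,
                                   seed_biomass = 2.5e4, tol = 0.01,
                                   max_iter = 2000) {
  if (seed_biomass <= 0) stop("`seed_biomass` must be > 0", call. = FALSE)
  if (tol <= 0) stop("`tol` must be > 0", call. = FALSE)
  tau <- turnover_fraction(o2_mixing_ratio)
  habitable <- npp > 0
  biomass <- npp * 0
  iterations <- 0L
  if (any(habitable)) {
    b <- npp[habitable] * 0 + seed_biomass
    f <- npp[habitable]
    repeat {
      iterations <- iterations + 1L
      delta <- f - tau * b
      b_new <- b + delta
      dist <- abs(delta) / tau            # exact distance to NPP/turnover
      gap_total <- abs(sum(delta)) / tau  # global-total distance
      if (all(dist <= tol * b_new) && gap_total <= tol * sum(b_new)) {
        b <- b_new
        break
      }
      b <- b_new
      if (iterations >= max_iter)
        stop(sprintf(paste0(
          "biomass spin-up did not converge in %d iterations ",
          "(turnover %.4f, worst relative distance %.3g)"),
          max_iter, tau, max(dist / b_new)), call. = FALSE)
    }
    biomass[habitable] <- b
  }
  structure(
    list(npp = npp, biomass = biomass, turnover = tau,
         habitable = habitable, dominant_pft = NULL, v_rel = NA_real_,
         iterations_to_converge = iterations),
    class = "vegetation_state")
}

#' @export
print.vegetation_state <- function(x, ...) {
  cat(sprintf(
    "<vegetation_state: %d habitable cells, turnover %.4f, %d iterations>\n",
    sum(x$habitable), x$turnover, x$iterations_to_converge))
  invisible(x)
}

#' Grow vegetation on a world: NPP, dominant type and steady biomass
#'
#' Convenience pipeline composing [npp_grid()] and
#' [spin_to_steady_biomass()]; this is the vegetation step the coupler
#' performs once per carbon-cycle timestep.
#'
#' @inheritParams npp_grid
#' @param seed_biomass,tol,max_iter Passed to [spin_to_steady_biomass()].
#' @return A `vegetation_state` with `dominant_pft` filled in.
#' @export
grow_vegetation <- function(climate, forcing, rco2, grid,
                            pfts = default_pfts(),
                            params = photosynthesis_params(),
                            seed_biomass = 2.5e4, tol = 0.01,
                            max_iter = 2000) {
  ng <- npp_grid(climate, forcing, rco2, grid, pfts, params)
  state <- spin_to_steady_biomass(ng$npp, forcing$o2_mixing_ratio,
                                  seed_biomass, tol, max_iter)
  state$dominant_pft <- ng$dominant_pft
  state
}

#' Habitable land area
#'
#' Area-weighted (not cell-count) extent of land able to support plant
#' biomass.
#'
#' @param state A `vegetation_state`.
#' @param grid The matching `world_grid`.
#' @return List with `fraction` (of total land area) and `area_m2`.
#' @export
habitable_area <- function(state, grid) {
  stopifnot(inherits(state, "vegetation_state"),
            inherits(grid, "world_grid"))
  la <- land_area(grid)
  if (la <= 0) stop("world has zero land area", call. = FALSE)
  occupied <- grid$land_mask & state$biomass > 0
  a <- sum(grid$cell_area[occupied])
  list(fraction = a / la, area_m2 = a)
}

#' Global biomass, area-weighted
#'
#' @param state A `vegetation_state`.
#' @param grid The matching `world_grid`.
#' @return Total standing biomass in gC.
#' @export
total_biomass <- function(state, grid) {
  sum(state$biomass * grid$cell_area)
}

#' Global relative vegetation
#'
#' Area-weighted global biomass divided by a baseline total; the scalar
#' that scales land organic-carbon burial.
#'
#' @param state A `vegetation_state`.
#' @param grid The matching `world_grid`.
#' @param baseline_total Baseline global biomass, gC (> 0).
#' @return Dimensionless relative vegetation (>= 0).
#' @export
relative_vegetation <- function(state, grid, baseline_total) {
  if (baseline_total <= 0)
    stop("`baseline_total` must be positive", call. = FALSE)
  total_biomass(state, grid) / baseline_total
}
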