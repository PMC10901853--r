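# Biotic weathering enhancement, per-cell silicate/carbonate fluxes with a
# granite/basalt lithology split, and vegetation-scaled organic burial.

GAS_CONSTANT <- 8.314       # J mol^-1 K^-1
WEATHERING_T_REF_K <- 288.15  # 15 C reference of the Arrhenius kinetics

#' Biotic enhancement of weathering in a grid cell
#'
#' `f_biota = npp_slope * NPP + f_minbiota * rco2^r`: a linear gain with
#' local productivity on top of the abiotic pH-driven term
#' `f_minbiota * rco2^r` that a bare (NPP = 0) cell retains. With the
#' defaults (slope 5e-4, `f_minbiota` 0.32, r 0.25) the factor rises from
#' 0.32 on bare ground to 1.92 at the productivity ceiling of 3200
#' gC m^-2 yr^-1 at present-day CO2 -- a maximum six-fold enhancement.
#'
#' @param npp NPP in gC m^-2 yr^-1 (>= 0, vectorised).
#' @param rco2 Relative atmospheric CO2 (> 0).
#' @param params A [weathering_params()] block.
#' @return Dimensionless enhancement factor(s).
#' @export
#' @examples
#' p <- weathering_params()
#' biotic_enhancement(0, 1, p)      # 0.32
#' biotic_enhancement(3200, 1, p)   # 1.92 = 6 x 0.32
biotic_enhancement <- function(npp, rco2, params = weathering_params()) {
  stopifnot(inherits(params, "weathering_params"))
  if (any(!is.finite(rco2)) || any(rco2 <= 0))
    stop("`rco2` must be positive", call. = FALSE)
  if (any(npp < 0)) stop("`npp` must be >= 0", call. = FALSE)
  params$npp_slope * npp + params$f_minbiota * rco2^params$r
}

arrhenius <- function(temperature_c, act_energy) {
  exp(act_energy / GAS_CONSTANT *
        (1 / WEATHERING_T_REF_K - 1 / (temperature_c + 273.15)))
}

#' Silicate weathering flux of one cell
#'
#' Runoff-linear, Arrhenius-in-temperature kinetics with a two-member
#' lithology mix:
#' `flux = area * runoff * f_biota *
#'   sum_lith frac_lith * k_lith * exp[(E_lith/R)(1/288.15 - 1/T_K)]`.
#' Zero wherever runoff is zero.
#'
#' @param temperature Degrees C (vectorised).
#' @param runoff mm yr^-1 (>= 0).
#' @param f_biota Biotic enhancement factor.
#' @param basalt_fraction Basalt fraction of the cell's lithology, \[0, 1\].
#' @param cell_area Cell area, m^2.
#' @param params A [weathering_params()] block.
#' @return Flux in mol C yr^-1.
#' @export
cell_silicate_flux <- function(temperature, runoff, f_biota,
                               basalt_fraction, cell_area,
                               params = weathering_params()) {
  if (any(runoff < 0)) stop("`runoff` must be >= 0", call. = FALSE)
  k_eff <- basalt_fraction * params$k_sil_basalt *
    arrhenius(temperature, params$act_energy_basalt) +
    (1 - basalt_fraction) * params$k_sil_granite *
    arrhenius(temperature, params$act_energy_granite)
  cell_area * runoff * f_biota * k_eff
}

#' Carbonate weathering flux of one cell
#'
#' Same runoff-linear kernel as the silicate flux but with a single rate
#' constant and no temperature dependence (carbonate dissolution is
#' transport-limited on these timescales).
#'
#' @inheritParams cell_silicate_flux
#' @return Flux in mol C yr^-1.
#' @export
cell_carbonate_flux <- function(runoff, f_biota, cell_area,
                                params = weathering_params()) {
  if (any(runoff < 0)) stop("`runoff` must be >= 0", call. = FALSE)
  cell_area * runoff * f_biota * params$k_carb
}

#' Global weathering state of a world
#'
#' Applies the biotic enhancement to every cell (bare cells retain the
#' abiotic term), evaluates the per-cell silicate and carbonate fluxes,
#' and aggregates exact global totals. Ocean cells contribute nothing
#' (their runoff is zero). When a `baseline_total` is supplied the global
#' relative vegetation and the organic burial fluxes are filled in as
#' well.
#'
#' @param climate A `climate_field`.
#' @param veg A `vegetation_state`.
#' @param grid The matching `world_grid`.
#' @param rco2 Relative atmospheric CO2.
#' @param params A [weathering_params()] block.
#' @param baseline_total Optional baseline global biomass (gC) for the
#'   relative-vegetation scaling of burial.
#' @return An object of class `weathering_state`: matrices `f_biota`,
#'   `sil_flux`, `carb_flux`; scalars `total_sil`, `total_carb`,
#'   `burial_land`, `burial_marine` (the burials are `NA` without a
#'   baseline) and `v_rel`.
#' @export
global_weathering <- function(climate, veg, grid, rco2,
                              params = weathering_params(),
                              baseline_total = NULL) {
  stopifnot(inherits(climate, "climate_field"),
            inherits(veg, "vegetation_state"),
            inherits(grid, "world_grid"))
  if (!all(dim(climate$temperature) == c(grid$n_lat, grid$n_lon)) ||
      !all(dim(veg$npp) == c(grid$n_lat, grid$n_lon)))
    stop("climate, vegetation and grid shapes do not match", call. = FALSE)
  f_biota <- biotic_enhancement(veg$npp, rco2, params)
  bf <- grid$basalt_fraction
  bf[is.na(bf)] <- 0
  sil <- cell_silicate_flux(climate$temperature, climate$runoff, f_biota,
                            bf, grid$cell_area, params)
  carb <- cell_carbonate_flux(climate$runoff, f_biota, grid$cell_area,
                              params)
  v_rel <- NA_real_
  burial <- list(land = NA_real_, marine = NA_real_)
  if (!is.null(baseline_total)) {
    v_rel <- relative_vegetation(veg, grid, baseline_total)
    burial <- organic_burial(v_rel, params)
  }
  structure(
    list(f_biota = f_biota, sil_flux = sil, carb_flux = carb,
         total_sil = sum(sil), total_carb = sum(carb),
         burial_land = burial$land, burial_marine = burial$marine,
         v_rel = v_rel),
    class = "weathering_state")
}

#' @export
print.weathering_state <- function(x, ...) {
  cat(sprintf(
    "<weathering_state: silicate %.3g, carbonate %.3g mol C/yr>\n",
    x$total_sil, x$total_carb))
  invisible(x)
}

#' Organic carbon burial fluxes
#'
#' Land burial scales linearly with global relative vegetation
#' (`k_locb * v_rel`); marine burial is held constant at `k_mocb`.
#'
#' @param v_rel Global relative vegetation (>= 0).
#' @param params A [weathering_params()] block.
#' @return List with `land` and `marine` fluxes, mol C yr^-1.
#' @export
organic_burial <- function(v_rel, params = weathering_params()) {
  if (any(v_rel < 0)) stop("`v_rel` must be >= 0", call. = FALSE)
  list(land = params$k_locb * v_rel, marine = params$k_mocb)
}
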