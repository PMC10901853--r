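# Synthetic climate fields: zonal temperature with continentality,
# zonal runoff with subtropical dry belts and arid continental interiors.

#' Synthesize a gridded climate for a world
#'
#' Emulates the gross structure of a general-circulation climate on a
#' paleogeography: a zonal annual-mean temperature profile
#' `t_eq - dt_pole * sin(lat)^2` cooled inland by a capped continentality
#' term; a zonal runoff profile with a wet equatorial band, dry subtropical
#' belts and wetter mid-latitudes, decayed exponentially with grid distance
#' to the coast and cut off entirely at `d_arid` cells inland (the arid
#' interior belt of a large landmass); and the relative insolation of
#' [insolation_factor()]. A global temperature offset `gast_offset` is
#' applied with linear polar amplification (factor 1 at the equator to
#' `polar_amp_max` at the poles) and scales runoff by
#' `1 + hydro_sens * gast_offset` (warming-enhanced hydrology).
#'
#' Ocean cells carry zero runoff; runoff below `runoff_floor` is set to
#' zero, so deep continental interiors and decayed dry belts are arid in
#' the strict sense used by the habitability rule.
#'
#' @param grid A `world_grid` with its land mask set.
#' @param forcing A [forcing_state()] (time sets the luminosity).
#' @param gast_offset Global average surface temperature offset from the
#'   reference climate, degrees C.
#' @param params A [climate_params()] block.
#' @return An object of class `climate_field` with matrices `temperature`
#'   (degrees C), `runoff` (mm yr^-1) and `insolation_rel`.
#' @export
#' @examples
#' w <- make_supercontinent(make_grid(20, 24), 0.3, 0, seed = 1)
#' cl <- synth_climate(w, forcing_state())
#' range(cl$runoff[w$land_mask])
synth_climate <- function(grid, forcing = forcing_state(), gast_offset = 0,
                          params = climate_params()) {
  stopifnot(inherits(grid, "world_grid"),
            inherits(forcing, "forcing_state"),
            inherits(params, "climate_params"))
  lat <- lat_matrix(grid)
  land <- grid$land_mask
  d <- distance_to_coast(grid)

  temp <- params$t_eq - params$dt_pole * sin(deg2rad(lat))^2
  inland <- pmax(d - 1, 0)
  cooling <- pmin(params$interior_cooling * inland,
                  params$interior_cooling_max)
  temp[land] <- temp[land] - cooling[land]
  amp <- 1 + (params$polar_amp_max - 1) * abs(lat) / 90
  temp <- temp + amp * gast_offset

  zonal <- stats::approx(params$runoff_lat_knots, params$runoff_knot_values,
                         xout = abs(lat), rule = 2)$y
  zonal <- matrix(zonal, grid$n_lat, grid$n_lon)
  runoff <- zonal * exp(-inland / params$interior_efold)
  runoff <- runoff * max(0, 1 + params$hydro_sens * gast_offset)
  runoff[d >= params$d_arid] <- 0
  runoff[runoff < params$runoff_floor] <- 0
  runoff[!land] <- 0

  insol <- insolation_factor(lat, forcing$time_Ma)

  structure(list(temperature = temp, runoff = runoff,
                 insolation_rel = insol),
            class = "climate_field")
}

#' @export
print.climate_field <- function(x, ...) {
  cat(sprintf(
    "<climate_field %d x %d, T %.1f..%.1f C, runoff 0..%.0f mm/yr>\n",
    nrow(x$temperature), ncol(x$temperature),
    min(x$temperature), max(x$temperature), max(x$runoff)))
  invisible(x)
}

#' Fraction of land that is arid (zero runoff)
#'
#' Area-weighted fraction of land cells with zero runoff; the quantity that
#' separates a compact supercontinent (large arid interior) from dispersed
#' blocks of the same total area.
#'
#' @param climate A `climate_field`.
#' @param grid The matching `world_grid`.
#' @return Scalar fraction in \[0, 1\].
#' @export
arid_land_fraction <- function(climate, grid) {
  la <- land_area(grid)
  if (la <= 0) stop("world has no land", call. = FALSE)
  arid <- grid$land_mask & climate$runoff <= 0
  sum(grid$cell_area[arid]) / la
}
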