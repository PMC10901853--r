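# Plain-text (CSV) readers and writers for gridded fields and run
# summaries. Gridded files use the long format: one row per cell with
# lat, lon and the per-cell variables.

grid_to_long <- function(grid) {
  data.frame(
    lat = rep(grid$lat_centers, times = grid$n_lon),
    lon = rep(grid$lon_centers, each = grid$n_lat))
}

#' Write a world and its climate to a long-format CSV
#'
#' Columns: `lat`, `lon`, `land` (0/1), `basalt_fraction`,
#' `temperature_C`, `runoff_mm_yr`, `insolation_rel`. One row per cell,
#' cells ordered south-to-north within west-to-east columns.
#'
#' @param grid A `world_grid`.
#' @param climate Optional matching `climate_field`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_climate_csv <- function(grid, climate = NULL, path) {
  df <- grid_to_long(grid)
  df$land <- as.integer(grid$land_mask)
  df$basalt_fraction <- as.vector(grid$basalt_fraction)
  if (!is.null(climate)) {
    df$temperature_C <- as.vector(climate$temperature)
    df$runoff_mm_yr <- as.vector(climate$runoff)
    df$insolation_rel <- as.vector(climate$insolation_rel)
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Load a gridded climate from a long-format CSV
#'
#' Reconstructs the `world_grid` and `climate_field` written by
#' [write_climate_csv()], or any file providing the same variables under
#' other column names via `var_map`. The file must cover a complete
#' latitude-longitude grid; missing variables and negative runoff are
#' rejected with the offending name.
#'
#' @param path CSV file path.
#' @param var_map Optional named character vector mapping canonical names
#'   (`lat`, `lon`, `temperature_C`, `runoff_mm_yr`, `land`,
#'   `basalt_fraction`) to the column names used in the file.
#' @return List with `grid` (a `world_grid`) and `climate` (a
#'   `climate_field`; its insolation is recomputed for `time_Ma = 0`
#'   unless the file carries an `insolation_rel` column).
#' @export
load_climate <- function(path, var_map = NULL) {
  df <- utils::read.csv(path)
  canonical <- c("lat", "lon", "temperature_C", "runoff_mm_yr", "land",
                 "basalt_fraction")
  cols <- stats::setNames(canonical, canonical)
  if (!is.null(var_map)) cols[names(var_map)] <- var_map
  required <- c("lat", "lon", "temperature_C", "runoff_mm_yr", "land")
  for (v in required) {
    if (!cols[[v]] %in% names(df))
      stop("missing variable `", cols[[v]], "` (", v, ") in ", path,
           call. = FALSE)
  }
  lat <- sort(unique(df[[cols[["lat"]]]]))
  lon <- sort(unique(df[[cols[["lon"]]]]))
  n_lat <- length(lat); n_lon <- length(lon)
  if (nrow(df) != n_lat * n_lon)
    stop("file does not cover a complete ", n_lat, " x ", n_lon,
         " grid (", nrow(df), " rows)", call. = FALSE)
  if (any(df[[cols[["runoff_mm_yr"]]]] < 0))
    stop("negative runoff in ", path, call. = FALSE)

  grid <- make_grid(n_lat, n_lon)
  idx <- cbind(match(df[[cols[["lat"]]]], grid$lat_centers),
               match(df[[cols[["lon"]]]], grid$lon_centers))
  if (any(is.na(idx)))
    stop("lat/lon values do not form an equal-angle grid", call. = FALSE)
  put <- function(values, default = NA_real_) {
    m <- matrix(default, n_lat, n_lon)
    m[idx] <- values
    m
  }
  grid$land_mask <- put(df[[cols[["land"]]]] != 0, FALSE)
  grid$basalt_fraction <-
    if (cols[["basalt_fraction"]] %in% names(df))
      put(df[[cols[["basalt_fraction"]]]])
    else ifelse(grid$land_mask, 0.2, NA_real_)
  insol <- if ("insolation_rel" %in% names(df)) put(df$insolation_rel)
           else insolation_factor(lat_matrix(grid), 0)
  climate <- structure(
    list(temperature = put(df[[cols[["temperature_C"]]]]),
         runoff = put(df[[cols[["runoff_mm_yr"]]]]),
         insolation_rel = insol),
    class = "climate_field")
  if (any(climate$runoff[!grid$land_mask] != 0))
    stop("ocean cells must carry zero runoff", call. = FALSE)
  list(grid = grid, climate = climate)
}

#' Write a vegetation state to CSV
#'
#' Long format with per-cell NPP, biomass, dominant functional type as an
#' integer code (0 = none, 1 = tropical, 2 = temperate, 3 = boreal with
#' the default types) and the habitability flag.
#'
#' @param state A `vegetation_state`.
#' @param grid The matching `world_grid`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_vegetation_csv <- function(state, grid, path) {
  df <- grid_to_long(grid)
  df$npp <- as.vector(state$npp)
  df$biomass <- as.vector(state$biomass)
  df$dominant_pft <- if (is.null(state$dominant_pft)) 0L
                     else as.vector(state$dominant_pft)
  df$habitable <- as.integer(state$habitable)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a weathering state to CSV
#'
#' @param weath A `weathering_state`.
#' @param grid The matching `world_grid`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_weathering_csv <- function(weath, grid, path) {
  df <- grid_to_long(grid)
  df$f_biota <- as.vector(weath$f_biota)
  df$sil_flux <- as.vector(weath$sil_flux)
  df$carb_flux <- as.vector(weath$carb_flux)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a run trajectory to CSV
#'
#' @param run A `vc_run`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_trajectory_csv <- function(run, path) {
  stopifnot(inherits(run, "vc_run"))
  utils::write.csv(run$trajectory, path, row.names = FALSE)
  invisible(path)
}
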