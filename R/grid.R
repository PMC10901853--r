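# Grid geometry and synthetic land-mask generators.
#
# Matrices are oriented rows = latitude bands (row 1 = southernmost),
# columns = longitude (periodic). Latitude is closed at the poles.

EARTH_RADIUS_M <- 6.371e6

deg2rad <- function(x) x * pi / 180

#' Create an equal-angle latitude-longitude world grid
#'
#' Cells are equal-angle; per-cell areas follow the spherical band formula
#' `2 pi R^2 (sin(lat2) - sin(lat1)) / n_lon`, so the areas depend only on
#' the latitude band, are symmetric about the equator, and sum exactly to
#' the surface area of the sphere. The land mask starts all ocean.
#'
#' @param n_lat,n_lon Number of latitude bands and longitude columns
#'   (both at least 2). The default resolution used throughout the package
#'   examples is 40 x 48.
#' @return An object of class `world_grid` with fields `n_lat`, `n_lon`,
#'   `lat_centers` (degrees, south to north), `lon_centers` (degrees,
#'   0-360), `cell_area` (m^2 matrix), `land_mask` (logical matrix) and
#'   `basalt_fraction` (matrix, `NA` off land).
#' @export
#' @examples
#' g <- make_grid(40, 48)
#' sum(g$cell_area) / (4 * pi * 6.371e6^2)  # 1
make_grid <- function(n_lat, n_lon) {
  if (!is.numeric(n_lat) || !is.numeric(n_lon) ||
      n_lat < 2 || n_lon < 2 ||
      n_lat != round(n_lat) || n_lon != round(n_lon))
    stop("`n_lat` and `n_lon` must be integers >= 2", call. = FALSE)
  n_lat <- as.integer(n_lat); n_lon <- as.integer(n_lon)
  lat_edges <- seq(-90, 90, length.out = n_lat + 1)
  lat_centers <- (lat_edges[-1] + lat_edges[-(n_lat + 1)]) / 2
  lon_width <- 360 / n_lon
  lon_centers <- (seq_len(n_lon) - 0.5) * lon_width
  band_area <- 2 * pi * EARTH_RADIUS_M^2 *
    (sin(deg2rad(lat_edges[-1])) - sin(deg2rad(lat_edges[-(n_lat + 1)]))) /
    n_lon
  structure(
    list(n_lat = n_lat, n_lon = n_lon,
         lat_centers = lat_centers, lon_centers = lon_centers,
         cell_area = matrix(band_area, n_lat, n_lon),
         land_mask = matrix(FALSE, n_lat, n_lon),
         basalt_fraction = matrix(NA_real_, n_lat, n_lon)),
    class = "world_grid")
}

#' @export
print.world_grid <- function(x, ...) {
  land <- sum(x$cell_area[x$land_mask])
  cat(sprintf("<world_grid %d x %d, land fraction %.3f>\n",
              x$n_lat, x$n_lon, land / sum(x$cell_area)))
  invisible(x)
}

lat_matrix <- function(grid) matrix(grid$lat_centers, grid$n_lat, grid$n_lon)

total_area <- function(grid) sum(grid$cell_area)

#' Total land area of a world
#'
#' @param grid A `world_grid`.
#' @return Land area in m^2.
#' @export
land_area <- function(grid) sum(grid$cell_area[grid$land_mask])

# 4-neighbour dilation of a logical matrix; longitude (columns) periodic,
# latitude (rows) closed.
dilate4 <- function(m) {
  n <- nrow(m); p <- ncol(m)
  up    <- rbind(m[-1, , drop = FALSE], rep(FALSE, p))
  down  <- rbind(rep(FALSE, p), m[-n, , drop = FALSE])
  left  <- cbind(m[, -1, drop = FALSE], m[, 1])
  right <- cbind(m[, p], m[, -p, drop = FALSE])
  m | up | down | left | right
}

# Multi-source BFS distance on the grid metric (4-neighbour, periodic
# longitude) from the TRUE cells of `sources`. Unreachable cells get Inf.
grid_bfs_distance <- function(sources) {
  d <- matrix(Inf, nrow(sources), ncol(sources))
  d[sources] <- 0
  assigned <- sources
  k <- 0L
  while (any(!assigned)) {
    k <- k + 1L
    newly <- dilate4(assigned) & !assigned
    if (!any(newly)) break
    d[newly] <- k
    assigned <- assigned | newly
  }
  d
}

#' Grid distance to the nearest coast
#'
#' Breadth-first 4-neighbour distance (longitude-periodic) from the ocean:
#' ocean cells are 0, coastal land cells 1, and so on inland. On an
#' all-land grid (no ocean to measure from) every cell is assigned the
#' grid diameter `n_lat + n_lon` as an effective infinity.
#'
#' @param grid A `world_grid` with its land mask set.
#' @return Integer-valued matrix of distances.
#' @export
distance_to_coast <- function(grid) {
  stopifnot(inherits(grid, "world_grid"))
  land <- grid$land_mask
  if (!any(land)) return(matrix(0, grid$n_lat, grid$n_lon))
  if (all(land)) return(matrix(grid$n_lat + grid$n_lon,
                               grid$n_lat, grid$n_lon))
  d <- grid_bfs_distance(!land)
  d[!land] <- 0
  d
}

# Label 4-connected land components by repeated region growing.
label_components <- function(land) {
  labels <- matrix(0L, nrow(land), ncol(land))
  next_label <- 0L
  remaining <- land
  while (any(remaining)) {
    next_label <- next_label + 1L
    seed <- matrix(FALSE, nrow(land), ncol(land))
    seed[which(remaining)[1]] <- TRUE
    repeat {
      grown <- dilate4(seed) & land
      if (identical(grown, seed)) break
      seed <- grown
    }
    labels[seed] <- next_label
    remaining <- remaining & !seed
  }
  labels
}

#' Count 4-connected land blocks
#'
#' @param grid A `world_grid`.
#' @return Number of connected land components (longitude-periodic).
#' @export
n_land_blocks <- function(grid) {
  max(label_components(grid$land_mask), 0L)
}

# Grow a connected blob: order candidate cells by BFS distance from the
# seed cell plus Unif(0, 0.75) jitter and cut the sorted list at the
# cumulative-area target. Jitter < 1 keeps every prefix connected (any
# geodesic predecessor of an included cell sorts strictly earlier).
grow_blob <- function(grid, seed_cell, target_area, candidates,
                      dist_from_seed, jitter) {
  score <- dist_from_seed + jitter
  score[!candidates] <- Inf
  ord <- order(score)
  ord <- ord[is.finite(score[ord])]
  if (length(ord) == 0) return(NULL)
  cum <- cumsum(grid$cell_area[ord])
  if (cum[length(cum)] < target_area) return(NULL)
  m <- which(cum >= target_area)[1]
  ord[seq_len(m)]
}

single_source <- function(grid, row, col) {
  s <- matrix(FALSE, grid$n_lat, grid$n_lon)
  s[row, col] <- TRUE
  s
}

#' Generate a single connected supercontinent
#'
#' Builds one connected land block (4-neighbour, longitude-periodic) whose
#' total area lands within one cell of `land_fraction` times the global
#' area. The block accretes around a seed cell at `center_lat` in order of
#' grid distance with a small seeded jitter, which makes it compact enough
#' to develop the deep continental interior that dries out under the
#' synthetic climate.
#'
#' @param grid A `world_grid`.
#' @param land_fraction Target land fraction of the global area, in (0, 1).
#' @param center_lat Latitude of the blob centre, degrees.
#' @param seed Integer seed; identical seeds give identical masks.
#' @param basalt_fraction Uniform basalt fraction assigned to land cells.
#' @return The grid with `land_mask` and `basalt_fraction` set.
#' @export
#' @examples
#' w <- make_supercontinent(make_grid(20, 24), 0.3, 0, seed = 1)
#' land_area(w) / sum(w$cell_area)
make_supercontinent <- function(grid, land_fraction, center_lat = 0,
                                seed = 1, basalt_fraction = 0.2) {
  stopifnot(inherits(grid, "world_grid"))
  if (land_fraction <= 0 || land_fraction >= 1)
    stop("`land_fraction` must be in (0, 1)", call. = FALSE)
  target <- land_fraction * total_area(grid)
  withr::with_seed(seed, {
    row <- which.min(abs(grid$lat_centers - center_lat))
    col <- sample.int(grid$n_lon, 1)
    d <- grid_bfs_distance(single_source(grid, row, col))
    jitter <- matrix(stats::runif(grid$n_lat * grid$n_lon, 0, 0.75),
                     grid$n_lat, grid$n_lon)
    cells <- grow_blob(grid, c(row, col), target,
                       candidates = matrix(TRUE, grid$n_lat, grid$n_lon),
                       dist_from_seed = d, jitter = jitter)
  })
  if (is.null(cells))
    stop("land_fraction unreachable on this grid", call. = FALSE)
  mask <- matrix(FALSE, grid$n_lat, grid$n_lon)
  mask[cells] <- TRUE
  grid$land_mask <- mask
  grid$basalt_fraction <- ifelse(mask, basalt_fraction, NA_real_)
  grid
}

#' Generate dispersed continental blocks
#'
#' Places `n_blocks` disjoint land blocks (each 4-connected, separated by
#' at least one ocean cell) totalling, within one cell, `land_fraction`
#' times the global area. Blocks grow round-robin inside non-overlapping
#' "core" regions around well-separated seed cells, so that for the same
#' `land_fraction` the total land area matches [make_supercontinent()].
#' With `n_blocks = 1` the construction degenerates to the supercontinent
#' contract.
#'
#' @inheritParams make_supercontinent
#' @param n_blocks Number of disjoint blocks (>= 1).
#' @param max_seed_lat Restrict block seed cells to absolute latitudes at
#'   or below this value (degrees). The default 65 allows high-latitude
#'   blocks; use a tropical band (for example 35) to emulate the breakup
#'   of a low-latitude supercontinent while holding the latitudinal
#'   footprint roughly fixed.
#' @return The grid with `land_mask` and `basalt_fraction` set.
#' @export
make_dispersed <- function(grid, land_fraction, n_blocks = 4, seed = 1,
                           basalt_fraction = 0.2, max_seed_lat = 65) {
  stopifnot(inherits(grid, "world_grid"))
  if (land_fraction <= 0 || land_fraction >= 1)
    stop("`land_fraction` must be in (0, 1)", call. = FALSE)
  if (n_blocks < 1 || n_blocks != round(n_blocks))
    stop("`n_blocks` must be a positive integer", call. = FALSE)
  if (n_blocks == 1)
    return(make_supercontinent(grid, land_fraction, center_lat = 0,
                               seed = seed,
                               basalt_fraction = basalt_fraction))
  target <- land_fraction * total_area(grid)
  n <- grid$n_lat; p <- grid$n_lon
  ok_lat <- abs(grid$lat_centers) <= min(max_seed_lat, 65)
  if (!any(ok_lat))
    stop("`max_seed_lat` excludes every latitude band", call. = FALSE)
  cand_rows <- which(ok_lat)

  withr::with_seed(seed, {
    # Seed placement: keep the draw (of 200) maximising the minimum
    # pairwise separation in the periodic grid metric.
    best <- NULL; best_sep <- -1
    for (try in 1:200) {
      rows <- sample(cand_rows, n_blocks, replace = TRUE)
      cols <- sample.int(p, n_blocks, replace = TRUE)
      sep <- Inf
      for (i in seq_len(n_blocks - 1)) for (j in (i + 1):n_blocks) {
        dr <- abs(rows[i] - rows[j])
        dc <- abs(cols[i] - cols[j]); dc <- min(dc, p - dc)
        sep <- min(sep, dr + dc)
      }
      if (sep > best_sep) { best_sep <- sep; best <- cbind(rows, cols) }
    }
    seeds <- best
    dists <- lapply(seq_len(n_blocks), function(b)
      grid_bfs_distance(single_source(grid, seeds[b, 1], seeds[b, 2])))
    jitters <- lapply(seq_len(n_blocks), function(b)
      matrix(stats::runif(n * p, 0, 0.75), n, p))
  })

  # Core of block b: strictly closer (by >= 2) to its own seed than to any
  # other; guarantees a >= 1-cell ocean gap between grown blocks.
  other_min <- function(b) {
    m <- matrix(Inf, n, p)
    for (bb in setdiff(seq_len(n_blocks), b)) m <- pmin(m, dists[[bb]])
    m
  }
  lists <- vector("list", n_blocks)
  for (b in seq_len(n_blocks)) {
    core <- dists[[b]] <= other_min(b) - 2
    score <- dists[[b]] + jitters[[b]]
    score[!core] <- Inf
    ord <- order(score)
    lists[[b]] <- ord[is.finite(score[ord])]
  }
  if (any(vapply(lists, length, 1L) == 0))
    stop("cannot place ", n_blocks, " disjoint blocks on this grid",
         call. = FALSE)

  mask <- matrix(FALSE, n, p)
  area <- 0
  ptr <- rep(1L, n_blocks)
  repeat {
    advanced <- FALSE
    for (b in seq_len(n_blocks)) {
      if (ptr[b] > length(lists[[b]])) next
      cell <- lists[[b]][ptr[b]]
      ptr[b] <- ptr[b] + 1L
      mask[cell] <- TRUE
      area <- area + grid$cell_area[cell]
      advanced <- TRUE
      if (area >= target) break
    }
    if (area >= target) break
    if (!advanced)
      stop("cannot reach land_fraction with ", n_blocks,
           " disjoint blocks on this grid", call. = FALSE)
  }
  if (any(ptr == 1L))
    stop("cannot place ", n_blocks,
         " non-empty blocks at this land_fraction", call. = FALSE)
  grid$land_mask <- mask
  grid$basalt_fraction <- ifelse(mask, basalt_fraction, NA_real_)
  grid
}
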