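# Shared fixtures and independent oracles.

# Independent stack-based flood fill (4-neighbour, longitude-periodic);
# deliberately distinct from the package's dilation-based labelling.
oracle_n_components <- function(mask) {
  n <- nrow(mask); p <- ncol(mask)
  lab <- matrix(0L, n, p)
  cur <- 0L
  for (i in seq_len(n)) for (j in seq_len(p)) {
    if (mask[i, j] && lab[i, j] == 0L) {
      cur <- cur + 1L
      stack <- list(c(i, j))
      lab[i, j] <- cur
      while (length(stack) > 0) {
        c0 <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
          ii <- c0[1] + d[1]
          if (ii < 1 || ii > n) next
          jj <- ((c0[2] + d[2] - 1) %% p) + 1
          if (mask[ii, jj] && lab[ii, jj] == 0L) {
            lab[ii, jj] <- cur
            stack[[length(stack) + 1]] <- c(ii, jj)
          }
        }
      }
    }
  }
  cur
}

# A small world with a hand-set land mask (rows = lat, cols = lon).
toy_world <- function(n_lat = 6, n_lon = 8, land_cells = NULL,
                      basalt = 0.2) {
  g <- make_grid(n_lat, n_lon)
  if (!is.null(land_cells)) {
    g$land_mask[land_cells] <- TRUE
    g$basalt_fraction <- ifelse(g$land_mask, basalt, NA_real_)
  }
  g
}

# A uniform hand-built climate on a given world (no synthetic shaping).
flat_climate <- function(grid, temperature = 20, runoff = 1000,
                         insolation = 1) {
  structure(list(
    temperature = matrix(temperature, grid$n_lat, grid$n_lon),
    runoff = ifelse(grid$land_mask, runoff, 0),
    insolation_rel = matrix(insolation, grid$n_lat, grid$n_lon)),
    class = "climate_field")
}

# Type-7 quantile recomputed from first principles on the sorted sample.
oracle_quantile7 <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}
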