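test_that("insolation factor is normalised at the present-day equator", {
  expect_equal(insolation_factor(0, 0), 1)
  # luminosity dimming: direct evaluation of 1 / (1 + 0.4 t / 4570)
  expect_equal(insolation_factor(0, 541), 1 / (1 + 0.4 * 541 / 4570))
  expect_equal(round(insolation_factor(0, 541), 3), 0.955)
  expect_lt(insolation_factor(60, 0), insolation_factor(30, 0))
  expect_error(insolation_factor(95, 0), "lat")
  expect_error(insolation_factor(0, -1), "time_Ma")
})

test_that("leaf respiration scales as 24/h", {
  expect_equal(leaf_respiration_rate(12, 0.015), 0.03)
  expect_equal(leaf_respiration_rate(24, 0.07), 0.07)
  expect_equal(leaf_respiration_rate(12, 0), 0)
  expect_error(leaf_respiration_rate(0, 0.015), "h")
  expect_error(leaf_respiration_rate(-2, 0.015), "h")
})

test_that("oxygen-driven turnover is clamped, monotone, and hits its endpoints", {
  expect_identical(turnover_fraction(0.35), 0.2)
  expect_identical(turnover_fraction(0.10), 0.08)
  expect_equal(turnover_fraction(0.21), 0.1012)
  o2 <- seq(0, 0.6, by = 0.005)
  tau <- turnover_fraction(o2)
  expect_true(all(tau >= 0.08 & tau <= 0.2))
  expect_true(all(diff(tau) >= 0))
})

test_that("cell NPP obeys the habitability rule and its limitation factors", {
  pfts <- default_pfts()
  p <- photosynthesis_params()
  # zero under zero runoff or deep cold, for every functional type
  for (pft in pfts) {
    expect_equal(npp_cell(25, 0, 1, 1, 0.21, pft, p), 0)
    expect_equal(npp_cell(-12, 2000, 1, 1, 0.21, pft, p), 0)
    expect_equal(npp_cell(pft$t_max + 1, 2000, 1, 1, 0.21, pft, p), 0)
  }
  # optimal tropical cell at high CO2 hits the ceiling
  expect_equal(npp_cell(27, 5000, 1, 16, 0.21, pfts$tropical, p), p$npp_max)
  # present-day oxygen leaves the photorespiration factor at exactly 1:
  # the kernel value matches the explicit product without the O2 term
  g_t <- 1; runoff <- 300
  manual <- p$npp_max * g_t * (runoff / (runoff + p$runoff_half)) * 1 *
    (1 * (1 + p$k_co2) / (1 + p$k_co2)) * (1 - p$s)
  expect_equal(npp_cell(27, runoff, 1, 1, 0.21, pfts$tropical, p), manual)
  # monotone in runoff and insolation
  r_seq <- c(5, 20, 80, 320, 1280)
  vals <- npp_cell(27, r_seq, 0.9, 1, 0.21, pfts$tropical, p)
  expect_true(all(diff(vals) > 0))
  i_seq <- c(0.2, 0.5, 0.8, 1)
  vals <- npp_cell(27, 300, i_seq, 1, 0.21, pfts$tropical, p)
  expect_true(all(diff(vals) > 0))
})

test_that("dominant type selection prefers the listed order on ties", {
  g <- toy_world(5, 6, land_cells = cbind(rep(1:5, 6), rep(1:6, each = 5)))
  g$land_mask[, 6] <- FALSE       # keep one ocean column
  cl <- flat_climate(g, temperature = 27, runoff = 800)
  ng <- npp_grid(cl, forcing_state(), 1, g)
  expect_true(all(ng$dominant_pft[g$land_mask] == 1))  # warm: tropical
  # temperate and boreal share a plateau at 20 C; the tie goes to temperate
  cl2 <- flat_climate(g, temperature = 20, runoff = 800)
  ng2 <- npp_grid(cl2, forcing_state(), 1, g)
  expect_true(all(ng2$dominant_pft[g$land_mask] == 2))
  # ocean cells carry no vegetation
  expect_true(all(ng$npp[!g$land_mask] == 0))
  expect_true(all(ng$dominant_pft[!g$land_mask] == 0))
  # all-ocean world
  go <- toy_world(4, 5)
  ngo <- npp_grid(flat_climate(go), forcing_state(), 1, go)
  expect_true(all(ngo$npp == 0))
})

test_that("steady biomass matches NPP/turnover and the analytic iteration count", {
  seed_b <- 2.5e4; tol <- 0.01
  for (case in 1:4) {
    set.seed(100 + case)
    o2 <- c(0.15, 0.21, 0.28, 0.35)[case]
    npp <- matrix(stats::runif(60, 0, 3200), 6, 10)
    npp[sample(60, 12)] <- 0
    st <- spin_to_steady_biomass(npp, o2, seed_b, tol)
    tau <- turnover_fraction(o2)
    expect_equal(st$turnover, tau)
    bstar <- npp / tau
    hab <- npp > 0
    expect_true(all(abs(st$biomass[hab] - bstar[hab]) <=
                      tol / (1 - tol) * bstar[hab]))
    expect_true(all(st$biomass[!hab] == 0))
    expect_identical(st$habitable, hab)
    # analytic geometric count: first n with (1-tau)^n |B0-B*| <= tol B*
    per_cell <- ceiling(log(tol * bstar[hab] / abs(seed_b - bstar[hab])) /
                          log(1 - tau))
    per_cell[!is.finite(per_cell)] <- 1
    expect_lte(abs(st$iterations_to_converge - max(pmax(per_cell, 1))), 1)
  }
})

test_that("spin-up is bit-reproducible and degenerate inputs behave", {
  set.seed(42)
  npp <- matrix(stats::runif(30, 0, 2000), 5, 6)
  a <- spin_to_steady_biomass(npp, 0.21)
  b <- spin_to_steady_biomass(npp, 0.21)
  expect_identical(a$biomass, b$biomass)
  expect_identical(a$iterations_to_converge, b$iterations_to_converge)
  # all-zero NPP: nothing grows, nothing iterates
  z <- spin_to_steady_biomass(matrix(0, 3, 3), 0.21)
  expect_true(all(z$biomass == 0))
  expect_equal(sum(z$habitable), 0)
  # non-convergence raises with diagnostics
  expect_error(spin_to_steady_biomass(npp, 0.21, tol = 1e-12, max_iter = 5),
               "did not converge")
})

test_that("habitable area is area-weighted and relative vegetation is linear", {
  # four equal-area land cells straddling the equator; two occupied
  g <- toy_world(4, 4, land_cells = cbind(c(2, 2, 3, 3), c(1, 2, 1, 2)))
  npp <- matrix(0, 4, 4)
  npp[2, 1] <- 500; npp[3, 2] <- 800
  st <- spin_to_steady_biomass(npp, 0.21)
  ha <- habitable_area(st, g)
  expect_equal(ha$fraction, 0.5)
  expect_equal(ha$area_m2, g$cell_area[2, 1] + g$cell_area[3, 2])
  # empty state
  st0 <- spin_to_steady_biomass(matrix(0, 4, 4), 0.21)
  ha0 <- habitable_area(st0, g)
  expect_equal(ha0$fraction, 0)
  expect_equal(ha0$area_m2, 0)
  expect_error(habitable_area(st0, toy_world(4, 4)), "zero land")
  # relative vegetation: identity at baseline, linear in biomass
  base <- total_biomass(st, g)
  expect_equal(relative_vegetation(st, g, base), 1)
  st2 <- st; st2$biomass <- st$biomass * 2
  expect_equal(relative_vegetation(st2, g, base), 2)
  expect_equal(relative_vegetation(st0, g, base), 0)
  expect_error(relative_vegetation(st, g, 0), "baseline_total")
})
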