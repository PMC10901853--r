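# Coupled carbon cycle: climate mapping, calibration, stepping, steady
# states. Coupled runs here use small grids; the full-resolution
# experiments live in the acceptance suite.

ref_setup <- function(n_lat = 16, n_lon = 20, lf = 0.3, seed = 2) {
  world <- make_supercontinent(make_grid(n_lat, n_lon), lf, 0, seed = seed)
  forcing <- forcing_state()
  model <- calibrate_reference(world, forcing)
  list(world = world, forcing = forcing, model = model)
}

test_that("temperature map is logarithmic in CO2", {
  cfg <- coupler_config()
  expect_equal(gast_from_rco2(1, cfg), 14)
  expect_equal(gast_from_rco2(2, cfg), 19)
  expect_equal(gast_from_rco2(4, cfg), 24)
  expect_equal(gast_from_rco2(0.5, cfg), 9)
  expect_error(gast_from_rco2(0, cfg), "rco2")
})

test_that("carbon tendency is the signed sum of source and sinks", {
  cfg <- coupler_config()
  st <- carbon_state(1, cfg)
  mk_weath <- function(sil, locb, mocb) {
    structure(list(total_sil = sil, total_carb = 1e12,
                   burial_land = locb, burial_marine = mocb),
              class = "weathering_state")
  }
  f <- forcing_state()
  # balanced budget: zero tendency
  w0 <- mk_weath(0.8 * cfg$f_degas_ref, 0.1 * cfg$f_degas_ref,
                 0.1 * cfg$f_degas_ref)
  expect_equal(carbon_tendency(st, w0, f, cfg), 0)
  # degassing times 1.25 with fixed sinks raises the tendency by 0.25 F
  f125 <- forcing_state(degassing_rel = 1.25)
  expect_equal(carbon_tendency(st, w0, f125, cfg) -
                 carbon_tendency(st, w0, f, cfg), 0.25 * cfg$f_degas_ref)
  # worked micro-example: 8 - (3 + 1.5 + 0.5) = 3 Tmol/yr
  w1 <- mk_weath(3e12, 1.5e12, 0.5e12)
  expect_equal(carbon_tendency(st, w1, f, cfg), 3e12)
  # carbonate weathering is carbon-neutral: changing it changes nothing
  w2 <- w1; w2$total_carb <- 5e12
  expect_equal(carbon_tendency(st, w2, f, cfg),
               carbon_tendency(st, w1, f, cfg))
})

test_that("calibration balances the reference budget with the stated shares", {
  s <- ref_setup()
  cfg <- s$model$config
  ref <- s$model$reference
  expect_lt(abs(ref$tendency) / cfg$f_degas_ref, 1e-10)
  expect_equal(ref$total_sil / cfg$f_degas_ref, 0.8)
  expect_equal(ref$burial_land / cfg$f_degas_ref, 0.1)
  expect_equal(ref$burial_marine / cfg$f_degas_ref, 0.1)
  expect_equal(ref$v_rel, 1)
  # idempotent: calibrating with the calibrated constants reproduces them
  m2 <- calibrate_reference(s$world, s$forcing, s$model$params, cfg)
  expect_equal(m2$params$weathering$k_sil_granite,
               s$model$params$weathering$k_sil_granite)
  expect_equal(m2$params$weathering$k_locb,
               s$model$params$weathering$k_locb)
  expect_equal(m2$baseline_total, s$model$baseline_total)
  # uninhabitable reference world cannot calibrate: polar-band land only
  cold <- make_grid(16, 20)
  cold$land_mask[1:2, ] <- TRUE   # lat bands below -67 deg, far below -10 C
  cold$basalt_fraction <- ifelse(cold$land_mask, 0.2, NA_real_)
  expect_error(calibrate_reference(cold, s$forcing), "no vegetation")
})

test_that("a balanced state steps in place and the timestep grows", {
  s <- ref_setup()
  st <- carbon_state(1, s$model$config)
  out <- step_coupled(st, s$forcing, s$world, s$model)
  expect_equal(out$state$rco2, 1, tolerance = 1e-8)
  expect_equal(out$status, "ok")
  expect_gt(out$dt_next, s$model$config$dt_init)
})

test_that("an oversized timestep is shrunk back to stability", {
  s <- ref_setup()
  f <- forcing_state(degassing_rel = 1.5)
  st <- carbon_state(1, s$model$config)
  out <- step_coupled(st, f, s$world, s$model, dt = 1e9)
  expect_gt(out$n_retries, 0)
  expect_lte(abs(out$state$rco2 - 1), s$model$config$stab_threshold + 1e-12)
})

test_that("one coupled step equals the hand-composed pipeline on a toy world", {
  s <- ref_setup(n_lat = 5, n_lon = 6, lf = 0.35, seed = 8)
  f <- forcing_state(degassing_rel = 1.3)
  cfg <- s$model$config
  st <- carbon_state(1.1, cfg)
  out <- step_coupled(st, f, s$world, s$model, dt = cfg$dt_init)
  # explicit composition: climate -> spin -> enhancement -> sums -> Euler
  cl <- synth_climate(s$world, f, gast_offset = st$gast - cfg$t_ref,
                      params = s$model$params$climate)
  ng <- npp_grid(cl, f, st$rco2, s$world, s$model$params$pfts,
                 s$model$params$photo)
  veg <- spin_to_steady_biomass(ng$npp, f$o2_mixing_ratio,
                                cfg$seed_biomass, cfg$veg_tol)
  w <- global_weathering(cl, veg, s$world, st$rco2,
                         s$model$params$weathering, s$model$baseline_total)
  tend <- f$degassing_rel * cfg$f_degas_ref -
    (w$total_sil + w$burial_land + w$burial_marine)
  expect_equal(out$tendency, tend)
  expect_equal(out$state$atm_ocean_C,
               st$atm_ocean_C + out$dt_used * tend)
  expect_equal(out$weath$total_sil, w$total_sil)
})

test_that("the calibrated world is a fixed point and degassing shifts it up", {
  s <- ref_setup()
  r1 <- run_to_steady(carbon_state(1, s$model$config), s$forcing,
                      s$world, s$model)
  expect_true(r1$success)
  expect_equal(r1$steady$rco2, 1, tolerance = 1e-6)
  r2 <- run_to_steady(carbon_state(1, s$model$config),
                      forcing_state(degassing_rel = 1.25),
                      s$world, s$model)
  expect_true(r2$success)
  expect_gt(r2$steady$rco2, 1)
  # trajectory bookkeeping: inventory change equals integrated tendency
  tr <- r2$trajectory
  n <- nrow(tr)
  integrated <- sum(tr$tendency[-n] * tr$dt_yr[-n])
  cfg <- s$model$config
  expect_equal(tr$rco2[n] * cfg$c_ref - tr$rco2[1] * cfg$c_ref,
               integrated, tolerance = 1e-10)
})

test_that("steady state agrees with a scalar bisection of the carbon balance", {
  s <- ref_setup()
  f <- forcing_state(degassing_rel = 1.25)
  run <- run_to_steady(carbon_state(1, s$model$config), f, s$world, s$model)
  balance <- function(r) {
    st <- carbon_state(r, s$model$config)
    cl <- synth_climate(s$world, f, gast_offset = st$gast -
                          s$model$config$t_ref,
                        params = s$model$params$climate)
    veg <- grow_vegetation(cl, f, r, s$world, s$model$params$pfts,
                           s$model$params$photo)
    w <- global_weathering(cl, veg, s$world, r, s$model$params$weathering,
                           s$model$baseline_total)
    carbon_tendency(st, w, f, s$model$config)
  }
  root <- stats::uniroot(balance, c(0.5, 4), tol = 1e-6)$root
  expect_equal(run$steady$rco2, root, tolerance = 0.02)
})

test_that("identical configuration gives identical trajectories", {
  s <- ref_setup()
  f <- forcing_state(degassing_rel = 0.9)
  r1 <- run_to_steady(carbon_state(1, s$model$config), f, s$world, s$model)
  r2 <- run_to_steady(carbon_state(1, s$model$config), f, s$world, s$model)
  expect_identical(r1$trajectory, r2$trajectory)
})

test_that("extreme degassing is classified as a failure, not an error", {
  s <- ref_setup()
  f <- forcing_state(degassing_rel = 20)
  run <- run_to_steady(carbon_state(1, s$model$config), f, s$world, s$model)
  expect_false(run$success)
  expect_true(run$failure_mode %in% c("runaway_hot", "extinction"))
  expect_true(nrow(run$trajectory) >= 1)
})

test_that("a forcing history carries the carbon state between epochs", {
  s <- ref_setup()
  hist <- data.frame(time_Ma = c(200, 100), o2_mixing_ratio = 0.21,
                     degassing_rel = c(1.1, 0.95))
  out <- run_history(hist, s$world, s$model)
  expect_equal(nrow(out$summary), 2)
  expect_true(all(out$summary$success))
  expect_gt(out$summary$rco2[1], 1)
  expect_lt(out$summary$rco2[2], out$summary$rco2[1])
})
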