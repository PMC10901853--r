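# CLI layer: configuration validation, artifact contracts, replayability.

write_cfg <- function(cfg, dir) {
  path <- file.path(dir, "config.yml")
  yaml::write_yaml(cfg, path)
  path
}

small_cfg <- function(out_dir) {
  list(world = list(generator = "supercontinent", n_lat = 12, n_lon = 16,
                    land_fraction = 0.3, seed = 2),
       coupler = list(max_steps = 200),
       forcing = list(degassing_rel = 1.1),
       output_dir = out_dir, verbosity = 0)
}

test_that("unknown and invalid configuration keys fail before any compute", {
  dir <- withr::local_tempdir()
  p1 <- write_cfg(list(wrold = list(generator = "supercontinent")), dir)
  expect_error(read_run_config(p1), "wrold")
  p2 <- write_cfg(list(world = list(generatr = "x")), dir)
  expect_error(read_run_config(p2), "world.generatr")
  p3 <- write_cfg(list(photosynthesis = list(runoff_half = -5)), dir)
  expect_error(read_run_config(p3), "runoff_half")
  expect_equal(cli_validate_config(p3), 2L)
  expect_equal(cli_simulate(p3), 2L)
  p4 <- write_cfg(list(weathering = list(r = 0.7)), dir)
  expect_error(read_run_config(p4), "r")
  # the shipped template is valid
  tmpl <- system.file("extdata", "demo_config.yml", package = "vegcarb")
  expect_equal(cli_validate_config(tmpl), 0L)
})

test_that("simulate writes its declared artifacts and exits 0", {
  dir <- withr::local_tempdir()
  out <- file.path(dir, "out")
  p <- write_cfg(small_cfg(out), dir)
  expect_equal(cli_simulate(p), 0L)
  for (f in c("trajectory.csv", "world_climate.csv",
              "final_vegetation.csv", "final_weathering.csv",
              "resolved_config.yml", "run.log"))
    expect_true(file.exists(file.path(out, f)))
  tr <- utils::read.csv(file.path(out, "trajectory.csv"))
  expect_true(all(c("time_yr", "rco2", "gast_C", "v_rel",
                    "habitable_fraction", "F_sil", "dt_yr") %in% names(tr)))
  expect_gt(tr$rco2[nrow(tr)], 1)  # degassing 1.1 ends above reference CO2
})

test_that("a run replayed from its emitted config is byte-identical", {
  dir <- withr::local_tempdir()
  out1 <- file.path(dir, "a"); out2 <- file.path(dir, "b")
  p <- write_cfg(small_cfg(out1), dir)
  expect_equal(cli_simulate(p), 0L)
  expect_equal(cli_simulate(file.path(out1, "resolved_config.yml"),
                            out_dir = out2), 0L)
  expect_identical(readLines(file.path(out1, "trajectory.csv")),
                   readLines(file.path(out2, "trajectory.csv")))
})

test_that("compare-worlds contrasts the two configured geographies", {
  dir <- withr::local_tempdir()
  out <- file.path(dir, "cmp")
  cfg <- small_cfg(out)
  cfg$compare <- list(world_b = list(generator = "dispersed", n_lat = 12,
                                     n_lon = 16, n_blocks = 3,
                                     land_fraction = 0.3, seed = 2))
  p <- write_cfg(cfg, dir)
  expect_equal(cli_compare_worlds(p), 0L)
  tab <- utils::read.csv(file.path(out, "comparison.csv"))
  expect_setequal(tab$quantity, c("habitable_fraction", "steady_rco2",
                                  "steady_gast", "total_weathering"))
  # identical generators: every difference is zero
  cfg2 <- small_cfg(file.path(dir, "cmp2"))
  cfg2$compare <- list(world_b = cfg2$world)
  p2 <- write_cfg(cfg2, dir)
  expect_equal(cli_compare_worlds(p2), 0L)
  tab2 <- utils::read.csv(file.path(dir, "cmp2", "comparison.csv"))
  expect_true(all(tab2$difference == 0))
  # unequal land fractions are rejected
  cfg3 <- small_cfg(file.path(dir, "cmp3"))
  cfg3$compare <- list(world_b = list(generator = "dispersed",
                                      land_fraction = 0.4))
  expect_equal(cli_compare_worlds(write_cfg(cfg3, dir)), 2L)
})

test_that("ensemble subcommand writes summary, params and envelope tables", {
  dir <- withr::local_tempdir()
  out <- file.path(dir, "ens")
  cfg <- small_cfg(out)
  cfg$ensemble <- list(n_members = 5, degassing_range = c(0.9, 1.1),
                       lithology_shift = c(-0.1, 0.1), rng_seed = 4)
  p <- write_cfg(cfg, dir)
  expect_equal(cli_ensemble(p), 0L)
  summ <- utils::read.csv(file.path(out, "ensemble_summary.csv"))
  expect_equal(nrow(summ), 5)
  pars <- utils::read.csv(file.path(out, "ensemble_params.csv"))
  expect_equal(nrow(pars), 5)
  env <- utils::read.csv(file.path(out, "ensemble_envelope.csv"))
  expect_equal(env$quantile, c("q2.5", "q50", "q97.5"))
  # a different seed draws different parameters under the same schema
  cfg$ensemble$rng_seed <- 5
  cfg$output_dir <- file.path(dir, "ens2")
  expect_equal(cli_ensemble(write_cfg(cfg, dir)), 0L)
  pars2 <- utils::read.csv(file.path(dir, "ens2", "ensemble_params.csv"))
  expect_identical(names(pars2), names(pars))
  expect_false(identical(pars2$degassing_rel, pars$degassing_rel))
})

test_that("make-world emits a loadable world-climate file", {
  dir <- withr::local_tempdir()
  out <- file.path(dir, "mw")
  p <- write_cfg(small_cfg(out), dir)
  expect_equal(cli_make_world(p), 0L)
  back <- load_climate(file.path(out, "world_climate.csv"))
  expect_equal(back$grid$n_lat, 12)
  expect_gt(land_area(back$grid), 0)
})
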