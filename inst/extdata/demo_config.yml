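# vegcarb run configuration template.
# Every key is optional; omitted keys take the defaults shown here
# (see default_run_config()). Unknown keys are rejected.

world:
  generator: supercontinent   # supercontinent | dispersed | file
  n_lat: 20                   # latitude bands (package default 40)
  n_lon: 24                   # longitude columns (package default 48)
  land_fraction: 0.3          # fraction of the global area that is land
  center_lat: 0               # supercontinent centre latitude, deg
  n_blocks: 4                 # blocks for the dispersed generator
  seed: 1                     # mask-generator seed (deterministic)
  basalt_fraction: 0.2        # uniform basalt share of land lithology
  # path: my_world.csv        # for generator: file (long-format CSV)

forcing:
  time_Ma: 0                  # Myr before present (solar luminosity)
  o2_mixing_ratio: 0.21       # atmospheric O2 (fire-driven turnover)
  degassing_rel: 1.0          # degassing relative to the reference flux

photosynthesis:
  npp_max: 3200               # productivity ceiling, gC/m2/yr
  a: 0.015                    # leaf-respiration coefficient
  h: 12                       # daylight hours (s = 24/h * a)
  k_co2: 0.5                  # CO2 half-saturation (relative CO2 units)
  o2_sensitivity: 0.3         # photorespiration slope
  runoff_half: 30             # water half-saturation, mm/yr

weathering:
  npp_slope: 0.0005           # enhancement slope, per gC/m2/yr
  f_minbiota: 0.32            # abiotic enhancement at relative CO2 = 1
  r: 0.25                     # abiotic CO2 exponent, in [0.25, 0.5]
  act_energy_granite: 63000   # Arrhenius activation energy, J/mol
  act_energy_basalt: 50000

climate:
  t_eq: 27                    # equatorial temperature, deg C
  dt_pole: 45                 # equator-to-pole drop, deg C
  interior_cooling: 0.8       # continentality, deg C per inland cell
  interior_cooling_max: 8
  interior_efold: 3           # coastal-moisture e-folding, cells
  d_arid: 6                   # full aridity beyond this inland distance
  runoff_floor: 20            # runoff below this (mm/yr) is arid
  hydro_sens: 0.03            # runoff change per deg C of warming
  polar_amp_max: 2            # polar amplification of the offset

coupler:
  dt_init: 1.0e5              # yr (~100 kyr steps)
  dt_min: 1.0e3
  dt_max: 1.0e6
  step_shrink: 0.5            # dt factor on a rejected step
  step_grow: 1.2              # dt factor after an accepted step
  stab_threshold: 0.02        # max relative CO2 change per step
  steady_tol: 1.0e-3          # steady when |tendency| < tol * F_degas
  max_steps: 400
  co2_bounds: [0.05, 20]      # runaway classification bounds
  climate_sensitivity: 5      # deg C per CO2 doubling
  t_ref: 14                   # GAST at relative CO2 = 1, deg C
  seed_biomass: 2.5e4         # vegetation seed, gC/m2
  veg_tol: 0.01               # vegetation convergence (<1% rule)

ensemble:
  n_members: 5
  degassing_range: [0.75, 1.25]
  lithology_shift: [-0.2, 0.2]
  rng_seed: 1

# compare:                    # for the compare-worlds subcommand
#   world_b:
#     generator: dispersed
#     n_blocks: 4
#     land_fraction: 0.3      # must equal world.land_fraction

output_dir: vegcarb_out
rng_seed: 1
verbosity: 1
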