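# Fixtures built in code for the test suite.

# A randomized laboratory profile drawn from the current RNG state; used by
# property tests that compare optimal_batch() against a brute-force oracle.
random_lab_profile <- function() {
  tests_per_kit <- sample(2:30, 1)
  controls <- sample(0:min(2, tests_per_kit - 1), 1)
  kit <- kit_configuration(tests_per_kit,
                           kit_price = runif(1, 10, 1500),
                           controls_per_run = controls)
  disposables <- lapply(seq_len(sample(1:3, 1)), function(i) {
    lab_cost_line(paste("disp", i), per_run = runif(1, 0, 5),
                  per_specimen = runif(1, 0, 2))
  })
  labour <- lapply(seq_len(sample(1:4, 1)), function(i) {
    labour_step(paste("step", i), per_run_minutes = runif(1, 0, 120),
                per_specimen_minutes = runif(1, 0, 30),
                hourly_wage = runif(1, 0.3, 2))
  })
  lab_cost_profile(kit, disposables, labour,
                   facilities_equipment_per_specimen = runif(1, 0, 10))
}

# Brute-force per-specimen lab cost, written from first principles and
# independent of lab_cost_per_specimen(): whole kits to cover specimens plus
# controls, fixed per-run dollars amortized over the batch, marginal
# per-specimen dollars, facilities constant.
oracle_lab_total <- function(n, profile) {
  kit <- profile$kit
  kits <- ceiling((n + kit$controls_per_run) / kit$tests_per_kit)
  per_run <- sum(vapply(profile$disposables, `[[`, numeric(1), "per_run")) +
    sum(vapply(profile$labour_steps, function(st)
      st$per_run_minutes * st$hourly_wage / 60, numeric(1)))
  per_spec <- sum(vapply(profile$disposables, `[[`, numeric(1), "per_specimen")) +
    sum(vapply(profile$labour_steps, function(st)
      st$per_specimen_minutes * st$hourly_wage / 60, numeric(1)))
  kits * kit$kit_price / n + per_run / n + per_spec +
    profile$facilities_equipment_per_specimen
}

# A small catchment with controllable totals.
toy_catchment <- function(totals, counts, site = "toy") {
  # encode each desired total as pure transportation fare
  catchment(site, data.frame(
    name = paste("loc", seq_along(totals)),
    distance_km = seq_along(totals),
    round_trip_fare = totals, lodging_nights = 0, nightly_rate = 0,
    food_cost_total = 0, days_away = 0, daily_wage = 0,
    patient_count = counts))
}

demo_config_path <- function() {
  system.file("extdata", "demo_network.yaml", package = "vlcost")
}
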