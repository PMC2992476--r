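#' Synthetic network generator configuration
#'
#' Parameters of the seeded generator. The defaults emulate the structure of
#' a centralized testing service in a low-resource, low-prevalence setting:
#' a majority of patients living near their collection site with a heavy
#' lognormal tail of remote patients, an approximately linear fare-distance
#' relationship with multiplicative noise, visit lengths (and hence lodging
#' and lost income) tiered by distance up to three days, monthly incomes of
#' $90-117, per-site results-delivery fractions on 0.81-1.00, and a mix of
#' ground and air specimen shipment. The numeric defaults were calibrated
#' once so that, at large patient counts, roughly 65% of patients bear a
#' visit cost under $5 and roughly 95% under $10, and then frozen.
#'
#' @param seed integer seed; every sampled value derives from it.
#' @param n_sites number of collection sites, >= 1.
#' @param patients_per_site patients per site catchment, >= 1.
#' @param near_fraction fraction of patients living near the site, in (0,1).
#' @param near_distance_km range (min, max) of near-patient distances, km.
#' @param remote_distance_meanlog,remote_distance_sdlog lognormal parameters
#'   of remote-patient distances, km.
#' @param fare_intercept,fare_per_km round-trip fare model, dollars:
#'   `fare = (intercept + per_km * distance) * noise`.
#' @param fare_noise_sdlog sdlog of the multiplicative lognormal fare noise.
#' @param monthly_wage_range range of monthly incomes, dollars.
#' @param lodging_trigger_km distance beyond which overnight stays occur.
#' @param nightly_rate_range range of lodging rates, dollars per night.
#' @param food_per_day_range range of food spend, dollars per day away.
#' @param days_away_breaks_km distance cut points for the visit-length tiers.
#' @param days_away_values days away per tier (first tier may be fractional:
#'   a near visit costs a fraction of a day's wage).
#' @param delivery_fraction_range range of per-site results-to-SCS fractions.
#' @param patient_fraction_range range of per-site results-to-patient
#'   fractions.
#' @param turnaround_days_range range of mean result turnaround, days.
#' @param air_shipment_probability probability a site ships specimens by air.
#' @param specimens_per_shipment_range integer range of shipment batching.
#' @param specimens_per_session_range integer range of collection-session
#'   sizes.
#' @return an object of class `generator_config`.
#' @export
generator_config <- function(seed,
                             n_sites = 6,
                             patients_per_site = 1000,
                             near_fraction = 0.8,
                             near_distance_km = c(1, 20),
                             remote_distance_meanlog = log(40),
                             remote_distance_sdlog = 0.55,
                             fare_intercept = 0.30,
                             fare_per_km = 0.07,
                             fare_noise_sdlog = 0.15,
                             monthly_wage_range = c(90, 117),
                             lodging_trigger_km = 50,
                             nightly_rate_range = c(3, 8),
                             food_per_day_range = c(2.0, 3.0),
                             days_away_breaks_km = c(30, 100, 200),
                             days_away_values = c(0.26, 1, 2, 3),
                             delivery_fraction_range = c(0.81, 1.00),
                             patient_fraction_range = c(0.80, 0.99),
                             turnaround_days_range = c(15, 60),
                             air_shipment_probability = 1 / 3,
                             specimens_per_shipment_range = c(1, 12),
                             specimens_per_session_range = c(1, 10)) {
  check_range <- function(x, name, min = 0) {
    x <- check_number(x, name, min = min, len = 2L)
    if (x[1] > x[2]) stop_invalid(sprintf("`%s` must be ordered (min, max)", name))
    x
  }
  near_fraction <- check_number(near_fraction, "near_fraction")
  if (near_fraction <= 0 || near_fraction >= 1) {
    stop_invalid("`near_fraction` must be in (0, 1)")
  }
  if (length(days_away_values) != length(days_away_breaks_km) + 1) {
    stop_invalid("`days_away_values` needs one more entry than `days_away_breaks_km`")
  }
  structure(
    list(seed = check_count(seed, "seed"),
         n_sites = check_count(n_sites, "n_sites", min = 1L),
         patients_per_site = check_count(patients_per_site,
                                         "patients_per_site", min = 1L),
         near_fraction = near_fraction,
         near_distance_km = check_range(near_distance_km, "near_distance_km"),
         remote_distance_meanlog = check_number(remote_distance_meanlog,
                                                "remote_distance_meanlog"),
         remote_distance_sdlog = check_number(remote_distance_sdlog,
                                              "remote_distance_sdlog", min = 0),
         fare_intercept = check_number(fare_intercept, "fare_intercept", min = 0),
         fare_per_km = check_number(fare_per_km, "fare_per_km", min = 0),
         fare_noise_sdlog = check_number(fare_noise_sdlog, "fare_noise_sdlog",
                                         min = 0),
         monthly_wage_range = check_range(monthly_wage_range,
                                          "monthly_wage_range"),
         lodging_trigger_km = check_number(lodging_trigger_km,
                                           "lodging_trigger_km", min = 0),
         nightly_rate_range = check_range(nightly_rate_range,
                                          "nightly_rate_range"),
         food_per_day_range = check_range(food_per_day_range,
                                          "food_per_day_range"),
         days_away_breaks_km = check_number(days_away_breaks_km,
                                            "days_away_breaks_km", min = 0,
                                            len = length(days_away_breaks_km)),
         days_away_values = check_number(days_away_values, "days_away_values",
                                         min = 0,
                                         len = length(days_away_values)),
         delivery_fraction_range = check_range(delivery_fraction_range,
                                               "delivery_fraction_range"),
         patient_fraction_range = check_range(patient_fraction_range,
                                              "patient_fraction_range"),
         turnaround_days_range = check_range(turnaround_days_range,
                                             "turnaround_days_range"),
         air_shipment_probability = check_number(air_shipment_probability,
                                                 "air_shipment_probability",
                                                 min = 0, max = 1),
         specimens_per_shipment_range =
           check_range(specimens_per_shipment_range,
                       "specimens_per_shipment_range", min = 1),
         specimens_per_session_range =
           check_range(specimens_per_session_range,
                       "specimens_per_session_range", min = 1)),
    class = "generator_config"
  )
}

runif_range <- function(n, range) stats::runif(n, range[1], range[2])
sample_int_range <- function(range) {
  sample(seq.int(range[1], range[2]), 1L)
}

generate_catchment <- function(site_name, cfg) {
  n <- cfg$patients_per_site
  near <- stats::runif(n) < cfg$near_fraction
  distance <- ifelse(near,
                     runif_range(n, cfg$near_distance_km),
                     stats::rlnorm(n, cfg$remote_distance_meanlog,
                                   cfg$remote_distance_sdlog))
  tier <- findInterval(distance, cfg$days_away_breaks_km) + 1L
  days <- cfg$days_away_values[tier]
  fare <- (cfg$fare_intercept + cfg$fare_per_km * distance) *
    stats::rlnorm(n, 0, cfg$fare_noise_sdlog)
  daily_wage <- runif_range(n, cfg$monthly_wage_range) / 30
  nights <- ifelse(distance > cfg$lodging_trigger_km,
                   pmax(ceiling(days) - 1, 0), 0)
  catchment(site_name, data.frame(
    name = sprintf("%s patient %d", site_name, seq_len(n)),
    distance_km = distance,
    round_trip_fare = fare,
    lodging_nights = nights,
    nightly_rate = runif_range(n, cfg$nightly_rate_range),
    food_cost_total = runif_range(n, cfg$food_per_day_range) *
      pmax(1, ceiling(days)),
    days_away = days,
    daily_wage = daily_wage,
    patient_count = 1L,
    stringsAsFactors = FALSE))
}

generate_scs <- function(site_name, cfg) {
  wage <- hourly_from_monthly(runif_range(1, cfg$monthly_wage_range))
  supplies <- list(
    supply_item("latex gloves", stats::runif(1, 0.04, 0.12), 2),
    supply_item("vacutainers", stats::runif(1, 0.08, 0.20), 3),
    supply_item("cold-chain thermos share", stats::runif(1, 0.05, 0.40), 1),
    supply_item("waste disposal box share", stats::runif(1, 0.02, 0.10), 1)
  )
  labour <- list(
    labour_step("site preparation",
                per_run_minutes = stats::runif(1, 10, 30),
                hourly_wage = wage),
    labour_step("registration and administration",
                per_specimen_minutes = stats::runif(1, 3, 10),
                hourly_wage = wage),
    labour_step("counselling, collection, processing and packaging",
                per_specimen_minutes = stats::runif(1, 8, 25),
                hourly_wage = wage)
  )
  air <- stats::runif(1) < cfg$air_shipment_probability
  shipment <- shipment_profile(
    mode = if (air) "air" else "ground",
    driver_labour_per_trip = stats::runif(1, 1, 5),
    fuel_per_trip = stats::runif(1, 1, 12),
    vehicle_depreciation_per_trip = stats::runif(1, 0.5, 4),
    airfare_per_trip = if (air) stats::runif(1, 5, 25) else 0,
    specimens_per_shipment = sample_int_range(cfg$specimens_per_shipment_range)
  )
  scs_profile(site_name, supplies = supplies, labour = labour,
              accommodation_per_specimen =
                if (stats::runif(1) < 1 / 3) stats::runif(1, 1, 3) else 0,
              transport = shipment)
}

#' Generate a synthetic testing network
#'
#' Draws a complete [network_config()] — catchments of patient locations,
#' itemized collection-site profiles, per-site delivery chains — from the
#' distributions described in [generator_config()]. The laboratory tier is
#' the deterministic [reference_lab_profile()], since a centralized network
#' has one laboratory. Output is fully determined by the configuration
#' (including its seed): the same configuration always yields an identical
#' network, and the seed is recorded in the network's provenance.
#'
#' @param config a [generator_config()].
#' @return a [network_config()] that every downstream function accepts.
#' @examples
#' net <- generate_network(generator_config(seed = 1, n_sites = 2,
#'                                          patients_per_site = 50))
#' tier_share_report(net)
#' @export
generate_network <- function(config) {
  if (!inherits(config, "generator_config")) {
    stop_invalid("`config` must be a generator_config")
  }
  old_seed <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(config$seed)

  sites <- lapply(seq_len(config$n_sites), function(i) {
    site_name <- sprintf("site %d", i)
    network_site(
      name = site_name,
      patient = generate_catchment(site_name, config),
      scs = generate_scs(site_name, config),
      delivery = delivery_chain(
        fraction_to_scs = runif_range(1, config$delivery_fraction_range),
        fraction_to_patient = runif_range(1, config$patient_fraction_range),
        mean_turnaround_days = round(runif_range(
          1, config$turnaround_days_range))),
      specimens_per_session =
        sample_int_range(config$specimens_per_session_range)
    )
  })
  network_config(sites, reference_lab_profile(),
                 batch_sizes = c(10, 22), operating_batch_size = 22,
                 provenance = list(source = "synthetic",
                                   seed = config$seed))
}
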