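test_that("shipment transport amortizes the trip cost over the batch", {
  ground <- shipment_profile("ground", driver_labour_per_trip = 5,
                             fuel_per_trip = 12,
                             vehicle_depreciation_per_trip = 3,
                             specimens_per_shipment = 4)
  expect_equal(transport_per_specimen(ground), 5)
  single <- shipment_profile("ground", driver_labour_per_trip = 5,
                             fuel_per_trip = 12,
                             vehicle_depreciation_per_trip = 3,
                             specimens_per_shipment = 1)
  expect_equal(transport_per_specimen(single), 20)
  air <- shipment_profile("air", airfare_per_trip = 13.30,
                          specimens_per_shipment = 10)
  expect_equal(money_round(transport_per_specimen(air)), 1.33)

  expect_error(shipment_profile("ground", specimens_per_shipment = 0),
               class = "vlcost_invalid_input")
  expect_error(shipment_profile("ground", airfare_per_trip = 10),
               class = "vlcost_invalid_input")
})

test_that("doubling shipment batching halves the transport component", {
  set.seed(41)
  for (i in 1:10) {
    args <- list(driver_labour_per_trip = runif(1, 0, 10),
                 fuel_per_trip = runif(1, 0, 20),
                 vehicle_depreciation_per_trip = runif(1, 0, 5))
    k <- sample(1:12, 1)
    a <- do.call(shipment_profile, c(list("ground"), args,
                                     specimens_per_shipment = k))
    b <- do.call(shipment_profile, c(list("ground"), args,
                                     specimens_per_shipment = 2 * k))
    expect_equal(transport_per_specimen(a), 2 * transport_per_specimen(b))
  }
})

test_that("aggregated site profiles reproduce the reference component totals", {
  ref <- reference_scs_components()
  expected_totals <- c(6.58, 3.31, 6.41, 14.97, 20.92, 9.48)
  for (i in 1:6) {
    bd <- scs_cost_per_specimen(scs_profile(
      ref$site[i], supplies = ref$supplies[i], labour = ref$labour[i],
      accommodation_per_specimen = ref$accommodations[i],
      transport = ref$transport[i]))
    expect_equal(money_round(bd$total), expected_totals[i])
    expect_equal(sum(bd$components), bd$total)
  }
  zero <- scs_cost_per_specimen(scs_profile("empty"))
  expect_equal(zero$total, 0)
})

test_that("the site total is additive in its components", {
  base <- list(site_name = "t", supplies = 0.61, labour = 6.66,
               accommodation_per_specimen = 2.89, transport = 10.76)
  full <- scs_cost_per_specimen(do.call(scs_profile, base))$total
  for (drop in c("supplies", "labour", "accommodation_per_specimen",
                 "transport")) {
    args <- base
    args[[drop]] <- 0
    reduced <- scs_cost_per_specimen(do.call(scs_profile, args))$total
    expect_equal(full - reduced, base[[drop]])
  }
})

test_that("itemized profiles price supplies, session labour and shipment", {
  prof <- scs_profile(
    "itemized",
    supplies = list(supply_item("gloves", 0.06, 2),
                    supply_item("vacutainer", 0.12, 3)),
    labour = list(
      labour_step("site preparation", per_run_minutes = 20, hourly_wage = 0.45),
      labour_step("collection", per_specimen_minutes = 18, hourly_wage = 0.45)),
    accommodation_per_specimen = 0.5,
    transport = shipment_profile("ground", fuel_per_trip = 6,
                                 specimens_per_shipment = 6))
  bd1 <- scs_cost_per_specimen(prof, specimens_per_session = 1)
  bd6 <- scs_cost_per_specimen(prof, specimens_per_session = 6)
  expect_equal(unname(bd6$components["supplies"]), 0.06 * 2 + 0.12 * 3)
  expect_equal(unname(bd6$components["transport"]), 1)
  # session labour amortizes, marginal labour does not
  expect_equal(unname(bd1$components["labour"] - bd6$components["labour"]),
               (20 - 20 / 6) * 0.45 / 60)
  expect_lt(bd6$total, bd1$total)
})
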