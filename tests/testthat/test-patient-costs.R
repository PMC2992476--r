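test_that("visit cost components follow the fare/lodging/food/lost-income model", {
  near <- visit_cost(patient_location("near town", round_trip_fare = 0.42,
                                      food_cost_total = 0.81,
                                      days_away = 0.26, daily_wage = 3.50))
  expect_equal(unname(near$components),
               c(0.42, 0, 0.81, 0.26 * 3.50))
  expect_equal(money_round(near$total), 2.14)

  expect_equal(visit_cost(patient_location("nowhere"))$total, 0)

  far <- visit_cost(patient_location("far", round_trip_fare = 10,
                                     lodging_nights = 2, nightly_rate = 5,
                                     food_cost_total = 7, days_away = 3,
                                     daily_wage = 6))
  expect_equal(far$total, 45)

  expect_error(patient_location("bad", round_trip_fare = -1),
               class = "vlcost_invalid_input")
})

test_that("catchment weighting averages components by patient counts", {
  one <- catchment("solo", patient_location("only", round_trip_fare = 3,
                                            food_cost_total = 2,
                                            patient_count = 7))
  expect_equal(weighted_average_catchment(one)$total,
               visit_cost(one$locations)$total)

  two <- toy_catchment(totals = c(2, 12), counts = c(80, 20))
  expect_equal(weighted_average_catchment(two)$total, 4)

  expect_error(weighted_average_catchment(
    toy_catchment(totals = 1, counts = 0)), class = "vlcost_invalid_input")
})

test_that("component-wise weighted averages sum to the weighted average total", {
  set.seed(31)
  for (i in 1:20) {
    k <- sample(2:8, 1)
    locs <- data.frame(
      name = paste("l", 1:k), distance_km = runif(k, 0, 300),
      round_trip_fare = runif(k, 0, 40),
      lodging_nights = sample(0:3, k, replace = TRUE),
      nightly_rate = runif(k, 0, 8), food_cost_total = runif(k, 0, 12),
      days_away = runif(k, 0, 3), daily_wage = runif(k, 3, 4),
      patient_count = sample(1:200, k, replace = TRUE))
    avg <- weighted_average_catchment(catchment("c", locs))
    expect_equal(sum(avg$components), avg$total) # conservation, pre-rounding
    tab <- visit_cost_table(locs)
    expect_equal(avg$total,
                 sum(tab$total * tab$patient_count) / sum(tab$patient_count))
    expect_gte(avg$total, min(tab$total))
    expect_lte(avg$total, max(tab$total))
  }
})

test_that("growing a location's patient count pulls the average toward it", {
  base <- c(2, 8, 20)
  for (boost in 1:3) {
    counts <- c(10, 10, 10)
    avg0 <- weighted_average_catchment(toy_catchment(base, counts))$total
    counts[boost] <- 60
    avg1 <- weighted_average_catchment(toy_catchment(base, counts))$total
    if (base[boost] > avg0) expect_gt(avg1, avg0) else expect_lt(avg1, avg0)
  }
})

test_that("catchment summaries report weighted median, extremes and threshold fractions", {
  solo <- toy_catchment(totals = 7.71, counts = 4)
  s <- catchment_summary(solo)
  expect_equal(s$median, 7.71)
  expect_equal(s$min, 7.71)
  expect_equal(s$max, 7.71)

  mix <- toy_catchment(totals = c(3, 8, 20), counts = c(65, 30, 5))
  s <- catchment_summary(mix, thresholds = c(5, 10))
  expect_equal(unname(s$fraction_below), c(0.65, 0.95))

  equal3 <- toy_catchment(totals = c(1, 2, 9), counts = c(10, 10, 10))
  s <- catchment_summary(equal3)
  expect_equal(s$median, 2)
  expect_equal(s$min, 1)
  expect_equal(s$max, 9)

  # even patient count: the lower of the two middle patients
  even <- toy_catchment(totals = c(1, 4), counts = c(1, 1))
  expect_equal(catchment_summary(even)$median, 1)
})

test_that("locations CSV round-trips into catchments", {
  path <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(
    site = c("A", "A", "B"), location = c("l1", "l2", "l3"),
    distance_km = c(2, 120, 5), fare = c(0.42, 8.4, 1),
    lodging_nights = c(0, 1, 0), nightly_rate = c(0, 4.5, 0),
    food_total = c(0.81, 5.2, 1.1), days_away = c(0.26, 2, 0.26),
    daily_wage = c(3.5, 3.6, 3.9), patients = c(80, 20, 10))
  write.csv(df, path, row.names = FALSE)
  catchments <- read_locations_csv(path)
  expect_named(catchments, c("A", "B"))
  expect_equal(nrow(catchments$A$locations), 2)
  expect_equal(weighted_average_catchment(catchments$B)$total,
               1 + 1.1 + 0.26 * 3.9)
  expect_error(read_locations_csv(tempfile()), class = "vlcost_io_error")
})
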