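test_that("money_round rounds half-up, not to even", {
  expect_equal(money_round(0.125), 0.13)
  expect_equal(money_round(0.135), 0.14)
  expect_equal(money_round(2.675), 2.68) # stored as 2.67499999... in binary
  expect_equal(money_round(1750 / 22), 79.55)
  expect_equal(money_round(11.1111, digits = 0), 11)
  expect_equal(money_format(3.7), "3.70")
})

test_that("displayed totals are independent of summation order", {
  set.seed(11)
  for (i in 1:20) {
    x <- runif(50, 0, 200)
    expect_identical(money_round(sum(x)), money_round(sum(sample(x))))
  }
})

test_that("straight-line annualization and utilization scaling", {
  expect_equal(annualize_asset(1000, 5), 200)
  expect_equal(annualize_asset(1000, 5, utilization_share = 0.1), 20)
  expect_error(annualize_asset(1000, 0), class = "vlcost_invalid_input")
  expect_error(annualize_asset(1000, -3), class = "vlcost_invalid_input")
})

test_that("discounted annualization matches an amortization-table oracle", {
  # oracle: the payment that exactly amortizes the purchase over 5 annual
  # instalments at 3%, found by rolling a 5-row balance table to zero
  balance_after <- function(payment, principal = 1000, rate = 0.03,
                            years = 5) {
    bal <- principal
    for (y in seq_len(years)) bal <- bal * (1 + rate) - payment
    bal
  }
  oracle <- uniroot(balance_after, c(100, 1000), tol = 1e-10)$root
  got <- annualize_asset(1000, 5, discount_rate = 0.03)
  expect_equal(got, oracle, tolerance = 1e-9)
  expect_equal(money_round(got), 218.35)
})

test_that("discounted annualization converges to straight line as r -> 0", {
  expect_equal(annualize_asset(1000, 5, discount_rate = 1e-8),
               annualize_asset(1000, 5), tolerance = 1e-4)
})

test_that("labour step cost amortizes per-run minutes over the batch", {
  st <- labour_step("prep", per_run_minutes = 30, per_specimen_minutes = 2,
                    hourly_wage = 3)
  expect_equal(labour_step_cost(st, 10), 0.25)

  marginal_only <- labour_step("entry", per_specimen_minutes = 2,
                               hourly_wage = 1.8)
  expect_equal(labour_step_cost(marginal_only, 10),
               labour_step_cost(marginal_only, 22))

  run_only <- labour_step("setup", per_run_minutes = 60, hourly_wage = 6)
  expect_equal(labour_step_cost(run_only, 1), 6)

  expect_error(labour_step_cost(st, 0), class = "vlcost_invalid_input")
})

test_that("labour step cost is non-increasing in batch size with the marginal cost as limit", {
  set.seed(21)
  for (i in 1:25) {
    st <- labour_step("s", per_run_minutes = runif(1, 0, 200),
                      per_specimen_minutes = runif(1, 0, 40),
                      hourly_wage = runif(1, 0.2, 5))
    costs <- labour_step_cost(st, 1:40)
    expect_true(all(diff(costs) <= 1e-12))
    expect_equal(labour_step_cost(st, 1e9),
                 st$per_specimen_minutes * st$hourly_wage / 60,
                 tolerance = 1e-6)
  }
})

test_that("monthly wages convert at 30 days and 8 hours", {
  expect_equal(hourly_from_monthly(108), 0.45)
  expect_equal(hourly_from_monthly(90), 0.375)
})

test_that("cost breakdowns enforce conservation before rounding", {
  bd <- cost_breakdown(c(a = 1.111, b = 2.222))
  expect_equal(bd$total, 3.333)
  expect_silent(cost_breakdown(c(a = 1, b = 2), total = 3.004))
  expect_error(cost_breakdown(c(a = 1, b = 2), total = 3.01),
               class = "vlcost_invalid_input")
  expect_error(cost_breakdown(c(a = -1, b = 2)),
               class = "vlcost_invalid_input")
  expect_error(cost_breakdown(c(1, 2)), class = "vlcost_invalid_input")
})
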