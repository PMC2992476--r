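ref_kit <- kit_configuration(12, 875, 2)

test_that("whole-kit consumption counts kits for specimens plus controls", {
  expect_equal(kits_required(10, ref_kit), 1L)
  expect_equal(kits_required(22, ref_kit), 2L)
  expect_equal(kits_required(12, ref_kit), 2L) # 14 tests spill into a 2nd kit
  expect_error(kits_required(0, ref_kit), class = "vlcost_invalid_input")
  expect_error(kit_configuration(2, 100, controls_per_run = 2),
               class = "vlcost_invalid_input")
})

test_that("reagent cost per specimen follows the kit ceiling", {
  expect_equal(money_round(reagent_cost_per_specimen(10, ref_kit)), 87.50)
  expect_equal(money_round(reagent_cost_per_specimen(22, ref_kit)), 79.55)
  expect_equal(money_round(reagent_cost_per_specimen(11, ref_kit)), 159.09)
})

test_that("reagent spend per run is a whole number of kit prices with minima at full runs", {
  set.seed(51)
  for (i in 1:15) {
    t <- sample(3:24, 1)
    kit <- kit_configuration(t, runif(1, 50, 1200),
                             controls_per_run = sample(0:2, 1))
    n <- 1:60
    spend <- reagent_cost_per_specimen(n, kit) * n
    expect_equal(spend / kit$kit_price,
                 round(spend / kit$kit_price), tolerance = 1e-9)
    # local minima of the per-specimen curve sit at n = k*t - controls
    curve <- reagent_cost_per_specimen(n, kit)
    full_runs <- seq(t - kit$controls_per_run, 60, by = t)
    for (m in setdiff(n, full_runs)) {
      nxt <- full_runs[full_runs > m][1]
      if (!is.na(nxt)) expect_gt(curve[m], curve[nxt])
    }
  }
})

test_that("the reference laboratory profile reproduces the published batch costs", {
  prof <- reference_lab_profile()
  bd10 <- lab_cost_per_specimen(10, prof)
  bd22 <- lab_cost_per_specimen(22, prof)
  expect_equal(bd10$total, 97.15, tolerance = 0.02)
  expect_equal(bd22$total, 88.73, tolerance = 0.02)
  expect_equal(money_round(bd10$total), 97.15)
  expect_equal(money_round(bd22$total), 88.73)
  expect_equal(money_round(bd_components <- bd10$components[["reagents"]]), 87.50)
  # itemized lines display as published
  expect_equal(money_round(sum(attr(bd10, "disposable_items"))), 2.85)
  expect_equal(money_round(sum(attr(bd22, "disposable_items"))), 2.54)
  expect_equal(money_round(sum(attr(bd10, "labour_items"))), 1.19)
  expect_equal(money_round(sum(attr(bd22, "labour_items"))), 1.03)
})

test_that("a reagent-only profile costs exactly the amortized kits", {
  bare <- lab_cost_profile(ref_kit)
  expect_equal(lab_cost_per_specimen(22, bare)$total, 1750 / 22)
})

test_that("batch 22 is optimal and batch 10 dominates 11..19 on the reference profile", {
  opt <- optimal_batch(reference_lab_profile(), 24)
  expect_equal(opt$n_opt, 22)
  curve <- opt$curve
  expect_true(all(curve$total[11:19] > curve$total[10]))
  # total run cost n * total(n) never decreases with batch size
  expect_true(all(diff(curve$n * curve$total) > -1e-9))
})

test_that("with free reagents the largest batch wins through labour amortization", {
  prof <- lab_cost_profile(
    kit_configuration(12, 0, 2),
    labour_steps = list(labour_step("setup", per_run_minutes = 60,
                                    hourly_wage = 1)))
  expect_equal(optimal_batch(prof, 24)$n_opt, 24)
})

test_that("optimal_batch agrees with a brute-force oracle on 200 random profiles", {
  set.seed(61)
  for (i in 1:200) {
    prof <- random_lab_profile()
    n_max <- sample(5:30, 1)
    oracle_totals <- vapply(seq_len(n_max), oracle_lab_total, numeric(1),
                            profile = prof)
    got <- optimal_batch(prof, n_max)
    expect_equal(got$n_opt, which.min(oracle_totals))
    expect_equal(got$curve$total, oracle_totals, tolerance = 1e-12)
  }
})

test_that("kit inference recovers the configuration under the published constraints", {
  obs <- data.frame(n = c(10, 22), cost = c(87.50, 79.55))
  kit <- infer_kit_config(obs, controls_per_run = 2, optimal_n = 22,
                          n_max = 24, dominant = 10, dominated = 11:19)
  expect_equal(kit$tests_per_kit, 12L)
  expect_equal(kit$kit_price, 875)
  expect_equal(kit$controls_per_run, 2L)
})

test_that("kit inference is ambiguous without constraints and infeasible on contradictions", {
  err <- expect_error(
    infer_kit_config(data.frame(n = 10, cost = 87.50), controls_per_run = 2),
    class = "vlcost_ambiguous")
  sizes <- vapply(err$data$candidates, `[[`, numeric(1), "tests_per_kit")
  expect_true(all(12:48 %in% sizes)) # any kit holding 10 + 2 tests fits

  expect_error(
    infer_kit_config(data.frame(n = c(10, 22), cost = c(87.50, 100.00)),
                     controls_per_run = 2),
    class = "vlcost_infeasible")
})

test_that("reagents are 90% of the batch-of-10 cost on the reference profile", {
  bd <- lab_cost_per_specimen(10, reference_lab_profile())
  share <- bd$components[["reagents"]] / bd$total * 100
  expect_equal(money_round(share, 0), 90)
})
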