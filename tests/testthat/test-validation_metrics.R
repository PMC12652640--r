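test_that("utilization summaries take medians over observed months only", {
  full <- summarize_utilization(make_ledger(rep(170, 12)), 2020)
  expect_equal(full$median_monthly_patients, 170)
  expect_equal(full$annualized_patients, 2040)
  expect_equal(full$months_observed, 12L)

  partial <- summarize_utilization(make_ledger(c(1, 2, 3, 4)), 2020)
  expect_equal(partial$median_monthly_patients, 2.5)
  expect_equal(partial$months_observed, 4L)
  expect_equal(partial$annualized_patients, 30)

  shuffled <- make_ledger(c(3, 1, 4, 2), month = c(3, 1, 4, 2))
  expect_equal(summarize_utilization(shuffled, 2020)[-1],
               partial[-1])  # identifiers aside, order cannot matter

  expect_error(summarize_utilization(make_ledger(1:4), 2021),
               "no observed months")
})

test_that("unit cost is median cost over median patients, undefined at zero", {
  su <- summarize_utilization(make_ledger(rep(50, 3), cost_eur = rep(1e5, 3)), 2020)
  expect_equal(compute_unit_cost(su), 2000)
  expect_equal(su$unit_cost_eur, 2000)

  zero_cost <- summarize_utilization(make_ledger(rep(10, 3), cost_eur = rep(0, 3)), 2020)
  expect_equal(compute_unit_cost(zero_cost), 0)

  zero_pat <- summarize_utilization(make_ledger(rep(0, 3), cost_eur = rep(10, 3)), 2020)
  expect_true(is.na(zero_pat$unit_cost_eur))
  expect_error(compute_unit_cost(zero_pat), "zero median monthly patients")
})

test_that("cost scenarios price projected volume at the observed unit cost", {
  parity <- make_ledger(rep(10, 12), cost_eur = rep(10000, 12))
  su <- summarize_utilization(parity, 2020)
  scen <- compute_cost_scenarios(su, 10, parity$cost_eur)
  expect_equal(scen$actual_cost_eur, 120000)
  expect_equal(scen$projected_cost_eur, 120000)

  half_year <- make_ledger(rep(15, 6), cost_eur = rep(15000, 6))
  su6 <- summarize_utilization(half_year, 2020)
  expect_equal(compute_unit_cost(su6), 1000)
  scen6 <- compute_cost_scenarios(su6, 10, half_year$cost_eur)
  expect_equal(scen6$actual_cost_eur, 90000)
  expect_equal(scen6$projected_cost_eur, 60000)
  expect_equal(scen6$actual_cost_eur - scen6$projected_cost_eur, 30000)

  expect_error(compute_cost_scenarios(su, 0, parity$cost_eur), "positive")
})

test_that("patient ratios follow the monthly-median convention of the cohort table", {
  avel <- make_ledger(rep(170, 12), cost_eur = rep(1000, 12))
  su <- summarize_utilization(avel, 2020)
  gaps <- compute_gap_metrics(compute_cost_scenarios(su, 8, avel$cost_eur),
                              su, 8)
  expect_equal(gaps$patient_ratio_med, 21.25)
  expect_equal(format_ratio(gaps$patient_ratio_med), 21.3)

  lura <- make_ledger(rep(672, 12), cost_eur = rep(1000, 12))
  su2 <- summarize_utilization(lura, 2020)
  gaps2 <- compute_gap_metrics(compute_cost_scenarios(su2, 690, lura$cost_eur),
                               su2, 690)
  expect_equal(gaps2$patient_ratio_med, 672 / 690)
  expect_equal(format_ratio(gaps2$patient_ratio_med), 0.97)

  parity <- make_ledger(rep(10, 12), cost_eur = rep(10000, 12))
  sup <- summarize_utilization(parity, 2020)
  gp <- compute_gap_metrics(compute_cost_scenarios(sup, 10, parity$cost_eur),
                            sup, 10)
  expect_equal(gp$cost_gap_eur, 0)
  expect_equal(gp$cost_ratio, 1)
  expect_true(gp$patient_ratio_min <= gp$patient_ratio_med)
  expect_true(gp$patient_ratio_med <= gp$patient_ratio_max)

  annual <- compute_gap_metrics(compute_cost_scenarios(sup, 10, parity$cost_eur),
                                sup, 120, ratio_convention = "annual")
  expect_equal(annual$patient_ratio_med, 1)
})

test_that("ratio is strictly increasing in the monthly median at fixed projection", {
  medians <- c(5, 10, 20, 40)
  ratios <- vapply(medians, function(m) {
    led <- make_ledger(rep(m, 12), cost_eur = rep(1000, 12))
    su <- summarize_utilization(led, 2020)
    compute_gap_metrics(compute_cost_scenarios(su, 8, led$cost_eur),
                        su, 8)$patient_ratio_med
  }, numeric(1))
  expect_true(all(diff(ratios) > 0))
})

test_that("gap decomposition isolates pure volume and pure price effects", {
  vol <- decompose_gap(10, 240, 1000, 1000, 12)
  expect_equal(vol$price_effect, 0)
  expect_equal(vol$volume_effect, 120000)

  price <- decompose_gap(10, 120, 1000, 1100, 12)
  expect_equal(price$volume_effect, 0)
  expect_equal(price$price_effect, 120 * 100)

  both <- decompose_gap(10, 150, 1000, 1100, 12)
  expect_equal(both$volume_effect, 30000)
  expect_equal(both$price_effect, 15000)
  expect_equal(both$volume_effect + both$price_effect,
               150 * 1100 - 10 * 12 * 1000)

  expect_error(decompose_gap(10, 120, 0, 1000, 12), "positive")
  expect_error(decompose_gap(Inf, 120, 1000, 1000, 12), "finite")
})

test_that("ratio/gap inversion recovers cost levels and round-trips", {
  avel <- invert_ratio_gap(21.5, 7642580)
  expect_equal(avel$projected_cost_eur, 372808.78, tolerance = 1e-6)
  expect_equal(avel$actual_cost_eur, 8015388.8, tolerance = 1e-6)

  cote <- invert_ratio_gap(0.03, -1151943)
  expect_equal(cote$projected_cost_eur, 1187570.1, tolerance = 1e-6)
  expect_equal(cote$actual_cost_eur, 35627.1, tolerance = 1e-5)

  simple <- invert_ratio_gap(2, 100)
  expect_equal(simple$projected_cost_eur, 100)
  expect_equal(simple$actual_cost_eur, 200)

  expect_error(invert_ratio_gap(1, 100), "inconsistent")
  expect_error(invert_ratio_gap(1, 0), "indeterminate")

  set.seed(3)
  ratio <- exp(runif(500, -4, 4))
  ratio <- ratio[abs(ratio - 1) > 1e-6]
  gap <- runif(length(ratio), -1e7, 1e7) * sign(ratio - 1)
  levels <- invert_ratio_gap(ratio, gap)
  expect_equal(levels$actual_cost_eur / levels$projected_cost_eur, ratio,
               tolerance = 1e-9)
  expect_equal(levels$actual_cost_eur - levels$projected_cost_eur, gap,
               tolerance = 1e-9)
})

test_that("annualized growth is the compound per-year rate", {
  expect_equal(annualized_growth(100, 100, 3), 0)
  expect_equal(annualized_growth(100, 1600, 4), 1)
  expect_equal(annualized_growth(60, 2040, 5), 1.0244, tolerance = 1e-4)
  expect_error(annualized_growth(0, 100, 5), "positive")
})

test_that("display rounding is half away from zero at printed precision", {
  expect_equal(round_half_up(0.125, 2), 0.13)
  expect_equal(round_half_up(2.495, 2), 2.50)
  expect_equal(round_half_up(21.25, 1), 21.3)
  expect_equal(round_half_up(-0.125, 2), -0.13)
  expect_equal(format_ratio(c(0.9739, 21.25, 2.495)), c(0.97, 21.3, 2.50))
})
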