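flat_product <- function(name = "flatdrug", channel = "hospital",
                         ceiling = 100, unit_cost = 500, cv = 0,
                         currency = "EUR", gap = integer(0), bias_ignore = NULL) {
  list(market_name = name, inn = paste0(name, "-inn"), channel = channel,
       atc_code = "l01xx", icd10 = "c00",
       uptake = uptake_params(ceiling = ceiling, growth_rate = 0,
                              poisson = FALSE, observation_gap = gap),
       cost = cost_params(unit_cost, unit_cost_cv = cv, currency = currency))
}

test_that("uptake trajectories honor their parameters", {
  flat <- simulate_uptake(uptake_params(ceiling = 100, growth_rate = 0,
                                        poisson = FALSE), 24)
  expect_equal(flat$patients, rep(100, 24))

  shocked <- simulate_uptake(
    uptake_params(ceiling = 100, growth_rate = 0.5, start_frac = 0.05,
                  expansion_month = 24, expansion_multiplier = 10,
                  poisson = FALSE), 60)
  expect_lt(max(shocked$mean_patients[1:23]), 101)
  expect_gt(shocked$mean_patients[60], 990)

  declining <- simulate_uptake(uptake_params(ceiling = 60, growth_rate = 0,
                                             dropout_rate = 0.1,
                                             poisson = FALSE), 12)
  expect_equal(declining$mean_patients, 60 * 0.9^(0:11))

  a <- simulate_uptake(uptake_params(ceiling = 50), 36, seed = 7)
  b <- simulate_uptake(uptake_params(ceiling = 50), 36, seed = 7)
  expect_identical(a, b)

  expect_error(uptake_params(ceiling = -1), "ceiling")
  expect_error(uptake_params(ceiling = 1, dropout_rate = 1), "dropout_rate")
  expect_error(simulate_uptake(uptake_params(ceiling = 1), 0), "horizon")
})

test_that("noise-free claims cost exactly patients times unit cost", {
  sim <- simulate_claims(list(flat_product()), years = 2020, seed = 1)
  expect_equal(nrow(sim$hospital), 12L)
  expect_equal(sim$hospital$cost, sim$hospital$patients * 500)
})

test_that("BGN emission survives the ingestion pipeline at the fixed peg", {
  dir <- tempfile(); dir.create(dir)
  sim <- simulate_claims(list(flat_product(currency = "BGN")),
                         years = 2020:2021, seed = 2, dir = dir)
  expect_equal(sim$hospital$cost, sim$hospital$patients * 500 * 1.95583)
  records <- read_claims_table(sim$paths[["hospital"]], "hospital",
                               currency = "BGN")
  pm <- aggregate_product_month(normalize_record(records))
  expect_equal(sum(pm$cost_eur), sum(sim$hospital$cost) / 1.95583,
               tolerance = 1e-12)
  expect_equal(sum(pm$patients), sum(sim$hospital$patients))
  expect_true(file.exists(sim$paths[["manifest"]]))
})

test_that("observation gaps reduce months observed", {
  sim <- simulate_claims(list(flat_product(gap = 1:3)), years = 2020:2021,
                         seed = 3)
  pm <- aggregate_product_month(
    normalize_record(make_records_from_sim(sim$hospital, "hospital")))
  expect_equal(summarize_utilization(pm, 2020)$months_observed, 9L)
  expect_equal(summarize_utilization(pm, 2021)$months_observed, 12L)
})

test_that("generated files are byte-identical under a fixed seed", {
  products <- list(
    flat_product("alpha"),
    list(market_name = "beta", inn = "beta-inn", channel = "outpatient",
         atc_code = "l04", icd10 = "l40", nhif_code = "NF007",
         uptake = uptake_params(ceiling = 40, growth_rate = 0.4),
         cost = cost_params(800, unit_cost_cv = 0.2, currency = "BGN"))
  )
  run <- function() {
    dir <- tempfile(); dir.create(dir)
    # one currency per channel: alpha is EUR/hospital, beta BGN/outpatient
    simulate_claims(products, years = 2020:2021, seed = 11, dir = dir,
                    n_regions = 3)$paths
  }
  p1 <- run(); p2 <- run()
  for (key in c("hospital", "outpatient")) {
    expect_identical(readLines(p1[[key]]), readLines(p2[[key]]))
  }
})

test_that("regional splitting conserves product-month totals", {
  product <- list(market_name = "gamma", inn = "gamma-inn",
                  channel = "outpatient", atc_code = "l04", icd10 = "l40",
                  nhif_code = "NF001",
                  uptake = uptake_params(ceiling = 200, growth_rate = 0.3),
                  cost = cost_params(100, currency = "EUR"))
  set_total <- simulate_claims(list(product), years = 2020, seed = 5)
  split <- simulate_claims(list(product), years = 2020, seed = 5, n_regions = 5)
  by_month <- split$outpatient |>
    dplyr::group_by(month) |>
    dplyr::summarise(patients = sum(patients), cost = sum(cost))
  expect_equal(by_month$patients, set_total$outpatient$patients)
  expect_equal(by_month$cost, set_total$outpatient$cost, tolerance = 1e-12)
})

test_that("derived projections encode the bias so ratios invert it exactly", {
  series <- tibble::tibble(year = rep(c(2020, 2025), each = 12),
                           month = rep(1:12, 2),
                           patients = rep(c(60, 2040), each = 12))
  unbiased <- derive_projections(series, "x", anchor_year_1 = 2020,
                                 anchor_year_5 = 2025)
  expect_equal(unbiased$patients_y1, 60)
  expect_equal(unbiased$patients_y5, 2040)

  over <- derive_projections(series, "x", anchor_year_1 = 2020,
                             anchor_year_5 = 2025,
                             bias = bias_params(1, 1 / 20))
  expect_equal(2040 / over$patients_y5, 20)

  under <- derive_projections(series, "x", anchor_year_1 = 2020,
                              anchor_year_5 = 2025,
                              bias = bias_params(1, 2))
  expect_equal(2040 / under$patients_y5, 0.5)

  expect_error(derive_projections(series, "x", anchor_year_1 = 2019,
                                  anchor_year_5 = 2025),
               "does not cover anchor year 2019")
})

test_that("noiseless elasticity cohorts recover the generating model exactly", {
  cohort <- simulate_elasticity_cohort(beta = 0.8, alpha = 2, noise_sd = 0,
                                       n = 25, seed = 21)
  fit <- fit_loglog(cohort)
  expect_equal(fit$beta, 0.8, tolerance = 1e-10)
  expect_equal(fit$alpha, 2, tolerance = 1e-8)
  expect_equal(fit$r2, 1)

  again <- simulate_elasticity_cohort(beta = 0.8, alpha = 2, noise_sd = 0,
                                      n = 25, seed = 21)
  expect_identical(cohort, again)
  expect_error(simulate_elasticity_cohort(1, n = 2), "n must be")
  expect_error(simulate_elasticity_cohort(1, projected_cost_range = c(-1, 5)),
               "range")
})

test_that("separated strata yield non-overlapping elasticity intervals", {
  low <- simulate_elasticity_cohort(beta = 0.79, noise_sd = 0.5, n = 200,
                                    seed = 31)
  low$channel <- "hospital"
  high <- simulate_elasticity_cohort(beta = 1.30, noise_sd = 0.5, n = 200,
                                     seed = 32)
  high$channel <- "outpatient"
  fits <- stratify_fit(dplyr::bind_rows(low, high), by = "channel")
  ci <- function(f) f$beta + c(-1, 1) * qt(0.975, f$n - 2) * f$se_beta
  expect_lt(ci(fits$hospital)[2], ci(fits$outpatient)[1])
})
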