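#' Uptake trajectory parameters
#'
#' Describes how a product's monthly treated-patient count evolves after
#' launch: a logistic rise from `start_frac x ceiling` toward `ceiling` at
#' per-month rate `growth_rate` (rate 0 is the saturated degenerate case -
#' the trajectory sits at the ceiling throughout), an optional indication
#' expansion multiplying the ceiling from a given month onward, geometric
#' attrition at `dropout_rate` per month, and optional observation gaps
#' (month indices with no reported data, emulating incomplete calendar
#' years). Monthly counts are Poisson around the mean trajectory unless
#' `poisson = FALSE`.
#'
#' @param ceiling Long-run monthly patients (> 0).
#' @param growth_rate Per-month logistic rate (>= 0).
#' @param start_frac Fraction of the ceiling treated in month 1 (0-1).
#' @param expansion_month,expansion_multiplier Month index from which the
#'   ceiling is multiplied (multiplier > 0); `NA` for none.
#' @param dropout_rate Per-month attrition fraction in `[0, 1)`.
#' @param observation_gap Integer month indices with no data.
#' @param poisson Draw Poisson counts around the mean (default) or return
#'   the rounded mean deterministically.
#' @return A list of validated parameters, class `"uptake_params"`.
#' @export
uptake_params <- function(ceiling, growth_rate = 0.3, start_frac = 0.05,
                          expansion_month = NA, expansion_multiplier = 1,
                          dropout_rate = 0, observation_gap = integer(0),
                          poisson = TRUE) {
  if (!is.numeric(ceiling) || ceiling <= 0) stop("ceiling must be > 0", call. = FALSE)
  if (growth_rate < 0) stop("growth_rate must be >= 0", call. = FALSE)
  if (start_frac <= 0 || start_frac > 1) stop("start_frac must be in (0, 1]", call. = FALSE)
  if (expansion_multiplier <= 0) stop("expansion_multiplier must be > 0", call. = FALSE)
  if (dropout_rate < 0 || dropout_rate >= 1) stop("dropout_rate must be in [0, 1)", call. = FALSE)
  structure(list(ceiling = ceiling, growth_rate = growth_rate,
                 start_frac = start_frac, expansion_month = expansion_month,
                 expansion_multiplier = expansion_multiplier,
                 dropout_rate = dropout_rate,
                 observation_gap = as.integer(observation_gap),
                 poisson = isTRUE(poisson)),
            class = "uptake_params")
}

#' Unit cost parameters
#'
#' @param unit_cost_eur Mean cost per patient-month, EUR (> 0).
#' @param unit_cost_cv Coefficient of variation of the multiplicative
#'   log-normal month-to-month cost noise (>= 0; 0 = deterministic costs).
#' @param currency Currency in which claims files are written.
#' @return A validated parameter list, class `"cost_params"`.
#' @export
cost_params <- function(unit_cost_eur, unit_cost_cv = 0,
                        currency = c("EUR", "BGN")) {
  currency <- match.arg(currency)
  if (unit_cost_eur <= 0) stop("unit_cost_eur must be > 0", call. = FALSE)
  if (unit_cost_cv < 0) stop("unit_cost_cv must be >= 0", call. = FALSE)
  structure(list(unit_cost_eur = unit_cost_eur, unit_cost_cv = unit_cost_cv,
                 currency = currency), class = "cost_params")
}

#' Projection bias parameters
#'
#' Multiplicative factors applied to the true utilization when forming the
#' synthetic HTA projection. A bias below 1 under-projects, so the realized
#' observed-to-projected ratio is approximately `1/bias` (exactly, for a
#' noise-free trajectory).
#'
#' @param volume_bias_y1,volume_bias_y5 Positive factors for the Year-1 and
#'   Year-5 horizons.
#' @return A validated parameter list, class `"bias_params"`.
#' @export
bias_params <- function(volume_bias_y1 = 1, volume_bias_y5 = 1) {
  if (volume_bias_y1 <= 0 || volume_bias_y5 <= 0) {
    stop("volume biases must be > 0", call. = FALSE)
  }
  structure(list(volume_bias_y1 = volume_bias_y1,
                 volume_bias_y5 = volume_bias_y5), class = "bias_params")
}

#' Simulate a monthly uptake series
#'
#' Deterministic mean trajectory per [uptake_params()], with Poisson
#' month-to-month variation when enabled. Reproducible for a fixed seed.
#'
#' @param params An [uptake_params()] object.
#' @param horizon_months Number of months to simulate (>= 1).
#' @param seed Optional integer seed; when `NULL` the current RNG stream is
#'   used (so batch simulations stay reproducible from one upstream seed).
#' @return Tibble with `month_index`, `mean_patients`, `patients`.
#' @export
simulate_uptake <- function(params, horizon_months, seed = NULL) {
  if (!inherits(params, "uptake_params")) {
    stop("params must come from uptake_params()", call. = FALSE)
  }
  if (horizon_months < 1) stop("horizon_months must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  t <- seq_len(horizon_months)
  ceiling_t <- params$ceiling *
    ifelse(!is.na(params$expansion_month) & t >= params$expansion_month,
           params$expansion_multiplier, 1)
  if (params$growth_rate == 0) {
    mean_t <- ceiling_t
  } else {
    odds0 <- (1 - params$start_frac) / params$start_frac
    mean_t <- ceiling_t / (1 + odds0 * exp(-params$growth_rate * (t - 1)))
  }
  mean_t <- mean_t * (1 - params$dropout_rate)^(t - 1)
  patients <- if (params$poisson) stats::rpois(horizon_months, mean_t) else
    round(mean_t)
  tibble::tibble(month_index = t, mean_patients = mean_t,
                 patients = as.numeric(patients))
}

#' Simulate claims tables in the hospital and outpatient dialects
#'
#' Draws monthly patient counts per product from [simulate_uptake()], prices
#' them at the product's unit cost with multiplicative log-normal noise
#' (mean 1), and assembles per-channel claims tables in the same column
#' layouts the readers consume. Outpatient products can be split across
#' regional offices (multinomial, equal shares) to exercise strata
#' aggregation; costs follow the split so totals are conserved. Costs are
#' written in BGN (at the fixed 1.95583 rate) or EUR per each product's cost
#' parameters. Months listed in a product's `observation_gap` are omitted,
#' emulating incomplete reporting years.
#'
#' @param products List of product descriptors, each a list with
#'   `market_name`, `inn`, `channel` (`"hospital"`/`"outpatient"`),
#'   `uptake` ([uptake_params()]), `cost` ([cost_params()]), and optionally
#'   `atc_code`, `icd10`, `nhif_code`.
#' @param years Calendar years to simulate (month index 1 = January of
#'   `years[1]`).
#' @param seed Integer seed governing all randomness.
#' @param dir Optional directory; when given, per-channel CSVs and a JSON
#'   manifest of all parameters are written there.
#' @param n_regions Number of regional offices for outpatient rows.
#' @return List with `hospital` and `outpatient` claims tibbles (possibly
#'   `NULL`), the `truth` per-product monthly series, and written `paths`.
#' @export
simulate_claims <- function(products, years, seed, dir = NULL, n_regions = 1L) {
  if (length(products) == 0L) stop("at least one product required", call. = FALSE)
  set.seed(seed)
  horizon <- 12L * length(years)
  rows <- list()
  truth <- list()
  for (i in seq_along(products)) {
    p <- products[[i]]
    up <- simulate_uptake(p$uptake, horizon)
    cv <- p$cost$unit_cost_cv
    sdlog <- sqrt(log(1 + cv^2))
    noise <- stats::rlnorm(horizon, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    cost_eur <- up$patients * p$cost$unit_cost_eur * noise
    keep <- !(up$month_index %in% p$uptake$observation_gap)
    tbl <- tibble::tibble(
      year = years[ceiling(up$month_index / 12)],
      month = ((up$month_index - 1L) %% 12L) + 1L,
      market_name = p$market_name, inn = p$inn,
      atc_code = p$atc_code %||% NA_character_,
      icd10 = p$icd10 %||% NA_character_,
      patients = up$patients, cost_eur = cost_eur
    )[keep, , drop = FALSE]
    truth[[p$market_name]] <- tibble::tibble(
      year = years[ceiling(up$month_index / 12)],
      month = ((up$month_index - 1L) %% 12L) + 1L,
      patients = up$patients, mean_patients = up$mean_patients
    )
    if (p$channel == "outpatient" && n_regions > 1L) {
      tbl <- .split_regions(tbl, n_regions, p$cost$unit_cost_eur, noise[keep],
                            p$nhif_code %||% sprintf("NF%03d", i))
    } else if (p$channel == "outpatient") {
      tbl$region <- "sofia"
      tbl$nhif_code <- p$nhif_code %||% sprintf("NF%03d", i)
    }
    cur <- p$cost$currency
    tbl$cost <- if (cur == "BGN") convert_currency(tbl$cost_eur, "EUR", "BGN") else
      tbl$cost_eur
    tbl$cost_eur <- NULL
    tbl$.channel <- p$channel
    tbl$.currency <- cur
    rows[[i]] <- tbl
  }
  all_rows <- dplyr::bind_rows(rows)
  out <- list(truth = truth, paths = character(0))
  for (ch in c("hospital", "outpatient")) {
    sub <- all_rows[all_rows$.channel == ch, , drop = FALSE]
    if (nrow(sub) == 0L) { out[[ch]] <- NULL; next }
    currencies <- unique(sub$.currency)
    if (length(currencies) > 1L) {
      stop("products within one channel must share a claims currency",
           call. = FALSE)
    }
    cols <- c("year", "month", "market_name", "inn", "atc_code", "icd10",
              if (ch == "outpatient") c("region", "nhif_code"),
              "patients", "cost")
    out[[ch]] <- sub[cols]
    attr(out[[ch]], "currency") <- currencies
    if (!is.null(dir)) {
      path <- file.path(dir, paste0(ch, "_claims.csv"))
      write_claims_table(out[[ch]], path)
      out$paths[ch] <- path
    }
  }
  if (!is.null(dir)) {
    manifest <- list(seed = seed, years = years, n_regions = n_regions,
                     products = lapply(products, function(p) {
                       list(market_name = p$market_name, inn = p$inn,
                            channel = p$channel,
                            uptake = unclass(p$uptake), cost = unclass(p$cost))
                     }))
    manifest_path <- file.path(dir, "manifest.json")
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
    out$paths["manifest"] <- manifest_path
  }
  out
}

.split_regions <- function(tbl, n_regions, unit_cost, noise, nhif_code) {
  regions <- sprintf("region_%02d", seq_len(n_regions))
  pieces <- lapply(seq_len(nrow(tbl)), function(j) {
    n <- tbl$patients[j]
    split <- if (n > 0) {
      as.numeric(stats::rmultinom(1, size = n, prob = rep(1, n_regions)))
    } else rep(0, n_regions)
    piece <- tbl[rep(j, n_regions), , drop = FALSE]
    piece$region <- regions
    piece$nhif_code <- nhif_code
    piece$patients <- split
    piece$cost_eur <- split * unit_cost * noise[j]
    piece[piece$patients > 0 | seq_len(n_regions) == 1L, , drop = FALSE]
  })
  dplyr::bind_rows(pieces)
}

#' Write a claims table in its file dialect
#'
#' The same writer the generator uses, so reader/writer drift is caught by
#' round-trip tests.
#'
#' @param tbl Claims table as produced by [simulate_claims()].
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_claims_table <- function(tbl, path) {
  utils::write.csv(tbl, path, row.names = FALSE, fileEncoding = "UTF-8",
                   na = "")
  invisible(path)
}

#' Derive a biased HTA projection from a true utilization series
#'
#' The synthetic projection at each horizon is the bias factor times the
#' true median monthly count of that anchor year, so the pipeline's realized
#' patient ratio for the year is `1/bias` up to sampling noise (exactly, for
#' a noise-free series).
#'
#' @param series Monthly series for one product: columns `year`, `patients`.
#' @param market_name,inn,channel Identifiers for the projection row.
#' @param anchor_year_1,anchor_year_5 Projection horizons; the series must
#'   cover both.
#' @param bias A [bias_params()] object.
#' @return A one-row projection tibble as from [hta_projection()].
#' @export
derive_projections <- function(series, market_name, inn = NA_character_,
                               channel = NA_character_,
                               anchor_year_1, anchor_year_5,
                               bias = bias_params()) {
  for (anchor in c(anchor_year_1, anchor_year_5)) {
    if (!any(series$year == anchor)) {
      stop("series does not cover anchor year ", anchor, call. = FALSE)
    }
  }
  med1 <- stats::median(series$patients[series$year == anchor_year_1])
  med5 <- stats::median(series$patients[series$year == anchor_year_5])
  hta_projection(market_name, inn, channel, anchor_year_1, anchor_year_5,
                 patients_y1 = bias$volume_bias_y1 * med1,
                 patients_y5 = bias$volume_bias_y5 * med5)
}

#' Simulate a cost-pair cohort from the elasticity model
#'
#' Generates product-level cost pairs directly from the generative form of
#' the elasticity model: projected costs log-uniform on a range and
#' `ln(actual) = alpha + beta ln(projected) + Normal(0, noise_sd)`. Used for
#' parameter-recovery checks of [fit_loglog()].
#'
#' @param beta True elasticity.
#' @param alpha True intercept (log-EUR).
#' @param noise_sd Residual SD in log-points (>= 0).
#' @param n Number of pairs (>= 3).
#' @param projected_cost_range Positive `(lo, hi)` range of projected costs.
#' @param seed Optional integer seed.
#' @return Tibble of cost pairs with `market_name`, `year`, `channel`,
#'   `projected_cost_eur`, `actual_cost_eur`.
#' @export
simulate_elasticity_cohort <- function(beta, alpha = 0, noise_sd = 1, n = 20,
                                       projected_cost_range = c(1e4, 1e7),
                                       seed = NULL) {
  if (n < 3) stop("n must be >= 3", call. = FALSE)
  lo <- projected_cost_range[1L]; hi <- projected_cost_range[2L]
  if (!(lo > 0 && hi > lo)) stop("invalid projected_cost_range", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  lp <- stats::runif(n, log(lo), log(hi))
  la <- alpha + beta * lp + stats::rnorm(n, 0, noise_sd)
  tibble::tibble(market_name = sprintf("product_%03d", seq_len(n)),
                 year = 2025L, channel = "simulated",
                 projected_cost_eur = exp(lp), actual_cost_eur = exp(la))
}
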