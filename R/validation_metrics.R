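#' Round half away from zero
#'
#' Display rounding for report emission (ties go up in magnitude, matching
#' how the reference tables print 0.125 as 0.13 and 2.495 as 2.50). A tiny
#' guard absorbs binary representation error on exact decimal ties.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

#' Display precision for a patient or cost ratio
#'
#' Ratios are printed with two decimals below 10 and one decimal at 10 or
#' above.
#'
#' @param x Ratio value(s).
#' @return The ratio rounded half-up at its display precision.
#' @export
format_ratio <- function(x) {
  round_half_up(x, ifelse(abs(x) >= 10, 1L, 2L))
}

#' Summarize observed utilization for one product-year
#'
#' Collapses the product-month ledger of a single product within one
#' calendar year into the statistics the validation works from: the median
#' (and extremes) of monthly treated patients over the months actually
#' observed, the count of observed months (1-12, tracking incomplete
#' calendar years), the annualized patient volume (always 12 x the monthly
#' median, regardless of how many months were observed), the median monthly
#' cost, and the unit cost per patient-month (median monthly cost / median
#' monthly patients; `NA` when the median patient count is zero).
#'
#' @param product_months Product-month ledger rows (one product only), as
#'   from [aggregate_product_month()].
#' @param year Calendar year to summarize.
#' @return One-row tibble: identifiers, `year`, `months_observed`,
#'   `median_monthly_patients`, `min_monthly_patients`,
#'   `max_monthly_patients`, `annualized_patients`,
#'   `median_monthly_cost_eur`, `total_cost_eur`, `total_patient_months`,
#'   `unit_cost_eur`.
#' @export
summarize_utilization <- function(product_months, year) {
  key_cols <- intersect(c("market_name", "inn", "channel"), names(product_months))
  if (length(key_cols) > 0L &&
      nrow(unique(product_months[key_cols])) > 1L) {
    stop("product_months spans more than one product; summarize one at a time",
         call. = FALSE)
  }
  rows <- product_months[product_months$year == year, , drop = FALSE]
  if (nrow(rows) == 0L) {
    stop("no observed months in year ", year, call. = FALSE)
  }
  if (anyDuplicated(rows$month) > 0L) {
    stop("duplicate months in ledger; aggregate_product_month() first",
         call. = FALSE)
  }
  med_pat <- stats::median(rows$patients)
  med_cost <- stats::median(rows$cost_eur)
  out <- tibble::tibble(
    year = as.integer(year),
    months_observed = nrow(rows),
    median_monthly_patients = med_pat,
    min_monthly_patients = min(rows$patients),
    max_monthly_patients = max(rows$patients),
    annualized_patients = 12 * med_pat,
    median_monthly_cost_eur = med_cost,
    total_cost_eur = sum(rows$cost_eur),
    total_patient_months = sum(rows$patients),
    unit_cost_eur = if (med_pat > 0) med_cost / med_pat else NA_real_
  )
  if (length(key_cols) > 0L) {
    out <- dplyr::bind_cols(unique(product_months[key_cols]), out)
  }
  out
}

#' Unit cost per patient-month
#'
#' The price proxy of the validation: median monthly total cost divided by
#' the median monthly patient count. Undefined (an error, so callers can log
#' and exclude the product-year) when the median patient count is zero.
#'
#' @param summary A [summarize_utilization()] row.
#' @return Unit cost in EUR per patient-month.
#' @export
compute_unit_cost <- function(summary) {
  med_pat <- summary$median_monthly_patients[[1L]]
  if (is.na(med_pat) || med_pat <= 0) {
    stop("unit cost undefined: zero median monthly patients", call. = FALSE)
  }
  summary$median_monthly_cost_eur[[1L]] / med_pat
}

#' Actual and projected cost scenarios for a product-year
#'
#' The actual scenario is the sum of the monthly reimbursed costs. The
#' projected (counterfactual) scenario prices the HTA-projected patient
#' volume at the observed unit cost per patient-month over the months
#' actually observed: `projected_patients x unit_cost x months_observed`.
#'
#' @param summary A [summarize_utilization()] row (defines the unit cost and
#'   months observed).
#' @param projected_patients HTA-projected patients for the year (> 0).
#' @param monthly_costs Observed monthly costs (EUR) for the year.
#' @return One-row tibble with `actual_cost_eur` and `projected_cost_eur`.
#' @export
compute_cost_scenarios <- function(summary, projected_patients, monthly_costs) {
  if (is.na(projected_patients) || projected_patients <= 0) {
    stop("projected_patients must be positive", call. = FALSE)
  }
  unit_cost <- compute_unit_cost(summary)
  tibble::tibble(
    actual_cost_eur = sum(monthly_costs),
    projected_cost_eur = projected_patients * unit_cost *
      summary$months_observed[[1L]]
  )
}

#' Gap and ratio metrics for a product-year
#'
#' Patient ratios follow the monthly-median convention: median (and min/max)
#' monthly patients divided by the projected annual patient count - the
#' convention under which annualized/12 / projected reproduces the reference
#' cohort's printed ratios. An annual/annual convention
#' (`annualized_patients / projected`) is available via `ratio_convention`.
#' The cost gap is actual minus projected; the cost ratio actual/projected.
#' The gap is decomposed into a volume effect (patient-month shortfall or
#' excess priced at the reference unit cost) and a price effect (realized
#' minus reference unit cost on the realized volume); with the default
#' reference (the observed unit cost) the decomposition attributes the whole
#' gap to volume, and the two effects always sum to the gap against the
#' reference-cost projection.
#'
#' @param scenario A [compute_cost_scenarios()] row.
#' @param summary The matching [summarize_utilization()] row.
#' @param projected_patients HTA-projected patients for the year (> 0).
#' @param reference_unit_cost Unit cost anchoring the decomposition;
#'   defaults to the observed unit cost (use the HTA-implied unit cost,
#'   projected budget / projected patient-months, when a projected budget
#'   exists).
#' @param ratio_convention `"monthly_median"` (default) or `"annual"`.
#' @return One-row tibble with patient ratios (min/med/max), cost gap, cost
#'   ratio and the volume/price effects (EUR).
#' @export
compute_gap_metrics <- function(scenario, summary, projected_patients,
                                reference_unit_cost = NULL,
                                ratio_convention = c("monthly_median", "annual")) {
  ratio_convention <- match.arg(ratio_convention)
  if (is.na(projected_patients) || projected_patients <= 0) {
    stop("projected_patients must be positive", call. = FALSE)
  }
  scale <- if (ratio_convention == "monthly_median") 1 else 12
  actual <- scenario$actual_cost_eur[[1L]]
  projected <- scenario$projected_cost_eur[[1L]]
  if (projected <= 0) {
    warning("projected cost is zero; cost ratio undefined", call. = FALSE)
  }
  unit_cost <- summary$unit_cost_eur[[1L]]
  ref <- reference_unit_cost %||% unit_cost
  pm <- summary$total_patient_months[[1L]]
  realized_unit <- if (pm > 0) actual / pm else ref
  dec <- decompose_gap(projected_patients, pm, ref, realized_unit,
                       summary$months_observed[[1L]])
  tibble::tibble(
    year = summary$year[[1L]],
    patient_ratio_min = scale * summary$min_monthly_patients[[1L]] / projected_patients,
    patient_ratio_med = scale * summary$median_monthly_patients[[1L]] / projected_patients,
    patient_ratio_max = scale * summary$max_monthly_patients[[1L]] / projected_patients,
    cost_gap_eur = actual - projected,
    cost_ratio = if (projected > 0) actual / projected else NA_real_,
    volume_effect_eur = dec$volume_effect,
    price_effect_eur = dec$price_effect
  )
}

#' Laspeyres-style volume/price decomposition of a cost gap
#'
#' Splits the gap between actual spending and a reference-cost projection
#' into a volume effect, the deviation of realized patient-months from the
#' projected patient-months priced at the reference unit cost, and a price
#' effect, the deviation of the realized unit cost from the reference priced
#' at the realized volume. The two effects sum exactly to
#' `actual_cost - projected_patients x months_observed x reference_unit_cost`.
#'
#' @param projected_patients Projected patients for the year (> 0 expected).
#' @param actual_patient_months Realized patient-months over the observed
#'   window.
#' @param reference_unit_cost Reference EUR per patient-month (> 0).
#' @param realized_unit_cost Realized EUR per patient-month.
#' @param months_observed Number of observed months (1-12).
#' @return List with `volume_effect` and `price_effect` (EUR).
#' @export
decompose_gap <- function(projected_patients, actual_patient_months,
                          reference_unit_cost, realized_unit_cost,
                          months_observed) {
  if (!all(is.finite(c(projected_patients, actual_patient_months,
                       reference_unit_cost, realized_unit_cost,
                       months_observed)))) {
    stop("decompose_gap requires finite inputs", call. = FALSE)
  }
  if (reference_unit_cost <= 0) {
    stop("reference_unit_cost must be positive", call. = FALSE)
  }
  list(
    volume_effect = (actual_patient_months -
                       projected_patients * months_observed) * reference_unit_cost,
    price_effect = actual_patient_months *
      (realized_unit_cost - reference_unit_cost)
  )
}

#' Recover cost levels from a printed ratio/gap pair
#'
#' Published validation tables often print only the actual-to-projected cost
#' ratio and the absolute gap. Those two numbers determine the levels:
#' `projected = gap / (ratio - 1)` and `actual = ratio x projected`, so
#' re-deriving gap and ratio from the recovered levels returns the inputs.
#'
#' @param cost_ratio Actual/projected cost ratio(s), not equal to 1.
#' @param cost_gap_eur Actual minus projected cost(s), EUR.
#' @return Tibble with `projected_cost_eur` and `actual_cost_eur`.
#' @export
invert_ratio_gap <- function(cost_ratio, cost_gap_eur) {
  if (length(cost_ratio) != length(cost_gap_eur)) {
    stop("cost_ratio and cost_gap_eur must have equal length", call. = FALSE)
  }
  at_one <- cost_ratio == 1
  if (any(at_one & cost_gap_eur != 0)) {
    stop("inconsistent inputs: ratio 1 implies zero gap", call. = FALSE)
  }
  if (any(at_one & cost_gap_eur == 0)) {
    stop("indeterminate levels: ratio 1 with zero gap carries no scale",
         call. = FALSE)
  }
  projected <- cost_gap_eur / (cost_ratio - 1)
  tibble::tibble(projected_cost_eur = projected,
                 actual_cost_eur = cost_ratio * projected)
}

#' Compound annualized growth rate
#'
#' The constant per-year rate taking `value_y1` to `value_y5` over
#' `span_years` years: `(value_y5/value_y1)^(1/span_years) - 1`.
#'
#' @param value_y1 Starting value (> 0).
#' @param value_y5 Ending value.
#' @param span_years Number of years spanned (>= 1).
#' @return Growth rate per year (0.70 means +70%/year).
#' @export
annualized_growth <- function(value_y1, value_y5, span_years) {
  if (any(value_y1 <= 0)) stop("starting value must be positive", call. = FALSE)
  if (any(span_years < 1)) stop("span_years must be >= 1", call. = FALSE)
  (value_y5 / value_y1)^(1 / span_years) - 1
}
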