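#' Run the full projection-validation pipeline
#'
#' Orchestrates the analysis from a configuration: reads and normalizes the
#' claims files, aggregates them to the product-month ledger, joins the HTA
#' projections, summarizes utilization per product and horizon year, builds
#' the actual and projected cost scenarios, computes gap/ratio metrics, and
#' fits the elasticity battery (overall, by channel, by year, and after the
#' fold-change sensitivity filter) together with the aggregate log-ratio
#' bias test. Products lacking projections or with zero median utilization
#' pass through the utilization summaries but are excluded from ratio/cost
#' analytics, with every exclusion logged.
#'
#' @param config A list (or path to a YAML file) with fields:
#'   `claims` - list of entries, each with `path`, `dialect`
#'   (`"hospital"`/`"outpatient"`), optional `currency` (default `"BGN"`)
#'   and optional `col_map`; `projections` - path to the projections table
#'   or a projections tibble; optional `years` (analysis years; default
#'   each product's two anchors), `ratio_convention`
#'   (`"monthly_median"`/`"annual"`), `max_fold` (default 10) and `out_dir`
#'   (when set, CSV/JSON reports are written there).
#' @return Invisibly, a list: `product_months`, `metrics` (per-product
#'   table in the published layout), `pairs`, `fits` (named list of
#'   `loglog_fit`), `bias`, `exclusions`.
#' @export
run_validation <- function(config) {
  if (is.character(config)) config <- read_claims_config(config)
  claims_cfg <- config$claims
  if (is.null(claims_cfg) || length(claims_cfg) == 0L) {
    stop("config must list at least one claims file", call. = FALSE)
  }
  records <- dplyr::bind_rows(lapply(claims_cfg, function(entry) {
    rec <- read_claims_table(entry$path, dialect = entry$dialect,
                             col_map = entry$col_map,
                             currency = entry$currency %||% "BGN")
    rec$cost <- convert_currency(rec$cost, from = rec$currency, to = "EUR")
    rec$currency <- "EUR"
    normalize_record(rec)
  }))
  ledger <- aggregate_product_month(records)

  projections <- config$projections
  if (is.character(projections)) projections <- read_projections(projections)
  if (is.null(projections)) stop("config must provide projections", call. = FALSE)

  ratio_convention <- config$ratio_convention %||% "monthly_median"
  max_fold <- config$max_fold %||% 10

  exclusions <- list()
  metric_rows <- list()
  pair_rows <- list()
  products <- unique(ledger[c("market_name", "inn", "channel")])
  for (i in seq_len(nrow(products))) {
    prod <- products[i, ]
    pm <- dplyr::semi_join(ledger, prod, by = c("market_name", "inn", "channel"))
    proj <- projections[projections$market_name == prod$market_name &
                          projections$inn == prod$inn, , drop = FALSE]
    has_proj <- nrow(proj) == 1L && !is.na(proj$patients_y1) &&
      !is.na(proj$patients_y5)
    if (!has_proj) {
      exclusions[[length(exclusions) + 1L]] <- tibble::tibble(
        market_name = prod$market_name, inn = prod$inn, year = NA_integer_,
        reason = if (nrow(proj) == 0L) "no projection record" else
          "projection published without patient counts")
    }
    years <- config$years %||%
      if (has_proj) c(proj$anchor_year_1, proj$anchor_year_5) else
        range(pm$year)
    row <- c(as.list(prod), list(therapeutic_class = NA_character_))
    for (k in seq_along(years)) {
      y <- years[k]
      tag <- paste0("_y", if (k == 1L) "1" else "5")
      if (!any(pm$year == y)) {
        exclusions[[length(exclusions) + 1L]] <- tibble::tibble(
          market_name = prod$market_name, inn = prod$inn, year = as.integer(y),
          reason = "no observed months in year")
        next
      }
      su <- summarize_utilization(pm, y)
      row[[paste0("actual", tag)]] <- su$annualized_patients
      row[[paste0("months_observed", tag)]] <- su$months_observed
      if (!has_proj) next
      pp <- tryCatch(interpolate_projection(proj, y), error = function(e) NA_real_)
      if (is.na(pp)) {
        exclusions[[length(exclusions) + 1L]] <- tibble::tibble(
          market_name = prod$market_name, inn = prod$inn, year = as.integer(y),
          reason = "year outside projection horizon")
        next
      }
      row[[paste0("proj", tag)]] <- pp
      if (su$median_monthly_patients <= 0) {
        exclusions[[length(exclusions) + 1L]] <- tibble::tibble(
          market_name = prod$market_name, inn = prod$inn, year = as.integer(y),
          reason = "zero median monthly patients; unit cost undefined")
        next
      }
      scen <- compute_cost_scenarios(su, pp, pm$cost_eur[pm$year == y])
      gaps <- compute_gap_metrics(scen, su, pp,
                                  ratio_convention = ratio_convention)
      row[[paste0("ratio", tag, "_min")]] <- gaps$patient_ratio_min
      row[[paste0("ratio", tag, "_med")]] <- gaps$patient_ratio_med
      row[[paste0("ratio", tag, "_max")]] <- gaps$patient_ratio_max
      row[[paste0("cost_ratio", tag)]] <- gaps$cost_ratio
      row[[paste0("cost_gap", tag)]] <- gaps$cost_gap_eur
      row[[paste0("volume_effect", tag)]] <- gaps$volume_effect_eur
      row[[paste0("price_effect", tag)]] <- gaps$price_effect_eur
      if (scen$actual_cost_eur > 0 && scen$projected_cost_eur > 0) {
        pair_rows[[length(pair_rows) + 1L]] <- tibble::tibble(
          market_name = prod$market_name, inn = prod$inn,
          channel = prod$channel, year = as.integer(y),
          period = if (k == 1L) "Y1" else "Y5",
          projected_cost_eur = scen$projected_cost_eur,
          actual_cost_eur = scen$actual_cost_eur)
      }
    }
    metric_rows[[i]] <- tibble::as_tibble(row)
  }
  metrics <- dplyr::bind_rows(metric_rows)
  pairs <- dplyr::bind_rows(pair_rows)
  exclusions <- if (length(exclusions) > 0L) dplyr::bind_rows(exclusions) else
    tibble::tibble(market_name = character(0), inn = character(0),
                   year = integer(0), reason = character(0))
  for (j in seq_len(nrow(exclusions))) {
    message("excluded ", exclusions$market_name[j],
            if (!is.na(exclusions$year[j])) paste0(" (", exclusions$year[j], ")"),
            ": ", exclusions$reason[j])
  }

  result <- list(product_months = ledger, metrics = metrics, pairs = pairs,
                 fits = .fit_battery(pairs, max_fold), exclusions = exclusions)
  result$bias <- if (nrow(pairs) >= 2L) {
    tryCatch(test_log_ratio_bias(pairs), error = function(e) NULL)
  }
  if (!is.null(config$out_dir)) .write_reports(result, config$out_dir)
  invisible(result)
}

.fit_battery <- function(pairs, max_fold) {
  fits <- list()
  if (nrow(pairs) >= 3L) fits$overall <- fit_loglog(pairs)
  if (nrow(pairs) > 0L) {
    for (by in intersect(c("channel", "period"), names(pairs))) {
      sub <- stratify_fit(pairs, by = by)
      if (length(sub) > 0L) {
        names(sub) <- paste0(by, ":", names(sub))
        fits <- c(fits, sub)
      }
    }
    filtered <- apply_sensitivity_filter(pairs, max_fold = max_fold)
    if (nrow(filtered) >= 3L) {
      fits$sensitivity <- fit_loglog(filtered)
      attr(fits$sensitivity, "exclusions") <- attr(filtered, "exclusions")
    }
  }
  fits
}

#' Tabulate a battery of elasticity fits
#'
#' @param fits Named list of `loglog_fit` objects.
#' @return Tibble with one row per fit (stratum, n, coefficients, SEs,
#'   p-values, R-squared, residual SD).
#' @export
fits_table <- function(fits) {
  dplyr::bind_rows(lapply(names(fits), function(name) {
    f <- fits[[name]]
    tibble::tibble(stratum = name, n = f$n, alpha = f$alpha, beta = f$beta,
                   se_alpha = f$se_alpha, se_beta = f$se_beta,
                   p_alpha = f$p_alpha, p_beta = f$p_beta,
                   r2 = f$r2, resid_sd = f$resid_sd)
  }))
}

.write_reports <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(result$metrics, file.path(out_dir, "metrics.csv"),
                   row.names = FALSE, fileEncoding = "UTF-8", na = "")
  utils::write.csv(fits_table(result$fits),
                   file.path(out_dir, "regression.csv"),
                   row.names = FALSE, fileEncoding = "UTF-8", na = "")
  utils::write.csv(result$exclusions, file.path(out_dir, "exclusions.csv"),
                   row.names = FALSE, fileEncoding = "UTF-8", na = "")
  summary <- list(
    n_products = nrow(result$metrics),
    n_cost_pairs = nrow(result$pairs),
    fits = lapply(result$fits, function(f) {
      list(n = f$n, alpha = f$alpha, beta = f$beta, se_beta = f$se_beta,
           p_beta = f$p_beta, r2 = f$r2, resid_sd = f$resid_sd)
    }),
    bias = if (!is.null(result$bias)) unclass(result$bias),
    exclusions = nrow(result$exclusions)
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' Validation report for the packaged 2019 cohort
#'
#' Reconstructs the twenty cost pairs from the published 2019 Bulgarian HTA
#' cohort table via [hta_cohort_cost_pairs()] and runs the elasticity
#' battery on them: the pooled fit over both horizons, channel strata,
#' horizon strata (Y1/Y5), the fold-change sensitivity refit and the
#' aggregate log-ratio bias test. Also summarizes the published patient
#' ratios (median and range per horizon).
#'
#' @param out_dir Optional directory for CSV/JSON output (same files as
#'   [run_validation()]).
#' @param max_fold Sensitivity fold-change threshold (default 10).
#' @return List with `cohort`, `pairs`, `fits`, `bias`, `ratio_summary`.
#' @export
cohort_report <- function(out_dir = NULL, max_fold = 10) {
  cohort <- hta_cohort_2019()
  pairs <- hta_cohort_cost_pairs(cohort)
  fits <- .fit_battery(pairs, max_fold)
  ratio_summary <- tibble::tibble(
    period = c("Y1", "Y5"),
    median_ratio = c(stats::median(cohort$ratio_y1_med, na.rm = TRUE),
                     stats::median(cohort$ratio_y5_med, na.rm = TRUE)),
    min_ratio = c(min(cohort$ratio_y1_min, na.rm = TRUE),
                  min(cohort$ratio_y5_min, na.rm = TRUE)),
    max_ratio = c(max(cohort$ratio_y1_max, na.rm = TRUE),
                  max(cohort$ratio_y5_max, na.rm = TRUE))
  )
  result <- list(cohort = cohort, metrics = cohort, pairs = pairs,
                 fits = fits, bias = test_log_ratio_bias(pairs),
                 ratio_summary = ratio_summary,
                 exclusions = tibble::tibble(
                   market_name = "spinraza", inn = "nusinersen",
                   year = NA_integer_,
                   reason = "projection published without patient counts"))
  if (!is.null(out_dir)) .write_reports(result, out_dir)
  result
}
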