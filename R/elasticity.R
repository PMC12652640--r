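#' Fit the log-log elasticity model
#'
#' Ordinary least squares of `ln(actual cost)` on `ln(projected cost)` at the
#' product-year level. The slope is the elasticity of realized relative to
#' projected expenditure: 1 means actual spending scales proportionally with
#' forecasts, below 1 less than proportionally (forecasts overshoot the
#' high-spend end), above 1 more than proportionally. Coefficients come from
#' the closed-form normal equations; the slope standard error is
#' `resid_sd / sqrt(Sxx)` with residual variance `RSS/(n-2)`, and two-sided
#' p-values use the t distribution with `n - 2` degrees of freedom.
#'
#' @param pairs Tibble of cost pairs with strictly positive
#'   `projected_cost_eur` and `actual_cost_eur`; identifier columns
#'   (`market_name`/`inn`, `year`) label the residuals when present.
#' @return An object of class `"loglog_fit"`: `alpha`, `beta`, `se_alpha`,
#'   `se_beta`, `t_alpha`, `p_alpha`, `t_beta`, `p_beta`, `r2`, `resid_sd`,
#'   `n` and the named per-observation log `residuals` (fitted + residual
#'   reconstructs observed log actual cost exactly).
#' @export
fit_loglog <- function(pairs) {
  needed <- c("projected_cost_eur", "actual_cost_eur")
  missing_cols <- setdiff(needed, names(pairs))
  if (length(missing_cols) > 0L) {
    stop("pairs lack column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  bad <- which(!(pairs$projected_cost_eur > 0 & pairs$actual_cost_eur > 0))
  if (length(bad) > 0L) {
    labels <- .pair_labels(pairs)[bad]
    stop("nonpositive cost (log undefined) for: ",
         paste(utils::head(labels, 5L), collapse = "; "), call. = FALSE)
  }
  n <- nrow(pairs)
  if (n < 3L) stop("need at least 3 cost pairs to fit", call. = FALSE)

  x <- log(pairs$projected_cost_eur)
  y <- log(pairs$actual_cost_eur)
  xbar <- mean(x); ybar <- mean(y)
  sxx <- sum((x - xbar)^2)
  if (sxx <= 0) {
    stop("projected costs constant on the log scale; slope not identifiable",
         call. = FALSE)
  }
  beta <- sum((x - xbar) * (y - ybar)) / sxx
  alpha <- ybar - beta * xbar
  fitted <- alpha + beta * x
  resid <- y - fitted
  rss <- sum(resid^2)
  tss <- sum((y - ybar)^2)
  resid_sd <- sqrt(rss / (n - 2))
  se_beta <- resid_sd / sqrt(sxx)
  se_alpha <- resid_sd * sqrt(1 / n + xbar^2 / sxx)
  t_beta <- beta / se_beta
  t_alpha <- alpha / se_alpha
  r2 <- if (tss > 0) 1 - rss / tss else NA_real_

  structure(list(
    alpha = alpha, beta = beta,
    se_alpha = se_alpha, se_beta = se_beta,
    t_alpha = t_alpha, p_alpha = 2 * stats::pt(-abs(t_alpha), df = n - 2),
    t_beta = t_beta, p_beta = 2 * stats::pt(-abs(t_beta), df = n - 2),
    r2 = r2, resid_sd = resid_sd, n = n,
    residuals = stats::setNames(resid, .pair_labels(pairs))
  ), class = "loglog_fit")
}

.pair_labels <- function(pairs) {
  base <- if ("market_name" %in% names(pairs)) pairs$market_name
          else if ("inn" %in% names(pairs)) pairs$inn
          else as.character(seq_len(nrow(pairs)))
  if ("year" %in% names(pairs)) paste(base, pairs$year) else base
}

#' @export
print.loglog_fit <- function(x, ...) {
  cat("log-log elasticity fit (n =", x$n, ")\n")
  cat(sprintf("  beta (elasticity): %.4f  (SE %.4f, p %.3g)\n",
              x$beta, x$se_beta, x$p_beta))
  cat(sprintf("  alpha (intercept): %.4f  (SE %.4f, p %.3g)\n",
              x$alpha, x$se_alpha, x$p_alpha))
  cat(sprintf("  R-squared: %.4f   residual SD: %.4f log-points\n",
              x$r2, x$resid_sd))
  invisible(x)
}

#' Stratified elasticity fits
#'
#' Fits the log-log model independently within each stratum defined by one
#' or more columns of `pairs` (typically `channel`, `year` or both). Strata
#' failing the fit preconditions (fewer than 3 pairs, degenerate spread) are
#' skipped with a message and recorded in the `"skipped"` attribute, never
#' fatal.
#'
#' @param pairs Cost pairs as for [fit_loglog()].
#' @param by Stratifying column name(s) present in `pairs`.
#' @return Named list of `loglog_fit` objects, one per stratum that could be
#'   fitted; skipped strata in `attr(, "skipped")`.
#' @export
stratify_fit <- function(pairs, by = "channel") {
  missing_cols <- setdiff(by, names(pairs))
  if (length(missing_cols) > 0L) {
    stop("stratifying column(s) not in pairs: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  strata <- interaction(pairs[by], drop = TRUE, sep = ":")
  fits <- list()
  skipped <- character(0)
  for (level in levels(strata)) {
    sub <- pairs[strata == level, , drop = FALSE]
    result <- tryCatch(fit_loglog(sub), error = function(e) e)
    if (inherits(result, "error")) {
      skipped[level] <- conditionMessage(result)
      message("stratum '", level, "' skipped: ", conditionMessage(result))
    } else {
      fits[[level]] <- result
    }
  }
  attr(fits, "skipped") <- skipped
  fits
}

#' One-sample t-test of log cost ratios
#'
#' Tests whether `ln(actual/projected)` departs from zero on average - an
#' aggregate-bias check: a mean above zero means projections undershot
#' spending overall. The degenerate all-equal case at exact parity returns
#' the exact null (t = 0, p = 1); zero variance away from parity is an error
#' since the test statistic is undefined.
#'
#' @param pairs Cost pairs with strictly positive costs (n >= 2).
#' @return Object of class `"bias_test"`: `mean_log_ratio`, `t_statistic`,
#'   `p_value`, `n`.
#' @export
test_log_ratio_bias <- function(pairs) {
  if (nrow(pairs) < 2L) stop("need at least 2 pairs", call. = FALSE)
  if (any(!(pairs$projected_cost_eur > 0 & pairs$actual_cost_eur > 0))) {
    stop("nonpositive cost; log ratio undefined", call. = FALSE)
  }
  lr <- log(pairs$actual_cost_eur / pairs$projected_cost_eur)
  if (stats::sd(lr) == 0) {
    if (mean(lr) == 0) {
      out <- list(mean_log_ratio = 0, t_statistic = 0, p_value = 1,
                  n = length(lr))
      return(structure(out, class = "bias_test"))
    }
    stop("degenerate variance: identical nonzero log ratios", call. = FALSE)
  }
  tt <- stats::t.test(lr, mu = 0)
  structure(list(mean_log_ratio = mean(lr),
                 t_statistic = unname(tt$statistic),
                 p_value = tt$p.value, n = length(lr)),
            class = "bias_test")
}

#' @export
print.bias_test <- function(x, ...) {
  cat(sprintf("one-sample t-test of log(actual/projected): mean %.4f, t %.3f, p %.3g (n %d)\n",
              x$mean_log_ratio, x$t_statistic, x$p_value, x$n))
  invisible(x)
}

#' Sensitivity filter for extreme deviations and incomplete products
#'
#' Drops cost pairs whose actual/projected ratio deviates more than
#' `max_fold`-fold in either direction (strictly above `max_fold` or
#' strictly below `1/max_fold`), and optionally products that are missing an
#' observation in any of the years present in the input. Every exclusion is
#' recorded with its reason in the `"exclusions"` attribute.
#'
#' @param pairs Cost pairs.
#' @param max_fold Fold-change threshold (> 1); `Inf` disables the filter.
#' @param require_complete Also drop products not observed in every year of
#'   the input.
#' @return Filtered pairs; exclusion log in `attr(, "exclusions")`.
#' @export
apply_sensitivity_filter <- function(pairs, max_fold = 10,
                                     require_complete = FALSE) {
  if (!is.numeric(max_fold) || max_fold <= 1) {
    stop("max_fold must exceed 1", call. = FALSE)
  }
  ratio <- pairs$actual_cost_eur / pairs$projected_cost_eur
  labels <- .pair_labels(pairs)
  drop_extreme <- ratio > max_fold | ratio < 1 / max_fold
  exclusions <- tibble::tibble(
    pair = labels[drop_extreme],
    ratio = ratio[drop_extreme],
    reason = sprintf("cost ratio %.3g beyond %g-fold band",
                     ratio[drop_extreme], max_fold)
  )
  keep <- !drop_extreme
  if (require_complete && "year" %in% names(pairs)) {
    id_cols <- intersect(c("market_name", "inn", "channel"), names(pairs))
    product <- do.call(paste, c(pairs[id_cols], sep = "|"))
    n_years <- length(unique(pairs$year))
    complete <- names(which(tapply(pairs$year, product,
                                   function(y) length(unique(y))) == n_years))
    drop_incomplete <- keep & !(product %in% complete)
    if (any(drop_incomplete)) {
      exclusions <- dplyr::bind_rows(exclusions, tibble::tibble(
        pair = labels[drop_incomplete],
        ratio = ratio[drop_incomplete],
        reason = "incomplete: product missing in some years"
      ))
      keep <- keep & !drop_incomplete
    }
  }
  if (nrow(exclusions) > 0L) {
    message("sensitivity filter removed ", nrow(exclusions), " pair(s): ",
            paste(exclusions$pair, collapse = ", "))
  }
  out <- pairs[keep, , drop = FALSE]
  attr(out, "exclusions") <- exclusions
  out
}
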