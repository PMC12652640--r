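#' Construct an HTA patient projection
#'
#' An HTA dossier abstract states the expected number of treated patients in
#' the first and fifth year after a positive assessment (optionally with a
#' projected budget). The two horizons are anchored to calendar years; the
#' post-assessment trajectory between them is taken as linear.
#'
#' @param market_name,inn Product identifiers (normalized on construction).
#' @param channel Reimbursement channel, if known.
#' @param anchor_year_1,anchor_year_5 Calendar years of the Year-1 and
#'   Year-5 projection horizons (`anchor_year_5 > anchor_year_1`).
#' @param patients_y1,patients_y5 Projected annual patients at the anchors;
#'   both may be `NA` when the dossier published no counts, in which case the
#'   product is carried but excluded from ratio/cost analytics.
#' @param budget_y1,budget_y5 Optional projected budgets (EUR).
#' @return A one-row tibble with the projection fields.
#' @export
hta_projection <- function(market_name, inn = NA_character_,
                           channel = NA_character_,
                           anchor_year_1, anchor_year_5,
                           patients_y1 = NA_real_, patients_y5 = NA_real_,
                           budget_y1 = NA_real_, budget_y5 = NA_real_) {
  if (anchor_year_5 <= anchor_year_1) {
    stop("anchor_year_5 must be after anchor_year_1", call. = FALSE)
  }
  for (v in list(patients_y1, patients_y5)) {
    if (!is.na(v) && v <= 0) {
      stop("projected patients must be positive when present", call. = FALSE)
    }
  }
  tibble::tibble(
    market_name = normalize_text(market_name), inn = normalize_text(inn),
    channel = normalize_text(channel),
    anchor_year_1 = as.integer(anchor_year_1),
    anchor_year_5 = as.integer(anchor_year_5),
    patients_y1 = as.numeric(patients_y1), patients_y5 = as.numeric(patients_y5),
    budget_y1 = as.numeric(budget_y1), budget_y5 = as.numeric(budget_y5)
  )
}

#' Read an HTA projections table
#'
#' Expects a delimited file with columns `market_name`, `inn`,
#' `anchor_year_1`, `anchor_year_5`, `patients_y1`, `patients_y5` and
#' optionally `channel`, `budget_y1`, `budget_y5`. Patient cells may be blank
#' (projection not published).
#'
#' @param path Path to a UTF-8 delimited text file.
#' @return Tibble of projections, text fields normalized.
#' @export
read_projections <- function(path) {
  if (!file.exists(path)) stop("projections file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1L, warn = FALSE)
  if (length(header) == 0L || !nzchar(trimws(header))) {
    stop("empty projections file: ", path, call. = FALSE)
  }
  df <- utils::read.table(path, header = TRUE, sep = .sniff_sep(header),
                          colClasses = "character", check.names = FALSE,
                          quote = "\"", na.strings = c("", "NA"),
                          fileEncoding = "UTF-8", stringsAsFactors = FALSE)
  needed <- c("market_name", "inn", "anchor_year_1", "anchor_year_5",
              "patients_y1", "patients_y5")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0L) {
    stop("missing required column '", missing_cols[1L], "' in ", path,
         call. = FALSE)
  }
  num <- function(x) suppressWarnings(as.numeric(x))
  tibble::tibble(
    market_name = normalize_text(df$market_name),
    inn = normalize_text(df$inn),
    channel = if ("channel" %in% names(df)) normalize_text(df$channel) else NA_character_,
    anchor_year_1 = as.integer(num(df$anchor_year_1)),
    anchor_year_5 = as.integer(num(df$anchor_year_5)),
    patients_y1 = num(df$patients_y1), patients_y5 = num(df$patients_y5),
    budget_y1 = if ("budget_y1" %in% names(df)) num(df$budget_y1) else NA_real_,
    budget_y5 = if ("budget_y5" %in% names(df)) num(df$budget_y5) else NA_real_
  )
}

.proj_field <- function(projection, name) {
  v <- projection[[name]]
  if (is.null(v)) stop("projection lacks field '", name, "'", call. = FALSE)
  v[[1L]]
}

#' Linearly interpolate a projection at a calendar year
#'
#' Patient volumes (and budgets, when present) are interpolated on the
#' straight line between the two anchor years; anchor years are returned
#' exactly and no extrapolation beyond the Year-5 horizon is allowed.
#'
#' @param projection One projection (one-row tibble or list) as from
#'   [hta_projection()] or a [read_projections()] row.
#' @param target_year Calendar year(s) inside the closed anchor interval.
#' @param what `"patients"` (default) or `"budget"`.
#' @return Numeric vector of interpolated values.
#' @export
interpolate_projection <- function(projection, target_year,
                                   what = c("patients", "budget")) {
  what <- match.arg(what)
  y1 <- .proj_field(projection, "anchor_year_1")
  y5 <- .proj_field(projection, "anchor_year_5")
  v1 <- .proj_field(projection, paste0(what, "_y1"))
  v5 <- .proj_field(projection, paste0(what, "_y5"))
  if (is.na(v1) || is.na(v5)) {
    stop("missing projection anchors (", what, ") for ",
         .proj_field(projection, "market_name") %||% "product", call. = FALSE)
  }
  if (any(target_year < y1 | target_year > y5)) {
    stop("target year outside projection horizon [", y1, ", ", y5,
         "]; no extrapolation", call. = FALSE)
  }
  # exact at anchors, affine in between
  ifelse(target_year == y1, v1,
         ifelse(target_year == y5, v5,
                v1 + (v5 - v1) * (target_year - y1) / (y5 - y1)))
}

#' Materialize a projection as a yearly series
#'
#' One value per calendar year in the closed anchor interval, collinear by
#' construction (zero second differences).
#'
#' @inheritParams interpolate_projection
#' @return Tibble with `year`, `patients` and, when both budget anchors are
#'   present, `budget`.
#' @export
build_projection_series <- function(projection) {
  y1 <- .proj_field(projection, "anchor_year_1")
  y5 <- .proj_field(projection, "anchor_year_5")
  years <- seq.int(y1, y5)
  out <- tibble::tibble(
    year = years,
    patients = interpolate_projection(projection, years, "patients")
  )
  b1 <- .proj_field(projection, "budget_y1")
  b5 <- .proj_field(projection, "budget_y5")
  if (!is.na(b1) && !is.na(b5)) {
    out$budget <- interpolate_projection(projection, years, "budget")
  }
  out
}
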