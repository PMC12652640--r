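#' Default column mapping for a claims dialect
#'
#' Claims extracts arrive in two layouts: the hospital dialect (one row per
#' product-month) and the outpatient dialect (one row per product-month and
#' regional office, optionally carrying an NHIF product code and ICD-10
#' diagnosis). The mapping links the canonical field names used throughout
#' the package to the column headers found in the file; headers can be
#' overridden via a config list or YAML (see [read_claims_config()]).
#'
#' @param dialect `"hospital"` or `"outpatient"`.
#' @return Named list mapping canonical fields to file column names.
#' @export
default_col_map <- function(dialect = c("hospital", "outpatient")) {
  dialect <- match.arg(dialect)
  map <- list(
    year = "year", month = "month",
    market_name = "market_name", inn = "inn",
    atc_code = "atc_code", icd10 = "icd10",
    patients = "patients", cost = "cost"
  )
  if (dialect == "outpatient") {
    map$region <- "region"
    map$nhif_code <- "nhif_code"
  }
  map
}

.required_fields <- c("year", "month", "market_name", "inn", "patients", "cost")
.text_fields <- c("market_name", "inn", "atc_code", "icd10", "region", "channel")

.sniff_sep <- function(header_line) {
  counts <- vapply(c(",", "\t", ";"), function(s) {
    lengths(regmatches(header_line, gregexpr(s, header_line, fixed = TRUE)))
  }, integer(1))
  if (all(counts == 0L)) return(",")
  names(counts)[which.max(counts)]
}

.parse_numeric <- function(x, field, path) {
  v <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(v))
  if (length(bad) > 0L) {
    stop("non-numeric '", field, "' value in ", path, " at data row(s) ",
         paste(utils::head(bad, 10L), collapse = ", "),
         if (length(bad) > 10L) " ...", call. = FALSE)
  }
  v
}

#' Read a monthly reimbursement claims table
#'
#' Parses a delimited claims extract (delimiter sniffed among comma, tab and
#' semicolon) into one claims record per data row. The reimbursement channel
#' is taken from the dialect unless the file carries a mapped `channel`
#' column (combined extracts). Malformed rows are rejected with their row
#' numbers so the offending source lines can be located.
#'
#' @param path Path to a UTF-8 delimited text file with a header row.
#' @param dialect Which claims layout the file uses; sets the channel.
#' @param col_map Canonical-field to column-header mapping; defaults to
#'   [default_col_map()] for the dialect.
#' @param currency Currency tag (`"BGN"` or `"EUR"`) applied to the cost
#'   column when the file has no mapped `currency` column.
#' @return A tibble of claims records: `year`, `month`, `channel`,
#'   `market_name`, `inn`, `atc_code`, `icd10`, `region`, `nhif_code`,
#'   `patient_count`, `cost`, `currency`.
#' @seealso [normalize_record()], [aggregate_product_month()]
#' @export
read_claims_table <- function(path, dialect = c("hospital", "outpatient"),
                              col_map = NULL, currency = c("BGN", "EUR")) {
  dialect <- match.arg(dialect)
  currency <- match.arg(currency)
  if (is.null(col_map)) col_map <- default_col_map(dialect)
  if (!file.exists(path)) stop("claims file not found: ", path, call. = FALSE)
  lines <- readLines(path, n = 2L, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty claims file: ", path, call. = FALSE)

  sep <- .sniff_sep(lines[1L])
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", check.names = FALSE,
                          quote = "\"", comment.char = "",
                          na.strings = c("", "NA"), fileEncoding = "UTF-8",
                          stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("empty claims file (no data rows): ", path, call. = FALSE)

  for (field in .required_fields) {
    colname <- col_map[[field]]
    if (is.null(colname) || !colname %in% names(df)) {
      stop("missing required column '", colname %||% field, "' (", field,
           ") in ", path, call. = FALSE)
    }
  }
  pick <- function(field) {
    colname <- col_map[[field]]
    if (!is.null(colname) && colname %in% names(df)) df[[colname]] else
      rep(NA_character_, nrow(df))
  }

  year <- .parse_numeric(pick("year"), "year", path)
  month <- .parse_numeric(pick("month"), "month", path)
  patients <- .parse_numeric(pick("patients"), "patients", path)
  cost <- .parse_numeric(pick("cost"), "cost", path)

  bad_month <- which(month < 1 | month > 12 | month != floor(month))
  if (length(bad_month) > 0L) {
    stop("month outside 1-12 in ", path, " at data row(s) ",
         paste(utils::head(bad_month, 10L), collapse = ", "), call. = FALSE)
  }
  bad_neg <- which(patients < 0 | cost < 0)
  if (length(bad_neg) > 0L) {
    stop("negative patients/cost in ", path, " at data row(s) ",
         paste(utils::head(bad_neg, 10L), collapse = ", "), call. = FALSE)
  }

  channel <- pick("channel")
  channel <- ifelse(is.na(channel), dialect, tolower(trimws(channel)))
  bad_channel <- which(!channel %in% c("hospital", "outpatient"))
  if (length(bad_channel) > 0L) {
    stop("unknown channel in ", path, " at data row(s) ",
         paste(utils::head(bad_channel, 10L), collapse = ", "), call. = FALSE)
  }
  cur <- pick("currency")
  cur <- ifelse(is.na(cur), currency, toupper(trimws(cur)))
  bad_cur <- which(!cur %in% c("BGN", "EUR"))
  if (length(bad_cur) > 0L) {
    stop("unknown currency tag in ", path, " at data row(s) ",
         paste(utils::head(bad_cur, 10L), collapse = ", "), call. = FALSE)
  }

  tibble::tibble(
    year = as.integer(year), month = as.integer(month), channel = channel,
    market_name = pick("market_name"), inn = pick("inn"),
    atc_code = pick("atc_code"), icd10 = pick("icd10"),
    region = pick("region"), nhif_code = pick("nhif_code"),
    patient_count = patients, cost = cost, currency = cur
  )
}

#' Read a YAML claims configuration
#'
#' The config may carry, per dialect, a `col_map` block (canonical field ->
#' file column header) and a `currency` tag for the cost column.
#'
#' @param path Path to a YAML file.
#' @return The configuration as a nested list.
#' @export
read_claims_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  yaml::read_yaml(path)
}

#' Normalize free-text fields of claims records
#'
#' Lowercases, trims leading/trailing whitespace and collapses internal runs
#' of spaces/tabs to a single space, so that product identities survive the
#' inconsistent capitalization and separators typical of administrative
#' extracts. Idempotent; numeric fields are untouched.
#'
#' @param records A tibble of claims records (any number of rows).
#' @return The records with text fields normalized.
#' @export
normalize_record <- function(records) {
  for (field in intersect(.text_fields, names(records))) {
    records[[field]] <- normalize_text(records[[field]])
  }
  records
}

#' @rdname normalize_record
#' @param x Character vector.
#' @export
normalize_text <- function(x) {
  gsub("[ \t]+", " ", trimws(tolower(x)))
}

#' Convert monetary amounts between BGN and EUR
#'
#' Uses the fixed currency-board rate 1 EUR = 1.95583 BGN. Converting an
#' amount to its own currency is the identity; the conversion is exactly
#' invertible up to floating-point rounding.
#'
#' @param amount Numeric vector of amounts.
#' @param from,to Currency tags, `"BGN"` or `"EUR"` (vectorized over `from`).
#' @return Numeric vector in the target currency.
#' @export
convert_currency <- function(amount, from, to = "EUR") {
  known <- c("BGN", "EUR")
  if (length(to) != 1L || !to %in% known) {
    stop("unknown target currency tag: ", paste(to, collapse = ", "), call. = FALSE)
  }
  if (any(!from %in% known)) {
    stop("unknown currency tag: ",
         paste(unique(from[!from %in% known]), collapse = ", "), call. = FALSE)
  }
  divisor <- rep_len(ifelse(from == "BGN", BGN_PER_EUR, 1), length(amount))
  in_eur <- amount / divisor
  if (to == "BGN") in_eur * BGN_PER_EUR else in_eur
}

#' Aggregate claims records into a product-month ledger
#'
#' Sums patients and cost over regional/diagnostic strata within each
#' (market name, INN, channel, year, month) cell and emits the cost in EUR.
#' Duplicate rows are additive strata and are summed with a warning. All
#' records must share one currency tag; convert first otherwise.
#'
#' @param records Tibble of (normalized) claims records as returned by
#'   [read_claims_table()].
#' @return Tibble with one row per product-month: `market_name`, `inn`,
#'   `channel`, `year`, `month`, `patients`, `cost_eur`, sorted by product
#'   then calendar.
#' @export
aggregate_product_month <- function(records) {
  needed <- c("market_name", "inn", "channel", "year", "month",
              "patient_count", "cost", "currency")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols) > 0L) {
    stop("records lack column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(records) == 0L) stop("no claims records to aggregate", call. = FALSE)
  if (length(unique(records$currency)) > 1L) {
    stop("mixed currencies in ledger; convert with convert_currency() first",
         call. = FALSE)
  }
  if (anyDuplicated(records) > 0L) {
    warning("duplicate claim rows detected; summing them as additive strata",
            call. = FALSE)
  }
  records$cost_eur <- convert_currency(records$cost, from = records$currency,
                                       to = "EUR")
  out <- records |>
    dplyr::group_by(.data$market_name, .data$inn, .data$channel,
                    .data$year, .data$month) |>
    dplyr::summarise(patients = sum(.data$patient_count),
                     cost_eur = sum(.data$cost_eur), .groups = "drop") |>
    dplyr::arrange(.data$market_name, .data$inn, .data$channel,
                   .data$year, .data$month)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
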