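# Small constructors used across tests; everything is built in code.

make_records <- function(n = 3, market_name = "bavencio", inn = "avelumab",
                         channel = "hospital", year = 2020,
                         month = seq_len(n), patients = rep(10, n),
                         cost = rep(1000, n), currency = "EUR",
                         region = NA_character_) {
  tibble::tibble(
    year = as.integer(year), month = as.integer(month), channel = channel,
    market_name = market_name, inn = inn,
    atc_code = NA_character_, icd10 = NA_character_,
    region = region, nhif_code = NA_character_,
    patient_count = patients, cost = cost, currency = currency
  )
}

make_ledger <- function(patients, cost_eur = patients * 1000,
                        market_name = "bavencio", inn = "avelumab",
                        channel = "hospital", year = 2020,
                        month = seq_along(patients)) {
  tibble::tibble(market_name = market_name, inn = inn, channel = channel,
                 year = as.integer(year), month = as.integer(month),
                 patients = patients, cost_eur = cost_eur)
}

write_claims_file <- function(df, sep = ",") {
  path <- tempfile(fileext = if (sep == ",") ".csv" else ".tsv")
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = TRUE,
                     fileEncoding = "UTF-8", na = "")
  path
}

hospital_claims_df <- function() {
  data.frame(
    year = c(2020, 2020, 2020), month = 1:3,
    market_name = c("BAVENCIO", "Bavencio", "bavencio"),
    inn = "Avelumab", atc_code = "L01FX04", icd10 = "C44",
    patients = c(4, 5, 6), cost = c(40000, 50000, 60000)
  )
}

# Lift a simulate_claims() channel table into the claims-record layout,
# as read_claims_table() would produce it from the written file.
make_records_from_sim <- function(tbl, channel) {
  tibble::tibble(
    year = as.integer(tbl$year), month = as.integer(tbl$month),
    channel = channel, market_name = tbl$market_name, inn = tbl$inn,
    atc_code = tbl$atc_code, icd10 = tbl$icd10,
    region = if ("region" %in% names(tbl)) tbl$region else NA_character_,
    nhif_code = if ("nhif_code" %in% names(tbl)) tbl$nhif_code else NA_character_,
    patient_count = tbl$patients, cost = tbl$cost,
    currency = attr(tbl, "currency")
  )
}

write_projections_file <- function(df) {
  path <- tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8", na = "")
  path
}
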