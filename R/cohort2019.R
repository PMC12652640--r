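#' Reference validation table: the 2019 Bulgarian HTA cohort
#'
#' The published per-product validation summary for the eleven medicines
#' from Bulgaria's 2019 HTA cohort that entered NHIF reimbursement, covering
#' the first (2020; 2021 for brigatinib) and fifth (2025) projection
#' horizons: projected annual patients at both anchors, annualized actual
#' patients (12 x the median monthly treated count), realized-to-projected
#' patient ratios (min-median-max across observed months), the
#' actual-to-projected cost ratio and the absolute cost gap (EUR). Nusinersen
#' published no patient or budget projections; its projection and cost cells
#' are `NA` and the product is excluded from ratio/cost analytics downstream.
#' The HIV combination from the same approval cohort is absent because it is
#' funded outside the NHIF.
#'
#' On every load the transcription is self-checked: the monthly-median
#' patient-ratio convention (`annualized/12 / projected`, rounded half-up at
#' display precision) must agree with the printed median ratio to within one
#' unit in the last printed decimal (the source table itself carries a
#' one-unit rounding inconsistency in a single cell), and the ratio/gap
#' inversion must yield strictly positive cost levels for every populated
#' row. A failure indicates a corrupted transcription and raises an error.
#'
#' @return Tibble with one row per product.
#' @seealso [hta_cohort_cost_pairs()], [invert_ratio_gap()], [cohort_report()]
#' @export
hta_cohort_2019 <- function() {
  tab <- tibble::tribble(
    ~market_name, ~inn,            ~channel,     ~therapeutic_class,
      ~anchor_year_1, ~anchor_year_5, ~proj_y1, ~proj_y5, ~actual_y1, ~actual_y5,
      ~ratio_y1_min, ~ratio_y1_med, ~ratio_y1_max,
      ~ratio_y5_min, ~ratio_y5_med, ~ratio_y5_max,
      ~cost_ratio_y1, ~cost_ratio_y5, ~cost_gap_y1, ~cost_gap_y5,
    "alunbrig",  "brigatinib",    "hospital",   "oncology",
      2021L, 2025L,   4.6,  11,   36,   198,
      0.22, 0.65, 1.09,   1.27, 1.50, 1.64,
      0.66, 1.52,  -62606,    179497,
    "bavencio",  "avelumab",      "hospital",   "oncology",
      2020L, 2025L,   4,    8,    60,   2040,
      0.50, 1.25, 1.75,   19.4, 21.3, 22.2,
      1.10, 21.5,  14117,    7642580,
    "cotellic",  "cobimetinib",   "hospital",   "oncology",
      2020L, 2025L,   43,   45,   60,   12,
      0.07, 0.12, 0.23,   0.02, 0.02, 0.04,
      0.14, 0.03, -1257502, -1151943,
    "hemlibra",  "emicizumab",    "outpatient", "hematology",
      2020L, 2025L,   16,   38,   24,   336,
      0.13, 0.13, 0.13,   0.63, 0.74, 0.92,
      0.12, 0.76, -1394694, -1264157,
    "imfinzi",   "durvalumab",    "hospital",   "oncology",
      2020L, 2025L,   46,   144,  198,  2688,
      0.22, 0.36, 0.41,   1.48, 1.55, 1.62,
      0.36, 1.54,  -757149,  4476511,
    "imnovid",   "pomalidomide",  "hospital",   "oncology",
      2020L, 2025L,   25,   35,   30,   174,
      0.08, 0.10, 0.12,   0.31, 0.41, 0.91,
      0.10, 0.72,  -468769,  -154140,
    "latuda",    "lurasidone",    "outpatient", "psychiatry",
      2020L, 2025L,   270,  690,  1416, 8064,
      0.22, 0.44, 0.55,   0.95, 0.97, 1.01,
      0.41, 1.06,  -66716,    26920,
    "skyrizi",   "risankizumab",  "outpatient", "immunology",
      2020L, 2025L,   45,   400,  558,  11976,
      0.71, 1.03, 1.58,   2.13, 2.50, 2.80,
      1.04, 2.50,   46091,   11140253,
    "spinraza",  "nusinersen",    "outpatient", "neurology",
      2020L, 2025L,   NA,   NA,   66,   132,
      NA, NA, NA,         NA, NA, NA,
      NA, NA,       NA,        NA,
    "tremfya",   "guselkumab",    "outpatient", "immunology",
      2020L, 2025L,   110,  570,  288,  13296,
      0.21, 0.22, 0.41,   1.68, 1.94, 2.23,
      0.24, 1.94, -1101437,  6275740,
    "verzenios", "abemaciclib",   "hospital",   "oncology",
      2020L, 2025L,   167,  927,  246,  7464,
      0.02, 0.12, 0.29,   0.64, 0.67, 0.74,
      0.15, 0.66, -1926427, -6036965
  )
  .validate_cohort(tab)
  tab
}

.validate_cohort <- function(tab) {
  for (period in c("y1", "y5")) {
    proj <- tab[[paste0("proj_", period)]]
    actual <- tab[[paste0("actual_", period)]]
    printed <- tab[[paste0("ratio_", period, "_med")]]
    ratio_cells <- which(!is.na(proj) & !is.na(printed))
    computed <- actual[ratio_cells] / 12 / proj[ratio_cells]
    digits <- ifelse(abs(printed[ratio_cells]) >= 10, 1L, 2L)
    off <- abs(round_half_up(computed, digits) - printed[ratio_cells]) >
      10^(-digits) + 1e-9
    if (any(off)) {
      stop("cohort fixture corrupted: patient-ratio cell(s) inconsistent for ",
           paste(tab$market_name[ratio_cells][off], period, collapse = ", "),
           call. = FALSE)
    }
    ratio <- tab[[paste0("cost_ratio_", period)]]
    gap <- tab[[paste0("cost_gap_", period)]]
    cost_cells <- which(!is.na(ratio))
    levels <- invert_ratio_gap(ratio[cost_cells], gap[cost_cells])
    if (any(levels$projected_cost_eur <= 0 | levels$actual_cost_eur <= 0)) {
      stop("cohort fixture corrupted: nonpositive cost level implied for ",
           paste(tab$market_name[cost_cells][
             levels$projected_cost_eur <= 0 | levels$actual_cost_eur <= 0
           ], period, collapse = ", "), call. = FALSE)
    }
  }
  invisible(tab)
}

#' Reconstructed cost pairs from the 2019 cohort table
#'
#' Inverts the printed cost-ratio/cost-gap pairs into projected and actual
#' cost levels via [invert_ratio_gap()] - one pair per product and horizon
#' for the ten products with cost data (twenty pairs). These reconstructed
#' levels are the inputs of the elasticity and bias analyses.
#'
#' @param cohort The cohort table; defaults to [hta_cohort_2019()].
#' @return Tibble with `market_name`, `inn`, `channel`, `therapeutic_class`,
#'   `period` (`"Y1"`/`"Y5"`), `year` (the anchor calendar year),
#'   `projected_cost_eur`, `actual_cost_eur`.
#' @export
hta_cohort_cost_pairs <- function(cohort = hta_cohort_2019()) {
  one_period <- function(period, year_col) {
    ratio <- cohort[[paste0("cost_ratio_", tolower(period))]]
    gap <- cohort[[paste0("cost_gap_", tolower(period))]]
    keep <- !is.na(ratio)
    levels <- invert_ratio_gap(ratio[keep], gap[keep])
    tibble::tibble(
      market_name = cohort$market_name[keep], inn = cohort$inn[keep],
      channel = cohort$channel[keep],
      therapeutic_class = cohort$therapeutic_class[keep],
      period = period, year = cohort[[year_col]][keep],
      projected_cost_eur = levels$projected_cost_eur,
      actual_cost_eur = levels$actual_cost_eur
    )
  }
  dplyr::bind_rows(one_period("Y1", "anchor_year_1"),
                   one_period("Y5", "anchor_year_5"))
}
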