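#' Risk classification thresholds
#'
#' The conventional US EPA decision bands: a hazard quotient or hazard index
#' is of concern at 1; a cancer risk below 1e-6 is negligible, between 1e-6
#' and 1e-4 borderline, and above 1e-4 unacceptable.
#'
#' @return A list with `hq_threshold`, `cr_negligible`, `cr_unacceptable`.
#' @export
risk_bands <- function() {
  list(hq_threshold = 1, cr_negligible = 1e-6, cr_unacceptable = 1e-4)
}

#' Target hazard quotient
#'
#' `THQ = CDI / RfD` with the chronic daily intake taken as the
#' non-carcinogenic average daily dose. Doses are carried in ug/kg/day
#' throughout the package while reference doses are in mg/kg/day, so the
#' unit conversion happens here, at a single point.
#'
#' @param add Average daily dose(s), ug/kg/day (non-carcinogenic endpoint).
#' @param rfd Reference dose, mg/kg/day, matched to the pathway (oral RfD
#'   for ingestion, dermal RfD for dermal contact).
#'
#' @return Dimensionless hazard quotient(s).
#' @export
#' @examples
#' thq(2.6156, 0.003)  # high-Cr station, child ingestion
thq <- function(add, rfd) {
  if (any(!is.finite(rfd) | rfd <= 0)) {
    stop("reference dose must be strictly positive", call. = FALSE)
  }
  if (any(add < 0, na.rm = TRUE)) stop("negative dose", call. = FALSE)
  (add / 1000) / rfd
}

#' Hazard index
#'
#' Sum of target hazard quotients over metals for one station, receptor,
#' and pathway. Metals that are non-detect contribute whatever the active
#' substitution policy assigned them (zero under the default policy).
#'
#' @param thqs Numeric vector of hazard quotients.
#' @return Their sum.
#' @export
hazard_index <- function(thqs) sum(thqs)

#' Incremental lifetime cancer risk
#'
#' `CR = CDI * CSF` with the chronic daily intake taken as the carcinogenic
#' average daily dose (lifetime averaging time; 0.01 dermal absorption).
#'
#' @param add_carc Average daily dose(s), ug/kg/day, computed with the
#'   carcinogenic endpoint.
#' @param csf Cancer slope factor, (mg/kg/day)^-1, matched to the pathway.
#'   `NA` marks a metal without a quantified slope factor and is an error.
#'
#' @return Dimensionless lifetime cancer probability(ies).
#' @export
cancer_risk <- function(add_carc, csf) {
  if (any(is.na(csf))) {
    stop("not a quantified carcinogen (no cancer slope factor)", call. = FALSE)
  }
  if (any(csf <= 0)) stop("cancer slope factor must be positive", call. = FALSE)
  if (any(add_carc < 0, na.rm = TRUE)) stop("negative dose", call. = FALSE)
  (add_carc / 1000) * csf
}

#' Total cancer risk
#'
#' Sum of per-metal, per-pathway cancer risks (ingestion + dermal over the
#' quantified carcinogens).
#'
#' @param crs Numeric vector of cancer risks.
#' @return Their sum.
#' @export
total_cancer_risk <- function(crs) sum(crs)

#' Classify a non-carcinogenic hazard value
#'
#' @param value Hazard quotient(s) or index(es), >= 0.
#' @return `"safe"` when strictly below 1, else `"unsafe"` (the boundary is
#'   unsafe).
#' @export
classify_noncarcinogenic <- function(value) {
  if (any(value < 0, na.rm = TRUE)) stop("negative hazard value", call. = FALSE)
  ifelse(value < risk_bands()$hq_threshold, "safe", "unsafe")
}

#' Classify a cancer risk
#'
#' @param cr Cancer risk(s), >= 0.
#' @return `"negligible"` below 1e-6, `"borderline"` from 1e-6 up to and
#'   including 1e-4 (a risk must surpass 1e-4 to be unacceptable),
#'   `"unacceptable"` above 1e-4.
#' @export
classify_carcinogenic <- function(cr) {
  if (any(cr < 0, na.rm = TRUE)) stop("negative cancer risk", call. = FALSE)
  b <- risk_bands()
  dplyr::case_when(
    cr < b$cr_negligible ~ "negligible",
    cr <= b$cr_unacceptable ~ "borderline",
    TRUE ~ "unacceptable"
  )
}

#' Percentage contribution of each component
#'
#' Shares of a set of non-negative risk components (e.g. per-metal hazard
#' quotients) in percent of their total; the shares sum to 100.
#'
#' @param values Named (or unnamed) numeric vector with at least one
#'   positive entry.
#' @return Numeric vector of percentages, same names and order.
#' @export
#' @examples
#' contribution_pct(c(As = 0.069, Hg = 0.005, Pb = 0.046, Cr = 0.189, Ni = 0.009))
contribution_pct <- function(values) {
  if (any(values < 0, na.rm = TRUE)) stop("negative component", call. = FALSE)
  total <- sum(values)
  if (!is.finite(total) || total <= 0) {
    stop("all components are zero; contributions undefined", call. = FALSE)
  }
  100 * values / total
}

#' Full risk table for a dose table
#'
#' Converts a [dose_table()] into the complete set of risk measures:
#' per-metal target hazard quotients, per-pathway hazard indices, the
#' combined (ingestion + dermal) hazard index, per-metal cancer risks for
#' the quantified carcinogens, and the total cancer risk per station and
#' receptor, each with its threshold classification.
#'
#' @param doses A `dose_tbl` from [dose_table()].
#' @param params The same [parameter_set()] used to build the doses (its
#'   toxicity registry supplies pathway-matched RfDs and CSFs).
#'
#' @return A list of class `metal_risk` with tibbles `thq`, `hi`,
#'   `hi_total`, `cr`, `tcr` and the parameter-set name.
#' @export
#' @examples
#' risk <- mashhad_stations() |>
#'   dose_table(builtin_parameter_set("paper_reproduction")) |>
#'   risk_table(builtin_parameter_set("paper_reproduction"))
#' dplyr::filter(risk$hi, classification == "unsafe")
risk_table <- function(doses, params) {
  stopifnot(inherits(params, "parameter_set"))
  tox <- params$toxicity

  thq_tbl <- doses |>
    dplyr::filter(.data$endpoint == "noncarcinogenic") |>
    dplyr::left_join(tox, by = "metal") |>
    dplyr::mutate(
      rfd = ifelse(.data$pathway == "ingestion", .data$RfD_oral, .data$RfD_dermal),
      thq = thq(.data$add_ugkgday, .data$rfd)
    ) |>
    dplyr::select("station", "site", "metal", "receptor", "pathway", "thq")

  hi_tbl <- thq_tbl |>
    dplyr::group_by(.data$station, .data$site, .data$receptor, .data$pathway) |>
    dplyr::summarise(hi = hazard_index(.data$thq), .groups = "drop") |>
    dplyr::mutate(classification = classify_noncarcinogenic(.data$hi))

  hi_total_tbl <- hi_tbl |>
    dplyr::group_by(.data$station, .data$site, .data$receptor) |>
    dplyr::summarise(hi_total = sum(.data$hi), .groups = "drop") |>
    dplyr::mutate(classification = classify_noncarcinogenic(.data$hi_total))

  carcinogens <- tox$metal[tox$carcinogen]
  cr_tbl <- doses |>
    dplyr::filter(.data$endpoint == "carcinogenic",
                  .data$metal %in% carcinogens) |>
    dplyr::left_join(tox, by = "metal") |>
    dplyr::mutate(
      csf = ifelse(.data$pathway == "ingestion", .data$CSF_oral, .data$CSF_dermal),
      cr = cancer_risk(.data$add_ugkgday, .data$csf)
    ) |>
    dplyr::select("station", "site", "metal", "receptor", "pathway", "cr")

  tcr_tbl <- cr_tbl |>
    dplyr::group_by(.data$station, .data$site, .data$receptor) |>
    dplyr::summarise(tcr = total_cancer_risk(.data$cr), .groups = "drop") |>
    dplyr::mutate(classification = classify_carcinogenic(.data$tcr))

  structure(
    list(thq = thq_tbl, hi = hi_tbl, hi_total = hi_total_tbl,
         cr = cr_tbl, tcr = tcr_tbl, parameter_set = params$name),
    class = "metal_risk"
  )
}

#' @export
print.metal_risk <- function(x, ...) {
  cat("<metal_risk> parameter set:", x$parameter_set, "\n")
  cat(sprintf("  %d THQ entries over %d stations\n",
              nrow(x$thq), dplyr::n_distinct(x$thq$station)))
  unsafe <- dplyr::filter(x$hi, .data$classification == "unsafe")
  cat(sprintf("  hazard index unsafe (>= 1) at %d station/receptor/pathway combinations\n",
              nrow(unsafe)))
  cat(sprintf("  total cancer risk: %d negligible, %d borderline, %d unacceptable\n",
              sum(x$tcr$classification == "negligible"),
              sum(x$tcr$classification == "borderline"),
              sum(x$tcr$classification == "unacceptable")))
  invisible(x)
}

#' Round half away from zero
#'
#' Decimal rounding with ties going away from zero, matching the convention
#' of the survey's printed tables (base R's `round()` rounds half to even).
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 3) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Publication-layout risk tables
#'
#' Pivots a [risk_table()] result into the wide station x (metal, receptor)
#' layout of the survey's printed hazard tables, one pathway at a time,
#' with values rounded half away from zero to three decimals and the hazard
#' index appended.
#'
#' @param risk A `metal_risk` object.
#' @param pathway `"ingestion"` or `"dermal"`.
#' @param digits Decimal places for rounding (default 3).
#'
#' @return A wide tibble, one row per station, columns
#'   `<metal>_<receptor>` plus `HI_adult`, `HI_child`.
#' @export
risk_wide <- function(risk, pathway = c("ingestion", "dermal"), digits = 3) {
  pathway <- match.arg(pathway)
  metal_order <- unique(risk$thq$metal)
  thq_w <- risk$thq |>
    dplyr::filter(.data$pathway == .env$pathway) |>
    dplyr::mutate(value = round_half_up(.data$thq, digits),
                  metal = factor(.data$metal, levels = metal_order)) |>
    dplyr::select("station", "site", "metal", "receptor", "value") |>
    dplyr::arrange(.data$metal) |>
    tidyr::pivot_wider(names_from = c("metal", "receptor"),
                       values_from = "value", names_sep = "_")
  hi_w <- risk$hi |>
    dplyr::filter(.data$pathway == .env$pathway) |>
    dplyr::mutate(value = round_half_up(.data$hi, digits)) |>
    dplyr::select("station", "receptor", "value") |>
    tidyr::pivot_wider(names_from = "receptor", values_from = "value",
                       names_prefix = "HI_")
  dplyr::left_join(thq_w, hi_w, by = "station") |>
    dplyr::arrange(.data$station)
}

#' Export a risk table to tidy CSV files
#'
#' Writes `thq.csv`, `hi.csv`, `hi_total.csv`, `cr.csv`, and `tcr.csv`
#' (one row per key) into a directory.
#'
#' @param risk A `metal_risk` object.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_risk_tables <- function(risk, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in c("thq", "hi", "hi_total", "cr", "tcr")) {
    readr::write_csv(risk[[nm]], file.path(dir, paste0(nm, ".csv")),
                     progress = FALSE)
  }
  invisible(dir)
}
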