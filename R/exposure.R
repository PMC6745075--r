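#' Average daily dose through water ingestion
#'
#' Implements the standard US EPA ingestion dose model
#' `ADD = C * IR_d * EF * ED / (BW * AT)` with the averaging time set by the
#' endpoint: `AT = ED * 365` days for the non-carcinogenic endpoint (so with
#' `EF = 365` the dose reduces to `C * IR_d / BW`) and
#' `AT = lifetime * 365` days for the carcinogenic endpoint.
#'
#' @param C Concentration(s) in ug/L; vectorized.
#' @param receptor A one-row receptor tibble (see [receptor_profile()]).
#' @param settings An [exposure_settings()] object.
#' @param endpoint `"noncarcinogenic"` or `"carcinogenic"`.
#'
#' @return Average daily dose(s) in ug/kg/day.
#' @export
#' @examples
#' child <- receptor_profile("child", 1.8, 16, 6, 365, 2800, 200)
#' add_ingestion(17.67, child, exposure_settings(), "noncarcinogenic")
add_ingestion <- function(C, receptor, settings,
                          endpoint = c("noncarcinogenic", "carcinogenic")) {
  endpoint <- match.arg(endpoint)
  if (any(C < 0, na.rm = TRUE)) stop("negative concentration", call. = FALSE)
  at_days <- .averaging_time(receptor, settings, endpoint)
  C * receptor$IR_d * receptor$EF * receptor$ED / (receptor$BW * at_days)
}

#' Average daily dose through dermal contact
#'
#' Implements the dermal dose model
#' `ADD = C * SA * SL * ABS * EF * ED * CF / (BW * AT)` where `ABS` is the
#' endpoint-specific dermal absorption fraction (0.001 non-carcinogenic,
#' 0.01 carcinogenic by default) and `CF` is the volumetric conversion
#' (`1e-3` L/cm^3) required for the result to land in ug/kg/day. For the
#' default child profile and the non-carcinogenic endpoint the expression
#' collapses to `0.035 * C`.
#'
#' @inheritParams add_ingestion
#' @return Average daily dose(s) in ug/kg/day.
#' @export
add_dermal <- function(C, receptor, settings,
                       endpoint = c("noncarcinogenic", "carcinogenic")) {
  endpoint <- match.arg(endpoint)
  if (any(C < 0, na.rm = TRUE)) stop("negative concentration", call. = FALSE)
  abs_frac <- if (endpoint == "carcinogenic") settings$ABS_carc else settings$ABS_noncarc
  at_days <- .averaging_time(receptor, settings, endpoint)
  C * receptor$SA * receptor$SL * abs_frac * receptor$EF * receptor$ED *
    settings$CF_dermal / (receptor$BW * at_days)
}

.averaging_time <- function(receptor, settings, endpoint) {
  if (endpoint == "carcinogenic") settings$lifetime * 365 else receptor$ED * 365
}

#' Full dose table for a concentration survey
#'
#' Crosses every station x metal measurement with every receptor, pathway
#' (ingestion, dermal), and endpoint (non-carcinogenic, carcinogenic) of a
#' parameter set and evaluates [add_ingestion()] / [add_dermal()] for each
#' combination. Non-detects must have been substituted; under the `"zero"`
#' policy their doses are exactly zero.
#'
#' @param table A substituted `conc_tbl`.
#' @param params A [parameter_set()].
#'
#' @return A tibble of class `dose_tbl` with columns `station`, `site`,
#'   `metal`, `receptor`, `pathway`, `endpoint`, `add_ugkgday`, and a
#'   `parameter_set` attribute recording provenance.
#' @export
#' @examples
#' doses <- mashhad_stations() |> dose_table(builtin_parameter_set("paper_reproduction"))
#' nrow(doses)  # 35 stations x 5 metals x 2 receptors x 2 pathways x 2 endpoints
dose_table <- function(table, params) {
  stopifnot(inherits(params, "parameter_set"))
  if (anyNA(table$conc_ugL)) {
    stop("non-detects present; apply substitute_nondetects() first",
         call. = FALSE)
  }
  grid <- tidyr::expand_grid(
    receptor = params$receptors$label,
    pathway = c("ingestion", "dermal"),
    endpoint = c("noncarcinogenic", "carcinogenic")
  )
  out <- tidyr::crossing(
    dplyr::select(table, "station", "site", "metal", "conc_ugL"), grid
  ) |>
    dplyr::group_by(.data$receptor, .data$pathway, .data$endpoint) |>
    dplyr::group_modify(function(df, key) {
      prof <- dplyr::filter(params$receptors, .data$label == key$receptor)
      fn <- if (key$pathway == "ingestion") add_ingestion else add_dermal
      df$add_ugkgday <- fn(df$conc_ugL, prof, params$settings, key$endpoint)
      df
    }) |>
    dplyr::ungroup() |>
    dplyr::select("station", "site", "metal", "receptor", "pathway",
                  "endpoint", "add_ugkgday") |>
    dplyr::arrange(.data$station, .data$metal, .data$receptor,
                   .data$pathway, .data$endpoint)
  class(out) <- unique(c("dose_tbl", class(out)))
  attr(out, "parameter_set") <- params$name
  out
}
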