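#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a risk table
#'
#' One row per station x metal x receptor x pathway x measure, stacking the
#' hazard quotients and (for quantified carcinogens) the cancer risks.
#'
#' @param x A `metal_risk` object from [risk_table()].
#' @param ... Unused.
#' @return A tibble with columns `station`, `site`, `metal`, `receptor`,
#'   `pathway`, `measure` (`"thq"` or `"cr"`), `value`.
#' @method tidy metal_risk
#' @export
tidy.metal_risk <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(dplyr::rename(x$thq, value = "thq"), measure = "thq"),
    dplyr::mutate(dplyr::rename(x$cr, value = "cr"), measure = "cr")
  ) |>
    dplyr::select("station", "site", "metal", "receptor", "pathway",
                  "measure", "value")
}

#' Summarise a risk table in one row
#'
#' @param x A `metal_risk` object.
#' @param ... Unused.
#' @return A one-row tibble: parameter-set name, station count, mean and
#'   maximum combined hazard index per receptor, the number of unsafe
#'   hazard-index entries, and the mean and maximum total cancer risk.
#' @method glance metal_risk
#' @export
glance.metal_risk <- function(x, ...) {
  hit <- x$hi_total
  tcr <- x$tcr
  tibble::tibble(
    parameter_set = x$parameter_set,
    n_stations = dplyr::n_distinct(hit$station),
    mean_hi_adult = mean(hit$hi_total[hit$receptor == "adult"]),
    mean_hi_child = mean(hit$hi_total[hit$receptor == "child"]),
    max_hi_child = max(hit$hi_total[hit$receptor == "child"]),
    n_hi_unsafe = sum(x$hi$classification == "unsafe"),
    mean_tcr_adult = mean(tcr$tcr[tcr$receptor == "adult"]),
    mean_tcr_child = mean(tcr$tcr[tcr$receptor == "child"]),
    max_tcr = max(tcr$tcr),
    n_tcr_unacceptable = sum(tcr$classification == "unacceptable")
  )
}
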