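#' Drinking-water guideline sets
#'
#' Maximum permissible concentrations (ug/L) for the five surveyed metals.
#' Three built-in agencies are provided: WHO, US EPA, and the Iranian
#' national standard (identical to the WHO values). Custom sets can be
#' built by passing `limits`.
#'
#' @param name Agency label: `"WHO"`, `"EPA"`, `"Iran"`, or any label when
#'   `limits` is supplied.
#' @param limits Optional named numeric vector of limits in ug/L (strictly
#'   positive), overriding the built-ins.
#'
#' @return A list of class `guideline_set` with elements `name` and
#'   `limits`.
#' @export
#' @examples
#' guideline_set("WHO")$limits
guideline_set <- function(name, limits = NULL) {
  if (is.null(limits)) {
    limits <- switch(name,
      WHO = c(As = 10, Hg = 6, Pb = 10, Cr = 50, Ni = 70),
      EPA = c(As = 10, Hg = 2, Pb = 15, Cr = 100, Ni = 20),
      Iran = c(As = 10, Hg = 6, Pb = 10, Cr = 50, Ni = 70),
      stop("unknown guideline set '", name,
           "'; supply limits= for a custom set", call. = FALSE)
    )
  }
  if (any(!is.finite(limits) | limits <= 0)) {
    stop("guideline limits must be strictly positive", call. = FALSE)
  }
  structure(list(name = name, limits = limits), class = "guideline_set")
}

#' Compare a concentration table against guideline limits
#'
#' Flags each station x metal measurement as compliant when its
#' concentration is at or below the agency limit (the boundary counts as
#' compliant: limits are maxima). Non-detects are compliant by
#' construction; unsubstituted non-detects are compared at zero.
#'
#' @param table A `conc_tbl`.
#' @param guides A [guideline_set()]. Every metal in the table must have a
#'   limit.
#'
#' @return A tibble with one row per station x metal: `station`, `site`,
#'   `metal`, `conc_ugL`, `limit_ugL`, `compliant`, and `margin_ugL`
#'   (concentration minus limit; positive for exceedances).
#' @export
#' @examples
#' mashhad_stations() |> compare_to_guidelines(guideline_set("WHO")) |>
#'   dplyr::filter(!compliant)
compare_to_guidelines <- function(table, guides) {
  stopifnot(inherits(guides, "guideline_set"))
  missing <- setdiff(unique(table$metal), names(guides$limits))
  if (length(missing) > 0) {
    stop("no guideline limit for metal(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  value <- ifelse(is.na(table$conc_ugL) & table$nondetect, 0, table$conc_ugL)
  tibble::tibble(
    station = table$station,
    site = table$site,
    metal = table$metal,
    conc_ugL = value,
    limit_ugL = unname(guides$limits[table$metal]),
    compliant = value <= unname(guides$limits[table$metal]),
    margin_ugL = value - unname(guides$limits[table$metal])
  )
}

#' List guideline exceedances
#'
#' Convenience filter over [compare_to_guidelines()] returning only the
#' non-compliant rows.
#'
#' @inheritParams compare_to_guidelines
#' @return A tibble of exceedances (zero rows when fully compliant).
#' @export
guideline_exceedances <- function(table, guides) {
  dplyr::filter(compare_to_guidelines(table, guides), !.data$compliant)
}
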