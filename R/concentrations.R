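#' Limits of detection used in the packaged survey
#'
#' Instrumental ICP-MS limits of detection (ug/L) for the five metals of the
#' packaged drinking-water survey.
#'
#' @return Named numeric vector of LODs in ug/L.
#' @export
default_lods <- function() {
  c(As = 0.11, Hg = 0.01, Pb = 0.15, Cr = 0.06, Ni = 0.22)
}

.meta_cols <- c("site", "station", "lat", "lon")

#' Read a station-level concentration table
#'
#' Reads a delimited concentration table (CSV, header row
#' `site,station,lat,lon,<metal>...`) in which each metal cell is either a
#' non-negative decimal concentration in ug/L or the token `"ND"` for a
#' measurement below the limit of detection. The result is a long tibble,
#' one row per station x metal, with non-detects carrying the metal's LOD
#' and an `NA` concentration until a substitution policy is applied with
#' [substitute_nondetects()].
#'
#' @param source Path to the CSV file.
#' @param lods Named numeric vector mapping each metal column to its limit
#'   of detection in ug/L. Defaults to [default_lods()].
#'
#' @return A tibble of class `conc_tbl` with columns `site`, `station`,
#'   `lat`, `lon`, `metal`, `conc_ugL`, `nondetect`, `lod`. Coordinates are
#'   kept as opaque strings.
#' @export
#' @examples
#' tbl <- read_concentration_table(
#'   system.file("extdata", "mashhad_stations.csv", package = "aquarisk"))
#' dplyr::count(tbl, nondetect)
read_concentration_table <- function(source, lods = default_lods()) {
  raw <- readr::read_csv(source, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (nrow(raw) == 0) stop("empty concentration table: ", source, call. = FALSE)
  missing_meta <- setdiff(.meta_cols, names(raw))
  if (length(missing_meta) > 0) {
    stop("missing required column(s): ", paste(missing_meta, collapse = ", "),
         call. = FALSE)
  }
  metals <- setdiff(names(raw), .meta_cols)
  if (length(metals) == 0) stop("no metal columns found", call. = FALSE)
  unknown <- setdiff(metals, names(lods))
  if (length(unknown) > 0) {
    stop("metal column(s) without a registered LOD: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }

  station <- suppressWarnings(as.integer(raw$station))
  if (anyNA(station)) {
    stop("unparseable station id in row(s) ",
         paste(which(is.na(station)), collapse = ", "), call. = FALSE)
  }
  dup <- station[duplicated(station)]
  if (length(dup) > 0) {
    stop("duplicated station id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }

  raw$station <- station
  raw$.row <- seq_len(nrow(raw))
  long <- tidyr::pivot_longer(
    raw, cols = dplyr::all_of(metals), names_to = "metal", values_to = "cell"
  )
  nondetect <- long$cell == "ND"
  value <- suppressWarnings(as.numeric(long$cell))
  bad <- which(!nondetect & (is.na(value) | value < 0))
  if (length(bad) > 0) {
    b <- bad[1]
    stop("invalid concentration cell '", long$cell[b], "' at row ",
         long$.row[b], ", column ", long$metal[b],
         " (expected a non-negative number or 'ND')", call. = FALSE)
  }

  out <- tibble::tibble(
    site = long$site,
    station = long$station,
    lat = long$lat,
    lon = long$lon,
    metal = factor(long$metal, levels = metals),
    conc_ugL = ifelse(nondetect, NA_real_, value),
    nondetect = nondetect,
    lod = unname(lods[long$metal])
  )
  out <- dplyr::arrange(out, .data$station, .data$metal)
  out$metal <- as.character(out$metal)
  new_conc_tbl(out, policy = NULL)
}

new_conc_tbl <- function(x, policy = NULL) {
  class(x) <- unique(c("conc_tbl", class(tibble::as_tibble(x))))
  attr(x, "nd_policy") <- policy
  x
}

#' The packaged 35-station distribution-network survey
#'
#' Station-level As, Hg, Pb, Cr, and Ni concentrations (ug/L) measured in
#' piped treated drinking water at 35 stations grouped into five city sites
#' (north, south, east, west, center), with mercury below the limit of
#' detection at 32 of the 35 stations.
#'
#' @param policy Non-detect substitution policy passed to
#'   [substitute_nondetects()], or `NULL` to leave non-detects
#'   unsubstituted.
#'
#' @return A `conc_tbl` tibble (35 stations x 5 metals, long format).
#' @export
#' @examples
#' mashhad_stations() |> site_summary()
mashhad_stations <- function(policy = "zero") {
  tbl <- read_concentration_table(
    system.file("extdata", "mashhad_stations.csv", package = "aquarisk"),
    lods = default_lods()
  )
  if (is.null(policy)) tbl else substitute_nondetects(tbl, policy)
}

#' Substitute non-detect concentrations
#'
#' Replaces below-LOD measurements by 0 (`"zero"`, the default convention
#' used throughout the packaged survey's tables), half the limit of
#' detection (`"half_lod"`), or the limit of detection itself (`"lod"`).
#' Detected values are never touched and the `nondetect` provenance flag is
#' retained, so the operation is idempotent for a fixed policy.
#'
#' @param table A `conc_tbl` tibble.
#' @param policy One of `"zero"`, `"half_lod"`, `"lod"`.
#'
#' @return The table with `conc_ugL` filled for non-detect rows.
#' @export
substitute_nondetects <- function(table, policy = c("zero", "half_lod", "lod")) {
  policy <- match.arg(policy)
  sub <- switch(policy,
                zero = 0,
                half_lod = table$lod / 2,
                lod = table$lod)
  table$conc_ugL[table$nondetect] <-
    if (length(sub) == 1) sub else sub[table$nondetect]
  new_conc_tbl(table, policy = policy)
}

#' Per-site concentration summaries
#'
#' Arithmetic mean and sample standard deviation (n - 1 denominator) of each
#' metal over the stations of each site, in ug/L. Non-detects must already
#' have been substituted; the SD is reported as `NA` for single-station
#' sites.
#'
#' @param table A substituted `conc_tbl`.
#'
#' @return A tibble with columns `site`, `metal`, `n`, `mean_ugL`, `sd_ugL`.
#' @export
site_summary <- function(table) {
  if (anyNA(table$conc_ugL)) {
    stop("non-detects present; apply substitute_nondetects() first",
         call. = FALSE)
  }
  if (any(is.na(table$site) | table$site == "")) {
    stop("station(s) without a site label", call. = FALSE)
  }
  table |>
    dplyr::group_by(.data$site, .data$metal) |>
    dplyr::summarise(
      n = dplyr::n_distinct(.data$station),
      mean_ugL = mean(.data$conc_ugL),
      sd_ugL = if (dplyr::n() >= 2) stats::sd(.data$conc_ugL) else NA_real_,
      .groups = "drop"
    )
}

#' Write a concentration table back to CSV
#'
#' Emits the same wide CSV dialect [read_concentration_table()] consumes,
#' with `"ND"` tokens for non-detect cells.
#'
#' @param table A `conc_tbl`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_concentration_table <- function(table, path) {
  wide <- table |>
    dplyr::mutate(cell = ifelse(.data$nondetect, "ND",
                                format(.data$conc_ugL, trim = TRUE,
                                       scientific = FALSE))) |>
    dplyr::select(dplyr::all_of(.meta_cols), "metal", "cell") |>
    tidyr::pivot_wider(names_from = "metal", values_from = "cell")
  readr::write_csv(wide, path, progress = FALSE)
  invisible(path)
}
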