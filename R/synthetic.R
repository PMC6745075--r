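#' Configure a synthetic monitoring campaign
#'
#' Describes the generative model standing in for a raw monitoring dataset:
#' per-metal lognormal concentration distributions (natural-log
#' parameterization, ug/L), a station layout grouped into sites, repeated
#' sampling rounds per station, and metal-specific limits of detection that
#' censor individual rounds.
#'
#' @param sites Named integer vector: station count per site label.
#' @param metals Tibble with columns `metal`, `meanlog`, `sdlog`
#'   (`sdlog >= 0`; `sdlog = 0` gives a degenerate point distribution).
#' @param rounds Sampling rounds per station (default 4, two per season in
#'   a dry/rainy design).
#' @param lods Named numeric vector of limits of detection, ug/L, one per
#'   metal.
#' @param seed Integer seed for the single pseudo-random stream.
#' @param site_offsets Optional tibble `site`, `metal`, `offset` of
#'   additive log-scale (i.e. multiplicative) site effects.
#'
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(sites, metals, rounds = 4, lods, seed = 1,
                             site_offsets = NULL) {
  stopifnot(is.numeric(sites), length(sites) >= 1, !is.null(names(sites)))
  if (any(sites < 1)) stop("each site needs at least one station", call. = FALSE)
  if (rounds < 1) stop("need at least one sampling round", call. = FALSE)
  if (any(metals$sdlog < 0)) stop("sdlog must be >= 0", call. = FALSE)
  missing_lod <- setdiff(metals$metal, names(lods))
  if (length(missing_lod) > 0) {
    stop("no LOD for metal(s): ", paste(missing_lod, collapse = ", "),
         call. = FALSE)
  }
  structure(
    list(sites = sites, metals = metals, rounds = as.integer(rounds),
         lods = lods, seed = as.integer(seed), site_offsets = site_offsets),
    class = "synthetic_config"
  )
}

#' Campaign configuration mirroring the packaged survey
#'
#' Five sites of seven stations sampled over four rounds, with per-metal
#' lognormal parameters moment-matched to the mean and standard deviation
#' of the packaged survey's 35 detected station values (As, Pb, Cr, Ni).
#' Mercury, detected at too few stations to moment-match, instead has its
#' log-location calibrated so the cell-level non-detect probability -- the
#' per-round censoring probability raised to the number of rounds, since a
#' cell is non-detect only when every round censors -- equals the survey's
#' observed Hg non-detect fraction (32/35).
#'
#' @param seed Integer seed (default 101).
#' @return A [synthetic_config()].
#' @export
paper_like_config <- function(seed = 101) {
  obs <- mashhad_stations(policy = NULL)
  detected <- obs |>
    dplyr::filter(!.data$nondetect) |>
    dplyr::group_by(.data$metal) |>
    dplyr::summarise(m = mean(.data$conc_ugL), s = stats::sd(.data$conc_ugL),
                     .groups = "drop")
  fit <- detected |>
    dplyr::filter(.data$metal != "Hg") |>
    dplyr::mutate(
      sdlog = sqrt(log(1 + (.data$s / .data$m)^2)),
      meanlog = log(.data$m) - .data$sdlog^2 / 2
    ) |>
    dplyr::select("metal", "meanlog", "sdlog")
  # Hg cannot be moment-matched (detected at only 3 of 35 stations), so its
  # log-location is calibrated instead: a cell is non-detect when all
  # `rounds` draws censor, so with sdlog = 1 the survey's observed cell-level
  # ND fraction (32/35) pins meanlog via
  # Phi((log(LOD) - meanlog) / sdlog)^rounds = 32/35.
  hg_nd <- mean(obs$nondetect[obs$metal == "Hg"])
  hg_meanlog <- log(0.01) - stats::qnorm(hg_nd^(1 / 4))
  metals <- dplyr::bind_rows(
    fit, tibble::tibble(metal = "Hg", meanlog = hg_meanlog, sdlog = 1)
  )
  metals <- metals[match(c("As", "Hg", "Pb", "Cr", "Ni"), metals$metal), ]
  synthetic_config(
    sites = c(north = 7, south = 7, east = 7, west = 7, center = 7),
    metals = metals, rounds = 4, lods = default_lods(), seed = seed
  )
}

#' Generate a synthetic concentration table
#'
#' For each station x metal x round, draws
#' `lognormal(meanlog + site offset, sdlog)`; rounds falling below the
#' metal's limit of detection are censored. A station x metal cell is the
#' mean of its detected rounds, or a non-detect if every round was
#' censored. Generation order is fixed (site, station, metal, round) under
#' one seeded stream, so the same configuration always yields a
#' byte-identical table. The uncensored round-level draws are attached as
#' the `"rounds"` attribute for oracle use in tests; they are not part of
#' the analysis table.
#'
#' @param config A [synthetic_config()].
#' @return A `conc_tbl` tibble (non-detects unsubstituted), with attribute
#'   `"rounds"` holding the true per-round values.
#' @export
#' @examples
#' tbl <- generate_concentration_table(paper_like_config())
#' site_summary(substitute_nondetects(tbl, "zero"))
generate_concentration_table <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))

  grid <- tidyr::expand_grid(
    site = names(config$sites),
    station_in_site = seq_len(max(config$sites))
  ) |>
    dplyr::filter(.data$station_in_site <= config$sites[.data$site]) |>
    dplyr::arrange(match(.data$site, names(config$sites)),
                   .data$station_in_site) |>
    dplyr::mutate(station = dplyr::row_number()) |>
    tidyr::expand_grid(metal = config$metals$metal,
                       round = seq_len(config$rounds))

  mpar <- config$metals[match(grid$metal, config$metals$metal), ]
  offset <- rep(0, nrow(grid))
  if (!is.null(config$site_offsets)) {
    key <- paste(grid$site, grid$metal)
    off <- stats::setNames(config$site_offsets$offset,
                           paste(config$site_offsets$site,
                                 config$site_offsets$metal))
    offset <- ifelse(key %in% names(off), off[key], 0)
  }

  # one seeded stream; restore the caller's RNG state afterwards
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(config$seed)
  z <- stats::rnorm(nrow(grid))

  rounds <- grid |>
    dplyr::mutate(
      true_ugL = exp(mpar$meanlog + offset + mpar$sdlog * z),
      lod = unname(config$lods[.data$metal]),
      censored = .data$true_ugL < .data$lod
    )

  cells <- rounds |>
    dplyr::group_by(.data$site, .data$station, .data$metal, .data$lod) |>
    dplyr::summarise(
      nondetect = all(.data$censored),
      conc_ugL = ifelse(all(.data$censored), NA_real_,
                        mean(.data$true_ugL[!.data$censored])),
      .groups = "drop"
    ) |>
    dplyr::mutate(lat = "", lon = "",
                  metal = factor(.data$metal, levels = config$metals$metal)) |>
    dplyr::arrange(.data$station, .data$metal) |>
    dplyr::mutate(metal = as.character(.data$metal)) |>
    dplyr::select("site", "station", "lat", "lon", "metal", "conc_ugL",
                  "nondetect", "lod")

  out <- new_conc_tbl(cells, policy = NULL)
  attr(out, "rounds") <- dplyr::select(rounds, "site", "station", "metal",
                                       "round", "true_ugL", "censored")
  out
}

#' Serialize a synthetic configuration to YAML
#'
#' @param config A [synthetic_config()].
#' @param path File to write.
#' @return `path`, invisibly.
#' @export
write_synthetic_config <- function(config, path) {
  obj <- list(
    sites = as.list(config$sites),
    metals = lapply(seq_len(nrow(config$metals)),
                    function(i) as.list(config$metals[i, ])),
    rounds = config$rounds,
    lods = as.list(config$lods),
    seed = config$seed
  )
  if (!is.null(config$site_offsets)) {
    obj$site_offsets <- lapply(seq_len(nrow(config$site_offsets)),
                               function(i) as.list(config$site_offsets[i, ]))
  }
  yaml::write_yaml(obj, path, precision = 17)
  invisible(path)
}

#' @rdname write_synthetic_config
#' @export
read_synthetic_config <- function(path) {
  obj <- yaml::read_yaml(path)
  synthetic_config(
    sites = unlist(obj$sites),
    metals = dplyr::bind_rows(lapply(obj$metals, tibble::as_tibble)),
    rounds = obj$rounds,
    lods = unlist(obj$lods),
    seed = obj$seed,
    site_offsets = if (is.null(obj$site_offsets)) NULL else
      dplyr::bind_rows(lapply(obj$site_offsets, tibble::as_tibble))
  )
}
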