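# Published hazard-index columns of the 35-station survey, in station order
# 1..35 (ingestion and dermal pathways, adult and child receptors). The
# dermal child value for station 1 is a documented erratum in the source
# table (prints 0.321 where the column's constant factors give 0.147) and
# is stored as NA here so comparisons skip it.
golden_hi <- list(
  ingestion_adult = c(
    0.046, 0.036, 0.050, 0.133, 0.065, 0.095, 0.244, 0.035, 0.031, 0.084,
    0.133, 0.130, 0.110, 0.154, 0.029, 0.169, 0.304, 0.058, 0.045, 0.040,
    0.089, 0.088, 0.179, 0.119, 0.047, 0.060, 0.100, 0.113, 0.091, 0.070,
    0.053, 0.153, 0.047, 0.295, 0.040),
  ingestion_child = c(
    0.145, 0.112, 0.156, 0.420, 0.206, 0.298, 0.769, 0.111, 0.098, 0.264,
    0.420, 0.409, 0.348, 0.484, 0.091, 0.533, 0.957, 0.183, 0.142, 0.127,
    0.281, 0.279, 0.565, 0.376, 0.147, 0.190, 0.316, 0.357, 0.288, 0.220,
    0.166, 0.482, 0.148, 0.929, 0.125),
  dermal_adult = c(
    0.030, 0.023, 0.050, 0.090, 0.050, 0.067, 0.182, 0.020, 0.018, 0.058,
    0.091, 0.099, 0.084, 0.110, 0.016, 0.120, 0.244, 0.036, 0.021, 0.022,
    0.061, 0.054, 0.205, 0.084, 0.043, 0.051, 0.070, 0.090, 0.065, 0.047,
    0.040, 0.100, 0.037, 0.236, 0.027),
  dermal_child = c(
    NA, 0.111, 0.247, 0.440, 0.246, 0.331, 0.894, 0.097, 0.088, 0.284,
    0.445, 0.484, 0.413, 0.541, 0.078, 0.589, 1.200, 0.178, 0.101, 0.109,
    0.302, 0.267, 1.008, 0.411, 0.212, 0.249, 0.342, 0.442, 0.318, 0.229,
    0.195, 0.491, 0.183, 1.159, 0.131)
)

# Published child ingestion dose column for Cr (ug/kg/day), station order.
golden_add_cr_child_ing <- c(
  0.047, 0.064, 0.109, 0.678, 0.307, 0.411, 1.988, 0.041, 0.060, 0.430,
  0.928, 0.930, 0.721, 1.149, 0.077, 1.257, 2.616, 0.053, 0.064, 0.066,
  0.468, 0.272, 0.713, 0.845, 0.035, 0.133, 0.501, 0.626, 0.459, 0.284,
  0.179, 0.886, 0.161, 2.194, 0.045)

fixture_table <- function(policy = "zero") mashhad_stations(policy)

repro_set <- function() builtin_parameter_set("paper_reproduction")
stated_set <- function() builtin_parameter_set("paper_stated")

fixture_risk <- function(params = repro_set()) {
  tbl <- fixture_table()
  risk_table(dose_table(tbl, params), params)
}

hi_column <- function(risk, pw, rec) {
  risk$hi |>
    dplyr::filter(.data$pathway == pw, .data$receptor == rec) |>
    dplyr::arrange(.data$station) |>
    dplyr::pull(.data$hi)
}

# Brute-force exact Kruskal-Wallis permutation distribution for tiny N:
# enumerates every assignment of the pooled observations to the group
# layout and returns the exact upper-tail probability of the observed H.
kw_exact_p <- function(x, g) {
  g <- as.factor(g)
  h_stat <- function(xx) {
    r <- rank(xx)
    n <- length(xx)
    rj <- tapply(r, g, sum)
    nj <- tabulate(g)
    h <- 12 / (n * (n + 1)) * sum(rj^2 / nj) - 3 * (n + 1)
    ties <- table(xx)
    C <- 1 - sum(ties^3 - ties) / (n^3 - n)
    if (C == 0) 0 else h / C
  }
  obs <- h_stat(x)
  perms <- combinat_permutations(length(x))
  stats <- apply(perms, 1, function(idx) h_stat(x[idx]))
  mean(stats >= obs - 1e-12)
}

# all permutations of 1..n as a matrix (n! rows); fine for n <= 8
combinat_permutations <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- combinat_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}
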