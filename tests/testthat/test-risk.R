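test_that("hazard quotients reproduce published cells", {
  expect_equal(round_half_up(thq(2.6156, 0.003), 3), 0.872)
  expect_equal(round_half_up(thq(0.814, 0.00075), 3), 1.085)
  expect_equal(thq(0, 0.003), 0)
  expect_error(thq(1, 0), "positive")
  expect_error(thq(-1, 0.003), "negative")
})

test_that("hazard indices reproduce published station cells and sums", {
  r <- fixture_risk()
  hi <- function(st, rec, pw) {
    dplyr::filter(r$hi, station == st, receptor == rec, pathway == pw)$hi
  }
  expect_equal(round_half_up(hi(7, "child", "ingestion"), 3), 0.769)
  expect_equal(round_half_up(hi(7, "child", "dermal"), 3), 0.894)
  expect_equal(round_half_up(hi(1, "child", "ingestion"), 3), 0.145)
  expect_equal(hazard_index(5), 5)  # single metal: HI is its THQ

  # HI is the exact sum of the per-metal THQs for every key
  check <- r$thq |>
    dplyr::group_by(station, receptor, pathway) |>
    dplyr::summarise(s = sum(thq), .groups = "drop") |>
    dplyr::left_join(r$hi, by = c("station", "receptor", "pathway"))
  expect_true(all(abs(check$s - check$hi) < 1e-12))
})

test_that("the full published hazard-index columns reproduce to 3 decimals", {
  r <- fixture_risk()
  for (pw in c("ingestion", "dermal")) {
    for (rec in c("adult", "child")) {
      got <- round_half_up(hi_column(r, pw, rec), 3)
      exp <- golden_hi[[paste(pw, rec, sep = "_")]]
      keep <- !is.na(exp)  # station-1 dermal child erratum excluded
      expect_equal(got[keep], exp[keep],
                   label = paste("HI", pw, rec))
    }
  }
  # published column means (computed from unrounded hazard indices)
  expect_equal(mean(hi_column(r, "ingestion", "child")), 0.318,
               tolerance = 0.002)
  expect_equal(mean(hi_column(r, "ingestion", "adult")), 0.101,
               tolerance = 0.002)
})

test_that("cancer risk matches the hand oracle and rejects non-carcinogens", {
  adult56 <- dplyr::filter(repro_set()$receptors, label == "adult")
  add <- add_ingestion(0.15, adult56, exposure_settings(), "carcinogenic")
  expect_equal(cancer_risk(add, 1.5), 3.44e-6, tolerance = 1e-3)
  expect_equal(cancer_risk(add, 1.5), (0.15 * 2 * 30 / (56 * 70)) / 1000 * 1.5)
  expect_equal(cancer_risk(0, 1.5), 0)
  expect_error(cancer_risk(1, NA_real_), "not a quantified carcinogen")
  expect_error(cancer_risk(1, toxicity_for(repro_set(), "Ni")$CSF_oral),
               "not a quantified carcinogen")
})

test_that("total cancer risk is additive and doubles with concentration", {
  expect_equal(total_cancer_risk(c(2e-6, 3e-6)), 5e-6)
  expect_equal(total_cancer_risk(rep(0, 6)), 0)

  tbl <- fixture_table()
  params <- repro_set()
  r <- risk_table(dose_table(tbl, params), params)
  r2 <- risk_table(dose_table(dplyr::mutate(tbl, conc_ugL = 2 * conc_ugL),
                              params), params)
  expect_equal(r2$tcr$tcr, 2 * r$tcr$tcr)
  expect_equal(r2$hi$hi, 2 * r$hi$hi)

  # TCR is the exact sum of per-metal, per-pathway cancer risks
  check <- r$cr |>
    dplyr::group_by(station, receptor) |>
    dplyr::summarise(s = sum(cr), .groups = "drop") |>
    dplyr::left_join(r$tcr, by = c("station", "receptor"))
  expect_true(all(abs(check$s - check$tcr) < 1e-18))
  # only the quantified carcinogens contribute
  expect_setequal(unique(r$cr$metal), c("As", "Pb", "Cr"))
})

test_that("children carry the higher total cancer risk at every station under as-published factors", {
  params <- stated_set()
  r <- risk_table(dose_table(fixture_table(), params), params)
  w <- tidyr::pivot_wider(r$tcr, id_cols = "station",
                          names_from = "receptor", values_from = "tcr")
  expect_true(all(w$child > w$adult))
})

test_that("threshold classifications follow the stated conventions", {
  expect_equal(classify_noncarcinogenic(0.769), "safe")
  expect_equal(classify_noncarcinogenic(1.2), "unsafe")
  expect_equal(classify_noncarcinogenic(1.0), "unsafe")  # boundary is unsafe

  expect_equal(classify_carcinogenic(5e-5), "borderline")
  expect_equal(classify_carcinogenic(1e-4), "borderline")  # must surpass 1e-4
  expect_equal(classify_carcinogenic(3e-4), "unacceptable")
  expect_equal(classify_carcinogenic(9.9e-7), "negligible")

  # monotone severity
  severity <- c(negligible = 1, borderline = 2, unacceptable = 3)
  crs <- sort(withr::with_seed(1, 10^stats::runif(200, -8, -3)))
  cls <- severity[classify_carcinogenic(crs)]
  expect_true(all(diff(cls) >= 0))
})

test_that("the dermal-contact hazard flags exactly the published unsafe stations", {
  r <- fixture_risk()
  unsafe <- dplyr::filter(r$hi, classification == "unsafe")
  expect_true(all(unsafe$receptor == "child" & unsafe$pathway == "dermal"))
  expect_setequal(unsafe$station, c(17, 23, 34))
  expect_true(all(dplyr::filter(r$hi, receptor == "adult")$classification ==
                    "safe"))
})

test_that("contribution percentages sum to 100 with Cr dominant", {
  # published mean ingestion THQ row (child)
  pct <- contribution_pct(c(As = 0.069, Hg = 0.005, Pb = 0.046,
                            Cr = 0.189, Ni = 0.009))
  expect_equal(sum(pct), 100, tolerance = 1e-9)
  expect_equal(unname(pct["Cr"]), 59.4, tolerance = 0.05)

  expect_equal(unname(contribution_pct(c(a = 0, b = 3))), c(0, 100))
  expect_equal(unname(contribution_pct(c(2, 2))), c(50, 50))
  expect_error(contribution_pct(c(0, 0)), "zero")

  # Cr carries the largest hazard-index share in the survey for both receptors
  r <- fixture_risk()
  shares <- r$thq |>
    dplyr::group_by(receptor, metal) |>
    dplyr::summarise(total = sum(thq), .groups = "drop_last") |>
    dplyr::mutate(pct = contribution_pct(total)) |>
    dplyr::slice_max(pct, n = 1)
  expect_true(all(shares$metal == "Cr"))
  expect_true(all(shares$pct > 50))
})

test_that("publication-layout export rounds half away from zero", {
  expect_equal(round_half_up(0.0125, 3), 0.013)
  expect_equal(round_half_up(-0.0125, 3), -0.013)
  r <- fixture_risk()
  w <- risk_wide(r, "ingestion")
  expect_equal(nrow(w), 35)
  expect_equal(w$Cr_child[w$station == 17], 0.872)
  expect_equal(w$HI_child[w$station == 7], 0.769)

  dir <- withr::local_tempdir()
  write_risk_tables(r, dir)
  expect_setequal(list.files(dir),
                  c("thq.csv", "hi.csv", "hi_total.csv", "cr.csv", "tcr.csv"))
})

test_that("tidy and glance summarise a risk table", {
  r <- fixture_risk()
  td <- tidy(r)
  expect_setequal(unique(td$measure), c("thq", "cr"))
  expect_equal(nrow(td), nrow(r$thq) + nrow(r$cr))
  g <- glance(r)
  expect_equal(g$n_stations, 35L)
  expect_equal(g$n_hi_unsafe, 3L)
  expect_gt(g$mean_hi_child, g$mean_hi_adult)
})

test_that("plot methods return ggplot objects", {
  r <- fixture_risk()
  expect_s3_class(autoplot(r, "hi"), "ggplot")
  expect_s3_class(autoplot(r, "tcr"), "ggplot")
  expect_s3_class(autoplot(r, "contribution"), "ggplot")
  d <- dose_table(fixture_table(), repro_set())
  expect_s3_class(autoplot(d), "ggplot")
})
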