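test_that("survey design validates and yields one row per station-month", {
  d <- taihu_design()
  expect_equal(sum(d$sub_regions$stations), 33)
  ab <- default_survey()$abiotic
  expect_equal(nrow(ab), 396)
  expect_equal(length(unique(ab$site_id)), 33)
  expect_equal(as.integer(table(ab$site_id)), rep(12L, 33))

  tiny <- lake_design(data.frame(name = "A", stations = 1L), months = 1L)
  ab1 <- generate_abiotic(tiny, taihu_variable_specs(), seed = 5)
  expect_equal(nrow(ab1), 1)

  expect_error(lake_design(data.frame(name = "A", stations = 0L)),
               "invalid design")
  expect_error(lake_design(data.frame(name = "A", stations = 2L), months = 0),
               "invalid design")
})

test_that("abiotic generation is deterministic and respects spec ranges", {
  specs <- taihu_variable_specs()
  a1 <- generate_abiotic(taihu_design(), specs, seed = 11)
  a2 <- generate_abiotic(taihu_design(), specs, seed = 11)
  expect_identical(a1, a2)
  a3 <- generate_abiotic(taihu_design(), specs, seed = 12)
  expect_false(identical(a1, a3))
  for (i in seq_len(nrow(specs))) {
    v <- a1[[specs$name[i]]]
    expect_true(all(v >= specs$min[i] & v <= specs$max[i]), label = specs$name[i])
  }
  # annual temperature cycle: summer warmer than winter
  jul <- mean(a1$WTEMP[a1$month == 7])
  jan <- mean(a1$WTEMP[a1$month == 1])
  expect_gt(jul - jan, 10)
})

test_that("sample means of uncensored variables track the design marginals", {
  ab <- default_survey()$abiotic
  specs <- taihu_variable_specs()
  open <- specs[is.na(specs$lod), ]
  for (i in seq_len(nrow(open))) {
    se <- open$sd[i] / sqrt(396)
    expect_lt(abs(mean(ab[[open$name[i]]]) - open$mean[i]), 3 * se,
              label = open$name[i])
  }
})

test_that("plankton generation follows the configured response truth", {
  # ramp threshold: biomass strictly larger on the warm side
  tiny <- data.frame(site_id = c("A01", "A01"), sub_region = "A",
                     month = c(1, 7), WTEMP = c(10, 25), PH = 8.4,
                     TSS = 60, PO4_P = 0.02)
  resp <- response_spec(
    phyto_intercept = 1, phyto_components = list(resp_ramp("WTEMP", 16, 0.14)),
    zoo_components = list(), zoo_intercepts = c(protozoa = -2, rotifera = -2,
                                                cladocera = -1, copepoda = -1),
    noise_sd = 0)
  pl <- generate_plankton(tiny, resp, seed = 1)
  phyt <- pl[pl$group == "algae", ]
  expect_gt(phyt$wet_biomass_mg_per_L[phyt$month == 7],
            phyt$wet_biomass_mg_per_L[phyt$month == 1])
  # the configured components evaluated directly give the exact log-biomass
  expect_equal(log(phyt$wet_biomass_mg_per_L),
               1 + 0.14 * pmax(tiny$WTEMP - 16, 0))

  # zero noise + constant drivers -> identical biomass everywhere
  const <- tiny; const$WTEMP <- 20
  plc <- generate_plankton(const, resp, seed = 1)
  expect_equal(length(unique(plc$wet_biomass_mg_per_L[plc$group == "algae"])), 1)

  # missing driver column is a configuration error
  bad <- tiny; bad$WTEMP <- NULL
  expect_error(generate_plankton(bad, resp, seed = 1), "missing from abiotic")

  # incomplete abiotic table rejected
  nas <- tiny; nas$PH[1] <- NA
  expect_error(generate_plankton(nas, resp, seed = 1), "complete")
})

test_that("default plankton draw is positive and spans the published range", {
  pl <- default_survey()$plankton
  expect_true(all(pl$wet_biomass_mg_per_L > 0))
  expect_setequal(unique(pl$group),
                  c("algae", "protozoa", "rotifera", "cladocera", "copepoda"))
  phyt <- pl$wet_biomass_mg_per_L[pl$group == "algae"]
  expect_equal(length(phyt), 396)
  expect_lt(min(phyt), 3)       # published minimum 0.67 mg/L
  expect_gt(max(phyt), 75)      # published maximum 224 mg/L
  expect_lt(max(phyt), 1500)
  expect_gt(max(phyt) / min(phyt), 30)  # spans > 1.5 orders of magnitude
})

test_that("censoring flags strictly below-LOD values and retains truth", {
  ab <- default_survey()$abiotic
  lods <- taihu_lods()
  cen <- apply_censoring(ab, lods)
  frac <- attr(cen, "nondetect_fraction")

  # fraction targets from the published non-detect counts (out of 396),
  # within 4 binomial standard errors of the calibrated expectation
  target <- c(NH4_N = 10, NO2_N = 366, NO3_N = 91, PO4_P = 154, DTP = 30) / 396
  for (v in names(target)) {
    tol <- 4 * sqrt(target[v] * (1 - target[v]) / 396)
    expect_lt(abs(frac[v] - target[v]), tol, label = v)
  }

  # flagged values are NA; truth attribute recovers every withheld value
  truth <- attr(cen, "censored_truth")
  for (v in names(lods)) {
    flag <- cen[[paste0(v, "_below_lod")]]
    expect_true(all(is.na(cen[[v]][flag])))
    expect_true(all(!is.na(cen[[v]][!flag])))
    tv <- truth$true_value[truth$variable == v]
    expect_equal(sort(tv), sort(ab[[v]][ab[[v]] < lods[v]]))
    expect_true(all(tv < lods[v]))
  }

  # zero LODs flag nothing; value exactly at the LOD is a detect
  none <- apply_censoring(ab, c(WTEMP = 0))
  expect_equal(sum(none$WTEMP_below_lod), 0)
  t2 <- data.frame(site_id = "A01", sub_region = "A", month = 1, X = 0.03)
  expect_false(apply_censoring(t2, c(X = 0.03))$X_below_lod)

  expect_error(apply_censoring(ab, c(NOPE = 1)), "unknown variable")
})

test_that("synthetic station coordinates are distinct and seeded", {
  co <- station_coordinates(taihu_design(), seed = 2)
  expect_equal(nrow(co), 33)
  expect_false(anyDuplicated(co[c("x", "y")]) > 0)
  expect_identical(co, station_coordinates(taihu_design(), seed = 2))
})
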