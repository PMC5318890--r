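sample_of <- function(...) {
  rows <- list(...)
  if (!length(rows))
    return(data.frame(taxon = character(), group = character(),
                      wet_biomass_mg_per_L = numeric(),
                      stringsAsFactors = FALSE))
  data.frame(taxon = paste0("t", seq_along(rows)),
             group = vapply(rows, `[[`, "", 1),
             wet_biomass_mg_per_L = vapply(rows, function(r) as.numeric(r[[2]]), 0),
             stringsAsFactors = FALSE)
}

test_that("eco-exergy density matches hand-computed oracles", {
  expect_equal(eco_exergy_density(sample_of()), 0)

  # single algal taxon at 1 mg/L wet: 18.7 * 20 * 0.16
  expect_equal(eco_exergy_density(sample_of(list("algae", 1))), 59.84)

  # algae 10 + copepoda 1: 18.7 * (20*0.16*10 + 232*0.06*1)
  mix <- sample_of(list("algae", 10), list("copepoda", 1))
  expect_equal(eco_exergy_density(mix), 858.704)
  expect_equal(specific_eco_exergy(mix), 858.704 / 1.66)

  expect_error(eco_exergy_density(sample_of(list("algae", -1))), "negative")
  expect_error(eco_exergy_density(sample_of(list("fish", 1))), "unknown taxon group")
})

test_that("specific eco-exergy is the biomass-weighted mean beta times 18.7", {
  # all-algae community: 20 * 18.7 regardless of biomass
  for (b in c(0.1, 1, 500)) {
    s <- sample_of(list("algae", b), list("algae", 2 * b))
    expect_equal(specific_eco_exergy(s), 374.0)
  }
  # detritus baseline: every beta = 1 gives 18.7 kJ/g for any community
  ones <- beta_table(1, 1, 1, 1, 1)
  set.seed(42)
  for (i in 1:20)
    expect_equal(specific_eco_exergy(random_sample(), betas = ones), 18.7)

  zero <- sample_of(list("algae", 0))
  expect_error(specific_eco_exergy(zero), "undefined")
})

test_that("homogeneity, additivity and beta bounds hold over random communities", {
  set.seed(101)
  for (i in seq_len(1000)) {
    s <- random_sample(n_taxa = sample(5:10, 1))
    ex <- eco_exergy_density(s)
    sp <- specific_eco_exergy(s)
    # bounds: between the smallest and largest beta times 18.7
    expect_gte(sp, 18.7 * 20 - 1e-9)
    expect_lte(sp, 18.7 * 232 + 1e-9)
    # homogeneity: scaling biomass scales Ex, leaves Ex_sp unchanged
    a <- runif(1, 0.1, 10)
    s2 <- s; s2$wet_biomass_mg_per_L <- a * s$wet_biomass_mg_per_L
    expect_equal(eco_exergy_density(s2), a * ex)
    expect_equal(specific_eco_exergy(s2), sp)
    # additivity of density under sample merging
    t <- random_sample(n_taxa = 5)
    expect_equal(eco_exergy_density(rbind(s, t)),
                 ex + eco_exergy_density(t))
  }
})

test_that("phytoplankton-dominated samples carry lower specific eco-exergy", {
  phyto <- sample_of(list("algae", 10))
  ex <- eco_exergy_density(phyto)
  # copepod community scaled to the same eco-exergy density
  b_cop <- ex / (18.7 * 232 * 0.06)
  cop <- sample_of(list("copepoda", b_cop))
  expect_equal(eco_exergy_density(cop), ex)
  expect_lt(specific_eco_exergy(phyto), specific_eco_exergy(cop))
})

test_that("exergy table reports per station-month in kJ/L with the identity Ex = Ex_sp * C", {
  sv <- default_survey()
  ex <- sv$indicators
  expect_equal(nrow(ex), 396)
  expect_equal(ex$Ex_kJ_per_L * 1000,
               ex$Ex_sp_kJ_per_g * ex$C_total_mg_per_L)
  # spot-check one station-month against the per-sample functions
  one <- sv$plankton[sv$plankton$site_id == "CZ01" & sv$plankton$month == 5, ]
  row <- ex[ex$site_id == "CZ01" & ex$month == 5, ]
  expect_equal(row$Ex_kJ_per_L, eco_exergy_density(one) / 1000)
  expect_equal(row$Ex_sp_kJ_per_g, specific_eco_exergy(one))
})

test_that("aggregation reproduces brute-force group-by with percentile bands", {
  expect_equal(aggregate_indicator(c(5, 5, 5), c("a", "a", "a")),
               data.frame(group = "a", n = 3, mean = 5, lower = 5, upper = 5))
  expect_equal(aggregate_indicator(1:3, rep("g", 3))$mean, 2)

  sv <- default_survey()
  ex <- merge(sv$indicators, unique(sv$abiotic[c("site_id", "sub_region")]),
              by = "site_id")
  monthly <- aggregate_indicator(ex$Ex_kJ_per_L, ex$month)
  regional <- aggregate_indicator(ex$Ex_kJ_per_L, ex$sub_region)
  expect_equal(nrow(monthly), 12)
  expect_equal(nrow(regional), 9)
  expect_equal(monthly$n, rep(33L, 12))
  expect_equal(sort(regional$n), sort(taihu_design()$sub_regions$stations * 12))
  # brute-force oracle for one group
  v <- ex$Ex_kJ_per_L[ex$month == 8]
  expect_equal(monthly$mean[monthly$group == "8"], mean(v))
  expect_equal(monthly$lower[monthly$group == "8"],
               unname(quantile(v, 0.025)))
  expect_equal(monthly$upper[monthly$group == "8"],
               unname(quantile(v, 0.975)))

  # se-band variant is mean +/- 2 SE
  a <- aggregate_indicator(c(1, 2, 3, 4), rep("g", 4), method = "se")
  expect_equal(a$lower, 2.5 - 2 * sd(1:4) / 2)

  expect_warning(aggregate_indicator(c(1, NA), c("a", "a")), "missing")
})
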