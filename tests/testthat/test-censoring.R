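test_that("three-tier classification reproduces the published treatment", {
  pol <- censoring_policy()
  # published non-detect counts out of 396 samples
  expect_equal(classify_variable(366 / 396, pol), "drop")          # 92.4%
  expect_equal(classify_variable(154 / 396, pol), "random_normal") # 38.9%
  expect_equal(classify_variable(91 / 396, pol), "random_normal")  # 23.0%
  expect_equal(classify_variable(30 / 396, pol), "half_lod")       # 7.6%
  expect_equal(classify_variable(10 / 396, pol), "half_lod")       # 2.5%
  expect_equal(classify_variable(0, pol), "none")

  # boundaries: thresholds are strict "greater than"
  expect_equal(classify_variable(0.50, pol), "random_normal")
  expect_equal(classify_variable(0.10, pol), "half_lod")
  expect_error(classify_variable(1.2, pol), "\\[0, 1\\]")
  expect_error(censoring_policy(drop_threshold = 0.1, random_threshold = 0.5))
  expect_error(lod_table(c(NH4_N = 0)), "strictly positive")
})

test_that("half-LOD substitution returns exactly LOD/2 for flagged records", {
  expect_equal(substitute_half_lod(TRUE, 0.025), 0.0125)  # NH4-N
  expect_equal(substitute_half_lod(TRUE, 0.01), 0.005)    # DTP
  expect_error(substitute_half_lod(FALSE, 0.025), "flagged")
  expect_error(substitute_half_lod(TRUE, 0), "positive")
})

test_that("truncated-normal imputation obeys the clamping rules", {
  x <- impute_random_normal(0.08, 1e4, seed = 3)
  expect_true(all(x >= 0 & x <= 0.08))
  expect_identical(as.numeric(x), as.numeric(impute_random_normal(0.08, 1e4, seed = 3)))

  # symmetric truncation of a symmetric distribution preserves the mean
  big <- impute_random_normal(0.08, 1e6, seed = 9)
  expect_lt(abs(mean(big) - 0.04), 3 * 0.02 / sqrt(1e6) + 1e-4)
  # ~95% of raw draws fall within two sds of the mean, i.e. inside [0, LOD]
  expect_gte(attr(big, "raw_within"), 0.95)

  expect_error(impute_random_normal(0, 10), "positive")
  expect_error(impute_random_normal(0.08, 0), "at least 1")
})

test_that("resolve_table applies the published per-variable strategies", {
  sv <- default_survey()
  cen <- apply_censoring(sv$abiotic, taihu_lods())
  res <- resolve_table(cen, taihu_lods(), censoring_policy(), seed = 5)
  rep <- res$report

  strat <- setNames(rep$strategy, rep$variable)
  expect_equal(strat[["NO2_N"]], "drop")
  expect_equal(strat[["NH4_N"]], "half_lod")
  expect_equal(strat[["DTP"]], "half_lod")
  expect_equal(strat[["NO3_N"]], "random_normal")
  expect_equal(strat[["PO4_P"]], "random_normal")
  expect_equal(attr(rep, "dropped"), "NO2_N")
  expect_false("NO2_N" %in% names(res$table))
  expect_false(any(grepl("_below_lod$", names(res$table))))
  expect_false(anyNA(res$table))

  # every substituted/imputed value lies in [0, LOD]
  flag <- cen$PO4_P_below_lod
  expect_true(all(res$table$PO4_P[flag] >= 0 & res$table$PO4_P[flag] <= 0.005))
  expect_true(all(res$table$NH4_N[cen$NH4_N_below_lod] == 0.0125))

  # seeded reproducibility
  res2 <- resolve_table(cen, taihu_lods(), censoring_policy(), seed = 5)
  expect_identical(res$table, res2$table)
  res3 <- resolve_table(cen, taihu_lods(), censoring_policy(), seed = 6)
  expect_false(identical(res$table$PO4_P, res3$table$PO4_P))
})

test_that("resolve_table handles degenerate and misconfigured inputs", {
  # already-complete table returned unchanged
  clean <- data.frame(site_id = "A01", sub_region = "A", month = 1:3,
                      WTEMP = c(5, 10, 15))
  out <- resolve_table(clean, taihu_lods())
  expect_identical(out$table, clean)
  expect_equal(nrow(out$report), 0)

  # flagged variable missing from the LOD table is a configuration error
  t <- data.frame(site_id = "A", sub_region = "A", month = 1:4,
                  X = c(NA, NA, 3, 4), X_below_lod = c(TRUE, TRUE, FALSE, FALSE))
  expect_error(resolve_table(t, c(Y = 1)), "absent from LOD table")

  # everything censored above the drop threshold -> dropped with warning
  t$X_below_lod <- c(TRUE, TRUE, TRUE, FALSE)
  t$X <- c(NA, NA, NA, 4)
  expect_warning(res <- resolve_table(t, c(X = 1)), "dropped")
  expect_false("X" %in% names(res$table))
})
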