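# Independent oracles and shared fixtures for the test suite.

# Exhaustive greedy split search: scans every (variable, midpoint) candidate
# and computes the within-node SSE reduction directly from the definition.
oracle_best_split <- function(X, r, rows, min_node) {
  best <- list(imp = 0, var = NA_integer_, thr = NA_real_)
  n <- length(rows)
  S <- sum(r[rows])
  base <- S^2 / n
  for (j in seq_len(ncol(X))) {
    xs <- sort(unique(X[rows, j]))
    if (length(xs) < 2) next
    thrs <- (xs[-length(xs)] + xs[-1]) / 2
    for (t in thrs) {
      L <- rows[X[rows, j] < t]
      R <- rows[X[rows, j] >= t]
      if (length(L) < min_node || length(R) < min_node) next
      imp <- sum(r[L])^2 / length(L) + sum(r[R])^2 / length(R) - base
      if (imp > best$imp) best <- list(imp = imp, var = j, thr = t)
    }
  }
  best
}

# Greedy best-first tree by exhaustive search; returns per-row predictions.
oracle_tree_predictions <- function(X, r, max_splits, min_node) {
  leaves <- list(seq_len(nrow(X)))
  for (s in seq_len(max_splits)) {
    cands <- lapply(leaves, function(rows)
      oracle_best_split(X, r, rows, min_node))
    imps <- vapply(cands, function(b) b$imp, numeric(1))
    if (max(imps) <= 0) break
    k <- which.max(imps)
    b <- cands[[k]]
    rows <- leaves[[k]]
    leaves[[k]] <- NULL
    leaves <- c(leaves, list(rows[X[rows, b$var] < b$thr]),
                list(rows[X[rows, b$var] >= b$thr]))
  }
  pred <- numeric(nrow(X))
  for (rows in leaves) pred[rows] <- mean(r[rows])
  pred
}

# Random plankton community across all five groups.
random_sample <- function(n_taxa = 8, max_biomass = 50) {
  groups <- c("algae", "protozoa", "rotifera", "cladocera", "copepoda")
  g <- c(groups, sample(groups, max(n_taxa - 5, 0), replace = TRUE))
  data.frame(taxon = paste0("t", seq_along(g)), group = g,
             wet_biomass_mg_per_L = runif(length(g), 0.01, max_biomass),
             stringsAsFactors = FALSE)
}

# The default synthetic survey, generated once per test run.
default_survey <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ab <- generate_abiotic(taihu_design(), taihu_variable_specs(), seed = 1)
      pl <- generate_plankton(ab, taihu_response_spec(), seed = 3)
      ex <- exergy_table(pl)
      merged <- merge(ex, ab, by = c("site_id", "month"))
      merged <- merged[order(merged$site_id, merged$month), ]
      cache <<- list(abiotic = ab, plankton = pl, indicators = ex,
                     merged = merged,
                     predictors = c("NH4_N", "NO3_N", "PO4_P", "WTEMP",
                                    "TSS", "PH", "WIND", "SOLR", "WD",
                                    "SDD", "PREC", "NOISE"))
    }
    cache
  }
})

# Full-scale CV-selected fits on a 75% training split, fitted once and
# shared across boosting and adequacy checks.
heldout_fits <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sv <- default_survey()
      m <- sv$merged
      set.seed(7)
      test <- sort(sample(nrow(m), round(0.25 * nrow(m))))
      fits <- lapply(c(Ex = "Ex_kJ_per_L", Ex_sp = "Ex_sp_kJ_per_g"),
                     function(tgt) {
        fit <- fit_gbm(m[-test, sv$predictors], m[[tgt]][-test],
                       gbm_config(seed = 42))
        list(fit = fit, target = tgt,
             obs = m[[tgt]][test],
             pred = predict(fit, m[test, sv$predictors]))
      })
      cache <<- list(fits = fits, test = test)
    }
    cache
  }
})

# Expected eco-exergy (J/L) with the synthetic truth's deterministic
# response, every covariate at its observed value except WTEMP forced to
# `wtemp`; the lognormal noise factor exp(sd^2/2) multiplies every group
# alike. Serves as the ground-truth partial-dependence oracle.
truth_pdp_exergy <- function(abiotic, wtemp, resp = taihu_response_spec(),
                             betas = beta_table(),
                             conv = conversion_factors()) {
  ab <- abiotic
  ab$WTEMP <- wtemp
  comp_sum <- function(components) {
    total <- numeric(nrow(ab))
    for (cm in components) total <- total + cm$fun(ab[[cm$var]])
    total
  }
  noise_factor <- exp(resp$noise_sd^2 / 2)
  phyto <- exp(resp$phyto_intercept + comp_sum(resp$phyto_components)) *
    noise_factor
  zoo_sig <- comp_sum(resp$zoo_components)
  ex <- betas[["algae"]] * conv$f_phy * phyto
  for (g in c("protozoa", "rotifera", "cladocera", "copepoda")) {
    zg <- exp(resp$zoo_intercepts[[g]] + zoo_sig) * noise_factor
    ex <- ex + betas[[g]] * conv$f_zoo * zg
  }
  mean(conv$detritus_energy * ex)
}
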