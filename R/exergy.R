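#' Genetic-information weighting factors and biomass conversion factors
#'
#' `beta_table()` holds the dimensionless weighting factors expressing each
#' plankton group's genetic information content relative to detritus
#' (beta = 1): algae 20, protozoa 39, rotifera 163, cladocera 232,
#' copepoda 232. `conversion_factors()` holds the wet-weight to
#' exergy-reference (dry/C) biomass conversions, `f_phy` = 0.16 for
#' phytoplankton and `f_zoo` = 0.06 for zooplankton, and the chemical
#' exergy of detritus, 18.7 kJ/g.
#'
#' @param algae,protozoa,rotifera,cladocera,copepoda group weighting
#'   factors, all >= 1.
#' @param f_phy,f_zoo conversion factors in (0, 1].
#' @param detritus_energy detritus exergy in kJ/g (> 0).
#' @return Named numeric vector (`beta_table`) or list
#'   (`conversion_factors`).
#' @export
beta_table <- function(algae = 20, protozoa = 39, rotifera = 163,
                       cladocera = 232, copepoda = 232) {
  b <- c(algae = algae, protozoa = protozoa, rotifera = rotifera,
         cladocera = cladocera, copepoda = copepoda)
  if (any(b < 1)) stop("all beta values must be >= 1 (detritus baseline)")
  b
}

#' @rdname beta_table
#' @export
conversion_factors <- function(f_phy = 0.16, f_zoo = 0.06,
                               detritus_energy = 18.7) {
  if (f_phy <= 0 || f_phy > 1 || f_zoo <= 0 || f_zoo > 1)
    stop("conversion factors must lie in (0, 1]")
  if (detritus_energy <= 0) stop("detritus_energy must be positive")
  list(f_phy = f_phy, f_zoo = f_zoo, detritus_energy = detritus_energy)
}

validate_sample <- function(sample, betas) {
  stopifnot(is.data.frame(sample),
            all(c("group", "wet_biomass_mg_per_L") %in% names(sample)))
  if (any(sample$wet_biomass_mg_per_L < 0))
    stop("negative biomass in plankton sample")
  unknown <- setdiff(unique(sample$group), names(betas))
  if (length(unknown))
    stop("unknown taxon group(s): ", paste(unknown, collapse = ", "))
  invisible(sample)
}

group_factor <- function(group, conv) {
  ifelse(group == "algae", conv$f_phy, conv$f_zoo)
}

#' Eco-exergy density of a plankton sample
#'
#' The work energy (relative to detritus) stored in the community at one
#' (site, month):
#' `Ex = 18.7 * (beta_alg * f_phy * sum C_phy + f_zoo * sum_g beta_g * C_g)`
#' with wet biomass C in mg/L, so Ex is in J/L (18.7 kJ/g = 18.7 J/mg).
#'
#' @param sample data.frame with columns `group` (one of the five plankton
#'   groups) and `wet_biomass_mg_per_L` (>= 0); one row per taxon.
#' @param betas a [beta_table()].
#' @param conv [conversion_factors()].
#' @return Eco-exergy density in J/L (0 for an empty sample).
#' @export
eco_exergy_density <- function(sample, betas = beta_table(),
                               conv = conversion_factors()) {
  validate_sample(sample, betas)
  if (!nrow(sample)) return(0)
  f <- group_factor(sample$group, conv)
  conv$detritus_energy *
    sum(betas[sample$group] * f * sample$wet_biomass_mg_per_L)
}

#' Total converted (exergy-reference) biomass of a sample, mg/L
#'
#' @inheritParams eco_exergy_density
#' @export
converted_biomass <- function(sample, conv = conversion_factors()) {
  if (!nrow(sample)) return(0)
  sum(group_factor(sample$group, conv) * sample$wet_biomass_mg_per_L)
}

#' Specific eco-exergy of a plankton sample
#'
#' Eco-exergy per unit of total converted biomass, in kJ/g: the
#' converted-biomass-weighted mean weighting factor times 18.7. A sample
#' with zero total biomass has no defined community composition and raises
#' an error rather than returning 0 or infinity.
#'
#' @inheritParams eco_exergy_density
#' @return Specific eco-exergy in kJ/g.
#' @export
specific_eco_exergy <- function(sample, betas = beta_table(),
                                conv = conversion_factors()) {
  validate_sample(sample, betas)
  ctot <- converted_biomass(sample, conv)
  if (ctot == 0)
    stop("specific eco-exergy undefined: total converted biomass is zero")
  eco_exergy_density(sample, betas, conv) / ctot
}

#' Indicator table: eco-exergy and specific eco-exergy per (site, month)
#'
#' @param plankton long plankton table (`site_id`, `month`, `group`,
#'   `wet_biomass_mg_per_L`).
#' @inheritParams eco_exergy_density
#' @return data.frame `site_id`, `month`, `Ex_kJ_per_L`, `Ex_sp_kJ_per_g`,
#'   `C_total_mg_per_L`.
#' @export
exergy_table <- function(plankton, betas = beta_table(),
                         conv = conversion_factors()) {
  validate_sample(plankton, betas)
  key <- interaction(plankton$site_id, plankton$month, drop = TRUE)
  pieces <- lapply(split(plankton, key), function(s) {
    data.frame(site_id = s$site_id[1], month = s$month[1],
               Ex_kJ_per_L = eco_exergy_density(s, betas, conv) / 1000,
               Ex_sp_kJ_per_g = specific_eco_exergy(s, betas, conv),
               C_total_mg_per_L = converted_biomass(s, conv),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  out <- out[order(out$site_id, out$month), ]
  rownames(out) <- NULL
  out
}

#' Aggregate an indicator over a grouping with an uncertainty band
#'
#' Group means with a 95% band across member (site, month) values. The band
#' is the 2.5th-97.5th percentile by default; `method = "se"` gives mean
#' plus/minus two standard errors instead. Groups with a single member
#' return a degenerate band; empty groups are skipped with a warning.
#'
#' @param x numeric indicator values.
#' @param by grouping vector (e.g. month or sub-region), same length as `x`.
#' @param level coverage of the band (default 0.95).
#' @param method `"percentile"` or `"se"`.
#' @return data.frame `group`, `n`, `mean`, `lower`, `upper`.
#' @export
aggregate_indicator <- function(x, by, level = 0.95,
                                method = c("percentile", "se")) {
  method <- match.arg(method)
  stopifnot(length(x) == length(by), level > 0, level < 1)
  keep <- !is.na(x)
  if (any(!keep)) {
    warning("dropping ", sum(!keep), " missing indicator value(s)")
    x <- x[keep]; by <- by[keep]
  }
  groups <- split(x, by)
  empty <- lengths(groups) == 0
  if (any(empty)) {
    warning("skipping empty group(s): ",
            paste(names(groups)[empty], collapse = ", "))
    groups <- groups[!empty]
  }
  a <- (1 - level) / 2
  rows <- lapply(names(groups), function(g) {
    v <- groups[[g]]
    if (method == "percentile") {
      lo <- unname(quantile(v, a)); hi <- unname(quantile(v, 1 - a))
    } else {
      se <- if (length(v) > 1) sd(v) / sqrt(length(v)) else 0
      lo <- mean(v) - 2 * se; hi <- mean(v) + 2 * se
    }
    data.frame(group = g, n = length(v), mean = mean(v),
               lower = lo, upper = hi, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
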