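#' Configuration for a full analysis run
#'
#' Bundles every stage's parameters. Exactly one of `input` (paths to
#' monitoring, plankton and station-coordinate CSVs) or `synthetic` (a
#' generation block with `design`, `specs`, `response`) must be given; the
#' default is a fully synthetic run emulating the 33-station by 12-month
#' campaign.
#'
#' @param input optional list with `monitoring`, `plankton`, `coordinates`
#'   CSV paths.
#' @param synthetic optional list with `design` ([lake_design()]), `specs`
#'   (variable spec table) and `response` ([response_spec()]).
#' @param lods [lod_table()].
#' @param policy [censoring_policy()].
#' @param betas [beta_table()].
#' @param conv [conversion_factors()].
#' @param screening list: `threshold`, `alpha`, `retain_policy`, `exclude`
#'   (candidate variables never offered to the model; chlorophyll-a by
#'   default since it enters the indicators themselves).
#' @param gbm [gbm_config()] (its `seed` is overridden from the master
#'   seed).
#' @param adequacy list of gate thresholds (`nse_min`, `rsr_max`,
#'   `pbias_max`).
#' @param grid list with `cell_size` for the interpolation grid laid over
#'   the station bounding box.
#' @param seed master integer seed for the run.
#' @return A `run_config` object.
#' @export
run_config <- function(input = NULL,
                       synthetic = list(design = taihu_design(),
                                        specs = taihu_variable_specs(),
                                        response = taihu_response_spec()),
                       lods = taihu_lods(),
                       policy = censoring_policy(),
                       betas = beta_table(),
                       conv = conversion_factors(),
                       screening = list(threshold = 0.7, alpha = 0.05,
                                        retain_policy = taihu_retain_policy(),
                                        exclude = "Chla"),
                       gbm = gbm_config(),
                       adequacy = list(nse_min = 0.5, rsr_max = 0.7,
                                       pbias_max = 25),
                       grid = list(cell_size = 2),
                       seed = 1L) {
  if (!missing(input) && !is.null(input)) synthetic <- NULL
  if (is.null(input) == is.null(synthetic))
    stop("exactly one of 'input' and 'synthetic' must be given")
  structure(list(input = input, synthetic = synthetic, lods = lods,
                 policy = policy, betas = betas, conv = conv,
                 screening = screening, gbm = gbm, adequacy = adequacy,
                 grid = grid, seed = as.integer(seed)),
            class = "run_config")
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "': ", conditionMessage(e), call. = FALSE))
}

serialize_response <- function(resp) {
  comp <- function(cl) lapply(cl, function(cm)
    list(type = cm$type, var = cm$var, params = cm$params))
  list(phyto_intercept = resp$phyto_intercept,
       phyto_components = comp(resp$phyto_components),
       zoo_components = comp(resp$zoo_components),
       zoo_intercepts = as.list(resp$zoo_intercepts),
       noise_sd = resp$noise_sd)
}

serialize_config <- function(config) {
  out <- list(seed = config$seed, lods = as.list(config$lods),
              policy = unclass(config$policy),
              betas = as.list(config$betas), conv = config$conv,
              screening = config$screening, gbm = unclass(config$gbm),
              adequacy = config$adequacy, grid = config$grid)
  if (!is.null(config$input)) out$input <- config$input
  if (!is.null(config$synthetic))
    out$synthetic <- list(
      sub_regions = config$synthetic$design$sub_regions,
      months = config$synthetic$design$months,
      specs = config$synthetic$specs,
      response = serialize_response(config$synthetic$response))
  out
}

#' Run the full analysis pipeline
#'
#' Orchestrates generate (or load) -> censor-resolve -> exergy indicators ->
#' collinearity screening -> boosted models for eco-exergy and specific
#' eco-exergy -> relative influence and partial dependence (top-3
#' predictors, single and pairwise) -> adequacy reports -> IDW maps, writing
#' every product plus a machine-readable manifest under `out_dir`. Stage
#' failures abort with a stage-labelled error; outputs of completed stages
#' are retained.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a list with the in-memory stage products (`abiotic`,
#'   `resolved`, `censor_report`, `indicators`, `correlations`,
#'   `predictors`, `models`, `influence`, `adequacy`, `pdp`, `maps`,
#'   `manifest`).
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  if (!is.null(config$input)) {
    paths <- unlist(config$input)
    missing_files <- paths[!file.exists(paths)]
    if (length(missing_files))
      stop("configuration error: missing input file(s): ",
           paste(missing_files, collapse = ", "))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed

  dat <- run_stage("inputs", {
    if (!is.null(config$synthetic)) {
      syn <- config$synthetic
      abiotic <- generate_abiotic(syn$design, syn$specs, seed)
      coords <- station_coordinates(syn$design, seed + 1L)
      plankton <- generate_plankton(abiotic, syn$response, seed + 2L)
      censored <- apply_censoring(abiotic, config$lods)
      message("inputs: synthetic survey, ", nrow(abiotic), " station-months")
      list(censored = censored, plankton = plankton, coords = coords)
    } else {
      censored <- read_monitoring_csv(config$input$monitoring)
      plankton <- read_plankton_csv(config$input$plankton)
      coords <- read.csv(config$input$coordinates, stringsAsFactors = FALSE)
      message("inputs: read ", nrow(censored), " station-months")
      list(censored = censored, plankton = plankton, coords = coords)
    }
  })

  res <- run_stage("censoring", {
    r <- resolve_table(dat$censored, config$lods, config$policy, seed + 3L)
    write_monitoring_csv(r$table, file.path(out_dir, "monitoring_resolved.csv"))
    write_censor_report(r$report, file.path(out_dir, "censoring_report.json"))
    message("censoring: ", nrow(r$report), " flagged variable(s), dropped: ",
            paste(attr(r$report, "dropped"), collapse = ", "))
    r
  })

  indicators <- run_stage("exergy", {
    ex <- exergy_table(dat$plankton, config$betas, config$conv)
    site_region <- unique(res$table[c("site_id", "sub_region")])
    ex <- merge(ex, site_region, by = "site_id", sort = TRUE)
    ex <- ex[order(ex$site_id, ex$month), ]
    write.csv(ex, file.path(out_dir, "indicators.csv"), row.names = FALSE)
    for (target in c("Ex_kJ_per_L", "Ex_sp_kJ_per_g")) {
      agg_m <- aggregate_indicator(ex[[target]], ex$month)
      agg_r <- aggregate_indicator(ex[[target]], ex$sub_region)
      write.csv(agg_m, file.path(out_dir, paste0("monthly_", target, ".csv")),
                row.names = FALSE)
      write.csv(agg_r, file.path(out_dir, paste0("regional_", target, ".csv")),
                row.names = FALSE)
    }
    message("exergy: indicators for ", nrow(ex), " station-months")
    ex
  })

  screen <- run_stage("screening", {
    drop_cols <- c("site_id", "sub_region", "month", config$screening$exclude)
    candidates <- setdiff(names(res$table), drop_cols)
    cm <- pearson_matrix(res$table, candidates)
    preds <- select_predictors(cm, config$screening$retain_policy,
                               config$screening$threshold,
                               config$screening$alpha)
    write_correlation_csv(cm, file.path(out_dir, "correlation_matrix.csv"))
    jsonlite::write_json(list(predictors = preds,
                              strong_pairs = strong_pairs(
                                cm, config$screening$threshold,
                                config$screening$alpha)),
                         file.path(out_dir, "predictors.json"),
                         auto_unbox = TRUE, digits = NA)
    message("screening: ", length(preds), " predictors retained of ",
            length(candidates), " candidates")
    list(cm = cm, predictors = preds)
  })

  targets <- c("Ex_kJ_per_L", "Ex_sp_kJ_per_g")
  merged <- merge(indicators, res$table, by = c("site_id", "month"))
  merged <- merged[order(merged$site_id, merged$month), ]
  models <- list(); influence <- list(); adequacy_reports <- list()
  pdps <- list()
  for (i in seq_along(targets)) {
    target <- targets[i]
    model <- run_stage("boosting", {
      cfg <- config$gbm
      cfg$seed <- as.integer(seed + 100L * i)
      m <- fit_gbm(merged[, screen$predictors, drop = FALSE],
                   merged[[target]], cfg)
      write.csv(data.frame(iteration = seq_along(m$train_error),
                           train_mse = m$train_error, cv_mse = m$cv_error),
                file.path(out_dir, paste0("error_curves_", target, ".csv")),
                row.names = FALSE)
      write_gbm_json(m, file.path(out_dir, paste0("model_", target, ".json")))
      message("boosting [", target, "]: best iteration ", m$best_iteration,
              " of ", cfg$n_trees)
      m
    })
    models[[target]] <- model

    influence[[target]] <- run_stage("influence", {
      ri <- relative_influence(model)
      write.csv(data.frame(variable = names(ri), influence_pct = as.numeric(ri)),
                file.path(out_dir, paste0("influence_", target, ".csv")),
                row.names = FALSE)
      ri
    })

    adequacy_reports[[target]] <- run_stage("evaluation", {
      rep <- adequacy(merged[[target]], predict(model, merged),
                      config$adequacy$nse_min, config$adequacy$rsr_max,
                      config$adequacy$pbias_max)
      write_adequacy_json(rep, file.path(out_dir,
                                         paste0("adequacy_", target, ".json")))
      message("evaluation [", target, "]: NSE ", round(rep$nse, 3),
              ", RSR ", round(rep$rsr, 3), ", PBIAS ",
              round(rep$pbias, 1), "% -> ",
              ifelse(rep$pass_all, "agreeable", "NOT agreeable"))
      rep
    })

    pdps[[target]] <- run_stage("pdp", {
      top3 <- names(influence[[target]])[1:3]
      out <- list()
      for (v in top3) {
        pd <- partial_dependence(model, v)
        write.csv(pd, file.path(out_dir,
                                paste0("pdp_", target, "_", v, ".csv")),
                  row.names = FALSE)
        out[[v]] <- pd
      }
      pairs <- utils::combn(top3, 2, simplify = FALSE)
      for (pr in pairs) {
        pd2 <- partial_dependence(model, pr)
        write.csv(pd2, file.path(out_dir, paste0(
          "pdp2_", target, "_", pr[1], "_", pr[2], ".csv")),
          row.names = FALSE)
        out[[paste(pr, collapse = ":")]] <- pd2
      }
      out
    })
  }

  maps <- run_stage("mapping", {
    ann <- stats::aggregate(
      indicators[c("Ex_kJ_per_L", "Ex_sp_kJ_per_g")],
      by = list(site_id = indicators$site_id), FUN = mean)
    st <- merge(dat$coords, ann, by = "site_id")
    cs <- config$grid$cell_size
    gs <- grid_spec(min(st$x) - cs, max(st$x) + cs,
                    min(st$y) - cs, max(st$y) + cs, cs, config$grid$mask)
    out <- list()
    for (target in targets) {
      st_v <- data.frame(x = st$x, y = st$y, value = st[[target]])
      g <- idw(st_v, gs)
      write.csv(g, file.path(out_dir, paste0("idw_", target, ".csv")),
                row.names = FALSE)
      write_esri_ascii(g, gs, file.path(out_dir, paste0("idw_", target, ".asc")))
      out[[target]] <- g
    }
    message("mapping: ", nrow(out[[1]]), " grid cells interpolated")
    out
  })

  manifest <- run_stage("manifest", {
    man <- list(
      package = "lakexergy",
      version = as.character(utils::packageVersion("lakexergy")),
      config = serialize_config(config),
      n_station_months = nrow(merged),
      predictors = screen$predictors,
      best_iterations = lapply(models, function(m) m$best_iteration),
      outputs = sort(list.files(out_dir)))
    jsonlite::write_json(man, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    man
  })

  invisible(list(abiotic = dat$censored, resolved = res$table,
                 censor_report = res$report, indicators = indicators,
                 correlations = screen$cm, predictors = screen$predictors,
                 models = models, influence = influence,
                 adequacy = adequacy_reports, pdp = pdps, maps = maps,
                 manifest = manifest))
}

#' Load a run configuration from a YAML file
#'
#' Scalar parameters (seed, thresholds, GBM settings, LODs, betas,
#' conversion factors, grid) are read from YAML; the synthetic generation
#' block always uses the packaged default design, variable specs and
#' response truth (YAML cannot carry arbitrary response functions).
#'
#' @param path YAML file.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(y$input)) args$input <- y$input
  if (!is.null(y$seed)) args$seed <- y$seed
  if (!is.null(y$lods)) args$lods <- lod_table(unlist(y$lods))
  if (!is.null(y$policy))
    args$policy <- do.call(censoring_policy, y$policy)
  if (!is.null(y$betas)) args$betas <- do.call(beta_table, y$betas)
  if (!is.null(y$conversion)) args$conv <- do.call(conversion_factors, y$conversion)
  if (!is.null(y$gbm)) args$gbm <- do.call(gbm_config, y$gbm)
  if (!is.null(y$screening)) {
    scr <- list(threshold = 0.7, alpha = 0.05,
                retain_policy = taihu_retain_policy(), exclude = "Chla")
    scr[names(y$screening)] <- y$screening
    args$screening <- scr
  }
  if (!is.null(y$adequacy)) args$adequacy <- y$adequacy
  if (!is.null(y$grid)) args$grid <- y$grid
  do.call(run_config, args)
}
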