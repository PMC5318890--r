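#' Read and write the pipeline's CSV dialects
#'
#' Monitoring CSV: wide, one row per (site, month), columns `site_id`,
#' `sub_region`, `month`, one column per variable and optional
#' `<variable>_below_lod` logical flags. Plankton CSV: long, columns
#' `site_id`, `month`, `taxon`, `group`, `wet_biomass_mg_per_L`. Both are
#' UTF-8 with a header row and "." decimal separator.
#'
#' @param table data.frame to write.
#' @param path CSV file.
#' @name csv_dialects
NULL

#' @rdname csv_dialects
#' @export
write_monitoring_csv <- function(table, path) {
  write.csv(table, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname csv_dialects
#' @export
read_monitoring_csv <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- c("site_id", "sub_region", "month")
  if (!all(need %in% names(d)))
    stop("monitoring CSV must have columns: ", paste(need, collapse = ", "))
  for (f in grep("_below_lod$", names(d), value = TRUE))
    d[[f]] <- as.logical(d[[f]])
  d
}

#' @rdname csv_dialects
#' @export
write_plankton_csv <- function(table, path) {
  write.csv(table, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname csv_dialects
#' @export
read_plankton_csv <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- c("site_id", "month", "taxon", "group", "wet_biomass_mg_per_L")
  if (!all(need %in% names(d)))
    stop("plankton CSV must have columns: ", paste(need, collapse = ", "))
  d
}
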