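#' Regular grid specification for interpolation
#'
#' Cell centres are laid out from `xmin + cell_size/2` upward in both axes.
#' An optional boundary mask polygon (data.frame/matrix with columns `x`,
#' `y`) restricts output to in-polygon cells.
#'
#' @param xmin,xmax,ymin,ymax bounding box (non-degenerate).
#' @param cell_size positive cell edge length.
#' @param mask optional polygon (columns `x`, `y`).
#' @return A `grid_spec` object.
#' @export
grid_spec <- function(xmin, xmax, ymin, ymax, cell_size, mask = NULL) {
  if (cell_size <= 0) stop("cell_size must be positive")
  if (xmax <= xmin || ymax <= ymin) stop("degenerate bounding box")
  if (!is.null(mask)) stopifnot(all(c("x", "y") %in% colnames(mask)))
  structure(list(xmin = xmin, xmax = xmax, ymin = ymin, ymax = ymax,
                 cell_size = cell_size, mask = mask),
            class = "grid_spec")
}

grid_points <- function(grid) {
  gx <- seq(grid$xmin + grid$cell_size / 2, grid$xmax, by = grid$cell_size)
  gy <- seq(grid$ymin + grid$cell_size / 2, grid$ymax, by = grid$cell_size)
  expand.grid(x = gx, y = gy, KEEP.OUT.ATTRS = FALSE)
}

#' Inverse-distance-weighted interpolation onto a grid
#'
#' Each grid value is the distance-decay weighted average of all station
#' values, `sum(w_i v_i) / sum(w_i)` with `w_i = d_i^(-power)`; a grid
#' point coinciding with a station returns that station's value exactly,
#' and every interpolated value lies within the range of the station values
#' (IDW is a convex combination). Masked-out cells emit no value.
#'
#' @param stations data.frame with columns `x`, `y`, `value`; pairwise
#'   distinct coordinates (duplicates with equal value are collapsed,
#'   duplicates with conflicting values are an error).
#' @param grid a [grid_spec()] or a data.frame of target points (`x`, `y`).
#' @param power positive distance-decay exponent (default 2).
#' @return data.frame `x`, `y`, `value` (one row per unmasked cell).
#' @export
idw <- function(stations, grid, power = 2) {
  stopifnot(all(c("x", "y", "value") %in% names(stations)),
            nrow(stations) >= 1, power > 0)
  if (anyNA(stations[c("x", "y", "value")]) ||
      any(!is.finite(stations$x) | !is.finite(stations$y)))
    stop("station coordinates and values must be finite")
  key <- paste(stations$x, stations$y)
  if (anyDuplicated(key)) {
    agg <- tapply(stations$value, key, function(v) length(unique(v)))
    if (any(agg > 1))
      stop("duplicate station coordinates with conflicting values")
    stations <- stations[!duplicated(key), ]
  }
  pts <- if (inherits(grid, "grid_spec")) grid_points(grid) else grid[, c("x", "y")]
  if (inherits(grid, "grid_spec") && !is.null(grid$mask)) {
    inside <- mgcv::in.out(as.matrix(grid$mask[, c("x", "y")]),
                           as.matrix(pts))
    pts <- pts[inside, , drop = FALSE]
  }
  d2 <- outer(pts$x, stations$x, "-")^2 + outer(pts$y, stations$y, "-")^2
  d <- sqrt(d2)
  w <- d^(-power)
  val <- numeric(nrow(pts))
  hit <- d == 0
  at_station <- rowSums(hit) > 0
  if (any(at_station)) {
    j <- apply(hit[at_station, , drop = FALSE], 1, which.max)
    val[at_station] <- stations$value[j]
  }
  if (any(!at_station)) {
    ws <- w[!at_station, , drop = FALSE]
    val[!at_station] <- as.vector(ws %*% stations$value) / rowSums(ws)
  }
  data.frame(x = pts$x, y = pts$y, value = val)
}

#' Write an interpolated grid as an ESRI ASCII raster
#'
#' Cells of the grid spec absent from `result` (masked) are written as
#' NODATA.
#'
#' @param result output of [idw()].
#' @param grid the [grid_spec()] used.
#' @param path output file.
#' @param nodata NODATA sentinel (default -9999).
#' @export
write_esri_ascii <- function(result, grid, path, nodata = -9999) {
  stopifnot(inherits(grid, "grid_spec"))
  pts <- grid_points(grid)
  ncols <- length(unique(pts$x))
  nrows <- length(unique(pts$y))
  m <- matrix(nodata, nrows, ncols)
  ix <- round((result$x - grid$xmin - grid$cell_size / 2) / grid$cell_size) + 1
  iy <- round((result$y - grid$ymin - grid$cell_size / 2) / grid$cell_size) + 1
  m[cbind(iy, ix)] <- result$value
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncols), sprintf("nrows %d", nrows),
    sprintf("xllcorner %g", grid$xmin), sprintf("yllcorner %g", grid$ymin),
    sprintf("cellsize %g", grid$cell_size),
    sprintf("NODATA_value %g", nodata)), con)
  # ESRI ASCII rows run north to south
  for (i in nrows:1)
    writeLines(paste(format(m[i, ], trim = TRUE, digits = 15),
                     collapse = " "), con)
  invisible(path)
}
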