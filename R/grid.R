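#' Gridded monthly climatology
#'
#' Container for a 12-month precipitation + temperature climatology on a
#' regular cell-centered longitude/latitude grid with a land mask.  All
#' downstream stages (bioclim derivation, candidate sampling, ensemble
#' statistics) consume this structure.
#'
#' @param lon,lat numeric vectors of cell-center coordinates, strictly
#'   increasing and regularly spaced (degrees).
#' @param precip numeric array `length(lon) x length(lat) x 12`, monthly
#'   precipitation in mm/month, non-negative where not `NA`.
#' @param temp numeric array of the same shape, monthly mean temperature
#'   in degrees Celsius.
#' @param mask logical matrix `length(lon) x length(lat)`; `TRUE` marks land.
#' @return An object of class `monthly_grid`.
#' @export
monthly_grid <- function(lon, lat, precip, temp, mask) {
  stopifnot(is.numeric(lon), is.numeric(lat),
            length(lon) >= 2, length(lat) >= 2)
  if (any(diff(lon) <= 0) || any(diff(lat) <= 0))
    stop("lon and lat must be strictly increasing")
  dims <- c(length(lon), length(lat), 12L)
  if (!identical(dim(precip), as.integer(dims)))
    stop("precip must be a lon x lat x 12 array")
  if (!identical(dim(temp), as.integer(dims)))
    stop("temp must be a lon x lat x 12 array")
  if (!identical(dim(mask), as.integer(dims[1:2])))
    stop("mask shape must match the grid")
  if (any(precip < 0, na.rm = TRUE))
    stop("precipitation must be non-negative")
  structure(list(lon = as.numeric(lon), lat = as.numeric(lat),
                 precip = precip, temp = temp,
                 mask = mask),
            class = "monthly_grid")
}

#' Single gridded field
#'
#' A 2-D field (one variable, one time slice or aggregate) on a regular
#' cell-centered lon/lat grid.  Missing cells are `NA`.
#'
#' @param lon,lat cell-center coordinates (degrees), strictly increasing.
#' @param values numeric matrix `length(lon) x length(lat)`.
#' @param units character unit string (e.g. `"mm/month"`).
#' @param mask optional logical land mask of the same shape.
#' @return An object of class `grid_field`.
#' @export
grid_field <- function(lon, lat, values, units = "", mask = NULL) {
  stopifnot(length(lon) >= 1, length(lat) >= 1)
  if (!identical(dim(values), c(length(lon), length(lat))))
    stop("values shape must match lon x lat")
  if (!is.null(mask) && !identical(dim(mask), dim(values)))
    stop("mask shape matches values")
  structure(list(lon = as.numeric(lon), lat = as.numeric(lat),
                 values = values, units = units, mask = mask),
            class = "grid_field")
}

#' @export
print.monthly_grid <- function(x, ...) {
  cat(sprintf("<monthly_grid> %d x %d cells, %.4g deg resolution, %d land (%.0f%%)\n",
              length(x$lon), length(x$lat), grid_resolution(x)[1],
              sum(x$mask), 100 * mean(x$mask)))
  cat(sprintf("  lon %g..%g, lat %g..%g; precip mm/month, temp degC\n",
              min(x$lon), max(x$lon), min(x$lat), max(x$lat)))
  invisible(x)
}

#' @export
print.grid_field <- function(x, ...) {
  cat(sprintf("<grid_field> %d x %d cells [%s], range %.4g..%.4g\n",
              length(x$lon), length(x$lat), x$units,
              suppressWarnings(min(x$values, na.rm = TRUE)),
              suppressWarnings(max(x$values, na.rm = TRUE))))
  invisible(x)
}

grid_resolution <- function(g) {
  c(mean(diff(g$lon)), mean(diff(g$lat)))
}

# Linear cell index (lon-major) for coordinate pairs; points are snapped to
# the nearest cell center with ties broken toward the smaller lon index,
# then the smaller lat index.
nearest_cell_index <- function(g, lon, lat) {
  i <- snap_index(g$lon, lon)
  j <- snap_index(g$lat, lat)
  cbind(i = i, j = j)
}

snap_index <- function(centers, x) {
  n <- length(centers)
  d <- mean(diff(centers))
  f <- (x - centers[1]) / d
  i <- floor(f) + 1L
  frac <- f - (i - 1L)
  # strictly greater than half a cell away -> next center; exact midpoint
  # stays with the smaller index (documented tie-break)
  i <- i + as.integer(frac > 0.5 + 1e-12)
  pmin(pmax(i, 1L), n)
}

congruent_grids <- function(a, b, tol = 1e-8) {
  length(a$lon) == length(b$lon) && length(a$lat) == length(b$lat) &&
    max(abs(a$lon - b$lon)) < tol && max(abs(a$lat - b$lat)) < tol
}

#' Write / read a monthly climatology as plain text
#'
#' Grids are exchanged as a self-describing long-format CSV: metadata header
#' lines (prefixed `#`) carry the dimension sizes and units, followed by one
#' row per (cell, month) with columns `lon, lat, land, month, precip, temp`.
#'
#' @param grid a [monthly_grid()].
#' @param path file path.
#' @return `write_monthly_grid` returns `path` invisibly; `read_monthly_grid`
#'   returns a `monthly_grid`.
#' @export
write_monthly_grid <- function(grid, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# paleorain monthly grid v1",
               sprintf("# nlon: %d", length(grid$lon)),
               sprintf("# nlat: %d", length(grid$lat)),
               "# units_precip: mm/month",
               "# units_temp: degC"), con)
  idx <- expand.grid(i = seq_along(grid$lon), j = seq_along(grid$lat),
                     month = 1:12)
  df <- data.frame(lon = grid$lon[idx$i], lat = grid$lat[idx$j],
                   land = as.integer(grid$mask[cbind(idx$i, idx$j)]),
                   month = idx$month,
                   precip = grid$precip[as.matrix(idx)],
                   temp = grid$temp[as.matrix(idx)])
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_monthly_grid
#' @export
read_monthly_grid <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  need <- c("lon", "lat", "land", "month", "precip", "temp")
  if (!all(need %in% names(df))) stop("malformed grid file: ", path)
  lon <- sort(unique(df$lon))
  lat <- sort(unique(df$lat))
  i <- match(df$lon, lon); j <- match(df$lat, lat)
  precip <- array(NA_real_, c(length(lon), length(lat), 12))
  temp <- precip
  precip[cbind(i, j, df$month)] <- df$precip
  temp[cbind(i, j, df$month)] <- df$temp
  mask <- matrix(FALSE, length(lon), length(lat))
  mask[cbind(i, j)] <- df$land > 0
  monthly_grid(lon, lat, precip, temp, mask)
}
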