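#' Rectangular analysis region
#'
#' Cell membership everywhere in the package is by cell-center inclusion;
#' longitudes are normalised to [-180, 180).
#'
#' @param lon_min,lon_max,lat_min,lat_max box edges in degrees.
#' @param land_only restrict to land cells where a mask is available.
#' @return An object of class `region_box`.
#' @export
region_box <- function(lon_min, lon_max, lat_min, lat_max, land_only = FALSE) {
  lon_min <- norm_lon(lon_min); lon_max <- norm_lon(lon_max)
  if (lon_min >= lon_max) stop("lon_min must be < lon_max after normalisation")
  if (lat_min >= lat_max) stop("lat_min must be < lat_max")
  structure(list(lon_min = lon_min, lon_max = lon_max,
                 lat_min = lat_min, lat_max = lat_max,
                 land_only = land_only),
            class = "region_box")
}

norm_lon <- function(x) ((x + 180) %% 360) - 180

in_box <- function(lon, lat, box) {
  lon <- norm_lon(lon)
  lon >= box$lon_min & lon <= box$lon_max &
    lat >= box$lat_min & lat <= box$lat_max
}

#' Bilinear regridding of a field
#'
#' Interpolates `field` to the cell centers of `target`.  Missing source
#' cells are dropped from each bilinear stencil and the remaining weights
#' renormalised; target cells with no valid support are `NA`.  A land mask,
#' if present, is regridded by majority rule (interpolated land fraction
#' >= 0.5).  Used to bring ensemble members to a lowest common resolution
#' before computing multi-model statistics.
#'
#' @param field a [grid_field()].
#' @param target a `grid_field`, [monthly_grid()], or list with `lon`, `lat`.
#' @return A `grid_field` on the target grid.
#' @export
regrid_bilinear <- function(field, target) {
  lon <- target$lon; lat <- target$lat
  res <- grid_resolution(field)
  if (min(lon) < min(field$lon) - res[1] / 2 - 1e-9 ||
      max(lon) > max(field$lon) + res[1] / 2 + 1e-9 ||
      min(lat) < min(field$lat) - res[2] / 2 - 1e-9 ||
      max(lat) > max(field$lat) + res[2] / 2 + 1e-9)
    stop("target extent outside source extent")
  vals <- bilinear_matrix(field$lon, field$lat, field$values, lon, lat)
  mask <- NULL
  if (!is.null(field$mask)) {
    frac <- bilinear_matrix(field$lon, field$lat,
                            matrix(as.numeric(field$mask),
                                   length(field$lon), length(field$lat)),
                            lon, lat)
    mask <- !is.na(frac) & frac >= 0.5
  }
  grid_field(lon, lat, vals, units = field$units, mask = mask)
}

# NA-aware bilinear interpolation of a matrix S (on centers lonc x latc) to
# the product grid xi x yi; weights of NA corners are renormalised away.
bilinear_matrix <- function(lonc, latc, S, xi, yi) {
  dx <- mean(diff(lonc)); dy <- mean(diff(latc))
  fx <- (xi - lonc[1]) / dx
  fy <- (yi - latc[1]) / dy
  i <- pmin(pmax(floor(fx) + 1L, 1L), length(lonc) - 1L)
  j <- pmin(pmax(floor(fy) + 1L, 1L), length(latc) - 1L)
  tx <- pmin(pmax(fx - (i - 1L), 0), 1)
  ty <- pmin(pmax(fy - (j - 1L), 0), 1)
  num <- matrix(0, length(xi), length(yi))
  den <- num
  for (k in 1:4) {
    ii <- if (k %% 2 == 0) i + 1L else i
    jj <- if (k > 2) j + 1L else j
    wx <- if (k %% 2 == 0) tx else 1 - tx
    wy <- if (k > 2) ty else 1 - ty
    V <- S[ii, jj, drop = FALSE]
    W <- outer(wx, wy)
    ok <- !is.na(V)
    num[ok] <- num[ok] + (W * ifelse(ok, V, 0))[ok]
    den <- den + W * ok
  }
  out <- num / den
  out[den <= 1e-12] <- NA_real_
  out
}

#' Multi-model ensemble mean
#'
#' The cell-wise unweighted mean across ensemble members on a common grid
#' (regrid members first; see [regrid_bilinear()]).  A cell is averaged over
#' the members where it is non-missing and is missing only where every
#' member is missing.
#'
#' @param fields list of congruent [grid_field()]s.
#' @return A `grid_field`.
#' @export
ensemble_mean <- function(fields) {
  stopifnot(length(fields) >= 1)
  f1 <- fields[[1]]
  for (f in fields[-1])
    if (!congruent_grids(f1, f)) stop("ensemble members on mismatched grids")
  num <- matrix(0, length(f1$lon), length(f1$lat)); den <- num
  for (f in fields) {
    ok <- !is.na(f$values)
    num[ok] <- num[ok] + f$values[ok]
    den <- den + ok
  }
  out <- num / den
  out[den == 0] <- NA_real_
  grid_field(f1$lon, f1$lat, out, units = f1$units, mask = f1$mask)
}

#' Seasonal mean of a monthly climatology
#'
#' Unweighted mean of the named calendar months (e.g. `months = 6:8` for
#' JJA).  The annual total in mm/yr is [annual_map()].
#'
#' @param grid a [monthly_grid()] or a lon x lat x 12 array plus `lon`,`lat`.
#' @param months integer subset of 1..12.
#' @param var `"precip"` or `"temp"`.
#' @return A `grid_field` (mm/month or degC).
#' @export
seasonal_mean <- function(grid, months, var = c("precip", "temp")) {
  var <- match.arg(var)
  if (length(months) == 0 || !all(months %in% 1:12))
    stop("months must be a non-empty subset of 1..12")
  a <- grid[[var]][, , months, drop = FALSE]
  vals <- apply(a, c(1, 2), mean)
  grid_field(grid$lon, grid$lat, vals,
             units = if (var == "precip") "mm/month" else "degC",
             mask = grid$mask)
}

#' Annual precipitation total
#'
#' @param grid a [monthly_grid()].
#' @return A `grid_field` of MAP in mm/yr (the sum of the 12 monthly fields).
#' @export
annual_map <- function(grid) {
  vals <- apply(grid$precip, c(1, 2), sum)
  grid_field(grid$lon, grid$lat, vals, units = "mm/yr", mask = grid$mask)
}

box_selection <- function(field, box) {
  list(i = which(norm_lon(field$lon) >= box$lon_min &
                   norm_lon(field$lon) <= box$lon_max),
       j = which(field$lat >= box$lat_min & field$lat <= box$lat_max))
}

#' Area-weighted regional mean of a field
#'
#' cos(latitude)-weighted mean over cells whose centers fall inside the box,
#' restricted to land when the box is flagged `land_only` (requires a mask
#' on the field).  Missing cells are excluded.
#'
#' @param field a [grid_field()].
#' @param box a [region_box()].
#' @param weighted use cos-latitude area weights (default `TRUE`).
#' @return Scalar mean.
#' @export
regional_mean <- function(field, box, weighted = TRUE) {
  sel <- box_selection(field, box)
  if (length(sel$i) == 0 || length(sel$j) == 0)
    stop("box does not intersect the grid")
  V <- field$values[sel$i, sel$j, drop = FALSE]
  W <- outer(rep(1, length(sel$i)),
             if (weighted) cos(field$lat[sel$j] * pi / 180)
             else rep(1, length(sel$j)))
  keep <- !is.na(V)
  if (box$land_only) {
    if (is.null(field$mask)) stop("land_only box but field has no mask")
    keep <- keep & field$mask[sel$i, sel$j, drop = FALSE]
  }
  if (!any(keep)) stop("empty selection: no valid cells in the box")
  sum(V[keep] * W[keep]) / sum(W[keep])
}

#' Zonal mean within a box
#'
#' Averages along longitude only, returning one value per latitude row whose
#' center falls in the box (rows with no valid cells are `NA`).
#'
#' @inheritParams regional_mean
#' @return data.frame with columns `lat` and `mean`.
#' @export
zonal_mean <- function(field, box) {
  sel <- box_selection(field, box)
  if (length(sel$i) == 0 || length(sel$j) == 0)
    stop("box does not intersect the grid")
  out <- vapply(sel$j, function(j) {
    v <- field$values[sel$i, j]
    keep <- !is.na(v)
    if (box$land_only) keep <- keep & field$mask[sel$i, j]
    if (!any(keep)) NA_real_ else mean(v[keep])
  }, numeric(1))
  data.frame(lat = field$lat[sel$j], mean = out)
}

#' Root-mean-square error between two fields over a region
#'
#' @param a,b congruent [grid_field()]s.
#' @param box a [region_box()]; `NULL` means the whole grid (no land
#'   restriction).
#' @param weighted cos-latitude weighting of the squared differences.
#' @return Scalar RMSE in the fields' units.
#' @export
field_rmse <- function(a, b, box = NULL, weighted = FALSE) {
  if (!congruent_grids(a, b)) stop("fields on mismatched grids")
  d <- grid_field(a$lon, a$lat, (a$values - b$values)^2,
                  units = a$units, mask = a$mask)
  if (is.null(box))
    box <- region_box(min(a$lon) - 1, max(a$lon) + 1,
                      min(a$lat) - 1, max(a$lat) + 1)
  sqrt(regional_mean(d, box, weighted = weighted))
}

#' Cell-wise difference of two fields
#'
#' `a - b`; missing where either operand is missing.  Also serves as the
#' precipitation-minus-evaporation balance when given P and E fields.
#'
#' @param a,b congruent [grid_field()]s.
#' @return A `grid_field`.
#' @export
field_difference <- function(a, b) {
  if (!congruent_grids(a, b)) stop("fields on mismatched grids")
  grid_field(a$lon, a$lat, a$values - b$values, units = a$units,
             mask = a$mask)
}
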