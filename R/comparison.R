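#' Euler-pole rotation specification
#'
#' A rigid rotation of the sphere about the axis through the given pole, by
#' `angle` degrees (right-handed, i.e. counterclockwise seen from outside
#' the pole).  Used to rotate fossil-site coordinates between plate
#' configurations.  Alternatively a per-site lookup table (columns `site`,
#' `lon`, `lat`) supplies precomputed rotated coordinates.
#'
#' @param pole_lon,pole_lat Euler pole coordinates, degrees.
#' @param angle rotation angle in degrees, in (-360, 360].
#' @return An object of class `rotation_spec`.
#' @export
rotation_spec <- function(pole_lon, pole_lat, angle) {
  if (!(angle > -360 && angle <= 360)) stop("angle must be in (-360, 360]")
  if (abs(pole_lat) > 90) stop("pole must be on the sphere")
  structure(list(pole_lon = norm_lon(pole_lon), pole_lat = pole_lat,
                 angle = angle),
            class = "rotation_spec")
}

#' @rdname rotation_spec
#' @param table data.frame with columns `site`, `lon`, `lat`.
#' @export
rotation_lookup <- function(table) {
  stopifnot(all(c("site", "lon", "lat") %in% names(table)))
  structure(list(table = table), class = "rotation_lookup")
}

ll_to_xyz <- function(lon, lat) {
  lon <- lon * pi / 180; lat <- lat * pi / 180
  cbind(cos(lat) * cos(lon), cos(lat) * sin(lon), sin(lat))
}

xyz_to_ll <- function(v) {
  cbind(lon = atan2(v[, 2], v[, 1]) * 180 / pi,
        lat = asin(pmin(pmax(v[, 3], -1), 1)) * 180 / pi)
}

#' Rotate geographic coordinates about an Euler pole
#'
#' Rodrigues' formula on Cartesian unit vectors:
#' `v' = v cos(t) + (k x v) sin(t) + k (k . v) (1 - cos(t))` with `k` the
#' pole axis.  Composing a rotation with its inverse returns the input to
#' within 1e-9 degrees, and pairwise great-circle distances are preserved.
#' With a lookup spec the tabulated coordinates are returned instead.
#'
#' @param lon,lat point coordinates, degrees (vectorised).
#' @param spec a [rotation_spec()] or [rotation_lookup()].
#' @param site site names; required for a lookup spec.
#' @return Matrix with columns `lon`, `lat`.
#' @export
rotate_point <- function(lon, lat, spec, site = NULL) {
  if (inherits(spec, "rotation_lookup")) {
    if (is.null(site)) stop("lookup rotation needs site names")
    m <- match(site, spec$table$site)
    if (anyNA(m)) stop("site absent from rotation lookup table: ",
                       paste(site[is.na(m)], collapse = ", "))
    return(cbind(lon = spec$table$lon[m], lat = spec$table$lat[m]))
  }
  stopifnot(inherits(spec, "rotation_spec"))
  k <- drop(ll_to_xyz(spec$pole_lon, spec$pole_lat))
  v <- ll_to_xyz(lon, lat)
  t <- spec$angle * pi / 180
  kxv <- cbind(k[2] * v[, 3] - k[3] * v[, 2],
               k[3] * v[, 1] - k[1] * v[, 3],
               k[1] * v[, 2] - k[2] * v[, 1])
  kdv <- drop(v %*% k)
  vr <- v * cos(t) + kxv * sin(t) + outer(kdv * (1 - cos(t)), k)
  xyz_to_ll(vr)
}

# Central angle between point pairs, in degrees.
great_circle_deg <- function(lon1, lat1, lon2, lat2) {
  d <- rowSums(ll_to_xyz(lon1, lat1) * ll_to_xyz(lon2, lat2))
  acos(pmin(pmax(d, -1), 1)) * 180 / pi
}

#' Sample a model MAP field at site locations
#'
#' Each site receives the value of the nearest land cell; sites whose
#' containing cell is ocean are matched to the nearest land cell within
#' `radius` grid cells and flagged `relocated` (coarse paleo grids put
#' coastal sites offshore).  Sites with no land cell in reach get `NA` and
#' are flagged `unmatched`.  Sites falling in one shared coarse cell all
#' receive that cell's value; the shared cell index is reported.
#'
#' @param map_field a [grid_field()] of annual MAP (mm/yr) with a land mask.
#' @param sites data.frame with columns `site`, `lon`, `lat`.
#' @param radius search radius in grid cells.
#' @return data.frame: `site`, `lon`, `lat`, `model_map`, `cell`,
#'   `relocated`, `unmatched`.
#' @export
sample_model_at_sites <- function(map_field, sites, radius = 2L) {
  if (nrow(sites) == 0) stop("empty site list")
  if (is.null(map_field$mask)) stop("MAP field needs a land mask")
  g <- map_field
  n <- nrow(sites)
  val <- rep(NA_real_, n); cell <- rep(NA_integer_, n)
  reloc <- logical(n); unmatched <- logical(n)
  ij <- nearest_cell_index(g, sites$lon, sites$lat)
  nlon <- length(g$lon)
  for (k in seq_len(n)) {
    i <- ij[k, 1]; j <- ij[k, 2]
    if (!g$mask[i, j]) {
      alt <- nearest_land_cell(g, sites$lon[k], sites$lat[k], i, j, radius)
      if (is.null(alt)) { unmatched[k] <- TRUE; next }
      i <- alt[1]; j <- alt[2]; reloc[k] <- TRUE
    }
    val[k] <- g$values[i, j]
    cell[k] <- i + (j - 1L) * nlon
  }
  data.frame(site = sites$site, lon = sites$lon, lat = sites$lat,
             model_map = val, cell = cell, relocated = reloc,
             unmatched = unmatched, stringsAsFactors = FALSE)
}

#' Merge co-located reconstructions
#'
#' Records whose coordinates coincide after rounding to `digits` decimal
#' degrees are averaged into one: central values and both range endpoints
#' are arithmetic means of the members, and the provenance column lists the
#' merged rows.  Idempotent and order-independent.
#'
#' @param sites a site table with `site`, `lon`, `lat`, `map_early_low`,
#'   `map_early_high` and (optionally) `map_central`, `map_modern`.
#' @param digits coordinate rounding used to define co-location.
#' @return Merged site table with a `members` column.
#' @export
average_colocated <- function(sites, digits = 2) {
  if (nrow(sites) == 0) stop("empty site table")
  if (is.null(sites$map_central))
    sites$map_central <- (sites$map_early_low + sites$map_early_high) / 2
  key <- paste(round(sites$lon, digits), round(sites$lat, digits))
  out <- lapply(unique(key), function(k) {
    grp <- sites[key == k, , drop = FALSE]
    data.frame(site = grp$site[1], lon = grp$lon[1], lat = grp$lat[1],
               map_early_low = mean(grp$map_early_low),
               map_early_high = mean(grp$map_early_high),
               map_central = mean(grp$map_central),
               map_modern = if (!is.null(grp$map_modern))
                 mean(grp$map_modern) else NA_real_,
               n_members = nrow(grp),
               members = paste(grp$site, collapse = " | "),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' RMSE between model values and site reconstructions
#'
#' Root-mean-square of (model MAP - reconstruction comparand) over matched
#' sites; sites with missing model values are excluded and counted.  The
#' comparand is the central value (range midpoint) by default.  Each row
#' also reports whether the model value falls inside the reconstructed
#' range.
#'
#' @param model_values numeric per-site model MAP (mm/yr), or the data.frame
#'   from [sample_model_at_sites()].
#' @param sites merged site table (see [average_colocated()]) with
#'   `map_central`, `map_early_low`, `map_early_high`.
#' @param model_id label recorded in the comparison table.
#' @return List of class `comparison_table`: `rmse`, `n_matched`,
#'   `n_excluded`, `table` (one row per site).
#' @export
rmse_vs_reconstructions <- function(model_values, sites, model_id = "model") {
  if (is.data.frame(model_values)) model_values <- model_values$model_map
  if (length(model_values) != nrow(sites))
    stop("one model value per site required")
  central <- sites$map_central
  ok <- !is.na(model_values) & !is.na(central)
  if (!any(ok)) stop("zero matched sites")
  err <- model_values[ok] - central[ok]
  tab <- data.frame(model = model_id, site = sites$site[ok],
                    model_map = model_values[ok],
                    reconstruction = central[ok],
                    error = err,
                    within_range = model_values[ok] >= sites$map_early_low[ok] &
                      model_values[ok] <= sites$map_early_high[ok],
                    stringsAsFactors = FALSE)
  structure(list(rmse = sqrt(mean(err^2)), n_matched = sum(ok),
                 n_excluded = sum(!ok), model = model_id, table = tab),
            class = "comparison_table")
}

#' @export
print.comparison_table <- function(x, ...) {
  cat(sprintf("<comparison_table> %s: RMSE %.1f mm/yr over %d sites (%d excluded); %d/%d within range\n",
              x$model, x$rmse, x$n_matched, x$n_excluded,
              sum(x$table$within_range), x$n_matched))
  invisible(x)
}
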