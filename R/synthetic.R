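#' Configuration for the synthetic climatology generator
#'
#' The generator emulates the gross structure of tropical African
#' precipitation that the reconstruction pipeline operates on: a zonally
#' symmetric monsoon-like wet belt, Gaussian in latitude, whose center
#' migrates sinusoidally through the year, on top of a dry background, with
#' optional mean-one lognormal multiplicative noise.  Temperature has a
#' meridional gradient and a hemisphere-antisymmetric seasonal cycle so that
#' warmest/coldest quarters are well defined.  The land mask is a smooth
#' elliptical continent occupying `land_frac` of the domain.
#'
#' @param lon_range,lat_range domain extent in degrees.
#' @param resolution cell size in degrees (> 0).
#' @param base background precipitation, mm/month.
#' @param amplitude equator-peak wet-belt amplitude, mm/month (>= 0).
#' @param decay meridional Gaussian decay scale of the wet belt, degrees.
#' @param belt_migration seasonal north-south migration of the belt center,
#'   degrees of latitude.
#' @param phase month (1..12) at which the belt is furthest north.
#' @param temp_eq equatorial annual-mean temperature, degC.
#' @param temp_pole_drop meridional temperature drop toward the poles, degC.
#' @param temp_seasonal amplitude of the seasonal temperature cycle at the
#'   poleward domain edge, degC.
#' @param noise_sd approximate sd of the multiplicative precipitation noise
#'   at the wet-belt peak, mm/month (>= 0; 0 disables noise exactly).
#' @param land_frac fraction of cells that are land.
#' @param seed integer seed; a fixed seed gives bit-identical grids.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(lon_range = c(-20, 52), lat_range = c(-40, 40),
                             resolution = 1, base = 20, amplitude = 200,
                             decay = 15, belt_migration = 10, phase = 7,
                             temp_eq = 27, temp_pole_drop = 30,
                             temp_seasonal = 18, noise_sd = 10,
                             land_frac = 0.55, seed = 1L) {
  if (resolution <= 0) stop("resolution must be positive")
  if (amplitude < 0) stop("amplitude must be non-negative")
  if (noise_sd < 0) stop("noise sd must be non-negative")
  if (diff(lon_range) < 2 * resolution || diff(lat_range) < 2 * resolution)
    stop("extent must span at least 2 cells per axis")
  structure(list(lon_range = lon_range, lat_range = lat_range,
                 resolution = resolution, base = base, amplitude = amplitude,
                 decay = decay, belt_migration = belt_migration,
                 phase = phase, temp_eq = temp_eq,
                 temp_pole_drop = temp_pole_drop,
                 temp_seasonal = temp_seasonal, noise_sd = noise_sd,
                 land_frac = land_frac, seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Generate a synthetic monthly climatology grid
#'
#' @param config a [synthetic_config()].
#' @return A [monthly_grid()] (12 precipitation fields in mm/month, 12
#'   temperature fields in degC, elliptical land mask), deterministic under
#'   the config seed.
#' @export
generate_climate_grid <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  r <- config$resolution
  lon <- seq(config$lon_range[1] + r / 2, config$lon_range[2] - r / 2, by = r)
  lat <- seq(config$lat_range[1] + r / 2, config$lat_range[2] - r / 2, by = r)
  nlon <- length(lon); nlat <- length(lat)

  # smooth elliptical continent sized to the requested land fraction
  cx <- mean(config$lon_range); cy <- mean(config$lat_range)
  rr <- outer(((lon - cx) / diff(config$lon_range))^2,
              ((lat - cy) / diff(config$lat_range))^2, "+")
  mask <- rr <= stats::quantile(rr, config$land_frac)

  set.seed(config$seed)
  precip <- array(0, c(nlon, nlat, 12))
  temp <- array(0, c(nlon, nlat, 12))
  s <- if (config$noise_sd > 0)
    config$noise_sd / (config$base + config$amplitude) else 0
  for (m in 1:12) {
    belt <- config$belt_migration * cos(2 * pi * (m - config$phase) / 12)
    sig <- config$base +
      config$amplitude * exp(-(lat - belt)^2 / (2 * config$decay^2))
    P <- matrix(rep(sig, each = nlon), nlon, nlat)
    if (s > 0)
      P <- P * matrix(stats::rlnorm(nlon * nlat, -s^2 / 2, s), nlon, nlat)
    precip[, , m] <- P
    tm <- config$temp_eq - config$temp_pole_drop * (abs(lat) / 90)^1.5 +
      config$temp_seasonal * (lat / 90) * cos(2 * pi * (m - 7) / 12)
    temp[, , m] <- matrix(rep(tm, each = nlon), nlon, nlat)
  }
  monthly_grid(lon, lat, precip, temp, mask)
}

#' Generate a synthetic fossil assemblage with known climatic truth
#'
#' Draws taxa whose occurrences are sampled in climate space: each land cell
#' is assigned a probability proportional to a six-variable Gaussian density
#' centered on the bioclim vector of the designated fossil-site cell (the
#' "true" climate), with per-variable sds `envelope_sd`.  Occurrences are
#' placed at the sampled cells' centers.  The returned truth record holds
#' the generating parameters, enabling parameter-recovery tests.
#'
#' @param grid a [monthly_grid()].
#' @param site `c(lon, lat)` of the fossil site; must fall on a land cell.
#' @param n_taxa number of taxa (>= 1).
#' @param n_occ_per_taxon occurrences per taxon (>= 2).
#' @param envelope_sd named numeric(6) of generating sds; `NULL` (default)
#'   uses 0.25 x the per-variable sd over land cells, a moderate envelope.
#' @param seed integer seed.
#' @return List with `occurrences` (data.frame: taxon, lon, lat, flags,
#'   source) and `truth` (list: `bioclim` — the site cell's vector, `site`,
#'   `cell`, `envelope_mu`, `envelope_sd`).
#' @export
generate_assemblage <- function(grid, site, n_taxa, n_occ_per_taxon,
                                envelope_sd = NULL, seed = 1L) {
  stopifnot(n_taxa >= 1, n_occ_per_taxon >= 2)
  ij <- nearest_cell_index(grid, site[1], site[2])
  if (!grid$mask[ij[1], ij[2]]) stop("fossil site must be a land cell")
  B <- bioclim_grid(grid)
  nlon <- length(grid$lon)
  cell <- ij[1] + (ij[2] - 1L) * nlon
  truth_vec <- B[cell, ]
  land <- which(grid$mask)
  if (is.null(envelope_sd))
    envelope_sd <- 0.25 * apply(B[land, , drop = FALSE], 2, stats::sd)
  if (any(envelope_sd <= 0)) stop("envelope_sd must be positive in every variable")
  names(envelope_sd) <- bioclim_vars

  # log-weights of every land cell under the generating Gaussian
  Z <- sweep(B[land, , drop = FALSE], 2, truth_vec)
  Z <- sweep(Z, 2, envelope_sd, "/")
  lw <- -rowSums(Z^2) / 2
  w <- exp(lw - max(lw))

  set.seed(seed)
  occ <- vector("list", n_taxa)
  for (t in seq_len(n_taxa)) {
    cells <- sample(land, n_occ_per_taxon, replace = TRUE, prob = w)
    i <- (cells - 1L) %% nlon + 1L
    j <- (cells - 1L) %/% nlon + 1L
    occ[[t]] <- data.frame(taxon = sprintf("taxon_%02d", t),
                           lon = grid$lon[i], lat = grid$lat[j],
                           flags = "", source = "synthetic",
                           stringsAsFactors = FALSE)
  }
  list(occurrences = do.call(rbind, occ),
       truth = list(bioclim = truth_vec,
                    site = c(lon = grid$lon[ij[1]], lat = grid$lat[ij[2]]),
                    cell = cell,
                    envelope_mu = truth_vec,
                    envelope_sd = envelope_sd))
}

#' Generate a pseudo-model ensemble from a base climatology
#'
#' Model `k` is the base climatology regridded to its own resolution, plus a
#' constant additive precipitation bias, plus seeded Gaussian noise
#' (truncated at zero).  The known biases and noise sd are attached so tests
#' can assert recovery of ensemble statistics.
#'
#' @param base a [monthly_grid()].
#' @param n_models number of pseudo-models (>= 1).
#' @param biases numeric(n_models), additive biases in mm/month.
#' @param resolutions numeric(n_models), target resolutions in degrees.
#' @param noise_sd additive noise sd in mm/month.
#' @param seed integer seed.
#' @return List of `monthly_grid`s with attribute `truth` (biases, noise_sd).
#' @export
generate_model_ensemble <- function(base, n_models, biases = NULL,
                                    resolutions = NULL, noise_sd = 0,
                                    seed = 1L) {
  stopifnot(n_models >= 1)
  if (is.null(biases)) biases <- rep(0, n_models)
  if (is.null(resolutions)) resolutions <- rep(grid_resolution(base)[1], n_models)
  if (length(biases) == 0 || length(resolutions) == 0)
    stop("biases and resolutions must be non-empty")
  if (length(biases) != n_models || length(resolutions) != n_models)
    stop("biases/resolutions length must equal n_models")
  set.seed(seed)
  out <- vector("list", n_models)
  for (k in seq_len(n_models)) {
    g <- regrid_monthly(base, resolutions[k])
    g$precip <- pmax(g$precip + biases[k], 0)
    if (noise_sd > 0) {
      g$precip <- pmax(g$precip +
                         array(stats::rnorm(length(g$precip), 0, noise_sd),
                               dim(g$precip)), 0)
    }
    out[[k]] <- g
  }
  names(out) <- sprintf("model_%02d", seq_len(n_models))
  attr(out, "truth") <- list(biases = biases, noise_sd = noise_sd,
                             resolutions = resolutions)
  out
}

# Regrid a full monthly climatology to a new resolution over the same extent.
regrid_monthly <- function(grid, resolution) {
  r0 <- grid_resolution(grid)
  if (abs(resolution - r0[1]) < 1e-9 && abs(resolution - r0[2]) < 1e-9)
    return(grid)
  ext_lon <- c(min(grid$lon) - r0[1] / 2, max(grid$lon) + r0[1] / 2)
  ext_lat <- c(min(grid$lat) - r0[2] / 2, max(grid$lat) + r0[2] / 2)
  lon <- seq(ext_lon[1] + resolution / 2, ext_lon[2] - resolution / 2,
             by = resolution)
  lat <- seq(ext_lat[1] + resolution / 2, ext_lat[2] - resolution / 2,
             by = resolution)
  precip <- array(NA_real_, c(length(lon), length(lat), 12))
  temp <- precip
  for (m in 1:12) {
    precip[, , m] <- bilinear_matrix(grid$lon, grid$lat, grid$precip[, , m],
                                     lon, lat)
    temp[, , m] <- bilinear_matrix(grid$lon, grid$lat, grid$temp[, , m],
                                   lon, lat)
  }
  frac <- bilinear_matrix(grid$lon, grid$lat,
                          matrix(as.numeric(grid$mask),
                                 length(grid$lon), length(grid$lat)),
                          lon, lat)
  monthly_grid(lon, lat, pmax(precip, 0), temp, !is.na(frac) & frac >= 0.5)
}

#' Packaged early-Eocene African site table
#'
#' Loads the packaged fixture of fossil plant localities: one row per
#' published record (19 rows), with site name, modern latitude/longitude,
#' the low/high bounds of the reconstructed early-Eocene MAP (mm/yr), the
#' modern MAP where the site is on land in the observational climatology
#' (`NA` over ocean), the uncertainty convention of the range (`ci95` for
#' the 11 NLR-analysed assemblages, `sd1` for the 8 leaf-area records at
#' Mahenge, Tanzania) and the reconstruction method.
#'
#' @return data.frame of class `site_table` with columns `site`, `lat`,
#'   `lon`, `map_early_low`, `map_early_high`, `map_central` (range
#'   midpoint), `map_modern`, `uncertainty`, `method`, `frame`.
#' @export
load_site_fixture <- function() {
  path <- system.file("extdata", "eocene_africa_sites.csv",
                      package = "paleorain")
  if (path == "" || !file.exists(path)) stop("site fixture missing")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("site", "lat", "lon", "map_early_low", "map_early_high",
            "map_modern", "uncertainty", "method")
  if (!all(need %in% names(df))) stop("site fixture malformed")
  df$map_central <- (df$map_early_low + df$map_early_high) / 2
  df$frame <- "modern"
  class(df) <- c("site_table", "data.frame")
  df
}
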