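#' Names of the six precipitation bioclim variables
#'
#' `map` mean annual precipitation (mm/yr); `wmp`/`dmp` wettest/driest month
#' precipitation (mm/month); `ps` precipitation seasonality (coefficient of
#' variation of the monthly series, in percent); `wqp`/`cqp` precipitation of
#' the warmest/coldest 3-month quarter (mm per quarter).
#' @export
bioclim_vars <- c("map", "wmp", "dmp", "ps", "wqp", "cqp")

# Circular 3-month window indicator: window j covers months j, j+1, j+2
# (wrapping), so W %*% x gives all 12 quarter sums of x.
quarter_window_matrix <- function() {
  W <- matrix(0, 12, 12)
  for (j in 1:12) W[(j + 0:2 - 1) %% 12 + 1, j] <- 1
  W
}

# Vectorised bioclim reduction: P, T are n x 12 matrices of monthly
# precipitation (mm/month) and temperature (degC); returns an n x 6 matrix.
# Quarters are the 12 circular consecutive 3-month windows; the warmest
# (coldest) quarter is the window with the highest (lowest) mean temperature,
# ties resolved toward the wetter (drier) window, then the earliest start.
bioclim_from_series <- function(P, T) {
  stopifnot(ncol(P) == 12, ncol(T) == 12, nrow(P) == nrow(T))
  n <- nrow(P)
  W <- quarter_window_matrix()
  map <- rowSums(P)
  wmp <- apply(P, 1, max)
  dmp <- apply(P, 1, min)
  mu <- map / 12
  popsd <- sqrt(rowMeans((P - mu)^2))
  ps <- ifelse(mu > 0, 100 * popsd / mu, 0)
  PW <- P %*% W            # quarter precipitation sums
  TW <- (T %*% W) / 3      # quarter mean temperatures
  wqp <- pick_quarter(TW, PW, warmest = TRUE)
  cqp <- pick_quarter(TW, PW, warmest = FALSE)
  out <- cbind(map, wmp, dmp, ps, wqp, cqp)
  colnames(out) <- bioclim_vars
  out
}

pick_quarter <- function(TW, PW, warmest) {
  eps <- 1e-9
  n <- nrow(TW)
  best_t <- TW[, 1]; best_p <- PW[, 1]
  for (j in 2:12) {
    tj <- TW[, j]; pj <- PW[, j]
    if (warmest) {
      upd <- (tj > best_t + eps) | (abs(tj - best_t) <= eps & pj > best_p + eps)
    } else {
      upd <- (tj < best_t - eps) | (abs(tj - best_t) <= eps & pj < best_p - eps)
    }
    best_t[upd] <- tj[upd]; best_p[upd] <- pj[upd]
  }
  best_p
}

#' Derive the six precipitation bioclim variables from a monthly series
#'
#' Reduces a 12-month precipitation and temperature series to the vector
#' (MAP, WMP, DMP, PS, WQP, CQP).  MAP is the annual sum, WMP/DMP the
#' wettest/driest month, PS the coefficient of variation of the monthly
#' series in percent (population standard deviation over the plain monthly
#' mean; 0 when the mean is 0).  Quarters are the 12 circular consecutive
#' 3-month windows; WQP (CQP) is the precipitation sum of the window with the
#' highest (lowest) mean temperature, temperature ties broken toward the
#' wetter (drier) window.
#'
#' @param monthly_precip numeric(12), mm/month, non-negative.
#' @param monthly_temp numeric(12), degrees Celsius.
#' @return Named numeric vector of length 6 (see [bioclim_vars]).
#' @examples
#' derive_bioclim(rep(100, 12), c(20,22,25,28,30,33,31,30,28,26,23,21))
#' @export
derive_bioclim <- function(monthly_precip, monthly_temp) {
  if (length(monthly_precip) != 12 || length(monthly_temp) != 12)
    stop("monthly series must have exactly 12 values")
  if (any(is.na(monthly_precip)) || any(monthly_precip < 0))
    stop("precipitation must be non-negative and non-missing")
  drop(bioclim_from_series(matrix(monthly_precip, 1), matrix(monthly_temp, 1)))
}

# Bioclim vectors for every cell of a grid (ocean cells NA): ncell x 6,
# lon-major linear cell indexing.  The per-cell reduction is shared with
# derive_bioclim so the two paths cannot drift apart.
bioclim_grid <- function(grid) {
  nlon <- length(grid$lon); nlat <- length(grid$lat)
  ncell <- nlon * nlat
  P <- matrix(grid$precip, ncell, 12)
  T <- matrix(grid$temp, ncell, 12)
  B <- bioclim_from_series(P, T)
  B[!as.vector(grid$mask), ] <- NA_real_
  B
}

#' Extract bioclim vectors at point locations
#'
#' For `method = "nearest"` each point takes the monthly series of its
#' containing (nearest-center) cell; if that cell is ocean, the nearest land
#' cell within `radius` cells is used instead and the point is flagged
#' `relocated`.  For `method = "bilinear"` the monthly series is interpolated
#' from the 4 surrounding cell centers (ocean corners dropped and weights
#' renormalised) before the bioclim reduction.  Points whose whole
#' neighbourhood is ocean get an `NA` row and are flagged `missing` rather
#' than silently dropped.  Nearest-cell ties go to the smaller lon index,
#' then the smaller lat index.
#'
#' @param grid a [monthly_grid()].
#' @param lon,lat point coordinates (degrees), inside the grid extent.
#' @param method `"nearest"` (default) or `"bilinear"`.
#' @param radius land-search radius for `"nearest"`, in cells.
#' @return Numeric matrix `n x 6` with an attribute `flags`: a data.frame
#'   with logical columns `relocated` and `missing`.
#' @export
extract_at_points <- function(grid, lon, lat,
                              method = c("nearest", "bilinear"),
                              radius = 2L) {
  method <- match.arg(method)
  stopifnot(length(lon) == length(lat))
  res <- grid_resolution(grid)
  half <- res / 2
  if (any(lon < min(grid$lon) - half[1] - 1e-9) ||
      any(lon > max(grid$lon) + half[1] + 1e-9) ||
      any(lat < min(grid$lat) - half[2] - 1e-9) ||
      any(lat > max(grid$lat) + half[2] + 1e-9))
    stop("point outside grid extent")
  n <- length(lon)
  out <- matrix(NA_real_, n, 6, dimnames = list(NULL, bioclim_vars))
  relocated <- logical(n); missing <- logical(n)
  if (method == "nearest") {
    ij <- nearest_cell_index(grid, lon, lat)
    for (k in seq_len(n)) {
      i <- ij[k, 1]; j <- ij[k, 2]
      if (!grid$mask[i, j]) {
        alt <- nearest_land_cell(grid, lon[k], lat[k], i, j, radius)
        if (is.null(alt)) { missing[k] <- TRUE; next }
        i <- alt[1]; j <- alt[2]; relocated[k] <- TRUE
      }
      out[k, ] <- bioclim_from_series(matrix(grid$precip[i, j, ], 1),
                                      matrix(grid$temp[i, j, ], 1))
    }
  } else {
    for (k in seq_len(n)) {
      s <- bilinear_series(grid, lon[k], lat[k])
      if (is.null(s)) { missing[k] <- TRUE; next }
      out[k, ] <- bioclim_from_series(matrix(s$precip, 1), matrix(s$temp, 1))
    }
  }
  attr(out, "flags") <- data.frame(relocated = relocated, missing = missing)
  out
}

nearest_land_cell <- function(grid, x, y, i0, j0, radius) {
  nlon <- length(grid$lon); nlat <- length(grid$lat)
  ii <- max(1L, i0 - radius):min(nlon, i0 + radius)
  jj <- max(1L, j0 - radius):min(nlat, j0 + radius)
  cand <- expand.grid(i = ii, j = jj)
  cand <- cand[grid$mask[as.matrix(cand)], , drop = FALSE]
  if (nrow(cand) == 0) return(NULL)
  d2 <- (grid$lon[cand$i] - x)^2 + (grid$lat[cand$j] - y)^2
  # ties: smaller lon index, then smaller lat index
  o <- order(d2, cand$i, cand$j)
  c(cand$i[o[1]], cand$j[o[1]])
}

# Bilinear interpolation of the 24 monthly fields at one point, dropping
# ocean corners and renormalising; NULL when all 4 corners are ocean.
bilinear_series <- function(grid, x, y) {
  w <- bilinear_weights(grid$lon, grid$lat, x, y)
  land <- grid$mask[w$idx]
  if (!any(land & w$w > 0) || sum(w$w[land]) <= 0) return(NULL)
  ww <- ifelse(land, w$w, 0)
  ww <- ww / sum(ww)
  pr <- numeric(12); te <- numeric(12)
  for (m in 1:12) {
    pm <- grid$precip[, , m][w$idx]
    tm <- grid$temp[, , m][w$idx]
    pr[m] <- sum(ww * pm); te[m] <- sum(ww * tm)
  }
  list(precip = pr, temp = te)
}

# Corner indices and weights of the bilinear stencil at (x, y); coordinates
# outside the cell-center span are clamped (constant extrapolation over the
# half-cell margin).
bilinear_weights <- function(lonc, latc, x, y) {
  fx <- (x - lonc[1]) / mean(diff(lonc))
  fy <- (y - latc[1]) / mean(diff(latc))
  i <- min(max(floor(fx) + 1L, 1L), length(lonc) - 1L)
  j <- min(max(floor(fy) + 1L, 1L), length(latc) - 1L)
  tx <- min(max(fx - (i - 1L), 0), 1)
  ty <- min(max(fy - (j - 1L), 0), 1)
  idx <- cbind(c(i, i + 1L, i, i + 1L), c(j, j, j + 1L, j + 1L))
  w <- c((1 - tx) * (1 - ty), tx * (1 - ty), (1 - tx) * ty, tx * ty)
  list(idx = idx, w = w)
}

#' Fit a Gaussian climatic envelope for one taxon
#'
#' The envelope is the per-variable sample mean and standard deviation
#' (n-1 denominator) of the bioclim vectors extracted at the taxon's modern
#' occurrences.  Standard deviations that are undefined (a single occurrence)
#' or fall below the floor are replaced by `sigma_floor` so the envelope
#' never degenerates to a delta function.
#'
#' @param taxon taxon identifier.
#' @param vectors numeric matrix `n x 6` of bioclim vectors (rows with any
#'   `NA` are dropped).
#' @param sigma_floor named numeric(6), per-variable lower bound for the sd;
#'   see [sigma_floor_default()].
#' @return An object of class `nlr_envelope`: list with `taxon`, `n`, `mu`,
#'   `sigma`.
#' @export
fit_envelope <- function(taxon, vectors, sigma_floor) {
  vectors <- as.matrix(vectors)
  if (ncol(vectors) != 6) stop("vectors must have 6 columns")
  keep <- stats::complete.cases(vectors)
  vectors <- vectors[keep, , drop = FALSE]
  n <- nrow(vectors)
  if (n == 0) stop("no usable bioclim vectors for taxon ", taxon)
  stopifnot(length(sigma_floor) == 6, all(sigma_floor > 0))
  mu <- colMeans(vectors)
  if (n == 1) {
    sigma <- as.numeric(sigma_floor)
    warning("single occurrence for taxon ", taxon,
            "; envelope sd set to the floor")
  } else {
    sigma <- pmax(apply(vectors, 2, stats::sd), as.numeric(sigma_floor))
  }
  names(mu) <- names(sigma) <- bioclim_vars
  structure(list(taxon = taxon, n = n, mu = mu, sigma = sigma),
            class = "nlr_envelope")
}

#' @export
print.nlr_envelope <- function(x, ...) {
  cat(sprintf("<nlr_envelope> %s (n = %d)\n", x$taxon, x$n))
  print(round(rbind(mu = x$mu, sigma = x$sigma), 2))
  invisible(x)
}

#' Default per-variable envelope sd floor
#'
#' 5% of each bioclim variable's standard deviation across all land cells of
#' the reference grid: scale-aware, and small enough not to inflate
#' well-sampled envelopes.
#'
#' @param grid reference [monthly_grid()].
#' @param fraction fraction of the land-cell sd to use.
#' @return Named numeric(6).
#' @export
sigma_floor_default <- function(grid, fraction = 0.05) {
  B <- bioclim_grid(grid)
  s <- apply(B, 2, stats::sd, na.rm = TRUE)
  pmax(fraction * s, 1e-6)
}

#' Write / read envelope tables
#'
#' One CSV row per taxon: `taxon, n`, then the six means (`mu_*`) and six
#' standard deviations (`sigma_*`).
#' @param envelopes list of `nlr_envelope`.
#' @param path file path.
#' @export
write_envelopes <- function(envelopes, path) {
  rows <- lapply(envelopes, function(e) {
    v <- c(list(taxon = e$taxon, n = e$n),
           as.list(stats::setNames(e$mu, paste0("mu_", bioclim_vars))),
           as.list(stats::setNames(e$sigma, paste0("sigma_", bioclim_vars))))
    as.data.frame(v, stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_envelopes
#' @export
read_envelopes <- function(path) {
  df <- utils::read.csv(path)
  lapply(seq_len(nrow(df)), function(k) {
    structure(list(taxon = df$taxon[k], n = df$n[k],
                   mu = stats::setNames(as.numeric(df[k, paste0("mu_", bioclim_vars)]),
                                        bioclim_vars),
                   sigma = stats::setNames(as.numeric(df[k, paste0("sigma_", bioclim_vars)]),
                                           bioclim_vars)),
              class = "nlr_envelope")
  })
}
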