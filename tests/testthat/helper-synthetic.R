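# Shared fixtures, built in code.

# Small all-land grid with hand-set fields: precip constant per month unless
# a function of (lon, lat, month) is given.
tiny_grid <- function(nlon = 8, nlat = 6, precip_fun = NULL,
                      temp_fun = NULL, mask = NULL) {
  lon <- seq(0.5, by = 1, length.out = nlon)
  lat <- seq(-2.5, by = 1, length.out = nlat)
  precip <- array(100, c(nlon, nlat, 12))
  temp <- array(0, c(nlon, nlat, 12))
  for (m in 1:12) {
    temp[, , m] <- 20 + 10 * cos(2 * pi * (m - 7) / 12)
    if (!is.null(precip_fun))
      precip[, , m] <- outer(lon, lat, precip_fun, month = m)
    if (!is.null(temp_fun))
      temp[, , m] <- outer(lon, lat, temp_fun, month = m)
  }
  if (is.null(mask)) mask <- matrix(TRUE, nlon, nlat)
  monthly_grid(lon, lat, precip, temp, mask)
}

# Moderate-size seeded synthetic climatology shared across tests.
small_synth <- function(seed = 11, noise_sd = 10) {
  generate_climate_grid(synthetic_config(lon_range = c(0, 30),
                                         lat_range = c(-20, 20),
                                         resolution = 1, noise_sd = noise_sd,
                                         seed = seed))
}

# Envelope with given mean/sd, bypassing occurrence fitting.
make_envelope <- function(taxon, mu, sigma) {
  names(mu) <- names(sigma) <- bioclim_vars
  structure(list(taxon = taxon, n = 10L, mu = mu, sigma = sigma),
            class = "nlr_envelope")
}

random_envelope <- function(taxon) {
  mu <- c(stats::runif(1, 500, 2500), stats::runif(1, 50, 400),
          stats::runif(1, 0, 50), stats::runif(1, 10, 150),
          stats::runif(1, 100, 900), stats::runif(1, 0, 500))
  sigma <- c(stats::runif(1, 50, 400), stats::runif(1, 10, 80),
             stats::runif(1, 2, 20), stats::runif(1, 5, 40),
             stats::runif(1, 20, 200), stats::runif(1, 10, 120))
  make_envelope(taxon, mu, sigma)
}

# Candidate set built directly from a value matrix.
make_candidates <- function(values) {
  structure(list(values = values, cells = seq_len(nrow(values)),
                 lon = rep(0, nrow(values)), lat = rep(0, nrow(values)),
                 n = nrow(values), seed = 0L),
            class = "candidate_set")
}

# Independent linear-space oracle for the assemblage likelihood: the direct
# product of 6 x n_taxa univariate normal densities via stats::dnorm.
brute_force_loglik <- function(envelopes, values) {
  apply(values, 1, function(x) {
    p <- 1
    for (e in envelopes)
      p <- p * prod(stats::dnorm(x, e$mu, e$sigma))
    log(p)
  })
}

# Small fast pipeline configuration for smoke/determinism tests.
small_run_config <- function(out_dir, seed = 1L) {
  cfg <- default_config(out_dir = out_dir, seed = seed)
  cfg$synthetic$resolution <- 2
  cfg$synthetic$n_taxa <- 3
  cfg$synthetic$n_occ_per_taxon <- 40
  cfg$nlr$n_candidates <- 500
  cfg$ensemble$resolutions <- c(4, 2, 8)
  cfg
}
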