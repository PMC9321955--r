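test_that("regridding: identity on the same grid, exact on linear fields", {
  g <- tiny_grid(precip_fun = function(lon, lat, month) 5 + lon - 2 * lat)
  f <- grid_field(g$lon, g$lat, g$precip[, , 1], units = "mm/month",
                  mask = g$mask)
  same <- regrid_bilinear(f, f)
  expect_equal(same$values, f$values, tolerance = 1e-12)

  tgt <- list(lon = seq(1.25, 7.25, by = 1.5), lat = seq(-2, 2, by = 1))
  out <- regrid_bilinear(f, tgt)
  expect_equal(out$values, outer(tgt$lon, tgt$lat,
                                 function(x, y) 5 + x - 2 * y),
               tolerance = 1e-12)

  expect_error(regrid_bilinear(f, list(lon = c(-50, 0), lat = c(0, 1))),
               "outside")
})

test_that("ensemble mean is the cell-wise unweighted mean, NA-aware", {
  g <- tiny_grid()
  mk <- function(v) grid_field(g$lon, g$lat,
                               matrix(v, length(g$lon), length(g$lat)))
  expect_equal(ensemble_mean(list(mk(100), mk(200)))$values, mk(150)$values)
  expect_equal(ensemble_mean(list(mk(7), mk(7), mk(7)))$values, mk(7)$values)

  a <- mk(1); b <- mk(2); c3 <- mk(6)
  a$values[2, 2] <- 1; b$values[2, 2] <- 2; c3$values[2, 2] <- 6
  expect_equal(ensemble_mean(list(a, b, c3))$values[2, 2], 3)

  # missing in one member only: mean over the remaining two
  b$values[1, 1] <- NA
  m <- ensemble_mean(list(a, b, c3))
  expect_equal(m$values[1, 1], (1 + 6) / 2)
  # missing in all members: stays missing
  a$values[3, 3] <- b$values[3, 3] <- c3$values[3, 3] <- NA
  expect_true(is.na(ensemble_mean(list(a, b, c3))$values[3, 3]))

  # permutation invariance and idempotence on identical inputs
  expect_equal(ensemble_mean(list(a, c3))$values,
               ensemble_mean(list(c3, a))$values)
  expect_error(ensemble_mean(list(mk(1), grid_field(g$lon + 5, g$lat,
                                                    a$values))), "mismatch")
})

test_that("seasonal means reduce the monthly stack as plain arithmetic", {
  p <- c(0, 0, 0, 0, 50, 150, 200, 150, 50, 0, 0, 0)
  g <- tiny_grid(precip_fun = function(lon, lat, month) 0 * lon + p[month])
  jja <- seasonal_mean(g, 6:8)
  expect_equal(jja$values[1, 1], (150 + 200 + 150) / 3, tolerance = 1e-12)

  july <- seasonal_mean(g, 7)
  expect_equal(july$values, g$precip[, , 7])

  cst <- tiny_grid()  # constant 100 mm/month
  expect_equal(seasonal_mean(cst, 6:8)$values[3, 3], 100)
  expect_equal(annual_map(cst)$values[3, 3], 1200)

  # 12 x mean over all months equals the annual sum exactly
  gs <- small_synth(seed = 6)
  expect_equal(12 * seasonal_mean(gs, 1:12)$values, annual_map(gs)$values,
               tolerance = 1e-12)

  expect_error(seasonal_mean(g, integer(0)), "months")
  expect_error(seasonal_mean(g, 13), "months")
})

test_that("regional means weight by cos(latitude) over box cells", {
  # closed-form two-row case: lat 0 (value 1) and 60 (value 3)
  f <- grid_field(c(10), c(0, 60), matrix(c(1, 3), 1, 2))
  m <- regional_mean(f, region_box(0, 20, -10, 70))
  expect_equal(m, (1 * 1 + 3 * 0.5) / 1.5, tolerance = 1e-12)

  # constants are invariant to weighting
  g <- tiny_grid()
  f2 <- grid_field(g$lon, g$lat, matrix(42, length(g$lon), length(g$lat)),
                   mask = g$mask)
  box <- region_box(1, 6, -2, 2)
  expect_equal(regional_mean(f2, box), 42)
  expect_equal(regional_mean(f2, box, weighted = FALSE), 42)

  # land-only over all-ocean cells errors
  f2$mask[] <- FALSE
  expect_error(regional_mean(f2, region_box(1, 6, -2, 2, land_only = TRUE)),
               "empty selection")
  expect_error(regional_mean(f2, region_box(100, 120, 0, 10)), "intersect")
})

test_that("zonal means average along longitude only", {
  g <- tiny_grid(precip_fun = function(lon, lat, month) 10 + 3 * lat)
  f <- grid_field(g$lon, g$lat, g$precip[, , 1], mask = g$mask)
  box <- region_box(0, 8, -3, 3)
  z <- zonal_mean(f, box)
  expect_equal(z$mean, 10 + 3 * z$lat, tolerance = 1e-12)

  # constant along longitude: zonal mean equals any single column
  expect_equal(z$mean, f$values[1, f$lat %in% z$lat])

  # masked half-row: mean over unmasked cells only (direct oracle)
  f3 <- grid_field(g$lon, g$lat, outer(g$lon, g$lat, function(x, y) x),
                   mask = g$mask)
  f3$mask[1:4, ] <- FALSE
  zb <- zonal_mean(f3, region_box(0, 8, -3, 3, land_only = TRUE))
  expect_equal(zb$mean[1], mean(g$lon[5:8]))
})

test_that("field RMSE and differences follow direct arithmetic", {
  f <- grid_field(c(0, 1), c(0, 1), matrix(c(1, 2, 3, 4), 2, 2))
  gfd <- grid_field(c(0, 1), c(0, 1), matrix(c(0, 2, 3, 8), 2, 2))
  expect_equal(field_rmse(f, f), 0)
  expect_equal(field_rmse(f, gfd), sqrt(17 / 4), tolerance = 1e-12)
  expect_equal(field_rmse(f, gfd), field_rmse(gfd, f))

  # constant offset k gives RMSE |k| under any weighting
  k <- -7.5
  off <- grid_field(f$lon, f$lat, f$values + k)
  expect_equal(field_rmse(f, off), abs(k), tolerance = 1e-12)
  expect_equal(field_rmse(f, off, weighted = TRUE), abs(k), tolerance = 1e-12)

  d <- field_difference(f, gfd)
  expect_equal(d$values, f$values - gfd$values)
  expect_equal(field_difference(f, f)$values, matrix(0, 2, 2))
  expect_equal(field_difference(gfd, f)$values, -d$values)
  expect_equal(d$values + gfd$values, f$values)
  expect_error(field_difference(f, grid_field(c(0, 2), c(0, 1), f$values)),
               "mismatch")
})

test_that("regrid-then-mean agrees with mean-then-regrid on smooth ensembles", {
  g <- generate_climate_grid(synthetic_config(lon_range = c(0, 40),
                                              lat_range = c(-20, 20),
                                              noise_sd = 0, seed = 2))
  ens <- generate_model_ensemble(g, 3, biases = c(-20, 0, 20),
                                 resolutions = rep(1, 3), noise_sd = 0)
  maps <- lapply(ens, annual_map)
  tgt <- list(lon = seq(2, 38, by = 4), lat = seq(-18, 18, by = 4))
  a <- regrid_bilinear(ensemble_mean(maps), tgt)
  b <- ensemble_mean(lapply(maps, regrid_bilinear, target = tgt))
  box <- region_box(1, 39, -19, 19)
  expect_lt(abs(regional_mean(a, box) - regional_mean(b, box)) /
              regional_mean(b, box), 0.02)
})

test_that("monthly grids round-trip through the text exchange format", {
  g <- small_synth(seed = 30)
  path <- withr::local_tempfile(fileext = ".csv")
  write_monthly_grid(g, path)
  back <- read_monthly_grid(path)
  expect_equal(back$lon, g$lon)
  expect_equal(back$precip, g$precip, tolerance = 1e-12)
  expect_equal(back$temp, g$temp, tolerance = 1e-12)
  expect_identical(back$mask, g$mask)
})
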