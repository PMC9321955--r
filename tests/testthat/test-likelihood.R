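test_that("candidate sampling is exhaustive, unique and seeded", {
  g <- small_synth(seed = 8)
  n_land <- sum(g$mask)

  expect_warning(cs <- sample_candidates(g, n_land + 1000, seed = 1),
                 "available")
  expect_equal(cs$n, n_land)
  expect_equal(length(unique(cs$cells)), n_land)

  cs_all <- sample_candidates(g, n_land, seed = 1)
  expect_setequal(cs_all$cells, which(g$mask))

  cs1 <- sample_candidates(g, 200, seed = 5)
  cs2 <- sample_candidates(g, 200, seed = 5)
  expect_identical(cs1$cells, cs2$cells)

  # domain restriction and the empty-domain error
  box <- region_box(10, 20, -5, 5)
  csd <- sample_candidates(g, 50, seed = 1, domain = box)
  expect_true(all(csd$lon >= 10 & csd$lon <= 20))
  expect_error(sample_candidates(g, 10, domain = region_box(28, 29.9, 18, 19.9)),
               "no land")
})

test_that("two-seed candidate overlap matches the hypergeometric expectation", {
  g <- small_synth(seed = 8)
  n_land <- sum(g$mask)
  n <- 600
  a <- sample_candidates(g, n, seed = 1)$cells
  b <- sample_candidates(g, n, seed = 2)$cells
  overlap <- length(intersect(a, b))
  p <- n / n_land
  expected <- n * p
  v <- n * p * (1 - p) * (n_land - n) / (n_land - 1)
  expect_lt(abs(overlap - expected), 3 * sqrt(v))
})

test_that("the per-taxon log-density matches its closed form and symmetries", {
  sigma <- c(200, 50, 5, 20, 100, 30)
  mu <- c(1500, 250, 10, 80, 600, 200)
  env <- make_envelope("t", mu, sigma)

  # at x = mu: -sum(log sigma) - 6 log sqrt(2 pi), ~ -27.34
  at_mu <- taxon_log_density(env, mu)
  expect_equal(at_mu, -sum(log(sigma)) - 3 * log(2 * pi), tolerance = 1e-12)
  expect_equal(at_mu, -27.34, tolerance = 1e-2)

  # even function around the mean
  delta <- c(100, 20, 3, 10, 50, 15)
  expect_equal(taxon_log_density(env, mu + delta),
               taxon_log_density(env, mu - delta), tolerance = 1e-12)

  # doubling every sd at the mean costs exactly 6 ln 2
  env2 <- make_envelope("t", mu, 2 * sigma)
  expect_equal(at_mu - taxon_log_density(env2, mu), 6 * log(2),
               tolerance = 1e-12)

  expect_error(taxon_log_density(make_envelope("t", mu, c(0, sigma[-1])), mu),
               "positive")
})

test_that("assemblage likelihood is the row-sum of per-taxon surfaces", {
  set.seed(31)
  envs <- lapply(1:3, function(i) random_envelope(paste0("t", i)))
  X <- do.call(rbind, lapply(1:20, function(i) {
    e <- envs[[sample(3, 1)]]
    e$mu + stats::rnorm(6) * e$sigma  # within a few sds: no linear underflow
  }))
  cs <- make_candidates(X)

  surf <- assemblage_log_likelihood(assemblage("s", envs), cs)
  expect_equal(surf$combined, rowSums(surf$per_taxon), tolerance = 1e-15)

  # single taxon: surface equals the taxon density row-wise
  s1 <- assemblage_log_likelihood(assemblage("s", envs[1]), cs)
  expect_equal(s1$combined, taxon_log_density(envs[[1]], X))

  # duplicated taxon: combined doubles, maximiser unchanged
  e2 <- envs[[1]]; e2$taxon <- "copy"
  s2 <- assemblage_log_likelihood(assemblage("s", list(envs[[1]], e2)), cs)
  expect_equal(s2$combined, 2 * s1$combined, tolerance = 1e-12)
  expect_equal(s2$max_index, s1$max_index)

  # independent brute-force oracle in linear space
  expect_equal(surf$combined, brute_force_loglik(envs, X), tolerance = 1e-9)
})

test_that("extreme z-scores stay finite in log space", {
  env <- make_envelope("t", rep(0, 6), rep(1, 6))
  lf <- taxon_log_density(env, rep(100, 6))  # |z| = 100 per variable
  expect_true(is.finite(lf))
  expect_equal(lf, -6 * (log(sqrt(2 * pi)) + 5000), tolerance = 1e-12)
})

test_that("reconstruction summary applies the relative-likelihood threshold", {
  vals <- cbind(map = c(1000, 1400, 1800), wmp = 1:3, dmp = 0, ps = 1,
                wqp = 1:3, cqp = 0)
  cs <- make_candidates(vals)
  surf <- structure(list(per_taxon = NULL,
                         combined = log(c(1, 0.2, 0.04)), max_index = 1L),
                    class = "likelihood_surface")
  res <- summarize_reconstruction(surf, cs, threshold = 0.05)
  expect_equal(unname(res$mle["map"]), 1000)
  expect_equal(unname(res$ranges[, "map"]), c(1000, 1400))

  # threshold 1: collapses onto the maximiser
  res1 <- summarize_reconstruction(surf, cs, threshold = 1)
  expect_equal(unname(res1$ranges[, "map"]), c(1000, 1000))

  # single candidate: low = high = mle everywhere
  css <- make_candidates(vals[2, , drop = FALSE])
  surfs <- structure(list(combined = 0, max_index = 1L),
                     class = "likelihood_surface")
  ress <- summarize_reconstruction(surfs, css)
  expect_equal(ress$ranges["low", ], ress$ranges["high", ])
  expect_equal(unname(ress$ranges["low", ]), unname(vals[2, ]))

  expect_error(summarize_reconstruction(surf, cs, threshold = 0), "0, 1")
})

test_that("a single sharp envelope recovers its source cell exactly", {
  g <- small_synth(seed = 21)
  B <- paleorain:::bioclim_grid(g)
  land <- which(g$mask)
  cell <- land[123]
  env <- make_envelope("only", B[cell, ], 0.02 * pmax(abs(B[cell, ]), 1))
  fit <- reconstruct_assemblage(assemblage("x", list(env)), g,
                                n_candidates = length(land), seed = 1)
  expect_equal(unname(fit$mle), unname(B[cell, ]))

  fit2 <- reconstruct_assemblage(assemblage("x", list(env)), g,
                                 n_candidates = length(land), seed = 1)
  expect_identical(fit, fit2)
})

test_that("nested thresholds nest and added taxa obey max sub-additivity", {
  set.seed(99)
  g <- small_synth(seed = 13)
  n_land <- sum(g$mask)
  cs <- sample_candidates(g, n_land, seed = 1)
  envs <- lapply(1:4, function(i) {
    cell <- sample(n_land, 1)
    make_envelope(paste0("t", i), cs$values[cell, ] * stats::runif(6, 0.9, 1.1),
                  0.3 * pmax(abs(cs$values[cell, ]), 1))
  })
  asm3 <- assemblage("s", envs[1:3])
  surf3 <- assemblage_log_likelihood(asm3, cs)
  r05 <- summarize_reconstruction(surf3, cs, 0.05)
  r01 <- summarize_reconstruction(surf3, cs, 0.01)
  expect_true(all(r01$ranges["low", ] <= r05$ranges["low", ] + 1e-12))
  expect_true(all(r01$ranges["high", ] >= r05$ranges["high", ] - 1e-12))
  # low <= mle <= high in every variable
  expect_true(all(r05$ranges["low", ] <= r05$mle & r05$mle <= r05$ranges["high", ]))

  surf4 <- assemblage_log_likelihood(assemblage("s", envs), cs)
  gain <- max(surf4$combined) - max(surf3$combined)
  expect_lte(gain, max(taxon_log_density(envs[[4]], cs$values)) + 1e-12)
})

test_that("model methods expose the fit: coef, confint, summary, plot", {
  g <- small_synth(seed = 21)
  B <- paleorain:::bioclim_grid(g)
  cell <- which(g$mask)[50]
  env <- make_envelope("t", B[cell, ], 0.2 * pmax(abs(B[cell, ]), 1))
  fit <- reconstruct_assemblage(assemblage("demo", list(env)), g,
                                n_candidates = 500, seed = 3)
  expect_equal(coef(fit), fit$mle)
  ci <- confint(fit)
  expect_equal(dim(ci), c(6, 2))
  expect_true(all(ci[, "low"] <= coef(fit) & coef(fit) <= ci[, "high"]))
  expect_output(print(fit), "MAP")
  expect_output(print(summary(fit)), "candidate climates")
  pdf(NULL)
  expect_silent(plot(fit))
  dev.off()
})
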