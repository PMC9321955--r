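#' Bundle fitted envelopes into an assemblage
#'
#' @param site site name.
#' @param envelopes list of [fit_envelope()] results with unique taxon ids.
#' @return An object of class `nlr_assemblage`.
#' @export
assemblage <- function(site, envelopes) {
  if (length(envelopes) < 1) stop("an assemblage needs at least one envelope")
  ids <- vapply(envelopes, function(e) as.character(e$taxon), character(1))
  if (anyDuplicated(ids)) stop("taxon ids must be unique within an assemblage")
  structure(list(site = site, envelopes = envelopes),
            class = "nlr_assemblage")
}

#' @export
print.nlr_assemblage <- function(x, ...) {
  cat(sprintf("<nlr_assemblage> %s: %d taxa (%s)\n", x$site,
              length(x$envelopes),
              paste(vapply(x$envelopes, `[[`, "", "taxon"), collapse = ", ")))
  invisible(x)
}

#' Sample candidate extant climate combinations
#'
#' Draws `n` distinct land cells uniformly without replacement (all land
#' cells, with a warning, when fewer than `n` exist) and reduces each to its
#' bioclim vector.  The candidate set is the search space of the likelihood
#' grid search; "uniqueness" is by source cell, so identical climate vectors
#' from distinct cells may co-occur.
#'
#' @param grid a [monthly_grid()].
#' @param n number of candidates requested.
#' @param seed integer RNG seed (sampling is deterministic given the seed).
#' @param domain optional [region_box()] restricting the cells considered.
#' @return An object of class `candidate_set`: list with `values` (`n x 6`
#'   matrix), `cells` (linear cell indices), `lon`, `lat`, `n`, `seed`.
#' @export
sample_candidates <- function(grid, n, seed = 1L, domain = NULL) {
  stopifnot(n >= 1)
  nlon <- length(grid$lon)
  land <- which(grid$mask)
  if (!is.null(domain)) {
    i <- (land - 1L) %% nlon + 1L
    j <- (land - 1L) %/% nlon + 1L
    land <- land[in_box(grid$lon[i], grid$lat[j], domain)]
  }
  if (length(land) == 0) stop("no land cells in the candidate domain")
  if (n >= length(land)) {
    if (n > length(land))
      warning(sprintf("only %d land cells available; using all of them",
                      length(land)))
    cells <- land
  } else {
    set.seed(seed)
    cells <- sample(land, n)
  }
  B <- bioclim_grid(grid)
  i <- (cells - 1L) %% nlon + 1L
  j <- (cells - 1L) %/% nlon + 1L
  structure(list(values = B[cells, , drop = FALSE], cells = cells,
                 lon = grid$lon[i], lat = grid$lat[j],
                 n = length(cells), seed = seed),
            class = "candidate_set")
}

#' Per-taxon Gaussian envelope log-density
#'
#' The log of the product of six independent univariate normal densities,
#' one per bioclim variable, evaluated at the candidate climate(s):
#' `sum_c [ -log(sigma_c * sqrt(2*pi)) - (x_c - mu_c)^2 / (2 sigma_c^2) ]`.
#' Working in natural-log space keeps products over many taxa finite for
#' |z-scores| far beyond anything linear-space arithmetic can represent.
#'
#' @param env an `nlr_envelope`.
#' @param x a bioclim vector (length 6) or an `n x 6` matrix of candidates.
#' @return Numeric log-density, one value per row of `x`.
#' @export
taxon_log_density <- function(env, x) {
  if (any(env$sigma <= 0)) stop("envelope sd must be positive")
  if (is.null(dim(x))) x <- matrix(x, 1)
  if (ncol(x) != 6) stop("candidate vectors must have 6 variables")
  z2 <- sweep(x, 2, env$mu)
  z2 <- sweep(z2, 2, env$sigma, "/")^2
  -sum(log(env$sigma)) - 6 * log(sqrt(2 * pi)) - rowSums(z2) / 2
}

#' Assemblage log-likelihood surface over a candidate set
#'
#' The combined likelihood of a candidate climate is the product over taxa
#' of the per-taxon envelope densities; here it is accumulated as the row
#' sum of the per-taxon log-densities, which is exact in log space.  The
#' maximiser is recorded with ties broken toward the lowest candidate index.
#'
#' @param assemblage an [assemblage()].
#' @param candidates a [sample_candidates()] result.
#' @return An object of class `likelihood_surface`: list with `per_taxon`
#'   (`n_candidates x n_taxa` matrix of log f_t), `combined` (log f(z)),
#'   `max_index`.
#' @export
assemblage_log_likelihood <- function(assemblage, candidates) {
  stopifnot(inherits(assemblage, "nlr_assemblage"),
            inherits(candidates, "candidate_set"))
  if (ncol(candidates$values) != 6)
    stop("candidate set and envelopes disagree on the variables")
  per_taxon <- vapply(assemblage$envelopes,
                      taxon_log_density, numeric(candidates$n),
                      x = candidates$values)
  per_taxon <- matrix(per_taxon, nrow = candidates$n)
  colnames(per_taxon) <- vapply(assemblage$envelopes, `[[`, "", "taxon")
  combined <- rowSums(per_taxon)
  structure(list(per_taxon = per_taxon, combined = combined,
                 max_index = which.max(combined)),
            class = "likelihood_surface")
}

#' Summarise a likelihood surface into a reconstruction
#'
#' The most representative climate is the candidate maximising the combined
#' likelihood.  The uncertainty range per variable is the min and max over
#' all candidates whose combined likelihood is at least `threshold` times
#' the maximum (the relative-likelihood region; with the default 0.05 this
#' is the 5%-of-maximum range).  The threshold is applied in log space.
#'
#' @param surface an [assemblage_log_likelihood()] result.
#' @param candidates the candidate set the surface was computed on.
#' @param threshold relative-likelihood cutoff in (0, 1].
#' @return An object of class `nlr_reconstruction`.
#' @export
summarize_reconstruction <- function(surface, candidates, threshold = 0.05) {
  stopifnot(inherits(surface, "likelihood_surface"))
  if (length(surface$combined) == 0) stop("empty likelihood surface")
  if (!(threshold > 0 && threshold <= 1)) stop("threshold must be in (0, 1]")
  logmax <- surface$combined[surface$max_index]
  keep <- surface$combined >= logmax + log(threshold)
  vals <- candidates$values[keep, , drop = FALSE]
  ranges <- rbind(low = apply(vals, 2, min), high = apply(vals, 2, max))
  colnames(ranges) <- bioclim_vars
  structure(list(mle = candidates$values[surface$max_index, ],
                 ranges = ranges,
                 log_max = logmax,
                 n_candidates = candidates$n,
                 n_qualifying = sum(keep),
                 threshold = threshold,
                 mle_lon = candidates$lon[surface$max_index],
                 mle_lat = candidates$lat[surface$max_index],
                 provenance = list(candidate_seed = candidates$seed)),
            class = "nlr_reconstruction")
}

#' Reconstruct paleoclimate from an assemblage of NLR envelopes
#'
#' The package's main fitting function.  Composes the candidate grid search:
#' `n_candidates` extant climate combinations are sampled from the land
#' cells of `grid`, the assemblage log-likelihood (the log of the product of
#' all taxa's six-variable Gaussian envelope densities) is evaluated at each,
#' and the maximum-likelihood combination plus the `threshold`-of-maximum
#' uncertainty range per variable is returned.
#'
#' @param assemblage an [assemblage()] of fitted envelopes.
#' @param grid a [monthly_grid()] supplying the extant climate combinations.
#' @param n_candidates number of candidate combinations (default 100,000).
#' @param seed integer seed for candidate sampling.
#' @param threshold relative-likelihood cutoff for the uncertainty range.
#' @param domain optional [region_box()] for the candidate domain.
#' @param keep_surface keep the per-candidate surface in the result (needed
#'   by [plot.nlr_reconstruction()]).
#' @return An object of class `nlr_reconstruction`, with methods `print`,
#'   `summary`, `coef` (the MLE bioclim vector), `confint` (the
#'   relative-likelihood range) and `plot`.
#' @examples
#' g <- generate_climate_grid(synthetic_config(seed = 7))
#' syn <- generate_assemblage(g, site = c(25, -15), n_taxa = 4,
#'                            n_occ_per_taxon = 60, seed = 7)
#' flo <- sigma_floor_default(g)
#' env <- lapply(split(syn$occurrences, syn$occurrences$taxon), function(d) {
#'   fit_envelope(d$taxon[1], extract_at_points(g, d$lon, d$lat), flo)
#' })
#' fit <- reconstruct_assemblage(assemblage("demo", env), g,
#'                               n_candidates = 2000, seed = 7)
#' coef(fit)["map"]
#' @export
reconstruct_assemblage <- function(assemblage, grid, n_candidates = 100000L,
                                   seed = 1L, threshold = 0.05,
                                   domain = NULL, keep_surface = TRUE) {
  candidates <- sample_candidates(grid, n_candidates, seed = seed,
                                  domain = domain)
  surface <- assemblage_log_likelihood(assemblage, candidates)
  res <- summarize_reconstruction(surface, candidates, threshold = threshold)
  res$site <- assemblage$site
  res$taxa <- vapply(assemblage$envelopes, `[[`, "", "taxon")
  res$provenance <- list(seed = seed, n_candidates = n_candidates,
                         threshold = threshold,
                         n_taxa = length(assemblage$envelopes),
                         envelope_n = vapply(assemblage$envelopes,
                                             `[[`, 0, "n"))
  if (keep_surface) {
    res$surface_map <- candidates$values[, "map"]
    res$surface_logf <- surface$combined
  }
  res
}

#' @export
print.nlr_reconstruction <- function(x, ...) {
  cat("Nearest-living-relative bioclimatic reconstruction\n")
  if (!is.null(x$site)) cat("Site:", x$site, "\n")
  cat(sprintf("Candidates: %d (%d within %.0f%% of the maximum likelihood)\n",
              x$n_candidates, x$n_qualifying, 100 * x$threshold))
  cat(sprintf("MAP: %.0f mm/yr  [%.0f, %.0f]\n",
              x$mle["map"], x$ranges["low", "map"], x$ranges["high", "map"]))
  invisible(x)
}

#' @export
summary.nlr_reconstruction <- function(object, ...) {
  tab <- rbind(mle = object$mle, object$ranges)
  structure(list(table = tab, site = object$site,
                 n_taxa = length(object$taxa),
                 n_candidates = object$n_candidates,
                 n_qualifying = object$n_qualifying,
                 threshold = object$threshold,
                 log_max = object$log_max),
            class = "summary.nlr_reconstruction")
}

#' @export
print.summary.nlr_reconstruction <- function(x, ...) {
  cat("NLR bioclimatic reconstruction",
      if (!is.null(x$site)) paste0("for ", x$site), "\n")
  cat(sprintf("%d taxa; %d candidate climates; max log f(z) = %.3f\n",
              x$n_taxa, x$n_candidates, x$log_max))
  cat(sprintf("Uncertainty: range of candidates with f(z) >= %.0f%% of max (%d qualify)\n",
              100 * x$threshold, x$n_qualifying))
  print(round(x$table, 2))
  invisible(x)
}

#' @export
coef.nlr_reconstruction <- function(object, ...) object$mle

#' Relative-likelihood uncertainty range of a reconstruction
#'
#' Returns the per-variable `[low, high]` range over candidates whose
#' combined likelihood is at least the reconstruction's threshold times the
#' maximum.  Note this is a relative-likelihood region, not a frequentist
#' confidence interval, although the 5% default is conventionally reported
#' as a 95% interval in the NLR literature.
#'
#' @param object an `nlr_reconstruction`.
#' @param parm variables to report (names or indices; default all six).
#' @param level unused; the range is fixed by the fitting threshold.
#' @param ... ignored.
#' @export
confint.nlr_reconstruction <- function(object, parm, level = 0.95, ...) {
  ci <- t(object$ranges)
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
plot.nlr_reconstruction <- function(x, ...) {
  if (is.null(x$surface_map))
    stop("refit with keep_surface = TRUE to plot the likelihood profile")
  rel <- exp(x$surface_logf - x$log_max)
  graphics::plot(x$surface_map, rel, pch = 16, cex = 0.4,
                 col = grDevices::grey(0.4, 0.5),
                 xlab = "candidate MAP (mm/yr)",
                 ylab = "relative likelihood f(z)/max f(z)", ...)
  graphics::abline(h = x$threshold, lty = 2)
  graphics::abline(v = x$mle["map"], col = 2)
  graphics::abline(v = x$ranges[, "map"], col = 2, lty = 3)
  invisible(x)
}
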