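#' Default pipeline configuration
#'
#' A single declarative configuration drives every stage; flags on the
#' command-line tool override these values.  All randomness flows from the
#' one top-level `seed` via named per-stage substreams, so each stage is
#' independently reproducible.
#'
#' @param out_dir output directory for all artifacts.
#' @param seed top-level integer seed.
#' @return Nested list of class `run_config` with sections `synthetic`
#'   (generator settings), `nlr` (candidate count, threshold, sigma-floor
#'   fraction, thinning cell/max, extraction method, optional candidate
#'   domain), `ensemble` (pseudo-model biases/resolutions/noise) and
#'   `compare` (season months, region boxes, RMSE weighting, comparand,
#'   search radius).
#' @export
default_config <- function(out_dir = "paleorain_run", seed = 1L) {
  structure(list(
    out_dir = out_dir,
    seed = as.integer(seed),
    synthetic = list(resolution = 1, base = 20, amplitude = 200,
                     noise_sd = 10, land_frac = 0.55,
                     site_lon = 25, site_lat = -15,
                     n_taxa = 10, n_occ_per_taxon = 100),
    nlr = list(n_candidates = 100000, threshold = 0.05,
               sigma_floor_fraction = 0.05,
               thin_cell = 1, thin_max = 1,
               extraction = "nearest"),
    ensemble = list(n_models = 3, biases = c(-30, 0, 60),
                    resolutions = c(2, 1, 4), noise_sd = 5),
    compare = list(season = c(6, 7, 8),
                   rmse_weighted = FALSE, comparand = "central",
                   search_radius = 2)
  ), class = "run_config")
}

#' Load a configuration from a YAML file
#'
#' @param path YAML file; keys override the defaults section-wise.
#' @param seed optional seed override.
#' @return A validated `run_config`.
#' @export
read_config <- function(path, seed = NULL) {
  user <- yaml::read_yaml(path)
  cfg <- default_config()
  for (k in names(user)) {
    if (is.list(user[[k]]) && is.list(cfg[[k]]))
      cfg[[k]][names(user[[k]])] <- user[[k]]
    else cfg[[k]] <- user[[k]]
  }
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  fail <- function(msg) stop(structure(class = c("paleorain_config_error",
                                                 "error", "condition"),
                                       list(message = msg, call = NULL)))
  if (is.null(cfg$nlr$n_candidates) || cfg$nlr$n_candidates < 1)
    fail("n_candidates must be at least 1")
  thr <- cfg$nlr$threshold
  if (is.null(thr) || !(thr > 0 && thr <= 1))
    fail("threshold must be in (0, 1]")
  if (cfg$synthetic$resolution <= 0) fail("resolution must be positive")
  invisible(cfg)
}

# Deterministic per-stage substream seed below 2^31, derived from the
# top-level seed and the stage name.
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647L)
}

artifact <- function(cfg, ...) file.path(cfg$out_dir, ...)

#' Run the reconstruction pipeline
#'
#' Orchestrates the stages behind one entry point.  `"simulate"` generates
#' the synthetic climatology, occurrence records (with truth record) and the
#' pseudo-model ensemble; `"prepare"` cleans and spatially thins the
#' occurrences; `"reconstruct"` fits envelopes and runs the NLR likelihood
#' grid search; `"compare"` regrids the ensemble to its coarsest member,
#' forms the multi-model mean MAP and compares it (and each member) against
#' the packaged site table; `"report"` writes a JSON manifest linking every
#' artifact to the configuration hash.  `"all"` runs the five in order.
#' Artifacts carry no timestamps, so identical config + seed gives
#' byte-identical tabular outputs.
#'
#' @param config a `run_config` (see [default_config()], [read_config()]) or
#'   a path to a YAML config file.
#' @param command one of `"simulate"`, `"prepare"`, `"reconstruct"`,
#'   `"compare"`, `"report"`, `"all"`.
#' @param seed optional seed override.
#' @return Invisibly, a named list of artifact paths written by the stage(s).
#' @export
run_pipeline <- function(config = default_config(),
                         command = c("all", "simulate", "prepare",
                                     "reconstruct", "compare", "report"),
                         seed = NULL) {
  command <- match.arg(command)
  if (is.character(config)) config <- read_config(config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  validate_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- if (command == "all")
    c("simulate", "prepare", "reconstruct", "compare", "report")
  else command
  arts <- list()
  for (st in stages) {
    arts <- c(arts, switch(st,
                           simulate = stage_simulate(config),
                           prepare = stage_prepare(config),
                           reconstruct = stage_reconstruct(config),
                           compare = stage_compare(config),
                           report = stage_report(config)))
  }
  invisible(arts)
}

stage_simulate <- function(cfg) {
  s <- cfg$synthetic
  sc <- synthetic_config(resolution = s$resolution, base = s$base,
                         amplitude = s$amplitude, noise_sd = s$noise_sd,
                         land_frac = s$land_frac,
                         seed = stage_seed(cfg$seed, "grid"))
  grid <- generate_climate_grid(sc)
  write_monthly_grid(grid, artifact(cfg, "climatology.csv"))
  syn <- generate_assemblage(grid, c(s$site_lon, s$site_lat),
                             n_taxa = s$n_taxa,
                             n_occ_per_taxon = s$n_occ_per_taxon,
                             seed = stage_seed(cfg$seed, "assemblage"))
  write_occurrences(syn$occurrences, artifact(cfg, "occurrences.csv"))
  jsonlite::write_json(lapply(syn$truth, unclass),
                       artifact(cfg, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  e <- cfg$ensemble
  ens <- generate_model_ensemble(grid, e$n_models, e$biases, e$resolutions,
                                 e$noise_sd,
                                 seed = stage_seed(cfg$seed, "ensemble"))
  for (k in seq_along(ens))
    write_monthly_grid(ens[[k]], artifact(cfg, sprintf("model_%02d.csv", k)))
  list(climatology = artifact(cfg, "climatology.csv"),
       occurrences = artifact(cfg, "occurrences.csv"),
       truth = artifact(cfg, "truth.json"))
}

stage_prepare <- function(cfg) {
  occ <- read_occurrences(artifact(cfg, "occurrences.csv"))
  occ <- filter_occurrences(occ, filter_rules())
  occ <- thin_occurrences(occ, cfg$nlr$thin_cell, cfg$nlr$thin_max,
                          seed = stage_seed(cfg$seed, "thin"))
  write_occurrences(occ, artifact(cfg, "occurrences_clean.csv"))
  utils::write.csv(provenance(occ), artifact(cfg, "provenance.csv"),
                   row.names = FALSE)
  list(clean = artifact(cfg, "occurrences_clean.csv"),
       provenance = artifact(cfg, "provenance.csv"))
}

stage_reconstruct <- function(cfg) {
  grid <- read_monthly_grid(artifact(cfg, "climatology.csv"))
  occ <- read_occurrences(artifact(cfg, "occurrences_clean.csv"))
  if (nrow(occ) == 0)
    stop(structure(class = c("paleorain_data_error", "error", "condition"),
                   list(message = "no occurrences after cleaning",
                        call = NULL)))
  floor6 <- sigma_floor_default(grid, cfg$nlr$sigma_floor_fraction)
  envs <- lapply(split(occ, occ$taxon), function(d) {
    v <- extract_at_points(grid, d$lon, d$lat, method = cfg$nlr$extraction)
    fit_envelope(d$taxon[1], v, floor6)
  })
  write_envelopes(envs, artifact(cfg, "envelopes.csv"))
  fit <- reconstruct_assemblage(assemblage("synthetic_site", envs), grid,
                                n_candidates = cfg$nlr$n_candidates,
                                seed = stage_seed(cfg$seed, "candidates"),
                                threshold = cfg$nlr$threshold,
                                keep_surface = FALSE)
  out <- list(site = fit$site, mle = as.list(fit$mle),
              low = as.list(fit$ranges["low", ]),
              high = as.list(fit$ranges["high", ]),
              log_max = fit$log_max, n_candidates = fit$n_candidates,
              n_qualifying = fit$n_qualifying, threshold = fit$threshold,
              provenance = fit$provenance)
  jsonlite::write_json(out, artifact(cfg, "reconstruction.json"),
                       auto_unbox = TRUE, digits = NA)
  row <- data.frame(site = fit$site, lat = cfg$synthetic$site_lat,
                    lon = cfg$synthetic$site_lon,
                    map_early_low = fit$ranges["low", "map"],
                    map_early_high = fit$ranges["high", "map"],
                    map_central = fit$mle[["map"]])
  utils::write.csv(row, artifact(cfg, "reconstruction.csv"),
                   row.names = FALSE)
  list(envelopes = artifact(cfg, "envelopes.csv"),
       reconstruction = artifact(cfg, "reconstruction.json"))
}

stage_compare <- function(cfg) {
  e <- cfg$ensemble
  files <- artifact(cfg, sprintf("model_%02d.csv", seq_len(e$n_models)))
  models <- lapply(files, read_monthly_grid)
  maps <- lapply(models, annual_map)
  # lowest common resolution: regrid every member to the coarsest grid
  coarsest <- which.max(vapply(maps, function(f) grid_resolution(f)[1],
                               numeric(1)))
  maps_c <- lapply(maps, regrid_bilinear, target = maps[[coarsest]])
  mme <- ensemble_mean(maps_c)
  sites <- average_colocated(load_site_fixture())
  rows <- list()
  for (k in seq_along(maps_c)) {
    sm <- sample_model_at_sites(maps_c[[k]], sites,
                                radius = cfg$compare$search_radius)
    ct <- rmse_vs_reconstructions(sm, sites,
                                  model_id = sprintf("model_%02d", k))
    rows[[k]] <- ct$table
  }
  sm <- sample_model_at_sites(mme, sites, radius = cfg$compare$search_radius)
  ct <- rmse_vs_reconstructions(sm, sites, model_id = "MME")
  rows[["mme"]] <- ct$table
  tab <- do.call(rbind, rows)
  utils::write.csv(tab, artifact(cfg, "comparison.csv"), row.names = FALSE)
  rmse <- stats::aggregate(error ~ model, tab,
                           function(e) sqrt(mean(e^2)))
  names(rmse)[2] <- "rmse_map"
  utils::write.csv(rmse, artifact(cfg, "rmse.csv"), row.names = FALSE)
  list(comparison = artifact(cfg, "comparison.csv"),
       rmse = artifact(cfg, "rmse.csv"))
}

stage_report <- function(cfg) {
  files <- list.files(cfg$out_dir, pattern = "\\.(csv|json)$",
                      full.names = TRUE)
  files <- files[basename(files) != "manifest.json"]
  cfg_path <- artifact(cfg, "config_used.yaml")
  yaml::write_yaml(unclass(cfg), cfg_path)
  manifest <- list(config = unclass(cfg),
                   config_md5 = unname(tools::md5sum(cfg_path)),
                   seed = cfg$seed,
                   artifacts = lapply(stats::setNames(files, basename(files)),
                                      function(f) list(
                                        md5 = unname(tools::md5sum(f)),
                                        bytes = file.size(f))))
  jsonlite::write_json(manifest, artifact(cfg, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  list(manifest = artifact(cfg, "manifest.json"))
}
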