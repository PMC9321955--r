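#' Filtering rules for occurrence records
#'
#' @param drop_flags character flags whose bearers are removed; records
#'   carrying any of them (in the semicolon-separated `flags` column) drop.
#' @param drop_duplicates remove exact duplicates, defined as identical
#'   (taxon, lon, lat) after rounding coordinates to 4 decimal places
#'   (GBIF-style precision noise).
#' @param coordinate_validity remove records with out-of-bounds coordinates.
#' @param domain optional [region_box()]; records outside it are removed.
#' @return A list of class `filter_rules`.  At least one rule must be active.
#' @export
filter_rules <- function(drop_flags = c("uncertain", "exotic", "superfluous"),
                         drop_duplicates = TRUE,
                         coordinate_validity = TRUE,
                         domain = NULL) {
  if (length(drop_flags) == 0 && !drop_duplicates && !coordinate_validity &&
      is.null(domain))
    stop("at least one filtering rule must be active")
  structure(list(drop_flags = drop_flags, drop_duplicates = drop_duplicates,
                 coordinate_validity = coordinate_validity, domain = domain),
            class = "filter_rules")
}

check_occurrences <- function(records) {
  need <- c("taxon", "lon", "lat")
  if (!all(need %in% names(records)))
    stop("occurrence table needs columns taxon, lon, lat")
  if (any(!nzchar(records$taxon))) stop("taxon ids must be non-empty")
  if (is.null(records$flags)) records$flags <- ""
  records$flags[is.na(records$flags)] <- ""
  records
}

coords_valid <- function(records) {
  !is.na(records$lon) & !is.na(records$lat) &
    records$lon >= -180 & records$lon <= 180 &
    records$lat >= -90 & records$lat <= 90
}

has_flag <- function(flags, drop) {
  vapply(strsplit(as.character(flags), ";", fixed = TRUE),
         function(f) any(trimws(f) %in% drop), logical(1))
}

#' Provenance log of an occurrence table
#'
#' Each cleaning step appends a row (step, rule, input, retained, removed);
#' counts are conserved: input = retained + removed for every step.
#' @param records an occurrence table.
#' @return data.frame of applied steps (zero rows if none).
#' @export
provenance <- function(records) {
  p <- attr(records, "provenance")
  if (is.null(p))
    p <- data.frame(step = character(), rule = character(),
                    input = integer(), retained = integer(),
                    removed = integer(), stringsAsFactors = FALSE)
  p
}

log_step <- function(records, step, rule, input, retained) {
  p <- rbind(provenance(records),
             data.frame(step = step, rule = rule, input = input,
                        retained = retained, removed = input - retained,
                        stringsAsFactors = FALSE))
  attr(records, "provenance") <- p
  message(sprintf("[occurrences] %s (%s): %d -> %d (-%d)",
                  step, rule, input, retained, input - retained))
  records
}

#' Filter occurrence records
#'
#' Applies the active rules in a fixed order (coordinate validity, flag
#' removal, domain, duplicate removal), preserving record order and
#' appending per-rule removal counts to the provenance log.  Records with
#' malformed coordinates violate the type invariant and raise an error when
#' the coordinate-validity rule is inactive (they cannot be silently kept).
#'
#' @param records data.frame with columns `taxon`, `lon`, `lat`, optional
#'   `flags` (semicolon-separated) and `source`.
#' @param rules a [filter_rules()].
#' @return The filtered data.frame, provenance attached (see [provenance()]).
#' @export
filter_occurrences <- function(records, rules = filter_rules()) {
  stopifnot(inherits(rules, "filter_rules"))
  records <- check_occurrences(records)
  ok <- coords_valid(records)
  if (rules$coordinate_validity) {
    n0 <- nrow(records)
    records <- records[ok, , drop = FALSE]
    records <- log_step(records, "filter", "coordinate_validity", n0,
                        nrow(records))
  } else if (!all(ok)) {
    stop("malformed coordinates present; enable the coordinate-validity ",
         "rule or repair the records")
  }
  if (length(rules$drop_flags) > 0) {
    n0 <- nrow(records)
    records <- records[!has_flag(records$flags, rules$drop_flags), ,
                       drop = FALSE]
    records <- log_step(records, "filter",
                        paste0("flags:", paste(rules$drop_flags,
                                               collapse = "+")),
                        n0, nrow(records))
  }
  if (!is.null(rules$domain)) {
    n0 <- nrow(records)
    records <- records[in_box(records$lon, records$lat, rules$domain), ,
                       drop = FALSE]
    records <- log_step(records, "filter", "domain", n0, nrow(records))
  }
  if (rules$drop_duplicates) {
    n0 <- nrow(records)
    key <- paste(records$taxon, round(records$lon, 4), round(records$lat, 4))
    records <- records[!duplicated(key), , drop = FALSE]
    records <- log_step(records, "filter", "duplicates", n0, nrow(records))
  }
  records
}

#' Spatially thin occurrence records
#'
#' Random resampling against regional overrepresentation: within each
#' `cell_size` x `cell_size` graticule cell (anchored at -180, -90, so bins
#' are fixed and order-independent) at most `max_per_cell` records per taxon
#' are retained, chosen uniformly at random under the seed.  Bins at or
#' under capacity are untouched and record order is preserved.
#'
#' @param records occurrence data.frame.
#' @param cell_size bin size in degrees (> 0).
#' @param max_per_cell retention cap per bin (>= 1).
#' @param seed integer seed; thinning is deterministic given the seed.
#' @return Thinned data.frame with provenance appended.
#' @export
thin_occurrences <- function(records, cell_size = 1, max_per_cell = 1,
                             seed = 1L) {
  if (cell_size <= 0) stop("cell_size must be positive")
  if (max_per_cell < 1) stop("max_per_cell must be at least 1")
  records <- check_occurrences(records)
  if (nrow(records) == 0)
    return(log_step(records, "thin", "resample", 0L, 0L))
  bin <- paste(records$taxon,
               floor((records$lon + 180) / cell_size),
               floor((records$lat + 90) / cell_size))
  set.seed(seed)
  keep <- logical(nrow(records))
  for (b in unique(bin)) {
    idx <- which(bin == b)
    if (length(idx) <= max_per_cell) keep[idx] <- TRUE
    else keep[sample(idx, max_per_cell)] <- TRUE
  }
  n0 <- nrow(records)
  out <- records[keep, , drop = FALSE]
  attr(out, "provenance") <- provenance(records)
  log_step(out, "thin",
           sprintf("cell=%g,max=%d,seed=%d", cell_size, max_per_cell,
                   as.integer(seed)),
           n0, nrow(out))
}

#' Read / write occurrence tables
#'
#' CSV with header `taxon, lon, lat, flags, source`.
#' @param records occurrence data.frame.
#' @param path file path.
#' @export
write_occurrences <- function(records, path) {
  cols <- intersect(c("taxon", "lon", "lat", "flags", "source"),
                    names(records))
  utils::write.csv(records[, cols, drop = FALSE], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_occurrences
#' @export
read_occurrences <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_occurrences(df)
}
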