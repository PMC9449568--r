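#' Labelled occurrence records
#'
#' An `occurrence_set` is a data frame of point records with columns `lon`,
#' `lat` (decimal degrees, WGS84), `label` (1 = presence, 0 =
#' pseudo-absence) and `source` (free text).
#'
#' @param lon,lat numeric coordinate vectors (degrees).
#' @param label integer vector of 0/1 labels; defaults to all presences.
#' @param source character vector of record provenance.
#' @return an object of class `occurrence_set` (also a data frame).
#' @export
occurrence_set <- function(lon, lat, label = rep(1L, length(lon)),
                           source = rep("unknown", length(lon))) {
  if (length(lat) != length(lon)) stop("lon and lat differ in length")
  if (!all(label %in% c(0L, 1L))) stop("labels must be 0 or 1")
  if (length(lon) && (any(lon < -180 | lon > 180) ||
                      any(lat < -90 | lat > 90))) {
    stop("coordinates out of range: lon in [-180, 180], lat in [-90, 90]")
  }
  structure(
    data.frame(lon = as.numeric(lon), lat = as.numeric(lat),
               label = as.integer(label), source = as.character(source),
               stringsAsFactors = FALSE),
    class = c("occurrence_set", "data.frame"))
}

#' Read occurrence records from a delimited text file
#'
#' Rows with unparsable or out-of-range coordinates are dropped; the number
#' dropped is reported in a message and attached as attribute `n_dropped`.
#' When `label_col` is absent or `NULL` every record is a presence.
#'
#' @param path path to a comma-delimited file with a header row.
#' @param lon_col,lat_col names of the coordinate columns.
#' @param label_col optional name of a 0/1 label column.
#' @param source_col optional name of a provenance column.
#' @return an `occurrence_set` with attribute `n_dropped`.
#' @export
read_occurrences <- function(path, lon_col = "lon", lat_col = "lat",
                             label_col = NULL, source_col = NULL) {
  if (!file.exists(path)) stop("occurrence file does not exist: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c(lon_col, lat_col, label_col, source_col)) {
    if (!col %in% names(raw)) {
      stop("column '", col, "' not found in ", path)
    }
  }
  lon <- suppressWarnings(as.numeric(raw[[lon_col]]))
  lat <- suppressWarnings(as.numeric(raw[[lat_col]]))
  keep <- is.finite(lon) & is.finite(lat) &
    lon >= -180 & lon <= 180 & lat >= -90 & lat <= 90
  n_dropped <- sum(!keep)
  if (n_dropped) {
    message(n_dropped, " record(s) with unparsable or out-of-range ",
            "coordinates dropped")
  }
  label <- if (is.null(label_col)) rep(1L, sum(keep)) else
    as.integer(raw[[label_col]][keep])
  src <- if (is.null(source_col)) rep("file", sum(keep)) else
    as.character(raw[[source_col]][keep])
  out <- occurrence_set(lon[keep], lat[keep], label, src)
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Write occurrence records to CSV
#'
#' @param points an `occurrence_set`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_occurrences <- function(points, path) {
  utils::write.csv(as.data.frame(points), path, row.names = FALSE)
  invisible(path)
}

#' Great-circle distance in kilometres
#'
#' Haversine distance on a sphere of mean Earth radius 6371.0088 km.
#' Vectorised over both arguments.
#'
#' @param lon1,lat1,lon2,lat2 coordinates in decimal degrees.
#' @return distances in kilometres.
#' @export
haversine_km <- function(lon1, lat1, lon2, lat2) {
  r <- 6371.0088
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad / 2
  dlon <- (lon2 - lon1) * to_rad / 2
  a <- sin(dlat)^2 +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon)^2
  2 * r * asin(pmin(1, sqrt(a)))
}

#' Thin presences to one record per analysis-grid cell
#'
#' Keeps the first record (by input order) in each grid cell, and removes
#' records that fall outside the grid extent or on cells where any predictor
#' layer is nodata. Removal counts are attached as attribute `removed`
#' (named: `duplicate`, `nodata_or_outside`).
#'
#' @param points an `occurrence_set`.
#' @param stack the `predictor_stack` defining the analysis grid.
#' @return the thinned `occurrence_set`.
#' @export
deduplicate <- function(points, stack) {
  if (!inherits(stack, "predictor_stack") || length(stack) < 1L) {
    stop("`stack` must be a non-empty predictor_stack")
  }
  grid <- stack$layers[[1]]
  valid <- stack_valid_mask(stack)
  idx <- cell_index(grid, points$lon, points$lat)
  on_grid <- !is.na(idx[, 1])
  on_data <- on_grid
  on_data[on_grid] <- valid[cbind(idx[on_grid, 1], idx[on_grid, 2])]
  cell_id <- ifelse(on_data, (idx[, 1] - 1L) * ncol(grid$values) + idx[, 2],
                    NA_integer_)
  first <- !duplicated(cell_id) & on_data
  out <- points[first, , drop = FALSE]
  class(out) <- c("occurrence_set", "data.frame")
  attr(out, "removed") <- c(
    duplicate = sum(on_data & !first),
    nodata_or_outside = sum(!on_data))
  out
}

#' Pseudo-absence sampling configuration
#'
#' @param n_pseudo_absence number of background points to draw.
#' @param min_distance_km minimum great-circle distance from any presence.
#' @param seed integer seed making the draw reproducible.
#' @param max_attempts cap on candidate cells examined before giving up.
#' @return an object of class `sampling_config`.
#' @export
sampling_config <- function(n_pseudo_absence = 2000, min_distance_km = 5,
                            seed = 1L, max_attempts = 10 * n_pseudo_absence) {
  stopifnot(n_pseudo_absence >= 0, min_distance_km >= 0,
            max_attempts >= n_pseudo_absence)
  structure(list(n_pseudo_absence = as.integer(n_pseudo_absence),
                 min_distance_km = min_distance_km,
                 seed = as.integer(seed),
                 max_attempts = as.integer(max_attempts)),
            class = "sampling_config")
}

#' Generate spatially constrained pseudo-absence points
#'
#' Draws background points uniformly over the valid (non-nodata) cells of
#' the analysis grid, placing each point at a cell centre, sampling cells
#' without replacement, and rejecting any cell whose centre lies closer than
#' `min_distance_km` (great-circle) to any presence. The draw is fully
#' reproducible from `cfg$seed`.
#'
#' @param presences an `occurrence_set` of presence records (label 1).
#' @param stack the `predictor_stack` defining the analysis grid.
#' @param cfg a [sampling_config()].
#' @return an `occurrence_set` of `cfg$n_pseudo_absence` label-0 records.
#' @export
generate_pseudo_absences <- function(presences, stack, cfg) {
  if (!inherits(cfg, "sampling_config")) stop("`cfg` must be a sampling_config")
  if (nrow(presences) == 0L) stop("`presences` must be non-empty")
  grid <- stack$layers[[1]]
  valid <- stack_valid_mask(stack)
  cand <- which(valid)  # column-major linear indices of valid cells
  if (!length(cand)) stop("stack has no valid cells")
  nr <- nrow(grid$values)
  rows <- ((cand - 1L) %% nr) + 1L
  cols <- ((cand - 1L) %/% nr) + 1L
  lon <- grid$xmin + (cols - 0.5) * grid$dx
  lat <- grid$ymax - (rows - 0.5) * abs(grid$dy)

  order <- with_seed(cfg$seed, sample.int(length(cand)))
  n_want <- cfg$n_pseudo_absence
  kept <- integer(0)
  attempts <- 0L
  for (i in order) {
    if (length(kept) >= n_want || attempts >= cfg$max_attempts) break
    attempts <- attempts + 1L
    d <- haversine_km(lon[i], lat[i], presences$lon, presences$lat)
    if (all(d >= cfg$min_distance_km)) kept <- c(kept, i)
  }
  if (length(kept) < n_want) {
    stop("could only place ", length(kept), " of ", n_want,
         " pseudo-absences within ", attempts,
         " attempts; extent too small or exclusion buffer too large")
  }
  occurrence_set(lon[kept], lat[kept], rep(0L, n_want),
                 rep("pseudo-absence", n_want))
}
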