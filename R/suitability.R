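#' Four-class suitability scheme
#'
#' The conventional suitability bins: not suitable (0-0.25), low
#' (0.25-0.5), moderate (0.5-0.75), high (0.75-1). Bins are half-open
#' `[lower, upper)` with the top bin closed at 1, so a value on a shared
#' edge always belongs to the upper bin; this convention is stamped into
#' every derived report.
#'
#' @param labels class labels, ordered from least to most suitable.
#' @param breaks numeric vector of bin edges covering `[0, 1]`, length
#'   `length(labels) + 1`.
#' @return an object of class `suitability_scheme`.
#' @export
suitability_scheme <- function(labels = c("not", "low", "moderate", "high"),
                               breaks = c(0, 0.25, 0.5, 0.75, 1)) {
  if (length(breaks) != length(labels) + 1L) {
    stop("`breaks` must have one more element than `labels`")
  }
  if (breaks[1] != 0 || breaks[length(breaks)] != 1 ||
      any(diff(breaks) <= 0)) {
    stop("breaks must increase strictly from 0 to 1")
  }
  structure(list(labels = labels, breaks = breaks,
                 convention = "[lower, upper); top bin closed at 1"),
            class = "suitability_scheme")
}

#' Classify a suitability raster into discrete classes
#'
#' Values marginally outside `[0, 1]` (within `tol`) are clamped with a
#' warning; larger excursions are an error. Nodata propagates.
#'
#' @param map a `raster_grid` of suitability values in `[0, 1]`.
#' @param scheme a [suitability_scheme()].
#' @param tol clamping tolerance for values marginally outside `[0, 1]`.
#' @return a `raster_grid` of integer class codes (1 = first label), with
#'   the scheme attached as attribute `scheme`.
#' @export
classify_suitability <- function(map, scheme = suitability_scheme(),
                                 tol = 1e-8) {
  v <- map$values
  bad <- !is.na(v) & (v < -tol | v > 1 + tol)
  if (any(bad)) stop("suitability values outside [0, 1] beyond tolerance")
  if (any(!is.na(v) & (v < 0 | v > 1))) {
    warning("suitability values marginally outside [0, 1] clamped")
    v[] <- pmin(1, pmax(0, v))
  }
  # [lower, upper) bins, top bin closed: shared edges go to the upper bin
  code <- matrix(findInterval(v, scheme$breaks, rightmost.closed = TRUE),
                 nrow(v), ncol(v))
  code[is.na(v)] <- NA_integer_
  out <- raster_grid(code, map$xmin, map$ymax, map$dx, map$dy, map$crs)
  attr(out, "scheme") <- scheme
  out
}

#' Per-class area percentages
#'
#' Shares of the valid (non-nodata) area per suitability class. By default
#' every cell counts equally; `latitude_weighted = TRUE` weights each cell
#' by the cosine of its centre latitude, approximating true area on a
#' geographic grid.
#'
#' @param classified a class-coded `raster_grid` from
#'   [classify_suitability()].
#' @param scenario_tag character tag, e.g. `"current"` or `"2050 RCP4.5"`.
#' @param scheme the `suitability_scheme` (defaults to the one attached to
#'   `classified`).
#' @param latitude_weighted weight cells by `cos(latitude)`.
#' @return an `area_summary`: data frame with one row per class and columns
#'   `class`, `percent`; percentages sum to 100.
#' @export
area_summary <- function(classified, scenario_tag = "current",
                         scheme = attr(classified, "scheme"),
                         latitude_weighted = FALSE) {
  if (is.null(scheme)) scheme <- suitability_scheme()
  v <- classified$values
  if (all(is.na(v))) stop("raster has no valid cells")
  w <- matrix(1, nrow(v), ncol(v))
  if (latitude_weighted) {
    lat <- cell_center_lat(classified, seq_len(nrow(v)))
    w <- matrix(cos(lat * pi / 180), nrow(v), ncol(v))
  }
  w[is.na(v)] <- 0
  total <- sum(w)
  pct <- vapply(seq_along(scheme$labels), function(k) {
    100 * sum(w[!is.na(v) & v == k]) / total
  }, numeric(1))
  structure(data.frame(class = scheme$labels, percent = pct,
                       stringsAsFactors = FALSE),
            scenario_tag = scenario_tag,
            latitude_weighted = latitude_weighted,
            convention = scheme$convention,
            class = c("area_summary", "data.frame"))
}

#' Total suitable area percentage
#'
#' Sum of every class at or above `floor_class` (low + moderate + high by
#' default); the complement of the "not suitable" share.
#'
#' @param summary an `area_summary`.
#' @param floor_class first class counted as suitable.
#' @return percentage of valid area that is suitable.
#' @export
total_suitable <- function(summary, floor_class = "low") {
  k <- match(floor_class, summary$class)
  if (is.na(k)) stop("class '", floor_class, "' not in summary")
  sum(summary$percent[seq(k, nrow(summary))])
}

#' Habitat change rate between two scenarios
#'
#' `AC = (Af - Ac) / Ac * 100`: the percentage change of a future area
#' share `Af` relative to the current share `Ac`. Positive values indicate
#' expansion, negative contraction.
#'
#' @param Ac current area percentage; must be positive.
#' @param Af future area percentage.
#' @return change rate in percent.
#' @export
change_rate <- function(Ac, Af) {
  if (any(Ac <= 0)) stop("change rate undefined for a zero current area")
  (Af - Ac) / Ac * 100
}

#' Four-category habitat change map
#'
#' Binarises both class maps (suitable = class at or above
#' `suitable_floor`) and overlays them: cells unsuitable in both are
#' `stable_unsuitable`; newly suitable cells are `gain`; suitable in both
#' are `stable_suitable`; cells losing suitability are `loss`. The nodata
#' mask is the union of the inputs'.
#'
#' @param current,future class-coded `raster_grid`s on the same grid.
#' @param suitable_floor label of the lowest class counted as suitable.
#' @param scheme the `suitability_scheme` of the class codes.
#' @return a `change_map`: `raster_grid` of codes 1-4 with attributes
#'   `categories` and `binarization_rule`, plus a `counts` attribute with
#'   the per-category cell counts.
#' @export
change_map <- function(current, future, suitable_floor = "low",
                       scheme = attr(current, "scheme")) {
  if (is.null(scheme)) scheme <- suitability_scheme()
  if (!grids_aligned(current, future)) {
    stop("current and future rasters are not co-registered")
  }
  floor_code <- match(suitable_floor, scheme$labels)
  if (is.na(floor_code)) stop("unknown class '", suitable_floor, "'")
  cur <- current$values >= floor_code
  fut <- future$values >= floor_code
  code <- matrix(NA_integer_, nrow(cur), ncol(cur))
  code[!cur & !fut] <- 1L  # stable_unsuitable
  code[!cur & fut]  <- 2L  # gain
  code[cur & fut]   <- 3L  # stable_suitable
  code[cur & !fut]  <- 4L  # loss
  categories <- c("stable_unsuitable", "gain", "stable_suitable", "loss")
  counts <- vapply(1:4, function(k) sum(code == k, na.rm = TRUE), integer(1))
  out <- raster_grid(code, current$xmin, current$ymax, current$dx,
                     current$dy, current$crs)
  attr(out, "categories") <- categories
  attr(out, "counts") <- stats::setNames(counts, categories)
  attr(out, "binarization_rule") <- paste0(
    "suitable iff class >= '", suitable_floor, "'")
  class(out) <- c("change_map", class(out))
  out
}

#' Scenario report: class percentages and per-class change rates
#'
#' Assembles the two standard report tables of a scenario analysis: the
#' per-scenario class-percentage grid and the per-class change-rate grid
#' (each future scenario against current, change rate computed per class
#' from the class percentages).
#'
#' @param current an `area_summary` for the baseline.
#' @param futures named list of `area_summary` objects, one per scenario
#'   (names like `"2050 RCP4.5"`).
#' @return list with data frames `suitability` (rows = scenarios, columns =
#'   classes) and `change_rate` (rows = future scenarios, columns = classes,
#'   `NA` where the current share is zero).
#' @export
scenario_report <- function(current, futures) {
  if (!length(futures)) stop("no future scenarios supplied")
  classes <- current$class
  for (f in futures) {
    if (!identical(f$class, classes)) {
      stop("scenario summaries use inconsistent classification schemes")
    }
  }
  suit <- do.call(rbind, c(list(current = current$percent),
                           lapply(futures, `[[`, "percent")))
  colnames(suit) <- classes
  suit <- data.frame(scenario = c("current", names(futures)), suit,
                     check.names = FALSE, row.names = NULL)
  ac <- do.call(rbind, lapply(futures, function(f) {
    vapply(seq_along(classes), function(k) {
      if (current$percent[k] <= 0) return(NA_real_)
      change_rate(current$percent[k], f$percent[k])
    }, numeric(1))
  }))
  colnames(ac) <- classes
  ac <- data.frame(scenario = names(futures), ac,
                   check.names = FALSE, row.names = NULL)
  list(suitability = suit, change_rate = ac)
}
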