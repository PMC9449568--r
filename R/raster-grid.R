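#' Georeferenced raster grid
#'
#' A `raster_grid` is a single north-up layer of cell values on a regular
#' geographic (lon/lat, WGS84) grid. It is the atom all map algebra in the
#' package operates on. Cells with no data are stored as `NA`.
#'
#' The georeference follows the usual north-up convention: `xmin` is the west
#' edge, `ymax` the north edge, `dx > 0` the cell width and `dy < 0` the row
#' step, all in decimal degrees. Row 1 is the northernmost row.
#'
#' @param values numeric matrix of cell values; `NA` marks nodata.
#' @param xmin west edge of the grid (degrees).
#' @param ymax north edge of the grid (degrees).
#' @param dx cell width in degrees; must be positive.
#' @param dy row step in degrees; must be negative (north-up).
#' @param crs coordinate reference tag; only geographic WGS84 is supported.
#' @return an object of class `raster_grid`.
#' @export
raster_grid <- function(values, xmin, ymax, dx, dy = -dx, crs = "EPSG:4326") {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!is.finite(dx) || dx <= 0) stop("cell width `dx` must be positive")
  if (!is.finite(dy) || dy >= 0) {
    stop("row step `dy` must be negative (north-up convention)")
  }
  if (any(is.infinite(values))) stop("raster values must be finite or NA")
  structure(
    list(values = values, xmin = xmin, ymax = ymax, dx = dx, dy = dy,
         crs = crs),
    class = "raster_grid"
  )
}

#' @export
print.raster_grid <- function(x, ...) {
  cat(sprintf(
    "<raster_grid> %d x %d cells, origin (%.6g, %.6g), cell %.6g deg, %s\n",
    nrow(x$values), ncol(x$values), x$xmin, x$ymax, x$dx, x$crs))
  cat(sprintf("  valid cells: %d / %d\n",
              sum(!is.na(x$values)), length(x$values)))
  invisible(x)
}

#' @export
dim.raster_grid <- function(x) dim(x$values)

grid_xmax <- function(g) g$xmin + ncol(g$values) * g$dx
grid_ymin <- function(g) g$ymax + nrow(g$values) * g$dy

#' Test whether two grids share shape, georeference and CRS
#'
#' @param a,b `raster_grid` objects.
#' @param tol tolerance on georeference components.
#' @return logical scalar.
#' @export
grids_aligned <- function(a, b, tol = 1e-9) {
  identical(dim(a$values), dim(b$values)) &&
    abs(a$xmin - b$xmin) < tol && abs(a$ymax - b$ymax) < tol &&
    abs(a$dx - b$dx) < tol && abs(a$dy - b$dy) < tol &&
    identical(a$crs, b$crs)
}

#' Locate the cell containing a lon/lat point
#'
#' Cell membership uses half-open intervals `[west, east)` in longitude and
#' `(south, north]` in latitude so that points on shared cell edges are
#' assigned unambiguously. Points outside the grid extent map to `NA`.
#'
#' @param grid a `raster_grid`.
#' @param lon,lat numeric vectors of coordinates (degrees).
#' @return a two-column integer matrix of (row, col), `NA` outside the extent.
#' @export
cell_index <- function(grid, lon, lat) {
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  col <- floor((lon - grid$xmin) / grid$dx) + 1L
  # (south, north] in latitude: a point on a shared edge belongs to the
  # cell whose north edge it is
  row <- floor((grid$ymax - lat) / abs(grid$dy)) + 1L
  bad <- !is.finite(lon) | !is.finite(lat) |
    col < 1L | col > nc | row < 1L | row > nr
  row[bad] <- NA_integer_; col[bad] <- NA_integer_
  cbind(row = as.integer(row), col = as.integer(col))
}

#' Coordinates of cell centres
#'
#' @param grid a `raster_grid`.
#' @param rows,cols integer vectors of cell indices (recycled together).
#' @return a two-column matrix of (lon, lat) cell-centre coordinates.
#' @export
cell_center <- function(grid, rows, cols) {
  cbind(lon = grid$xmin + (cols - 0.5) * grid$dx,
        lat = grid$ymax - (rows - 0.5) * abs(grid$dy))
}

cell_center_lon <- function(grid, col) grid$xmin + (col - 0.5) * grid$dx
cell_center_lat <- function(grid, row) grid$ymax - (row - 0.5) * abs(grid$dy)

#' Read a raster from an ESRI ASCII grid file
#'
#' Reads a single-band georeferenced raster in the plain-text ESRI ASCII grid
#' (`.asc`) format. Cells equal to the declared nodata sentinel become `NA`.
#'
#' @param path path to an existing `.asc` file.
#' @return a `raster_grid`.
#' @export
read_raster <- function(path) {
  if (!file.exists(path)) stop("raster file does not exist: ", path)
  lines <- readLines(path, n = 6L)
  hdr <- list()
  n_hdr <- 0L
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "[[:space:]]+")[[1]]
    key <- tolower(parts[1])
    if (key %in% c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
                   "nodata_value")) {
      hdr[[key]] <- as.numeric(parts[2])
      n_hdr <- n_hdr + 1L
    } else break
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  miss <- setdiff(need, names(hdr))
  if (length(miss)) {
    stop("raster file ", path, " lacks georeference header field(s): ",
         paste(miss, collapse = ", "))
  }
  nc <- as.integer(hdr$ncols); nr <- as.integer(hdr$nrows)
  vals <- scan(path, what = double(), skip = n_hdr, quiet = TRUE)
  if (length(vals) != nr * nc) {
    stop("raster file ", path, " holds ", length(vals),
         " values; header promises ", nr * nc)
  }
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA_real_
  raster_grid(m,
              xmin = hdr$xllcorner,
              ymax = hdr$yllcorner + nr * hdr$cellsize,
              dx = hdr$cellsize, dy = -hdr$cellsize)
}

#' Write a raster to an ESRI ASCII grid file
#'
#' Writes the grid with its full georeference and a `-9999` nodata sentinel.
#' The format carries one `cellsize`, so cells must be square
#' (`dx == |dy|`). Values round-trip through [read_raster()] at the written
#' precision (15 significant digits).
#'
#' @param grid a `raster_grid` with square cells.
#' @param path output file path; the parent directory must exist.
#' @param nodata sentinel written at `NA` cells.
#' @return `path`, invisibly.
#' @export
write_raster <- function(grid, path, nodata = -9999) {
  if (!inherits(grid, "raster_grid")) stop("`grid` must be a raster_grid")
  if (abs(grid$dx - abs(grid$dy)) > 1e-12) {
    stop("ASCII grid format requires square cells (dx == |dy|)")
  }
  if (!dir.exists(dirname(path))) {
    stop("parent directory does not exist: ", dirname(path))
  }
  m <- grid$values
  if (any(m == nodata, na.rm = TRUE)) {
    stop("grid contains the nodata sentinel ", nodata, " as a real value")
  }
  m[is.na(m)] <- nodata
  hdr <- c(
    sprintf("ncols %d", ncol(m)),
    sprintf("nrows %d", nrow(m)),
    sprintf("xllcorner %.15g", grid$xmin),
    sprintf("yllcorner %.15g", grid_ymin(grid)),
    sprintf("cellsize %.15g", grid$dx),
    sprintf("NODATA_value %.15g", nodata))
  body <- apply(m, 1L, function(r) paste(sprintf("%.15g", r), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Combine co-registered layers into a predictor stack
#'
#' A `predictor_stack` is a named, ordered set of co-registered
#' [raster_grid()] layers (the environmental variables). No resampling is
#' performed: layers that do not share shape, georeference and CRS are a hard
#' error, never silently aligned.
#'
#' @param layers list of `raster_grid` objects.
#' @param names character vector of unique layer names.
#' @param provenance optional character vector describing each layer.
#' @return an object of class `predictor_stack`.
#' @export
align_stack <- function(layers, names, provenance = names) {
  if (length(layers) < 1L) stop("a predictor stack needs at least one layer")
  if (length(names) != length(layers)) {
    stop("`names` must match `layers` in length")
  }
  if (anyDuplicated(names)) {
    stop("duplicate layer name(s): ",
         paste(unique(names[duplicated(names)]), collapse = ", "))
  }
  ok <- vapply(layers, inherits, logical(1), "raster_grid")
  if (!all(ok)) stop("all layers must be raster_grid objects")
  ref <- layers[[1]]
  mis <- names[!vapply(layers, grids_aligned, logical(1), b = ref)]
  if (length(mis)) {
    stop("layers not co-registered with '", names[1], "': ",
         paste(mis, collapse = ", "))
  }
  names(layers) <- names
  structure(list(layers = layers,
                 provenance = stats::setNames(provenance, names)),
            class = "predictor_stack")
}

#' @export
print.predictor_stack <- function(x, ...) {
  g <- x$layers[[1]]
  cat(sprintf("<predictor_stack> %d layer(s), %d x %d cells\n",
              length(x$layers), nrow(g$values), ncol(g$values)))
  cat("  layers:", paste(names(x$layers), collapse = ", "), "\n")
  invisible(x)
}

#' @export
length.predictor_stack <- function(x) length(x$layers)

#' Layer names of a predictor stack
#' @param stack a `predictor_stack`.
#' @return character vector of layer names.
#' @export
stack_names <- function(stack) names(stack$layers)

# union-of-masks validity matrix: TRUE where every layer has data
stack_valid_mask <- function(stack) {
  valid <- !is.na(stack$layers[[1]]$values)
  for (g in stack$layers[-1]) valid <- valid & !is.na(g$values)
  valid
}
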