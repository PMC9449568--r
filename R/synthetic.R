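#' Configuration of a synthetic climate world
#'
#' Describes the simulated landscape every pipeline stage can be exercised
#' on: a regular lon/lat grid carrying spatially autocorrelated,
#' standardised climate-like fields — `n_signal_layers` that drive the
#' virtual species, `n_decoy_layers` of irrelevant variation, and
#' `n_collinear_copies` near-duplicates of signal layers that a collinearity
#' screen must catch. The default grid is 100 x 100 cells of 5 arc-minutes
#' (1/12 degree), the native resolution of widely used bioclimatic data.
#'
#' @param n_rows,n_cols grid dimensions in cells.
#' @param xmin,ymax west and north edges (degrees).
#' @param cellsize square cell size (degrees).
#' @param n_signal_layers layers the virtual species responds to.
#' @param n_decoy_layers autocorrelated layers with no effect on the species.
#' @param n_collinear_copies near-duplicates of signal layers (target
#'   correlation with the parent around 0.98).
#' @param autocorr_length Gaussian smoothing length in cells (0 = white
#'   noise).
#' @param seed integer seed; the whole world is reproducible from it.
#' @return an object of class `world_config`.
#' @export
world_config <- function(n_rows = 100L, n_cols = 100L,
                         xmin = 25, ymax = 15, cellsize = 1 / 12,
                         n_signal_layers = 2L, n_decoy_layers = 4L,
                         n_collinear_copies = 1L,
                         autocorr_length = 8, seed = 1L) {
  stopifnot(n_rows >= 2L, n_cols >= 2L, n_signal_layers >= 1L,
            n_decoy_layers >= 0L, n_collinear_copies >= 0L,
            autocorr_length >= 0)
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 xmin = xmin, ymax = ymax, cellsize = cellsize,
                 n_signal_layers = as.integer(n_signal_layers),
                 n_decoy_layers = as.integer(n_decoy_layers),
                 n_collinear_copies = as.integer(n_collinear_copies),
                 autocorr_length = autocorr_length,
                 seed = as.integer(seed)),
            class = "world_config")
}

# Gaussian smoothing with reflecting edges via an explicit row-normalised
# banded operator: smoothed = S_r %*% m %*% t(S_c).
smooth_operator <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  d <- outer(seq_len(n), seq_len(n), `-`)
  s <- exp(-d^2 / (2 * sigma^2))
  s / rowSums(s)
}

smooth_field <- function(m, sigma) {
  if (sigma <= 0) return(m)
  sr <- smooth_operator(nrow(m), sigma)
  sc <- smooth_operator(ncol(m), sigma)
  sr %*% m %*% t(sc)
}

standardize_field <- function(m) {
  mu <- mean(m, na.rm = TRUE)
  sd_ <- stats::sd(as.vector(m), na.rm = TRUE)
  if (sd_ == 0) m - mu else (m - mu) / sd_
}

#' Simulate an autocorrelated climate-like predictor stack
#'
#' Each layer is seeded white noise smoothed to the configured
#' autocorrelation length and standardised to mean 0 / sd 1 over the grid.
#' Signal layers are named `sig1..sigK`, decoys `decoy1..decoyM`, and each
#' collinear copy `sigJ_copy` is its parent plus a small independent noise
#' admixture (pairwise correlation with the parent around 0.98). Identical
#' seeds give bit-identical stacks.
#'
#' @param cfg a [world_config()].
#' @return a `predictor_stack`; layer roles are attached as attribute
#'   `roles` (`signal`, `decoy`, `collinear`).
#' @export
make_climate_stack <- function(cfg) {
  n_base <- cfg$n_signal_layers + cfg$n_decoy_layers
  names_sig <- paste0("sig", seq_len(cfg$n_signal_layers))
  names_dec <- if (cfg$n_decoy_layers) paste0("decoy",
                                              seq_len(cfg$n_decoy_layers))
  seeds <- derive_seeds(cfg$seed, n_base + cfg$n_collinear_copies, salt = 3L)
  base_field <- function(s) {
    noise <- with_seed(s, matrix(stats::rnorm(cfg$n_rows * cfg$n_cols),
                                 cfg$n_rows, cfg$n_cols))
    standardize_field(smooth_field(noise, cfg$autocorr_length))
  }
  fields <- lapply(seeds[seq_len(n_base)], base_field)
  names(fields) <- c(names_sig, names_dec)
  roles <- stats::setNames(
    rep(c("signal", "decoy"), c(cfg$n_signal_layers, cfg$n_decoy_layers)),
    names(fields))
  if (cfg$n_collinear_copies > 0L) {
    for (i in seq_len(cfg$n_collinear_copies)) {
      parent <- names_sig[((i - 1L) %% cfg$n_signal_layers) + 1L]
      contam <- base_field(seeds[n_base + i])
      copy <- standardize_field(fields[[parent]] + 0.2 * contam)
      nm <- paste0(parent, "_copy")
      fields[[nm]] <- copy
      roles[nm] <- "collinear"
    }
  }
  grids <- lapply(fields, function(m) {
    raster_grid(m, cfg$xmin, cfg$ymax, cfg$cellsize)
  })
  stack <- align_stack(grids, names(fields))
  attr(stack, "roles") <- roles
  stack
}

#' A virtual species with a known suitability function
#'
#' True suitability is `plogis(beta0 + sum_j betas[j] * x_j + sum_j
#' quadratic[j] * x_j^2)` over named stack layers — a logistic niche the
#' fitted models must recover. The defaults give a species responding to
#' the two signal layers of the default world with moderate prevalence.
#'
#' The default coefficients define a species occupying roughly 15 percent
#' of the landscape (a low-prevalence niche, the regime habitat-suitability
#' studies typically operate in), with a curved response to `sig1` and a
#' monotone response to `sig2`.
#'
#' @param beta0 intercept on the logit scale.
#' @param betas named vector of linear coefficients (names = layer names).
#' @param quadratic optional named vector of curvature terms.
#' @return an object of class `virtual_species`.
#' @export
virtual_species <- function(beta0 = -5,
                            betas = c(sig1 = 5, sig2 = -4),
                            quadratic = c(sig1 = -1)) {
  structure(list(beta0 = beta0, betas = betas,
                 quadratic = quadratic, link = "logistic"),
            class = "virtual_species")
}

#' True suitability surface of a virtual species
#'
#' @param species a [virtual_species()].
#' @param stack a `predictor_stack` containing every layer the species
#'   responds to.
#' @return a `raster_grid` of true suitabilities in `(0, 1)`; nodata cells
#'   propagate from the used layers.
#' @export
true_suitability <- function(species, stack) {
  need <- union(names(species$betas), names(species$quadratic))
  missing <- setdiff(need, stack_names(stack))
  if (length(missing)) {
    stop("stack lacks layer(s) used by the species: ",
         paste(missing, collapse = ", "))
  }
  g <- stack$layers[[1]]
  eta <- matrix(species$beta0, nrow(g$values), ncol(g$values))
  for (nm in names(species$betas)) {
    eta <- eta + species$betas[[nm]] * stack$layers[[nm]]$values
  }
  for (nm in names(species$quadratic)) {
    eta <- eta + species$quadratic[[nm]] * stack$layers[[nm]]$values^2
  }
  raster_grid(stats::plogis(eta), g$xmin, g$ymax, g$dx, g$dy, g$crs)
}

#' Sample presence points from a true suitability surface
#'
#' Draws `n` distinct cells without replacement with probability
#' proportional to true suitability (a species recorded at most once per
#' cell, mirroring the one-per-cell thinning applied to real records), and
#' places each presence at the cell centre.
#'
#' @param truth a `raster_grid` of suitabilities.
#' @param n number of presence points.
#' @param seed integer seed.
#' @return an `occurrence_set` of `n` presence records.
#' @export
sample_presences <- function(truth, n, seed = 1L) {
  valid <- which(!is.na(truth$values))
  if (n > length(valid)) {
    stop("cannot draw ", n, " presences from ", length(valid), " valid cells")
  }
  w <- truth$values[valid]
  picked <- with_seed(seed, sample(valid, n, prob = w))
  nr <- nrow(truth$values)
  rows <- ((picked - 1L) %% nr) + 1L
  cols <- ((picked - 1L) %/% nr) + 1L
  occurrence_set(cell_center_lon(truth, cols), cell_center_lat(truth, rows),
                 rep(1L, n), rep("virtual-species", n))
}

#' An additive climate-change scenario
#'
#' @param deltas named vector of additive shifts (layer units) applied to
#'   existing layers.
#' @param tag scenario tag, e.g. `"2050 RCP4.5"`.
#' @return an object of class `scenario_shift`.
#' @export
scenario_shift <- function(deltas, tag = "future") {
  structure(list(deltas = deltas, tag = tag), class = "scenario_shift")
}

#' Apply an additive scenario shift to a predictor stack
#'
#' Named layers receive their delta; untouched layers are shared unchanged
#' and nodata masks are preserved.
#'
#' @param stack a `predictor_stack`.
#' @param shift a [scenario_shift()].
#' @return the shifted `predictor_stack`.
#' @export
apply_shift <- function(stack, shift) {
  unknown <- setdiff(names(shift$deltas), stack_names(stack))
  if (length(unknown)) {
    stop("shift names layer(s) absent from the stack: ",
         paste(unknown, collapse = ", "))
  }
  layers <- stack$layers
  for (nm in names(shift$deltas)) {
    g <- layers[[nm]]
    layers[[nm]] <- raster_grid(g$values + shift$deltas[[nm]],
                                g$xmin, g$ymax, g$dx, g$dy, g$crs)
  }
  out <- align_stack(layers, names(layers), stack$provenance)
  attr(out, "roles") <- attr(stack, "roles")
  attr(out, "scenario_tag") <- shift$tag
  out
}
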