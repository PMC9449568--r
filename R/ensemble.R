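#' Build a skill-weighted ensemble from fitted base learners
#'
#' Member weights are proportional to the member's evaluation metric above a
#' no-skill floor: `w_i = max(metric_i - floor, 0)`, normalised to sum to 1.
#' The floor is 0.5 for AUC (a random ranker) and 0 for TSS; `"uniform"`
#' ignores the metric. If every member sits at or below the floor the
#' ensemble falls back to uniform weights with a warning.
#'
#' @param members list of `fitted_model` objects sharing feature names.
#' @param evaluations data frame with one row per member (matched by
#'   position) carrying `auc` and `tss` columns, e.g. a subset of
#'   [performance_table()] output.
#' @param metric weighting metric: `"AUC"`, `"TSS"` or `"uniform"`.
#' @return an object of class `ensemble_model`.
#' @export
build_ensemble <- function(members, evaluations, metric = c("AUC", "TSS",
                                                            "uniform")) {
  metric <- match.arg(metric)
  if (metric != "uniform" && nrow(evaluations) != length(members)) {
    stop("need exactly one evaluation row per member")
  }
  feats <- lapply(members, `[[`, "feature_names")
  if (length(unique(feats)) != 1L) {
    stop("ensemble members disagree on feature names")
  }
  raw <- switch(metric,
    AUC = pmax(evaluations$auc - 0.5, 0),
    TSS = pmax(evaluations$tss, 0),
    uniform = rep(1, length(members)))
  if (sum(raw) <= 0) {
    warning("no member exceeds the no-skill floor; using uniform weights")
    raw <- rep(1, length(members))
  }
  structure(list(members = members,
                 evaluations = if (metric == "uniform") NULL else evaluations,
                 weights = raw / sum(raw),
                 weighting_metric = metric,
                 feature_names = feats[[1]]),
            class = "ensemble_model")
}

#' @export
print.ensemble_model <- function(x, ...) {
  ids <- vapply(x$members, function(m) m$spec$algorithm_id, character(1))
  cat(sprintf("<ensemble_model> %d members, %s-weighted\n",
              length(ids), x$weighting_metric))
  for (i in seq_along(ids)) {
    cat(sprintf("  %-5s weight %.3f\n", ids[i], x$weights[i]))
  }
  invisible(x)
}

#' Ensemble prediction on feature rows
#'
#' Weighted average of member probabilities; by convexity the output lies
#' within the per-row envelope of member predictions.
#'
#' @param model an `ensemble_model`.
#' @param table data frame or matrix of feature rows matching the members'
#'   feature names in order.
#' @return numeric vector of probabilities.
#' @export
ensemble_predict_points <- function(model, table) {
  preds <- vapply(model$members, predict_proba, numeric(nrow(table)),
                  table = table)
  if (is.null(dim(preds))) preds <- matrix(preds, nrow = 1)
  drop(preds %*% model$weights)
}

#' Ensemble suitability raster
#'
#' Scores every valid cell of the stack (valid = data present in every
#' required layer) and returns a suitability grid in `[0, 1]` with the union
#' of the input nodata masks. Prediction is block-wise over cells to bound
#' memory; results do not depend on the block size.
#'
#' @param model an `ensemble_model`.
#' @param stack a `predictor_stack` whose layers include every feature.
#' @param block_size number of cells scored per block.
#' @return a `raster_grid` of suitability values.
#' @export
ensemble_predict_raster <- function(model, stack, block_size = 50000L) {
  missing <- setdiff(model$feature_names, stack_names(stack))
  if (length(missing)) {
    stop("stack lacks required layer(s): ", paste(missing, collapse = ", "))
  }
  grid <- stack$layers[[1]]
  layers <- stack$layers[model$feature_names]
  valid <- !is.na(layers[[1]]$values)
  for (g in layers[-1]) valid <- valid & !is.na(g$values)
  cells <- which(valid)
  out <- matrix(NA_real_, nrow(grid$values), ncol(grid$values))
  if (length(cells)) {
    xfull <- vapply(layers, function(g) g$values[cells],
                    numeric(length(cells)))
    if (is.null(dim(xfull))) {
      xfull <- matrix(xfull, ncol = length(layers),
                      dimnames = list(NULL, names(layers)))
    }
    for (start in seq(1L, length(cells), by = block_size)) {
      idx <- start:min(start + block_size - 1L, length(cells))
      out[cells[idx]] <- ensemble_predict_points(
        model, xfull[idx, , drop = FALSE])
    }
  }
  raster_grid(out, grid$xmin, grid$ymax, grid$dx, grid$dy, grid$crs)
}

#' Permutation variable importance on the ensemble (correlation metric)
#'
#' For each predictor the importance is `100 * mean over repeats of
#' (1 - r)`, where `r` is the Pearson correlation between ensemble
#' predictions on the intact table and on a copy with that column permuted.
#' A predictor the ensemble never uses scores 0; scores are floored at 0 and
#' are not constrained to sum to 100 (each is a standalone contribution).
#'
#' @param model an `ensemble_model`.
#' @param table a `feature_table` (the `label` column, if present, is
#'   ignored).
#' @param repeats independent permutations averaged per variable.
#' @param seed integer seed for the permutations.
#' @return an `importance_table` data frame with columns `variable`,
#'   `contribution` (percent), sorted by decreasing contribution.
#' @export
variable_importance <- function(model, table, repeats = 5L, seed = 1L) {
  x <- table[, model$feature_names, drop = FALSE]
  if (nrow(x) < 3L) stop("need at least 3 rows for permutation importance")
  base_pred <- ensemble_predict_points(model, x)
  base_sd <- stats::sd(base_pred)
  seeds <- derive_seeds(seed, repeats, salt = 23L)
  contrib <- vapply(model$feature_names, function(v) {
    vals <- vapply(seq_len(repeats), function(r) {
      xp <- x
      xp[[v]] <- with_seed(seeds[r] + match(v, model$feature_names),
                           sample(xp[[v]]))
      perm_pred <- ensemble_predict_points(model, xp)
      if (base_sd == 0 || stats::sd(perm_pred) == 0) {
        if (base_sd == 0) warning("ensemble predictions are constant; ",
                                  "importance undefined, reported as 0")
        return(0)
      }
      1 - stats::cor(base_pred, perm_pred)
    }, numeric(1))
    mean(vals)
  }, numeric(1))
  out <- data.frame(variable = model$feature_names,
                    contribution = pmax(0, 100 * contrib),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$contribution), ]
  rownames(out) <- NULL
  attr(out, "method_tag") <- sprintf(
    "permutation 1 - Pearson r on ensemble output, %d repeat(s)", repeats)
  class(out) <- c("importance_table", "data.frame")
  out
}
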