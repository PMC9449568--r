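#' Extract predictor values at occurrence points
#'
#' Reads, for every point, the value of every stack layer in the cell
#' containing the point. Points outside the grid extent or on a nodata cell
#' are an error (clean them upstream with [deduplicate()]).
#'
#' @param stack a `predictor_stack`.
#' @param points an `occurrence_set`.
#' @return a `feature_table`: data frame of predictor columns, plus the 0/1
#'   labels as attribute `label` and a `label` column.
#' @export
extract_features <- function(stack, points) {
  grid <- stack$layers[[1]]
  idx <- cell_index(grid, points$lon, points$lat)
  outside <- which(is.na(idx[, 1]))
  if (length(outside)) {
    stop("point(s) outside the stack extent at row(s): ",
         paste(utils::head(outside, 10), collapse = ", "))
  }
  flat <- cbind(idx[, 1], idx[, 2])
  vals <- vapply(stack$layers, function(g) g$values[flat],
                 numeric(nrow(points)))
  if (nrow(points) == 1L) vals <- matrix(vals, nrow = 1,
                                         dimnames = list(NULL, stack_names(stack)))
  on_nodata <- which(rowSums(is.na(vals)) > 0)
  if (length(on_nodata)) {
    stop("point(s) on nodata cell(s) at row(s): ",
         paste(utils::head(on_nodata, 10), collapse = ", "))
  }
  out <- as.data.frame(vals)
  out$label <- points$label
  class(out) <- c("feature_table", "data.frame")
  out
}

feature_columns <- function(table) {
  setdiff(names(table), "label")
}

feature_matrix <- function(table) {
  as.matrix(table[, feature_columns(table), drop = FALSE])
}

#' Greedy pairwise Pearson correlation screen
#'
#' While any pair of predictors has `|r|` above `threshold`, drops one member
#' of the worst-offending pair: the one with the larger mean absolute
#' correlation against all remaining predictors (ties broken towards the
#' later column). Zero-variance columns have undefined correlations; they are
#' treated as uncorrelated, retained, and listed in the report.
#'
#' @param table a `feature_table` (or plain data frame of predictors).
#' @param threshold correlation magnitude above which a pair is collinear.
#' @return a `screen_report` fragment: list with `retained`,
#'   `dropped_by_correlation` (data frame of name/partner/r) and
#'   `zero_variance`.
#' @export
pearson_screen <- function(table, threshold = 0.7) {
  x <- feature_matrix(table)
  if (nrow(x) < 3L) stop("need at least 3 rows to estimate correlations")
  keep <- colnames(x)
  const <- keep[apply(x, 2, stats::sd) == 0]
  dropped <- data.frame(name = character(), partner = character(),
                        r = numeric(), stringsAsFactors = FALSE)
  repeat {
    live <- setdiff(keep, const)
    if (length(live) < 2L) break
    cm <- suppressWarnings(stats::cor(x[, live, drop = FALSE]))
    cm[!is.finite(cm)] <- 0
    diag(cm) <- 0
    worst <- max(abs(cm))
    if (worst <= threshold) break
    pair <- which(abs(cm) == worst, arr.ind = TRUE)[1, ]
    cand <- live[pair]
    # drop the member more entangled with everything else; tie -> later column
    mean_abs <- colMeans(abs(cm))[cand]
    victim <- if (mean_abs[1] > mean_abs[2]) cand[1]
              else if (mean_abs[2] > mean_abs[1]) cand[2]
              else cand[which.max(match(cand, live))]
    partner <- setdiff(cand, victim)
    dropped <- rbind(dropped, data.frame(
      name = victim, partner = partner, r = cm[cand[1], cand[2]],
      stringsAsFactors = FALSE))
    keep <- setdiff(keep, victim)
  }
  list(retained = keep, dropped_by_correlation = dropped,
       zero_variance = const, threshold = threshold)
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R2_j)`, where `R2_j` is the coefficient of
#' determination from regressing predictor `j` (with intercept) on all other
#' predictors. Perfectly collinear columns are reported at a finite cap
#' (`1e12`) and flagged via attribute `capped`.
#'
#' @param x numeric matrix or data frame of predictor columns.
#' @return named numeric vector of VIFs (all `>= 1`).
#' @export
vif <- function(x) {
  x <- as.matrix(x)
  p <- ncol(x)
  if (p < 2L) {
    out <- stats::setNames(rep(1, p), colnames(x))
    attr(out, "capped") <- character(0)
    return(out)
  }
  if (nrow(x) < p + 1L) stop("need at least p + 1 rows for p predictors")
  out <- numeric(p)
  capped <- character(0)
  for (j in seq_len(p)) {
    y <- x[, j]
    design <- cbind(1, x[, -j, drop = FALSE])
    fit <- stats::lm.fit(design, y)
    rss <- sum(fit$residuals^2)
    tss <- sum((y - mean(y))^2)
    r2 <- if (tss == 0) 1 else 1 - rss / tss
    if (r2 >= 1 - 1e-12) {
      out[j] <- 1e12
      capped <- c(capped, colnames(x)[j])
    } else {
      out[j] <- max(1, 1 / (1 - r2))
    }
  }
  names(out) <- colnames(x)
  attr(out, "capped") <- capped
  out
}

#' Stepwise VIF elimination
#'
#' Iteratively removes the predictor with the largest VIF while that VIF
#' exceeds `vif_threshold` (ties broken towards the later column). On return
#' every retained predictor has VIF at or below the threshold.
#'
#' @param table a `feature_table` or data frame of predictors.
#' @param vif_threshold VIF above which a predictor is eliminated.
#' @return a `screen_report`: list with `retained`, `dropped_by_vif`
#'   (data frame of name / vif_at_removal, in removal order) and
#'   `vif_threshold`.
#' @export
vifstep <- function(table, vif_threshold = 10) {
  x <- feature_matrix(if (is.data.frame(table)) table else as.data.frame(table))
  keep <- colnames(x)
  dropped <- data.frame(name = character(), vif_at_removal = numeric(),
                        stringsAsFactors = FALSE)
  while (length(keep) >= 2L) {
    v <- vif(x[, keep, drop = FALSE])
    worst <- max(v)
    if (worst <= vif_threshold) break
    # ties -> later column order
    victim <- keep[max(which(v == worst))]
    dropped <- rbind(dropped, data.frame(
      name = victim, vif_at_removal = worst, stringsAsFactors = FALSE))
    keep <- setdiff(keep, victim)
  }
  structure(list(retained = keep, dropped_by_vif = dropped,
                 vif_threshold = vif_threshold),
            class = "screen_report")
}

#' Two-stage collinearity screen
#'
#' The full predictor screen: greedy pairwise Pearson elimination
#' (`|r| > r_threshold`) first, then stepwise VIF elimination on the
#' survivors. Both stages are deterministic given column order.
#'
#' @param table a `feature_table`.
#' @param r_threshold pairwise correlation threshold.
#' @param vif_threshold stepwise VIF threshold.
#' @return a `screen_report` combining both stages, with `retained`,
#'   `dropped_by_correlation`, `dropped_by_vif`, `zero_variance`.
#' @export
screen_predictors <- function(table, r_threshold = 0.7, vif_threshold = 10) {
  stage1 <- pearson_screen(table, r_threshold)
  surv <- table[, c(stage1$retained, "label"), drop = FALSE]
  class(surv) <- class(table)
  stage2 <- vifstep(surv, vif_threshold)
  structure(list(retained = stage2$retained,
                 dropped_by_correlation = stage1$dropped_by_correlation,
                 dropped_by_vif = stage2$dropped_by_vif,
                 zero_variance = stage1$zero_variance,
                 r_threshold = r_threshold,
                 vif_threshold = vif_threshold),
            class = "screen_report")
}

#' @export
print.screen_report <- function(x, ...) {
  cat("<screen_report>\n")
  cat("  retained:", paste(x$retained, collapse = ", "), "\n")
  if (!is.null(x$dropped_by_correlation) && nrow(x$dropped_by_correlation)) {
    cat("  dropped by |r| >", x$r_threshold, ":",
        paste(x$dropped_by_correlation$name, collapse = ", "), "\n")
  }
  if (nrow(x$dropped_by_vif)) {
    cat("  dropped by VIF >", x$vif_threshold, ":",
        paste(x$dropped_by_vif$name, collapse = ", "), "\n")
  }
  invisible(x)
}
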