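#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC: the probability that a randomly chosen
#' presence outscores a randomly chosen absence, with ties counted one half.
#' Identical to the trapezoidal area under the empirical ROC curve.
#'
#' @param scores numeric vector of predicted probabilities or scores.
#' @param labels 0/1 vector of the same length.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  if (length(scores) != length(labels)) stop("scores/labels length mismatch")
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present to compute AUC")
  r <- rank(scores)  # midranks handle ties
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' True skill statistic, maximised over thresholds
#'
#' `TSS(t) = sensitivity(t) + specificity(t) - 1`, with a prediction counted
#' positive when `score >= t`. The maximum is searched over every observed
#' score plus 0 and 1 (the maximum of a step function is attained at an
#' observed score); the smallest maximising threshold is returned.
#'
#' @param scores numeric vector of predicted probabilities.
#' @param labels 0/1 vector.
#' @return list with `tss` (in `[-1, 1]`) and `threshold` (in `[0, 1]`).
#' @export
tss <- function(scores, labels) {
  if (length(scores) != length(labels)) stop("scores/labels length mismatch")
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present to compute TSS")
  thr <- sort(unique(c(0, 1, scores)))
  val <- vapply(thr, function(t) {
    pos <- scores >= t
    sum(pos & labels == 1) / n1 + sum(!pos & labels == 0) / n0 - 1
  }, numeric(1))
  best <- max(val)
  list(tss = best, threshold = thr[which(val == best)[1]])
}

#' Per-replicate AUC and TSS from a cross-validation result
#'
#' Pools, for each algorithm and run, the held-out scores of all folds and
#' computes one AUC and one maximised TSS per replicate.
#'
#' @param cv a `cv_result` from [cross_validate()].
#' @return data frame with columns `algorithm`, `run`, `auc`, `tss`,
#'   `tss_threshold`.
#' @export
evaluate_cv <- function(cv) {
  parts <- split(cv, list(cv$algorithm, cv$run), drop = TRUE)
  out <- do.call(rbind, lapply(parts, function(d) {
    t <- tss(d$score, d$label)
    data.frame(algorithm = d$algorithm[1], run = d$run[1],
               auc = auc(d$score, d$label),
               tss = t$tss, tss_threshold = t$threshold,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$algorithm, out$run), ]
}

#' Per-algorithm mean performance table
#'
#' Averages replicate metrics per algorithm and appends a final
#' `"Mean value"` row holding the unweighted mean over algorithms — the
#' summary convention of ensemble SDM studies. Values are carried at full
#' precision; the print method renders two decimals.
#'
#' @param results data frame of per-replicate metrics (from [evaluate_cv()]
#'   or assembled by hand) with columns `algorithm`, `auc`, `tss`.
#' @return a `performance_table` data frame with columns `algorithm`,
#'   `auc`, `tss`, `n_replicates`.
#' @export
performance_table <- function(results) {
  stopifnot(all(c("algorithm", "auc", "tss") %in% names(results)))
  algs <- unique(results$algorithm)
  rows <- do.call(rbind, lapply(algs, function(a) {
    d <- results[results$algorithm == a, ]
    data.frame(algorithm = a, auc = mean(d$auc), tss = mean(d$tss),
               n_replicates = nrow(d), stringsAsFactors = FALSE)
  }))
  grand <- data.frame(algorithm = "Mean value",
                      auc = mean(rows$auc), tss = mean(rows$tss),
                      n_replicates = sum(rows$n_replicates),
                      stringsAsFactors = FALSE)
  out <- rbind(rows, grand)
  rownames(out) <- NULL
  class(out) <- c("performance_table", "data.frame")
  out
}

#' @export
print.performance_table <- function(x, ...) {
  y <- x
  y$auc <- sprintf("%.2f", y$auc)
  y$tss <- sprintf("%.2f", y$tss)
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}

# default model-skill bands; lower edge inclusive, upper exclusive, top
# band closed at the metric's maximum
AUC_BANDS <- c(fail = 0, poor = 0.6, fair = 0.7, good = 0.8, excellent = 0.9)
TSS_BANDS <- c(fail = -1, poor = 0.2, fair = 0.4, good = 0.6, excellent = 0.8)

band_lookup <- function(value, bands, top) {
  if (value < bands[1] || value > top) {
    stop("metric value ", value, " outside its legal range")
  }
  names(bands)[findInterval(value, bands)]
}

#' Categorical grade of model skill
#'
#' Maps AUC and TSS onto the conventional fail/poor/fair/good/excellent
#' bands (half-open intervals, lower edge inclusive; top band closed).
#' The band edges are returned alongside the grades so reports always state
#' the convention applied.
#'
#' @param auc AUC value in `[0, 1]`.
#' @param tss TSS value in `[-1, 1]`.
#' @param auc_bands,tss_bands named vectors of band lower edges.
#' @return list with `auc_grade`, `tss_grade`, and the band definitions.
#' @export
classify_performance <- function(auc, tss,
                                 auc_bands = AUC_BANDS,
                                 tss_bands = TSS_BANDS) {
  list(auc_grade = band_lookup(auc, auc_bands, 1),
       tss_grade = band_lookup(tss, tss_bands, 1),
       auc_bands = auc_bands, tss_bands = tss_bands)
}
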