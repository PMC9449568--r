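ALGORITHM_IDS <- c("MARS", "BRT", "MLP", "RF", "SVM")

#' Specification of one base learner
#'
#' The five supported algorithms are MARS (adaptive regression splines),
#' BRT (boosted regression trees), MLP (single-hidden-layer perceptron),
#' RF (random forest) and SVM (support vector machine, RBF kernel).
#' Hyperparameters are fixed, sensible defaults; anything supplied in
#' `hyperparameters` overrides them and is recorded in the fitted model.
#'
#' @param algorithm_id one of `"MARS"`, `"BRT"`, `"MLP"`, `"RF"`, `"SVM"`.
#' @param hyperparameters named list of overrides (see Details per backend).
#' @param seed integer seed controlling any stochastic element of training.
#' @return an object of class `algorithm_spec`.
#' @export
algorithm_spec <- function(algorithm_id, hyperparameters = list(), seed = 1L) {
  if (!algorithm_id %in% ALGORITHM_IDS) {
    stop("unknown algorithm id '", algorithm_id, "'; must be one of: ",
         paste(ALGORITHM_IDS, collapse = ", "))
  }
  structure(list(algorithm_id = algorithm_id,
                 hyperparameters = hyperparameters,
                 seed = as.integer(seed)),
            class = "algorithm_spec")
}

#' Default specs for the five-algorithm ensemble
#'
#' @param seed master seed; each algorithm gets a derived child seed.
#' @return list of five [algorithm_spec()] objects, one per algorithm.
#' @export
default_algorithm_specs <- function(seed = 1L) {
  seeds <- derive_seeds(seed, length(ALGORITHM_IDS), salt = 101L)
  stats::setNames(
    lapply(seq_along(ALGORITHM_IDS), function(i) {
      algorithm_spec(ALGORITHM_IDS[i], seed = seeds[i])
    }),
    ALGORITHM_IDS)
}

default_hp <- function(id, p) {
  switch(id,
    RF   = list(ntree = 500),
    BRT  = list(nrounds = 200, eta = 0.1, max_depth = 3),
    MLP  = list(size = max(2L, p), decay = 0.01, maxit = 300),
    SVM  = list(kernel = "radial", cost = 1),
    MARS = list(max_pairs = 8L, n_knots = 15L, penalty = 3))
}

#' Train one base learner
#'
#' Trains a probabilistic presence/absence classifier. Training is
#' deterministic for a fixed `spec$seed` and input table.
#'
#' @param spec an [algorithm_spec()].
#' @param table a `feature_table` with a 0/1 `label` column and at least one
#'   row of each class.
#' @return a `fitted_model` holding the backend fit, the ordered feature
#'   names and the resolved hyperparameters.
#' @export
fit_model <- function(spec, table) {
  if (!inherits(spec, "algorithm_spec")) stop("`spec` must be an algorithm_spec")
  x <- feature_matrix(table)
  y <- table$label
  if (length(unique(y)) < 2L) {
    stop("training table must contain both presence and absence labels")
  }
  hp <- utils::modifyList(default_hp(spec$algorithm_id, ncol(x)),
                          spec$hyperparameters)
  fit <- with_seed(spec$seed, switch(spec$algorithm_id,
    RF = randomForest::randomForest(
      x = x, y = factor(y, levels = c(0, 1)), ntree = hp$ntree),
    BRT = xgboost::xgb.train(
      params = list(objective = "binary:logistic", eta = hp$eta,
                    max_depth = hp$max_depth, nthread = 1),
      data = xgboost::xgb.DMatrix(x, label = y, nthread = 1),
      nrounds = hp$nrounds),
    MLP = {
      ctr <- list(center = colMeans(x), scale = apply(x, 2, stats::sd))
      ctr$scale[ctr$scale == 0] <- 1
      xs <- scale(x, ctr$center, ctr$scale)
      net <- nnet::nnet(xs, y, size = hp$size, decay = hp$decay,
                        maxit = hp$maxit, entropy = TRUE, trace = FALSE)
      list(net = net, center = ctr$center, scale = ctr$scale)
    },
    SVM = e1071::svm(
      x = x, y = factor(y, levels = c(0, 1)), kernel = hp$kernel,
      cost = hp$cost, probability = TRUE),
    MARS = fit_mars(x, y, max_pairs = hp$max_pairs, n_knots = hp$n_knots,
                    penalty = hp$penalty)
  ))
  structure(list(spec = spec, hyperparameters = hp,
                 feature_names = colnames(x),
                 fitted_state = fit, training_rows = nrow(x)),
            class = "fitted_model")
}

#' Predict presence probability from a fitted base learner
#'
#' Columns of `table` must match the model's `feature_names` exactly and in
#' order; no silent reordering is performed.
#'
#' @param model a `fitted_model` from [fit_model()].
#' @param table data frame or matrix of feature rows.
#' @return numeric vector of probabilities in `[0, 1]`.
#' @export
predict_proba <- function(model, table) {
  x <- if (is.data.frame(table)) {
    as.matrix(table[, setdiff(names(table), "label"), drop = FALSE])
  } else as.matrix(table)
  if (!identical(colnames(x), model$feature_names)) {
    stop("feature columns (", paste(colnames(x), collapse = ", "),
         ") do not match the model's training columns (",
         paste(model$feature_names, collapse = ", "), ") in name and order")
  }
  fit <- model$fitted_state
  p <- switch(model$spec$algorithm_id,
    RF = stats::predict(fit, x, type = "prob")[, "1"],
    BRT = stats::predict(fit, x),
    MLP = {
      xs <- scale(x, fit$center, fit$scale)
      drop(stats::predict(fit$net, xs))
    },
    SVM = {
      pr <- stats::predict(fit, x, probability = TRUE)
      attr(pr, "probabilities")[, "1"]
    },
    MARS = predict_mars(fit, x))
  p <- as.numeric(p)
  p[!is.finite(p)] <- 0.5
  pmin(1, pmax(0, p))
}

#' Seeded stratified k-fold assignment
#'
#' @param labels 0/1 vector.
#' @param k number of folds.
#' @param seed integer seed.
#' @return integer vector of fold ids (1..k), stratified so per-fold class
#'   counts differ by at most one from proportionality.
#' @export
stratified_folds <- function(labels, k, seed) {
  if (k < 2L) stop("k must be at least 2")
  if (min(table(labels)) < k) {
    stop("smallest class has fewer rows than folds; cannot stratify")
  }
  fold <- integer(length(labels))
  with_seed(seed, {
    for (cls in unique(labels)) {
      idx <- which(labels == cls)
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  fold
}

#' Repeated stratified cross-validation of the base learners
#'
#' Runs `runs` independent seeded `k`-fold stratified partitions. Within a
#' run every row is scored exactly once, by a model whose training set did
#' not contain it. Evaluation mode `"split"` instead draws, per run, a
#' single stratified 70/30 train/test split.
#'
#' @param table a `feature_table` with a `label` column.
#' @param specs list of [algorithm_spec()]; default all five algorithms.
#' @param k folds per run.
#' @param runs number of repeated runs.
#' @param seed master seed; run seeds and per-fit seeds derive from it.
#' @param scheme `"cv"` (k-fold) or `"split"` (70/30 per run).
#' @param train_fraction training share for `scheme = "split"`.
#' @return a `cv_result`: data frame with columns `algorithm`, `run`,
#'   `fold`, `row`, `label`, `score`.
#' @export
cross_validate <- function(table, specs = default_algorithm_specs(seed),
                           k = 4L, runs = 10L, seed = 1L,
                           scheme = c("cv", "split"), train_fraction = 0.7) {
  scheme <- match.arg(scheme)
  labels <- table$label
  run_seeds <- derive_seeds(seed, runs, salt = 7L)
  out <- vector("list", runs * length(specs))
  slot <- 0L
  for (r in seq_len(runs)) {
    if (scheme == "cv") {
      fold <- stratified_folds(labels, k, run_seeds[r])
      fold_set <- seq_len(k)
    } else {
      # one stratified holdout per run; the held-out rows form "fold 1"
      fold <- integer(length(labels))
      with_seed(run_seeds[r], for (cls in unique(labels)) {
        idx <- which(labels == cls)
        n_test <- max(1L, round((1 - train_fraction) * length(idx)))
        fold[sample(idx, n_test)] <- 1L
      })
      fold[fold == 0L] <- 2L
      fold_set <- 1L
    }
    for (s in seq_along(specs)) {
      spec <- specs[[s]]
      scores <- rep(NA_real_, length(labels))
      for (f in fold_set) {
        train <- fold != f
        test <- !train
        stopifnot(!any(train & test))  # leakage guard
        fit_spec <- algorithm_spec(
          spec$algorithm_id, spec$hyperparameters,
          seed = (spec$seed + 1009L * r + f) %% .Machine$integer.max)
        m <- fit_model(fit_spec, table[train, , drop = FALSE])
        scores[test] <- predict_proba(
          m, table[test, setdiff(names(table), "label"), drop = FALSE])
      }
      scored <- which(!is.na(scores))
      slot <- slot + 1L
      out[[slot]] <- data.frame(
        algorithm = spec$algorithm_id, run = r,
        fold = fold[scored], row = scored,
        label = labels[scored], score = scores[scored],
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  class(res) <- c("cv_result", "data.frame")
  res
}
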