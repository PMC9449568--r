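fit_two_member_ensemble <- function(aucs = c(0.9, 0.7), tbl = NULL) {
  if (is.null(tbl)) tbl <- separable_table(n_per_class = 25)
  members <- list(fit_model(algorithm_spec("RF", seed = 1), tbl),
                  fit_model(algorithm_spec("SVM", seed = 2), tbl))
  evals <- data.frame(auc = aucs, tss = aucs - 0.2)
  list(tbl = tbl,
       ens = build_ensemble(members, evals, "AUC"),
       members = members, evals = evals)
}

test_that("ensemble weights are skill above the no-skill floor, normalised", {
  f <- fit_two_member_ensemble(c(0.9, 0.7))
  # (0.9 - 0.5, 0.7 - 0.5) -> (0.4, 0.2) -> (2/3, 1/3)
  expect_equal(f$ens$weights, c(2 / 3, 1 / 3))
  expect_equal(sum(f$ens$weights), 1, tolerance = 1e-12)

  u <- build_ensemble(f$members, f$evals, "uniform")
  expect_equal(u$weights, c(0.5, 0.5))

  expect_warning(
    z <- build_ensemble(f$members, data.frame(auc = c(0.5, 0.4),
                                              tss = c(0, 0)), "AUC"),
    "uniform")
  expect_equal(z$weights, c(0.5, 0.5))

  expect_error(build_ensemble(f$members, data.frame(auc = 0.9, tss = 0.6)),
               "one evaluation row per member")
})

test_that("ensemble predictions are convex combinations of member outputs", {
  f <- fit_two_member_ensemble()
  x <- f$tbl[, c("f1", "f2")]
  p_members <- sapply(f$members, predict_proba, table = x)
  p_ens <- ensemble_predict_points(f$ens, x)
  expect_equal(p_ens, drop(p_members %*% f$ens$weights))
  expect_true(all(p_ens >= apply(p_members, 1, min) - 1e-12))
  expect_true(all(p_ens <= apply(p_members, 1, max) + 1e-12))
  # member order must not matter
  rev_ens <- build_ensemble(rev(f$members), f$evals[2:1, ], "AUC")
  expect_equal(ensemble_predict_points(rev_ens, x), p_ens)
})

test_that("raster prediction agrees with point prediction cell by cell", {
  stack <- random_stack(2, nr = 10, nc = 10, seed = 6)
  names(stack$layers) <- c("f1", "f2")
  # punch one nodata hole in one layer
  stack$layers$f1$values[4, 7] <- NA
  f <- fit_two_member_ensemble()
  suit <- ensemble_predict_raster(f$ens, stack)
  expect_true(is.na(suit$values[4, 7]))
  expect_identical(sum(is.na(suit$values)), 1L)
  # two-path consistency on the valid cells
  valid <- which(!is.na(suit$values))
  x <- data.frame(f1 = stack$layers$f1$values[valid],
                  f2 = stack$layers$f2$values[valid])
  expect_equal(suit$values[valid], ensemble_predict_points(f$ens, x))
  # block size must not change the result
  suit_small_blocks <- ensemble_predict_raster(f$ens, stack, block_size = 7L)
  expect_equal(suit_small_blocks$values, suit$values)
  # a constant stack gives a constant map
  const <- align_stack(list(raster_grid(matrix(0.3, 5, 5), 0, 5, 1),
                            raster_grid(matrix(-1, 5, 5), 0, 5, 1)),
                       c("f1", "f2"))
  p_const <- ensemble_predict_raster(f$ens, const)
  expect_lt(diff(range(p_const$values)), 1e-12)

  missing_layer <- align_stack(list(stack$layers$f1), "f1")
  expect_error(ensemble_predict_raster(f$ens, missing_layer), "f2")
})

test_that("permutation importance finds the signal and ignores decoys", {
  # one-signal fixture: label depends on f1 only; f2 is shuffled noise
  set.seed(77)
  n <- 150
  tbl <- data.frame(f1 = rnorm(n), f2 = rnorm(n))
  tbl$label <- as.integer(tbl$f1 + rnorm(n, sd = 0.3) > 0)
  class(tbl) <- c("feature_table", "data.frame")
  members <- list(fit_model(algorithm_spec("RF", seed = 1), tbl),
                  fit_model(algorithm_spec("BRT", seed = 2), tbl))
  ens <- build_ensemble(members, data.frame(auc = c(0.9, 0.9),
                                            tss = c(0.7, 0.7)), "AUC")
  imp <- variable_importance(ens, tbl, repeats = 3, seed = 5)
  expect_identical(imp$variable[1], "f1")
  expect_gt(imp$contribution[imp$variable == "f1"], 10)
  expect_lt(imp$contribution[imp$variable == "f2"],
            imp$contribution[imp$variable == "f1"] / 5)
  expect_true(all(imp$contribution >= 0))
  # determinism under a fixed seed
  imp2 <- variable_importance(ens, tbl, repeats = 3, seed = 5)
  expect_equal(as.data.frame(imp), as.data.frame(imp2))
})
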