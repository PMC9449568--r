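test_that("the climate stack is seeded, standardised and collinear on cue", {
  cfg <- world_config(n_rows = 40, n_cols = 40, autocorr_length = 4,
                      seed = 12)
  s1 <- make_climate_stack(cfg)
  s2 <- make_climate_stack(cfg)
  expect_equal(s1$layers$sig1$values, s2$layers$sig1$values)  # bit-identical
  for (g in s1$layers) {
    expect_equal(mean(g$values), 0, tolerance = 1e-10)
    expect_equal(sd(as.vector(g$values)), 1, tolerance = 1e-10)
  }
  # the injected duplicate tracks its parent
  r <- cor(as.vector(s1$layers$sig1$values),
           as.vector(s1$layers$sig1_copy$values))
  expect_gte(r, 0.95)
  # autocorrelation length zero leaves neighbouring cells uncorrelated
  white <- make_climate_stack(world_config(n_rows = 60, n_cols = 60,
                                           autocorr_length = 0, seed = 9))
  v <- white$layers$sig1$values
  lag1 <- cor(as.vector(v[-1, ]), as.vector(v[-60, ]))
  expect_lt(abs(lag1), 0.05)
  # smoothing induces strong neighbour correlation
  v2 <- s1$layers$sig1$values
  expect_gt(cor(as.vector(v2[-1, ]), as.vector(v2[-40, ])), 0.5)
})

test_that("true suitability is the cell-wise logistic of the niche", {
  g1 <- raster_grid(matrix(c(-1, 0, 1, 2), 2, 2), 0, 2, 1)
  g2 <- raster_grid(matrix(c(0.5, -0.5, 1, -1), 2, 2), 0, 2, 1)
  stack <- align_stack(list(g1, g2), c("sig1", "sig2"))
  sp <- virtual_species(beta0 = 0.25, betas = c(sig1 = 2, sig2 = -1),
                        quadratic = c(sig1 = -0.5))
  truth <- true_suitability(sp, stack)
  # hand-computed logistic at every cell
  eta <- 0.25 + 2 * g1$values - 1 * g2$values - 0.5 * g1$values^2
  expect_equal(truth$values, 1 / (1 + exp(-eta)))
  # flat niche: constant one half
  flat <- true_suitability(virtual_species(0, c(sig1 = 0), NULL), stack)
  expect_true(all(flat$values == 0.5))
  # strongly negative intercept saturates near zero
  rare <- true_suitability(virtual_species(-20, c(sig1 = 0), NULL), stack)
  expect_true(all(rare$values < 1e-8))
  expect_error(true_suitability(virtual_species(0, c(bio19 = 1), NULL),
                                stack), "bio19")
})

test_that("presence sampling follows the suitability surface", {
  # degenerate weights: all mass on one cell
  w <- matrix(1e-12, 5, 5); w[3, 4] <- 1
  truth <- raster_grid(w, 0, 5, 1)
  p <- sample_presences(truth, 1, seed = 4)
  expect_equal(p$lon, 3.5)
  expect_equal(p$lat, 2.5)
  # without replacement: n distinct cells, error past the cell count
  many <- sample_presences(raster_grid(matrix(0.5, 4, 4), 0, 4, 1), 16,
                           seed = 1)
  expect_identical(nrow(unique(many[, c("lon", "lat")])), 16L)
  expect_error(sample_presences(truth, 26, seed = 1), "26")
  # determinism
  t2 <- raster_grid(matrix(runif(100), 10, 10), 0, 10, 1)
  expect_equal(as.data.frame(sample_presences(t2, 20, seed = 6)),
               as.data.frame(sample_presences(t2, 20, seed = 6)))
  # uniform truth: occupancy uniform by a chi-square over many draws
  flat <- raster_grid(matrix(0.4, 5, 5), 0, 5, 1)
  counts <- numeric(25)
  for (r in 1:200) {
    s <- sample_presences(flat, 10, seed = 3000 + r)
    idx <- cell_index(flat, s$lon, s$lat)
    lin <- (idx[, 1] - 1) * 5 + idx[, 2]
    counts[lin] <- counts[lin] + 1
  }
  expect_gt(stats::chisq.test(counts)$p.value, 0.01)
})

test_that("scenario shifts move only the named layers", {
  stack <- make_climate_stack(world_config(n_rows = 20, n_cols = 20,
                                           seed = 3))
  shift <- scenario_shift(c(sig1 = 1, decoy1 = -0.5), "2050 test")
  out <- apply_shift(stack, shift)
  expect_equal(mean(out$layers$sig1$values),
               mean(stack$layers$sig1$values) + 1)
  expect_equal(mean(out$layers$decoy1$values),
               mean(stack$layers$decoy1$values) - 0.5)
  expect_equal(out$layers$sig2$values, stack$layers$sig2$values)
  # zero shift is the identity
  zero <- apply_shift(stack, scenario_shift(c(sig1 = 0), "none"))
  expect_equal(zero$layers$sig1$values, stack$layers$sig1$values)
  expect_error(apply_shift(stack, scenario_shift(c(bio1 = 1), "x")), "bio1")
  # truth responds only through the shifted layers
  sp <- virtual_species(0, c(sig1 = 1, sig2 = 1), NULL)
  t_cur <- true_suitability(sp, stack)
  t_fut <- true_suitability(sp, out)
  sp_sig2 <- virtual_species(0, c(sig2 = 1), NULL)
  expect_equal(true_suitability(sp_sig2, out)$values,
               true_suitability(sp_sig2, stack)$values)
  expect_false(isTRUE(all.equal(t_cur$values, t_fut$values)))
})
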