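test_that("feature extraction reads the containing cell", {
  # constant layer: every row gets the constant
  const <- raster_grid(matrix(7, 5, 5), 0, 5, 1)
  count <- counting_grid(5, 5, xmin = 0, ymax = 5, cell = 1)
  stack <- align_stack(list(const, count), c("flat", "pattern"))
  pts <- occurrence_set(lon = c(0.5, 3.2, 4.9), lat = c(4.5, 2.7, 0.1),
                        label = c(1L, 1L, 0L))
  ft <- extract_features(stack, pts)
  expect_equal(ft$flat, c(7, 7, 7))
  # brute-force lookup of the counting pattern
  expected <- sapply(seq_len(nrow(pts)), function(i) {
    rc <- brute_force_cell(count, pts$lon[i], pts$lat[i])
    count$values[rc[1], rc[2]]
  })
  expect_equal(ft$pattern, expected)
  expect_identical(ft$label, pts$label)

  outside <- occurrence_set(12, 2)
  expect_error(extract_features(stack, outside), "outside")

  masked <- raster_grid(matrix(c(NA, rep(1, 24)), 5, 5), 0, 5, 1)
  stack2 <- align_stack(list(masked), "m")
  on_na <- occurrence_set(0.5, 4.5)  # cell (1,1)
  expect_error(extract_features(stack2, on_na), "nodata")
})

test_that("pearson screen eliminates exactly the collinear offenders", {
  set.seed(21)
  n <- 500
  base <- rnorm(n)
  tbl <- data.frame(c1 = base, c2 = rnorm(n),
                    c3 = base + rnorm(n, sd = 0.05),
                    label = rbinom(n, 1, 0.5))
  class(tbl) <- c("feature_table", "data.frame")
  rep1 <- pearson_screen(tbl, 0.7)
  # exactly one of the c1/c3 pair goes, c2 stays
  expect_identical(nrow(rep1$dropped_by_correlation), 1L)
  expect_true(rep1$dropped_by_correlation$name %in% c("c1", "c3"))
  expect_true("c2" %in% rep1$retained)
  # retained pairs all satisfy the threshold
  cm <- cor(tbl[, rep1$retained, drop = FALSE])
  expect_true(all(abs(cm[upper.tri(cm)]) <= 0.7))

  # identical columns: r = 1, one dropped
  dup <- data.frame(a = base, b = base, label = tbl$label)
  class(dup) <- class(tbl)
  expect_identical(nrow(pearson_screen(dup)$dropped_by_correlation), 1L)

  # independent noise columns survive untouched
  noise <- data.frame(matrix(rnorm(n * 4), n), label = tbl$label)
  names(noise)[1:4] <- paste0("n", 1:4)
  class(noise) <- class(tbl)
  expect_identical(pearson_screen(noise)$retained, paste0("n", 1:4))

  # zero-variance column is retained and logged
  zv <- data.frame(a = base, z = rep(1, n), label = tbl$label)
  class(zv) <- class(tbl)
  repz <- pearson_screen(zv)
  expect_identical(repz$zero_variance, "z")
  expect_true("z" %in% repz$retained)
})

test_that("vif matches the normal-equations oracle", {
  set.seed(33)
  for (p in c(3, 4, 6)) {
    x <- matrix(rnorm(200 * p), 200, p,
                dimnames = list(NULL, paste0("x", seq_len(p))))
    x[, p] <- x[, 1] * 0.6 + rnorm(200, sd = 0.8)  # induce some correlation
    expect_equal(unname(c(vif(x))), brute_force_vif(x), tolerance = 1e-8)
  }
  # columns orthogonalised against each other and the intercept: VIF = 1
  q <- qr.Q(qr(cbind(1, matrix(rnorm(100 * 3), 100, 3))))[, -1]
  colnames(q) <- c("a", "b", "c")
  expect_equal(unname(c(vif(q))), rep(1, 3), tolerance = 1e-9)
  # exact duplicate: flagged at the finite cap, no crash
  d <- cbind(a = rnorm(50), b = 0)
  d[, "b"] <- d[, "a"]
  v <- vif(d)
  expect_true(all(v >= 1e12))
  expect_setequal(attr(v, "capped"), c("a", "b"))
})

test_that("vifstep leaves no retained predictor above the threshold", {
  set.seed(44)
  n <- 300
  base <- matrix(rnorm(n * 3), n, 3)
  tbl <- data.frame(u1 = base[, 1], u2 = base[, 2], u3 = base[, 3],
                    dup = base[, 1] + rnorm(n, sd = 0.1),
                    chain = base[, 1] + base[, 2] + rnorm(n, sd = 0.1),
                    label = rbinom(n, 1, 0.5))
  class(tbl) <- c("feature_table", "data.frame")
  rep1 <- vifstep(tbl, 10)
  # the oracle recheck: every retained column satisfies the threshold
  v <- brute_force_vif(as.matrix(tbl[, rep1$retained]))
  expect_true(all(v <= 10))
  # every recorded removal exceeded the threshold at removal time
  expect_true(all(rep1$dropped_by_vif$vif_at_removal > 10))
  # a clean table is returned unchanged
  clean <- tbl[, c("u1", "u2", "u3", "label")]
  class(clean) <- class(tbl)
  rep2 <- vifstep(clean, 10)
  expect_identical(rep2$retained, c("u1", "u2", "u3"))
  expect_identical(nrow(rep2$dropped_by_vif), 0L)
})

test_that("the two-stage screen is deterministic and self-consistent", {
  set.seed(55)
  n <- 400
  b <- matrix(rnorm(n * 4), n, 4)
  tbl <- data.frame(v1 = b[, 1], v2 = b[, 2], v3 = b[, 3], v4 = b[, 4],
                    v5 = b[, 1] + rnorm(n, sd = 0.05),
                    v6 = b[, 2] + b[, 3] + rnorm(n, sd = 0.2),
                    label = rbinom(n, 1, 0.5))
  class(tbl) <- c("feature_table", "data.frame")
  s1 <- screen_predictors(tbl)
  s2 <- screen_predictors(tbl)
  expect_identical(s1$retained, s2$retained)
  # post-screen guarantee on both thresholds
  kept <- as.matrix(tbl[, s1$retained])
  cm <- cor(kept)
  expect_true(all(abs(cm[upper.tri(cm)]) <= 0.7))
  expect_true(all(brute_force_vif(kept) <= 10))
  # partition: every input column is retained or dropped, never both
  dropped <- c(s1$dropped_by_correlation$name, s1$dropped_by_vif$name)
  expect_length(intersect(s1$retained, dropped), 0)
  expect_setequal(c(s1$retained, dropped), paste0("v", 1:6))
})
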