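test_that("classification uses half-open bins with a closed top", {
  vals <- matrix(c(0, 0.1, 0.25, 0.3, 0.49, 0.5, 0.74, 0.75, 1), 3, 3)
  g <- raster_grid(vals, 0, 3, 1)
  cls <- classify_suitability(g)
  # 0.25 and 0.3 are "low"; 0.5 "moderate"; 0.75 and 1.0 "high"
  expect_equal(as.vector(cls$values), c(1, 1, 2, 2, 2, 3, 3, 4, 4))
  # nodata propagates
  vals[2, 2] <- NA
  cls2 <- classify_suitability(raster_grid(vals, 0, 3, 1))
  expect_true(is.na(cls2$values[2, 2]))
  # marginal overshoot is clamped with a warning, gross overshoot errors
  expect_warning(classify_suitability(raster_grid(matrix(1 + 1e-10, 2, 2),
                                                  0, 2, 1)), "clamped")
  expect_error(classify_suitability(raster_grid(matrix(1.5, 2, 2), 0, 2, 1)),
               "outside")
  expect_error(suitability_scheme(breaks = c(0, 0.25, 0.5, 0.75, 0.9)),
               "0 to 1")
})

test_that("area percentages count cells and sum to 100", {
  cls <- raster_grid(matrix(c(1, 1, 2, 4), 2, 2), 0, 2, 1)
  s <- area_summary(cls, "current")
  expect_equal(s$percent, c(50, 25, 0, 25))
  expect_equal(sum(s$percent), 100, tolerance = 1e-9)
  # single class
  one <- area_summary(raster_grid(matrix(3, 2, 2), 0, 2, 1))
  expect_equal(one$percent, c(0, 0, 100, 0))
  expect_error(area_summary(raster_grid(matrix(NA_real_, 2, 2), 0, 2, 1)),
               "no valid cells")
  # nodata cells leave the denominator
  cls$values[1, 1] <- NA
  s2 <- area_summary(cls)
  expect_equal(sum(s2$percent), 100, tolerance = 1e-9)
  expect_equal(s2$percent[1], 100 / 3)
})

test_that("total suitable area is the complement of the unsuitable share", {
  s <- area_summary(raster_grid(matrix(c(1, 2, 3, 4), 2, 2), 0, 2, 1))
  expect_equal(total_suitable(s), 75)
  expect_equal(total_suitable(s), 100 - s$percent[1], tolerance = 1e-9)
  all_not <- area_summary(raster_grid(matrix(1, 2, 2), 0, 2, 1))
  expect_equal(total_suitable(all_not), 0)
})

test_that("the change rate follows its defining formula", {
  expect_equal(change_rate(50, 50), 0)
  expect_equal(change_rate(40, 50), 25)
  expect_equal(change_rate(50, 40), -20)
  expect_error(change_rate(0, 10), "undefined")
  # anti-symmetry sanity: AC(a,b) and AC(b,a) scale by -a/b
  a <- 37.5; b <- 61.2
  expect_equal(change_rate(a, b), -change_rate(b, a) * b / a,
               tolerance = 1e-12)
})

test_that("change maps match a per-cell truth table and overlay identities", {
  set.seed(88)
  cur <- raster_grid(matrix(sample(1:4, 400, TRUE), 20, 20), 0, 20, 1)
  fut <- raster_grid(matrix(sample(1:4, 400, TRUE), 20, 20), 0, 20, 1)
  cur$values[3, 5] <- NA
  cm <- change_map(cur, fut)
  counts <- attr(cm, "counts")
  # exhaustive per-cell oracle
  expected <- matrix(NA_integer_, 20, 20)
  for (r in 1:20) for (c in 1:20) {
    a <- cur$values[r, c]; b <- fut$values[r, c]
    if (is.na(a) || is.na(b)) next
    expected[r, c] <- if (a < 2 && b < 2) 1L else if (a < 2) 2L
      else if (b >= 2) 3L else 4L
  }
  mode(expected) <- "double"
  expect_equal(cm$values, expected)
  # overlay identities
  fut_suit <- as.integer(sum(fut$values >= 2 & !is.na(cur$values)))
  cur_suit <- as.integer(sum(cur$values >= 2 & !is.na(cur$values),
                             na.rm = TRUE))
  expect_identical(unname(counts["gain"] + counts["stable_suitable"]),
                   fut_suit)
  expect_identical(unname(counts["loss"] + counts["stable_suitable"]),
                   cur_suit)
  expect_identical(unname(sum(counts)), sum(!is.na(expected)))

  # identical maps show only stable categories
  same <- change_map(cur, cur)
  expect_identical(unname(attr(same, "counts")[c("gain", "loss")]), c(0L, 0L))
  # total reversal: everything suitable becomes loss
  all_s <- raster_grid(matrix(4, 4, 4), 0, 4, 1)
  all_n <- raster_grid(matrix(1, 4, 4), 0, 4, 1)
  expect_identical(unname(attr(change_map(all_s, all_n), "counts")["loss"]),
                   16L)
  shifted <- raster_grid(matrix(1, 4, 4), 0.5, 4, 1)
  expect_error(change_map(all_s, shifted), "co-registered")
})

test_that("scenario reports stay consistent with cell-wise change rates", {
  cur <- area_summary(raster_grid(matrix(c(1, 1, 2, 3), 2, 2), 0, 2, 1),
                      "current")
  futA <- area_summary(raster_grid(matrix(c(1, 2, 2, 4), 2, 2), 0, 2, 1),
                       "A")
  rep1 <- scenario_report(cur, list(A = futA))
  expect_identical(dim(rep1$suitability), c(2L, 5L))
  for (k in seq_along(cur$class)) {
    expected <- if (cur$percent[k] <= 0) NA_real_ else
      change_rate(cur$percent[k], futA$percent[k])
    expect_equal(rep1$change_rate[[cur$class[k]]], expected)
  }
  # a future equal to current has zero change everywhere current is nonzero
  rep2 <- scenario_report(cur, list(same = cur))
  ac <- unlist(rep2$change_rate[1, -1])
  expect_true(all(ac[!is.na(ac)] == 0))
})
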