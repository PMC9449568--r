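# Shared fixture builders: everything is generated in code at test time.

# small grid with a deterministic counting pattern (value = row * 100 + col)
counting_grid <- function(nr = 5, nc = 5, xmin = 0, ymax = 5, cell = 1) {
  raster_grid(outer(seq_len(nr), seq_len(nc), function(r, c) r * 100 + c),
              xmin = xmin, ymax = ymax, dx = cell)
}

# a co-registered stack of k random layers, all cells valid
random_stack <- function(k = 3, nr = 8, nc = 8, seed = 1, cell = 0.5) {
  set.seed(seed)
  layers <- lapply(seq_len(k), function(i) {
    raster_grid(matrix(rnorm(nr * nc), nr, nc), xmin = 0, ymax = nr * cell,
                dx = cell)
  })
  align_stack(layers, paste0("v", seq_len(k)))
}

# linearly separable two-feature classification fixture
separable_table <- function(n_per_class = 40, seed = 42, gap = 4) {
  set.seed(seed)
  x1 <- c(rnorm(n_per_class, -gap / 2), rnorm(n_per_class, gap / 2))
  x2 <- c(rnorm(n_per_class, gap / 2), rnorm(n_per_class, -gap / 2))
  out <- data.frame(f1 = x1, f2 = x2,
                    label = rep(c(0L, 1L), each = n_per_class))
  class(out) <- c("feature_table", "data.frame")
  out
}

# brute-force cell assignment by scanning every cell's bounding box,
# [west, east) x (south, north]
brute_force_cell <- function(grid, lon, lat) {
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  for (r in seq_len(nr)) {
    north <- grid$ymax - (r - 1) * abs(grid$dy)
    south <- grid$ymax - r * abs(grid$dy)
    for (c in seq_len(nc)) {
      west <- grid$xmin + (c - 1) * grid$dx
      east <- grid$xmin + c * grid$dx
      if (lon >= west && lon < east && lat > south && lat <= north) {
        return(c(r, c))
      }
    }
  }
  c(NA_integer_, NA_integer_)
}

# all-pairs AUC oracle: (wins + half ties) / (n1 * n0)
brute_force_auc <- function(scores, labels) {
  s1 <- scores[labels == 1]; s0 <- scores[labels == 0]
  cmp <- outer(s1, s0, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# exhaustive-threshold TSS oracle
brute_force_tss <- function(scores, labels) {
  thr <- sort(unique(c(0, 1, scores)))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  vals <- sapply(thr, function(t) {
    sum(scores >= t & labels == 1) / n1 +
      sum(scores < t & labels == 0) / n0 - 1
  })
  list(tss = max(vals), threshold = thr[which(vals == max(vals))[1]])
}

# VIF oracle by explicit normal-equations least squares
brute_force_vif <- function(x) {
  x <- as.matrix(x)
  sapply(seq_len(ncol(x)), function(j) {
    y <- x[, j]
    d <- cbind(1, x[, -j, drop = FALSE])
    beta <- solve(crossprod(d), crossprod(d, y))
    rss <- sum((y - d %*% beta)^2)
    1 / (1 - (1 - rss / sum((y - mean(y))^2)))
  })
}
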