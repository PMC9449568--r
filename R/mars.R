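# Adaptive regression spline classifier.
#
# A compact hinge-basis learner in the MARS family: a forward pass greedily
# adds reflected hinge pairs max(x - t, 0) / max(t - x, 0) chosen by the
# residual variance they explain, a backward pass prunes terms by
# generalised cross-validation (GCV), and the surviving basis is refit as a
# binomial GLM so predictions are calibrated probabilities. Fully
# deterministic: candidate knots are quantiles of each predictor.

hinge <- function(x, knot, dir) {
  if (dir > 0) pmax(x - knot, 0) else pmax(knot - x, 0)
}

mars_basis <- function(x, terms) {
  n <- nrow(x)
  b <- matrix(1, n, 1L + length(terms))
  for (i in seq_along(terms)) {
    tm <- terms[[i]]
    b[, i + 1L] <- hinge(x[, tm$var], tm$knot, tm$dir)
  }
  b
}

mars_gcv <- function(rss, n, n_terms, penalty = 3) {
  # effective parameters: one per basis column plus a knot-selection charge
  c_m <- n_terms + penalty * (n_terms - 1) / 2
  if (c_m >= n) return(Inf)
  (rss / n) / (1 - c_m / n)^2
}

fit_mars <- function(x, y, max_pairs = 8L, n_knots = 15L, penalty = 3,
                     min_gain = 1e-6) {
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  vars <- colnames(x)
  # candidate knots: interior quantiles per predictor
  probs <- seq(0.05, 0.95, length.out = n_knots)
  knots <- lapply(seq_len(p), function(j) unique(stats::quantile(x[, j], probs,
                                                                 names = FALSE)))
  terms <- list()
  b <- matrix(1, n, 1)
  qr_fit <- stats::lm.fit(b, y)
  res <- qr_fit$residuals
  for (step in seq_len(max_pairs)) {
    best <- list(gain = 0)
    res_ss <- sum(res^2)
    if (res_ss < 1e-12) break
    for (j in seq_len(p)) {
      xj <- x[, j]
      for (t in knots[[j]]) {
        h1 <- pmax(xj - t, 0); h2 <- pmax(t - xj, 0)
        # variance of the residual explained by the centred hinge pair
        h <- cbind(h1 - mean(h1), h2 - mean(h2))
        g <- crossprod(h)           # 2x2
        rhs <- crossprod(h, res)
        det_g <- g[1, 1] * g[2, 2] - g[1, 2]^2
        expl <- if (det_g > 1e-10 * max(g[1, 1], g[2, 2], 1)^2) {
          beta <- solve(g, rhs)
          sum(rhs * beta)
        } else if (g[1, 1] > 0) rhs[1]^2 / g[1, 1] else 0
        if (expl > best$gain) best <- list(gain = expl, var = vars[j], knot = t)
      }
    }
    if (best$gain < min_gain * res_ss) break
    terms <- c(terms, list(list(var = best$var, knot = best$knot, dir = 1),
                           list(var = best$var, knot = best$knot, dir = -1)))
    b <- mars_basis(x, terms)
    qr_fit <- stats::lm.fit(b, y)
    res <- qr_fit$residuals
  }
  # backward pruning by GCV
  repeat {
    b <- mars_basis(x, terms)
    fit <- stats::lm.fit(b, y)
    gcv_now <- mars_gcv(sum(fit$residuals^2), n, ncol(b), penalty)
    if (!length(terms)) break
    gcv_del <- vapply(seq_along(terms), function(i) {
      bi <- mars_basis(x, terms[-i])
      mars_gcv(sum(stats::lm.fit(bi, y)$residuals^2), n, ncol(bi), penalty)
    }, numeric(1))
    if (min(gcv_del) < gcv_now) {
      terms <- terms[-which.min(gcv_del)]
    } else break
  }
  # binomial refit of the selected basis for probability output
  b <- mars_basis(x, terms)
  coefs <- tryCatch({
    g <- suppressWarnings(stats::glm.fit(b, y,
                                         family = stats::binomial()))
    cf <- g$coefficients
    cf[!is.finite(cf)] <- 0
    cf
  }, error = function(e) NULL)
  if (is.null(coefs)) {
    # fall back to the least-squares fit on the probability scale
    cf <- stats::lm.fit(b, y)$coefficients
    cf[!is.finite(cf)] <- 0
    coefs <- cf
    link <- "identity"
  } else link <- "logit"
  structure(list(terms = terms, coefficients = coefs, link = link,
                 feature_names = vars),
            class = "mars_fit")
}

predict_mars <- function(object, x) {
  b <- mars_basis(as.matrix(x), object$terms)
  eta <- drop(b %*% object$coefficients)
  if (object$link == "logit") stats::plogis(eta) else pmin(1, pmax(0, eta))
}
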