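mk_counts <- function(means, n = 60, seed = 1) {
  set.seed(seed)
  out <- lapply(means, function(m) stats::rpois(n, m))
  names(out) <- names(means)
  out
}

test_that("rCTI hits its boundary values on constructed populations", {
  dirs <- as.character(BJ_DIRS)   # cat1: 75,135,195; cat2: 255,315,15
  # identical distributions everywhere: no discriminability difference
  flat <- mk_counts(stats::setNames(rep(10, 6), dirs), seed = 2)
  expect_lt(abs(rcti(flat)), 0.06)
  # perfect across-category separation, none within: rCTI = +0.5
  cat_resp <- stats::setNames(c(0, 200, 200, 200, 0, 0), dirs)  # by category
  across <- lapply(cat_resp, function(m) rep(m, 30))
  expect_equal(rcti(across), 0.5)
  # perfect separation of within-category neighbors with identical
  # responses across the boundary: rCTI = -0.5
  within_resp <- stats::setNames(c(0, 0, 100, 200, 200, 300), dirs)
  within <- lapply(within_resp, function(m) rep(m, 30))
  expect_equal(rcti(within), -0.5)
  # bounded on arbitrary inputs
  set.seed(3)
  for (rep in 1:10) {
    rnd <- mk_counts(stats::setNames(stats::runif(6, 1, 30), dirs),
                     n = 20, seed = rep)
    v <- rcti(rnd)
    expect_gte(v, -0.5); expect_lte(v, 0.5)
  }
  expect_error(rcti(flat[c("75", "255", "315", "15")]), "two directions")
})

test_that("rDSI is shuffle-corrected direction selectivity", {
  dirs <- as.character(BJ_DIRS)
  # direction-blind cell: near zero after correction
  flat <- mk_counts(stats::setNames(rep(8, 6), dirs), seed = 4)
  expect_lt(abs(rdsi(flat, n_shuffles = 50)), 0.15)
  # strong within-category two-direction separation: near 0.5
  tuned <- lapply(stats::setNames(c(5, 0, 200, 5, 5, 5), dirs),
                  function(m) rep(m, 40))
  expect_gt(rdsi(tuned, n_shuffles = 50), 0.4)
  # the correction subtracts a nonnegative bias in expectation
  raw_stat <- function(cbd) {
    cats <- direction_category(as.numeric(names(cbd)))
    best <- 0
    for (i in 1:5) for (j in (i + 1):6)
      if (cats[i] == cats[j])
        best <- max(best, abs(popGMLM:::auc_counts(cbd[[i]], cbd[[j]]) - 0.5))
    best
  }
  expect_lte(rdsi(flat, n_shuffles = 50), raw_stat(flat) + 1e-12)
})

test_that("tuning-curve fits recover cosine tuning and the peak-to-trough magnitude", {
  set.seed(5)
  th <- rep(BJ_DIRS, each = 80)
  amp <- 0.6
  # tune along the boundary axis (45 deg), which is orthogonal to the
  # category code over this direction set; any other phase aliases into
  # beta_cat because category and direction are correlated in the task
  lam <- exp(log(10) + amp * cos((th - 45) * pi / 180))
  y <- stats::rpois(length(th), lam)
  fit <- fit_tuning_curve(y, th, n_shuffles = 40)
  expect_lt(abs(fit$coef["beta_cat"]), 0.25)
  expect_lt(abs(fit$raw["direction"] - 2 * amp), 0.2)
  # peak-to-trough magnitude equals the analytic maximization of the
  # cosine part over a fine angle grid
  b <- fit$coef
  grid <- seq(0, 359.9, by = 0.1) * pi / 180
  f <- b["beta_sin"] * sin(grid) + b["beta_cos"] * cos(grid)
  expect_equal(max(f - (b["beta_sin"] * sin(grid + pi) +
                        b["beta_cos"] * cos(grid + pi))),
               unname(2 * sqrt(b["beta_sin"]^2 + b["beta_cos"]^2)),
               tolerance = 1e-6)
  # flat data: shuffle-corrected magnitudes near zero
  yflat <- stats::rpois(length(th), 10)
  fit0 <- fit_tuning_curve(yflat, th, n_shuffles = 40)
  expect_lt(abs(fit0$category_magnitude), 0.1)
  expect_lt(abs(fit0$direction_magnitude), 0.2)
})

test_that("beta-binomial performance matches the closed form", {
  p0 <- beta_binomial_performance(0, 0)
  expect_equal(p0$mean, 0.5)
  p1 <- beta_binomial_performance(20, 20)
  expect_equal(p1$mean, 21 / 22)
  p2 <- beta_binomial_performance(37, 50)
  expect_equal(p2$mean, 38 / 52)
  expect_equal(p2$lo, qbeta(0.005, 38, 14))
  expect_equal(p2$hi, qbeta(0.995, 38, 14))
  expect_lt(p2$lo, p2$mean); expect_gt(p2$hi, p2$mean)
  # frequentist coverage of the 99% interval is near nominal
  set.seed(6)
  p_true <- 0.8; n <- 120
  cover <- mean(vapply(1:800, function(i) {
    k <- stats::rbinom(1, n, p_true)
    ci <- beta_binomial_performance(k, n)
    ci$lo <= p_true && p_true <= ci$hi
  }, TRUE))
  expect_gt(cover, 0.96)
})

test_that("bootstrap error bars are reproducible under a fixed seed", {
  dirs <- as.character(BJ_DIRS)
  cbd <- mk_counts(stats::setNames(c(4, 10, 16, 10, 4, 2), dirs), seed = 7)
  b1 <- bootstrap_metric(cbd, rcti, n_boot = 100, seed = 3)
  b2 <- bootstrap_metric(cbd, rcti, n_boot = 100, seed = 3)
  expect_identical(b1$boot, b2$boot)
  expect_lte(b1$ci99[1], b1$ci99[2])
  expect_equal(b1$estimate, rcti(cbd))
})
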