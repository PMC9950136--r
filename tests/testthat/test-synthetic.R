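test_that("ground truths are reproducible and template structure holds", {
  t1 <- sample_ground_truth("mixed", N = 5, rank = 2, seed = 1)
  t2 <- sample_ground_truth("mixed", N = 5, rank = 2, seed = 1)
  expect_identical(t1$params, t2$params)
  t3 <- sample_ground_truth("mixed", N = 5, rank = 2, seed = 2)
  expect_false(identical(t1$params$V_stim, t3$params$V_stim))
  # category_axis: category vector dominates the direction ellipse
  tc <- sample_ground_truth("category_axis", N = 8, rank = 2, seed = 3)
  U <- tc$params$U_stim
  expect_gt(mean(abs(U["cs1", ] - U["cs2", ])),
            3 * mean(sqrt(U["cos", ]^2 + U["sin", ]^2)))
  # circular_direction: no category offset, tuned in cos/sin
  tr <- sample_ground_truth("circular_direction", N = 8, rank = 2, seed = 4)
  expect_equal(tr$params$U_stim["cs1", ], tr$params$U_stim["cs2", ])
  expect_gt(min(sqrt(tr$params$U_stim["cos", ]^2 +
                     tr$params$U_stim["sin", ]^2)), 0)
  # categoryless: flat stimulus weights
  t0 <- sample_ground_truth("categoryless", N = 4, rank = 1, seed = 5)
  expect_true(all(t0$params$U_stim == 0))
})

test_that("simulated spiking matches its generative rate and dispersion", {
  truth <- sample_ground_truth("categoryless", N = 2, rank = 1, seed = 6,
                               schedule = task_schedule(touch_bar = "none"))
  ds1 <- simulate_trials(truth, 30, seed = 7)
  ds2 <- simulate_trials(truth, 30, seed = 7)
  expect_identical(ds1$trials[[5]]$counts, ds2$trials[[5]]$counts)
  ds3 <- simulate_trials(truth, 30, seed = 8)
  expect_false(identical(ds1$trials[[5]]$counts, ds3$trials[[5]]$counts))
  # baseline-only truth: empirical rate near exp(w), Fano factor near 1
  for (n in 1:2) {
    idx <- vapply(ds1$trials, function(tr)
      tr$neuron == sprintf("n%02d", n), TRUE)
    cnt <- unlist(lapply(ds1$trials[idx], `[[`, "counts"))
    rate <- mean(cnt) / ds1$bin_width
    expect_lt(abs(rate - exp(truth$params$w[n])) /
                exp(truth$params$w[n]), 0.1)
    expect_lt(abs(var(cnt) / mean(cnt) - 1), 0.1)   # Poisson dispersion
  }
})

test_that("refractory spike history suppresses short interspike intervals", {
  truth <- sample_ground_truth("categoryless", N = 1, rank = 1, seed = 9,
                               schedule = task_schedule(touch_bar = "none"),
                               include_history = TRUE)
  truth$params$w[] <- log(40)        # high rate makes short ISIs common
  ds <- simulate_trials(truth, 25, seed = 10)
  isi <- function(tr) diff(which(tr$counts > 0))
  isis <- unlist(lapply(ds$trials, isi))
  # compare with a history-free control at the same baseline
  ctrl <- truth
  ctrl$model$include_history <- FALSE
  ctrl$params$H_spk <- NULL
  ds0 <- simulate_trials(ctrl, 25, seed = 10)
  isis0 <- unlist(lapply(ds0$trials, isi))
  expect_lt(mean(isis <= 2), 0.5 * mean(isis0 <= 2))
})

test_that("recovery reports zero error at truth, ~90 deg for random spaces", {
  truth <- tiny_truth(N = 10, rank = 2, seed = 11)
  rep0 <- recovery_report(truth, truth$params)
  expect_equal(rep0$tensor_rel_error, 0, tolerance = 1e-12)
  expect_lt(max(rep0$principal_angles_deg), 1e-5)
  set.seed(12)
  # unrelated loadings in high dimension: angles near 90 degrees
  big <- sample_ground_truth("mixed", N = 120, rank = 2, seed = 13)
  rnd <- big$params
  rnd$V_stim <- matrix(rnorm(120 * 2), 120)
  repr <- recovery_report(big, rnd)
  expect_gt(min(repr$principal_angles_deg), 60)
})

test_that("match trials get touch-bar releases inside the configured range", {
  truth <- sample_ground_truth("mixed", N = 2, rank = 1, seed = 14,
                               schedule = task_schedule())   # uniform RT
  ds <- simulate_trials(truth, 20, seed = 15)
  is_match <- vapply(ds$trials, function(tr)
    identical(tr$c_sample, tr$c_test), TRUE)
  has_tb <- !vapply(ds$trials, function(tr) is.na(tr$t_tbar), TRUE)
  expect_equal(is_match, has_tb)
  rt <- vapply(ds$trials[has_tb], function(tr)
    (tr$t_tbar - tr$t_test_on) * ds$bin_width, 0)
  expect_true(all(rt >= 0.2 - 1e-9 & rt <= 0.5 + 1e-9))
  # trial end 50 ms after release (or after test offset when no release)
  lens <- vapply(ds$trials, function(tr) length(tr$counts), 0L)
  ends_tb <- vapply(ds$trials[has_tb], function(tr)
    length(tr$counts) - tr$t_tbar, 0L)
  expect_true(all(ends_tb == 10L))
})
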