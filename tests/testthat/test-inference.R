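test_that("leapfrog trajectory length follows S = min(100, ceil(1/eps))", {
  lp_gauss <- function(q) list(lp = -sum(q^2) / 2, grad = -q)
  set.seed(1)
  s1 <- leapfrog_hmc_step(rnorm(3), lp_gauss, eps = 0.01, mass_diag = rep(1, 3))
  expect_equal(s1$n_steps, 100)
  s2 <- leapfrog_hmc_step(rnorm(3), lp_gauss, eps = 0.5, mass_diag = rep(1, 3))
  expect_equal(s2$n_steps, 2)
})

test_that("HMC samples a standard normal target", {
  lp_gauss <- function(q) list(lp = -sum(q^2) / 2, grad = -q)
  set.seed(2)
  q <- rnorm(2)
  draws <- matrix(0, 3000, 2)
  for (i in seq_len(3000)) {
    st <- leapfrog_hmc_step(q, lp_gauss, eps = 0.4, mass_diag = rep(1, 2))
    q <- st$q
    draws[i, ] <- q
  }
  expect_lt(max(abs(colMeans(draws))), 0.08)
  expect_true(all(apply(draws, 2, var) > 0.85 & apply(draws, 2, var) < 1.15))
  # energy error vanishes as eps -> 0 on the quadratic potential
  err <- vapply(c(0.4, 0.1, 0.025), function(e) {
    set.seed(3)
    st <- leapfrog_hmc_step(rnorm(2), lp_gauss, e, rep(1, 2))
    1 - st$accept_stat
  }, 0)
  expect_true(all(diff(err) <= 1e-6))
})

test_that("dual averaging moves the step size toward the target", {
  da <- dual_averaging_init(0.1, target = 0.8)
  for (i in 1:50) da <- dual_averaging_update(da, 1)   # always accepted
  expect_gt(exp(da$logeps), 0.1)
  da2 <- dual_averaging_init(0.1, target = 0.8)
  for (i in 1:50) da2 <- dual_averaging_update(da2, 0)  # always rejected
  expect_lt(exp(da2$logeps), 0.1)
})

test_that("mass matrix updates use inverse window variances", {
  set.seed(4)
  W <- cbind(rnorm(500, 0, 2), rnorm(500, 0, 0.5))
  md <- mass_from_window(W)
  expect_equal(md[1], 1 / var(W[, 1]))
  expect_equal(md[2], 1 / var(W[, 2]))
  expect_warning(mass_from_window(cbind(rep(1, 100), rnorm(100))), "variance")
})

test_that("MH rescaling preserves the component product norm exactly", {
  set.seed(5)
  for (rep in 1:20) {
    u <- runif(1, 0.2, 3); t <- runif(1, 0.2, 3); v <- runif(1, 0.2, 3)
    mv <- mh_rescale_component(u, t, v, eta_u = 1.3, eta_t = 1, eta_v = 1,
                               df_u = 6, df_t = 24, df_v = 10,
                               omega = 0.2, n_steps = 10)
    u2 <- u * mv$scale_u; t2 <- t * mv$scale_t
    v2 <- v / (mv$scale_u * mv$scale_t)
    expect_equal(u2 * t2 * v2, u * t * v, tolerance = 1e-12)
  }
})

test_that("a reduced sampler run is reproducible and mixes on a tiny model", {
  truth <- tiny_truth(N = 3, rank = 1, seed = 4)
  ds <- simulate_trials(truth, 8, 5)
  cfg <- sampler_config(n_warmup = 250, n_samples = 250, seed = 6)
  s1 <- run_sampler(ds, truth$model, cfg)
  s2 <- run_sampler(ds, truth$model, cfg)
  expect_identical(s1$draws, s2$draws)          # same seed, same chain
  expect_equal(nrow(s1$draws), 250)
  expect_true(all(hyper_draws(s1) > 0))
  expect_gt(mean(s1$accept), 0.5)
  # baselines are well identified: posterior covers the truth
  w_draws <- s1$draws[, 1:3]
  for (n in 1:3) {
    qs <- quantile(w_draws[, n], c(0.005, 0.995))
    expect_gt(truth$params$w[n], qs[1] - 0.3)
    expect_lt(truth$params$w[n], qs[2] + 0.3)
  }
})

test_that("MAP at posterior-median hyperparameters maximizes the posterior", {
  truth <- tiny_truth(N = 3, rank = 1, seed = 7)
  ds <- simulate_trials(truth, 8, 8)
  cfg <- sampler_config(n_warmup = 200, n_samples = 200, seed = 9)
  s <- run_sampler(ds, truth$model, cfg)
  fit <- map_with_median_hypers(ds, s, maxit = 300)
  # the optimum beats every stored draw's parameters at those hypers
  data <- prepare_pop_data(ds, truth$model)
  lp_at <- function(vec) gmlm_log_posterior(
    unpack_params(vec[seq_len(s$n_param)], truth$model), fit$hyper, data,
    truth$model, log_scale_hypers = FALSE)$lp
  draw_lps <- vapply(seq(1, 200, by = 20), function(i)
    lp_at(s$draws[i, ]), 0)
  expect_gte(fit$logpost + 1e-6, max(draw_lps))
})

test_that("PSIS-LOO separates a well-specified model from a noise-inflated one", {
  truth <- tiny_truth(N = 3, rank = 1, seed = 11)
  ds <- simulate_trials(truth, 10, 12)
  cfg <- sampler_config(n_warmup = 300, n_samples = 300, seed = 13)
  s <- run_sampler(ds, truth$model, cfg)
  loo <- suppressWarnings(psis_loo(s, ds, thin = 5))
  expect_length(loo$lp_neuron, 3)
  expect_true(all(is.finite(loo$elpd_trial)))
  # corrupt the draws by inflating every loading: predictive density drops
  s_bad <- s
  vcols <- s$n_param - (2:0)   # V_stim block is last in the packed layout
  s_bad$draws[, vcols] <- 3 * s_bad$draws[, vcols]
  loo_bad <- suppressWarnings(psis_loo(s_bad, ds, thin = 5))
  expect_gt(sum(loo$elpd_trial), sum(loo_bad$elpd_trial))
})

test_that("PSIS smoothing matches plain importance sampling on light tails", {
  set.seed(14)
  lr <- rnorm(4000, 0, 0.1)    # light-tailed log ratios
  sm <- psis_smooth(lr)
  expect_lt(sm$pareto_k, 0.5)
  w1 <- exp(sm$log_weights - max(sm$log_weights))
  w0 <- exp(lr - max(lr))
  expect_lt(abs(sum(w1 * lr) / sum(w1) - sum(w0 * lr) / sum(w0)), 0.01)
})
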