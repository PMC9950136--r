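test_that("GMLM log rate: rank 0, delta convolution, GLM equivalence", {
  bases <- default_bases()
  spec <- design_spec("cosine")
  tr <- new_trial("n1", stats::rpois(480, 0.05), 1L, 331L, 75, 255, 420L)
  # rank 0 reduces to baseline + history + touch-bar
  m0 <- gmlm_model(spec, 2, 0, bases, rank_tbar = 0, include_tbar = FALSE,
                   include_history = FALSE)
  p0 <- gmlm_params(m0, w = c(0.7, -0.2))
  expect_equal(gmlm_log_rate(p0, tr, m0, 2), rep(-0.2, 480))
  # rank 1, U one-hot on cs1, unit loading: T kernel shifted to sample onset
  m1 <- gmlm_model(spec, 1, 1, bases, rank_tbar = 0, include_tbar = FALSE,
                   include_history = FALSE)
  set.seed(3)
  Tc <- matrix(stats::rnorm(24), 24, 1)
  U <- matrix(0, 6, 1, dimnames = list(spec$labels, NULL)); U["cs1", 1] <- 1
  p1 <- gmlm_params(m1, w = 0, T_stim = Tc, U_stim = U,
                    V_stim = matrix(1, 1, 1))
  tr1 <- new_trial("n1", integer(480), 5L, 331L, 75, 255, NA)  # 75 = cat 1
  lam <- gmlm_log_rate(p1, tr1, m1, 1)
  kern <- drop(bases$stim$B %*% Tc)
  expect_equal(lam[5:(4 + length(kern))], kern)
  # random instance equals a per-neuron GLM built from the CP kernel fibers
  m <- gmlm_model(spec, 3, 2, bases, rank_tbar = 2)
  p <- init_gmlm_params(m, 4, w_center = log(8))
  Kc <- kernel_tensor(p, m, time_domain = FALSE)
  for (n in 1:3) {
    gp <- glm_params(w = p$w[n], stim_coeffs = Kc[, , n],
                     h_coeffs = p$H_spk[, n],
                     tbar_coeffs = drop(p$T_tbar %*% p$V_tbar[n, ]))
    expect_lt(max(abs(gmlm_log_rate(p, tr, m, n) -
                      glm_log_rate(gp, tr, spec, bases))), 1e-8)
  }
})

test_that("kernel tensor is an exact CP reconstruction, rescale-invariant", {
  bases <- default_bases()
  spec <- design_spec("cosine")
  m <- gmlm_model(spec, 4, 2, bases, include_history = FALSE,
                  include_tbar = FALSE)
  p <- init_gmlm_params(m, 5)
  K <- kernel_tensor(p, m)
  # brute-force triple loop
  Tm <- bases$stim$B %*% p$T_stim
  for (idx in list(c(3, 2, 1), c(100, 5, 4), c(250, 6, 2))) {
    expect_equal(unname(K[idx[1], idx[2], idx[3]]),
                 sum(Tm[idx[1], ] * p$U_stim[idx[2], ] * p$V_stim[idx[3], ]))
  }
  # rescaling (a = 2, b = 3, V / 6) leaves the tensor unchanged
  p2 <- p
  p2$U_stim[, 1] <- 2 * p2$U_stim[, 1]
  p2$T_stim[, 1] <- 3 * p2$T_stim[, 1]
  p2$V_stim[, 1] <- p2$V_stim[, 1] / 6
  expect_lt(max(abs(kernel_tensor(p2, m) - K)), 1e-12)
})

test_that("dynamic spike history multiplies gain and filtered history", {
  bases <- default_bases()
  spec <- design_spec("cosine")
  m <- gmlm_model(spec, 2, 1, bases, rank_tbar = 1, dyn_rank = 2,
                  dyn_rank_tbar = 1)
  p <- init_gmlm_params(m, 6, w_center = log(10))
  tr <- new_trial("n1", stats::rpois(480, 0.08), 1L, 331L, 75, 255, 420L)
  # zero factors or an empty spike train give zero contribution
  pz <- p
  for (nm in names(pz$dyn)) pz$dyn[[nm]][] <- 0
  expect_true(all(dynamic_history_log_rate(pz, tr, m, 1) == 0))
  tr0 <- new_trial("n1", integer(480), 1L, 331L, 75, 255, 420L)
  expect_true(all(dynamic_history_log_rate(p, tr0, m, 1) == 0))
  # two-pass oracle: gains and filtered history computed independently
  Hmat <- popGMLM:::history_design(tr$counts, bases$spk)
  Ms <- popGMLM:::shift_design(bases$stim, tr$t_sample_on, 480)
  Mt <- popGMLM:::shift_design(bases$stim, tr$t_test_on, 480)
  Mtb <- popGMLM:::shift_design(bases$tbar, tr$t_tbar, 480)
  d <- p$dyn
  n <- 2
  oracle <- numeric(480)
  for (r in 1:2) {
    gain <- d$U_dspk[1, r] * drop(Ms %*% d$T_dspk[, r]) +
      d$U_dspk[2, r] * drop(Mt %*% d$T_dspk[, r])
    oracle <- oracle + gain * drop(Hmat %*% d$H_dspk[, r]) * d$V_dspk[n, r]
  }
  oracle <- oracle + drop(Mtb %*% d$T_bdspk[, 1]) *
    drop(Hmat %*% d$H_bdspk[, 1]) * d$V_bdspk[n, 1]
  expect_lt(max(abs(dynamic_history_log_rate(p, tr, m, n) - oracle)), 1e-10)
  # doubling the loading doubles the stimulus-locked dynamic part
  p3 <- pz
  p3$dyn$H_dspk <- p$dyn$H_dspk; p3$dyn$T_dspk <- p$dyn$T_dspk
  p3$dyn$U_dspk <- p$dyn$U_dspk; p3$dyn$V_dspk <- p$dyn$V_dspk
  h1 <- dynamic_history_log_rate(p3, tr, m, n)
  p3$dyn$V_dspk <- 2 * p3$dyn$V_dspk
  expect_equal(dynamic_history_log_rate(p3, tr, m, n), 2 * h1)
})

test_that("the effective history kernel reproduces the dynamic log rate", {
  bases <- default_bases()
  spec <- design_spec("cosine")
  m <- gmlm_model(spec, 2, 1, bases, rank_tbar = 1, dyn_rank = 1,
                  dyn_rank_tbar = 1)
  p <- init_gmlm_params(m, 8, w_center = log(10))
  tr <- new_trial("n1", stats::rpois(480, 0.08), 1L, 331L, 75, 255, 420L)
  # with dynamic gains zeroed the effective kernel is the constant one
  pz <- p
  for (nm in names(pz$dyn)) pz$dyn[[nm]][] <- 0
  expect_equal(effective_history_kernel(pz, tr, m, 1, 200),
               drop(bases$spk$B %*% p$H_spk[, 1]))
  # convolving the spike train with the time-t effective kernel reproduces
  # the constant + dynamic history contribution at time t
  n <- 1
  Hmat <- popGMLM:::history_design(tr$counts, bases$spk)
  hconst <- drop(Hmat %*% p$H_spk[, n])
  hdyn <- dynamic_history_log_rate(p, tr, m, n)
  Bspk <- bases$spk$B
  for (t in c(150, 340, 425)) {
    keff <- effective_history_kernel(p, tr, m, n, t)
    contrib <- 0
    for (u in 2:nrow(Bspk)) {   # lag u-1 bins
      src <- t - (u - 1)
      if (src >= 1) contrib <- contrib + keff[u] * tr$counts[src]
    }
    expect_equal(contrib, hconst[t] + hdyn[t], tolerance = 1e-10)
  }
})

test_that("population log posterior: additivity and neuron independence", {
  spec <- design_spec("cosine")
  truth <- tiny_truth(N = 3, rank = 1, seed = 2)
  ds <- simulate_trials(truth, 4, 3)
  m <- truth$model
  p <- init_gmlm_params(m, 9, w_center = log(8))
  # population ll equals the sum of single-neuron evaluations
  ll_pop <- gmlm_log_likelihood(p, ds, m)
  nm <- vapply(ds$trials, function(tr) as.character(tr$neuron), "")
  ll_sum <- sum(vapply(seq_along(ds$trials), function(i)
    gmlm_trial_loglik(p, ds$trials[[i]], m,
                      match(nm[i], as.character(ds$neuron_ids))), 0))
  expect_equal(ll_pop, ll_sum, tolerance = 1e-10)
  # duplicating the data doubles the likelihood but not the prior
  h <- default_hyper(spec, FALSE, FALSE)
  d1 <- prepare_pop_data(ds, m)
  ds2 <- trial_dataset(c(ds$trials, ds$trials),
                       neuron_ids = ds$neuron_ids)
  d2 <- prepare_pop_data(ds2, m)
  lp1 <- gmlm_log_posterior(p, h, d1, m)$lp
  lp2 <- gmlm_log_posterior(p, h, d2, m)$lp
  prior_part <- lp1 - gmlm_ll_grad(p, d1, m, FALSE)$ll
  expect_equal(lp2 - prior_part, 2 * (lp1 - prior_part), tolerance = 1e-8)
})
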