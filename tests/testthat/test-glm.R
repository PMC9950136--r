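test_that("GLM log rate reduces to known cases and a brute-force convolution", {
  bases <- default_bases()
  spec <- design_spec("cosine")
  tr <- new_trial("n1", stats::rpois(480, 0.05), 1L, 331L, 75, 255, 420L)
  # zero kernels: lambda == w everywhere
  p0 <- glm_params(w = 1.3, stim_coeffs = matrix(0, 24, 6),
                   h_coeffs = numeric(10), tbar_coeffs = numeric(8))
  expect_equal(glm_log_rate(p0, tr, spec, bases), rep(1.3, 480))
  # one nonzero kernel with a sample impulse: kernel shifted to onset
  set.seed(5)
  K <- matrix(0, 24, 6)
  K[, 1] <- stats::rnorm(24)   # cs1 kernel; sample is category 1 (75 deg)
  p1 <- glm_params(w = 0, stim_coeffs = K)
  tr1 <- new_trial("n1", integer(480), 10L, 331L, 75, 255, NA)
  lam <- glm_log_rate(p1, tr1, spec, bases)
  kern <- drop(bases$stim$B %*% K[, 1])
  expect_equal(lam[10:(9 + length(kern))], kern)
  expect_true(all(lam[1:9] == 0))
  # random parameters match an explicit O(T^2) convolution of every stream
  p2 <- glm_params(w = 0.4, stim_coeffs = matrix(stats::rnorm(24 * 6, 0, .3), 24),
                   h_coeffs = stats::rnorm(10, 0, .2),
                   tbar_coeffs = stats::rnorm(8, 0, .3))
  lam2 <- glm_log_rate(p2, tr, spec, bases)
  reg <- trial_regressors(tr, spec)
  T_ <- 480
  brute <- rep(p2$w, T_)
  conv_at <- function(kern_td, stream, lag0 = 1L) {
    out <- numeric(T_)
    for (t in seq_len(T_)) for (u in seq_along(kern_td)) {
      src <- t - (u - lag0)
      if (src >= 1 && src <= T_) out[t] <- out[t] + kern_td[u] * stream[src]
    }
    out
  }
  for (s in 1:6) {
    stream <- reg$x_dir_sample[s] * reg$x_timing_sample +
      reg$x_dir_test[s] * reg$x_timing_test
    brute <- brute + conv_at(drop(bases$stim$B %*% p2$stim_coeffs[, s]), stream)
  }
  brute <- brute + conv_at(drop(bases$tbar$B %*% p2$tbar_coeffs), reg$x_tbar,
                           bases$tbar$lag0)
  brute <- brute + conv_at(drop(bases$spk$B %*% p2$h_coeffs),
                           as.numeric(tr$counts))
  expect_lt(max(abs(lam2 - brute)), 1e-10)
})

test_that("GLM log likelihood equals the Poisson pmf sum", {
  bases <- default_bases()
  spec <- design_spec("none")
  # y = 0 everywhere, lambda = 0: ll = -Delta * T
  tr0 <- new_trial("n1", integer(200), 1L, 120L, 75, 255, NA)
  p0 <- glm_params(w = 0, stim_coeffs = matrix(0, 24, 2))
  expect_equal(glm_trial_loglik(p0, tr0, spec, bases, 0.005), -0.005 * 200)
  # arbitrary small case vs dpois reference
  set.seed(6)
  tr <- new_trial("n1", stats::rpois(200, 0.4), 1L, 120L, 75, 255, 150L)
  p <- glm_params(w = log(30), stim_coeffs = matrix(stats::rnorm(48, 0, .3), 24),
                  h_coeffs = stats::rnorm(10, 0, .1),
                  tbar_coeffs = stats::rnorm(8, 0, .2))
  lam <- glm_log_rate(p, tr, spec, bases)
  ref <- sum(stats::dpois(tr$counts, exp(lam) * 0.005, log = TRUE))
  expect_equal(glm_trial_loglik(p, tr, spec, bases, 0.005), ref,
               tolerance = 1e-10)
})

test_that("structured priors match their latent-sum constructions", {
  # circular GP kernel boundary values
  expect_equal(gp_direction_kernel(30, 30, tau = 2)[1, 1], 1)
  expect_equal(gp_direction_kernel(0, 180, tau = 2)[1, 1], 0)
  # no-tuning model: shared latent induces the sample/test correlation
  h <- list(psi_0 = 0.8, psi_s = 0.5)
  pr <- build_prior(design_spec("none"), h)
  expect_equal(pr$Sigma_stim[1, 2], 0.8^2)
  expect_equal(pr$Sigma_stim[1, 1], 0.8^2 + 0.5^2)
  # Monte-Carlo covariance of the sampled latent-sum construction (cosine)
  hc <- list(psi_0 = 0.7, psi_c = 0.4, psi_d = 1.2)
  prc <- build_prior(design_spec("cosine"), hc)
  set.seed(7)
  nmc <- 2e5
  b0 <- stats::rnorm(nmc, 0, hc$psi_0)
  draws <- cbind(b0 + stats::rnorm(nmc, 0, hc$psi_c),
                 b0 + stats::rnorm(nmc, 0, hc$psi_c),
                 b0 + stats::rnorm(nmc, 0, hc$psi_c),
                 b0 + stats::rnorm(nmc, 0, hc$psi_c),
                 stats::rnorm(nmc, 0, hc$psi_d),
                 stats::rnorm(nmc, 0, hc$psi_d))
  expect_lt(max(abs(stats::cov(draws) - prc$Sigma_stim)), 0.02)
  # full model: GP term appears on the direction kernels
  hf <- list(psi_0 = 0.5, psi_c = 0.5, psi_d = 0.5, psi_theta = 1, tau = 1)
  prf <- build_prior(design_spec("full"), hf)
  expect_true(all(eigen(prf$Sigma_stim, symmetric = TRUE,
                        only.values = TRUE)$values > -1e-10))
  set.seed(8)
  spec_f <- design_spec("full")
  th <- spec_f$direction_set
  Kgp <- gp_direction_kernel(th, tau = hf$tau)
  ch <- chol(Kgp + diag(1e-10, 6))
  cats <- direction_category(th)
  mc <- matrix(0, 8, 8)
  nmc <- 1e5
  g0 <- stats::rnorm(nmc, 0, hf$psi_0)
  gcs <- matrix(stats::rnorm(nmc * 2, 0, hf$psi_c), nmc)
  gct <- matrix(stats::rnorm(nmc * 2, 0, hf$psi_c), nmc)
  gco <- stats::rnorm(nmc, 0, hf$psi_d); gsi <- stats::rnorm(nmc, 0, hf$psi_d)
  ggp <- matrix(stats::rnorm(nmc * 6), nmc) %*% ch * hf$psi_theta
  X <- matrix(0, nmc, 8)
  for (d in 1:6)
    X[, d] <- g0 + gcs[, cats[d]] + gco * cos(th[d] * pi / 180) +
      gsi * sin(th[d] * pi / 180) + ggp[, d]
  for (k in 1:2) X[, 6 + k] <- g0 + gct[, k] - gcs[, k]
  expect_lt(max(abs(stats::cov(X) - prf$Sigma_stim)), 0.06)
})

test_that("MAP fitting recovers an offset-only cell and approaches the MLE", {
  set.seed(9)
  rate <- 12
  trials <- lapply(1:30, function(i)
    new_trial("n1", stats::rpois(480, rate * 0.005), 1L, 331L,
              sample(BJ_DIRS, 1), sample(BJ_DIRS, 1)))
  ds <- trial_dataset(trials)
  spec <- design_spec("none")
  fit <- fit_glm_map(ds, spec, "n1", include_history = FALSE,
                     include_tbar = FALSE)
  expect_lt(abs(fit$params$w - log(rate)), 0.1)
  # shrinkage: tightening the prior pulls the noise kernels toward zero
  tight <- list(psi_0 = 0.05, psi_s = 0.05)
  fit_t <- fit_glm_map(ds, spec, "n1", tight, include_history = FALSE,
                       include_tbar = FALSE)
  expect_lt(sqrt(sum(fit_t$params$stim_coeffs^2)),
            0.2 * sqrt(sum(fit$params$stim_coeffs^2)))
  # dual-route optimizer check: an independent quasi-Newton optimizer of
  # the same penalized objective reaches the same posterior mode
  fit1 <- fit_glm_map(ds, spec, "n1", include_history = FALSE,
                      include_tbar = FALSE)
  des <- popGMLM:::build_glm_design(ds, spec, default_bases(), "n1",
                                    FALSE, FALSE)
  pm <- popGMLM:::glm_prior_matrices(
    des, build_prior(spec, default_hyper(spec, FALSE, FALSE)))
  negpost <- function(b) {
    eta <- drop(des$X %*% b)
    -(sum(des$y * eta) - sum(des$mult * 0.005 * exp(eta)) -
        0.5 * sum(b * (pm$P %*% b)))
  }
  grad <- function(b) {
    eta <- drop(des$X %*% b)
    -(drop(crossprod(des$X, des$y - des$mult * 0.005 * exp(eta))) -
        drop(pm$P %*% b))
  }
  alt <- stats::optim(numeric(des$d), negpost, grad, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
  expect_lt(max(abs(des$X %*% fit1$beta - des$X %*% alt$par)), 0.02)
  expect_lte(negpost(fit1$beta), alt$value + 1e-4)
})

test_that("half-t style hyperprior is finite and maximal at zero", {
  h <- seq(0, 5, by = 0.25)
  lp <- log_hyperprior(h)
  expect_true(all(is.finite(lp)))
  expect_equal(which.max(lp), 1L)
  expect_true(all(diff(lp) < 0))
})

test_that("evidence optimization tracks the scale of the true kernels", {
  # stronger true stimulus kernels should select larger psi than near-null
  bases <- default_bases()
  spec <- design_spec("none")
  set.seed(10)
  mk_cell <- function(scale, nid) {
    K <- matrix(stats::rnorm(24 * 2, 0, scale), 24)
    p <- glm_params(w = log(10), stim_coeffs = K)
    lapply(1:40, function(i) {
      tr <- new_trial(nid, integer(480), 1L, 331L, sample(BJ_DIRS, 1),
                      sample(BJ_DIRS, 1))
      lam <- glm_log_rate(p, tr, spec, bases)
      tr$counts <- stats::rpois(480, exp(lam) * 0.005)
      tr
    })
  }
  ds <- trial_dataset(c(mk_cell(1.0, "big"), mk_cell(0.02, "small")))
  eb <- optimize_evidence(ds, spec, "big", include_history = FALSE,
                          include_tbar = FALSE, maxit = 40)
  es <- optimize_evidence(ds, spec, "small", include_history = FALSE,
                          include_tbar = FALSE, maxit = 40)
  expect_gt(max(unlist(eb$hyper[c("psi_0", "psi_s")])),
            max(unlist(es$hyper[c("psi_0", "psi_s")])))
})
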