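test_that("HOSVD projection captures low-rank structure exactly", {
  set.seed(1)
  Tt <- 50; D <- 6; N <- 12
  U1 <- qr.Q(qr(matrix(rnorm(Tt * 3), Tt)))
  U2 <- qr.Q(qr(matrix(rnorm(D * 3), D)))
  U3 <- qr.Q(qr(matrix(rnorm(N * 3), N)))
  core <- array(rnorm(27), c(3, 3, 3))
  K <- array(0, c(Tt, D, N))
  for (a in 1:3) for (b in 1:3) for (cc in 1:3)
    K <- K + core[a, b, cc] * outer(U1[, a], outer(U2[, b], U3[, cc]))
  h3 <- hosvd_subspace(K, n_dims = 3)
  expect_equal(h3$energy, 1, tolerance = 1e-10)   # exactly rank 3
  h2 <- hosvd_subspace(K, n_dims = 2)
  expect_lte(h2$energy, h3$energy + 1e-12)        # energy monotone
  h1 <- hosvd_subspace(K, n_dims = 1)
  expect_lte(h1$energy, h2$energy + 1e-12)
  expect_error(hosvd_subspace(K, n_dims = N + 1), "mode")
  # mean removal: the tensor sums to zero across directions everywhere
  Km <- K
  mu <- apply(K, c(1, 3), mean)
  for (d in seq_len(D)) Km[, d, ] <- K[, d, ] - mu
  hm <- hosvd_subspace(K, n_dims = 3, remove_mean = TRUE)
  expect_lt(max(abs(apply(Km, c(1, 3), sum))), 1e-10)
})

test_that("the direction ellipse obeys its symmetries and a dense oracle", {
  spec <- design_spec("cosine")
  bases <- default_bases()
  m <- gmlm_model(spec, 6, 2, bases, include_history = FALSE,
                  include_tbar = FALSE)
  p <- init_gmlm_params(m, 3)
  ell <- direction_ellipse(p, m, t_bin = 60)
  # odd symmetry
  th <- c(0, 30, 77, 145)
  expect_lt(max(abs(ell$E(th) + ell$E(th + 180))), 1e-12)
  # dense oracle through the kernel tensor: E_t(theta) is the projected
  # difference between a cosine-direction response and the category part
  K <- kernel_tensor(p, m)     # time x S x N
  Rmap <- popGMLM:::output_map(p$V_stim)
  Vpinv <- Rmap %*% solve(crossprod(p$V_stim), t(p$V_stim))  # maps N -> R_s
  for (theta in c(20, 110, 290)) {
    fib <- K[60, "cos", ] * cos(theta * pi / 180) +
      K[60, "sin", ] * sin(theta * pi / 180)    # per-neuron tuning at t
    expect_equal(drop(Vpinv %*% fib), drop(ell$E(theta)), tolerance = 1e-8)
  }
})

test_that("ellipse axes: constructed cases and the grid argmax agree", {
  # circle: f1, f2 orthogonal equal-norm -> degenerate, major == minor
  ell_c <- list(f1 = c(1, 0), f2 = c(0, 1))
  ax_c <- ellipse_axes(ell_c, grid_step = 0)
  expect_true(ax_c$degenerate)
  expect_equal(ax_c$major, ax_c$minor, tolerance = 1e-10)
  # ellipse elongated along 135 degrees
  u <- c(cos(135 * pi / 180), sin(135 * pi / 180))
  v <- c(-u[2], u[1])
  ell_e <- list(f1 = 3 * u * cos(135 * pi / 180) + 0.5 * v * -sin(135 * pi / 180),
                f2 = 3 * u * sin(135 * pi / 180) + 0.5 * v * cos(135 * pi / 180))
  ax_e <- ellipse_axes(ell_e, grid_step = 0)
  expect_equal(ax_e$theta_max, 135, tolerance = 1e-6)
  expect_gt(ax_e$major, ax_e$minor)
  # random ellipses: closed form within 1 degree of a 0.1-degree grid argmax
  set.seed(4)
  for (rep in 1:25) {
    ell <- list(f1 = rnorm(4), f2 = rnorm(4))
    ax <- ellipse_axes(ell, grid_step = 0)
    grid <- seq(45, 225, by = 0.1)
    Dt <- vapply(grid, function(g) {
      th <- g * pi / 180
      2 * sqrt(sum((ell$f1 * cos(th) + ell$f2 * sin(th))^2))
    }, 0)
    tg <- grid[which.max(Dt)]
    dd <- min(abs(tg - ax$theta_max), abs(abs(tg - ax$theta_max) - 180))
    expect_lte(dd, 1)
    expect_true(ax$theta_max >= 45 && ax$theta_max < 225.0001)
    expect_gte(ax$major, ax$minor)
  }
})

test_that("the category vector is the projected sample-category difference", {
  spec <- design_spec("cosine")
  m <- gmlm_model(spec, 5, 2, default_bases(), include_history = FALSE,
                  include_tbar = FALSE)
  p <- init_gmlm_params(m, 5)
  # equal category weights give a zero category vector
  p0 <- p
  p0$U_stim["cs2", ] <- p0$U_stim["cs1", ]
  expect_equal(category_vector_norm(p0, m, 80), 0, tolerance = 1e-12)
  # linearity in the weight difference
  nrm1 <- category_vector_norm(p, m, 80)
  p2 <- p
  d <- p$U_stim["cs1", ] - p$U_stim["cs2", ]
  p2$U_stim["cs1", ] <- p$U_stim["cs1", ] + d / 2
  p2$U_stim["cs2", ] <- p$U_stim["cs2", ] - d / 2
  expect_equal(category_vector_norm(p2, m, 80), 2 * nrm1, tolerance = 1e-10)
  # oracle through the kernel tensor fibers
  K <- kernel_tensor(p, m)
  Rmap <- popGMLM:::output_map(p$V_stim)
  Vpinv <- Rmap %*% solve(crossprod(p$V_stim), t(p$V_stim))
  fib <- K[80, "cs1", ] - K[80, "cs2", ]
  expect_equal(sqrt(sum((Vpinv %*% fib)^2)),
               category_vector_norm(p, m, 80), tolerance = 1e-8)
})

test_that("geometry metrics are invariant to rescaling and rotation", {
  spec <- design_spec("cosine")
  m <- gmlm_model(spec, 6, 3, default_bases(), include_history = FALSE,
                  include_tbar = FALSE)
  p <- init_gmlm_params(m, 7)
  ax <- ellipse_axes(direction_ellipse(p, m, 100), grid_step = 0)
  cv <- category_vector_norm(p, m, 100)
  # component rescaling (likelihood-flat direction)
  p2 <- p
  p2$U_stim[, 2] <- 3 * p2$U_stim[, 2]
  p2$T_stim[, 2] <- 0.25 * p2$T_stim[, 2]
  p2$V_stim[, 2] <- p2$V_stim[, 2] / 0.75
  ax2 <- ellipse_axes(direction_ellipse(p2, m, 100), grid_step = 0)
  expect_equal(ax2$theta_max, ax$theta_max, tolerance = 1e-6)
  expect_equal(ax2$major, ax$major, tolerance = 1e-8)
  expect_equal(category_vector_norm(p2, m, 100), cv, tolerance = 1e-8)
  # joint rotation of the neuron loading space leaves norms unchanged
  set.seed(8)
  Q <- qr.Q(qr(matrix(rnorm(36), 6)))
  p3 <- p
  p3$V_stim <- Q %*% p$V_stim
  ax3 <- ellipse_axes(direction_ellipse(p3, m, 100), grid_step = 0)
  expect_equal(ax3$major, ax$major, tolerance = 1e-8)
  expect_equal(ax3$minor, ax$minor, tolerance = 1e-8)
  expect_equal(category_vector_norm(p3, m, 100), cv, tolerance = 1e-8)
})

test_that("component metrics report angle and magnitudes", {
  U <- matrix(0, 6, 2, dimnames = list(design_spec("cosine")$labels, NULL))
  U["cos", 1] <- 1
  U["cs1", 2] <- 0.4; U["cs2", 2] <- -0.4
  cm <- component_metrics(U)
  expect_equal(cm$theta_deg[1], 0)
  expect_equal(cm$direction_magnitude[1], 1)
  expect_true(is.na(cm$theta_deg[2]))
  expect_equal(cm$direction_magnitude[2], 0)
  expect_equal(cm$C_sample[2], 0.8)
  # direction magnitude is invariant under joint rotation of (cos, sin)
  phi <- 0.7
  U2 <- U
  U2["cos", 1] <- cos(phi); U2["sin", 1] <- sin(phi)
  expect_equal(component_metrics(U2)$direction_magnitude[1], 1)
})

test_that("component normalization moves scale into the loadings", {
  m <- gmlm_model(design_spec("cosine"), 5, 2, default_bases(),
                  include_history = FALSE, include_tbar = FALSE)
  p <- init_gmlm_params(m, 9)
  p$T_stim <- 3 * p$T_stim; p$U_stim <- 0.2 * p$U_stim
  K <- kernel_tensor(p, m)
  pn <- normalize_components(p)
  expect_lt(max(abs(kernel_tensor(pn, m) - K)), 1e-10)
  for (r in 1:2) {
    expect_equal(sqrt(sum(pn$T_stim[, r]^2)), 1, tolerance = 1e-12)
    expect_equal(sqrt(sum(pn$U_stim[, r]^2)), 1, tolerance = 1e-12)
  }
  pnn <- normalize_components(pn)
  expect_equal(pnn$V_stim, pn$V_stim, tolerance = 1e-12)  # idempotent
})

test_that("posterior geometry summarizes draws with ordered intervals", {
  truth <- tiny_truth(N = 4, rank = 1, seed = 10)
  ds <- simulate_trials(truth, 6, 11)
  cfg <- sampler_config(n_warmup = 150, n_samples = 150, seed = 12)
  s <- run_sampler(ds, truth$model, cfg)
  geo <- posterior_geometry(s, t_bins = c(50, 150), thin = 15)
  expect_equal(nrow(geo), 2)
  expect_true(all(geo$major_lo <= geo$major_med & geo$major_med <= geo$major_hi))
  expect_true(all(geo$major_med >= geo$minor_med - 1e-12))
  expect_true(all(geo$theta_max_med >= 45 & geo$theta_max_med <= 225))
  # a single draw collapses the interval to a point
  s1 <- s
  s1$draws <- s$draws[1, , drop = FALSE]
  geo1 <- posterior_geometry(s1, t_bins = 50, thin = 1)
  expect_equal(geo1$major_lo, geo1$major_hi)
})

test_that("history timescale fitting recovers an exponential decay", {
  tt <- (0:40) * 0.005
  kern <- 0.8 * exp(-tt / 0.010)
  fit <- fit_history_timescale(kern)
  expect_equal(fit$tau_ms, 10, tolerance = 1e-4)
  fit2 <- fit_history_timescale(5 * kern)       # scale leaves tau unchanged
  expect_equal(fit2$tau_ms, 10, tolerance = 1e-4)
  set.seed(13)
  fit3 <- fit_history_timescale(kern + rnorm(41, 0, 0.02))
  expect_lt(abs(fit3$tau_ms - 10), 3)
  expect_warning(fit_history_timescale(seq(0.1, 1, length.out = 41)),
                 "decay")
  expect_error(fit_history_timescale(numeric(10)), "zero")
})
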