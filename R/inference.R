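#' Sampler configuration
#'
#' Defaults follow the published schedule: 25,000 warmup samples with
#' dual-averaging step-size adaptation (frozen for the last 4% of warmup),
#' a diagonal mass matrix re-estimated at 16% and 76% of warmup from the
#' preceding sample windows, then 50,000 retained draws; 10
#' Metropolis-Hastings rescaling steps per tensor component are interleaved
#' between HMC steps with proposal width omega = 0.2. Tests use a reduced
#' schedule via \code{n_warmup}/\code{n_samples}; the mass/adaptation
#' breakpoints scale proportionally.
#'
#' @param n_warmup,n_samples warmup and retained draw counts.
#' @param target_accept dual-averaging target acceptance statistic.
#' @param eps0 initial leapfrog step size.
#' @param max_leapfrog cap on leapfrog steps (S = min(cap, ceil(1/eps))).
#' @param mass_update_points iteration indices of the two mass-matrix
#'   updates (defaults proportional to the published 4001/19001 of 25000).
#' @param adapt_until last warmup iteration of step-size adaptation.
#' @param mh_interleave MH rescaling steps per component per HMC step.
#' @param mh_omega lognormal proposal SD of the rescaling move.
#' @param seed RNG seed.
#' @return list of class \code{sampler_config}.
#' @export
sampler_config <- function(n_warmup = 25000L, n_samples = 50000L,
                           target_accept = 0.8, eps0 = 0.01,
                           max_leapfrog = 100L, mass_update_points = NULL,
                           adapt_until = NULL, mh_interleave = 10L,
                           mh_omega = 0.2, seed = 1L) {
  if (is.null(mass_update_points))
    mass_update_points <- c(1L, as.integer(round(0.16 * n_warmup)) + 1L,
                            as.integer(round(0.76 * n_warmup)) + 1L)
  if (is.null(adapt_until))
    adapt_until <- n_warmup - as.integer(round(0.04 * n_warmup))
  structure(list(n_warmup = as.integer(n_warmup),
                 n_samples = as.integer(n_samples),
                 target_accept = target_accept, eps0 = eps0,
                 max_leapfrog = as.integer(max_leapfrog),
                 mass_update_points = as.integer(mass_update_points),
                 adapt_until = as.integer(adapt_until),
                 mh_interleave = as.integer(mh_interleave),
                 mh_omega = mh_omega, seed = as.integer(seed)),
            class = "sampler_config")
}

#' Dual-averaging step-size adaptation state and update
#'
#' Nesterov-style dual averaging toward the target acceptance statistic,
#' with the published constants gamma = 0.05, t0 = 10, kappa = 0.75.
#'
#' @param eps0 initial step size.
#' @param target target acceptance probability.
#' @return adaptation state; advance with \code{dual_averaging_update}.
#' @export
dual_averaging_init <- function(eps0 = 0.01, target = 0.8) {
  list(mu = log(10 * eps0), Hbar = 0, logeps_bar = log(eps0),
       logeps = log(eps0), m = 0L, target = target,
       gamma = 0.05, t0 = 10, kappa = 0.75)
}

#' @rdname dual_averaging_init
#' @param state adaptation state.
#' @param accept_stat realized acceptance probability of the last proposal.
#' @export
dual_averaging_update <- function(state, accept_stat) {
  m <- state$m + 1L
  eta <- 1 / (m + state$t0)
  state$Hbar <- (1 - eta) * state$Hbar + eta * (state$target - accept_stat)
  state$logeps <- state$mu - sqrt(m) / state$gamma * state$Hbar
  w <- m^(-state$kappa)
  state$logeps_bar <- w * state$logeps + (1 - w) * state$logeps_bar
  state$m <- m
  state
}

#' One leapfrog HMC proposal with Metropolis correction
#'
#' @param q position vector.
#' @param lp_grad function(q) returning list(lp, grad).
#' @param eps step size; the trajectory uses \code{min(max_leapfrog,
#'   ceiling(1/eps))} steps.
#' @param mass_diag diagonal of the mass matrix.
#' @param max_leapfrog step cap.
#' @param cur optional precomputed list(lp, grad) at q.
#' @return list: \code{q}, \code{accepted}, \code{accept_stat},
#'   \code{divergent}, \code{cur} (lp/grad at the returned position),
#'   \code{n_steps}.
#' @export
leapfrog_hmc_step <- function(q, lp_grad, eps, mass_diag,
                              max_leapfrog = 100L, cur = NULL) {
  if (is.null(cur)) cur <- lp_grad(q)
  S <- min(max_leapfrog, ceiling(1 / eps))
  p <- stats::rnorm(length(q), 0, sqrt(mass_diag))
  H0 <- -cur$lp + 0.5 * sum(p^2 / mass_diag)
  qn <- q; gn <- cur$grad
  p <- p + eps / 2 * gn
  bad <- FALSE
  for (s in seq_len(S)) {
    qn <- qn + eps * p / mass_diag
    prop <- lp_grad(qn)
    if (!all(is.finite(prop$grad)) || !is.finite(prop$lp)) {bad <- TRUE; break}
    if (s < S) p <- p + eps * prop$grad
  }
  if (!bad) {
    p <- p + eps / 2 * prop$grad
    H1 <- -prop$lp + 0.5 * sum(p^2 / mass_diag)
    dH <- H1 - H0
  } else dH <- Inf
  divergent <- !is.finite(dH) || dH > 1000
  astat <- if (divergent) 0 else min(1, exp(-dH))
  if (!divergent && stats::runif(1) < astat) {
    list(q = qn, accepted = TRUE, accept_stat = astat, divergent = FALSE,
         cur = prop, n_steps = S)
  } else {
    list(q = q, accepted = FALSE, accept_stat = astat,
         divergent = divergent, cur = cur, n_steps = S)
  }
}

#' Diagonal mass matrix from a window of draws
#'
#' Inverse per-coordinate empirical variances, floored at a small positive
#' value (with a warning) for zero-variance coordinates.
#'
#' @param draws matrix (iterations x dimensions) of warmup draws.
#' @return numeric diagonal of M.
#' @export
mass_from_window <- function(draws) {
  v <- apply(draws, 2, stats::var)
  if (any(v <= 1e-12)) {
    warning("zero-variance coordinate in mass window; flooring")
    v <- pmax(v, 1e-12)
  }
  1 / v
}

# chi log density of a norm x with shape df and scale parameter eta
# (x = |z|, z ~ N(0, Sigma) restricted to direction with eta^2 = uhat' Sinv uhat)
chi_lpdf <- function(x, df, eta) {
  df * log(eta) - (df / 2 - 1) * log(2) - lgamma(df / 2) +
    (df - 1) * log(x) - (eta * x)^2 / 2
}

#' Metropolis-Hastings rescaling of one tensor component
#'
#' Random walk along the likelihood-flat rescaling direction of a CP
#' component: lognormal scale factors multiply the stimulus-weight and
#' temporal-factor norms while the loading norm absorbs their inverse, so
#' the component (and the likelihood) is unchanged; acceptance uses the
#' chi-distribution priors over the three norms conditioned on the
#' component product norm, with the 1/(u t) change-of-variables factor and
#' the lognormal proposal ratio.
#'
#' @param u,t,v current norms of the three factors.
#' @param eta_u,eta_t,eta_v prior scale parameters of the chi densities
#'   (direction-dependent for a correlated prior).
#' @param df_u,df_t,df_v dimensions of the three factors.
#' @param omega proposal width.
#' @param n_steps number of MH steps.
#' @return list: \code{scale_u}, \code{scale_t} (net accepted rescalings of
#'   the first two factors; the third is their inverse), \code{n_accept}.
#' @export
mh_rescale_component <- function(u, t, v, eta_u, eta_t, eta_v,
                                 df_u, df_t, df_v, omega = 0.2,
                                 n_steps = 10L) {
  stopifnot(u > 0, t > 0, v > 0)
  zeta <- u * t * v
  lcond <- function(uu, tt) {
    vv <- zeta / (uu * tt)
    -log(uu) - log(tt) + chi_lpdf(uu, df_u, eta_u) +
      chi_lpdf(tt, df_t, eta_t) + chi_lpdf(vv, df_v, eta_v)
  }
  u0 <- u; t0 <- t
  nacc <- 0L
  for (s in seq_len(n_steps)) {
    su <- exp(stats::rnorm(1, 0, omega))
    st <- exp(stats::rnorm(1, 0, omega))
    us <- su * u; ts <- st * t
    # multiplicative random walk: the lognormal proposal density in norm
    # space is f(s)/u, so the Hastings ratio contributes su * st (one
    # Jacobian factor per rescaled norm)
    la <- lcond(us, ts) - lcond(u, t) + log(su) + log(st)
    if (is.finite(la) && log(stats::runif(1)) < la) {
      u <- us; t <- ts
      nacc <- nacc + 1L
    }
  }
  list(scale_u = u / u0, scale_t = t / t0, n_accept = nacc)
}

# two-factor variant for the touch-bar components (zeta = t * v)
mh_rescale_component2 <- function(t, v, eta_t, eta_v, df_t, df_v,
                                  omega = 0.2, n_steps = 10L) {
  zeta <- t * v
  lcond <- function(tt) {
    vv <- zeta / tt
    -log(tt) + chi_lpdf(tt, df_t, eta_t) + chi_lpdf(vv, df_v, eta_v)
  }
  t0 <- t
  for (s in seq_len(n_steps)) {
    st <- exp(stats::rnorm(1, 0, omega))
    ts <- st * t
    la <- lcond(ts) - lcond(t) + log(st)
    if (is.finite(la) && log(stats::runif(1)) < la) t <- ts
  }
  list(scale_t = t / t0)
}

# apply interleaved MH rescaling moves to all tensor components in place
apply_mh_rescaling <- function(params, hyper, model, omega, n_steps) {
  if (model$rank > 0) {
    Sinv <- solve(stim_prior_terms(model$spec, hyper)$Sigma)
    for (r in seq_len(model$rank)) {
      u <- sqrt(sum(params$U_stim[, r]^2))
      t <- sqrt(sum(params$T_stim[, r]^2))
      v <- sqrt(sum(params$V_stim[, r]^2))
      if (u <= 0 || t <= 0 || v <= 0) next
      uh <- params$U_stim[, r] / u
      eta_u <- sqrt(drop(uh %*% Sinv %*% uh))
      mv <- mh_rescale_component(u, t, v, eta_u, 1, 1,
                                 model$spec$S, model$P_stim, model$N,
                                 omega, n_steps)
      params$U_stim[, r] <- params$U_stim[, r] * mv$scale_u
      params$T_stim[, r] <- params$T_stim[, r] * mv$scale_t
      params$V_stim[, r] <- params$V_stim[, r] / (mv$scale_u * mv$scale_t)
    }
  }
  if (model$include_tbar && model$rank_tbar > 0) {
    for (q in seq_len(model$rank_tbar)) {
      t <- sqrt(sum(params$T_tbar[, q]^2))
      v <- sqrt(sum(params$V_tbar[, q]^2))
      if (t <= 0 || v <= 0) next
      mv <- mh_rescale_component2(t, v, 1 / hyper$psi_tbar, 1,
                                  model$P_tbar, model$N, omega, n_steps)
      params$T_tbar[, q] <- params$T_tbar[, q] * mv$scale_t
      params$V_tbar[, q] <- params$V_tbar[, q] / mv$scale_t
    }
  }
  params
}

#' Run the HMC sampler over GMLM parameters and log-hyperparameters
#'
#' Joint Hamiltonian Monte Carlo over the packed parameters and
#' log-transformed hyperparameters with the configured warmup schedule
#' (dual-averaging step size, staged diagonal mass matrix) and interleaved
#' MH component-rescaling moves.
#'
#' @param dataset a \code{trial_dataset} (or prepared \code{gmlm_data}).
#' @param model a \code{gmlm_model}.
#' @param config a \code{sampler_config}.
#' @param init optional initial \code{gmlm_params}.
#' @return object of class \code{posterior_samples}: \code{draws}
#'   (n_samples x dim), \code{hyper_names}, \code{n_param},
#'   \code{accept} (post-warmup flags), \code{accept_stat},
#'   \code{eps_trace}, \code{eps_final}, \code{divergences}, \code{lp},
#'   \code{model}, \code{config}.
#' @export
run_sampler <- function(dataset, model, config = sampler_config(),
                        init = NULL) {
  data <- if (inherits(dataset, "gmlm_data")) dataset else
    prepare_pop_data(dataset, model)
  set.seed(config$seed)
  if (is.null(init)) {
    rate0 <- log(max(data$sum_y, 1) /
                 (sum(vapply(data$bylayout, function(b)
                   nrow(b$Y) * sum(b$m), 0)) * data$bin_width))
    init <- init_gmlm_params(model, config$seed, w_center = rate0)
  }
  hn <- gmlm_hyper_names(model)
  lh <- stats::rnorm(length(hn))  # log hypers init: standard normal draws
  q <- c(pack_params(init), lh)
  n_par <- length(q) - length(hn)
  to_hyper <- function(qv)
    as.list(stats::setNames(exp(qv[n_par + seq_along(hn)]), hn))
  lp_grad <- function(qv) {
    params <- unpack_params(qv[seq_len(n_par)], model)
    hyper <- to_hyper(qv)
    r <- gmlm_log_posterior(params, hyper, data, model, want_grad = TRUE)
    list(lp = r$lp, grad = c(r$grad_params, r$grad_hyper))
  }
  nw <- config$n_warmup; ns <- config$n_samples
  d <- length(q)
  mass <- rep(1, d)
  da <- dual_averaging_init(config$eps0, config$target_accept)
  eps <- config$eps0
  warm_draws <- matrix(0, nw, d)
  draws <- matrix(0, ns, d)
  accept <- logical(ns); astat <- numeric(ns); lp_tr <- numeric(ns)
  eps_trace <- numeric(nw + ns)
  ndiv <- 0L
  cur <- lp_grad(q)
  mup <- config$mass_update_points
  for (i in seq_len(nw + ns)) {
    warm <- i <= nw
    if (warm && i %in% mup && i > 1) {
      lo <- if (i == mup[2]) floor((mup[2] - 1) / 2) + 1L else mup[2]
      mass <- mass_from_window(warm_draws[lo:(i - 1L), , drop = FALSE])
    }
    step <- leapfrog_hmc_step(q, lp_grad, eps, mass, config$max_leapfrog,
                              cur)
    q <- step$q; cur <- step$cur
    if (step$divergent) ndiv <- ndiv + 1L
    if (warm && i <= config$adapt_until) {
      da <- dual_averaging_update(da, step$accept_stat)
      eps <- exp(da$logeps)
    } else if (warm) {
      eps <- exp(da$logeps_bar)
    }
    # interleaved MH rescaling of tensor components
    if (model$rank > 0 || (model$include_tbar && model$rank_tbar > 0)) {
      params <- unpack_params(q[seq_len(n_par)], model)
      params <- apply_mh_rescaling(params, to_hyper(q), model,
                                   config$mh_omega, config$mh_interleave)
      qnew <- c(pack_params(params), q[n_par + seq_along(hn)])
      if (any(qnew != q)) {
        q <- qnew
        cur <- lp_grad(q)  # likelihood unchanged; prior terms differ
      }
    }
    eps_trace[i] <- eps
    if (warm) {
      warm_draws[i, ] <- q
    } else {
      j <- i - nw
      draws[j, ] <- q
      accept[j] <- step$accepted
      astat[j] <- step$accept_stat
      lp_tr[j] <- cur$lp
    }
  }
  structure(list(draws = draws, hyper_names = hn, n_param = n_par,
                 accept = accept, accept_stat = astat,
                 eps_trace = eps_trace, eps_final = eps,
                 divergences = ndiv, lp = lp_tr, model = model,
                 config = config),
            class = "posterior_samples")
}

#' Extract hyperparameter draws (natural scale)
#' @param samples a \code{posterior_samples}.
#' @return matrix draws x hyperparameters.
#' @export
hyper_draws <- function(samples) {
  H <- exp(samples$draws[, samples$n_param + seq_along(samples$hyper_names),
                         drop = FALSE])
  colnames(H) <- samples$hyper_names
  H
}

#' MAP fit at the marginal posterior medians of the hyperparameters
#'
#' @param dataset a \code{trial_dataset} or \code{gmlm_data}.
#' @param samples a \code{posterior_samples} for the same model.
#' @param maxit optimizer cap.
#' @return as \code{fit_gmlm_map}, plus \code{hyper}.
#' @export
map_with_median_hypers <- function(dataset, samples, maxit = 500L) {
  med <- apply(hyper_draws(samples), 2, stats::median)
  hyper <- as.list(med)
  best <- which.max(samples$lp)
  init <- unpack_params(samples$draws[best, seq_len(samples$n_param)],
                        samples$model)
  fit <- fit_gmlm_map(dataset, samples$model, hyper, init = init,
                      maxit = maxit)
  fit$hyper <- hyper
  fit
}

#' Split-chain R-hat and bulk effective sample size (simple versions)
#' @param x numeric vector of draws for one quantity.
#' @return list(rhat, ess).
#' @export
rhat_ess <- function(x) {
  n <- floor(length(x) / 2)
  ch <- cbind(x[seq_len(n)], x[n + seq_len(n)])
  m <- ncol(ch)
  W <- mean(apply(ch, 2, stats::var))
  B <- n * stats::var(colMeans(ch))
  vhat <- (n - 1) / n * W + B / n
  rhat <- sqrt(vhat / W)
  # lag-autocorrelation ESS on the pooled chain
  ac <- stats::acf(x, lag.max = min(200, length(x) - 2), plot = FALSE,
                   demean = TRUE)$acf[-1]
  pos <- which(ac < 0.05)
  L <- if (length(pos)) pos[1] else length(ac)
  ess <- length(x) / (1 + 2 * sum(ac[seq_len(L)]))
  list(rhat = rhat, ess = max(1, ess))
}
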