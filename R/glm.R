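#' Single-neuron GLM parameters
#'
#' The full-rank reference model for one cell: log baseline \code{w},
#' spike-history coefficients \code{h_coeffs} (P_spk), touch-bar
#' coefficients \code{tbar_coeffs} (P_tbar), and stimulus kernel
#' coefficients \code{stim_coeffs} (P_stim x S, one column per stimulus
#' event kernel).
#'
#' @param w log-rate offset.
#' @param stim_coeffs P_stim x S matrix.
#' @param h_coeffs,tbar_coeffs coefficient vectors or NULL when the term is
#'   excluded.
#' @return object of class \code{glm_params}.
#' @export
glm_params <- function(w, stim_coeffs, h_coeffs = NULL, tbar_coeffs = NULL) {
  structure(list(w = w, h_coeffs = h_coeffs, tbar_coeffs = tbar_coeffs,
                 stim_coeffs = stim_coeffs),
            class = "glm_params")
}

#' Per-bin log rate of the single-neuron GLM
#'
#' \eqn{\lambda(t) = w + (h * y)(t) + (k^{tbar} * x^{tbar})(t) +
#' \sum_s (k^{(s)} * x^{(s)})(t)}; the spike count is Poisson with mean
#' \eqn{\exp(\lambda)\Delta}.
#'
#' @param params a \code{glm_params}.
#' @param trial a \code{gmlm_trial}.
#' @param spec a \code{design_spec}.
#' @param bases basis bundle.
#' @return numeric per-bin log rate.
#' @export
glm_log_rate <- function(params, trial, spec, bases) {
  T_ <- length(trial$counts)
  reg <- trial_regressors(trial, spec)
  lam <- rep(params$w, T_)
  if (!is.null(params$h_coeffs))
    lam <- lam + history_design(trial$counts, bases$spk) %*% params$h_coeffs
  if (!is.null(params$tbar_coeffs))
    lam <- lam + shift_design(bases$tbar, trial$t_tbar, T_) %*%
      params$tbar_coeffs
  Ms <- shift_design(bases$stim, trial$t_sample_on, T_)
  Mt <- shift_design(bases$stim, trial$t_test_on, T_)
  # each kernel's impulse stream carries the stimulus coefficients
  lam <- lam + Ms %*% (params$stim_coeffs %*% reg$x_dir_sample) +
    Mt %*% (params$stim_coeffs %*% reg$x_dir_test)
  drop(lam)
}

#' Poisson log likelihood of trials under a single-neuron GLM
#'
#' @inheritParams glm_log_rate
#' @param bin_width bin width in seconds.
#' @return scalar log likelihood.
#' @export
glm_trial_loglik <- function(params, trial, spec, bases,
                             bin_width = bases$stim$bin_width) {
  lam <- glm_log_rate(params, trial, spec, bases)
  y <- trial$counts
  sum(y * (lam + log(bin_width)) - exp(lam) * bin_width - lfactorial(y))
}

# Stacked (optionally trial-aggregated) design for one neuron's GLM.
# Returns X, y, mult (per-row trial multiplicity), sum_lfact, block index.
build_glm_design <- function(dataset, spec, bases, neuron,
                             include_history = TRUE, include_tbar = TRUE,
                             trial_idx = NULL) {
  idx <- usable_trials(dataset, spec)
  if (!is.null(trial_idx)) idx <- intersect(idx, trial_idx)
  idx <- idx[vapply(dataset$trials[idx],
                    function(tr) as.character(tr$neuron) ==
                      as.character(neuron), TRUE)]
  if (length(idx) == 0) stop("no usable trials for neuron ", neuron)
  sub <- trial_dataset(dataset$trials[idx], neuron_ids = neuron,
                       bin_width = dataset$bin_width,
                       boundary = dataset$boundary,
                       stim_dur_bins = dataset$stim_dur_bins)
  model <- gmlm_model(spec, N = 1, rank = 0, bases = bases,
                      rank_tbar = if (include_tbar) 1L else 0L,
                      include_history = include_history,
                      include_tbar = include_tbar)
  data <- prepare_pop_data(sub, model)
  P_spk <- if (include_history) ncol(bases$spk$B) else 0L
  P_tb <- if (include_tbar) ncol(bases$tbar$B) else 0L
  P_st <- ncol(bases$stim$B)
  S <- spec$S
  d <- 1L + P_spk + P_tb + S * P_st
  blocks <- list(w = 1L,
                 h = if (P_spk) 1L + seq_len(P_spk),
                 tbar = if (P_tb) 1L + P_spk + seq_len(P_tb),
                 stim = 1L + P_spk + P_tb + seq_len(S * P_st))
  Xl <- list(); yl <- list(); ml <- list()
  lf <- 0
  for (bl in data$bylayout) {
    lay <- bl$layout
    for (j in seq_along(bl$m)) {
      X <- matrix(0, lay$T, d)
      X[, 1] <- 1
      if (P_spk) X[, blocks$h] <- bl$H[[j]]
      if (P_tb && !is.null(lay$Mtb)) X[, blocks$tbar] <- lay$Mtb
      for (s in seq_len(S)) {
        cols <- blocks$stim[(s - 1) * P_st + seq_len(P_st)]
        X[, cols] <- bl$XS[s, j] * lay$Ms + bl$XT[s, j] * lay$Mt
      }
      Xl[[length(Xl) + 1L]] <- X
      yl[[length(yl) + 1L]] <- bl$Y[, j]
      ml[[length(ml) + 1L]] <- rep(bl$m[j], lay$T)
      lf <- lf + bl$lfact[j]
    }
  }
  list(X = do.call(rbind, Xl), y = unlist(yl), mult = unlist(ml),
       sum_lfact = lf, blocks = blocks, S = S, P_stim = P_st,
       P_spk = P_spk, P_tbar = P_tb, d = d,
       bin_width = dataset$bin_width, n_trials = length(idx))
}

# prior precision matrix and proper-prior log density over the stacked GLM
# coefficients (flat on w)
glm_prior_matrices <- function(design, prior) {
  d <- design$d
  P <- matrix(0, d, d)
  if (design$P_spk) diag(P)[design$blocks$h] <- 1 / prior$var_spk
  if (design$P_tbar) diag(P)[design$blocks$tbar] <- 1 / prior$var_tbar
  Sinv <- solve(prior$Sigma_stim)
  P[design$blocks$stim, design$blocks$stim] <-
    kronecker(Sinv, diag(design$P_stim))
  ldet <- 0  # log det of the proper prior covariance (excluding flat w)
  if (design$P_spk) ldet <- ldet + design$P_spk * log(prior$var_spk)
  if (design$P_tbar) ldet <- ldet + design$P_tbar * log(prior$var_tbar)
  ldet <- ldet + design$P_stim *
    determinant(prior$Sigma_stim, TRUE)$modulus
  list(P = P, logdet_cov = as.numeric(ldet), n_proper = d - 1L)
}

# Newton solver for the penalized likelihood; family "poisson" (counts,
# exp link, bin width, multiplicities) or "gaussian" (unit-variance
# surrogate used to validate the Laplace evidence).
newton_map <- function(design, prec, family = c("poisson", "gaussian"),
                       beta0 = NULL, maxit = 50L, tol = 1e-9) {
  family <- match.arg(family)
  X <- design$X; y <- design$y; mult <- design$mult
  d <- ncol(X)
  beta <- if (is.null(beta0)) {
    b <- numeric(d)
    if (family == "poisson")
      b[1] <- log(max(sum(y), 1) / (sum(mult) * design$bin_width))
    b
  } else beta0
  loglik <- function(eta) {
    if (family == "poisson") {
      mu <- mult * design$bin_width * exp(eta)
      list(ll = sum(y * eta) + sum(y) * log(design$bin_width) - sum(mu) -
             design$sum_lfact, mu = mu)
    } else {
      r <- y - eta
      list(ll = -0.5 * sum(r^2) - length(y) / 2 * log(2 * pi), mu = eta)
    }
  }
  obj <- function(beta) {
    eta <- drop(X %*% beta)
    l <- loglik(eta)
    list(val = l$ll - 0.5 * sum(beta * (prec %*% beta)), eta = eta,
         mu = l$mu, ll = l$ll)
  }
  cur <- obj(beta)
  for (it in seq_len(maxit)) {
    resid <- if (family == "poisson") y - cur$mu else y - cur$eta
    grad <- drop(crossprod(X, resid)) - drop(prec %*% beta)
    W <- if (family == "poisson") cur$mu else rep(1, length(y))
    H <- crossprod(X * sqrt(W)) + prec
    step <- tryCatch(solve(H, grad), error = function(e) {
      warning("singular Hessian; adding jitter")
      solve(H + diag(1e-8 * (1 + mean(diag(H))), d), grad)
    })
    alpha <- 1
    repeat {
      cand <- beta + alpha * step
      nxt <- obj(cand)
      if (nxt$val >= cur$val - 1e-12 || alpha < 1e-8) break
      alpha <- alpha / 2
    }
    moved <- nxt$val - cur$val
    beta <- cand; cur <- nxt
    if (abs(moved) < tol * (abs(cur$val) + 1) &&
        sqrt(sum(grad^2)) < 1e-5 * (1 + abs(cur$val))) break
    if (family == "gaussian" && it >= 2) break
  }
  W <- if (family == "poisson") cur$mu else rep(1, length(y))
  H <- crossprod(X * sqrt(W)) + prec
  list(beta = beta, ll = cur$ll, penalty = cur$val - cur$ll, hess = H,
       converged = TRUE)
}

#' Laplace approximation of the log evidence
#'
#' \eqn{\log p(y|H) \approx \ell(\beta^*) + \log p(\beta^*|H) + (d/2)\log 2\pi
#' - \tfrac12 \log|H^*|} with \eqn{H^*} the negative Hessian of the log
#' posterior at the mode. Exact when likelihood and prior are Gaussian.
#'
#' @param ll log likelihood at the mode.
#' @param lp_prior log prior density at the mode.
#' @param hess negative Hessian of the log posterior at the mode.
#' @return scalar approximate log evidence.
#' @export
laplace_log_evidence <- function(ll, lp_prior, hess) {
  ll + lp_prior + nrow(hess) / 2 * log(2 * pi) -
    0.5 * as.numeric(determinant(hess, logarithm = TRUE)$modulus)
}

# assemble glm_params from a stacked coefficient vector
beta_to_glm_params <- function(beta, design) {
  glm_params(w = beta[1],
             stim_coeffs = matrix(beta[design$blocks$stim], design$P_stim,
                                  design$S),
             h_coeffs = if (design$P_spk) beta[design$blocks$h],
             tbar_coeffs = if (design$P_tbar) beta[design$blocks$tbar])
}

#' MAP fit of the single-neuron GLM
#'
#' Newton optimization of the log-concave Poisson log posterior under the
#' structured Gaussian prior at fixed hyperparameters.
#'
#' @param dataset a \code{trial_dataset}.
#' @param spec a \code{design_spec}.
#' @param neuron neuron id.
#' @param hyper hyperparameter list (see \code{default_hyper}).
#' @param bases basis bundle.
#' @param include_history,include_tbar term switches.
#' @param trial_idx optional training-trial subset.
#' @return list: \code{params} (a \code{glm_params}), \code{loglik},
#'   \code{logpost}, \code{evidence} (Laplace log evidence), \code{design}.
#' @export
fit_glm_map <- function(dataset, spec, neuron, hyper = default_hyper(spec),
                        bases = default_bases(), include_history = TRUE,
                        include_tbar = TRUE, trial_idx = NULL) {
  design <- build_glm_design(dataset, spec, bases, neuron,
                             include_history, include_tbar, trial_idx)
  prior <- build_prior(spec, hyper)
  pm <- glm_prior_matrices(design, prior)
  fit <- newton_map(design, pm$P, "poisson")
  lp_prior <- -0.5 * sum(fit$beta * (pm$P %*% fit$beta)) -
    0.5 * pm$logdet_cov - pm$n_proper / 2 * log(2 * pi)
  evid <- laplace_log_evidence(fit$ll, lp_prior, fit$hess)
  list(params = beta_to_glm_params(fit$beta, design), loglik = fit$ll,
       logpost = fit$ll + lp_prior, evidence = evid, design = design,
       beta = fit$beta)
}

#' Evidence optimization for the single-neuron GLM
#'
#' Maximizes the Laplace approximation of the log evidence plus the half-t
#' hyperprior over log-transformed hyperparameters (Nelder-Mead, inner MAP
#' re-solved and warm-started at each step).
#'
#' @inheritParams fit_glm_map
#' @param maxit outer iteration cap.
#' @return list: \code{params}, \code{hyper}, \code{fit} (final MAP fit),
#'   \code{objective}.
#' @export
optimize_evidence <- function(dataset, spec, neuron,
                              bases = default_bases(),
                              include_history = TRUE, include_tbar = TRUE,
                              trial_idx = NULL, maxit = 100L) {
  design <- build_glm_design(dataset, spec, bases, neuron,
                             include_history, include_tbar, trial_idx)
  h0 <- default_hyper(spec, include_tbar, include_history)
  hn <- names(h0)
  beta_warm <- NULL
  objective <- function(lh) {
    if (any(abs(lh) > 12)) return(1e12)  # keep scales in a sane range
    hyper <- as.list(stats::setNames(exp(lh), hn))
    prior <- tryCatch(build_prior(spec, hyper), error = function(e) NULL)
    if (is.null(prior)) return(1e12)
    pm <- glm_prior_matrices(design, prior)
    fit <- tryCatch(newton_map(design, pm$P, "poisson", beta0 = beta_warm),
                    error = function(e) NULL)
    if (is.null(fit)) return(1e12)
    beta_warm <<- fit$beta
    lp_prior <- -0.5 * sum(fit$beta * (pm$P %*% fit$beta)) -
      0.5 * pm$logdet_cov - pm$n_proper / 2 * log(2 * pi)
    evid <- laplace_log_evidence(fit$ll, lp_prior, fit$hess)
    -(evid + sum(log_hyperprior(unlist(hyper))))
  }
  opt <- stats::optim(log(unlist(h0)), objective, method = "Nelder-Mead",
                      control = list(maxit = maxit))
  hyper <- as.list(stats::setNames(exp(opt$par), hn))
  fit <- fit_glm_map(dataset, spec, neuron, hyper, bases,
                     include_history, include_tbar, trial_idx)
  list(params = fit$params, hyper = hyper, fit = fit,
       objective = -opt$value)
}
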