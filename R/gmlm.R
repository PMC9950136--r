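#' GMLM model configuration
#'
#' Fixes the pieces of a population model: the stimulus parameterization,
#' temporal bases, number of neurons, the stimulus tensor rank \code{rank}
#' (R_s), the touch-bar matrix rank \code{rank_tbar} (R_l, default 3), and
#' whether spike-history and touch-bar terms are included. Optional
#' low-rank dynamic spike-history tensors are configured through
#' \code{dyn_rank} (R_h, stimulus-locked) and \code{dyn_rank_tbar} (R_bh,
#' release-locked).
#'
#' @param spec a \code{design_spec}.
#' @param N number of neurons.
#' @param rank stimulus tensor rank R_s (>= 0).
#' @param bases basis bundle from \code{default_bases()}.
#' @param rank_tbar touch-bar rank R_l.
#' @param include_history,include_tbar logical switches.
#' @param dyn_rank,dyn_rank_tbar dynamic spike-history ranks (0 = absent).
#' @return object of class \code{gmlm_model}.
#' @export
gmlm_model <- function(spec, N, rank, bases = default_bases(),
                       rank_tbar = 3L, include_history = TRUE,
                       include_tbar = TRUE, dyn_rank = 0L,
                       dyn_rank_tbar = 0L) {
  stopifnot(rank >= 0, rank_tbar >= 0, N >= 1)
  if ((dyn_rank > 0 || dyn_rank_tbar > 0) && !include_history)
    stop("dynamic spike history requires include_history = TRUE")
  structure(list(spec = spec, N = as.integer(N), rank = as.integer(rank),
                 bases = bases, rank_tbar = as.integer(rank_tbar),
                 include_history = include_history,
                 include_tbar = include_tbar,
                 dyn_rank = as.integer(dyn_rank),
                 dyn_rank_tbar = as.integer(dyn_rank_tbar),
                 P_stim = ncol(bases$stim$B), P_tbar = ncol(bases$tbar$B),
                 P_spk = ncol(bases$spk$B)),
            class = "gmlm_model")
}

#' GMLM parameter set
#'
#' Coefficient-space parameters: per-neuron baselines \code{w} (length N),
#' spike-history coefficients \code{H_spk} (P_spk x N), touch-bar factors
#' \code{T_tbar} (P_tbar x R_l) and \code{V_tbar} (N x R_l), and the CP
#' stimulus factors \code{T_stim} (P_stim x R_s), \code{U_stim} (S x R_s),
#' \code{V_stim} (N x R_s). \code{dyn}, when present, carries the dynamic
#' spike-history factors (\code{H_dspk} P_spk x R_h, \code{T_dspk} P_stim x
#' R_h, \code{U_dspk} 2 x R_h for sample/test weights, \code{V_dspk} N x
#' R_h; and \code{H_bdspk}, \code{T_bdspk} P_tbar x R_bh, \code{V_bdspk}).
#'
#' @param model a \code{gmlm_model}.
#' @param w,H_spk,T_tbar,V_tbar,T_stim,U_stim,V_stim,dyn components; any
#'   omitted component defaults to zeros of the right shape.
#' @return object of class \code{gmlm_params}.
#' @export
gmlm_params <- function(model, w = NULL, H_spk = NULL, T_tbar = NULL,
                        V_tbar = NULL, T_stim = NULL, U_stim = NULL,
                        V_stim = NULL, dyn = NULL) {
  z <- function(r, c) matrix(0, r, c)
  N <- model$N; R <- model$rank; Rl <- model$rank_tbar
  p <- list(
    w = if (is.null(w)) numeric(N) else w,
    H_spk = if (model$include_history)
      (if (is.null(H_spk)) z(model$P_spk, N) else H_spk),
    T_tbar = if (model$include_tbar)
      (if (is.null(T_tbar)) z(model$P_tbar, Rl) else T_tbar),
    V_tbar = if (model$include_tbar)
      (if (is.null(V_tbar)) z(N, Rl) else V_tbar),
    T_stim = if (is.null(T_stim)) z(model$P_stim, R) else T_stim,
    U_stim = if (is.null(U_stim)) z(model$spec$S, R) else U_stim,
    V_stim = if (is.null(V_stim)) z(N, R) else V_stim)
  rownames(p$U_stim) <- model$spec$labels
  if (model$dyn_rank > 0 || model$dyn_rank_tbar > 0) {
    if (is.null(dyn)) dyn <- list()
    dz <- function(nm, r, c) if (is.null(dyn[[nm]])) z(r, c) else dyn[[nm]]
    p$dyn <- list(
      H_dspk = dz("H_dspk", model$P_spk, model$dyn_rank),
      T_dspk = dz("T_dspk", model$P_stim, model$dyn_rank),
      U_dspk = dz("U_dspk", 2, model$dyn_rank),
      V_dspk = dz("V_dspk", N, model$dyn_rank),
      H_bdspk = dz("H_bdspk", model$P_spk, model$dyn_rank_tbar),
      T_bdspk = dz("T_bdspk", model$P_tbar, model$dyn_rank_tbar),
      V_bdspk = dz("V_bdspk", N, model$dyn_rank_tbar))
  }
  stopifnot(length(p$w) == N, ncol(p$T_stim) == R, ncol(p$U_stim) == R,
            nrow(p$U_stim) == model$spec$S, nrow(p$V_stim) == N)
  structure(p, class = "gmlm_params")
}

#' Random initialization of GMLM parameters
#'
#' Neuron loadings, stimulus weights and spike-history coefficients are
#' standard normal; temporal coefficient matrices are random orthonormal;
#' baselines are normal around the log mean firing rate.
#'
#' @param model a \code{gmlm_model}.
#' @param seed RNG seed.
#' @param w_center center for the baseline draw (log rate in sp/s).
#' @return a \code{gmlm_params}.
#' @export
init_gmlm_params <- function(model, seed = 1L, w_center = log(5)) {
  set.seed(seed)
  rorth <- function(r, c) {
    if (c == 0) return(matrix(0, r, 0))
    qr.Q(qr(matrix(stats::rnorm(r * c), r, c)))[, seq_len(c), drop = FALSE]
  }
  N <- model$N; R <- model$rank; Rl <- model$rank_tbar
  dyn <- NULL
  if (model$dyn_rank > 0 || model$dyn_rank_tbar > 0) {
    dyn <- list(H_dspk = matrix(stats::rnorm(model$P_spk * model$dyn_rank),
                                model$P_spk),
                T_dspk = rorth(model$P_stim, model$dyn_rank),
                U_dspk = matrix(stats::rnorm(2 * model$dyn_rank), 2),
                V_dspk = matrix(stats::rnorm(N * model$dyn_rank), N),
                H_bdspk = matrix(stats::rnorm(model$P_spk * model$dyn_rank_tbar),
                                 model$P_spk),
                T_bdspk = rorth(model$P_tbar, model$dyn_rank_tbar),
                V_bdspk = matrix(stats::rnorm(N * model$dyn_rank_tbar), N))
  }
  gmlm_params(model,
    w = stats::rnorm(N, w_center, 0.1),
    H_spk = if (model$include_history)
      matrix(stats::rnorm(model$P_spk * N, 0, 0.1), model$P_spk),
    T_tbar = if (model$include_tbar) rorth(model$P_tbar, Rl),
    V_tbar = if (model$include_tbar) matrix(stats::rnorm(N * Rl, 0, 0.1), N),
    T_stim = rorth(model$P_stim, R),
    U_stim = matrix(stats::rnorm(model$spec$S * R, 0, 0.5), model$spec$S),
    V_stim = matrix(stats::rnorm(N * R, 0, 0.5), N),
    dyn = dyn)
}

# design matrix of a basis aligned to an event bin: M[t, p] = B[t - event +
# lag0, p] within range, 0 outside; NULL event gives all zeros.
shift_design <- function(basis, event_bin, T_) {
  M <- matrix(0, T_, ncol(basis$B))
  if (is.na(event_bin)) return(M)
  L <- nrow(basis$B)
  rows <- seq_len(T_) - event_bin + basis$lag0  # basis row per time bin
  ok <- rows >= 1 & rows <= L
  M[ok, ] <- basis$B[rows[ok], , drop = FALSE]
  M
}

# spike-history design: Hmat[t, p] = sum_lag B[lag row, p] y(t - lag)
history_design <- function(counts, basis) {
  T_ <- length(counts)
  P <- ncol(basis$B)
  H <- matrix(0, T_, P)
  L <- nrow(basis$B)
  for (r in seq_len(L)) {
    lag <- r - basis$lag0
    if (lag < 1 || lag >= T_) next  # lag-0 row is structurally zero
    b <- basis$B[r, ]
    if (all(b == 0)) next
    H[(lag + 1):T_, ] <- H[(lag + 1):T_, ] +
      tcrossprod(counts[1:(T_ - lag)], b)
  }
  H
}

#' Per-bin log firing rate of the GMLM for one neuron and trial
#'
#' Reference evaluation: baseline + filtered spike history + low-rank
#' touch-bar response + the CP stimulus terms
#' \eqn{Z_r^{(s)}(t) = (x^{(dir,s)} \cdot U_r)(T_r * x^{(timing,s)})(t)},
#' each weighted by the neuron's loading. With dynamic spike history
#' configured, adds \code{dynamic_history_log_rate}.
#'
#' @param params a \code{gmlm_params}.
#' @param trial a \code{gmlm_trial}.
#' @param model a \code{gmlm_model}.
#' @param n neuron index (row of the loading matrices).
#' @return numeric per-bin log rate (rate in sp/s is \code{exp(.)}).
#' @export
gmlm_log_rate <- function(params, trial, model, n) {
  T_ <- length(trial$counts)
  reg <- trial_regressors(trial, model$spec)
  lam <- rep(params$w[n], T_)
  if (model$include_history)
    lam <- lam + history_design(trial$counts, model$bases$spk) %*%
      params$H_spk[, n]
  if (model$include_tbar && model$rank_tbar > 0) {
    Mtb <- shift_design(model$bases$tbar, trial$t_tbar, T_)
    lam <- lam + (Mtb %*% params$T_tbar) %*% params$V_tbar[n, ]
  }
  if (model$rank > 0) {
    Ms <- shift_design(model$bases$stim, trial$t_sample_on, T_)
    Mt <- shift_design(model$bases$stim, trial$t_test_on, T_)
    cs <- drop(crossprod(params$U_stim, reg$x_dir_sample))
    ct <- drop(crossprod(params$U_stim, reg$x_dir_test))
    lam <- lam + (Ms %*% params$T_stim) %*% (cs * params$V_stim[n, ]) +
      (Mt %*% params$T_stim) %*% (ct * params$V_stim[n, ])
  }
  if (!is.null(params$dyn))
    lam <- lam + dynamic_history_log_rate(params, trial, model, n)
  drop(lam)
}

#' Dynamic spike-history contribution to the log rate
#'
#' Low-rank gain modulation of the spike-history filter around task events:
#' each component multiplies a stimulus- (or release-) locked temporal gain
#' by the spike train filtered with a shared history kernel and the neuron's
#' loading. Zero whenever the dynamic factors or the spike train are zero.
#'
#' @inheritParams gmlm_log_rate
#' @return numeric per-bin additive log-rate term h_n(t).
#' @export
dynamic_history_log_rate <- function(params, trial, model, n) {
  if (is.null(params$dyn)) stop("model has no dynamic spike history")
  d <- params$dyn
  T_ <- length(trial$counts)
  Hmat <- history_design(trial$counts, model$bases$spk)
  h <- numeric(T_)
  if (model$dyn_rank_tbar > 0) {
    Mtb <- shift_design(model$bases$tbar, trial$t_tbar, T_)
    for (q in seq_len(model$dyn_rank_tbar))
      h <- h + (Mtb %*% d$T_bdspk[, q]) * (Hmat %*% d$H_bdspk[, q]) *
        d$V_bdspk[n, q]
  }
  if (model$dyn_rank > 0) {
    Ms <- shift_design(model$bases$stim, trial$t_sample_on, T_)
    Mt <- shift_design(model$bases$stim, trial$t_test_on, T_)
    for (r in seq_len(model$dyn_rank)) {
      fh <- Hmat %*% d$H_dspk[, r]
      h <- h + (d$U_dspk[1, r] * (Ms %*% d$T_dspk[, r]) +
                d$U_dspk[2, r] * (Mt %*% d$T_dspk[, r])) * fh * d$V_dspk[n, r]
    }
  }
  drop(h)
}

#' Effective spike-history kernel at a point in the trial
#'
#' The lag kernel a neuron applies to its own spiking at trial time t: the
#' constant history kernel plus the dynamic components scaled by their
#' event-locked temporal gains at t.
#'
#' @inheritParams gmlm_log_rate
#' @param t bin index within the trial.
#' @return numeric lag kernel on the spike-history basis time grid.
#' @export
effective_history_kernel <- function(params, trial, model, n, t) {
  Bspk <- model$bases$spk$B
  k <- drop(Bspk %*% params$H_spk[, n])
  if (is.null(params$dyn)) return(k)
  d <- params$dyn
  T_ <- length(trial$counts)
  if (model$dyn_rank_tbar > 0) {
    Mtb <- shift_design(model$bases$tbar, trial$t_tbar, T_)
    for (q in seq_len(model$dyn_rank_tbar))
      k <- k + d$V_bdspk[n, q] * drop(Mtb[t, ] %*% d$T_bdspk[, q]) *
        drop(Bspk %*% d$H_bdspk[, q])
  }
  if (model$dyn_rank > 0) {
    Ms <- shift_design(model$bases$stim, trial$t_sample_on, T_)
    Mt <- shift_design(model$bases$stim, trial$t_test_on, T_)
    for (r in seq_len(model$dyn_rank)) {
      gain <- d$U_dspk[1, r] * drop(Ms[t, ] %*% d$T_dspk[, r]) +
        d$U_dspk[2, r] * drop(Mt[t, ] %*% d$T_dspk[, r])
      k <- k + d$V_dspk[n, r] * gain * drop(Bspk %*% d$H_dspk[, r])
    }
  }
  k
}

#' Poisson log likelihood of one trial under the GMLM
#'
#' @inheritParams gmlm_log_rate
#' @return scalar \eqn{\sum_t [y \log(e^\lambda \Delta) - e^\lambda \Delta -
#'   \log y!]}.
#' @export
gmlm_trial_loglik <- function(params, trial, model, n,
                              bin_width = model$bases$stim$bin_width) {
  lam <- gmlm_log_rate(params, trial, model, n)
  y <- trial$counts
  sum(y * (lam + log(bin_width)) - exp(lam) * bin_width - lfactorial(y))
}

#' CP reconstruction of the stimulus kernel tensor
#'
#' \eqn{K(t,s,n) = \sum_r T_r(t) U_{s,r} V_{n,r}}; the fiber (., s, n) is
#' neuron n's GLM kernel for stimulus index s.
#'
#' @param params a \code{gmlm_params}.
#' @param model a \code{gmlm_model}.
#' @param time_domain multiply through the temporal basis (default) or stay
#'   in basis-coefficient space.
#' @return 3-way array, time (or coefficient) x S x N.
#' @export
kernel_tensor <- function(params, model, time_domain = TRUE) {
  Tm <- if (time_domain) model$bases$stim$B %*% params$T_stim else
    params$T_stim
  Tt <- nrow(Tm); S <- nrow(params$U_stim); N <- nrow(params$V_stim)
  K <- array(0, c(Tt, S, N))
  for (r in seq_len(model$rank))
    K <- K + outer(Tm[, r], outer(params$U_stim[, r], params$V_stim[, r]))
  dimnames(K) <- list(NULL, model$spec$labels, NULL)
  K
}

#' Total GMLM log likelihood over a dataset
#'
#' Reference path: neurons contribute independently; the population value is
#' the sum of per-trial single-neuron evaluations.
#'
#' @param params a \code{gmlm_params}.
#' @param dataset a \code{trial_dataset}.
#' @param model a \code{gmlm_model}.
#' @param trial_idx optional subset of trials.
#' @return scalar log likelihood.
#' @export
gmlm_log_likelihood <- function(params, dataset, model, trial_idx = NULL) {
  if (is.null(trial_idx)) trial_idx <- seq_along(dataset$trials)
  nmap <- stats::setNames(seq_along(dataset$neuron_ids),
                          as.character(dataset$neuron_ids))
  sum(vapply(trial_idx, function(i) {
    tr <- dataset$trials[[i]]
    gmlm_trial_loglik(params, tr, model, nmap[[as.character(tr$neuron)]],
                      dataset$bin_width)
  }, 0))
}
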