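# per-group log likelihood over grouped data (groups = trials when the
# data were prepared with per_trial = TRUE)
gmlm_ll_by_group <- function(params, data, model) {
  dt <- data$bin_width
  out <- list()
  for (bl in data$bylayout) {
    lay <- bl$layout
    Gn <- length(bl$m)
    Vt <- t(params$V_stim[bl$n_idx, , drop = FALSE])
    if (model$rank > 0) {
      As <- lay$Ms %*% params$T_stim; At <- lay$Mt %*% params$T_stim
      CSV <- crossprod(params$U_stim, bl$XS) * Vt
      CTV <- crossprod(params$U_stim, bl$XT) * Vt
      BASE <- cbind(As, At) %*% rbind(CSV, CTV)
      BASE <- BASE + rep(params$w[bl$n_idx], each = lay$T)
    } else BASE <- matrix(rep(params$w[bl$n_idx], each = lay$T), lay$T, Gn)
    if (model$include_tbar && model$rank_tbar > 0 && !is.null(lay$Mtb))
      BASE <- BASE + (lay$Mtb %*% params$T_tbar) %*%
        t(params$V_tbar[bl$n_idx, , drop = FALSE])
    if (model$include_history)
      for (j in seq_len(Gn))
        BASE[, j] <- BASE[, j] + bl$H[[j]] %*% params$H_spk[, bl$n_idx[j]]
    if (!is.null(params$dyn))
      BASE <- BASE + dyn_forward(params$dyn, bl, lay, model)$add
    ll <- colSums(bl$Y * BASE) + colSums(bl$Y) * log(dt) -
      dt * colSums(exp(BASE)) * bl$m - bl$lfact
    out[[length(out) + 1L]] <- list(ll = ll,
                                    trial = vapply(bl$trials, `[`, 0L, 1L),
                                    neuron = bl$n_idx)
  }
  list(ll = unlist(lapply(out, `[[`, "ll")),
       trial = unlist(lapply(out, `[[`, "trial")),
       neuron = unlist(lapply(out, `[[`, "neuron")))
}

# generalized Pareto fit to exceedances (Zhang & Stephens 2009 posterior-
# mean style estimator)
gpd_fit <- function(x) {
  x <- sort(x)
  n <- length(x)
  m <- 30L + floor(sqrt(n))
  j <- seq_len(m)
  xq <- x[max(1L, floor(n / 4 + 0.5))]
  b <- 1 / x[n] + (1 - sqrt(m / (j - 0.5))) / (3 * xq)
  k_j <- -vapply(b, function(bb) mean(log1p(-bb * x)), 0)
  l_j <- n * (log(b / k_j) + k_j - 1)
  w <- 1 / vapply(l_j, function(l) sum(exp(l_j - l)), 0)
  b_hat <- sum(b * w)
  k_hat <- -mean(log1p(-b_hat * x))
  list(k = k_hat, sigma = k_hat / b_hat)
}

qgpd <- function(p, k, sigma) sigma * expm1(-k * log1p(-p)) / k

#' Pareto-smoothed importance-sampling weights
#'
#' Smooths the largest importance ratios by replacing them with expected
#' order statistics of a generalized Pareto fit to the tail, then truncates
#' at the raw maximum.
#'
#' @param log_ratios raw log importance ratios for one held-out point.
#' @return list: \code{log_weights} (same length, unnormalized),
#'   \code{pareto_k}.
#' @export
psis_smooth <- function(log_ratios) {
  S <- length(log_ratios)
  M <- ceiling(min(0.2 * S, 3 * sqrt(S)))
  lw <- log_ratios - max(log_ratios)
  ord <- order(lw)
  tail_ids <- ord[(S - M + 1):S]
  cut <- lw[ord[S - M]]
  exc <- exp(lw[tail_ids]) - exp(cut)
  if (length(unique(exc)) < 2 || max(exc) <= 0)
    return(list(log_weights = lw, pareto_k = -Inf))
  fit <- gpd_fit(exc[exc > 0])
  if (!is.finite(fit$k))
    return(list(log_weights = lw, pareto_k = Inf))
  p <- (seq_len(M) - 0.5) / M
  repl <- log(exp(cut) + qgpd(p, fit$k, fit$sigma))
  lw[tail_ids[order(lw[tail_ids])]] <- pmin(repl, 0)
  list(log_weights = lw, pareto_k = fit$k)
}

log_sum_exp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' PSIS-LOO model assessment from posterior draws
#'
#' Leave-one-trial-out predictive log likelihood estimated by
#' Pareto-smoothed importance sampling over the posterior draws, then
#' averaged within neuron (mean held-out log likelihood per trial per
#' cell).
#'
#' @param samples a \code{posterior_samples}.
#' @param dataset the \code{trial_dataset} the sampler was run on.
#' @param thin keep every \code{thin}-th draw.
#' @param k_warn Pareto-k threshold for the reliability warning.
#' @return list: \code{elpd_trial} (per trial), \code{lp_neuron} (per-neuron
#'   means), \code{pareto_k}, \code{neuron} (index per trial),
#'   \code{frac_high_k}.
#' @export
psis_loo <- function(samples, dataset, thin = 10L, k_warn = 0.7) {
  model <- samples$model
  data <- prepare_pop_data(dataset, model, per_trial = TRUE)
  keep <- seq(1, nrow(samples$draws), by = thin)
  LL <- vapply(keep, function(i) {
    p <- unpack_params(samples$draws[i, seq_len(samples$n_param)], model)
    gmlm_ll_by_group(p, data, model)$ll
  }, numeric(data$n_trials))          # n_trials x S after transpose
  meta <- gmlm_ll_by_group(unpack_params(samples$draws[1,
                             seq_len(samples$n_param)], model), data, model)
  LL <- t(LL)                          # draws x trials
  n <- ncol(LL)
  elpd <- numeric(n); pk <- numeric(n)
  for (i in seq_len(n)) {
    sm <- psis_smooth(-LL[, i])        # ratios 1/p(y_i | theta)
    elpd[i] <- log_sum_exp(sm$log_weights + LL[, i]) -
      log_sum_exp(sm$log_weights)
    pk[i] <- sm$pareto_k
  }
  frac_high <- mean(pk > k_warn)
  if (frac_high > 0)
    warning(sprintf("%.0f%% of trials have Pareto k > %.2f",
                    100 * frac_high, k_warn))
  lp_neuron <- tapply(elpd, meta$neuron, mean)
  list(elpd_trial = elpd, lp_neuron = lp_neuron, pareto_k = pk,
       neuron = meta$neuron, frac_high_k = frac_high)
}
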