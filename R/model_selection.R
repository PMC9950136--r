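# per-neuron log likelihood over grouped data (no gradient); also returns
# per-neuron trial counts and, optionally, per-(neuron, fold) sums
gmlm_ll_by_neuron <- function(params, data, model) {
  dt <- data$bin_width
  lln <- numeric(data$N)
  mn <- numeric(data$N)
  for (bl in data$bylayout) {
    lay <- bl$layout
    Gn <- length(bl$m)
    Vt <- t(params$V_stim[bl$n_idx, , drop = FALSE])
    if (model$rank > 0) {
      As <- lay$Ms %*% params$T_stim; At <- lay$Mt %*% params$T_stim
      CSV <- crossprod(params$U_stim, bl$XS) * Vt
      CTV <- crossprod(params$U_stim, bl$XT) * Vt
      BASE <- As %*% CSV + At %*% CTV
    } else BASE <- matrix(0, lay$T, Gn)
    BASE <- sweep(BASE, 2, params$w[bl$n_idx], "+")
    if (model$include_tbar && model$rank_tbar > 0 && !is.null(lay$Mtb))
      BASE <- BASE + (lay$Mtb %*% params$T_tbar) %*%
        t(params$V_tbar[bl$n_idx, , drop = FALSE])
    if (model$include_history)
      for (j in seq_len(Gn))
        BASE[, j] <- BASE[, j] + bl$H[[j]] %*% params$H_spk[, bl$n_idx[j]]
    contrib <- colSums(bl$Y * BASE) + colSums(bl$Y) * log(dt) -
      dt * colSums(exp(BASE)) * bl$m - bl$lfact
    for (j in seq_len(Gn)) {
      lln[bl$n_idx[j]] <- lln[bl$n_idx[j]] + contrib[j]
      mn[bl$n_idx[j]] <- mn[bl$n_idx[j]] + bl$m[j]
    }
  }
  list(ll = lln, n_trials = mn)
}

#' Cross-validated log likelihood of a model family
#'
#' Refits the model on each training fold and evaluates held-out trials,
#' reporting the mean test log likelihood per trial per cell, its
#' population average, and per-fold population averages for error bars.
#' GMLM fits use maximum likelihood (as in rank selection); the single-cell
#' GLM reference is MAP at fixed hyperparameters.
#'
#' @param dataset a \code{trial_dataset}.
#' @param folds a \code{fold_assignment} over the dataset's trials.
#' @param family list describing the model: \code{list(type = "gmlm", model
#'   = <gmlm_model>)} or \code{list(type = "glm", spec = <design_spec>,
#'   include_history =, include_tbar =, hyper =)}.
#' @param bases basis bundle (GLM family).
#' @param seed,maxit,n_starts fitting controls.
#' @return object of class \code{cv_report}: \code{lp} per neuron (mean
#'   held-out log likelihood per trial), \code{lp_bar}, \code{lp_bar_fold} (length K),
#'   \code{K}.
#' @export
cv_log_likelihood <- function(dataset, folds, family,
                              bases = default_bases(), seed = 1L,
                              maxit = 500L, n_starts = 1L) {
  K <- folds$K
  spec <- if (family$type == "gmlm") family$model$spec else family$spec
  usable <- usable_trials(dataset, spec)
  N <- length(dataset$neuron_ids)
  ll_nk <- matrix(0, N, K)  # per-neuron, per-fold held-out loglik sums
  m_nk <- matrix(0, N, K)
  nmap <- stats::setNames(seq_len(N), as.character(dataset$neuron_ids))
  for (k in seq_len(K)) {
    train <- intersect(which(folds$fold_of_trial != k), usable)
    test <- intersect(which(folds$fold_of_trial == k), usable)
    if (length(test) == 0) {
      warning("fold ", k, " has no test trials; skipped")
      next
    }
    if (family$type == "gmlm") {
      fit <- fit_gmlm_ml(dataset, family$model, seed = seed + k,
                         trial_idx = train, maxit = maxit,
                         n_starts = n_starts)
      td <- prepare_pop_data(dataset, family$model, trial_idx = test)
      # per-(neuron, fold) sums from the aggregated engine
      res <- gmlm_ll_by_neuron(fit$params, td, family$model)
      ll_nk[, k] <- res$ll
      tn <- nmap[vapply(dataset$trials[intersect(test, usable)],
                        function(tr) as.character(tr$neuron), "")]
      m_nk[, k] <- tabulate(tn, nbins = N)
    } else {
      hyper <- if (!is.null(family$hyper)) family$hyper else
        default_hyper(spec, isTRUE(family$include_tbar),
                      isTRUE(family$include_history))
      for (nid in dataset$neuron_ids) {
        n <- nmap[[as.character(nid)]]
        tr_n <- test[vapply(dataset$trials[test], function(tr)
          as.character(tr$neuron) == as.character(nid), TRUE)]
        if (length(tr_n) == 0) next
        fit <- if (isTRUE(family$evidence)) {
          # hyperparameters re-optimized independently on each training fold
          optimize_evidence(dataset, spec, nid, bases,
                            include_history = isTRUE(family$include_history),
                            include_tbar = isTRUE(family$include_tbar),
                            trial_idx = train, maxit = 40)$fit
        } else {
          fit_glm_map(dataset, spec, nid, hyper, bases,
                      include_history = isTRUE(family$include_history),
                      include_tbar = isTRUE(family$include_tbar),
                      trial_idx = train)
        }
        ll_nk[n, k] <- sum(vapply(dataset$trials[tr_n], function(tr)
          glm_trial_loglik(fit$params, tr, spec, bases,
                           dataset$bin_width), 0))
        m_nk[n, k] <- length(tr_n)
      }
    }
  }
  M_n <- rowSums(m_nk)
  lp <- ifelse(M_n > 0, rowSums(ll_nk) / pmax(M_n, 1), NA_real_)
  lp_fold <- colSums(ll_nk) / pmax(colSums(m_nk), 1)  # population mean per fold
  # population average of per-neuron means, per fold
  lp_bar_fold <- vapply(seq_len(K), function(k)
    mean(ifelse(m_nk[, k] > 0, ll_nk[, k] / pmax(m_nk[, k], 1), NA_real_),
         na.rm = TRUE), 0)
  structure(list(lp = lp, lp_bar = mean(lp, na.rm = TRUE),
                 lp_bar_fold = lp_bar_fold, K = K),
            class = "cv_report")
}

#' Fraction of explainable cross-validated log likelihood
#'
#' \code{frac = (lp_bar(model) - lp_bar(rank0)) / (lp_bar(GLM) -
#' lp_bar(rank0))}: the rank-0 model (no stimulus terms) defines zero and
#' the full-rank single-cell GLM defines one. May exceed 1 when the
#' low-rank model generalizes better than the GLM.
#'
#' @param report_model,report_rank0,report_glm \code{cv_report}s.
#' @return scalar fraction.
#' @export
fraction_explained <- function(report_model, report_rank0, report_glm) {
  d_glm <- report_glm$lp_bar - report_rank0$lp_bar
  if (!is.finite(d_glm) || d_glm <= 0)
    stop("GLM explainable log likelihood is not positive; frac undefined")
  (report_model$lp_bar - report_rank0$lp_bar) / d_glm
}

#' Select the stimulus tensor rank
#'
#' Smallest rank whose explainable-likelihood fraction exceeds the
#' threshold (default 0.9). If none qualifies, the largest tested rank is
#' returned with attribute \code{saturated = FALSE}.
#'
#' @param frac named numeric vector of fractions, names = ranks.
#' @param threshold fraction threshold.
#' @return selected rank (integer) with attribute \code{saturated}.
#' @export
select_rank <- function(frac, threshold = 0.9) {
  stopifnot(length(frac) > 0)
  ranks <- as.integer(names(frac))
  if (any(is.na(ranks))) ranks <- seq_along(frac)
  ok <- which(frac > threshold)
  if (length(ok) == 0)
    return(structure(max(ranks), saturated = FALSE))
  structure(ranks[min(ok)], saturated = TRUE)
}

#' Stimulus-parameter counts: GMLM vs per-cell GLMs
#'
#' The rank-R GMLM uses \code{P_stim*R + S*R + N*R} stimulus parameters
#' against \code{N*S*P_stim} for independent single-cell GLM kernels. Totals
#' including baselines, spike history and touch-bar terms are also
#' reported.
#'
#' @param spec a \code{design_spec}.
#' @param N number of neurons.
#' @param rank tensor rank.
#' @param P_stim,P_spk,P_tbar basis sizes.
#' @param rank_tbar touch-bar rank.
#' @return list: \code{gmlm_stim}, \code{glm_stim}, \code{ratio},
#'   \code{gmlm_total}, \code{glm_total}, \code{ratio_total}.
#' @export
count_parameters <- function(spec, N, rank, P_stim = 24, P_spk = 10,
                             P_tbar = 8, rank_tbar = 3) {
  S <- spec$S
  gmlm_stim <- P_stim * rank + S * rank + N * rank
  glm_stim <- N * S * P_stim
  extra_gmlm <- N + P_spk * N + P_tbar * rank_tbar + N * rank_tbar
  extra_glm <- N * (1 + P_spk + P_tbar)
  list(gmlm_stim = gmlm_stim, glm_stim = glm_stim,
       ratio = gmlm_stim / glm_stim,
       gmlm_total = gmlm_stim + extra_gmlm,
       glm_total = glm_stim + extra_glm,
       ratio_total = (gmlm_stim + extra_gmlm) / (glm_stim + extra_glm))
}

#' Two-standard-error bars over folds
#'
#' @param per_fold per-fold values (e.g. \code{lp_bar_fold} differences).
#' @return list: \code{mean}, \code{half_width} (2 SEM), \code{lo},
#'   \code{hi}.
#' @export
fold_error_bars <- function(per_fold) {
  stopifnot(length(per_fold) >= 2)
  m <- mean(per_fold)
  hw <- 2 * stats::sd(per_fold) / sqrt(length(per_fold))
  list(mean = m, half_width = hw, lo = m - hw, hi = m + hw)
}

#' Cross-validated rank sweep with rank selection
#'
#' Fits the rank-0 reference, the GMLM at each requested rank, and the
#' single-cell GLM of the same parameterization on each training fold, and
#' assembles per-rank explainable-likelihood fractions and the selected
#' rank.
#'
#' @param dataset a \code{trial_dataset}.
#' @param spec a \code{design_spec}.
#' @param ranks integer vector of candidate ranks (>= 1).
#' @param folds a \code{fold_assignment}.
#' @param bases basis bundle.
#' @param include_history,include_tbar model switches (shared).
#' @param rank_tbar touch-bar rank when included.
#' @param threshold selection threshold on frac.
#' @param seed,maxit,n_starts fitting controls.
#' @return list: \code{table} (data.frame rank/delta_lp_bar/frac),
#'   \code{selected}, \code{reports}.
#' @export
rank_sweep <- function(dataset, spec, ranks = 1:4, folds,
                       bases = default_bases(), include_history = FALSE,
                       include_tbar = FALSE, rank_tbar = 3L,
                       threshold = 0.9, seed = 1L, maxit = 500L,
                       n_starts = 1L, glm_evidence = TRUE) {
  N <- length(dataset$neuron_ids)
  mk <- function(r) gmlm_model(spec, N, r, bases,
                               rank_tbar = if (include_tbar) rank_tbar else 0L,
                               include_history = include_history,
                               include_tbar = include_tbar)
  rep0 <- cv_log_likelihood(dataset, folds, list(type = "gmlm",
                                                 model = mk(0L)),
                            bases, seed, maxit, n_starts)
  rep_glm <- cv_log_likelihood(dataset, folds,
                               list(type = "glm", spec = spec,
                                    include_history = include_history,
                                    include_tbar = include_tbar,
                                    evidence = glm_evidence),
                               bases, seed, maxit, n_starts)
  reports <- lapply(ranks, function(r)
    cv_log_likelihood(dataset, folds, list(type = "gmlm", model = mk(r)),
                      bases, seed, maxit, n_starts))
  frac <- vapply(reports, fraction_explained, 0, report_rank0 = rep0,
                 report_glm = rep_glm)
  names(frac) <- ranks
  tab <- data.frame(rank = ranks,
                    delta_lp_bar = vapply(reports, function(r)
                      r$lp_bar - rep0$lp_bar, 0),
                    frac = as.numeric(frac))
  list(table = tab, selected = select_rank(frac, threshold),
       reports = c(list(rank0 = rep0, glm = rep_glm),
                   stats::setNames(reports, paste0("rank", ranks))))
}
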