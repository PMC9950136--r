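# Stimulus prior covariance and its derivatives w.r.t. the log
# hyperparameters. Sigma is linear in the squared scales except for the
# Gaussian-process arc-length tau of the full models.
stim_prior_terms <- function(spec, hyper, want_d = FALSE) {
  p <- spec$parameterization
  S <- spec$S
  pad <- function(M, at) {
    out <- matrix(0, S, S)
    out[at, at] <- M
    out
  }
  comps <- list()
  if (p == "none") {
    comps$psi_0 <- matrix(1, 2, 2)
    comps$psi_s <- diag(2)
  } else if (p == "category") {
    comps$psi_0 <- matrix(1, 4, 4)
    comps$psi_c <- diag(4)
  } else if (p %in% c("cosine", "cosine_independent")) {
    comps$psi_0 <- pad(matrix(1, 4, 4), 1:4)
    comps$psi_c <- pad(diag(4), 1:4)
    comps$psi_d <- pad(diag(S - 4), 5:S)
  } else {
    # full / full_independent: latent-sum construction via loading matrix L
    th <- spec$direction_set
    D <- spec$D
    cats <- direction_category(th, spec$boundary)
    if (p == "full") {
      L0 <- matrix(0, S, 1); Lc <- matrix(0, S, 4); Ld <- matrix(0, S, 2)
      Lgp <- matrix(0, S, D)
      rn <- spec$labels
      for (d in seq_len(D)) {
        i <- match(paste0("theta_", th[d]), rn)
        L0[i, 1] <- 1; Lc[i, cats[d]] <- 1
        Ld[i, 1] <- cos(th[d] * pi / 180); Ld[i, 2] <- sin(th[d] * pi / 180)
        Lgp[i, d] <- 1
      }
      for (k in 1:2) {
        i <- match(paste0("ct", k), rn)
        L0[i, 1] <- 1; Lc[i, 2 + k] <- 1; Lc[i, k] <- -1
      }
      gp_list <- list(Lgp)
    } else {
      L0 <- matrix(0, S, 1); Lc <- matrix(0, S, 4); Ld <- matrix(0, S, 4)
      Lgp_s <- matrix(0, S, D); Lgp_t <- matrix(0, S, D)
      rn <- spec$labels
      for (role in 1:2) {
        pre <- if (role == 1) "stheta_" else "ttheta_"
        for (d in seq_len(D)) {
          i <- match(paste0(pre, th[d]), rn)
          L0[i, 1] <- 1; Lc[i, cats[d]] <- 1
          Ld[i, (role - 1) * 2 + 1] <- cos(th[d] * pi / 180)
          Ld[i, (role - 1) * 2 + 2] <- sin(th[d] * pi / 180)
          if (role == 1) Lgp_s[i, d] <- 1 else Lgp_t[i, d] <- 1
        }
      }
      for (k in 1:2) {
        i <- match(paste0("ct", k), rn)
        L0[i, 1] <- 1; Lc[i, 2 + k] <- 1; Lc[i, k] <- -1
      }
      gp_list <- list(Lgp_s, Lgp_t)
    }
    comps$psi_0 <- tcrossprod(L0)
    comps$psi_c <- tcrossprod(Lc)
    comps$psi_d <- tcrossprod(Ld)
    K <- gp_direction_kernel(th, tau = hyper$tau)
    comps$psi_theta <- Reduce(`+`, lapply(gp_list,
                                          function(Lg) Lg %*% K %*% t(Lg)))
    if (want_d) {
      dK <- gp_kernel_dtau(th, hyper$tau)
      attr(comps, "dtau") <- hyper$psi_theta^2 * hyper$tau *
        Reduce(`+`, lapply(gp_list, function(Lg) Lg %*% dK %*% t(Lg)))
    }
  }
  Sigma <- Reduce(`+`, lapply(names(comps),
                              function(nm) hyper[[nm]]^2 * comps[[nm]]))
  dimnames(Sigma) <- list(spec$labels, spec$labels)
  list(Sigma = Sigma, comps = comps, dtau = attr(comps, "dtau"))
}

# derivative of the circular GP kernel w.r.t. tau
gp_kernel_dtau <- function(theta, tau) {
  d <- acos(pmin(pmax(cos(outer(theta, theta, "-") * pi / 180), -1), 1))
  base <- 1 - d / pi
  out <- (d / pi) * base^(tau + 4)
  pos <- base > 0
  out[pos] <- out[pos] +
    (1 + (tau + 4) / pi * d[pos]) * base[pos]^(tau + 4) * log(base[pos])
  out[!pos] <- 0
  out
}

# names of the active hyperparameters for a model
gmlm_hyper_names <- function(model) {
  nm <- stim_hyper_names(model$spec)
  if (model$include_tbar && model$rank_tbar > 0) nm <- c(nm, "psi_tbar")
  if (model$include_history) nm <- c(nm, "psi_spk")
  if (!is.null(model$dyn_rank) && model$dyn_rank_tbar > 0)
    nm <- c(nm, "psi_bdspk")
  if (!is.null(model$dyn_rank) && model$dyn_rank > 0)
    nm <- c(nm, "psi_0_dyn", "psi_s_dyn")
  nm
}

#' Joint log posterior of the GMLM
#'
#' Log likelihood plus log priors: each column of the stimulus weight matrix
#' U is priced by the structured stimulus prior of the matching single-cell
#' GLM; temporal stimulus coefficients and all neuron loadings are i.i.d.
#' standard normal; touch-bar coefficients are N(0, psi_tbar^2) and
#' spike-history coefficients N(0, psi_spk^2); baselines get an improper
#' flat prior. Hyperparameters get the half-t-style hyperprior; when
#' \code{log_scale_hypers} the density includes the log-transform Jacobian
#' (for sampling in log space).
#'
#' @param params a \code{gmlm_params}.
#' @param hyper named list of hyperparameters.
#' @param data grouped data from \code{prepare_pop_data} (or a
#'   \code{trial_dataset}, which is prepared on the fly).
#' @param model a \code{gmlm_model}.
#' @param want_grad also return gradients.
#' @param log_scale_hypers include hyperprior + Jacobian terms and gradients
#'   with respect to the log hyperparameters.
#' @return list(lp, grad_params (packed vector), grad_hyper (named)).
#' @export
gmlm_log_posterior <- function(params, hyper, data, model,
                               want_grad = FALSE, log_scale_hypers = TRUE) {
  if (inherits(data, "trial_dataset")) data <- prepare_pop_data(data, model)
  res <- gmlm_ll_grad(params, data, model, want_grad)
  lp <- res$ll
  g <- res$grad
  hn <- gmlm_hyper_names(model)
  gh <- stats::setNames(numeric(length(hn)), hn)
  bad <- function() list(lp = -Inf,
                         grad_params = if (want_grad)
                           numeric(length(pack_params(params))),
                         grad_hyper = if (want_grad) gh)
  if (!all(is.finite(unlist(hyper))) || any(unlist(hyper) <= 0))
    return(bad())
  spt <- stim_prior_terms(model$spec, hyper, want_d = want_grad)
  Sigma <- spt$Sigma
  if (!all(is.finite(Sigma))) return(bad())
  ch <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(ch) || any(diag(ch) < sqrt(.Machine$double.xmin)))
    return(bad())  # numerically singular prior: reject this hyper state
  Sinv <- chol2inv(ch)
  ld <- 2 * sum(log(diag(ch)))
  R <- model$rank
  if (R > 0) {
    SU <- Sinv %*% params$U_stim                     # S x R
    lp <- lp - 0.5 * sum(params$U_stim * SU) -
      R / 2 * (ld + model$spec$S * log(2 * pi))
    # standard normal on T_stim, V_stim
    lp <- lp - 0.5 * sum(params$T_stim^2) -
      length(params$T_stim) / 2 * log(2 * pi)
    lp <- lp - 0.5 * sum(params$V_stim^2) -
      length(params$V_stim) / 2 * log(2 * pi)
    if (want_grad) {
      g$U_stim <- g$U_stim - SU
      g$T_stim <- g$T_stim - params$T_stim
      g$V_stim <- g$V_stim - params$V_stim
      for (nm in intersect(names(spt$comps), hn)) {
        C <- 2 * hyper[[nm]]^2 * spt$comps[[nm]]     # dSigma/dlog psi
        A <- Sinv %*% C
        gh[nm] <- gh[nm] + 0.5 * sum(SU * (C %*% SU)) - R / 2 * sum(diag(A))
      }
      if (!is.null(spt$dtau) && "tau" %in% hn) {
        A <- Sinv %*% spt$dtau
        gh["tau"] <- gh["tau"] + 0.5 * sum(SU * (spt$dtau %*% SU)) -
          R / 2 * sum(diag(A))
      }
    }
  }
  if (model$include_tbar && model$rank_tbar > 0) {
    v2 <- hyper$psi_tbar^2
    nT <- length(params$T_tbar)
    lp <- lp - 0.5 * sum(params$T_tbar^2) / v2 -
      nT / 2 * log(2 * pi * v2) -
      0.5 * sum(params$V_tbar^2) - length(params$V_tbar) / 2 * log(2 * pi)
    if (want_grad) {
      g$T_tbar <- g$T_tbar - params$T_tbar / v2
      g$V_tbar <- g$V_tbar - params$V_tbar
      gh["psi_tbar"] <- sum(params$T_tbar^2) / v2 - nT
    }
  }
  if (model$include_history) {
    v2 <- hyper$psi_spk^2
    nH <- length(params$H_spk)
    lp <- lp - 0.5 * sum(params$H_spk^2) / v2 - nH / 2 * log(2 * pi * v2)
    if (want_grad) {
      g$H_spk <- g$H_spk - params$H_spk / v2
      gh["psi_spk"] <- sum(params$H_spk^2) / v2 - nH
    }
  }
  if (!is.null(params$dyn)) {
    d <- params$dyn
    std <- c("H_dspk", "T_dspk", "V_dspk", "H_bdspk", "V_bdspk")
    for (nm in std) {
      lp <- lp - 0.5 * sum(d[[nm]]^2) - length(d[[nm]]) / 2 * log(2 * pi)
      if (want_grad) g$dyn[[nm]] <- g$dyn[[nm]] - d[[nm]]
    }
    if (model$dyn_rank_tbar > 0) {
      v2 <- hyper$psi_bdspk^2
      nT <- length(d$T_bdspk)
      lp <- lp - 0.5 * sum(d$T_bdspk^2) / v2 - nT / 2 * log(2 * pi * v2)
      if (want_grad) {
        g$dyn$T_bdspk <- g$dyn$T_bdspk - d$T_bdspk / v2
        gh["psi_bdspk"] <- sum(d$T_bdspk^2) / v2 - nT
      }
    }
    if (model$dyn_rank > 0) {
      Sd <- matrix(hyper$psi_0_dyn^2, 2, 2) + diag(hyper$psi_s_dyn^2, 2)
      Sdi <- solve(Sd)
      Rh <- model$dyn_rank
      SUd <- Sdi %*% d$U_dspk
      lp <- lp - 0.5 * sum(d$U_dspk * SUd) -
        Rh / 2 * (determinant(Sd, TRUE)$modulus + 2 * log(2 * pi))
      if (want_grad) {
        g$dyn$U_dspk <- g$dyn$U_dspk - SUd
        for (nm in c("psi_0_dyn", "psi_s_dyn")) {
          C <- if (nm == "psi_0_dyn") 2 * hyper$psi_0_dyn^2 * matrix(1, 2, 2)
               else 2 * hyper$psi_s_dyn^2 * diag(2)
          gh[nm] <- gh[nm] + 0.5 * sum(SUd * (C %*% SUd)) -
            Rh / 2 * sum(diag(Sdi %*% C))
        }
      }
    }
  }
  if (log_scale_hypers) {
    for (nm in hn) {
      h <- hyper[[nm]]
      lp <- lp + log_hyperprior(h) + log(h)       # Jacobian of h = exp(lh)
      if (want_grad) gh[nm] <- gh[nm] + dlog_hyperprior_dlogh(h) + 1
    }
  }
  list(lp = as.numeric(lp),
       grad_params = if (want_grad) pack_params(g),
       grad_hyper = if (want_grad) gh)
}

#' Maximum-likelihood fit of the GMLM
#'
#' L-BFGS-B on the packed parameter vector using the analytic gradient of
#' the Poisson log likelihood (no priors); this is the estimate used for
#' rank selection.
#'
#' @param dataset a \code{trial_dataset} (or prepared \code{gmlm_data}).
#' @param model a \code{gmlm_model}.
#' @param init optional \code{gmlm_params} starting point.
#' @param seed seed for the random initialization.
#' @param trial_idx optional trial subset (training fold).
#' @param maxit optimizer iteration cap.
#' @return list(params, loglik, convergence).
#' @export
fit_gmlm_ml <- function(dataset, model, init = NULL, seed = 1L,
                        trial_idx = NULL, maxit = 500L, n_starts = 2L) {
  data <- if (inherits(dataset, "gmlm_data")) dataset else
    prepare_pop_data(dataset, model, trial_idx)
  rate0 <- log(max(data$sum_y, 1) /
               (sum(vapply(data$bylayout, function(b)
                 nrow(b$Y) * sum(b$m), 0)) * data$bin_width))
  fn <- function(x) {
    v <- -gmlm_ll_grad(unpack_params(x, model), data, model,
                       want_grad = FALSE)$ll
    if (!is.finite(v)) 1e12 else v  # line search backtracks from overflow
  }
  gr <- function(x) {
    g <- -pack_params(gmlm_ll_grad(unpack_params(x, model), data,
                                   model, want_grad = TRUE)$grad)
    g[!is.finite(g)] <- 0
    g
  }
  starts <- if (!is.null(init)) list(pack_params(init)) else
    lapply(seq_len(max(1L, n_starts)), function(k)
      pack_params(init_gmlm_params(model, seed + (k - 1L) * 1000L,
                                   w_center = rate0)))
  best <- NULL
  for (x0 in starts) {
    opt <- stats::optim(x0, fn, gr, method = "L-BFGS-B",
                        control = list(maxit = maxit, factr = 1e8))
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  list(params = unpack_params(best$par, model), loglik = -best$value,
       convergence = best$convergence)
}

#' MAP fit of the GMLM at fixed hyperparameters
#'
#' @inheritParams fit_gmlm_ml
#' @param hyper named hyperparameter list.
#' @return list(params, logpost, convergence).
#' @export
fit_gmlm_map <- function(dataset, model, hyper, init = NULL, seed = 1L,
                         trial_idx = NULL, maxit = 500L) {
  data <- if (inherits(dataset, "gmlm_data")) dataset else
    prepare_pop_data(dataset, model, trial_idx)
  if (is.null(init)) init <- init_gmlm_params(model, seed)
  x0 <- pack_params(init)
  fn <- function(x) {
    v <- -gmlm_log_posterior(unpack_params(x, model), hyper, data,
                             model, log_scale_hypers = FALSE)$lp
    if (!is.finite(v)) 1e12 else v
  }
  gr <- function(x) {
    g <- -gmlm_log_posterior(unpack_params(x, model), hyper, data,
                             model, want_grad = TRUE,
                             log_scale_hypers = FALSE)$grad_params
    g[!is.finite(g)] <- 0
    g
  }
  opt <- stats::optim(x0, fn, gr, method = "L-BFGS-B",
                      control = list(maxit = maxit, factr = 1e8))
  list(params = unpack_params(opt$par, model), logpost = -opt$value,
       convergence = opt$convergence)
}
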