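#' Circular Gaussian-process kernel over motion direction
#'
#' \eqn{K(\theta,\theta') = (1 + ((\tau+4)/\pi) d)(1 - d/\pi)^{\tau+4}} with
#' arc distance \eqn{d = \arccos(\cos(\theta-\theta'))}. Positive definite on
#' the circle for \eqn{\tau \ge 0}; K = 1 at d = 0 and K = 0 at d = \eqn{\pi}.
#'
#' @param theta,theta_p angles in degrees.
#' @param tau nonnegative arc-length hyperparameter.
#' @return kernel matrix over the angle pairs.
#' @export
gp_direction_kernel <- function(theta, theta_p = theta, tau = 1) {
  stopifnot(tau >= 0)
  d <- acos(pmin(pmax(cos(outer(theta, theta_p, "-") * pi / 180), -1), 1))
  (1 + (tau + 4) / pi * d) * (1 - d / pi)^(tau + 4)
}

#' Names of the stimulus hyperparameters for a parameterization
#' @param spec a \code{design_spec}.
#' @return character vector of hyperparameter names.
#' @export
stim_hyper_names <- function(spec) {
  switch(spec$parameterization,
         none = c("psi_0", "psi_s"),
         category = c("psi_0", "psi_c"),
         cosine = ,
         cosine_independent = c("psi_0", "psi_c", "psi_d"),
         full = ,
         full_independent = c("psi_0", "psi_c", "psi_d", "psi_theta", "tau"))
}

#' Default hyperparameter set
#' @param spec a \code{design_spec}.
#' @param include_tbar,include_history whether those kernel groups exist.
#' @return named list of positive scales (and \code{tau}).
#' @export
default_hyper <- function(spec, include_tbar = TRUE, include_history = TRUE) {
  h <- as.list(stats::setNames(rep(1, length(stim_hyper_names(spec))),
                               stim_hyper_names(spec)))
  if (include_tbar) h$psi_tbar <- 1
  if (include_history) h$psi_spk <- 1
  h
}

#' Structured Gaussian prior over the stimulus coefficients
#'
#' Builds the S x S covariance over the per-basis-index stimulus
#' coefficients from the latent-sum constructions: a shared kernel latent
#' (variance \code{psi_0^2}) induces sample/test correlations; category
#' latents add \code{psi_c^2} (or \code{psi_s^2} for the no-tuning model);
#' the cosine weights get independent \code{psi_d^2}; the full model adds
#' latent cosine weighting plus a circular Gaussian-process term
#' (\code{psi_theta^2}, \code{tau}) over the direction kernels, with the
#' test-category kernels built as shared + test-category - sample-category
#' to match the identifiability convention. Scalar variances are returned
#' for the touch-bar and spike-history coefficients.
#'
#' @param spec a \code{design_spec}.
#' @param hyper named list of hyperparameters (see \code{default_hyper}).
#' @return list of class \code{gaussian_prior}: \code{Sigma_stim} (S x S),
#'   \code{var_tbar}, \code{var_spk}.
#' @export
build_prior <- function(spec, hyper) {
  p <- spec$parameterization
  lab <- spec$labels
  S <- spec$S
  v <- function(nm) hyper[[nm]]^2
  if (p == "none") {
    Sigma <- matrix(v("psi_0"), 2, 2) + diag(v("psi_s"), 2)
  } else if (p == "category") {
    Sigma <- matrix(v("psi_0"), 4, 4) + diag(v("psi_c"), 4)
  } else if (p == "cosine") {
    Sigma <- diag(0, 6)
    Sigma[1:4, 1:4] <- matrix(v("psi_0"), 4, 4) + diag(v("psi_c"), 4)
    Sigma[5:6, 5:6] <- diag(v("psi_d"), 2)
  } else if (p == "cosine_independent") {
    Sigma <- diag(0, 8)
    Sigma[1:4, 1:4] <- matrix(v("psi_0"), 4, 4) + diag(v("psi_c"), 4)
    Sigma[5:8, 5:8] <- diag(v("psi_d"), 4)
  } else if (p == "full") {
    th <- spec$direction_set
    D <- spec$D
    cats <- direction_category(th, spec$boundary)
    # latents: gamma_0, gamma_cs1, gamma_cs2, gamma_ct1, gamma_ct2,
    #          gamma_cos, gamma_sin, gp(theta_1..D)
    L <- matrix(0, S, 7 + D)
    rownames(L) <- lab
    for (d in seq_len(D)) {
      r <- paste0("theta_", th[d])
      L[r, 1] <- 1; L[r, 1 + cats[d]] <- 1
      L[r, 6] <- cos(th[d] * pi / 180); L[r, 7] <- sin(th[d] * pi / 180)
      L[r, 7 + d] <- 1
    }
    for (k in 1:2) {
      r <- paste0("ct", k)
      L[r, 1] <- 1; L[r, 3 + k] <- 1; L[r, 1 + k] <- -1
    }
    Lambda <- diag(c(v("psi_0"), rep(v("psi_c"), 4), rep(v("psi_d"), 2),
                     rep(0, D)))
    Lambda[7 + seq_len(D), 7 + seq_len(D)] <-
      v("psi_theta") * gp_direction_kernel(th, tau = hyper$tau)
    Sigma <- L %*% Lambda %*% t(L)
  } else {  # full_independent: mirrors the shared-tuning construction with
    # separate cosine/GP latents for sample and test direction kernels
    th <- spec$direction_set
    D <- spec$D
    cats <- direction_category(th, spec$boundary)
    nlat <- 9 + 2 * D
    L <- matrix(0, S, nlat)
    rownames(L) <- lab
    for (role in 1:2) {
      pre <- if (role == 1) "stheta_" else "ttheta_"
      off_cs <- if (role == 1) 6 else 8  # cos/sin latent offsets
      for (d in seq_len(D)) {
        r <- paste0(pre, th[d])
        L[r, 1] <- 1; L[r, 1 + cats[d]] <- 1
        L[r, off_cs] <- cos(th[d] * pi / 180)
        L[r, off_cs + 1] <- sin(th[d] * pi / 180)
        L[r, 9 + (role - 1) * D + d] <- 1
      }
    }
    for (k in 1:2) {
      r <- paste0("ct", k)
      L[r, 1] <- 1; L[r, 3 + k] <- 1; L[r, 1 + k] <- -1
    }
    Lambda <- diag(c(v("psi_0"), rep(v("psi_c"), 4), rep(v("psi_d"), 4),
                     rep(0, 2 * D)))
    Kgp <- v("psi_theta") * gp_direction_kernel(th, tau = hyper$tau)
    Lambda[9 + seq_len(D), 9 + seq_len(D)] <- Kgp
    Lambda[9 + D + seq_len(D), 9 + D + seq_len(D)] <- Kgp
    Sigma <- L %*% Lambda %*% t(L)
  }
  dimnames(Sigma) <- list(lab, lab)
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(ev)) stop("assembled prior covariance not PSD")
  structure(list(Sigma_stim = Sigma,
                 var_tbar = if (!is.null(hyper$psi_tbar)) hyper$psi_tbar^2,
                 var_spk = if (!is.null(hyper$psi_spk)) hyper$psi_spk^2),
            class = "gaussian_prior")
}

#' Half-t-style hyperprior log density (unnormalized)
#'
#' \eqn{\log p(h) = -((\nu+1)/2) \log(1 + h/\nu)} for \eqn{h > 0},
#' with \eqn{\nu = 4}. Finite and maximal at h = 0.
#'
#' @param h positive hyperparameter value(s).
#' @param nu degrees of freedom.
#' @return unnormalized log density.
#' @export
log_hyperprior <- function(h, nu = 4) {
  ifelse(h >= 0, -(nu + 1) / 2 * log1p(h / nu), -Inf)
}

# derivative of log_hyperprior wrt log h (h = exp(lh))
dlog_hyperprior_dlogh <- function(h, nu = 4) {
  -(nu + 1) / 2 * (h / nu) / (1 + h / nu)
}

# multivariate normal log density with covariance Sigma (chol-based)
mvn_logpdf <- function(x, Sigma) {
  ch <- chol(Sigma)
  z <- backsolve(ch, x, transpose = TRUE)
  -0.5 * sum(z^2) - sum(log(diag(ch))) - length(x) / 2 * log(2 * pi)
}
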