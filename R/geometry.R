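# mode-k unfolding of a 3-way array and its inverse are all we need for the
# higher-order SVD
unfold3 <- function(A, mode) {
  d <- dim(A)
  perm <- c(mode, setdiff(1:3, mode))
  matrix(aperm(A, perm), d[mode], prod(d[-mode]))
}

#' Higher-order SVD projection of the stimulus kernel tensor
#'
#' Takes the kernel tensor over the sample directions, optionally removes
#' the across-direction mean, computes orthonormal factor matrices by HOSVD
#' (SVD of each unfolding), and returns the population trajectories
#' projected into the leading \code{n_dims} neuron-mode dimensions, scaled
#' by \eqn{1/\sqrt{N}}.
#'
#' @param K 3-way array, time x directions x neurons (e.g. the sample-
#'   direction fibers of \code{kernel_tensor}).
#' @param n_dims number of retained neuron-mode dimensions (default 3).
#' @param remove_mean subtract the across-direction mean tensor first.
#' @return list: \code{traj} (time x directions x n_dims), \code{Tfac},
#'   \code{Ufac}, \code{Vfac} (orthonormal factors), \code{energy}
#'   (fraction of squared norm retained).
#' @export
hosvd_subspace <- function(K, n_dims = 3, remove_mean = FALSE) {
  stopifnot(length(dim(K)) == 3)
  if (n_dims > dim(K)[3]) stop("n_dims exceeds the neuron mode size")
  if (remove_mean) {
    mu <- apply(K, c(1, 3), mean)          # mean over directions
    K <- K - aperm(array(mu, c(dim(K)[1], dim(K)[3], dim(K)[2])),
                   c(1, 3, 2))
  }
  Tfac <- svd(unfold3(K, 1))$u
  Ufac <- svd(unfold3(K, 2))$u
  Vfac <- svd(unfold3(K, 3))$u[, seq_len(n_dims), drop = FALSE]
  N <- dim(K)[3]
  # project onto the neuron-mode subspace: core x1 T x2 U == K x3 V^T
  proj <- unfold3(K, 3)                     # N x (T*D)
  low <- crossprod(Vfac, proj) / sqrt(N)    # n_dims x (T*D)
  traj <- aperm(array(t(low), c(dim(K)[1], dim(K)[2], n_dims)), c(1, 2, 3))
  energy <- sum(low^2) * N / sum(K^2)
  list(traj = traj, Tfac = Tfac, Ufac = Ufac, Vfac = Vfac, energy = energy)
}

# orthonormalized, 1/sqrt(N)-scaled output map R = orth(V)' V / sqrt(N)
output_map <- function(V_stim) {
  Q <- qr.Q(qr(V_stim))
  crossprod(Q, V_stim) / sqrt(nrow(V_stim))
}

#' Direction-tuning ellipse of the cosine-tuned model
#'
#' At each time point the cosine model's direction tuning traces an ellipse
#' in the R_s-dimensional stimulus subspace:
#' \eqn{E_t(\theta) = \sum_r T_r(t)(U_{r,cos}\cos\theta +
#' U_{r,sin}\sin\theta) R_{.,r}}. Returns the two generating vectors
#' \code{f1 = E_t(0)}, \code{f2 = E_t(90)} from which the whole curve
#' follows.
#'
#' @param params a \code{gmlm_params} under a cosine parameterization.
#' @param model a \code{gmlm_model}.
#' @param t_bin time bin (on the stimulus-basis grid, relative to onset).
#' @return list: \code{f1}, \code{f2} (length R_s), \code{Rmap}, and
#'   function \code{E(theta_deg)}.
#' @export
direction_ellipse <- function(params, model, t_bin) {
  if (!model$spec$parameterization %in% c("cosine"))
    stop("direction ellipse requires the cosine parameterization")
  Tt <- model$bases$stim$B %*% params$T_stim     # time-domain kernels
  Rmap <- output_map(params$V_stim)              # R_s x R_s
  co <- Tt[t_bin, ] * params$U_stim["cos", ]     # length R_s
  si <- Tt[t_bin, ] * params$U_stim["sin", ]
  f1 <- drop(Rmap %*% co)
  f2 <- drop(Rmap %*% si)
  list(f1 = f1, f2 = f2, Rmap = Rmap,
       E = function(theta_deg) {
         th <- theta_deg * pi / 180
         outer(f1, cos(th)) + outer(f2, sin(th))
       })
}

#' Ellipse axes and preferred-angle of the direction tuning
#'
#' Maximizes \eqn{D_t(\theta) = \|E_t(\theta) - E_t(\theta + 180)\|} in
#' closed form (\eqn{\tan 2\theta_0 = 2 f_1\cdot f_2 / (\|f_1\|^2 -
#' \|f_2\|^2)}), evaluates both candidate angles, folds the argmax into
#' [45, 225) degrees, and cross-checks against a grid argmax (a warning is
#' raised if they disagree by more than \code{grid_tol} degrees).
#'
#' @param ell output of \code{direction_ellipse}.
#' @param grid_step cross-check grid resolution in degrees (0 disables).
#' @param grid_tol allowed closed-form/grid discrepancy in degrees.
#' @return list: \code{theta_max} (degrees in [45, 225)), \code{major},
#'   \code{minor}, \code{degenerate} (circle flag).
#' @export
ellipse_axes <- function(ell, grid_step = 1, grid_tol = 1) {
  f1 <- ell$f1; f2 <- ell$f2
  Dt <- function(th_deg) {
    th <- th_deg * pi / 180
    2 * sqrt(colSums((outer(f1, cos(th)) + outer(f2, sin(th)))^2))
  }
  a <- sum(f1 * f1); b <- sum(f2 * f2); cxy <- sum(f1 * f2)
  degenerate <- abs(a - b) < 1e-12 && abs(cxy) < 1e-12
  t0 <- if (degenerate) 45 else 0.5 * atan2(2 * cxy, a - b) * 180 / pi
  cand <- c(t0, t0 + 90)
  Dc <- Dt(cand)
  theta <- cand[which.max(Dc)]
  theta <- ((theta - 45) %% 180) + 45            # fold into [45, 225)
  if (grid_step > 0 && !degenerate) {
    grid <- seq(45, 225 - grid_step, by = grid_step)
    tg <- grid[which.max(Dt(grid))]
    dd <- min(abs(tg - theta), abs(abs(tg - theta) - 180))
    if (dd > max(grid_tol, grid_step))
      warning(sprintf("closed-form theta_max %.2f disagrees with grid %.2f",
                      theta, tg))
  }
  list(theta_max = theta, major = max(Dt(theta)),
       minor = max(Dt(theta + 90)), degenerate = degenerate)
}

#' Category tuning vector norm
#'
#' \eqn{F_t = \sum_r T_r(t)(U_{r,cs1} - U_{r,cs2}) R_{.,r}}: the difference
#' between the category-1 and category-2 sample kernels in the
#' low-dimensional tuning space.
#'
#' @inheritParams direction_ellipse
#' @return \eqn{\|F_t\|} at the requested bin.
#' @export
category_vector_norm <- function(params, model, t_bin) {
  lab <- model$spec$labels
  if (!all(c("cs1", "cs2") %in% lab))
    stop("parameterization has no sample-category coefficients")
  Tt <- model$bases$stim$B %*% params$T_stim
  Rmap <- output_map(params$V_stim)
  dU <- params$U_stim[lab == "cs1", ] - params$U_stim[lab == "cs2", ]
  sqrt(sum((Rmap %*% (Tt[t_bin, ] * dU))^2))
}

#' Posterior summaries of the subspace geometry
#'
#' Computes theta_max, the major/minor direction-tuning axis norms, and the
#' category-vector norm for each posterior draw at each requested time, and
#' summarizes with the posterior median and a 99% credible interval
#' (0.5-99.5%).
#'
#' @param samples a \code{posterior_samples} from a cosine-model sampler.
#' @param t_bins time bins relative to stimulus onset.
#' @param thin keep every \code{thin}-th draw.
#' @return object of class \code{subspace_geometry}: data.frame with
#'   time_bin and median/lo/hi for each metric.
#' @export
posterior_geometry <- function(samples, t_bins, thin = 10L) {
  model <- samples$model
  keep <- seq(1, nrow(samples$draws), by = thin)
  qs <- function(x) stats::quantile(x, c(0.005, 0.5, 0.995), names = FALSE)
  out <- lapply(t_bins, function(tb) {
    met <- vapply(keep, function(i) {
      p <- unpack_params(samples$draws[i, seq_len(samples$n_param)], model)
      ax <- ellipse_axes(direction_ellipse(p, model, tb), grid_step = 0)
      c(ax$theta_max, ax$major, ax$minor,
        category_vector_norm(p, model, tb))
    }, numeric(4))
    c(tb, qs(met[1, ]), qs(met[2, ]), qs(met[3, ]), qs(met[4, ]))
  })
  df <- as.data.frame(do.call(rbind, out))
  names(df) <- c("time_bin",
                 paste0(rep(c("theta_max", "major", "minor", "category"),
                            each = 3),
                        c("_lo", "_med", "_hi")))
  class(df) <- c("subspace_geometry", "data.frame")
  df
}

#' Per-component direction and category tuning metrics
#'
#' For each CP component of a cosine-tuned model: the preferred direction
#' \code{theta = atan2(U_sin, U_cos)} (degrees; NA when untuned), the
#' direction-tuning magnitude \code{a = sqrt(U_sin^2 + U_cos^2)}, and the
#' sample/test category magnitudes (absolute category-weight differences).
#'
#' @param U_stim stimulus weight matrix with cosine-model row labels.
#' @return data.frame with one row per component.
#' @export
component_metrics <- function(U_stim) {
  stopifnot(all(c("cos", "sin", "cs1", "cs2", "ct1", "ct2") %in%
                  rownames(U_stim)))
  a <- sqrt(U_stim["cos", ]^2 + U_stim["sin", ]^2)
  th <- (atan2(U_stim["sin", ], U_stim["cos", ]) * 180 / pi) %% 360
  data.frame(component = seq_len(ncol(U_stim)),
             theta_deg = ifelse(a > 0, th, NA_real_),
             direction_magnitude = a,
             C_sample = abs(U_stim["cs1", ] - U_stim["cs2", ]),
             C_test = abs(U_stim["ct1", ] - U_stim["ct2", ]))
}

#' Normalize CP components for display
#'
#' Moves each component's magnitude into the neuron-loading dimension
#' (temporal and stimulus factors become unit norm); the kernel tensor is
#' unchanged. For dynamic-history components the sign convention fixes
#' \code{T} by the mode of sign(V) and sign of the first history
#' coefficient.
#'
#' @param params a \code{gmlm_params}.
#' @return rescaled \code{gmlm_params}.
#' @export
normalize_components <- function(params) {
  for (r in seq_len(ncol(params$T_stim))) {
    nt <- sqrt(sum(params$T_stim[, r]^2))
    nu <- sqrt(sum(params$U_stim[, r]^2))
    if (nt == 0 || nu == 0) {
      warning("zero-norm component ", r, " left unchanged")
      next
    }
    params$V_stim[, r] <- nt * nu * params$V_stim[, r]
    params$T_stim[, r] <- params$T_stim[, r] / nt
    params$U_stim[, r] <- params$U_stim[, r] / nu
  }
  if (!is.null(params$dyn) && ncol(params$dyn$T_dspk) > 0) {
    d <- params$dyn
    for (r in seq_len(ncol(d$T_dspk))) {
      sgn_v <- sign(sum(sign(d$V_dspk[, r])))  # mode of the loading signs
      if (sgn_v == 0) sgn_v <- 1
      s <- sgn_v * sign(d$H_dspk[1, r] + (d$H_dspk[1, r] == 0)) *
        sign(d$U_dspk[1, r] + (d$U_dspk[1, r] == 0))
      params$dyn$T_dspk[, r] <- s * d$T_dspk[, r]
      params$dyn$H_dspk[, r] <- sign(d$H_dspk[1, r] +
                                       (d$H_dspk[1, r] == 0)) * d$H_dspk[, r]
    }
  }
  params
}

#' Exponential time constant of a spike-history kernel
#'
#' Least-squares fit of \eqn{a e^{-t/\tau}} to a lag kernel; used to
#' summarize the timescale of the dynamic spike-history component.
#'
#' @param kernel numeric lag kernel (first element = lag 0 or 1 bin).
#' @param bin_width bin width in seconds.
#' @return list: \code{tau_ms}, \code{amplitude}, \code{decaying} (FALSE
#'   flags a non-decaying kernel; the best fit is still returned).
#' @export
fit_history_timescale <- function(kernel, bin_width = 0.005) {
  if (all(kernel == 0)) stop("kernel is identically zero")
  tt <- (seq_along(kernel) - 1) * bin_width
  obj <- function(par) {
    a <- par[1]; tau <- exp(par[2])
    sum((kernel - a * exp(-tt / tau))^2)
  }
  i0 <- which.max(abs(kernel))
  p0 <- c(kernel[i0], log(0.02))
  opt <- stats::optim(p0, obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  tau <- exp(opt$par[2])
  decaying <- abs(kernel[length(kernel)]) < abs(kernel[i0])
  if (!decaying) warning("kernel does not decay; reporting best fit anyway")
  list(tau_ms = tau * 1000, amplitude = opt$par[1], decaying = decaying)
}
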