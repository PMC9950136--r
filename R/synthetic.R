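#' Task schedule for simulated delayed-match trials
#'
#' Defaults follow the six-direction categorization task: 650 ms stimulus
#' presentations, 1000 ms delay, 5 ms bins, categories split at the 45-225
#' degree boundary, and (on match trials) a touch-bar release drawn
#' uniformly 200-500 ms after test onset. \code{touch_bar = "none"} disables
#' releases (all trials run to test offset + 50 ms).
#'
#' @param direction_set directions in degrees.
#' @param boundary category boundary.
#' @param stim_dur,delay,pad durations in seconds.
#' @param bin_width bin width in seconds.
#' @param touch_bar "uniform" or "none".
#' @param rt_range release-time range (s) after test onset.
#' @return a list of class \code{task_schedule}.
#' @export
task_schedule <- function(direction_set = c(15, 75, 135, 195, 255, 315),
                          boundary = c(45, 225), stim_dur = 0.650,
                          delay = 1.000, pad = 0.050, bin_width = 0.005,
                          touch_bar = c("uniform", "none"),
                          rt_range = c(0.200, 0.500)) {
  structure(list(direction_set = direction_set, boundary = boundary,
                 stim_dur = stim_dur, delay = delay, pad = pad,
                 bin_width = bin_width, touch_bar = match.arg(touch_bar),
                 rt_range = rt_range),
            class = "task_schedule")
}

#' Sample a ground-truth GMLM
#'
#' Draws a population model whose stimulus weights follow one of four
#' qualitative templates: \code{categoryless} (timing-only responses, no
#' direction or category tuning), \code{category_axis} (a strong
#' sample-category axis, negligible circular direction tuning),
#' \code{circular_direction} (cosine direction tuning, no category offset),
#' or \code{mixed}. Each component's temporal factor is a distinct positive
#' temporal motif plus random smooth dynamics; neuron loadings are random
#' with balanced component magnitudes; baselines are normal around
#' \code{log(8)} sp/s.
#'
#' @param template one of the four regimes.
#' @param N number of neurons.
#' @param rank stimulus tensor rank.
#' @param seed RNG seed.
#' @param schedule a \code{task_schedule}.
#' @param spec a \code{design_spec}; defaults to cosine tuning on the
#'   schedule's direction set.
#' @param include_history include refractory spike-history kernels.
#' @param include_tbar include a low-rank touch-bar response.
#' @param amp overall stimulus-modulation scale.
#' @return list of class \code{ground_truth}: \code{model}, \code{params},
#'   \code{hyper}, \code{schedule}, \code{template}, \code{seed}.
#' @export
sample_ground_truth <- function(template = c("mixed", "categoryless",
                                             "category_axis",
                                             "circular_direction"),
                                N, rank, seed = 1L,
                                schedule = task_schedule(),
                                spec = NULL, include_history = FALSE,
                                include_tbar = FALSE, amp = 4) {
  template <- match.arg(template)
  stopifnot(N >= 1, rank >= 1)
  if (is.null(spec))
    spec <- design_spec("cosine", schedule$direction_set, schedule$boundary)
  bases <- default_bases(schedule$bin_width)
  model <- gmlm_model(spec, N = N, rank = rank, bases = bases,
                      rank_tbar = if (include_tbar) 3L else 0L,
                      include_history = include_history,
                      include_tbar = include_tbar)
  set.seed(seed)
  rorth <- function(r, c) qr.Q(qr(matrix(stats::rnorm(r * c), r, c)))
  U <- matrix(0, spec$S, rank, dimnames = list(spec$labels, NULL))
  for (r in seq_len(rank)) {
    u0 <- stats::rnorm(1, 0, 0.4)           # shared timing response
    U[c("cs1", "cs2"), r] <- u0
    U[c("ct1", "ct2"), r] <- stats::rnorm(1, 0, 0.2)
    if (template %in% c("category_axis", "mixed")) {
      dcat <- stats::rnorm(1, 0, 0.5) + 0.4 * sign(stats::rnorm(1))
      U["cs1", r] <- U["cs1", r] + dcat / 2
      U["cs2", r] <- U["cs2", r] - dcat / 2
    }
    if (template %in% c("circular_direction", "mixed")) {
      U[c("cos", "sin"), r] <- stats::rnorm(2, 0, 0.5)
    }
  }
  if (template == "categoryless") U[] <- 0
  # temporal factors: each component is a distinct positive temporal motif
  # (a Gaussian envelope with its own peak time and width) plus random
  # smooth dynamics. Parietal task responses are elevations with component-
  # specific timecourses (transient, sustained, delay-ramping); a purely
  # random coefficient vector integrates to ~0 over the trial and would
  # carry no spike-count signal, while a single shared envelope would make
  # the components temporally collinear.
  tt <- (seq_len(nrow(bases$stim$B)) - 1) * schedule$bin_width
  mix <- 0.7
  Tst <- matrix(stats::rnorm(model$P_stim * rank), model$P_stim, rank)
  mu_r <- stats::runif(rank, 0.15, 1.2)
  sd_r <- stats::runif(rank, 0.15, 0.35)
  for (r in seq_len(rank)) {
    env <- project_kernel(bases$stim, exp(-0.5 * ((tt - mu_r[r]) / sd_r[r])^2))
    env <- env / sqrt(sum(env^2))
    z <- Tst[, r] - env * sum(Tst[, r] * env)
    z <- z / sqrt(sum(z^2))
    Tst[, r] <- mix * env + sqrt(1 - mix^2) * z
  }
  # balance component magnitudes so the nominal rank is the true rank: each
  # rank-1 component's tensor Frobenius norm is amp * 0.8 * sqrt(N)
  Vst <- matrix(stats::rnorm(N * rank), N)
  if (template != "categoryless") {
    for (r in seq_len(rank)) {
      nrm <- sqrt(sum(U[, r]^2)) * sqrt(sum(Vst[, r]^2))  # |T_r| = 1
      if (nrm > 0) Vst[, r] <- Vst[, r] * amp * 0.8 * sqrt(N) / nrm
    }
  }
  params <- gmlm_params(model,
    w = stats::rnorm(N, log(8), 0.3),
    T_stim = Tst[, seq_len(rank), drop = FALSE],
    U_stim = U,
    V_stim = Vst,
    T_tbar = if (include_tbar) 0.5 * rorth(model$P_tbar, 3),
    V_tbar = if (include_tbar) matrix(stats::rnorm(N * 3, 0, 0.5), N),
    H_spk = if (include_history) {
      lag_t <- (seq_len(nrow(bases$spk$B)) - 1) * schedule$bin_width
      kern <- -3 * exp(-lag_t / 0.010)
      kern[1] <- 0
      matrix(rep(project_kernel(bases$spk, kern), N), ncol = N)
    })
  structure(list(model = model, params = params,
                 hyper = default_hyper(spec, include_tbar, include_history),
                 schedule = schedule, template = template, seed = seed),
            class = "ground_truth")
}

#' Simulate trials from a ground truth
#'
#' Sequential bin-by-bin Poisson sampling of point-process counts:
#' the log rate at each bin combines the event-locked terms with the
#' realized spike history. Without spike history the rate trace per
#' condition is deterministic and trials are drawn in bulk. Sample
#' directions cycle through the direction set; test directions are uniform;
#' a match (same category) triggers a touch-bar release per the schedule.
#'
#' @param truth a \code{ground_truth}.
#' @param trials_per_direction trials per sample direction per neuron.
#' @param seed RNG seed.
#' @param rate_clip cap on the log rate (numerical safety).
#' @return a \code{trial_dataset}.
#' @export
simulate_trials <- function(truth, trials_per_direction = 20L, seed = 1L,
                            rate_clip = 4 - log(truth$schedule$bin_width)) {
  sch <- truth$schedule
  model <- truth$model
  params <- truth$params
  dt <- sch$bin_width
  t_test_on <- 1L + as.integer(round((sch$stim_dur + sch$delay) / dt))
  t_test_off <- t_test_on + as.integer(round(sch$stim_dur / dt))
  pad_b <- as.integer(round(sch$pad / dt))
  dirs <- sch$direction_set
  set.seed(seed)
  spk_kern <- if (model$include_history)
    model$bases$spk$B %*% params$H_spk else NULL
  trials <- list()
  cache <- new.env()
  for (n in seq_len(model$N)) {
    nid <- sprintf("n%02d", n)
    for (th_s in dirs) for (k in seq_len(trials_per_direction)) {
      th_t <- sample(dirs, 1)
      cs <- direction_category(th_s, sch$boundary)
      ct <- direction_category(th_t, sch$boundary)
      is_match <- identical(cs, ct)
      t_tbar <- NA_integer_
      if (is_match && sch$touch_bar == "uniform")
        t_tbar <- t_test_on +
          as.integer(round(stats::runif(1, sch$rt_range[1],
                                        sch$rt_range[2]) / dt))
      T_ <- if (!is.na(t_tbar)) t_tbar + pad_b else t_test_off + pad_b
      tr0 <- new_trial(nid, integer(T_), 1L, t_test_on, th_s, th_t,
                       t_tbar, TRUE, sch$boundary)
      key <- paste(n, T_, th_s, th_t, t_tbar)
      base <- if (!is.null(cache[[key]])) cache[[key]] else {
        b <- gmlm_log_rate(params, tr0, model, n)
        cache[[key]] <- b
        b
      }
      y <- integer(T_)
      if (is.null(spk_kern)) {
        y <- stats::rpois(T_, exp(pmin(base, rate_clip)) * dt)
      } else {
        lam_h <- numeric(T_)
        L <- nrow(spk_kern)
        for (t in seq_len(T_)) {
          y[t] <- stats::rpois(1, exp(pmin(base[t] + lam_h[t], rate_clip)) * dt)
          if (y[t] > 0 && t < T_) {
            to <- min(T_, t + L)
            seg <- seq_len(to - t)
            lam_h[t + seg] <- lam_h[t + seg] + y[t] * spk_kern[seg, n]
          }
        }
      }
      tr0$counts <- as.integer(y)
      trials[[length(trials) + 1L]] <- tr0
    }
  }
  trial_dataset(trials, neuron_ids = sprintf("n%02d", seq_len(model$N)),
                bin_width = dt, boundary = sch$boundary,
                stim_dur_bins = as.integer(round(sch$stim_dur / dt)))
}

#' Compare a fitted GMLM with its ground truth
#'
#' @param truth a \code{ground_truth}.
#' @param fitted a \code{gmlm_params} fit to data simulated from the truth.
#' @return list: \code{principal_angles_deg} between the true and fitted
#'   stimulus-loading subspaces, \code{tensor_rel_error} (relative Frobenius
#'   error of the stimulus kernel tensor), \code{rank_true},
#'   \code{rank_fit}.
#' @export
recovery_report <- function(truth, fitted) {
  Kt <- kernel_tensor(truth$params, truth$model)
  model_f <- truth$model
  model_f$rank <- ncol(fitted$V_stim)
  Kf <- kernel_tensor(fitted, model_f)
  rel <- sqrt(sum((Kt - Kf)^2) / sum(Kt^2))
  rmin <- min(ncol(fitted$V_stim), truth$model$rank)
  if (ncol(fitted$V_stim) != truth$model$rank)
    warning("rank mismatch; comparing on leading subspace of min rank")
  Qt <- qr.Q(qr(truth$params$V_stim))[, seq_len(rmin), drop = FALSE]
  Qf <- qr.Q(qr(fitted$V_stim))[, seq_len(rmin), drop = FALSE]
  sv <- svd(crossprod(Qt, Qf))$d
  ang <- acos(pmin(pmax(sv, -1), 1)) * 180 / pi
  list(principal_angles_deg = ang, tensor_rel_error = rel,
       rank_true = truth$model$rank, rank_fit = ncol(fitted$V_stim))
}
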