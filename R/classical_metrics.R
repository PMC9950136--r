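# area under the ROC curve between two count samples (midrank ties)
auc_counts <- function(x, y) {
  r <- rank(c(x, y))
  (sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2) /
    (length(x) * length(y))
}

#' ROC category tuning index (rCTI)
#'
#' Pairwise discriminability (|AUC - 0.5|) between direction-conditioned
#' spike-count distributions, compared at matched angular separation:
#' adjacent directions around the circle are paired, and the mean
#' discriminability of boundary-spanning (across-category) pairs minus that
#' of within-category pairs is scaled to [-0.5, 0.5]. 0 means direction
#' pairs across the boundary are no more separable than pairs within a
#' category; +0.5 perfect across-category separation with identical
#' within-category responses; -0.5 perfect within-category separation with
#' none across the boundary. Distance matching is what makes the
#' end points attainable: with all pairs pooled, perfect within-category
#' separation necessarily produces across-category separability as well.
#'
#' @param counts_by_direction named list: spike counts per trial for each
#'   direction (names = degrees).
#' @param boundary category boundary (degrees).
#' @return rCTI in [-0.5, 0.5].
#' @export
rcti <- function(counts_by_direction, boundary = c(45, 225)) {
  th <- as.numeric(names(counts_by_direction))
  ord <- order(th %% 360)
  th <- (th %% 360)[ord]
  cbd <- counts_by_direction[ord]
  cats <- direction_category(th, boundary)
  if (length(unique(th[cats == 1])) < 2 || length(unique(th[cats == 2])) < 2)
    stop("need at least two directions per category")
  if (any(vapply(cbd, length, 0L) == 0))
    stop("empty direction condition")
  D <- length(th)
  across <- c(); within <- c()
  for (i in seq_len(D)) {
    j <- if (i == D) 1L else i + 1L           # adjacent around the circle
    d <- abs(auc_counts(cbd[[i]], cbd[[j]]) - 0.5)
    if (cats[i] == cats[j]) within <- c(within, d) else across <- c(across, d)
  }
  mean(across) - mean(within)
}

#' Shuffle-corrected ROC direction selectivity index (rDSI)
#'
#' The maximum within-category pairwise discriminability (|AUC - 0.5|),
#' minus the mean of the same statistic on direction-label-shuffled data:
#' near 0 (possibly negative) for direction-blind cells, toward 0.5 for
#' strong within-category direction selectivity.
#'
#' @inheritParams rcti
#' @param n_shuffles shuffle repetitions for the bias correction.
#' @param seed RNG seed for the shuffles.
#' @return shuffle-corrected rDSI.
#' @export
rdsi <- function(counts_by_direction, boundary = c(45, 225),
                 n_shuffles = 100L, seed = 1L) {
  th <- as.numeric(names(counts_by_direction))
  cats <- direction_category(th, boundary)
  stat <- function(cbd) {
    best <- 0
    D <- length(cbd)
    for (i in seq_len(D - 1)) for (j in (i + 1):D) {
      if (cats[i] != cats[j]) next
      best <- max(best, abs(auc_counts(cbd[[i]], cbd[[j]]) - 0.5))
    }
    best
  }
  raw <- stat(counts_by_direction)
  set.seed(seed)
  lens <- vapply(counts_by_direction, length, 0L)
  allc <- unlist(counts_by_direction)
  null <- vapply(seq_len(n_shuffles), function(s) {
    sh <- split(sample(allc), rep(seq_along(lens), lens))
    stat(sh)
  }, 0)
  raw - mean(null)
}

#' Parametric tuning curve with category offset and cosine direction term
#'
#' Poisson maximum-likelihood fit of
#' \eqn{\lambda(\theta) = \exp[\beta_0 + \beta_{cat} c_\theta +
#' \beta_{\sin}\sin\theta + \beta_{\cos}\cos\theta]} with category code
#' \eqn{c_\theta \in \{0.5, -0.5\}}, to spike counts in a fixed window.
#' Category magnitude is \eqn{|\beta_{cat}|}; direction magnitude is the
#' peak-to-trough log-rate difference \eqn{2\sqrt{\beta_{\sin}^2 +
#' \beta_{\cos}^2}}. Both are positively biased, so the mean magnitude over
#' label-shuffled refits is subtracted.
#'
#' @param counts spike counts per trial.
#' @param theta_deg direction per trial (degrees).
#' @param boundary category boundary.
#' @param n_shuffles shuffle refits for the bias correction (0 disables).
#' @param seed RNG seed.
#' @return list: \code{coef} (beta0, beta_cat, beta_sin, beta_cos),
#'   \code{category_magnitude}, \code{direction_magnitude} (both
#'   shuffle-corrected when requested), \code{raw} magnitudes,
#'   \code{flagged} (TRUE when the fit was capped).
#' @export
fit_tuning_curve <- function(counts, theta_deg, boundary = c(45, 225),
                             n_shuffles = 100L, seed = 1L) {
  th <- theta_deg * pi / 180
  cth <- ifelse(direction_category(theta_deg, boundary) == 1, 0.5, -0.5)
  fit1 <- function(cc, cat_code) {
    df <- data.frame(y = cc, c = cat_code, s = sin(th), co = cos(th))
    fit <- suppressWarnings(stats::glm(y ~ c + s + co, family = stats::poisson,
                                       data = df))
    b <- stats::coef(fit)
    flagged <- any(abs(b[-1]) > 10) || !fit$converged
    b[-1] <- pmin(pmax(b[-1], -10), 10)  # cap under separation/divergence
    list(b = b, flagged = flagged)
  }
  f <- fit1(counts, cth)
  cat_raw <- abs(f$b[["c"]])
  dir_raw <- 2 * sqrt(f$b[["s"]]^2 + f$b[["co"]]^2)
  cat_corr <- cat_raw; dir_corr <- dir_raw
  if (n_shuffles > 0) {
    set.seed(seed)
    sh <- vapply(seq_len(n_shuffles), function(k) {
      # permute direction (and tied category) labels across trials
      idx <- sample(length(counts))
      ths <- th[idx]
      dfs <- data.frame(y = counts, c = cth[idx], s = sin(ths),
                        co = cos(ths))
      fit <- suppressWarnings(stats::glm(y ~ c + s + co,
                                         family = stats::poisson, data = dfs))
      b <- pmin(pmax(stats::coef(fit), -10), 10)
      c(abs(b[["c"]]), 2 * sqrt(b[["s"]]^2 + b[["co"]]^2))
    }, numeric(2))
    cat_corr <- cat_raw - mean(sh[1, ])
    dir_corr <- dir_raw - mean(sh[2, ])
  }
  list(coef = stats::setNames(as.numeric(f$b),
                              c("beta0", "beta_cat", "beta_sin", "beta_cos")),
       category_magnitude = cat_corr, direction_magnitude = dir_corr,
       raw = c(category = cat_raw, direction = dir_raw),
       flagged = f$flagged)
}

#' Beta-binomial estimate of behavioral performance
#'
#' With a Beta(1, 1) prior, k successes out of n give a Beta(1 + k,
#' 1 + n - k) posterior over the fraction correct; the point estimate is
#' the posterior mean and the interval a central 99% credible interval.
#'
#' @param successes number of correct (or touch-bar-release) trials.
#' @param n total trials.
#' @param level credible level (default 0.99).
#' @return list: \code{mean}, \code{lo}, \code{hi}, \code{alpha},
#'   \code{beta}.
#' @export
beta_binomial_performance <- function(successes, n, level = 0.99) {
  stopifnot(successes >= 0, successes <= n)
  a <- 1 + successes
  b <- 1 + n - successes
  half <- (1 - level) / 2
  list(mean = a / (a + b),
       lo = stats::qbeta(half, a, b), hi = stats::qbeta(1 - half, a, b),
       alpha = a, beta = b)
}

#' Bootstrap error bars for a single-neuron statistic
#'
#' Resamples (with replacement) an equal number of trials within each
#' sample direction and recomputes the statistic.
#'
#' @param counts_by_direction named list of per-direction counts.
#' @param stat_fn function taking such a list (e.g. \code{rcti}).
#' @param n_boot bootstrap repetitions (1000 in the analyses).
#' @param seed RNG seed.
#' @param ... passed to \code{stat_fn}.
#' @return list: \code{estimate}, \code{boot} (vector), \code{ci99}.
#' @export
bootstrap_metric <- function(counts_by_direction, stat_fn, n_boot = 1000L,
                             seed = 1L, ...) {
  est <- stat_fn(counts_by_direction, ...)
  set.seed(seed)
  boot <- vapply(seq_len(n_boot), function(b) {
    res <- lapply(counts_by_direction, function(v)
      v[sample.int(length(v), length(v), replace = TRUE)])
    stat_fn(res, ...)
  }, 0)
  list(estimate = est, boot = boot,
       ci99 = stats::quantile(boot, c(0.005, 0.995), names = FALSE))
}
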