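# spike count of one trial in a window aligned to a task event (seconds
# relative to the event; clipped to the recorded trial)
window_count <- function(trial, align = c("sample", "test"), window_s,
                         bin_width) {
  align <- match.arg(align)
  ev <- if (align == "sample") trial$t_sample_on else trial$t_test_on
  from <- ev + as.integer(round(window_s[1] / bin_width))
  to <- ev + as.integer(round(window_s[2] / bin_width)) - 1L
  from <- max(1L, from); to <- min(length(trial$counts), to)
  if (to < from) return(0L)
  sum(trial$counts[from:to])
}

#' Pseudopopulation trials for one condition
#'
#' Because neurons are recorded independently, population trials are
#' assembled by sampling (with replacement) one real trial per neuron from
#' the requested condition and taking spike counts in the given window.
#'
#' @param dataset a \code{trial_dataset}.
#' @param theta_sample sample direction of the condition (degrees).
#' @param align,window_s counting window (seconds relative to the event).
#' @param n pseudotrials per condition (default 50).
#' @param match restrict to match (TRUE) / non-match (FALSE) trials;
#'   NULL uses all.
#' @return n x N count matrix (one column per neuron).
#' @export
make_pseudopopulation <- function(dataset, theta_sample,
                                  align = "sample", window_s = c(0, 0.65),
                                  n = 50L, match = NULL) {
  N <- length(dataset$neuron_ids)
  X <- matrix(0L, n, N)
  for (j in seq_len(N)) {
    nid <- as.character(dataset$neuron_ids[j])
    sel <- which(vapply(dataset$trials, function(tr) {
      ok <- as.character(tr$neuron) == nid && tr$correct &&
        isTRUE(tr$theta_sample == theta_sample %% 360)
      if (ok && !is.null(match))
        ok <- identical(tr$c_sample == tr$c_test, match)
      ok
    }, TRUE))
    if (length(sel) == 0)
      stop("neuron ", nid, " has no qualifying trials for direction ",
           theta_sample)
    pick <- sel[sample.int(length(sel), n, replace = TRUE)]
    X[, j] <- vapply(dataset$trials[pick], window_count, 0L,
                     align = align, window_s = window_s,
                     bin_width = dataset$bin_width)
  }
  X
}

#' Ridge-regularized logistic decoder
#'
#' Features are z-scored with statistics estimated on the training set only
#' (variances floored at 1e-12); the linear classifier is logistic
#' regression with an L2 penalty of 0.1 (glmnet, alpha = 0).
#'
#' @param X training count matrix (trials x neurons).
#' @param labels two-class factor/vector.
#' @param lambda L2 penalty.
#' @return decoder object with \code{$predict(Xnew)} returning class labels.
#' @export
train_decoder <- function(X, labels, lambda = 0.1) {
  labels <- as.factor(labels)
  if (nlevels(labels) != 2) stop("decoder requires exactly two classes")
  mu <- colMeans(X)
  sdv <- sqrt(pmax(apply(X, 2, stats::var), 1e-12))
  Z <- scale(X, center = mu, scale = sdv)
  fit <- glmnet::glmnet(Z, labels, family = "binomial", alpha = 0,
                        lambda = lambda, standardize = FALSE,
                        thresh = 1e-8)
  lev <- levels(labels)
  structure(list(mu = mu, sd = sdv, fit = fit, levels = lev,
                 lambda = lambda,
                 predict = function(Xnew) {
                   Zn <- scale(Xnew, center = mu, scale = sdv)
                   p <- stats::predict(fit, Zn, type = "response")
                   lev[1 + (drop(p) > 0.5)]
                 }),
            class = "ridge_decoder")
}

# Precomputed pools of window counts per (neuron, direction): bootstraps
# then only resample indices.
pseudo_pool <- function(dataset, dirs, align, window_s, match = NULL) {
  N <- length(dataset$neuron_ids)
  nid_all <- vapply(dataset$trials, function(tr) as.character(tr$neuron), "")
  th_all <- vapply(dataset$trials, function(tr) tr$theta_sample, 0)
  ok <- vapply(dataset$trials, function(tr) {
    good <- tr$correct
    if (good && !is.null(match))
      good <- identical(tr$c_sample == tr$c_test, match)
    good
  }, TRUE)
  cnt <- vapply(dataset$trials, window_count, 0L, align = align,
                window_s = window_s, bin_width = dataset$bin_width)
  pool <- vector("list", N)
  for (j in seq_len(N)) {
    nid <- as.character(dataset$neuron_ids[j])
    pool[[j]] <- lapply(dirs, function(th) {
      v <- cnt[ok & nid_all == nid & th_all == th]
      if (length(v) == 0)
        stop("neuron ", nid, " has no qualifying trials for direction ", th)
      v
    })
  }
  pool
}

# sample one pseudopopulation (n trials per direction) from a pool
pseudo_sample <- function(pool, n) {
  N <- length(pool); D <- length(pool[[1]])
  lapply(seq_len(D), function(d)
    vapply(seq_len(N), function(j) {
      v <- pool[[j]][[d]]
      v[sample.int(length(v), n, replace = TRUE)]
    }, integer(n)))
}

# direction-split training schemes for direction-independent category
# generalization; chosen by the dataset's direction set
default_splits <- function(direction_set) {
  ds <- sort(direction_set %% 360)
  if (setequal(ds, c(15, 75, 135, 195, 255, 315))) {
    list(c(15, 195), c(75, 255))
  } else if (setequal(ds, c(22.5, 67.5, 112.5, 157.5, 202.5, 247.5,
                            292.5, 337.5))) {
    list(c(67.5, 112.5, 247.5, 292.5), c(157.5, 202.5, 337.5, 22.5))
  } else stop("no direction-split scheme configured for this direction set")
}

#' Direction-independent category generalization decoding
#'
#' Two decoders are trained on complementary direction subsets (one
#' direction pair, or quadruple, per category) and validated only on the
#' withheld directions; performance is the average of the two. A population
#' that encodes direction purely circularly, with no category-specific
#' component, does not generalize (accuracy near chance); a category axis
#' generalizes.
#'
#' @param dataset a \code{trial_dataset}.
#' @param align,window_s counting window (seconds relative to the event).
#' @param n_boot number of random pseudopopulations.
#' @param n_per_dir pseudotrials per direction.
#' @param splits list of training-direction vectors; default per the
#'   direction set.
#' @param seed RNG seed.
#' @return list: \code{accuracy} (per bootstrap), \code{mean},
#'   \code{ci99}.
#' @export
category_generalization <- function(dataset, align = "sample",
                                    window_s = c(0, 0.65), n_boot = 200L,
                                    n_per_dir = 50L, splits = NULL,
                                    seed = 1L) {
  dirs <- sort(unique(vapply(dataset$trials, function(tr) tr$theta_sample, 0)))
  if (is.null(splits)) splits <- default_splits(dirs)
  cats <- direction_category(dirs, dataset$boundary)
  set.seed(seed)
  pool <- pseudo_pool(dataset, dirs, align, window_s)
  acc <- vapply(seq_len(n_boot), function(b) {
    Xd <- pseudo_sample(pool, n_per_dir)
    names(Xd) <- as.character(dirs)
    mean(vapply(splits, function(tr_dirs) {
      va_dirs <- setdiff(dirs, tr_dirs)
      tri <- match(tr_dirs, dirs); vai <- match(va_dirs, dirs)
      Xtr <- do.call(rbind, Xd[tri])
      ytr <- rep(cats[tri], each = n_per_dir)
      Xva <- do.call(rbind, Xd[vai])
      yva <- rep(cats[vai], each = n_per_dir)
      dec <- train_decoder(Xtr, ytr)
      mean(dec$predict(Xva) == as.character(yva))
    }, 0))
  }, 0)
  list(accuracy = acc, mean = mean(acc),
       ci99 = stats::quantile(acc, c(0.005, 0.995), names = FALSE))
}

#' Sliding-window category generalization timecourse
#'
#' Runs \code{category_generalization} in a sliding window (default 200 ms
#' wide) centered at each requested time, with bootstrap confidence
#' intervals and a one-sided bootstrap test against chance,
#' Benjamini-Hochberg corrected across time points.
#'
#' @param dataset a \code{trial_dataset}.
#' @param times_s window centers, seconds relative to sample onset.
#' @param width_s window width.
#' @param n_boot,n_per_dir,splits,seed as in
#'   \code{category_generalization}.
#' @return data.frame: time_s, mean, median, lo99, hi99, p_boot,
#'   significant.
#' @export
category_generalization_timecourse <- function(dataset, times_s,
                                               width_s = 0.2,
                                               n_boot = 200L,
                                               n_per_dir = 50L,
                                               splits = NULL, seed = 1L) {
  rows <- lapply(seq_along(times_s), function(i) {
    tc <- times_s[i]
    cg <- category_generalization(dataset, "sample",
                                  c(tc - width_s / 2, tc + width_s / 2),
                                  n_boot, n_per_dir, splits, seed + i)
    p <- mean(cg$accuracy <= 0.5)   # one-sided bootstrap test vs chance
    data.frame(time_s = tc, mean = cg$mean,
               median = stats::median(cg$accuracy),
               lo99 = cg$ci99[1], hi99 = cg$ci99[2], p_boot = p)
  })
  df <- do.call(rbind, rows)
  df$p_bh <- stats::p.adjust(df$p_boot, method = "BH")
  df$significant <- df$p_bh < 0.05
  df
}

#' Match/non-match cross-condition category decoding
#'
#' Decoders for sample (or test) category are trained on match trials only
#' and tested on non-match trials (and vice versa), using counts 0-200 ms
#' after test motion onset; performance is averaged over the two training
#' regimes. Sample- and test-category accuracies are mirror images about
#' chance on non-match trials, where the two categories disagree.
#'
#' @param dataset a \code{trial_dataset}.
#' @param target decode "sample" or "test" category.
#' @param window_s window, seconds relative to test onset.
#' @param n_boot,n_per_dir,seed bootstrap controls.
#' @return list: \code{accuracy} (per bootstrap), \code{mean},
#'   \code{ci99}.
#' @export
match_condition_decoding <- function(dataset, target = c("sample", "test"),
                                     window_s = c(0, 0.2), n_boot = 200L,
                                     n_per_dir = 50L, seed = 1L) {
  target <- match.arg(target)
  dirs <- sort(unique(vapply(dataset$trials, function(tr) tr$theta_sample, 0)))
  cats <- direction_category(dirs, dataset$boundary)
  set.seed(seed)
  pool_m <- pseudo_pool(dataset, dirs, "test", window_s, match = TRUE)
  pool_n <- pseudo_pool(dataset, dirs, "test", window_s, match = FALSE)
  one <- function(train_match) {
    Xtr <- do.call(rbind, pseudo_sample(if (train_match) pool_m else pool_n,
                                        n_per_dir))
    Xva <- do.call(rbind, pseudo_sample(if (train_match) pool_n else pool_m,
                                        n_per_dir))
    scat <- rep(cats, each = n_per_dir)
    lab <- function(is_match) if (target == "sample") scat else
      if (is_match) scat else 3L - scat  # non-match: test is other category
    dec <- train_decoder(Xtr, lab(train_match))
    mean(dec$predict(Xva) == as.character(lab(!train_match)))
  }
  acc <- vapply(seq_len(n_boot), function(b) (one(TRUE) + one(FALSE)) / 2, 0)
  list(accuracy = acc, mean = mean(acc),
       ci99 = stats::quantile(acc, c(0.005, 0.995), names = FALSE))
}
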