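#' Motion-direction category under a fixed boundary
#'
#' Directions strictly between the two boundary angles (default 45 and 225
#' degrees) are category 1; directions on the other side are category 2;
#' directions exactly on the boundary are ambiguous and return \code{NA}.
#'
#' @param theta direction(s) in degrees, in [0, 360).
#' @param boundary length-2 boundary in degrees.
#' @return integer vector in \{1, 2, NA\}.
#' @export
direction_category <- function(theta, boundary = c(45, 225)) {
  th <- theta %% 360
  out <- ifelse(th > boundary[1] & th < boundary[2], 1L, 2L)
  out[th == boundary[1] | th == boundary[2]] <- NA_integer_
  out
}

#' Construct a single trial record
#'
#' One trial of one (non-simultaneously recorded) neuron: binned spike
#' counts plus task-event metadata. Event times are 1-based bin indices into
#' \code{counts}.
#'
#' @param neuron neuron identifier.
#' @param counts nonnegative integer spike counts per bin.
#' @param t_sample_on,t_test_on sample/test stimulus onset bins.
#' @param theta_sample,theta_test directions in degrees, [0, 360).
#' @param t_tbar touch-bar release bin, or \code{NA} if no release.
#' @param correct logical outcome flag.
#' @param boundary category boundary (degrees) used to label categories.
#' @return a list of class \code{gmlm_trial}.
#' @export
new_trial <- function(neuron, counts, t_sample_on, t_test_on,
                      theta_sample, theta_test, t_tbar = NA_integer_,
                      correct = TRUE, boundary = c(45, 225)) {
  counts <- as.integer(counts)
  if (any(counts < 0)) stop("counts must be nonnegative")
  if (!(t_sample_on < t_test_on)) stop("t_sample_on must precede t_test_on")
  if (!is.na(t_tbar) && (t_tbar < 1 || t_tbar > length(counts)))
    stop("t_tbar outside the trial window")
  structure(list(neuron = neuron, counts = counts,
                 t_sample_on = as.integer(t_sample_on),
                 t_test_on = as.integer(t_test_on),
                 theta_sample = theta_sample %% 360,
                 theta_test = theta_test %% 360,
                 c_sample = direction_category(theta_sample, boundary),
                 c_test = direction_category(theta_test, boundary),
                 t_tbar = as.integer(t_tbar), correct = isTRUE(correct)),
            class = "gmlm_trial")
}

#' Construct a trial dataset
#'
#' Container for one population of neurons recorded (non-simultaneously)
#' during the delayed-match task: a list of trials, the bin width, and task
#' constants.
#'
#' @param trials list of \code{gmlm_trial} objects.
#' @param neuron_ids identifiers; defaults to those present in trials.
#' @param bin_width bin width in seconds (default 0.005).
#' @param boundary category boundary in degrees.
#' @param stim_dur_bins stimulus presentation duration in bins (default 130,
#'   i.e. 650 ms at 5 ms bins).
#' @return object of class \code{trial_dataset}.
#' @export
trial_dataset <- function(trials, neuron_ids = NULL, bin_width = 0.005,
                          boundary = c(45, 225), stim_dur_bins = 130L) {
  if (bin_width <= 0) stop("bin_width must be positive")
  used <- unique(vapply(trials, function(tr) as.character(tr$neuron), ""))
  if (is.null(neuron_ids)) neuron_ids <- used
  if (!all(used %in% as.character(neuron_ids)))
    stop("trials reference unknown neurons")
  structure(list(neuron_ids = neuron_ids, trials = trials,
                 bin_width = bin_width, boundary = boundary,
                 stim_dur_bins = as.integer(stim_dur_bins),
                 simultaneity_flag = FALSE),
            class = "trial_dataset")
}

#' @export
print.trial_dataset <- function(x, ...) {
  cat(sprintf("trial_dataset: %d neurons, %d trials, bin width %g ms\n",
              length(x$neuron_ids), length(x$trials), x$bin_width * 1000))
  invisible(x)
}

#' Bin spike times into counts
#'
#' Half-open bins [t, t + bin_width): a spike exactly at the window end is
#' excluded, so binning conserves the number of spikes inside the window.
#'
#' @param spike_times sorted spike times in seconds.
#' @param window length-2 half-open window [start, end) in seconds.
#' @param bin_width bin width in seconds.
#' @return integer counts per bin, length \code{ceiling((end-start)/bin_width)}.
#' @export
bin_spikes <- function(spike_times, window, bin_width) {
  if (!is.finite(bin_width) || bin_width <= 0)
    stop("bin_width must be positive")
  if (window[2] <= window[1]) stop("window must be nonempty")
  nb <- ceiling((window[2] - window[1]) / bin_width)
  s <- spike_times[spike_times >= window[1] & spike_times < window[2]]
  idx <- floor((s - window[1]) / bin_width) + 1L
  idx <- pmin(idx, nb)  # guard float roundoff at the last bin edge
  tabulate(idx, nbins = nb)
}

#' Modeled trial window
#'
#' The window starts at sample stimulus onset and ends 50 ms after the
#' touch-bar release when a release occurred, otherwise 50 ms after the test
#' motion offset. The second test stimulus on non-match trials is never
#' modeled.
#'
#' @param t_sample_on sample onset (s).
#' @param t_test_off test motion offset (s).
#' @param t_release touch-bar release time (s) or \code{NA}.
#' @param pad post-event padding in seconds (50 ms).
#' @return numeric length-2 half-open window [start, end).
#' @export
trial_window <- function(t_sample_on, t_test_off, t_release = NA,
                         pad = 0.050) {
  if (!is.na(t_release) && t_release < t_sample_on)
    stop("invalid trial: release precedes sample onset")
  end <- if (!is.na(t_release)) t_release + pad else t_test_off + pad
  c(t_sample_on, end)
}

#' Drop low-rate neurons
#'
#' Retains neurons whose mean firing rate, averaged from sample stimulus
#' onset to test motion offset across their trials, is at least
#' \code{rate_threshold} (spikes/s).
#'
#' @param dataset a \code{trial_dataset}.
#' @param rate_threshold spikes/s (default 2).
#' @return filtered \code{trial_dataset}.
#' @export
filter_neurons <- function(dataset, rate_threshold = 2) {
  stopifnot(rate_threshold >= 0)
  if (length(dataset$trials) == 0) {
    warning("empty dataset")
    return(dataset)
  }
  nid <- vapply(dataset$trials, function(tr) as.character(tr$neuron), "")
  rate <- function(tr) {
    to <- min(tr$t_test_on + dataset$stim_dur_bins - 1L, length(tr$counts))
    idx <- tr$t_sample_on:to
    sum(tr$counts[idx]) / (length(idx) * dataset$bin_width)
  }
  rates <- tapply(vapply(dataset$trials, rate, 0), nid, mean)
  keep <- names(rates)[rates >= rate_threshold]
  trial_dataset(dataset$trials[nid %in% keep],
                neuron_ids = dataset$neuron_ids[
                  as.character(dataset$neuron_ids) %in% keep],
                bin_width = dataset$bin_width, boundary = dataset$boundary,
                stim_dur_bins = dataset$stim_dur_bins)
}

#' Stratified cross-validation folds
#'
#' Trials are divided into K folds evenly by sample direction within each
#' neuron (e.g. 40 trials of one direction become 10 groups of 4 for K =
#' 10). Within each (neuron, direction) stratum the trials are shuffled with
#' the given seed and the folds receiving an extra trial are randomized, so
#' per-stratum fold sizes differ by at most one.
#'
#' @param dataset a \code{trial_dataset}.
#' @param K number of folds (>= 2).
#' @param seed RNG seed for the within-stratum shuffle.
#' @return list of class \code{fold_assignment}: \code{K},
#'   \code{fold_of_trial} (integer per trial).
#' @export
make_folds <- function(dataset, K, seed = 1L) {
  stopifnot(K >= 2)
  n <- length(dataset$trials)
  strata <- paste(vapply(dataset$trials, function(tr) as.character(tr$neuron), ""),
                  vapply(dataset$trials, function(tr) tr$theta_sample, 0))
  fold <- integer(n)
  set.seed(seed)
  for (s in unique(strata)) {
    idx <- which(strata == s)
    m <- length(idx)
    if (m < K) warning(sprintf("stratum '%s' has fewer trials (%d) than folds", s, m))
    f <- rep_len(sample.int(K), m)
    fold[idx[sample.int(m)]] <- f
  }
  structure(list(K = as.integer(K), fold_of_trial = fold),
            class = "fold_assignment")
}

#' Trial-averaged smoothed firing rate (PSTH)
#'
#' Averages the spike rate over the selected trials and smooths with a
#' Gaussian kernel (default SD 30 ms). Trials of unequal length contribute
#' to the bins they cover.
#'
#' @param dataset a \code{trial_dataset}.
#' @param neuron neuron id; \code{NULL} selects all neurons.
#' @param theta_sample sample direction (degrees) to condition on;
#'   \code{NULL} selects all.
#' @param kernel_sd Gaussian kernel SD in seconds; 0 returns the raw PSTH.
#' @return numeric rate trace in spikes/s.
#' @export
smooth_psth <- function(dataset, neuron = NULL, theta_sample = NULL,
                        kernel_sd = 0.030) {
  sel <- vapply(dataset$trials, function(tr) {
    (is.null(neuron) || as.character(tr$neuron) == as.character(neuron)) &&
      (is.null(theta_sample) || isTRUE(tr$theta_sample == theta_sample %% 360))
  }, TRUE)
  trials <- dataset$trials[sel]
  if (length(trials) == 0) stop("condition selects no trials")
  L <- max(vapply(trials, function(tr) length(tr$counts), 0L))
  num <- den <- numeric(L)
  for (tr in trials) {
    k <- length(tr$counts)
    num[1:k] <- num[1:k] + tr$counts
    den[1:k] <- den[1:k] + 1
  }
  psth <- num / den / dataset$bin_width
  if (kernel_sd < dataset$bin_width / 2) return(psth)
  hw <- ceiling(4 * kernel_sd / dataset$bin_width)
  kt <- (-hw:hw) * dataset$bin_width
  kern <- exp(-0.5 * (kt / kernel_sd)^2)
  sm <- stats::filter(c(rep(psth[1], hw), psth, rep(psth[L], hw)),
                      kern / sum(kern), sides = 2)
  as.numeric(sm[(hw + 1):(hw + L)])
}

#' Write / read a trial dataset as JSON lines
#'
#' Plain-text serialization: the first line is a header with dataset
#' attributes, each subsequent line one trial.
#'
#' @param dataset a \code{trial_dataset}.
#' @param path file path.
#' @return (read) a \code{trial_dataset}; (write) the path, invisibly.
#' @export
write_trials_jsonl <- function(dataset, path) {
  hdr <- jsonlite::toJSON(list(type = "header", bin_width = dataset$bin_width,
                               boundary = dataset$boundary,
                               stim_dur_bins = dataset$stim_dur_bins,
                               neuron_ids = as.character(dataset$neuron_ids)),
                          auto_unbox = TRUE, digits = NA)
  lines <- vapply(dataset$trials, function(tr) {
    tr$counts <- as.integer(tr$counts)
    as.character(jsonlite::toJSON(unclass(tr), auto_unbox = TRUE, digits = NA,
                                  na = "null"))
  }, "")
  writeLines(c(as.character(hdr), lines), path)
  invisible(path)
}

#' @rdname write_trials_jsonl
#' @export
read_trials_jsonl <- function(path) {
  lines <- readLines(path)
  hdr <- jsonlite::fromJSON(lines[1])
  trials <- lapply(lines[-1], function(l) {
    x <- jsonlite::fromJSON(l)
    new_trial(x$neuron, x$counts, x$t_sample_on, x$t_test_on,
              x$theta_sample, x$theta_test,
              if (is.null(x$t_tbar)) NA_integer_ else x$t_tbar,
              x$correct, boundary = hdr$boundary)
  })
  trial_dataset(trials, neuron_ids = hdr$neuron_ids,
                bin_width = hdr$bin_width, boundary = hdr$boundary,
                stim_dur_bins = hdr$stim_dur_bins)
}
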