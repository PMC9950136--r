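#' Raised-cosine temporal basis
#'
#' Constructs a log-stretched raised-cosine basis of the kind used for
#' temporal kernels in point-process GLMs of spiking data. Each raw column is
#' a bump \eqn{0.5 (1 + \cos(\pi \cdot \mathrm{clip}((\phi(t)-\phi_j)/\delta, -1, 1)))}
#' on the warped time axis \eqn{\phi(t) = \log(t + \xi)} with
#' \eqn{\xi = \mathrm{stretch} \cdot \mathrm{peak\_last}}, peaks equally
#' spaced in \eqn{\phi} between \code{peak_first} and \code{peak_last}.
#' Neighbouring bumps overlap; bumps two apart do not. The returned basis is
#' orthonormalized by QR (in peak order, sign fixed so each column's
#' largest-magnitude entry is positive); the orthonormal columns control
#' temporal smoothness of the kernels they parameterize.
#'
#' @param n number of basis functions.
#' @param stretch nonnegative nonlinear stretching parameter; 0 gives a
#'   linear time axis.
#' @param peak_first,peak_last times (s) of the first and last bump peaks.
#' @param bin_width bin width \eqn{\Delta} in seconds (default 0.005).
#' @param snap_peaks snap bump peaks to the bin grid so each raw column
#'   attains exactly 1 at its peak bin.
#' @return an object of class \code{rc_basis}: list with \code{B}
#'   (orthonormalized, time bins x n), \code{raw}, \code{lag0} (row index of
#'   the event bin, i.e. lag zero), \code{bin_width}, \code{alignment},
#'   \code{peaks} (peak times in seconds relative to the event).
#' @export
raised_cosine_basis <- function(n, stretch, peak_first, peak_last,
                                bin_width = 0.005, snap_peaks = TRUE) {
  stopifnot(is.finite(n), n >= 1, is.finite(stretch), stretch >= 0,
            is.finite(peak_first), is.finite(peak_last),
            peak_first <= peak_last, is.finite(bin_width))
  if (bin_width <= 0) stop("bin_width must be positive")
  xi <- stretch * peak_last
  phi <- if (xi > 0) function(t) log(t + xi) else function(t) t
  phi_first <- phi(peak_first)
  phi_last <- phi(peak_last)
  delta <- if (n > 1) (phi_last - phi_first) / (n - 1) else
    max(phi(peak_first + bin_width) - phi_first, .Machine$double.eps)
  peaks_phi <- phi_first + (seq_len(n) - 1) * delta
  # last bump's support ends where phi(t) = phi_last + delta
  t_end <- if (xi > 0) exp(phi_last + delta) - xi else phi_last + delta
  tt <- seq(0, t_end + bin_width, by = bin_width)
  if (snap_peaks) {
    peak_t <- if (xi > 0) exp(peaks_phi) - xi else peaks_phi
    peak_t <- tt[pmax(1L, pmin(length(tt), round(peak_t / bin_width) + 1L))]
    peaks_phi <- phi(peak_t)
  }
  arg <- outer(phi(tt), peaks_phi, "-") / delta
  B_raw <- 0.5 * (1 + cos(pi * pmin(pmax(arg, -1), 1)))
  # trim trailing all-zero rows
  nz <- which(rowSums(B_raw) > 0)
  keep <- seq_len(if (length(nz)) max(nz) else 1L)
  B_raw <- B_raw[keep, , drop = FALSE]
  structure(list(B = orthonormalize_basis(B_raw),
                 raw = B_raw,
                 lag0 = 1L,
                 bin_width = bin_width,
                 alignment = "causal-post-event",
                 peaks = if (xi > 0) exp(peaks_phi) - xi else peaks_phi),
            class = "rc_basis")
}

# QR orthonormalization in column (peak) order; sign fixed so the
# largest-magnitude entry of each column is positive.
orthonormalize_basis <- function(B_raw) {
  qrd <- qr(B_raw)
  if (qrd$rank < ncol(B_raw))
    stop("raw basis is rank deficient; adjust peaks/stretch")
  Q <- qr.Q(qrd)
  sgn <- apply(Q, 2L, function(col) sign(col[which.max(abs(col))]))
  Q <- sweep(Q, 2L, sgn, "*")
  Q[rowSums(abs(B_raw)) == 0, ] <- 0  # keep structural zeros exact
  Q
}

#' Stimulus-onset temporal basis
#'
#' 24 causal raised-cosine functions (stretch 0.2, peaks spanning 0-1500 ms)
#' shifted so the basis is zero at the exact time of stimulus onset, giving
#' peaks between 40 and 1540 ms after onset.
#'
#' @param n,stretch,peak_first,peak_last,bin_width basis configuration;
#'   defaults as used throughout.
#' @param onset_shift shift (s) applied so the earliest function vanishes at
#'   the onset bin.
#' @return an \code{rc_basis}, causal (zero at and before the event bin).
#' @export
stimulus_basis <- function(n = 24, stretch = 0.2, peak_first = 0,
                           peak_last = 1.5, bin_width = 0.005,
                           onset_shift = 0.040) {
  b <- raised_cosine_basis(n, stretch, peak_first, peak_last, bin_width)
  k <- as.integer(round(onset_shift / bin_width))
  pad <- matrix(0, k, n)
  raw <- rbind(pad, b$raw)
  structure(list(B = orthonormalize_basis(raw), raw = raw, lag0 = 1L,
                 bin_width = bin_width, alignment = "causal-post-event",
                 peaks = b$peaks + k * bin_width),
            class = "rc_basis")
}

#' Touch-bar release temporal basis
#'
#' The first \code{n} functions of the stimulus basis, time-reversed and
#' shifted so that the fastest function peaks 25 ms after the release: the
#' basis is acausal (support mostly before the release, reflecting buildup to
#' the match decision) with its finest temporal resolution near the release.
#'
#' @param n number of functions (default 8).
#' @param stim basis to mirror; defaults to \code{stimulus_basis()}.
#' @param peak_end time (s) of the latest peak relative to release.
#' @return an \code{rc_basis} with \code{alignment = "acausal-pre-event"};
#'   \code{lag0} marks the release bin row.
#' @export
touchbar_basis <- function(n = 8, stim = stimulus_basis(),
                           peak_end = 0.025) {
  bw <- stim$bin_width
  raw_f <- stim$raw[, seq_len(n), drop = FALSE]
  raw <- raw_f[rev(seq_len(nrow(raw_f))), , drop = FALSE]
  # after reversal row i corresponds to lag -(nrow - i); shift so the first
  # (fastest) column peaks at +peak_end
  peaks <- -rev(stim$peaks[seq_len(n)])  # most negative first after reversal
  shift_s <- peak_end - max(peaks)
  k <- as.integer(round(shift_s / bw))
  pad <- matrix(0, max(k, 0L), n)
  raw <- rbind(raw, pad)
  lag0 <- nrow(raw_f) - k  # row index of lag 0
  peaks <- peaks + k * bw
  structure(list(B = orthonormalize_basis(raw),
                 raw = raw, lag0 = as.integer(lag0), bin_width = bw,
                 alignment = "acausal-pre-event",
                 peaks = sort(peaks)),
            class = "rc_basis")
}

#' Post-spike history basis
#'
#' Ten strictly causal columns: Kronecker deltas at lags 1 and 2 bins (0-5
#' and 5-10 ms after a spike), then \code{n_cosine} log-stretched
#' raised-cosine bumps. All columns are zero at lag 0, so a spike cannot
#' excite its own bin.
#'
#' @param n_delta number of leading single-bin indicator columns.
#' @param n_cosine number of raised-cosine columns.
#' @param stretch stretching parameter for the cosine part.
#' @param peak_first,peak_last peak range (s) of the cosine bumps post spike.
#'   The default 10-200 ms gives a well-conditioned basis at 5 ms bins.
#' @param bin_width bin width in seconds.
#' @return an \code{rc_basis}; row 1 is lag 0 (all zeros).
#' @export
spike_history_basis <- function(n_delta = 2, n_cosine = 8, stretch = 0.05,
                                peak_first = 0.010, peak_last = 0.200,
                                bin_width = 0.005) {
  bc <- raised_cosine_basis(n_cosine, stretch, peak_first, peak_last,
                            bin_width)
  L <- max(nrow(bc$raw), n_delta + 1L)
  raw <- matrix(0, L + 1L, n_delta + n_cosine)  # row 1 = lag 0
  for (j in seq_len(n_delta)) raw[j + 1L, j] <- 1
  raw[1L + seq_len(nrow(bc$raw)), n_delta + seq_len(n_cosine)] <- bc$raw
  # raw cosine bumps start after the delta lags by construction of peaks;
  # enforce causality margin: zero out lag 0 explicitly
  raw[1L, ] <- 0
  structure(list(B = orthonormalize_basis(raw), raw = raw, lag0 = 1L,
                 bin_width = bin_width, alignment = "post-spike",
                 peaks = c((seq_len(n_delta)) * bin_width, bc$peaks)),
            class = "rc_basis")
}

#' Default basis set
#'
#' Convenience bundle of the three bases at a common bin width.
#' @param bin_width bin width in seconds.
#' @return list with elements \code{stim}, \code{tbar}, \code{spk}.
#' @export
default_bases <- function(bin_width = 0.005) {
  st <- stimulus_basis(bin_width = bin_width)
  list(stim = st, tbar = touchbar_basis(stim = st),
       spk = spike_history_basis(bin_width = bin_width))
}

#' Least-squares projection of a kernel onto a basis
#'
#' @param basis an \code{rc_basis}.
#' @param kernel numeric vector on the basis' time grid.
#' @return coefficient vector \eqn{B^\top k} (columns orthonormal).
#' @export
project_kernel <- function(basis, kernel) {
  stopifnot(length(kernel) == nrow(basis$B))
  drop(crossprod(basis$B, kernel))
}
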