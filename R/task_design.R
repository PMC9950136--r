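#' Stimulus parameterization for the task design
#'
#' Defines one of the nested stimulus linearizations. The number of stimulus
#' coefficients S per parameterization: none 2, category 4, cosine 6, full
#' D+2 (direction kernels absorb the sample-category response; the two test
#' category kernels encode test-minus-sample category tuning, which keeps
#' the model identifiable), cosine_independent 8, full_independent 2D+2.
#'
#' @param parameterization one of "none", "category", "cosine", "full",
#'   "cosine_independent", "full_independent".
#' @param direction_set task motion directions in degrees.
#' @param boundary category boundary (degrees).
#' @return object of class \code{design_spec} with fields
#'   \code{parameterization}, \code{direction_set}, \code{boundary},
#'   \code{labels}, \code{S}.
#' @export
design_spec <- function(parameterization = c("cosine", "none", "category",
                                             "full", "cosine_independent",
                                             "full_independent"),
                        direction_set = c(15, 75, 135, 195, 255, 315),
                        boundary = c(45, 225)) {
  parameterization <- match.arg(parameterization)
  D <- length(direction_set)
  labels <- switch(parameterization,
    none = c("sample", "test"),
    category = c("cs1", "cs2", "ct1", "ct2"),
    cosine = c("cs1", "cs2", "ct1", "ct2", "cos", "sin"),
    full = c(paste0("theta_", direction_set), "ct1", "ct2"),
    cosine_independent = c("cs1", "cs2", "ct1", "ct2",
                           "cos_s", "sin_s", "cos_t", "sin_t"),
    full_independent = c(paste0("stheta_", direction_set),
                         paste0("ttheta_", direction_set), "ct1", "ct2"))
  structure(list(parameterization = parameterization,
                 direction_set = direction_set %% 360,
                 boundary = boundary, labels = labels,
                 S = length(labels), D = D),
            class = "design_spec")
}

#' Kernel labels of the matching single-cell GLM
#'
#' @param spec a \code{design_spec}.
#' @return character vector of kernel labels (the event set of the GLM with
#'   the same parameterization).
#' @export
glm_kernel_set <- function(spec) spec$labels

#' Stimulus coefficient vector for one stimulus presentation
#'
#' The length-S vector of direction/category weights attached to the timing
#' impulse of a sample or test stimulus, per the parameterization's support
#' pattern. Angles are converted to radians internally for the cosine terms.
#'
#' @param theta direction in degrees.
#' @param category category label in \{1, 2\}.
#' @param role "sample" or "test".
#' @param spec a \code{design_spec}.
#' @return numeric length-S coefficient vector, named by kernel label.
#' @export
stimulus_coefficients <- function(theta, category, role = c("sample", "test"),
                                  spec) {
  role <- match.arg(role)
  x <- stats::setNames(numeric(spec$S), spec$labels)
  th <- (theta %% 360) * pi / 180
  p <- spec$parameterization
  set1 <- function(nm) {x[nm] <<- 1}
  if (p == "none") {
    set1(role)
  } else if (p == "category") {
    set1(paste0(if (role == "sample") "cs" else "ct", category))
  } else if (p == "cosine") {
    set1(paste0(if (role == "sample") "cs" else "ct", category))
    x["cos"] <- cos(th); x["sin"] <- sin(th)
  } else if (p == "cosine_independent") {
    set1(paste0(if (role == "sample") "cs" else "ct", category))
    sfx <- if (role == "sample") "_s" else "_t"
    x[paste0("cos", sfx)] <- cos(th); x[paste0("sin", sfx)] <- sin(th)
  } else if (p == "full") {
    lab <- paste0("theta_", theta %% 360)
    if (!lab %in% spec$labels) stop("direction not in direction_set: ", theta)
    set1(lab)
    if (role == "test") set1(paste0("ct", category))
  } else if (p == "full_independent") {
    lab <- paste0(if (role == "sample") "stheta_" else "ttheta_", theta %% 360)
    if (!lab %in% spec$labels) stop("direction not in direction_set: ", theta)
    set1(lab)
    if (role == "test") set1(paste0("ct", category))
  }
  x
}

#' Timing and touch-bar regressors for one trial
#'
#' Unit impulses at the sample onset, test onset and (when present) the
#' touch-bar release bin; the touch-bar regressor is identically zero on
#' trials with no release.
#'
#' @param trial a \code{gmlm_trial}.
#' @return list of numeric vectors \code{x_timing_sample},
#'   \code{x_timing_test}, \code{x_tbar}, each of the trial's length.
#' @export
build_timing <- function(trial) {
  T_ <- length(trial$counts)
  ev <- c(trial$t_sample_on, trial$t_test_on)
  if (any(ev < 1 | ev > T_)) stop("event outside trial window")
  imp <- function(at) {x <- numeric(T_); if (!is.na(at)) x[at] <- 1; x}
  list(x_timing_sample = imp(trial$t_sample_on),
       x_timing_test = imp(trial$t_test_on),
       x_tbar = imp(trial$t_tbar))
}

#' Full regressor structure for one trial
#'
#' @param trial a \code{gmlm_trial}.
#' @param spec a \code{design_spec}.
#' @return list with the timing impulses plus \code{x_dir_sample} and
#'   \code{x_dir_test} coefficient vectors.
#' @export
trial_regressors <- function(trial, spec) {
  c(build_timing(trial),
    list(x_dir_sample = stimulus_coefficients(trial$theta_sample,
                                              trial$c_sample, "sample", spec),
         x_dir_test = stimulus_coefficients(trial$theta_test,
                                            trial$c_test, "test", spec)))
}

#' Linear map between nested stimulus designs
#'
#' Returns the matrix M such that the coarser design's coefficient vector is
#' \code{M \%*\%} the finer design's vector, for every trial. Supported
#' pairs follow the nesting chain none < category < cosine < full; requests
#' across non-adjacent members compose the maps.
#'
#' @param fine,coarse \code{design_spec}s sharing direction set and boundary.
#' @return numeric matrix (S_coarse x S_fine).
#' @export
nesting_map <- function(fine, coarse) {
  chain <- c("none", "category", "cosine", "full")
  i <- match(coarse$parameterization, chain)
  j <- match(fine$parameterization, chain)
  if (is.na(i) || is.na(j) || i > j) stop("unsupported nesting pair")
  M <- diag(fine$S)
  rownames(M) <- colnames(M) <- fine$labels
  cur <- fine
  while (j > i) {
    to <- design_spec(chain[j - 1], cur$direction_set, cur$boundary)
    M1 <- matrix(0, to$S, cur$S, dimnames = list(to$labels, cur$labels))
    if (cur$parameterization == "category") {
      M1["sample", c("cs1", "cs2")] <- 1
      M1["test", c("ct1", "ct2")] <- 1
    } else if (cur$parameterization == "cosine") {
      for (nm in c("cs1", "cs2", "ct1", "ct2")) M1[nm, nm] <- 1
    } else {  # full -> cosine
      th <- cur$direction_set
      cats <- direction_category(th, cur$boundary)
      for (k in 1:2) {
        dl <- paste0("theta_", th[cats == k])
        M1[paste0("cs", k), dl] <- 1
        M1[paste0("cs", k), paste0("ct", k)] <- -1
        M1[paste0("ct", k), paste0("ct", k)] <- 1
      }
      M1["cos", paste0("theta_", th)] <- cos(th * pi / 180)
      M1["sin", paste0("theta_", th)] <- sin(th * pi / 180)
    }
    M <- M1 %*% M
    cur <- to
    j <- j - 1
  }
  M
}
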