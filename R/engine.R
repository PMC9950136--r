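# Internal evaluation engine for the population model.
#
# Trials are grouped by (neuron, event layout, stimulus coefficients). When
# the model has no per-trial terms (no spike history), all trials in a group
# share their log-rate trace, so the Poisson log likelihood collapses onto
# the group's summed counts and trial multiplicity; this is what makes
# maximum-likelihood rank sweeps and HMC feasible at realistic trial counts.

#' Indices of trials usable for model fitting
#'
#' Only correct trials with unambiguous (off-boundary) sample and test
#' categories enter the design; for the full parameterizations the
#' directions must belong to the configured direction set.
#'
#' @param dataset a \code{trial_dataset}.
#' @param spec a \code{design_spec}.
#' @return integer vector of trial indices.
#' @export
usable_trials <- function(dataset, spec) {
  ok <- vapply(dataset$trials, function(tr) {
    good <- tr$correct && !is.na(tr$c_sample) && !is.na(tr$c_test)
    if (good && spec$parameterization %in% c("full", "full_independent"))
      good <- (tr$theta_sample %in% spec$direction_set) &&
        (tr$theta_test %in% spec$direction_set)
    good
  }, TRUE)
  which(ok)
}

#' Grouped design data for the population likelihood
#'
#' Builds the trial-aggregated structure the fitting and sampling routines
#' evaluate: trials are grouped by (neuron, event layout, stimulus
#' coefficients), and, without per-trial spike-history terms, further split
#' by kernel support with rate-identical columns merged (both reductions
#' are exact). \code{per_trial = TRUE} forces one group per trial (needed
#' for per-trial predictive evaluation).
#'
#' @param dataset a \code{trial_dataset}.
#' @param model a \code{gmlm_model}.
#' @param trial_idx optional trial subset.
#' @param per_trial keep one group per trial.
#' @return object of class \code{gmlm_data}.
#' @export
prepare_pop_data <- function(dataset, model, trial_idx = NULL,
                             per_trial = model$include_history) {
  spec <- model$spec
  if (is.null(trial_idx)) trial_idx <- usable_trials(dataset, spec)
  trials <- dataset$trials[trial_idx]
  nmap <- stats::setNames(seq_along(dataset$neuron_ids),
                          as.character(dataset$neuron_ids))
  per_trial <- per_trial || model$include_history
  lay_key <- vapply(trials, function(tr)
    paste(length(tr$counts), tr$t_sample_on, tr$t_test_on, tr$t_tbar), "")
  lay_ids <- match(lay_key, unique(lay_key))
  layouts <- lapply(which(!duplicated(lay_ids)), function(i) {
    tr <- trials[[i]]
    T_ <- length(tr$counts)
    list(T = T_,
         Ms = shift_design(model$bases$stim, tr$t_sample_on, T_),
         Mt = shift_design(model$bases$stim, tr$t_test_on, T_),
         Mtb = if (model$include_tbar && model$rank_tbar > 0)
           shift_design(model$bases$tbar, tr$t_tbar, T_))
  })
  XS <- vapply(trials, function(tr)
    stimulus_coefficients(tr$theta_sample, tr$c_sample, "sample", spec),
    numeric(spec$S))
  XT <- vapply(trials, function(tr)
    stimulus_coefficients(tr$theta_test, tr$c_test, "test", spec),
    numeric(spec$S))
  XS <- matrix(XS, nrow = spec$S); XT <- matrix(XT, nrow = spec$S)
  n_idx <- vapply(trials, function(tr) nmap[[as.character(tr$neuron)]], 1L)
  grp_key <- if (per_trial) seq_along(trials) else
    paste(lay_ids, n_idx, apply(XS, 2, paste, collapse = ","),
          apply(XT, 2, paste, collapse = ","))
  gid <- match(grp_key, unique(grp_key))
  G <- max(gid)
  bylayout <- vector("list", max(lay_ids))
  for (l in seq_len(max(lay_ids))) {
    gset <- unique(gid[lay_ids == l])
    T_ <- layouts[[l]]$T
    Y <- matrix(0, T_, length(gset))
    m <- numeric(length(gset)); lf <- numeric(length(gset))
    nn <- integer(length(gset))
    tl <- vector("list", length(gset))
    for (j in seq_along(gset)) {
      tt <- which(gid == gset[j])
      Y[, j] <- Reduce(`+`, lapply(trials[tt], `[[`, "counts"))
      m[j] <- length(tt)
      lf[j] <- sum(vapply(trials[tt],
                          function(tr) sum(lfactorial(tr$counts)), 0))
      nn[j] <- n_idx[tt[1]]
      tl[[j]] <- trial_idx[tt]
    }
    first <- vapply(gset, function(g) which(gid == g)[1], 1L)
    lay <- layouts[[l]]
    bylayout[[l]] <- list(
      layout = lay, n_idx = nn, m = m, Y = Y, lfact = lf,
      XS = XS[, first, drop = FALSE],
      XT = XT[, first, drop = FALSE],
      trials = tl,
      # basis-projected count statistics (all Y-linear terms use these)
      YS = crossprod(lay$Ms, Y), YT = crossprod(lay$Mt, Y),
      YTB = if (!is.null(lay$Mtb)) crossprod(lay$Mtb, Y),
      ycs = colSums(Y),
      H = if (model$include_history)
        lapply(first, function(i)
          history_design(trials[[i]]$counts, model$bases$spk)))
  }
  if (!per_trial)
    bylayout <- unlist(lapply(bylayout, split_layout_blocks),
                       recursive = FALSE)
  structure(list(bylayout = bylayout, N = length(dataset$neuron_ids),
                 bin_width = dataset$bin_width,
                 sum_y = sum(vapply(trials, function(tr) sum(tr$counts), 0)),
                 n_trials = length(trials)),
            class = "gmlm_data")
}

# Split one layout block into row blocks by kernel support (sample-only,
# test-only, overlap, neither) and merge rate-identical columns within each
# block. Exactness: the Poisson log likelihood is a sum over (bin, trial)
# cells, and within each block all merged trials share their rate trace.
# Only applies without spike history and without a touch-bar design (whose
# support would intersect both).
split_layout_blocks <- function(bl) {
  lay <- bl$layout
  if (!is.null(lay$Mtb) || !is.null(bl$H)) return(list(bl))
  rs <- rowSums(abs(lay$Ms)) > 0
  rt <- rowSums(abs(lay$Mt)) > 0
  seg <- list(s = which(rs & !rt), t = which(!rs & rt),
              b = which(rs & rt), n = which(!rs & !rt))
  if (length(seg$b) > 0.5 * lay$T) return(list(bl))  # little to gain
  keys <- list(
    s = paste(bl$n_idx, apply(bl$XS, 2, paste, collapse = ",")),
    t = paste(bl$n_idx, apply(bl$XT, 2, paste, collapse = ",")),
    b = seq_along(bl$m),
    n = bl$n_idx)
  first_lfact <- TRUE
  out <- list()
  for (nm in names(seg)) {
    rows <- seg[[nm]]
    if (length(rows) == 0) next
    key <- keys[[nm]]
    gid <- match(key, unique(key))
    first <- which(!duplicated(gid))
    Yr <- bl$Y[rows, , drop = FALSE]
    Ym <- t(rowsum(t(Yr), gid, reorder = FALSE))
    m <- drop(rowsum(bl$m, gid, reorder = FALSE))
    Msr <- lay$Ms[rows, , drop = FALSE]
    Mtr <- lay$Mt[rows, , drop = FALSE]
    sub <- list(
      layout = list(T = length(rows), Ms = Msr, Mt = Mtr, Mtb = NULL),
      n_idx = bl$n_idx[first], m = m, Y = Ym,
      lfact = if (first_lfact) sum(bl$lfact) else 0,
      XS = bl$XS[, first, drop = FALSE],
      XT = bl$XT[, first, drop = FALSE],
      trials = if (nm == "b") bl$trials else NULL,
      YS = crossprod(Msr, Ym), YT = crossprod(Mtr, Ym),
      YTB = NULL, ycs = colSums(Ym), H = NULL)
    sub$lfact <- rep(sub$lfact / length(m), length(m))
    first_lfact <- FALSE
    out[[length(out) + 1L]] <- sub
  }
  out
}

#' Pack / unpack GMLM parameters to and from a numeric vector
#'
#' Column-major per block, in the order w, H_spk, T_tbar, V_tbar, T_stim,
#' U_stim, V_stim, then any dynamic-history factors; this is the layout of
#' optimizer and sampler state vectors.
#'
#' @param params a \code{gmlm_params}.
#' @return numeric vector.
#' @export
pack_params <- function(params) {
  blocks <- list(params$w, params$H_spk, params$T_tbar, params$V_tbar,
                 params$T_stim, params$U_stim, params$V_stim)
  if (!is.null(params$dyn)) blocks <- c(blocks, unname(params$dyn))
  unlist(lapply(blocks, as.numeric), use.names = FALSE)
}

#' @rdname pack_params
#' @param vec packed parameter vector.
#' @param model a \code{gmlm_model}.
#' @export
unpack_params <- function(vec, model) {
  p <- gmlm_params(model)
  take <- local({
    pos <- 0L
    function(x) {
      n <- length(x)
      out <- if (n > 0) vec[pos + seq_len(n)] else numeric(0)
      pos <<- pos + n
      if (is.matrix(x))
        matrix(out, nrow(x), ncol(x), dimnames = dimnames(x)) else out
    }
  })
  p$w <- take(p$w)
  if (!is.null(p$H_spk)) p$H_spk <- take(p$H_spk)
  if (!is.null(p$T_tbar)) {p$T_tbar <- take(p$T_tbar); p$V_tbar <- take(p$V_tbar)}
  p$T_stim <- take(p$T_stim); p$U_stim <- take(p$U_stim)
  p$V_stim <- take(p$V_stim)
  if (!is.null(p$dyn)) for (nm in names(p$dyn)) p$dyn[[nm]] <- take(p$dyn[[nm]])
  p
}

#' Population log likelihood and gradient on grouped data
#'
#' @param params a \code{gmlm_params}.
#' @param data a \code{gmlm_data} from \code{prepare_pop_data}.
#' @param model a \code{gmlm_model}.
#' @param want_grad also compute the gradient.
#' @return list(ll, grad) with grad a \code{gmlm_params}-shaped list (NULL
#'   when \code{want_grad = FALSE}).
#' @export
gmlm_ll_grad <- function(params, data, model, want_grad = TRUE) {
  dt <- data$bin_width
  R <- model$rank; Rl <- model$rank_tbar
  use_tb <- model$include_tbar && Rl > 0
  use_h <- model$include_history
  dyn <- params$dyn
  ll <- data$sum_y * log(dt)
  if (want_grad) {
    g <- gmlm_params(model)  # zeros
    gw <- numeric(model$N)
  }
  fast <- !use_h && is.null(dyn)
  for (bl in data$bylayout) {
    lay <- bl$layout
    Gn <- length(bl$m)
    Vt <- t(params$V_stim[bl$n_idx, , drop = FALSE])    # R x G
    if (R > 0) {
      As <- lay$Ms %*% params$T_stim                    # T x R
      At <- lay$Mt %*% params$T_stim
      CS <- crossprod(params$U_stim, bl$XS)             # R x G
      CT <- crossprod(params$U_stim, bl$XT)
      CSV <- CS * Vt; CTV <- CT * Vt
      BASE <- cbind(As, At) %*% rbind(CSV, CTV)
      BASE <- BASE + rep(params$w[bl$n_idx], each = lay$T)
    } else BASE <- matrix(rep(params$w[bl$n_idx], each = lay$T),
                          lay$T, Gn)
    if (use_tb && !is.null(lay$Mtb)) {
      Atb <- lay$Mtb %*% params$T_tbar                  # T x Rl
      VtbG <- t(params$V_tbar[bl$n_idx, , drop = FALSE])
      BASE <- BASE + Atb %*% VtbG
    }
    if (use_h) {
      HB <- vapply(seq_len(Gn), function(j)
        drop(bl$H[[j]] %*% params$H_spk[, bl$n_idx[j]]), numeric(lay$T))
      HB <- matrix(HB, lay$T, Gn)
      BASE <- BASE + HB
    }
    dyn_terms <- NULL
    if (!is.null(dyn)) {
      dyn_terms <- dyn_forward(dyn, bl, lay, model)
      BASE <- BASE + dyn_terms$add
    }
    EM <- exp(BASE) * rep(dt * bl$m, each = lay$T)      # expected counts
    if (fast) {
      # all Y-linear terms via the projected statistics
      lin <- sum(bl$ycs * params$w[bl$n_idx]) - sum(bl$lfact)
      if (R > 0)
        lin <- lin + sum(bl$YS * (params$T_stim %*% CSV)) +
          sum(bl$YT * (params$T_stim %*% CTV))
      if (use_tb && !is.null(lay$Mtb))
        lin <- lin + sum(bl$YTB * (params$T_tbar %*% VtbG))
      ll <- ll + lin - sum(EM)
    } else {
      ll <- ll + sum(bl$Y * BASE) - sum(EM) - sum(bl$lfact)
    }
    if (!want_grad) next
    if (fast) {
      cg <- bl$ycs - colSums(EM)
      acc <- rowsum(cg, bl$n_idx)
      gw[as.integer(rownames(acc))] <- gw[as.integer(rownames(acc))] + acc
      if (R > 0) {
        P1 <- crossprod(params$T_stim, bl$YS) - crossprod(As, EM)
        P2 <- crossprod(params$T_stim, bl$YT) - crossprod(At, EM)
        g$T_stim <- g$T_stim + (bl$YS %*% t(CSV) -
                                crossprod(lay$Ms, EM %*% t(CSV))) +
          (bl$YT %*% t(CTV) - crossprod(lay$Mt, EM %*% t(CTV)))
        g$U_stim <- g$U_stim + bl$XS %*% t(P1 * Vt) + bl$XT %*% t(P2 * Vt)
        dV <- rowsum(t(P1 * CS + P2 * CT), bl$n_idx)
        ridx <- as.integer(rownames(dV))
        g$V_stim[ridx, ] <- g$V_stim[ridx, , drop = FALSE] + dV
      }
      if (use_tb && !is.null(lay$Mtb)) {
        P3 <- crossprod(params$T_tbar, bl$YTB) - crossprod(Atb, EM)
        g$T_tbar <- g$T_tbar +
          (bl$YTB - crossprod(lay$Mtb, EM)) %*%
          params$V_tbar[bl$n_idx, , drop = FALSE]
        dVtb <- rowsum(t(P3), bl$n_idx)
        ridx <- as.integer(rownames(dVtb))
        g$V_tbar[ridx, ] <- g$V_tbar[ridx, , drop = FALSE] + dVtb
      }
      next
    }
    GM <- bl$Y - EM                                     # T x G
    cg <- colSums(GM)
    acc <- rowsum(cg, bl$n_idx)
    gw[as.integer(rownames(acc))] <- gw[as.integer(rownames(acc))] + acc
    if (R > 0) {
      P1 <- crossprod(As, GM)                           # R x G
      P2 <- crossprod(At, GM)
      g$T_stim <- g$T_stim + crossprod(lay$Ms, GM %*% t(CSV)) +
        crossprod(lay$Mt, GM %*% t(CTV))
      g$U_stim <- g$U_stim + bl$XS %*% t(P1 * Vt) + bl$XT %*% t(P2 * Vt)
      dV <- rowsum(t(P1 * CS + P2 * CT), bl$n_idx)      # by neuron
      ridx <- as.integer(rownames(dV))
      g$V_stim[ridx, ] <- g$V_stim[ridx, , drop = FALSE] + dV
    }
    if (use_tb && !is.null(lay$Mtb)) {
      P3 <- crossprod(Atb, GM)                          # Rl x G
      g$T_tbar <- g$T_tbar + crossprod(lay$Mtb, GM) %*%
        params$V_tbar[bl$n_idx, , drop = FALSE]
      dVtb <- rowsum(t(P3), bl$n_idx)
      ridx <- as.integer(rownames(dVtb))
      g$V_tbar[ridx, ] <- g$V_tbar[ridx, , drop = FALSE] + dVtb
    }
    if (use_h) {
      for (j in seq_len(Gn))
        g$H_spk[, bl$n_idx[j]] <- g$H_spk[, bl$n_idx[j]] +
          crossprod(bl$H[[j]], GM[, j])
    }
    if (!is.null(dyn))
      g$dyn <- dyn_backward(g$dyn, dyn, dyn_terms, GM, bl, lay, model)
  }
  if (want_grad) {
    g$w <- gw
    list(ll = ll, grad = g)
  } else list(ll = ll, grad = NULL)
}

# forward pass of the dynamic spike-history terms for one layout block
dyn_forward <- function(dyn, bl, lay, model) {
  Gn <- length(bl$m)
  add <- matrix(0, lay$T, Gn)
  st <- list()
  if (model$dyn_rank > 0) {
    AS <- lay$Ms %*% dyn$T_dspk; AT <- lay$Mt %*% dyn$T_dspk  # T x Rh
    FH <- lapply(seq_len(Gn), function(j) bl$H[[j]] %*% dyn$H_dspk) # T x Rh
    for (j in seq_len(Gn)) {
      gain <- sweep(AS, 2, dyn$U_dspk[1, ], "*") +
        sweep(AT, 2, dyn$U_dspk[2, ], "*")
      add[, j] <- add[, j] +
        drop((gain * FH[[j]]) %*% dyn$V_dspk[bl$n_idx[j], ])
    }
    st$AS <- AS; st$AT <- AT; st$FH <- FH
  }
  if (model$dyn_rank_tbar > 0 && !is.null(lay$Mtb)) {
    ATB <- lay$Mtb %*% dyn$T_bdspk                      # T x Rbh
    FHB <- lapply(seq_len(Gn), function(j) bl$H[[j]] %*% dyn$H_bdspk)
    for (j in seq_len(Gn))
      add[, j] <- add[, j] +
        drop((ATB * FHB[[j]]) %*% dyn$V_bdspk[bl$n_idx[j], ])
    st$ATB <- ATB; st$FHB <- FHB
  }
  c(list(add = add), st)
}

# accumulate gradients of the dynamic terms
dyn_backward <- function(gdyn, dyn, st, GM, bl, lay, model) {
  Gn <- length(bl$m)
  if (model$dyn_rank > 0) {
    for (j in seq_len(Gn)) {
      n <- bl$n_idx[j]; gv <- GM[, j]
      fh <- st$FH[[j]]
      for (r in seq_len(model$dyn_rank)) {
        as_r <- st$AS[, r]; at_r <- st$AT[, r]; fr <- fh[, r]
        gain <- dyn$U_dspk[1, r] * as_r + dyn$U_dspk[2, r] * at_r
        V <- dyn$V_dspk[n, r]
        gdyn$V_dspk[n, r] <- gdyn$V_dspk[n, r] + sum(gv * gain * fr)
        gdyn$U_dspk[1, r] <- gdyn$U_dspk[1, r] + V * sum(gv * as_r * fr)
        gdyn$U_dspk[2, r] <- gdyn$U_dspk[2, r] + V * sum(gv * at_r * fr)
        gdyn$T_dspk[, r] <- gdyn$T_dspk[, r] +
          V * (crossprod(lay$Ms, gv * dyn$U_dspk[1, r] * fr) +
               crossprod(lay$Mt, gv * dyn$U_dspk[2, r] * fr))
        gdyn$H_dspk[, r] <- gdyn$H_dspk[, r] +
          V * crossprod(bl$H[[j]], gv * gain)
      }
    }
  }
  if (model$dyn_rank_tbar > 0 && !is.null(st$ATB)) {
    for (j in seq_len(Gn)) {
      n <- bl$n_idx[j]; gv <- GM[, j]
      for (q in seq_len(model$dyn_rank_tbar)) {
        gtb <- st$ATB[, q]; fhb <- st$FHB[[j]][, q]
        V <- dyn$V_bdspk[n, q]
        gdyn$V_bdspk[n, q] <- gdyn$V_bdspk[n, q] + sum(gv * gtb * fhb)
        gdyn$T_bdspk[, q] <- gdyn$T_bdspk[, q] +
          V * crossprod(lay$Mtb, gv * fhb)
        gdyn$H_bdspk[, q] <- gdyn$H_bdspk[, q] +
          V * crossprod(bl$H[[j]], gv * gtb)
      }
    }
  }
  gdyn
}
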