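#' Deterministic grouping phase of the object analysis
#'
#' Runs the seed-independent part of the object stage: temporal-rate
#' filtering, the sliding-window temporal-coherence factorization, and the
#' greedy conjugate-Bayesian grouping under every (kappa, beta)
#' interpretation. The result can be reused across simulations that differ
#' only in their competition noise (see [object_select()]).
#'
#' @param C a [scale_representation()] (central output).
#' @param step object-stage time step (s).
#' @param rates modulation rates in Hz.
#' @param kappa source-mean prior pseudo-counts, in frames of the object
#'   step (the prior is worth `kappa` observations of the source mean).
#' @param betas source-variance prior scales (per whitened coordinate).
#' @param alpha source-variance prior shape (per whitened coordinate).
#' @param z_ab Beta-Bernoulli presence prior `(Z_alpha, Z_beta)`.
#' @param t_hist source history length in frames.
#' @param sigma_f continuity neighborhood (natural-log-Hz).
#' @param nugget diagonal regularization of the continuity correlation.
#' @param window_len coherence window length (s).
#' @param nmf_iter multiplicative-update iterations per window.
#' @return object of class `object_grouping` holding per-frame
#'   per-interpretation scores, groupings and component spectra.
#' @export
object_grouping <- function(C, step = 0.1, rates = c(2, 4, 8, 16),
                            kappa = c(15, 20), betas = c(0.25, 0.5, 0.8),
                            alpha = 1, z_ab = c(2, 2), t_hist = 30,
                            sigma_f = 5, nugget = 0.003,
                            window_len = 0.5, nmf_iter = 60) {
  stopifnot(inherits(C, "scale_representation"))
  dt <- C$frame_step
  n_f <- dim(C$values)[2]; n_s <- dim(C$values)[3]
  total_s <- dim(C$values)[1] * dt
  R <- rate_analysis(C, rates)

  interp_table <- expand.grid(kappa = kappa, beta = betas,
                              KEEP.OUT.ATTRS = FALSE)
  n_i <- nrow(interp_table)
  wh <- continuity_whitener(C$channel_freqs, n_scales = n_s,
                            sigma_f = sigma_f, nugget = nugget)
  # alpha and beta are per-coordinate hyper-parameters of the shared
  # variance; scale them into the joint d-dimensional prior so the prior
  # predictive keeps variance ~beta per whitened coordinate with d*alpha
  # tail degrees of freedom
  interps <- lapply(seq_len(n_i), function(i)
    interpretation(kappa = interp_table$kappa[i],
                   beta = interp_table$beta[i] * wh$d / 2,
                   alpha = alpha * wh$d / 2,
                   z_alpha = z_ab[1], z_beta = z_ab[2], t_hist = t_hist,
                   whitener = wh))

  times <- seq(window_len, total_s + 1e-9, by = step)
  times <- times[round(times / dt) <= dim(C$values)[1]]
  n_t <- length(times)
  scores <- matrix(NA_real_, n_t, n_i)
  frame_info <- vector("list", n_t)
  prev_K <- NULL
  for (ti in seq_len(n_t)) {
    cs <- coherence_factorize(R, window_end = times[ti],
                              window_len = window_len, r = 2,
                              n_iter = nmf_iter)
    if (max(cs$amplitude) < 1e-10) {
      # silent window: carry interpretation state and scores
      scores[ti, ] <- if (ti > 1) scores[ti - 1, ] else 0
      frame_info[[ti]] <- list(silent = TRUE)
      next
    }
    # align component order with the previous window by cosine similarity
    if (!is.null(prev_K)) {
      keep <- sum(diag(cs$K %*% t(prev_K)))
      swap <- sum(diag(cs$K[2:1, ] %*% t(prev_K)))
      if (swap > keep) {
        cs$K <- cs$K[2:1, , drop = FALSE]
        cs$W <- cs$W[, 2:1, drop = FALSE]
        cs$amplitude <- cs$amplitude[2:1]
      }
    }
    prev_K <- cs$K
    for (ii in seq_len(n_i)) {
      interps[[ii]] <- greedy_group(interps[[ii]], cs)
      scores[ti, ii] <- interps[[ii]]$last$score
    }
    frame_info[[ti]] <- list(silent = FALSE,
                             grouping = lapply(interps, function(x)
                               x$last$grouping),
                             structure = vapply(interps, function(x)
                               x$last$structure, ""),
                             spectra = cs$amplitude * cs$K)
  }
  structure(list(C = C, times = times, step = step, scores = scores,
                 frame_info = frame_info, interp_table = interp_table),
            class = "object_grouping")
}

#' Competition, interpretation selection and mask inversion
#'
#' The seeded phase of the object stage: normalizes the per-frame relative
#' log densities (the running maximum after the first second of output is
#' scaled to 1), applies the competition transform across interpretations,
#' selects the dominant interpretation per frame, and inverts the selected
#' sources' masks to time-frequency representations.
#'
#' @param grouping an [object_grouping()].
#' @param comp a [competition_params()] for the object stage.
#' @param noise_mat optional pre-drawn noise matrix for the competition
#'   substream.
#' @param norm_skip seconds of initial output excluded when fixing the
#'   log-density normalization constant.
#' @return object of class `source_masks`: `values` (`frames x frequency x
#'   source` non-negative array), `times`, `interp_idx` (dominant
#'   interpretation per frame), `interp_table`, `structure` (grouping label
#'   per frame), `scores` (raw per-interpretation log densities), `comp_y`
#'   (post-competition interpretation weights) and axis metadata.
#' @export
object_select <- function(grouping, comp = stage_competition("object"),
                          noise_mat = NULL, norm_skip = 1) {
  stopifnot(inherits(grouping, "object_grouping"))
  C <- grouping$C
  dt <- C$frame_step
  n_f <- dim(C$values)[2]; n_s <- dim(C$values)[3]
  times <- grouping$times
  n_t <- length(times)
  scores <- grouping$scores
  interp_table <- grouping$interp_table
  n_i <- nrow(interp_table)
  if (n_t == 0)
    return(structure(list(values = array(0, c(0, n_f, 2)),
                          times = numeric(0),
                          frame_step = grouping$step,
                          channel_freqs = C$channel_freqs,
                          interp_idx = integer(0),
                          interp_table = interp_table,
                          structure = character(0),
                          scores = scores),
                     class = "source_masks"))

  # relative log densities, normalized so the running maximum after the
  # first `norm_skip` seconds of output equals 1
  rel <- scores - apply(scores, 1, min)
  late <- times > (times[1] + norm_skip)
  peak <- if (any(late)) max(rel[late, ]) else max(rel)
  cnorm <- if (is.finite(peak) && peak > 0) 1 / peak else 1
  x_in <- cnorm * rel

  comp$labels <- cbind(interp_table$kappa, interp_table$beta)
  cres <- competition_run(x_in, comp, noise_mat = noise_mat)
  interp_idx <- max.col(cres$y, ties.method = "first")

  # invert masks of the dominant interpretation: conjugate (matched-filter)
  # back-projection of each masked scale slice, summed over scales
  spacing <- mean(diff(log2(C$channel_freqs)))
  inv_mats <- lapply(C$scales, function(om)
    Conj(t(conv_matrix(tuned_kernel(om, spacing), n_f))))
  O <- array(0, c(n_t, n_f, 2))
  structure_lab <- character(n_t)
  for (ti in seq_len(n_t)) {
    fi <- grouping$frame_info[[ti]]
    if (isTRUE(fi$silent)) {
      structure_lab[ti] <- if (ti > 1) structure_lab[ti - 1] else "single"
      if (ti > 1) interp_idx[ti] <- interp_idx[ti - 1]
      next
    }
    sel <- interp_idx[ti]
    g <- fi$grouping[[sel]]
    structure_lab[ti] <- fi$structure[sel]
    spectra <- fi$spectra
    # per-source amplitude spectra over (frequency x scale) columns
    g_cols <- matrix(0, 2, ncol(spectra))
    for (s in names(g))
      g_cols[as.integer(s), ] <- colSums(spectra[g[[s]], , drop = FALSE])
    # Wiener-style masks normalized against the whole scene (squared
    # shares over all components, assigned or not)
    unassigned <- setdiff(seq_len(nrow(spectra)), unlist(g))
    tot2 <- colSums(g_cols^2) +
      colSums(spectra[unassigned, , drop = FALSE]^2) +
      1e-24 * max(spectra, 1e-300)^2
    row_c <- round(times[ti] / dt)
    c_frame <- matrix(C$values[row_c, , ], n_f, n_s)
    full <- numeric(n_f)
    for (s in seq_len(n_s))
      full <- full + Re(inv_mats[[s]] %*% c_frame[, s])
    full <- pmax(full, 0)
    for (h in 1:2) {
      if (all(g_cols[h, ] == 0)) next
      m_h <- matrix(g_cols[h, ]^2 / tot2, n_f, n_s)
      acc <- numeric(n_f)
      for (s in seq_len(n_s))
        acc <- acc + Re(inv_mats[[s]] %*% (c_frame[, s] * m_h[, s]))
      O[ti, , h] <- pmax(acc, 0)
    }
    # the sources partition the scene: where rectification recovers more
    # than the full reconstruction, scale the shares back
    tot_h <- O[ti, , 1] + O[ti, , 2]
    over <- tot_h > full & tot_h > 0
    if (any(over)) {
      fac <- full[over] / tot_h[over]
      O[ti, over, 1] <- O[ti, over, 1] * fac
      O[ti, over, 2] <- O[ti, over, 2] * fac
    }
  }

  structure(list(values = O, times = times, frame_step = grouping$step,
                 channel_freqs = C$channel_freqs,
                 interp_idx = interp_idx, interp_table = interp_table,
                 structure = structure_lab, scores = scores,
                 comp_y = cres$y, norm_const = cnorm),
            class = "source_masks")
}

#' Object analysis
#'
#' The full object stage: temporal-rate filtering, sliding-window
#' temporal-coherence factorization, greedy conjugate-Bayesian grouping
#' under every (kappa, beta) interpretation, competition across
#' interpretations on their normalized relative log densities, selection of
#' the dominant interpretation per frame, and inversion of each selected
#' source's mask back to a time-frequency representation. Composes
#' [object_grouping()] (deterministic) and [object_select()] (seeded).
#'
#' @inheritParams object_grouping
#' @inheritParams object_select
#' @param comp a [competition_params()] for the object stage (its `dt` is
#'   the object step).
#' @return a `source_masks` object (see [object_select()]).
#' @export
object_analysis <- function(C, comp = stage_competition("object"),
                            rates = c(2, 4, 8, 16),
                            kappa = c(15, 20), betas = c(0.25, 0.5, 0.8),
                            alpha = 1, z_ab = c(2, 2), t_hist = 30,
                            sigma_f = 5, nugget = 0.003,
                            window_len = 0.5, nmf_iter = 60,
                            norm_skip = 1, noise_mat = NULL) {
  grp <- object_grouping(C, step = comp$dt, rates = rates, kappa = kappa,
                         betas = betas, alpha = alpha, z_ab = z_ab,
                         t_hist = t_hist, sigma_f = sigma_f,
                         nugget = nugget, window_len = window_len,
                         nmf_iter = nmf_iter)
  object_select(grp, comp, noise_mat = noise_mat, norm_skip = norm_skip)
}

#' @export
print.source_masks <- function(x, ...) {
  cat(sprintf("source_masks: %d frames x %d channels x %d sources; %d interpretations\n",
              dim(x$values)[1], dim(x$values)[2], dim(x$values)[3],
              nrow(x$interp_table)))
  invisible(x)
}
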