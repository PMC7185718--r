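#' Simulation options
#'
#' Collects the signal-path parameters shared by every model in an
#' ensemble. Defaults reproduce the standard configuration (24
#' channels/octave from 220 Hz, scales 0.5-4 cycles/octave, rates 2-16 Hz,
#' 20 ms frame step, 100 ms object step, 0.5 s coherence window); tests and
#' exploratory sweeps can shrink the channel count or stimulus.
#'
#' @param n_channels,f_low,per_octave,q cochlear filterbank layout.
#' @param scales spectral scales (cycles/octave).
#' @param rates temporal rates (Hz).
#' @param kappa,betas,alpha,z_ab,t_hist,sigma_f,nugget object-stage
#'   continuity priors (see [object_analysis()]).
#' @param window_len,nmf_iter coherence factorization controls.
#' @param c_n noise magnitude applied at active stages.
#' @param heuristic a [heuristic_params()].
#' @return list of class `model_opts`.
#' @export
model_opts <- function(n_channels = 96, f_low = 220, per_octave = 24, q = 8,
                       scales = c(0.5, 1, 2, 4), rates = c(2, 4, 8, 16),
                       kappa = c(15, 20), betas = c(0.25, 0.5, 0.8),
                       alpha = 1, z_ab = c(2, 2), t_hist = 30, sigma_f = 5,
                       nugget = 0.003, window_len = 0.5, nmf_iter = 60,
                       c_n = 0.2, heuristic = heuristic_params()) {
  structure(list(n_channels = n_channels, f_low = f_low,
                 per_octave = per_octave, q = q, scales = scales,
                 rates = rates, kappa = kappa, betas = betas,
                 alpha = alpha, z_ab = z_ab, t_hist = t_hist,
                 sigma_f = sigma_f, nugget = nugget,
                 window_len = window_len, nmf_iter = nmf_iter, c_n = c_n,
                 heuristic = heuristic),
            class = "model_opts")
}

# derive a 32-bit sub-seed for a stage/simulation from the master seed
sub_seed <- function(seed, k) {
  ((as.numeric(seed) %% 65011) * 33023 + k * 7919 + 17) %% 2147483647
}

stage_noise <- function(seed, k, n_t, n_u, c_n) {
  if (c_n <= 0) return(NULL)
  set.seed(sub_seed(seed, k))
  matrix(stats::rnorm(n_t * n_u), n_t, n_u)
}

#' Run one end-to-end streaming simulation
#'
#' Synthesizes the ABA stimulus, runs the three analysis stages with the
#' requested adaptation/inhibition magnitudes, and converts the object
#' output into a labeled percept track. Noise (magnitude `opts$c_n`) is
#' applied at a stage whenever that stage has non-zero adaptation or
#' inhibition, or when `noise_stages` names it explicitly.
#'
#' @param spec a [stimulus_spec()] (or an [audio_signal()] to skip
#'   synthesis).
#' @param stages named list with entries `peripheral`, `central`, `object`,
#'   each `c(c_a, c_b)`; missing entries default to `c(0, 0)`.
#' @param seed master seed; per-stage noise uses independent substreams.
#' @param opts a [model_opts()].
#' @param noise_stages character vector of stages receiving noise even
#'   with zero adaptation/inhibition; by default noise follows the active
#'   stages.
#' @param run_id recorded in the track.
#' @return list of class `streaming_sim` with `track`, `masks`,
#'   `peripheral`, `condition_st`, `seed`.
#' @export
simulate_streaming <- function(spec, stages = list(), seed = 1,
                               opts = model_opts(),
                               noise_stages = NULL, run_id = 1) {
  get_mag <- function(s) {
    m <- stages[[s]]
    if (is.null(m)) c(0, 0) else c(m[1], m[2])
  }
  active <- function(s) {
    any(get_mag(s) > 0) || s %in% noise_stages
  }
  if (inherits(spec, "stimulus_spec")) {
    signal <- generate_aba(spec)
    cond <- spec$semitone_sep
  } else {
    signal <- spec
    cond <- NA_real_
  }
  freqs <- default_channels(opts$n_channels, opts$f_low, opts$per_octave)
  n_frames <- floor(duration(signal) / 0.02)

  pm <- get_mag("peripheral")
  comp_p <- stage_competition("peripheral", c_a = pm[1], c_b = pm[2],
                              c_n = if (active("peripheral")) opts$c_n else 0)
  P <- peripheral_analysis(signal, comp_p, channel_freqs = freqs, q = opts$q,
                           noise_mat = stage_noise(seed, 1, n_frames,
                                                   length(freqs), comp_p$c_n))

  cm <- get_mag("central")
  comp_c <- stage_competition("central", c_a = cm[1], c_b = cm[2],
                              c_n = if (active("central")) opts$c_n else 0)
  C <- central_analysis(P, comp_c, scales = opts$scales,
                        noise_mat = stage_noise(seed, 2, nrow(P$values),
                                                length(opts$scales),
                                                comp_c$c_n))

  om <- get_mag("object")
  comp_o <- stage_competition("object", c_a = om[1], c_b = om[2],
                              c_n = if (active("object")) opts$c_n else 0)
  n_obj <- length(seq(opts$window_len, duration(signal) + 1e-9, by = comp_o$dt))
  n_interp <- length(opts$kappa) * length(opts$betas)
  masks <- object_analysis(C, comp_o, rates = opts$rates,
                           kappa = opts$kappa, betas = opts$betas,
                           alpha = opts$alpha, z_ab = opts$z_ab,
                           t_hist = opts$t_hist, sigma_f = opts$sigma_f,
                           nugget = opts$nugget,
                           window_len = opts$window_len,
                           nmf_iter = opts$nmf_iter,
                           noise_mat = stage_noise(seed, 3, n_obj, n_interp,
                                                   comp_o$c_n))
  track <- classify_percepts(masks, P, opts$heuristic,
                             run_id = run_id, condition_st = cond)
  structure(list(track = track, masks = masks, peripheral = P,
                 condition_st = cond, seed = seed),
            class = "streaming_sim")
}

#' @export
print.streaming_sim <- function(x, ...) {
  cat(sprintf("streaming_sim: condition %g st, %d percepts, p(segregated) = %.2f\n",
              x$condition_st, nrow(x$track),
              proportion_segregated(x$track, drop_first = FALSE)))
  invisible(x)
}

#' Run several simulations of one condition efficiently
#'
#' When adaptation, inhibition and noise are confined to the object stage
#' (as for the "Object" example model or the "None" model), the peripheral
#' and central analyses and the grouping phase of the object stage are
#' deterministic and shared across seeds; only the interpretation
#' competition and read-out are recomputed per seed.
#'
#' @param spec a [stimulus_spec()].
#' @param stages per-stage `c(c_a, c_b)` magnitudes (see
#'   [simulate_streaming()]).
#' @param seeds integer vector of master seeds, one simulation per seed.
#' @param opts a [model_opts()].
#' @return list of [percept_track()] objects, one per seed.
#' @export
run_condition <- function(spec, stages = list(), seeds = 1,
                          opts = model_opts()) {
  upstream_active <- any(unlist(stages[c("peripheral", "central")]) > 0)
  if (upstream_active) {
    return(lapply(seeds, function(s)
      simulate_streaming(spec, stages, seed = s, opts = opts,
                         run_id = paste0("seed", s))$track))
  }
  signal <- generate_aba(spec)
  freqs <- default_channels(opts$n_channels, opts$f_low, opts$per_octave)
  P <- peripheral_analysis(signal, stage_competition("peripheral", c_n = 0),
                           channel_freqs = freqs, q = opts$q)
  C <- central_analysis(P, stage_competition("central", c_n = 0),
                        scales = opts$scales)
  grp <- object_grouping(C, step = 0.1, rates = opts$rates,
                         kappa = opts$kappa, betas = opts$betas,
                         alpha = opts$alpha, z_ab = opts$z_ab,
                         t_hist = opts$t_hist, sigma_f = opts$sigma_f,
                         nugget = opts$nugget,
                         window_len = opts$window_len,
                         nmf_iter = opts$nmf_iter)
  om <- stages[["object"]]
  if (is.null(om)) om <- c(0, 0)
  c_n <- if (any(om > 0)) opts$c_n else 0
  lapply(seeds, function(s) {
    comp_o <- stage_competition("object", c_a = om[1], c_b = om[2],
                                c_n = c_n)
    nm <- stage_noise(s, 3, length(grp$times),
                      nrow(grp$interp_table), c_n)
    masks <- object_select(grp, comp_o, noise_mat = nm)
    classify_percepts(masks, P, opts$heuristic,
                      run_id = paste0("seed", s),
                      condition_st = spec$semitone_sep)
  })
}
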