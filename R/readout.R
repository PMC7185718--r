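#' Read-out heuristic parameters
#'
#' Parameters of the bandwidth-ratio heuristic converting source masks into
#' fused/segregated reports.
#'
#' @param theta_r bandwidth-ratio threshold.
#' @param theta_c global quantile defining the robust peak of a
#'   representation's amplitude distribution.
#' @param theta_b fraction of the global-quantile peak a channel's local
#'   quantile must exceed to count as active.
#' @param theta_f local (per-channel, per-window) quantile.
#' @param theta_w analysis window length (s).
#' @param theta_delta analysis step (s).
#' @param min_switch minimum percept duration (s); quicker reversions are
#'   discarded as spurious.
#' @param direction `"coherent"` labels a window segregated when the
#'   dominant mask is narrow relative to the input (ratio below `theta_r`);
#'   `"literal"` labels it segregated when the ratio exceeds `theta_r`.
#' @return object of class `heuristic_params`.
#' @export
heuristic_params <- function(theta_r = 0.75, theta_c = 0.996,
                             theta_b = 0.3, theta_f = 0.95, theta_w = 0.5,
                             theta_delta = 0.25, min_switch = 0.25,
                             direction = c("coherent", "literal")) {
  direction <- match.arg(direction)
  if (any(c(theta_c, theta_f) <= 0) || any(c(theta_c, theta_f) >= 1))
    stop("quantiles must lie in (0, 1)", call. = FALSE)
  if (theta_w <= 0 || theta_delta <= 0)
    stop("windows must be positive", call. = FALSE)
  structure(list(theta_r = theta_r, theta_c = theta_c, theta_b = theta_b,
                 theta_f = theta_f,
                 theta_w = theta_w, theta_delta = theta_delta,
                 min_switch = min_switch, direction = direction),
            class = "heuristic_params")
}

# bandwidth (max log2-frequency distance between active channels) of a
# `time x frequency` window given an absolute activity threshold
window_bandwidth <- function(win, channel_freqs, theta_f, threshold) {
  if (nrow(win) == 0) return(0)
  qs <- apply(win, 2, stats::quantile, probs = theta_f, names = FALSE)
  active <- which(qs > threshold)
  if (length(active) < 2) return(0)
  diff(range(log2(channel_freqs[active])))
}

#' Bandwidth ratio of a mask window
#'
#' A channel of a representation is active over a window when its
#' `theta_f` quantile within the window exceeds the `theta_c` quantile of
#' that representation's full (whole-run) distribution; the bandwidth is
#' the maximum log-frequency distance between active channels. Mask and
#' reference are each thresholded against their own global quantile (their
#' amplitude scales differ), and the ratio compares the two bandwidths over
#' the same window.
#'
#' @param mask_window `time x frequency` matrix (dominant source mask).
#' @param ref_window `time x frequency` matrix (reference representation,
#'   same channels; may be sampled at a different frame rate).
#' @param channel_freqs channel frequencies (Hz).
#' @param params a [heuristic_params()].
#' @param mask_threshold,ref_threshold the `theta_c` global quantiles of
#'   the full mask and reference representations (precomputed by the
#'   caller).
#' @return the bandwidth ratio (0 when the mask has no active channels; 1
#'   when the reference itself has zero bandwidth but the mask is active).
#' @export
bandwidth_ratio <- function(mask_window, ref_window, channel_freqs, params,
                            mask_threshold, ref_threshold = mask_threshold) {
  bw_mask <- window_bandwidth(mask_window, channel_freqs, params$theta_f,
                              mask_threshold)
  if (bw_mask == 0) return(0)
  bw_ref <- window_bandwidth(ref_window, channel_freqs, params$theta_f,
                             ref_threshold)
  if (bw_ref == 0) return(1)
  bw_mask / bw_ref
}

#' A labeled percept track
#'
#' @param start_s,end_s interval boundaries (s).
#' @param label `"fused"` or `"segregated"` per interval.
#' @param run_id simulation run identifier.
#' @param condition_st stimulus condition (semitones).
#' @return a `percept_track` data frame with columns `run_id`,
#'   `condition_st`, `start_s`, `end_s`, `label`.
#' @export
percept_track <- function(start_s, end_s, label, run_id = 1,
                          condition_st = NA_real_) {
  stopifnot(length(start_s) == length(end_s),
            length(label) == length(start_s))
  if (length(start_s) > 0) {
    if (any(end_s <= start_s)) stop("empty intervals", call. = FALSE)
    if (any(abs(start_s[-1] - end_s[-length(end_s)]) > 1e-9))
      stop("intervals must be contiguous", call. = FALSE)
  }
  n <- length(start_s)
  structure(data.frame(run_id = rep(run_id, length.out = n),
                       condition_st = rep(condition_st, length.out = n),
                       start_s = start_s, end_s = end_s,
                       label = as.character(label),
                       stringsAsFactors = FALSE),
            class = c("percept_track", "data.frame"))
}

# merge consecutive intervals sharing a label
merge_track <- function(track) {
  if (nrow(track) <= 1) return(track)
  keep <- c(TRUE, track$label[-1] != track$label[-nrow(track)])
  grp <- cumsum(keep)
  starts <- tapply(track$start_s, grp, min)
  ends <- tapply(track$end_s, grp, max)
  labels <- track$label[keep]
  percept_track(as.numeric(starts), as.numeric(ends), labels,
                run_id = track$run_id[1], condition_st = track$condition_st[1])
}

#' Remove spurious switches from a percept track
#'
#' Any interval shorter than `min_switch` whose neighbors share a label (a
#' response that reverts to the original) is absorbed; merging repeats
#' until stable, so cleaning is idempotent.
#'
#' @param track a [percept_track()].
#' @param min_switch minimum interval duration (s).
#' @return a cleaned `percept_track`.
#' @export
clean_track <- function(track, min_switch = 0.25) {
  track <- merge_track(track)
  repeat {
    if (nrow(track) < 3) return(track)
    dur <- track$end_s - track$start_s
    inner <- 2:(nrow(track) - 1)
    bad <- inner[dur[inner] < min_switch &
                 track$label[inner - 1] == track$label[inner + 1]]
    if (length(bad) == 0) return(track)
    track <- merge_track(percept_track(
      track$start_s[-bad[1]],
      replace(track$end_s, bad[1] - 1, track$end_s[bad[1]])[-bad[1]],
      track$label[-bad[1]],
      run_id = track$run_id[1], condition_st = track$condition_st[1]))
  }
}

#' Classify source masks into a percept track
#'
#' Slides a window of length `theta_w` at step `theta_delta` over the run;
#' in each window the dominant (maximum-amplitude) source mask's bandwidth
#' ratio against the reference representation decides the label, which is
#' then merged and cleaned of spurious reversions.
#'
#' @param masks a `source_masks` object from [object_analysis()].
#' @param reference an [auditory_spectrogram()] (the peripheral output).
#' @param params a [heuristic_params()].
#' @param run_id,condition_st identifiers recorded in the track.
#' @return a [percept_track()].
#' @export
classify_percepts <- function(masks, reference,
                              params = heuristic_params(),
                              run_id = 1, condition_st = NA_real_) {
  if (length(masks$times) == 0)
    return(percept_track(numeric(0), numeric(0), character(0),
                         run_id, condition_st))
  ref_vals <- reference$values
  ref_thr <- params$theta_b * stats::quantile(ref_vals, probs = params$theta_c,
                                              names = FALSE)
  mask_thr <- params$theta_b * stats::quantile(masks$values,
                                               probs = params$theta_c,
                                               names = FALSE)
  t0 <- masks$times[1]
  t_end <- masks$times[length(masks$times)]
  steps <- seq(t0 + params$theta_w, t_end + 1e-9, by = params$theta_delta)
  if (length(steps) == 0) steps <- t_end
  labels <- character(length(steps))
  ref_times <- seq_len(nrow(ref_vals)) * reference$frame_step
  for (k in seq_along(steps)) {
    tw <- c(steps[k] - params$theta_w, steps[k])
    mi <- which(masks$times > tw[1] - 1e-9 & masks$times <= tw[2] + 1e-9)
    ri <- which(ref_times > tw[1] - 1e-9 & ref_times <= tw[2] + 1e-9)
    amp <- apply(masks$values[mi, , , drop = FALSE], 3, sum)
    dom <- which.max(amp)
    ratio <- bandwidth_ratio(
      matrix(masks$values[mi, , dom], length(mi)),
      ref_vals[ri, , drop = FALSE],
      masks$channel_freqs, params, mask_thr, ref_thr)
    seg <- if (params$direction == "coherent") ratio < params$theta_r
           else ratio > params$theta_r
    labels[k] <- if (seg) "segregated" else "fused"
  }
  bounds <- c(t0, steps)
  track <- percept_track(bounds[-length(bounds)], bounds[-1], labels,
                         run_id, condition_st)
  clean_track(track, params$min_switch)
}
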