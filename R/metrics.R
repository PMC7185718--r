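#' Proportion of segregated response time in a track
#'
#' Time-weighted fraction of a percept track labeled `"segregated"`. For
#' steady-state scoring the first response is removed (the early part of a
#' run is biased toward fused reports while streaming builds up).
#'
#' @param track a [percept_track()].
#' @param drop_first drop the first interval before weighting.
#' @return proportion in `[0, 1]` (`NA` when no time remains).
#' @export
proportion_segregated <- function(track, drop_first = TRUE) {
  if (nrow(track) == 0) return(NA_real_)
  # a run with a single sustained response keeps it: there is no post-
  # buildup response to fall back on
  if (drop_first && nrow(track) > 1) track <- track[-1, ]
  dur <- track$end_s - track$start_s
  sum(dur[track$label == "segregated"]) / sum(dur)
}

#' Percept lengths of a track
#'
#' Durations of the reported percepts with the first response removed and
#' responses shorter than `min_len` dropped as spurious.
#'
#' @param track a [percept_track()].
#' @param min_len minimum duration retained (s).
#' @param drop_first remove the first response.
#' @return numeric vector of durations (s).
#' @export
percept_lengths <- function(track, min_len = 0.25, drop_first = TRUE) {
  if (nrow(track) == 0) return(numeric(0))
  if (drop_first) track <- track[-1, , drop = FALSE]
  dur <- track$end_s - track$start_s
  dur[dur >= min_len]
}

#' Z-score durations in log space
#'
#' @param durations positive durations (s) of one individual (model run or
#'   listener).
#' @return z-scores of `log(durations)`; `NULL` (with a warning) when fewer
#'   than two durations are available.
#' @export
z_log_lengths <- function(durations) {
  if (length(durations) < 2) {
    warning("fewer than 2 durations; individual excluded from z-scoring")
    return(NULL)
  }
  if (any(durations <= 0)) stop("durations must be positive", call. = FALSE)
  l <- log(durations)
  s <- stats::sd(l)
  if (s == 0) return(rep(0, length(l)))
  (l - mean(l)) / s
}

#' Response deviation
#'
#' Root-mean-squared difference between each run's per-condition proportion
#' of segregated responses and the reference mean proportions, averaged
#' over runs.
#'
#' @param model_props matrix or data frame of proportions, one row per run,
#'   columns named by condition (e.g. `"3"`, `"6"`, `"12"`).
#' @param reference_mean named vector of reference mean proportions for the
#'   same conditions.
#' @return mean over runs of the per-run RMS difference.
#' @export
response_deviation <- function(model_props, reference_mean) {
  model_props <- as.matrix(model_props)
  conds <- names(reference_mean)
  missing_c <- setdiff(conds, colnames(model_props))
  if (length(missing_c) > 0)
    stop("missing condition(s): ", paste(missing_c, collapse = ", "),
         call. = FALSE)
  per_run <- apply(model_props[, conds, drop = FALSE], 1, function(p)
    sqrt(mean((p - reference_mean)^2)))
  mean(per_run)
}

#' Response-length deviation (two-sample KS statistic)
#'
#' Maximum absolute difference between the empirical CDFs of the pooled
#' z-scored log percept lengths of model and reference.
#'
#' @param model_z,reference_z pooled z-scored log lengths.
#' @return the KS statistic in `[0, 1]`.
#' @export
length_deviation <- function(model_z, reference_z) {
  if (length(model_z) == 0 || length(reference_z) == 0)
    stop("empty sample", call. = FALSE)
  unname(suppressWarnings(
    stats::ks.test(model_z, reference_z)$statistic))
}

#' Model:reference deviation ratio
#'
#' Places the two deviation measures on a common scale by dividing each by
#' the mean deviation of individual reference listeners from their group,
#' then averages the two ratios. A value of 1 means the model deviates from
#' the reference mean as much as the average individual listener does.
#'
#' @param model_response_dev,model_length_dev the model's deviations.
#' @param ref_response_devs,ref_length_devs per-individual reference
#'   deviations (computed with the same formulas against the group).
#' @return the averaged ratio.
#' @export
deviation_ratio <- function(model_response_dev, model_length_dev,
                            ref_response_devs, ref_length_devs) {
  mr <- mean(ref_response_devs)
  ml <- mean(ref_length_devs)
  if (mr <= 0 || ml <= 0)
    stop("degenerate reference population: zero mean deviation",
         call. = FALSE)
  mean(c(model_response_dev / mr, model_length_dev / ml))
}

#' Buildup curve
#'
#' Per time bin, the mean proportion of run time labeled segregated across
#' a collection of runs (the first response is not removed here: buildup is
#' precisely about the early responses).
#'
#' @param tracks list of [percept_track()] objects sharing a condition.
#' @param bin bin width (s).
#' @param t_max end of the analysis (s); defaults to the shortest track.
#' @return data frame with `time` (bin centers) and `p_segregated`.
#' @export
buildup_curve <- function(tracks, bin = 0.5, t_max = NULL) {
  if (length(tracks) == 0)
    return(data.frame(time = numeric(0), p_segregated = numeric(0)))
  ends <- vapply(tracks, function(tr) max(tr$end_s, 0), 1.0)
  starts <- vapply(tracks, function(tr) min(tr$start_s, Inf), 1.0)
  if (is.null(t_max)) t_max <- min(ends)
  edges <- seq(min(starts), t_max, by = bin)
  if (length(edges) < 2)
    return(data.frame(time = numeric(0), p_segregated = numeric(0)))
  centers <- edges[-1] - bin / 2
  p <- vapply(seq_along(centers), function(k) {
    lo <- edges[k]; hi <- edges[k + 1]
    per_run <- vapply(tracks, function(tr) {
      ov <- pmin(tr$end_s, hi) - pmax(tr$start_s, lo)
      ov <- pmax(ov, 0)
      if (sum(ov) == 0) return(NA_real_)
      sum(ov[tr$label == "segregated"]) / sum(ov)
    }, 1.0)
    mean(per_run, na.rm = TRUE)
  }, 1.0)
  data.frame(time = centers, p_segregated = p)
}

#' Percentile bootstrap confidence interval
#'
#' Non-parametric bootstrap (resampling with replacement) of an arbitrary
#' statistic.
#'
#' @param sample numeric vector.
#' @param statistic function of a numeric vector.
#' @param n_boot number of bootstrap resamples.
#' @param seed RNG seed.
#' @param conf confidence level.
#' @return numeric vector `c(low, high)`.
#' @export
bootstrap_ci <- function(sample, statistic = mean, n_boot = 10000,
                         seed = NULL, conf = 0.95) {
  if (length(sample) == 0) stop("empty sample", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  bt <- boot::boot(sample, function(x, i) statistic(x[i]), R = n_boot)
  a <- (1 - conf) / 2
  unname(stats::quantile(bt$t[, 1], probs = c(a, 1 - a)))
}

#' Log-space kernel density estimate
#'
#' Gaussian-kernel density of `log(sample)` with the Silverman
#' rule-of-thumb bandwidth, mapped back to the positive axis with the
#' Jacobian `1/x`.
#'
#' @param sample positive values (e.g. percept durations).
#' @param n number of evaluation points.
#' @return data frame with `x` and `density` (integrates to ~1 over x > 0).
#' @export
log_density <- function(sample, n = 512) {
  if (any(sample <= 0)) stop("sample must be positive", call. = FALSE)
  l <- log(sample)
  bw <- if (length(sample) > 1) stats::bw.nrd0(l) else 0.3
  d <- stats::density(l, bw = bw, n = n, kernel = "gaussian")
  data.frame(x = exp(d$x), density = d$y / exp(d$x))
}
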