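#' Generate a synthetic reference-listener population
#'
#' Stands in for a human continuous-report cohort: each listener draws
#' per-condition segregation proportions (logit-normal around the condition
#' means) and a sample of percept durations from a listener-specific
#' log-normal. The defaults emulate the qualitative pattern of streaming
#' reports (mostly fused at 3 st, bistable at 6 st, mostly segregated at
#' 12 st) and are explicitly synthetic, not measured values.
#'
#' @param n_listeners number of listeners.
#' @param condition_means mean segregation proportions named by condition
#'   in semitones.
#' @param between_listener_sd between-listener SD on the logit scale (0
#'   makes every listener identical to the means).
#' @param lognorm_mu_range range of listener log-mean percept duration
#'   (log-seconds).
#' @param lognorm_sigma_range range of listener log-SD.
#' @param samples_per_listener percept durations drawn per listener.
#' @param seed RNG seed.
#' @return object of class `reference_population`: `proportions` (listener
#'   x condition data frame), `durations` (list of per-listener duration
#'   vectors), and the generating parameters.
#' @export
generate_reference <- function(n_listeners = 35,
                               condition_means = c(`3` = 0.15, `6` = 0.5,
                                                   `12` = 0.85),
                               between_listener_sd = 0.6,
                               lognorm_mu_range = log(c(2, 6)),
                               lognorm_sigma_range = c(0.4, 0.8),
                               samples_per_listener = 200,
                               seed = 1) {
  if (any(condition_means < 0 | condition_means > 1))
    stop("condition means must lie in [0, 1]", call. = FALSE)
  if (n_listeners < 2) stop("need at least 2 listeners", call. = FALSE)
  if (diff(lognorm_mu_range) < 0 || diff(lognorm_sigma_range) < 0)
    stop("invalid parameter ranges", call. = FALSE)
  set.seed(seed)
  n_c <- length(condition_means)
  props <- matrix(0, n_listeners, n_c,
                  dimnames = list(NULL, names(condition_means)))
  durations <- vector("list", n_listeners)
  for (l in seq_len(n_listeners)) {
    dev <- stats::rnorm(n_c, 0, between_listener_sd)
    props[l, ] <- stats::plogis(stats::qlogis(
      pmin(pmax(condition_means, 1e-6), 1 - 1e-6)) + dev)
    if (between_listener_sd == 0) props[l, ] <- condition_means
    mu <- stats::runif(1, lognorm_mu_range[1], lognorm_mu_range[2])
    sg <- stats::runif(1, lognorm_sigma_range[1], lognorm_sigma_range[2])
    durations[[l]] <- stats::rlnorm(samples_per_listener, mu, sg)
  }
  structure(list(proportions = as.data.frame(props), durations = durations,
                 condition_means = condition_means, seed = seed),
            class = "reference_population")
}

#' Summarize a reference population for model scoring
#'
#' Computes the group-level quantities the deviation metrics need: mean
#' proportions per condition, the pooled z-scored log durations, and each
#' individual's own response and length deviations from the group (the
#' denominators of the model:reference deviation ratio).
#'
#' @param pop a [generate_reference()] population.
#' @return list with `mean_props`, `pooled_z`, `ind_response_dev`,
#'   `ind_length_dev`.
#' @export
reference_summary <- function(pop) {
  props <- as.matrix(pop$proportions)
  mean_props <- colMeans(props)
  z_list <- lapply(pop$durations, z_log_lengths)
  pooled_z <- unlist(z_list[!vapply(z_list, is.null, TRUE)])
  ind_response <- apply(props, 1, function(p)
    sqrt(mean((p - mean_props)^2)))
  ind_length <- vapply(seq_along(z_list), function(l) {
    if (is.null(z_list[[l]])) return(NA_real_)
    length_deviation(z_list[[l]], pooled_z)
  }, 1.0)
  list(mean_props = mean_props, pooled_z = pooled_z,
       ind_response_dev = ind_response,
       ind_length_dev = ind_length[!is.na(ind_length)])
}

#' Write percept tracks to CSV
#'
#' Shared schema for model and reference responses:
#' `run_id, condition_st, start_s, end_s, label`.
#'
#' @param tracks a [percept_track()] or list of them.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_percept_csv <- function(tracks, path) {
  if (inherits(tracks, "percept_track")) tracks <- list(tracks)
  all <- do.call(rbind, lapply(tracks, as.data.frame))
  utils::write.csv(all, path, row.names = FALSE)
  invisible(path)
}

#' Load continuous-report response intervals from CSV
#'
#' Reads percept tracks in the shared schema and applies the
#' steady-state/report-cleaning conventions of continuous-report streaming
#' experiments: per run, the condition summary is the time-weighted
#' proportion of segregated report within the 4-6 s window, and length
#' samples drop the first response and responses shorter than 0.25 s.
#'
#' @param path CSV path.
#' @param window summary window (s).
#' @return list with `tracks` (list of [percept_track()]), `summary` (data
#'   frame: `run_id`, `condition_st`, `p_segregated`) and `lengths` (list
#'   of per-run duration vectors).
#' @export
load_responses <- function(path, window = c(4, 6)) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("run_id", "condition_st", "start_s", "end_s", "label")
  if (!all(needed %in% names(raw)))
    stop("CSV must contain columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  bad <- which(!is.finite(raw$start_s) | !is.finite(raw$end_s) |
               raw$end_s <= raw$start_s |
               !(raw$label %in% c("fused", "segregated")))
  if (length(bad) > 0)
    stop("malformed response rows (data lines ", paste(bad, collapse = ", "),
         ")", call. = FALSE)
  runs <- split(raw, raw$run_id)
  tracks <- lapply(runs, function(df) {
    df <- df[order(df$start_s), ]
    percept_track(df$start_s, df$end_s, df$label,
                  run_id = df$run_id[1], condition_st = df$condition_st[1])
  })
  summary <- do.call(rbind, lapply(tracks, function(tr) {
    ov <- pmax(pmin(tr$end_s, window[2]) - pmax(tr$start_s, window[1]), 0)
    p <- if (sum(ov) > 0)
      sum(ov[tr$label == "segregated"]) / sum(ov) else NA_real_
    data.frame(run_id = tr$run_id[1], condition_st = tr$condition_st[1],
               p_segregated = p)
  }))
  rownames(summary) <- NULL
  lengths <- lapply(tracks, percept_lengths)
  list(tracks = tracks, summary = summary, lengths = lengths)
}
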