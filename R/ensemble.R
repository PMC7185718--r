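#' Ensemble grid of adaptation/inhibition magnitudes
#'
#' Within-stage mode varies adaptation and inhibition at one stage at a
#' time (zeros elsewhere), giving `3 * length(levels)^2` models; across-
#' stage mode varies both magnitudes at all three stages simultaneously,
#' giving `length(levels)^6` models.
#'
#' @param mode `"within"` or `"across"`.
#' @param levels magnitudes swept for both adaptation and inhibition;
#'   defaults are the standard 10-level (within) or 5-level (across) grids.
#' @param sims_per_model simulations per model and condition.
#' @param conditions stimulus conditions in semitones.
#' @param early_stop_sims number of 6 st simulations evaluated before the
#'   early-termination rule (across mode only).
#' @return list of class `ensemble_grid`.
#' @export
ensemble_grid <- function(mode = c("within", "across"), levels = NULL,
                          sims_per_model = 20, conditions = c(3, 6, 12),
                          early_stop_sims = 10) {
  mode <- match.arg(mode)
  if (is.null(levels))
    levels <- if (mode == "within")
      c(0, 5, 15, 44, 130, 390, 1100, 3400, 10000, 1e5)
    else c(0, 5, 63, 790, 1e5)
  structure(list(mode = mode, levels = levels,
                 sims_per_model = sims_per_model, conditions = conditions,
                 early_stop_sims = early_stop_sims),
            class = "ensemble_grid")
}

#' Enumerate model configurations of a grid
#'
#' @param grid an [ensemble_grid()].
#' @return data frame with one row per model: `model_id`, `stage` (within
#'   mode), and the six magnitudes `peripheral_ca`, `peripheral_cb`,
#'   `central_ca`, `central_cb`, `object_ca`, `object_cb`. Deterministic
#'   ordering.
#' @export
enumerate_models <- function(grid) {
  stages <- c("peripheral", "central", "object")
  cols <- as.vector(outer(c("ca", "cb"), stages,
                          function(a, s) paste(s, a, sep = "_")))
  cols <- c("peripheral_ca", "peripheral_cb", "central_ca", "central_cb",
            "object_ca", "object_cb")
  if (grid$mode == "within") {
    cells <- expand.grid(cb = grid$levels, ca = grid$levels,
                         stage = stages, KEEP.OUT.ATTRS = FALSE,
                         stringsAsFactors = FALSE)
    out <- data.frame(matrix(0, nrow(cells), 6, dimnames = list(NULL, cols)))
    for (s in stages) {
      sel <- cells$stage == s
      out[sel, paste0(s, "_ca")] <- cells$ca[sel]
      out[sel, paste0(s, "_cb")] <- cells$cb[sel]
    }
    out <- cbind(model_id = seq_len(nrow(out)), stage = cells$stage, out)
  } else {
    combos <- do.call(expand.grid, c(stats::setNames(
      rep(list(grid$levels), 6), rev(cols)),
      list(KEEP.OUT.ATTRS = FALSE)))
    combos <- combos[, cols]
    out <- cbind(model_id = seq_len(nrow(combos)), stage = "all", combos)
  }
  rownames(out) <- NULL
  out
}

model_stages <- function(config) {
  list(peripheral = c(config$peripheral_ca, config$peripheral_cb),
       central = c(config$central_ca, config$central_cb),
       object = c(config$object_ca, config$object_cb))
}

score_sims <- function(props, lengths, ref, conditions) {
  have <- colnames(props)[colSums(!is.na(props)) > 0]
  rd <- response_deviation(props[, have, drop = FALSE],
                           ref$mean_props[have])
  model_z <- unlist(lapply(lengths, function(d)
    if (length(d) >= 2) z_log_lengths(d) else NULL))
  ld <- if (length(model_z) > 0)
    length_deviation(model_z, ref$pooled_z) else 1
  ratio <- deviation_ratio(rd, ld, ref$ind_response_dev, ref$ind_length_dev)
  list(response_dev = rd, length_dev = ld, ratio = ratio)
}

#' Run one model of an ensemble
#'
#' Runs `sims_per_model` simulations per condition, 6 st first. In across
#' mode, after `early_stop_sims` 6 st simulations a provisional
#' model:reference deviation ratio is computed (from the conditions
#' available so far) and the model is terminated when it exceeds one.
#'
#' @param config one row of [enumerate_models()].
#' @param grid the [ensemble_grid()].
#' @param reference a [reference_summary()].
#' @param spec base [stimulus_spec()]; its `semitone_sep` is overridden per
#'   condition.
#' @param opts a [model_opts()].
#' @param seed master seed; per-simulation seeds are derived
#'   deterministically from `(seed, model_id, sim)`.
#' @return list: `config`, per-condition segregation proportions (`props`),
#'   `scores` (response/length deviation and ratio), `terminated`, and the
#'   simulated `tracks`.
#' @export
run_model <- function(config, grid, reference, spec = stimulus_spec(),
                      opts = model_opts(), seed = 1) {
  stages <- model_stages(config)
  conds <- unique(c(6, grid$conditions))
  conds <- conds[conds %in% grid$conditions]
  props <- matrix(NA_real_, grid$sims_per_model, length(grid$conditions),
                  dimnames = list(NULL, as.character(grid$conditions)))
  lengths <- list()
  tracks <- list()
  terminated <- FALSE
  for (cond in conds) {
    col <- as.character(cond)
    cspec <- spec
    cspec$semitone_sep <- cond
    for (sim in seq_len(grid$sims_per_model)) {
      sim_seed <- sub_seed(seed, config$model_id * 1013 + sim)
      res <- tryCatch(
        simulate_streaming(cspec, stages, seed = sim_seed, opts = opts,
                           run_id = sprintf("m%d_c%s_s%d", config$model_id,
                                            col, sim)),
        error = function(e) e)
      if (inherits(res, "error"))
        return(list(config = config, props = props, scores = NULL,
                    terminated = FALSE, failed = TRUE,
                    message = conditionMessage(res), tracks = tracks))
      props[sim, col] <- proportion_segregated(res$track)
      lengths <- c(lengths, list(percept_lengths(res$track)))
      tracks <- c(tracks, list(res$track))
      if (grid$mode == "across" && cond == 6 &&
          sim == grid$early_stop_sims) {
        partial <- score_sims(props[seq_len(sim), , drop = FALSE],
                              lengths, reference, grid$conditions)
        if (partial$ratio > 1) {
          terminated <- TRUE
          break
        }
      }
    }
    if (terminated) break
  }
  scores <- score_sims(props, lengths, reference, grid$conditions)
  list(config = config, props = props, scores = scores,
       terminated = terminated, failed = FALSE, tracks = tracks)
}

#' Run an ensemble of models
#'
#' @param grid an [ensemble_grid()].
#' @param reference a [reference_summary()].
#' @param models optional subset of [enumerate_models()] rows to run.
#' @param ... passed to [run_model()].
#' @return data frame of class `ensemble_result`: one row per model with
#'   magnitudes, deviations, ratio and termination status.
#' @export
run_ensemble <- function(grid, reference, models = NULL, ...) {
  if (is.null(models)) models <- enumerate_models(grid)
  rows <- lapply(seq_len(nrow(models)), function(i) {
    res <- run_model(models[i, ], grid, reference, ...)
    data.frame(models[i, ],
               response_dev = if (res$failed) NA else res$scores$response_dev,
               length_dev = if (res$failed) NA else res$scores$length_dev,
               ratio = if (res$failed) NA else res$scores$ratio,
               terminated = res$terminated, failed = res$failed)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("ensemble_result", "data.frame")
  out
}

#' Aggregate ensemble results per adaptation/inhibition cell
#'
#' Within mode: the mean ratio per `(stage, c_a, c_b)` cell (one model per
#' cell). Across mode: per stage and `(c_a, c_b)` cell, the minimum ratio
#' over all models sharing that marginal cell.
#'
#' @param results an `ensemble_result` from [run_ensemble()].
#' @param mode grid mode the results came from.
#' @return data frame with `stage`, `c_a`, `c_b`, `ratio`, `n_models`.
#' @export
aggregate_ensemble <- function(results, mode = c("within", "across")) {
  mode <- match.arg(mode)
  stages <- c("peripheral", "central", "object")
  if (mode == "within") {
    out <- do.call(rbind, lapply(stages, function(s) {
      sel <- results$stage == s
      if (!any(sel)) return(NULL)
      data.frame(stage = s,
                 c_a = results[sel, paste0(s, "_ca")],
                 c_b = results[sel, paste0(s, "_cb")],
                 ratio = results$ratio[sel], n_models = 1L)
    }))
  } else {
    out <- do.call(rbind, lapply(stages, function(s) {
      ca <- results[[paste0(s, "_ca")]]
      cb <- results[[paste0(s, "_cb")]]
      agg <- stats::aggregate(results$ratio,
                              by = list(c_a = ca, c_b = cb),
                              FUN = function(x) min(x, na.rm = TRUE))
      cnt <- stats::aggregate(results$ratio,
                              by = list(c_a = ca, c_b = cb), FUN = length)
      data.frame(stage = s, c_a = agg$c_a, c_b = agg$c_b, ratio = agg$x,
                 n_models = cnt$x)
    }))
  }
  rownames(out) <- NULL
  out
}

#' Select the best-fitting fraction of an ensemble
#'
#' @param results an `ensemble_result`.
#' @param top fraction retained (e.g. 0.25 keeps models at or below the
#'   25th percentile of the deviation ratio).
#' @return the retained rows.
#' @export
top_models <- function(results, top = 0.25) {
  thr <- stats::quantile(results$ratio, probs = top, na.rm = TRUE,
                         names = FALSE)
  results[!is.na(results$ratio) & results$ratio <= thr, , drop = FALSE]
}
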