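#' Seed function of the spectral-scale wavelet
#'
#' Direct evaluation of the scale seed
#' `H_omega(f) = omega * (1 - (omega f)^2) * exp(-(omega f)^2 / 2)`, the
#' negated second derivative of a Gaussian. `f` is position along the
#' log-frequency axis in octaves. Note `H_omega(0) = omega`.
#'
#' @param f position along the log-frequency axis (octaves).
#' @param omega scale parameter.
#' @return seed values.
#' @export
scale_seed <- function(f, omega) {
  u <- omega * f
  omega * (1 - u^2) * exp(-u^2 / 2)
}

# spectral peak (cycles/unit) of the unit-scale seed shape: 1 / (pi * sqrt(2))
SEED_PEAK <- 1 / (pi * sqrt(2))

# discrete analytic signal of a real kernel (Hilbert completion)
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# sampled analytic band-pass kernel tuned to `omega` cycles per unit of the
# axis, sampled with spacing `spacing`; normalized for unit passband peak.
# The seed shape is stretched so its spectral peak falls at omega (the raw
# seed of scale omega peaks at ~0.225*omega).
tuned_kernel <- function(omega, spacing) {
  om_eff <- omega / SEED_PEAK
  half <- max(2L, ceiling(4 / (om_eff * spacing)))
  x <- (-half:half) * spacing
  k <- scale_seed(x, om_eff)
  k <- k - mean(k)  # truncation leaves a small DC residue; remove it
  # unit gain at the passband peak
  nfft <- stats::nextn(max(length(k) * 8, 256), 2)
  gain <- max(Mod(stats::fft(c(k, numeric(nfft - length(k))))))
  analytic_signal(k / gain)
}

#' Apply a spectral-scale filter to a frequency profile
#'
#' Convolves a (real or complex) profile sampled on an even log-frequency
#' axis with the analytic (Hilbert-completed) scale kernel tuned to `omega`
#' cycles/octave, using edge zero-padding.
#'
#' @param profile numeric vector, one value per frequency channel.
#' @param omega scale in cycles per octave (> 0).
#' @param spacing channel spacing in octaves (e.g. 1/24).
#' @return complex vector of the same length.
#' @export
scale_filter <- function(profile, omega, spacing = 1 / 24) {
  if (omega <= 0) stop("omega must be positive", call. = FALSE)
  k <- tuned_kernel(omega, spacing)
  Tm <- conv_matrix(k, length(profile))
  drop(Tm %*% profile)
}

# centered convolution matrix for a kernel on an n-channel axis; returns an
# n x n complex matrix T with (T %*% profile)[f] = sum_f' k[f - f'] p[f']
conv_matrix <- function(kernel, n) {
  half <- (length(kernel) - 1) / 2
  idx <- outer(seq_len(n), seq_len(n), "-") + half + 1
  out <- matrix(0 + 0i, n, n)
  valid <- idx >= 1 & idx <= length(kernel)
  out[valid] <- kernel[idx[valid]]
  out
}

#' Scale representation container
#'
#' @param values complex `time x frequency x scale` array.
#' @param scales scales in cycles/octave.
#' @param frame_step frame step (s).
#' @param channel_freqs channel center frequencies (Hz).
#' @return object of class `scale_representation`.
#' @export
scale_representation <- function(values, scales, frame_step, channel_freqs) {
  stopifnot(length(dim(values)) == 3, dim(values)[3] == length(scales))
  if (is.unsorted(scales, strictly = TRUE))
    stop("scales must be strictly increasing", call. = FALSE)
  structure(list(values = values, scales = scales, frame_step = frame_step,
                 channel_freqs = channel_freqs),
            class = "scale_representation")
}

#' @export
print.scale_representation <- function(x, ...) {
  cat(sprintf("scale_representation: %d frames x %d channels x %d scales (%s c/o)\n",
              dim(x$values)[1], dim(x$values)[2], dim(x$values)[3],
              paste(x$scales, collapse = ", ")))
  invisible(x)
}

#' Central analysis
#'
#' Computes the spectral-scale decomposition of an auditory spectrogram:
#' each scale slice is the complex convolution of the spectrogram along the
#' log-frequency axis with an analytic wavelet tuned to that scale. The
#' competition transform is then applied over scale channels via each
#' scale's mean magnitude `C_S(t, omega)`, and each slice is rescaled by
#' `F[C_S] / C_S` (phase untouched; slices with `C_S < 1e-12` are zeroed).
#'
#' @param p an [auditory_spectrogram()] (peripheral output).
#' @param comp a [competition_params()] for the central stage.
#' @param scales scales in cycles/octave.
#' @param noise_mat optional pre-drawn noise matrix for the competition
#'   substream.
#' @return a [scale_representation()] with attributes `"c_s"` (mean
#'   magnitudes) and `"gain"` (applied rescaling factors).
#' @export
central_analysis <- function(p, comp = stage_competition("central"),
                             scales = c(0.5, 1, 2, 4), noise_mat = NULL) {
  stopifnot(inherits(p, "auditory_spectrogram"))
  n_t <- nrow(p$values); n_f <- ncol(p$values); n_s <- length(scales)
  spacing <- mean(diff(log2(p$channel_freqs)))
  vals <- array(0 + 0i, c(n_t, n_f, n_s))
  c_s <- matrix(0, n_t, n_s)
  for (s in seq_len(n_s)) {
    tk <- tuned_kernel(scales[s], spacing)
    Tm <- conv_matrix(tk, n_f)
    slice <- p$values %*% t(Tm)
    vals[, , s] <- slice
    c_s[, s] <- rowMeans(Mod(slice))
  }
  if (n_t == 0)
    return(scale_representation(vals, scales, p$frame_step, p$channel_freqs))
  comp$labels <- log2(scales)
  res <- competition_run(c_s, comp, noise_mat = noise_mat)
  gain <- matrix(0, n_t, n_s)
  ok <- c_s >= 1e-12
  gain[ok] <- pmax(res$y_u[ok], 0) / c_s[ok]
  for (s in seq_len(n_s))
    vals[, , s] <- vals[, , s] * gain[, s]
  out <- scale_representation(vals, scales, p$frame_step, p$channel_freqs)
  attr(out, "c_s") <- c_s
  attr(out, "gain") <- gain
  out
}
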