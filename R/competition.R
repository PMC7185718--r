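#' Parameters of the adaptation/inhibition/noise competition transform
#'
#' The same transform is applied at each stage of the hierarchy to a vector
#' of unit weights (frequency channels, scale channels, or scene
#' interpretations). Each unit's output is its softly bounded input, reduced
#' multiplicatively by adaptation (a low-pass of its own output history),
#' modulated by slow Gaussian noise, reduced subtractively by inhibition (a
#' low-pass of distant neighbors' output history), half-wave rectified and
#' finally smoothed with a causal order-3 Butterworth low-pass at 1.5 Hz.
#'
#' @param c_a adaptation magnitude (>= 0).
#' @param c_b inhibition magnitude (>= 0).
#' @param c_n noise magnitude (>= 0).
#' @param tau_a,tau_b,tau_n time constants (s) of adaptation, inhibition and
#'   noise.
#' @param theta_b asymptotic strength of the inhibition neighborhood.
#' @param sigma_b distance-weighting of inhibition: a scalar or a positive
#'   definite matrix matching the label dimensionality.
#' @param x_alpha,x_omega lower/upper soft input bounds (stage specific).
#' @param tau_x time constant (s) of input smoothing; defaults to `dt`
#'   (near-instantaneous).
#' @param dt simulation time step (s) of the stage.
#' @param labels per-unit coordinate vectors: a numeric vector (one
#'   coordinate per unit) or a matrix with one row per unit.
#' @param bound_sharpness sharpness of the soft bound on the normalized
#'   input range; large values make the bound an identity over most of
#'   `(x_alpha, x_omega)` with smooth saturation at the edges.
#' @param smooth_cutoff cutoff (Hz) of the causal output smoother.
#'
#' @return object of class `competition_params`.
#' @export
competition_params <- function(c_a = 0, c_b = 0, c_n = 0.2,
                               tau_a = 3, tau_b = 0.35, tau_n = 0.5,
                               theta_b = 6, sigma_b = 1,
                               x_alpha = 0, x_omega = 1, tau_x = NULL,
                               dt = 0.02, labels = NULL,
                               bound_sharpness = 2000,
                               smooth_cutoff = 1.5) {
  if (any(c(tau_a, tau_b, tau_n, dt) <= 0))
    stop("time constants and dt must be positive", call. = FALSE)
  if (any(c(c_a, c_b, c_n) < 0))
    stop("magnitudes must be non-negative", call. = FALSE)
  if (x_alpha >= x_omega) stop("x_alpha must be < x_omega", call. = FALSE)
  if (is.null(tau_x)) tau_x <- dt
  structure(list(c_a = c_a, c_b = c_b, c_n = c_n,
                 tau_a = tau_a, tau_b = tau_b, tau_n = tau_n,
                 theta_b = theta_b, sigma_b = sigma_b,
                 x_alpha = x_alpha, x_omega = x_omega, tau_x = tau_x,
                 dt = dt, labels = labels,
                 bound_sharpness = bound_sharpness,
                 smooth_cutoff = smooth_cutoff),
            class = "competition_params")
}

#' Inhibition weight matrix
#'
#' `B[i, j] = theta_b * (1 - exp(-d' solve(sigma_b) d))` with
#' `d = labels[i, ] - labels[j, ]`: units with identical labels do not
#' inhibit each other, and inhibition saturates at `theta_b` with label
#' distance.
#'
#' @param params a [competition_params()] with `labels` set.
#' @return a symmetric matrix with zero diagonal.
#' @export
inhibition_matrix <- function(params) {
  v <- params$labels
  if (is.null(v)) stop("unit labels required", call. = FALSE)
  if (!is.matrix(v)) v <- matrix(v, ncol = 1)
  k <- ncol(v)
  S <- params$sigma_b
  if (!is.matrix(S)) S <- diag(S, k)
  if (!all(dim(S) == k))
    stop("sigma_b dimension does not match labels", call. = FALSE)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) stop("sigma_b must be positive definite", call. = FALSE)
  Si <- solve(S)
  n <- nrow(v)
  B <- matrix(0, n, n)
  for (i in seq_len(n)) {
    d <- sweep(v, 2, v[i, ], "-")
    B[i, ] <- params$theta_b * (1 - exp(-rowSums((d %*% Si) * d)))
  }
  (B + t(B)) / 2
}

# soft sigmoid bound between x_alpha and x_omega: identity over the interior
# of the range, smooth softplus clamps at the edges
soft_bound <- function(x, x_alpha, x_omega, sharpness = 100) {
  r <- x_omega - x_alpha
  u <- (x - x_alpha) / r
  s <- sharpness
  # (1/s)*(softplus(s*u) - softplus(s*(u-1))), numerically stable
  sp <- function(z) ifelse(z > 30, z, log1p(exp(pmin(z, 30))))
  b <- (sp(s * u) - sp(s * (u - 1))) / s
  x_alpha + r * b
}

#' Initialize competition state
#'
#' @param n_units number of units.
#' @param params a [competition_params()].
#' @return object of class `competition_state` holding the adaptation trace,
#'   inhibition trace, noise value, smoothed input and the output
#'   smoother's three cascade sections.
#' @export
competition_init <- function(n_units, params) {
  z <- numeric(n_units)
  structure(list(a_d = z, b_d = z, n = z, x_tilde = z,
                 s1 = z, s2 = z, s3 = z, n_units = n_units),
            class = "competition_state")
}

# per-section coefficient of the 3-stage one-pole cascade whose composite
# -3 dB point sits at `cutoff`; each section's corner is raised by
# 1/sqrt(2^(1/3) - 1)
smoother_alpha <- function(cutoff, dt) {
  fc <- cutoff / sqrt(2^(1 / 3) - 1)
  1 - exp(-2 * pi * fc * dt)
}

#' One Euler step of the competition dynamics
#'
#' Advances the state by `params$dt` given the current input weights.
#' The unsmoothed output `y_u` is the softly bounded input modulated by the
#' adaptation, noise and inhibition terms; the causally smoothed output `y`
#' (a third-order low-pass of `y_u` at `smooth_cutoff`) is what drives the
#' adaptation and inhibition traces, so that brief amplitude dips (the
#' silences between tones) do not reset the slow competition dynamics.
#'
#' @param state a `competition_state`.
#' @param x input weight vector.
#' @param params a [competition_params()].
#' @param B inhibition matrix (precomputed by [inhibition_matrix()]); ignored
#'   when `c_b` is 0.
#' @param noise optional pre-drawn standard normal vector for this step (one
#'   per unit); drawn from the current RNG stream when `NULL`.
#' @return list with elements `state` (updated), `y_u` and `y` (smoothed).
#' @export
competition_step <- function(state, x, params, B = NULL, noise = NULL) {
  if (length(x) != state$n_units)
    stop("input length does not match number of units", call. = FALSE)
  if (any(!is.finite(x)))
    stop("non-finite input weights in competition step", call. = FALSE)
  dt <- params$dt
  if (params$c_n > 0) {
    if (is.null(noise)) noise <- stats::rnorm(state$n_units)
    state$n <- state$n + dt * (-state$n) / params$tau_n +
      params$c_n * sqrt(dt) * noise
  }
  xb <- soft_bound(x, params$x_alpha, params$x_omega, params$bound_sharpness)
  state$x_tilde <- state$x_tilde + dt * (xb - state$x_tilde) / params$tau_x
  a <- params$c_a * state$a_d
  b <- if (params$c_b > 0 && !is.null(B)) params$c_b * state$b_d else 0
  y_u <- pmax(0, state$x_tilde * (1 - a) * exp(state$n) - b)
  al <- smoother_alpha(params$smooth_cutoff, dt)
  state$s1 <- state$s1 + al * (y_u - state$s1)
  state$s2 <- state$s2 + al * (state$s1 - state$s2)
  state$s3 <- state$s3 + al * (state$s2 - state$s3)
  y <- state$s3
  state$a_d <- state$a_d + dt * (y - state$a_d) / params$tau_a
  if (params$c_b > 0 && !is.null(B))
    state$b_d <- state$b_d +
      dt * (drop(B %*% y) / state$n_units - state$b_d) / params$tau_b
  list(state = state, y_u = y_u, y = y)
}

#' Run the competition transform over a full input sequence
#'
#' @param x_mat input weights, a `time x units` matrix.
#' @param params a [competition_params()].
#' @param state optional initial state (default: zeros).
#' @param noise_mat optional pre-drawn `time x units` standard normal matrix
#'   (used for reproducible per-stage noise substreams).
#' @return list with `y` (smoothed output, `time x units`), `y_u`
#'   (unsmoothed gain-modulated output) and the final `state`.
#' @export
competition_run <- function(x_mat, params, state = NULL, noise_mat = NULL) {
  x_mat <- as.matrix(x_mat)
  n_t <- nrow(x_mat); n_u <- ncol(x_mat)
  if (is.null(state)) state <- competition_init(n_u, params)
  B <- if (params$c_b > 0) {
    if (is.null(params$labels)) stop("labels required for inhibition", call. = FALSE)
    inhibition_matrix(params)
  } else NULL
  if (params$c_n > 0 && is.null(noise_mat))
    noise_mat <- matrix(stats::rnorm(n_t * n_u), n_t, n_u)
  y_u <- matrix(0, n_t, n_u)
  y <- matrix(0, n_t, n_u)
  for (t in seq_len(n_t)) {
    res <- competition_step(state, x_mat[t, ], params, B,
                            noise = if (!is.null(noise_mat)) noise_mat[t, ])
    state <- res$state
    y_u[t, ] <- res$y_u
    y[t, ] <- res$y
  }
  list(y = y, y_u = y_u, state = state)
}

#' Stationary standard deviation of the discretized noise process
#'
#' Closed form for the AR(1) discretization used in [competition_step()]:
#' `n[t+1] = rho * n[t] + c_n * sqrt(dt) * z`, `rho = 1 - dt / tau_n`, so the
#' stationary SD is `c_n * sqrt(dt / (1 - rho^2))`.
#'
#' @param params a [competition_params()].
#' @return the stationary standard deviation.
#' @export
ou_stationary_sd <- function(params) {
  rho <- 1 - params$dt / params$tau_n
  params$c_n * sqrt(params$dt / (1 - rho^2))
}
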