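#' Temporal-rate analysis
#'
#' Filters each (frequency, scale) channel of the central representation
#' along time with a bank of analytic modulation filters, one per temporal
#' rate, built from the same seed shape as the spectral-scale kernels
#' (tuned at `psi` Hz, causal with a shared group delay).
#'
#' @param C a [scale_representation()].
#' @param rates modulation rates in Hz; every rate must lie below the
#'   Nyquist frequency of the frame rate (25 Hz at the default 20 ms
#'   step).
#' @return object of class `rate_scale_tensor`: list with `values` (real
#'   `time x frequency x scale x rate` array of modulation magnitudes),
#'   `rates`, `frame_step`, `delay_s` (shared filter group delay) and the
#'   axes metadata.
#' @export
rate_analysis <- function(C, rates = c(2, 4, 8, 16)) {
  stopifnot(inherits(C, "scale_representation"))
  if (is.unsorted(rates, strictly = TRUE))
    stop("rates must be strictly increasing", call. = FALSE)
  dt <- C$frame_step
  if (max(rates) >= 0.5 / dt)
    stop("rates must lie below the frame-rate Nyquist frequency ",
         0.5 / dt, " Hz", call. = FALSE)
  n_t <- dim(C$values)[1]; n_f <- dim(C$values)[2]; n_s <- dim(C$values)[3]
  # shared group delay: half-width of the slowest rate's kernel
  delay <- max(2L, ceiling(4 / (min(rates) / SEED_PEAK * dt)))
  x_ax <- (-delay:delay) * dt
  vals <- array(0, c(n_t, n_f, n_s, length(rates)))
  if (n_t == 0)
    return(structure(list(values = vals, rates = rates, frame_step = dt,
                          delay_s = delay * dt,
                          channel_freqs = C$channel_freqs, scales = C$scales),
                     class = "rate_scale_tensor"))
  flat <- matrix(C$values, n_t, n_f * n_s)
  L <- 2 * delay + 1
  nfft <- stats::nextn(n_t + L, 2)
  pad <- rbind(flat, matrix(0 + 0i, nfft - n_t, ncol(flat)))
  Xf <- stats::mvfft(pad)
  for (r in seq_along(rates)) {
    om_eff <- rates[r] / SEED_PEAK
    k <- scale_seed(x_ax, om_eff)
    k <- k - mean(k)  # enforce zero DC on the sampled band-pass kernel
    gain_fft <- stats::fft(c(k, numeric(stats::nextn(8 * L, 2) - L)))
    k <- analytic_signal(k / max(Mod(gain_fft)))
    Kf <- stats::fft(c(k, complex(real = numeric(nfft - L))))
    conv <- stats::mvfft(Xf * Kf, inverse = TRUE) / nfft
    aligned <- conv[delay + seq_len(n_t), , drop = FALSE]
    vals[, , , r] <- Mod(aligned)
  }
  structure(list(values = vals, rates = rates, frame_step = dt,
                 delay_s = delay * dt,
                 channel_freqs = C$channel_freqs, scales = C$scales),
            class = "rate_scale_tensor")
}

# ---- non-negative factorization (temporal coherence) ----------------------

# deterministic NNDSVD initialization
nndsvd_init <- function(M, r) {
  sv <- svd(M, nu = r, nv = r)
  W <- matrix(0, nrow(M), r); K <- matrix(0, r, ncol(M))
  for (j in seq_len(r)) {
    u <- sv$u[, j]; v <- sv$v[, j]
    up <- pmax(u, 0); un <- pmax(-u, 0)
    vp <- pmax(v, 0); vn <- pmax(-v, 0)
    npu <- sqrt(sum(up^2)); npv <- sqrt(sum(vp^2))
    nnu <- sqrt(sum(un^2)); nnv <- sqrt(sum(vn^2))
    if (npu * npv >= nnu * nnv) {
      scale_j <- sqrt(sv$d[j] * npu * npv)
      if (npu > 0) W[, j] <- scale_j * up / npu
      if (npv > 0) K[j, ] <- scale_j * vp / npv
    } else {
      scale_j <- sqrt(sv$d[j] * nnu * nnv)
      if (nnu > 0) W[, j] <- scale_j * un / nnu
      if (nnv > 0) K[j, ] <- scale_j * vn / nnv
    }
  }
  eps <- 1e-9 * max(M)
  W[W < eps] <- eps; K[K < eps] <- eps
  list(W = W, K = K)
}

# Frobenius multiplicative updates; objective is non-increasing
nmf_multiplicative <- function(M, r = 2, n_iter = 60, tol = 1e-8) {
  eps <- .Machine$double.eps
  init <- nndsvd_init(M, r)
  W <- init$W; K <- init$K
  obj <- numeric(n_iter + 1)
  obj[1] <- sum((M - W %*% K)^2)
  for (it in seq_len(n_iter)) {
    K <- K * (crossprod(W, M) + eps) / (crossprod(W) %*% K + eps)
    W <- W * (M %*% t(K) + eps) / (W %*% tcrossprod(K) + eps)
    obj[it + 1] <- sum((M - W %*% K)^2)
    if (it > 1 && abs(obj[it] - obj[it + 1]) < tol * (obj[1] + eps)) {
      obj <- obj[seq_len(it + 1)]
      break
    }
  }
  list(W = W, K = K, objective = obj)
}

#' Windowed temporal-coherence factorization
#'
#' Represents the trailing analysis window of the rate tensor as a
#' non-negative matrix `M` (rows: window frames x rates; columns:
#' frequency x scale) and finds the rank-`r` factorization `M ~ W K` by
#' multiplicative updates from a deterministic (NNDSVD) initialization.
#' Rows of `K` are L2-normalized with gains folded into `W`.
#'
#' @param R a `rate_scale_tensor` from [rate_analysis()].
#' @param window_end end time of the analysis window (s).
#' @param window_len window length (s); at least one cycle of the slowest
#'   rate.
#' @param r factorization rank (number of simultaneous components).
#' @param n_iter maximum multiplicative-update iterations.
#' @return object of class `component_set`: `W` (loadings), `K`
#'   (`r x (frequency*scale)` component spectra, unit L2 rows), `amplitude`
#'   (mean loading per component), `objective` (residual trace) and window
#'   metadata.
#' @export
coherence_factorize <- function(R, window_end, window_len = 0.5, r = 2,
                                n_iter = 60) {
  stopifnot(inherits(R, "rate_scale_tensor"))
  dt <- R$frame_step
  if (window_len < 1 / min(R$rates) / 2)
    warning("window shorter than one half-cycle of the slowest rate")
  i_end <- round(window_end / dt)
  n_win <- round(window_len / dt)
  if (i_end > dim(R$values)[1] || i_end - n_win < 0)
    stop("analysis window out of range", call. = FALSE)
  idx <- (i_end - n_win + 1):i_end
  n_f <- dim(R$values)[2]; n_s <- dim(R$values)[3]; n_r <- dim(R$values)[4]
  M <- do.call(rbind, lapply(seq_len(n_r), function(rr) {
    matrix(R$values[idx, , , rr], n_win, n_f * n_s)
  }))
  fit <- nmf_multiplicative(M, r = r, n_iter = n_iter)
  K <- fit$K; W <- fit$W
  nrm <- sqrt(rowSums(K^2))
  nrm[nrm == 0] <- 1
  K <- K / nrm
  W <- sweep(W, 2, nrm, "*")
  structure(list(W = W, K = K, amplitude = colMeans(W),
                 objective = fit$objective,
                 window_time = c(window_end - window_len, window_end),
                 n_f = n_f, n_s = n_s),
            class = "component_set")
}

# ---- conjugate Bayesian source tracking (object continuity) ---------------

#' Build the log-frequency correlation structure and its whitener
#'
#' `Sigma[i, j] = exp(-(log f_i - log f_j)^2 / sigma_f^2)` over the
#' (frequency x scale) feature columns; columns sharing a frequency are at
#' distance zero, which makes the kernel singular, so a diagonal nugget is
#' added before the Cholesky factorization.
#'
#' @param channel_freqs channel frequencies (Hz).
#' @param n_scales number of scale slices (columns are replicated per
#'   scale).
#' @param sigma_f continuity neighborhood in natural-log-Hz units.
#' @param nugget diagonal regularization.
#' @return list with `L` (lower Cholesky factor), `logdet_l` and the
#'   dimension `d`.
#' @export
continuity_whitener <- function(channel_freqs, n_scales = 1, sigma_f = 5,
                                nugget = 0.003) {
  lf <- rep(log(channel_freqs), times = n_scales)
  S <- exp(-outer(lf, lf, "-")^2 / sigma_f^2)
  diag(S) <- diag(S) + nugget
  Lt <- tryCatch(chol(S), error = function(e)
    stop("singular continuity correlation; increase the nugget", call. = FALSE))
  L <- t(Lt)
  list(L = L, logdet_l = sum(log(diag(L))), d = length(lf))
}

#' A source-grouping interpretation
#'
#' One hypothesis about the scene, indexed by its continuity
#' hyper-parameters: `kappa` (prior pseudo-count on the source mean, in
#' frames) and `beta` (prior scale of the source variance). Holds up to two
#' sources, each with a sliding window (length `t_hist` frames) of whitened
#' observations and presence indicators feeding conjugate
#' Normal-Inverse-Gamma and Beta-Bernoulli posteriors.
#'
#' @param kappa prior pseudo-count (frames).
#' @param beta prior variance scale.
#' @param alpha prior variance shape.
#' @param z_alpha,z_beta Beta-Bernoulli presence prior.
#' @param t_hist history length in frames.
#' @param whitener a [continuity_whitener()], or `NULL` for identity
#'   (features already uncorrelated).
#' @param n_sources maximum number of simultaneous sources.
#' @return object of class `interpretation`.
#' @export
interpretation <- function(kappa, beta, alpha = 1, z_alpha = 2, z_beta = 2,
                           t_hist = 30, whitener = NULL, n_sources = 2) {
  # presence log (`frames`, `present`) covers every frame the source was
  # considered; observation columns (`obs_frames`, `z`, `z_sq`) exist only
  # for frames where the source was present
  src <- function() list(frames = integer(0), present = logical(0),
                         obs_frames = integer(0), z = NULL,
                         z_sq = numeric(0))
  structure(list(kappa = kappa, beta = beta, alpha = alpha,
                 z_alpha = z_alpha, z_beta = z_beta, t_hist = t_hist,
                 whitener = whitener, frame = 0L,
                 sources = replicate(n_sources, src(), simplify = FALSE),
                 last = NULL),
            class = "interpretation")
}

whiten_obs <- function(interp, y) {
  if (is.null(interp$whitener)) return(as.numeric(y))
  as.numeric(forwardsolve(interp$whitener$L, y))
}

# posterior NIG statistics of a source from its windowed history
source_posterior <- function(interp, src, d) {
  n <- length(src$obs_frames)
  if (n > 0) {
    sz <- rowSums(src$z)
    ssq <- sum(src$z_sq)
  } else {
    sz <- numeric(d); ssq <- 0
  }
  k_n <- interp$kappa + n
  list(n = n,
       kappa_n = k_n,
       m_n = sz / k_n,
       alpha_n = interp$alpha + n * d / 2,
       beta_n = interp$beta + 0.5 * (ssq - sum(sz^2) / k_n),
       sz = sz, ssq = ssq, beta0 = interp$beta, d = d)
}

# exact incremental NIG update of a source_posterior with one observation
posterior_add <- function(post, z) {
  post$n <- post$n + 1
  post$kappa_n <- post$kappa_n + 1
  post$alpha_n <- post$alpha_n + post$d / 2
  post$sz <- post$sz + z
  post$ssq <- post$ssq + sum(z^2)
  post$m_n <- post$sz / post$kappa_n
  post$beta_n <- post$beta0 + 0.5 * (post$ssq - sum(post$sz^2) / post$kappa_n)
  post
}

# multivariate-t posterior predictive (whitened coordinates), including the
# Jacobian of the whitening so densities refer to the original features
nig_log_predictive <- function(post, z, logdet_l = 0) {
  d <- length(z)
  s2 <- post$beta_n * (post$kappa_n + 1) / (post$alpha_n * post$kappa_n)
  nu <- 2 * post$alpha_n
  q <- sum((z - post$m_n)^2)
  lgamma((nu + d) / 2) - lgamma(nu / 2) - (d / 2) * log(nu * pi * s2) -
    ((nu + d) / 2) * log1p(q / (nu * s2)) - logdet_l
}

# Beta-Bernoulli posterior predictive presence probability
presence_prob <- function(interp, src) {
  n1 <- sum(src$present)
  n0 <- length(src$present) - n1
  (interp$z_alpha + n1) / (interp$z_alpha + interp$z_beta + n1 + n0)
}

#' Posterior-predictive log density of an observation under one source
#'
#' Combines the Normal-Inverse-Gamma posterior predictive (a multivariate t
#' in whitened coordinates, with the fixed log-frequency correlation) with
#' the Beta-Bernoulli presence predictive.
#'
#' @param interp an [interpretation()].
#' @param source_h source index.
#' @param observation feature vector (original coordinates).
#' @return log predictive density (including the log presence probability).
#' @export
predictive_logpdf <- function(interp, source_h, observation) {
  src <- interp$sources[[source_h]]
  z <- whiten_obs(interp, observation)
  post <- source_posterior(interp, src, length(z))
  ld <- if (is.null(interp$whitener)) 0 else interp$whitener$logdet_l
  nig_log_predictive(post, z, ld) + log(presence_prob(interp, src))
}

# drop history entries older than t_hist frames
trim_source <- function(src, frame, t_hist) {
  keep <- src$frames > frame - t_hist
  if (!all(keep)) {
    src$frames <- src$frames[keep]
    src$present <- src$present[keep]
  }
  if (length(src$obs_frames) > 0) {
    okeep <- src$obs_frames > frame - t_hist
    if (!all(okeep)) {
      src$obs_frames <- src$obs_frames[okeep]
      src$z_sq <- src$z_sq[okeep]
      src$z <- src$z[, okeep, drop = FALSE]
      if (length(src$obs_frames) == 0) src$z <- NULL
    }
  }
  src
}

append_obs <- function(src, frame, z = NULL) {
  src$frames <- c(src$frames, frame)
  src$present <- c(src$present, !is.null(z))
  if (!is.null(z)) {
    src$obs_frames <- c(src$obs_frames, frame)
    src$z <- if (is.null(src$z)) matrix(z, ncol = 1) else cbind(src$z, z)
    src$z_sq <- c(src$z_sq, sum(z^2))
  }
  src
}

#' Greedy sequential grouping step
#'
#' Assigns the current frame's components to sources under one
#' interpretation. All assignments of the components to the available
#' sources are enumerated (both components to one source, one to each, or
#' one component alone with the other left unassigned); each is scored as
#' a mixture assignment: every component contributes the posterior
#' predictive of the source it is assigned to (an unassigned component is
#' scored under the empty-source prior predictive, i.e. as a transient from
#' an unknown source), and every source contributes its Beta-Bernoulli
#' presence predictive. The best assignment is committed to the
#' interpretation's history: assigned components become observations of
#' their source, and presence flags are appended for all sources.
#'
#' @param interp an [interpretation()].
#' @param components a `component_set` from [coherence_factorize()], or a
#'   list of feature vectors.
#' @return the updated interpretation; `$last` holds the winning score,
#'   grouping structure (`"fused"`, `"split"` or `"single"`) and per-source
#'   component assignment.
#' @export
greedy_group <- function(interp, components) {
  comps <- if (inherits(components, "component_set"))
    lapply(seq_len(nrow(components$K)), function(i) components$K[i, ])
  else components
  r <- length(comps)
  stopifnot(r >= 1)
  frame <- interp$frame + 1L
  n_src <- length(interp$sources)
  interp$sources <- lapply(interp$sources, trim_source,
                           frame = frame, t_hist = interp$t_hist)
  z_list <- lapply(comps, whiten_obs, interp = interp)
  d <- length(z_list[[1]])
  ld <- if (is.null(interp$whitener)) 0 else interp$whitener$logdet_l
  posts <- lapply(interp$sources, function(s) source_posterior(interp, s, d))
  pres <- vapply(interp$sources, function(s) presence_prob(interp, s), 1.0)
  # empty-source prior predictive for unassigned components
  prior_post <- source_posterior(
    interp, list(frames = integer(0), present = logical(0),
                 obs_frames = integer(0), z = NULL, z_sq = numeric(0)), d)

  # joint log predictive of assigning a sequence of components to one
  # source: chain rule, updating the conjugate posterior between components
  seq_logpred <- function(post, comps_z) {
    lp <- 0
    for (z in comps_z) {
      lp <- lp + nig_log_predictive(post, z, ld)
      post <- posterior_add(post, z)
    }
    lp
  }

  # candidate groupings: source index per component (0 = unassigned)
  assigns <- list()
  if (r == 2) {
    for (s in seq_len(n_src)) assigns <- c(assigns, list(c(s, s)))
    if (n_src >= 2) assigns <- c(assigns, list(c(1, 2)), list(c(2, 1)))
    for (s in seq_len(n_src))
      assigns <- c(assigns, list(c(s, 0)), list(c(0, s)))
  } else {
    for (s in seq_len(n_src))
      assigns <- c(assigns, list(rep(s, r)))
  }

  best <- NULL
  for (a in assigns) {
    present <- seq_len(n_src) %in% a
    score <- sum(ifelse(present, log(pres), log1p(-pres)))
    for (s in unique(a[a > 0]))
      score <- score + seq_logpred(posts[[s]], z_list[a == s])
    if (any(a == 0))
      for (cc in which(a == 0))
        score <- score + nig_log_predictive(prior_post, z_list[[cc]], ld)
    if (is.null(best) || score > best$score)
      best <- list(score = score, assign = a, present = present)
  }

  for (s in seq_len(n_src)) {
    cc_s <- which(best$assign == s)
    if (length(cc_s) == 0) {
      interp$sources[[s]] <- append_obs(interp$sources[[s]], frame, NULL)
    } else {
      for (cc in cc_s)
        interp$sources[[s]] <- append_obs(interp$sources[[s]], frame,
                                          z_list[[cc]])
      # one presence flag per frame, not per component
      ns <- length(interp$sources[[s]]$frames)
      if (length(cc_s) > 1) {
        dup <- seq(ns - length(cc_s) + 2, ns)
        interp$sources[[s]]$frames <- interp$sources[[s]]$frames[-dup]
        interp$sources[[s]]$present <- interp$sources[[s]]$present[-dup]
      }
    }
  }
  n_pres <- sum(best$present)
  grouping <- stats::setNames(
    lapply(which(best$present), function(s) which(best$assign == s)),
    which(best$present))
  structure_label <- if (n_pres >= 2) "split"
    else if (all(seq_len(r) %in% which(best$assign > 0))) "fused"
    else "single"
  interp$frame <- frame
  interp$last <- list(score = best$score, structure = structure_label,
                      grouping = grouping)
  interp
}
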