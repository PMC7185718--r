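# a small scale_representation carrying a prescribed envelope per channel
toy_scale_rep <- function(env_mat, freqs = 500 * 2^((0:(ncol(env_mat) - 1)) / 24)) {
  arr <- array(0 + 0i, c(nrow(env_mat), ncol(env_mat), 1))
  arr[, , 1] <- env_mat
  scale_representation(arr, scales = 1, frame_step = 0.02,
                       channel_freqs = freqs)
}

test_that("an amplitude modulation drives its matching rate channel", {
  t <- seq(0, 10, by = 0.02)
  env <- matrix(1 + 0.8 * sin(2 * pi * 4 * t), ncol = 1)
  R <- rate_analysis(toy_scale_rep(env), rates = c(2, 4, 8, 16))
  en <- apply(R$values[100:400, , , , drop = FALSE], 4, sum)
  expect_equal(which.max(en), 2L)
})

test_that("a constant input leaves all rate channels near zero", {
  env <- matrix(1, 400, 1)
  R <- rate_analysis(toy_scale_rep(env), rates = c(2, 4, 8, 16))
  expect_lt(max(R$values[100:300, , , ]), 0.02)
})

test_that("the ABA stimulus excites both the triplet and tone rates", {
  ch <- quiet_chain(sep = 6, reps = 10)
  R <- rate_analysis(ch$C)
  en <- apply(R$values[100:230, , , , drop = FALSE], 4, sum)
  frac <- en / sum(en)
  expect_gt(frac[R$rates == 2], 0.1)
  expect_gt(frac[R$rates == 8], 0.1)
})

test_that("rates at or above the frame Nyquist are rejected", {
  env <- matrix(1, 100, 1)
  expect_error(rate_analysis(toy_scale_rep(env), rates = c(2, 32)),
               "Nyquist")
})

test_that("a rank-1 matrix is recovered nearly exactly", {
  set.seed(5)
  M <- outer(runif(40, 0.5, 2), runif(30, 0.5, 2))
  fit <- bistream:::nmf_multiplicative(M, r = 2, n_iter = 200)
  rel_err <- sqrt(sum((M - fit$W %*% fit$K)^2) / sum(M^2))
  expect_lt(rel_err, 1e-3)
})

test_that("the multiplicative-update objective is non-increasing", {
  set.seed(6)
  M <- matrix(runif(600), 20, 30)
  fit <- bistream:::nmf_multiplicative(M, r = 2, n_iter = 80)
  expect_true(all(diff(fit$objective) <= 1e-9 * fit$objective[1]))
})

test_that("coherence components of the 12 st stimulus are A-like and B-like", {
  ch <- quiet_chain(sep = 12, reps = 10)
  R <- rate_analysis(ch$C)
  cs <- coherence_factorize(R, window_end = 3.0)
  fr <- ch$P$channel_freqs
  peaks <- vapply(1:2, function(j) {
    marg <- rowSums(matrix(cs$K[j, ], cs$n_f, cs$n_s))
    fr[which.max(marg)]
  }, 1.0)
  expect_gte(abs(log2(peaks[1] / peaks[2])) * 12, 9)
})

test_that("the conjugate predictive matches numeric quadrature in 1-D", {
  ip <- interpretation(kappa = 2, beta = 1, alpha = 1, whitener = NULL)
  ip <- greedy_group(ip, list(1.0))
  post <- bistream:::source_posterior(ip, ip$sources[[1]], 1)
  expect_equal(post$n, 1)
  lp <- bistream:::nig_log_predictive(post, 1.0, 0)
  # frozen value from brute-force integration over (mu, sigma^2) of the
  # Normal likelihood under the N(0, sigma^2/kappa) x InvGamma(1, 1) prior
  expect_equal(lp, -1.3213, tolerance = 1e-3)
})

test_that("a source with no history has presence probability 1/2", {
  ip <- interpretation(kappa = 15, beta = 0.5, whitener = NULL)
  expect_equal(bistream:::presence_prob(ip, ip$sources[[1]]), 0.5)
})

test_that("the continuity correlation has unit diagonal before the nugget", {
  fr <- default_channels(24)
  lf <- log(fr)
  S <- exp(-outer(lf, lf, "-")^2 / 25)
  expect_equal(diag(S), rep(1, 24))
  wh <- continuity_whitener(fr, n_scales = 2)
  expect_equal(wh$d, 48)
  expect_true(all(is.finite(wh$L)))
})

test_that("sequential conjugate updates equal the batch posterior", {
  set.seed(9)
  d <- 6
  obs <- lapply(1:5, function(i) rnorm(d))
  ip <- interpretation(kappa = 3, beta = 2, alpha = 1.5, whitener = NULL)
  post <- bistream:::source_posterior(ip, ip$sources[[1]], d)
  for (z in obs) post <- bistream:::posterior_add(post, z)
  # batch statistics
  zm <- do.call(cbind, obs)
  sz <- rowSums(zm)
  k_n <- 3 + 5
  expect_equal(post$kappa_n, k_n)
  expect_equal(post$m_n, sz / k_n, tolerance = 1e-8)
  expect_equal(post$alpha_n, 1.5 + 5 * d / 2)
  expect_equal(post$beta_n, 2 + 0.5 * (sum(zm^2) - sum(sz^2) / k_n),
               tolerance = 1e-8)
})

test_that("exchanging component order preserves the grouping structure", {
  set.seed(10)
  z1 <- runif(8); z2 <- runif(8) + 2
  ip_a <- interpretation(kappa = 5, beta = 0.5 * 4, alpha = 4,
                         whitener = NULL)
  ip_b <- ip_a
  for (k in 1:6) {
    ip_a <- greedy_group(ip_a, list(z1, z2))
    ip_b <- greedy_group(ip_b, list(z2, z1))
    expect_equal(ip_a$last$structure, ip_b$last$structure)
  }
})

test_that("strong slow priors split stationary alternating tones; weak priors fuse them", {
  ch <- quiet_chain(sep = 12, reps = 12)
  R <- rate_analysis(ch$C)
  wh <- continuity_whitener(ch$P$channel_freqs, n_scales = 4)
  run_interp <- function(beta) {
    ip <- interpretation(kappa = 20, beta = beta * wh$d / 2,
                         alpha = wh$d / 2, whitener = wh)
    prev <- NULL
    labs <- character(0)
    for (te in seq(0.5, 5.5, by = 0.1)) {
      cs <- coherence_factorize(R, window_end = te)
      if (!is.null(prev) &&
          sum(diag(cs$K[2:1, ] %*% t(prev))) > sum(diag(cs$K %*% t(prev)))) {
        cs$K <- cs$K[2:1, , drop = FALSE]
        cs$W <- cs$W[, 2:1, drop = FALSE]
        cs$amplitude <- cs$amplitude[2:1]
      }
      prev <- cs$K
      ip <- greedy_group(ip, cs)
      labs <- c(labs, ip$last$structure)
    }
    labs
  }
  strong <- run_interp(0.25)  # narrow variance prior: slow-moving sources
  weak <- run_interp(0.8)    # broad variance prior: fast-moving sources
  late <- -(1:20)
  expect_gt(mean(strong[late] %in% c("split", "single")), 0.5)
  expect_gt(mean(weak[late] == "fused"), 0.5)
})

test_that("masks partition the scene energy", {
  ch <- quiet_chain(sep = 12, reps = 12)
  masks <- object_analysis(ch$C, stage_competition("object", c_n = 0))
  tot_mask <- apply(masks$values, 1, sum)
  expect_true(all(tot_mask >= 0))
  # summed source masks never exceed the full back-projection by > 5 %
  n_f <- dim(ch$C$values)[2]
  spacing <- mean(diff(log2(ch$C$channel_freqs)))
  inv_m <- lapply(ch$C$scales, function(om)
    Conj(t(bistream:::conv_matrix(bistream:::tuned_kernel(om, spacing),
                                  n_f))))
  for (ti in c(15, 30, 45)) {
    row_c <- round(masks$times[ti] / ch$C$frame_step)
    acc <- numeric(n_f)
    for (s in seq_along(ch$C$scales))
      acc <- acc + Re(inv_m[[s]] %*% ch$C$values[row_c, , s])
    full <- sum(pmax(acc, 0))
    expect_lte(sum(masks$values[ti, , ]), full * 1.05)
  }
})

test_that("the dominant interpretation is constant for the noise-free model", {
  ch <- quiet_chain(sep = 6, reps = 10)
  masks <- object_analysis(ch$C, stage_competition("object", c_n = 0))
  late <- masks$times > masks$times[1] + 1
  expect_lte(length(unique(masks$interp_idx[late])), 2)
})
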