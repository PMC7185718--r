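test_that("without competition the transform passes a bounded input through", {
  p <- competition_params(c_a = 0, c_b = 0, c_n = 0, dt = 0.02,
                          x_alpha = 0, x_omega = 2)
  res <- competition_run(matrix(1, 400, 1), p)
  expect_equal(tail(res$y_u[, 1], 1), 1, tolerance = 1e-6)
  expect_equal(tail(res$y[, 1], 1), 1, tolerance = 1e-3)
})

test_that("adaptation steady state matches the fixed point y = x / (1 + c_a x)", {
  for (c_a in c(1, 4)) {
    p <- competition_params(c_a = c_a, c_b = 0, c_n = 0, dt = 0.02,
                            x_alpha = 0, x_omega = 2)
    res <- competition_run(matrix(1, 4000, 1), p)
    expect_equal(tail(res$y[, 1], 1), 1 / (1 + c_a), tolerance = 1e-3)
  }
})

test_that("the noise process has the AR(1) stationary standard deviation", {
  p <- competition_params(c_a = 0, c_b = 0, c_n = 0.2, tau_n = 0.5,
                          dt = 0.02, x_alpha = 0, x_omega = 2)
  st <- competition_init(1, p)
  set.seed(11)
  n_steps <- 10000  # 200 s of simulated noise
  vals <- numeric(n_steps)
  for (t in seq_len(n_steps)) {
    r <- competition_step(st, 1, p)
    st <- r$state
    vals[t] <- st$n
  }
  expect_equal(stats::sd(vals[-(1:500)]), ou_stationary_sd(p),
               tolerance = 0.1)
})

test_that("inhibition matrix follows theta_b * (1 - exp(-d' S^-1 d))", {
  p0 <- competition_params(c_b = 1, theta_b = 6, sigma_b = 1,
                           labels = c(0, 0), x_omega = 2)
  expect_equal(inhibition_matrix(p0), matrix(0, 2, 2))
  p1 <- competition_params(c_b = 1, theta_b = 6, sigma_b = 1,
                           labels = c(0, 1), x_omega = 2)
  B <- inhibition_matrix(p1)
  expect_equal(B[1, 2], 6 * (1 - exp(-1)))
  expect_equal(B, t(B))
  expect_equal(diag(B), c(0, 0))
  # inhibition saturates at theta_b with distance
  p2 <- competition_params(c_b = 1, theta_b = 6, sigma_b = 1,
                           labels = c(0, 100), x_omega = 2)
  expect_equal(inhibition_matrix(p2)[1, 2], 6, tolerance = 1e-6)
  # mismatched sigma_b dimension is a configuration error
  p3 <- competition_params(c_b = 1, sigma_b = diag(3),
                           labels = cbind(c(0, 1), c(0, 1)), x_omega = 2)
  expect_error(inhibition_matrix(p3), "dimension")
})

test_that("the transform is deterministic without noise", {
  p <- competition_params(c_a = 2, c_b = 3, c_n = 0, dt = 0.02,
                          sigma_b = 1, labels = c(0, 1), x_omega = 2)
  x <- matrix(runif(400), 200, 2)
  r1 <- competition_run(x, p)
  r2 <- competition_run(x, p)
  expect_identical(r1$y, r2$y)
})

test_that("outputs are non-negative and smoothing preserves that", {
  p <- competition_params(c_a = 5, c_b = 5, c_n = 0.2, dt = 0.02,
                          sigma_b = 1, labels = c(0, 2), x_omega = 2)
  set.seed(3)
  res <- competition_run(matrix(1, 1500, 2), p)
  expect_true(all(res$y_u >= 0))
  expect_gte(min(res$y), -0.05 * max(res$y))
})

test_that("increasing adaptation never increases the steady output", {
  ys <- vapply(c(0, 1, 3, 10, 30), function(c_a) {
    p <- competition_params(c_a = c_a, c_b = 0, c_n = 0, dt = 0.02,
                            x_alpha = 0, x_omega = 2)
    tail(competition_run(matrix(1, 3000, 1), p)$y[, 1], 1)
  }, 1.0)
  expect_true(all(diff(ys) <= 1e-9))
})

test_that("strong inhibition with weak noise produces competitive exclusion", {
  p <- competition_params(c_a = 0, c_b = 10, c_n = 0.05, tau_n = 0.5,
                          theta_b = 6, sigma_b = 1, labels = c(0, 3),
                          dt = 0.02, x_alpha = 0, x_omega = 2)
  set.seed(2)
  res <- competition_run(matrix(1, 4000, 2), p)
  late <- colMeans(res$y[3500:4000, ])
  expect_gt(abs(diff(late)), 0.5 * max(late))
})

test_that("non-finite inputs raise an error", {
  p <- competition_params(x_omega = 2, c_n = 0)
  st <- competition_init(1, p)
  expect_error(competition_step(st, NaN, p), "finite")
})
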