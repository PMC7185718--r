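ref_mean <- c(`3` = 0.1, `6` = 0.6, `12` = 0.9)

test_that("response deviation reproduces hand-computed values", {
  exact <- matrix(rep(ref_mean, 2), 2, byrow = TRUE,
                  dimnames = list(NULL, names(ref_mean)))
  expect_equal(response_deviation(exact, ref_mean), 0)
  one_run <- matrix(c(0.1, 0.5, 0.9), 1,
                    dimnames = list(NULL, c("3", "6", "12")))
  expect_equal(response_deviation(one_run, ref_mean), sqrt(0.01 / 3))
  maximal <- matrix(c(1, 1, 1), 1, dimnames = list(NULL, c("3", "6", "12")))
  expect_equal(response_deviation(maximal, c(`3` = 0, `6` = 0, `12` = 0)), 1)
  expect_error(response_deviation(one_run[, 1:2, drop = FALSE], ref_mean),
               "12")
})

test_that("response deviation is invariant to run order", {
  set.seed(4)
  runs <- matrix(runif(30), 10, 3, dimnames = list(NULL, c("3", "6", "12")))
  expect_equal(response_deviation(runs, ref_mean),
               response_deviation(runs[10:1, ], ref_mean))
})

test_that("the KS response-length deviation matches ECDF enumeration", {
  expect_equal(length_deviation(c(-1, 0, 1), c(-1, 0, 1)), 0)
  expect_equal(length_deviation(c(-1, 0, 1), c(9, 10, 11)), 1)
  expect_equal(length_deviation(c(0, 1), 0.5), 0.5)
  expect_error(length_deviation(numeric(0), 1), "empty")
})

test_that("KS is symmetric and invariant under monotone transforms", {
  set.seed(7)
  a <- rlnorm(40); b <- rlnorm(50, 0.4)
  expect_equal(length_deviation(a, b), length_deviation(b, a))
  expect_equal(length_deviation(log(a), log(b)), length_deviation(a, b))
})

test_that("the deviation ratio behaves as a scale-normalized average", {
  expect_equal(deviation_ratio(0.1, 0.2, c(0.1, 0.1), c(0.2, 0.2)), 1)
  expect_equal(deviation_ratio(0, 0, c(0.1), c(0.2)), 0)
  expect_equal(deviation_ratio(0.2, 0.4, c(0.1), c(0.2)), 2)
  expect_error(deviation_ratio(0.1, 0.1, c(0, 0), c(0.1)), "degenerate")
  # scale consistency: doubling everything leaves the ratio unchanged
  expect_equal(deviation_ratio(0.2, 0.3, c(0.1, 0.3), c(0.2, 0.4)),
               deviation_ratio(0.4, 0.6, 2 * c(0.1, 0.3), 2 * c(0.2, 0.4)))
})

test_that("buildup curves report the per-bin segregated fraction", {
  all_fused <- lapply(1:4, function(i)
    percept_track(0, 10, "fused", run_id = i))
  expect_true(all(buildup_curve(all_fused, bin = 1)$p_segregated == 0))
  all_seg <- lapply(1:4, function(i)
    percept_track(0, 10, "segregated", run_id = i))
  expect_true(all(buildup_curve(all_seg, bin = 1)$p_segregated == 1))
  half <- c(all_fused[1:2], all_seg[1:2])
  expect_true(all(buildup_curve(half, bin = 1)$p_segregated == 0.5))
})

test_that("percept lengths drop the first response and sub-250 ms reports", {
  tr <- percept_track(c(0, 2, 2.1, 5), c(2, 2.1, 5, 9),
                      c("fused", "segregated", "fused", "segregated"))
  expect_equal(percept_lengths(tr), c(2.9, 4))
})

test_that("z-scoring in log space centers and scales per individual", {
  z <- z_log_lengths(rlnorm(50, 1, 0.5))
  expect_equal(mean(z), 0, tolerance = 1e-10)
  expect_equal(sd(z), 1, tolerance = 1e-10)
  expect_warning(z1 <- z_log_lengths(3), "excluded")
  expect_null(z1)
})

test_that("bootstrap confidence intervals behave", {
  expect_equal(diff(bootstrap_ci(rep(2, 20), mean, n_boot = 100, seed = 1)),
               0)
  covered <- vapply(1:25, function(i) {
    set.seed(i)
    x <- rnorm(100)
    ci <- bootstrap_ci(x, mean, n_boot = 200, seed = i)
    ci[1] <= 0 && 0 <= ci[2]
  }, TRUE)
  expect_gte(mean(covered), 0.9)
  ci1 <- bootstrap_ci(c(1, 2, 3), mean, n_boot = 1, seed = 2)
  expect_equal(ci1[1], ci1[2])
})

test_that("log-space density recovers a log-normal mode and integrates to 1", {
  set.seed(8)
  x <- rlnorm(10000, meanlog = 1, sdlog = 0.5)
  d <- log_density(x)
  mode_est <- d$x[which.max(d$density)]
  mode_true <- exp(1 - 0.5^2)
  expect_lt(abs(mode_est - mode_true) / mode_true, 0.1)
  area <- sum(d$density[-1] * diff(d$x))
  expect_equal(area, 1, tolerance = 0.01)
  expect_error(log_density(c(1, -1)), "positive")
  d1 <- log_density(5)
  expect_equal(d1$x[which.max(d1$density)], 5, tolerance = 0.5)
})
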