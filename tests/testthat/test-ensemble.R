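test_that("within-stage enumeration has 3 x levels^2 models", {
  g <- ensemble_grid("within")
  models <- enumerate_models(g)
  expect_equal(nrow(models), 300)
  expect_equal(length(g$levels), 10)
  expect_false(anyDuplicated(g$levels) > 0)
  # each model touches exactly one stage
  mags <- models[, c("peripheral_ca", "peripheral_cb", "central_ca",
                     "central_cb", "object_ca", "object_cb")]
  active_stage <- vapply(seq_len(nrow(models)), function(i) {
    m <- unlist(mags[i, ])
    sum(tapply(m, rep(1:3, each = 2), function(v) any(v > 0)))
  }, 1.0)
  expect_true(all(active_stage <= 1))
})

test_that("across-stage enumeration crosses all six magnitude axes", {
  g <- ensemble_grid("across")
  models <- enumerate_models(g)
  expect_equal(nrow(models), length(g$levels)^6)
  expect_equal(length(g$levels), 5)
  expect_false(any(duplicated(models[, -(1:2)])))
})

test_that("a single zero level collapses to three copies of the None model", {
  g <- ensemble_grid("within", levels = 0)
  models <- enumerate_models(g)
  expect_equal(nrow(models), 3)
  mags <- models[, c("peripheral_ca", "peripheral_cb", "central_ca",
                     "central_cb", "object_ca", "object_cb")]
  expect_true(all(mags == 0))
})

test_that("across-stage marginal cells hold levels^4 models", {
  g <- ensemble_grid("across")
  models <- enumerate_models(g)
  fake <- cbind(models, response_dev = 0.1, length_dev = 0.1,
                ratio = seq_len(nrow(models)) / nrow(models),
                terminated = FALSE, failed = FALSE)
  class(fake) <- c("ensemble_result", "data.frame")
  agg <- aggregate_ensemble(fake, "across")
  expect_true(all(agg$n_models == 625))
  expect_equal(nrow(agg), 3 * 25)
  # the aggregate is the minimum over each marginal cell
  one <- subset(agg, stage == "object" & c_a == 0 & c_b == 0)
  sel <- models$object_ca == 0 & models$object_cb == 0
  expect_equal(one$ratio, min(fake$ratio[sel]))
})

test_that("top-quantile filtering reproduces the best-fraction rule", {
  res <- data.frame(ratio = (1:100) / 50)
  kept <- top_models(res, 0.25)
  expect_equal(nrow(kept), 25)
  expect_true(all(kept$ratio <= stats::quantile(res$ratio, 0.25)))
})

test_that("a reduced grid runs end to end and is reproducible", {
  pop <- generate_reference(n_listeners = 6, samples_per_listener = 40,
                            seed = 2)
  ref <- reference_summary(pop)
  g <- ensemble_grid("within", levels = c(0, 5), sims_per_model = 1,
                     conditions = c(6, 12))
  models <- enumerate_models(g)
  sel <- models[models$stage == "object", ][1:2, ]
  spec <- stimulus_spec(repetitions = 10)
  r1 <- run_ensemble(g, ref, models = sel, spec = spec, opts = tiny_opts(),
                     seed = 7)
  r2 <- run_ensemble(g, ref, models = sel, spec = spec, opts = tiny_opts(),
                     seed = 7)
  expect_false(any(r1$failed))
  expect_true(all(is.finite(r1$ratio)))
  expect_equal(r1$ratio, r2$ratio)
  agg <- aggregate_ensemble(r1, "within")
  expect_equal(sort(agg$ratio), sort(r1$ratio))
})

test_that("across mode can terminate a poor model after the 6 st batch", {
  pop <- generate_reference(n_listeners = 6, samples_per_listener = 40,
                            seed = 2)
  ref <- reference_summary(pop)
  # an impossible-to-match reference forces a provisional ratio > 1
  ref$mean_props[] <- c(0, 0, 0)
  g <- ensemble_grid("across", levels = c(0, 5), sims_per_model = 2,
                     conditions = c(6, 12), early_stop_sims = 1)
  models <- enumerate_models(g)
  config <- models[models$object_ca == 5 & models$object_cb == 5 &
                   models$peripheral_ca == 0 & models$peripheral_cb == 0 &
                   models$central_ca == 0 & models$central_cb == 0, ][1, ]
  res <- run_model(config, g, ref, spec = stimulus_spec(repetitions = 10),
                   opts = tiny_opts(), seed = 3)
  expect_true(res$terminated)
  expect_true(all(is.na(res$props[, "12"])))
})
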