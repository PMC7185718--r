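make_spectrogram <- function(mat, freqs = 500 * 2^((0:(ncol(mat) - 1)) / 24)) {
  auditory_spectrogram(mat, 0.02, freqs)
}

test_that("a mask identical to its reference has bandwidth ratio 1", {
  set.seed(1)
  w <- matrix(runif(200), 10, 20)
  hp <- heuristic_params()
  thr <- hp$theta_b * stats::quantile(w, hp$theta_c)
  fr <- 500 * 2^((0:19) / 24)
  expect_equal(bandwidth_ratio(w, w, fr, hp, thr, thr), 1)
})

test_that("an all-zero mask has ratio 0", {
  hp <- heuristic_params()
  fr <- 500 * 2^((0:19) / 24)
  ref <- matrix(1, 10, 20)
  expect_equal(bandwidth_ratio(matrix(0, 10, 20), ref, fr, hp, 0.5, 0.5), 0)
})

test_that("a mask covering one of two ridges has a small ratio", {
  fr <- 500 * 2^((0:47) / 24)
  ref <- matrix(0, 20, 48)
  ref[, 5:8] <- 1    # ridge A
  ref[, 40:43] <- 1  # ridge B, one octave plus up
  mask <- ref
  mask[, 40:43] <- 0 # mask keeps only ridge A
  hp <- heuristic_params()
  r <- bandwidth_ratio(mask, ref, fr, hp, 0.3, 0.3)
  # active set enumeration: mask spans channels 5-8, reference 5-43
  expect_equal(r, (3 / 24) / (38 / 24))
  expect_lt(r, hp$theta_r)
})

test_that("a constant trajectory yields a single interval", {
  fr <- 500 * 2^((0:47) / 24)
  O <- array(0, c(80, 48, 2))
  O[, 5:8, 1] <- 1
  masks <- structure(list(values = O, times = seq(0.5, by = 0.1, length = 80),
                          frame_step = 0.1, channel_freqs = fr),
                     class = "source_masks")
  ref <- make_spectrogram(matrix(rep(c(rep(0, 4), rep(1, 4), rep(0, 40)),
                                     each = 400), 400, 48), fr)
  tr <- classify_percepts(masks, ref)
  expect_equal(nrow(tr), 1)
  # the track covers the run up to the last full analysis step
  expect_gte(tr$end_s - tr$start_s, diff(range(masks$times)) - 0.25)
})

test_that("brief reversions within 250 ms are absorbed", {
  tr <- percept_track(c(0, 3, 3.2, 6), c(3, 3.2, 6, 9),
                      c("fused", "segregated", "fused", "segregated"))
  cleaned <- clean_track(tr, 0.25)
  expect_equal(cleaned$label[1], "fused")
  expect_equal(cleaned$end_s[1], 6)
  expect_equal(nrow(cleaned), 2)
})

test_that("cleaning is idempotent", {
  set.seed(2)
  bounds <- cumsum(c(0, runif(30, 0.05, 2)))
  labels <- rep(c("fused", "segregated"), length.out = 30)
  tr <- percept_track(head(bounds, -1), bounds[-1], labels)
  c1 <- clean_track(tr, 0.25)
  c2 <- clean_track(c1, 0.25)
  expect_equal(c1$start_s, c2$start_s)
  expect_equal(c1$label, c2$label)
})

test_that("alternating bandwidth blocks give alternating ~1 s percepts", {
  fr <- 500 * 2^((0:47) / 24)
  n_t <- 200  # 20 s at the 0.1 s mask step
  O <- array(0, c(n_t, 48, 2))
  wide <- c(5:8, 40:43)
  for (ti in seq_len(n_t)) {
    sec <- ceiling(ti / 10)
    if (sec %% 2 == 1) O[ti, wide, 1] <- 1  # broadband: fused
    else O[ti, 5:8, 1] <- 1                 # one ridge: segregated
  }
  masks <- structure(list(values = O,
                          times = seq(0.5, by = 0.1, length = n_t),
                          frame_step = 0.1, channel_freqs = fr),
                     class = "source_masks")
  ref_mat <- matrix(0, 2000, 48); ref_mat[, wide] <- 1
  tr <- classify_percepts(masks, make_spectrogram(ref_mat, fr))
  expect_gt(nrow(tr), 5)
  durs <- tr$end_s - tr$start_s
  inner <- durs[2:(length(durs) - 1)]
  expect_true(all(abs(inner - 1) <= 0.5))
  expect_true(all(tr$label[-1] != tr$label[-nrow(tr)]))
})

test_that("labeled time covers the classified span", {
  fr <- 500 * 2^((0:47) / 24)
  O <- array(0, c(60, 48, 2)); O[, 5:8, 1] <- 1
  masks <- structure(list(values = O, times = seq(0.5, by = 0.1, length = 60),
                          frame_step = 0.1, channel_freqs = fr),
                     class = "source_masks")
  ref_mat <- matrix(0, 600, 48); ref_mat[, c(5:8, 40:43)] <- 1
  tr <- classify_percepts(masks, make_spectrogram(ref_mat, fr))
  expect_equal(min(tr$start_s), masks$times[1])
  expect_equal(sum(tr$end_s - tr$start_s),
               max(tr$end_s) - min(tr$start_s))
})

test_that("empty masks give an empty track", {
  masks <- structure(list(values = array(0, c(0, 4, 2)), times = numeric(0),
                          frame_step = 0.1,
                          channel_freqs = 500 * 2^((0:3) / 24)),
                     class = "source_masks")
  ref <- make_spectrogram(matrix(1, 10, 4), 500 * 2^((0:3) / 24))
  tr <- classify_percepts(masks, ref)
  expect_equal(nrow(tr), 0)
})

test_that("the literal direction inverts the labeling", {
  fr <- 500 * 2^((0:47) / 24)
  O <- array(0, c(60, 48, 2)); O[, 5:8, 1] <- 1  # narrow mask
  masks <- structure(list(values = O, times = seq(0.5, by = 0.1, length = 60),
                          frame_step = 0.1, channel_freqs = fr),
                     class = "source_masks")
  ref_mat <- matrix(0, 600, 48); ref_mat[, c(5:8, 40:43)] <- 1
  ref <- make_spectrogram(ref_mat, fr)
  tr_coh <- classify_percepts(masks, ref, heuristic_params())
  tr_lit <- classify_percepts(masks, ref,
                              heuristic_params(direction = "literal"))
  expect_equal(unique(tr_coh$label), "segregated")
  expect_equal(unique(tr_lit$label), "fused")
})
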