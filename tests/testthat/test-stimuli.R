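test_that("FM sweep onsets, duration and down/up mirror symmetry", {
  up <- fm_sweep_current(3, onset_step_ms = 5.5, direction = "up", dt = 0.1)
  onset_of <- function(tr, ch) (which(tr$values[ch, ] > 0)[1] - 1) * tr$dt
  expect_equal(vapply(1:3, function(k) onset_of(up, k), numeric(1)),
               c(0, 5.5, 11))
  expect_equal(ncol(up$values) * up$dt, (3 - 1) * 5.5 + 5.5)
  dn <- fm_sweep_current(3, onset_step_ms = 5.5, direction = "down", dt = 0.1)
  expect_equal(dn$values, up$values[3:1, ])
})

test_that("OU noise is calibrated, zero-mean, seeded and independent across seeds", {
  spec <- noise_spec(sigma = 0.45, dt = 0.1, seed = 3)
  x <- ou_noise(2e5, spec)
  # zero mean within 3 standard errors (correlated samples: use batch s.e.)
  bm <- colMeans(matrix(x, 1000))
  expect_lt(abs(mean(x)), 3 * sd(bm) / sqrt(length(bm)))
  # stationary s.d. over pulse amplitude recovers sigma within 2%
  expect_lt(abs(sd(x) / 0.45 - 1), 0.02)
  # determinism
  expect_identical(x, ou_noise(2e5, spec))
  # independence across seeds
  y <- ou_noise(2e5, noise_spec(sigma = 0.45, dt = 0.1, seed = 4))
  expect_lt(abs(cor(x, y)), 0.05)
  # degenerate level
  expect_true(all(ou_noise(100, noise_spec(sigma = 0)) == 0))
})

test_that("noise is purely additive over the clean pulse component", {
  tr <- fm_sweep_current(4, 5.5)
  spec <- noise_spec(0.35, dt = 0.1, seed = 9)
  noisy <- add_noise(tr, spec)
  nz <- ou_noise_matrix(ncol(tr$values), spec, n_channels = 4)
  expect_equal(noisy$values - nz, tr$values)
})

test_that("spike encoding confines clean-stimulus spikes to pulse windows", {
  tr <- fm_sweep_current(6, 5.5)
  ras <- encode_to_spikes(tr)
  expect_true(all(ras$population == "A"))
  expect_gt(nrow(ras), 0)
  # every spike falls inside its channel's pulse window
  for (i in seq_len(nrow(ras))) {
    t0 <- (ras$channel[i] - 1) * 5.5
    expect_true(ras$time_ms[i] > t0 & ras$time_ms[i] <= t0 + 5.5 + 0.2)
  }
  # channels fire in sweep order as bursts
  first_by_ch <- tapply(ras$time_ms, ras$channel, min)
  expect_true(all(diff(first_by_ch) > 0))
  # determinism, and added noise produces out-of-window spikes
  expect_identical(as.data.frame(encode_to_spikes(tr)), as.data.frame(ras))
  noisy <- encode_to_spikes(tr, noise_spec(0.45, dt = 0.1, seed = 2))
  in_window <- function(r) {
    t0 <- (r$channel - 1) * 5.5
    r$time_ms > t0 & r$time_ms <= t0 + 5.5 + 0.2
  }
  expect_gt(sum(!in_window(noisy)), 0)
})

test_that("synthetic formant set has the documented structure", {
  pats <- synth_formant_patterns(seed = 5)
  expect_length(pats, 21)
  expect_equal(attr(pats, "classes"), paste0("class", 1:7))
  for (p in pats) {
    expect_equal(dim(p$grid), c(32, 25))
    expect_true(all(p$grid %in% c(0, 1)))
    # at most two formants per time bin
    expect_true(all(colSums(p$grid) <= 2))
    # no silent columns
    expect_true(all(colSums(p$grid) >= 1))
  }
  # determinism and jitter degeneracy
  expect_identical(synth_formant_patterns(seed = 5), pats)
  pj0 <- synth_formant_patterns(jitter = 0, seed = 5)
  expect_identical(pj0[[1]]$grid, pj0[[2]]$grid)
  expect_identical(pj0[[2]]$grid, pj0[[3]]$grid)
  # exemplars of one class differ under jitter but share the label
  expect_false(identical(pats[[1]]$grid, pats[[2]]$grid))
  expect_equal(pats[[1]]$label, pats[[2]]$label)
})

test_that("sentences warp word length by rate and balance classes gaplessly", {
  pats <- synth_formant_patterns(seed = 8)
  lens_for <- function(rate) {
    sen <- build_sentence(pats, n_reps_per_class = 2, rate_percent = rate,
                          seed = 3)
    with(sen$words, end_bin - start_bin + 1)
  }
  expect_true(all(lens_for(100) == 25))
  expect_true(all(lens_for(200) == 13))   # round-half-up of 12.5
  expect_true(all(lens_for(60) == 42))    # round of 41.67
  sen <- build_sentence(pats, n_reps_per_class = 3, rate_percent = 100,
                        seed = 3)
  expect_equal(as.integer(table(sen$words$label)), rep(3L, 7))
  # gapless: words tile the grid exactly, label track aligned
  expect_equal(sen$words$start_bin[-1], utils::head(sen$words$end_bin, -1) + 1)
  expect_equal(length(sen$label_track), ncol(sen$pattern$grid))
  expect_equal(sen$label_track[sen$words$start_bin], sen$words$label)
  # warping preserves the class sequence
  sen2 <- build_sentence(pats, n_reps_per_class = 3, rate_percent = 200,
                         seed = 3)
  expect_equal(sen2$words$label, sen$words$label)
  expect_identical(build_sentence(pats, 2, 150, seed = 7)$words,
                   build_sentence(pats, 2, 150, seed = 7)$words)
})

test_that("pattern-to-current maps bins to unit pulses and conserves on-time", {
  g <- matrix(0, 8, 6)
  g[5, 3] <- 1
  tr <- pattern_to_current(stimulus_pattern(g, bin_ms = 10), dt = 0.1)
  on <- which(tr$values[5, ] > 0)
  expect_equal(range(on), c(201, 300))   # [20, 30) ms
  expect_equal(sum(tr$values > 0) * tr$dt, 10 * sum(g))
  expect_true(all(tr$values[-5, ] == 0))
  empty <- pattern_to_current(stimulus_pattern(matrix(0, 4, 3)))
  expect_true(all(empty$values == 0))
})
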