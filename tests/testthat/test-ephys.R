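test_that("median waveform is robust and alignment-correct", {
  tr <- biphasic <- scenegate:::biphasic_template(400, 25)
  m <- median_waveform(rbind(tr, tr, tr))
  expect_equal(m, tr)

  # constant offsets {0, 1, 2} -> pointwise median is the offset-1 trace
  m2 <- median_waveform(rbind(tr, tr + 1, tr + 2))
  expect_equal(m2, tr + 1)

  # one outlier trace is suppressed by the median
  out <- tr; out[10] <- out[10] + 50
  m3 <- median_waveform(rbind(tr, tr, out))
  expect_equal(m3, tr)

  expect_error(median_waveform(list(1:5, 1:6)), "equal lengths")
  expect_error(median_waveform(matrix(numeric(0), nrow = 0, ncol = 5)),
               "at least one")
})

test_that("peak-trough duration recovers constructed durations", {
  for (d in c(300, 400, 700, 1200)) {
    tr <- scenegate:::biphasic_template(d, 25)
    expect_lt(abs(peak_trough_duration(tr, 25) - d), 25)
  }
  # upsampling factor 1 vs 10 agree within one raw sampling interval
  tr <- scenegate:::biphasic_template(500, 25)
  d1 <- peak_trough_duration(tr, 25, upsample = 1)
  d10 <- peak_trough_duration(tr, 25, upsample = 10)
  expect_lt(abs(d1 - d10), 25)

  expect_error(peak_trough_duration(rep(1, 50), 25), "peak")
  expect_error(peak_trough_duration(seq(0, 1, length.out = 50), 25), "trough")

  # duration is an amplitude-free time measure
  expect_equal(peak_trough_duration(3.7 * tr, 25), peak_trough_duration(tr, 25))
})

test_that("baseline rate counts spikes in disjoint pre-scene windows", {
  onsets <- c(1, 2, 3, 4)
  spikes <- c(0.9, 1.9, 2.9, 3.9)       # one spike in each 250 ms window
  expect_equal(baseline_rate(spikes, onsets), 4)
  expect_equal(baseline_rate(numeric(0), onsets), 0)
  expect_error(baseline_rate(spikes, c(1, 1.1)), "overlap")

  # unbiased on homogeneous Poisson input (CI check at 200 windows)
  set.seed(31)
  t_end <- 600
  spikes2 <- cumsum(rexp(20 * t_end * 2, rate = 20))
  spikes2 <- spikes2[spikes2 < t_end]
  onsets2 <- seq(1, 598, by = 3)[1:200]
  est <- baseline_rate(spikes2, onsets2)
  expect_lt(abs(est - 20), 4 * sqrt(20 / (200 * 0.25)))
})

test_that("unit classification applies the strict duration and rate criteria", {
  th <- classifier_thresholds("long")
  expect_equal(classify_unit(500, 15, th)$label, "FSI")
  expect_equal(classify_unit(1200, 1, th)$label, "MSN")
  expect_equal(classify_unit(500, 1, th)$label, "unclassified")
  expect_equal(classify_unit(1200, 15, th)$label, "unclassified")
  expect_equal(classify_unit(500, 15, th, tan_flag = TRUE)$label, "TAN_excluded")

  # boundary values satisfy neither strict inequality and are flagged
  b <- classify_unit(800, 15, th)
  expect_equal(b$label, "unclassified")
  expect_true(b$boundary)
  expect_true(classify_unit(1200, 10, th)$boundary)

  # the short-amplifier profile moves the cutoff to 480 us
  ths <- classifier_thresholds("short")
  expect_equal(classify_unit(500, 15, ths)$label, "unclassified")
  expect_equal(classify_unit(500, 1, ths)$label, "MSN")
})

test_that("classification of recorded units is invariant to waveform amplitude", {
  u <- synthetic_unit(400, baseline_hz = 15, n_events = 100, seed = 2)
  c1 <- classify_unit_record(u)
  u$waveform <- u$waveform * 25
  c2 <- classify_unit_record(u)
  expect_equal(c1$label, c2$label)
  expect_equal(c1$duration_us, c2$duration_us)
})

test_that("the classifier recovers ground truth on units clear of the thresholds", {
  # 100 synthetic units with every parameter at least 20% away from every
  # classification threshold
  set.seed(77)
  n_each <- 50
  specs <- rbind(
    data.frame(dur = runif(n_each, 200, 640), rate = runif(n_each, 3, 30),
               truth = "FSI"),
    data.frame(dur = runif(n_each, 960, 1600), rate = runif(n_each, 0.5, 8),
               truth = "MSN")
  )
  hits <- 0
  for (i in seq_len(nrow(specs))) {
    u <- synthetic_unit(specs$dur[i], specs$rate[i], n_events = 400,
                        seed = 1000 + i)
    if (classify_unit_record(u)$label == specs$truth[i]) hits <- hits + 1
  }
  expect_equal(hits, nrow(specs))
})

test_that("responsiveness testing normalises rates and Bonferroni-corrects", {
  # identical pre/post rates: never significant
  pre <- matrix(rep(5, 20), ncol = 1)
  post <- matrix(rep(7, 20), ncol = 1)   # 7/0.35 = 5/0.25 = 20 Hz both
  r <- response_significance(post, pre)
  expect_false(r$significant)

  # n_comparisons = 8 -> per-test threshold 0.00625
  r8 <- response_significance(post, pre, n_comparisons = 8)
  expect_equal(r8$threshold, 0.00625)

  # a unit with 3x evoked rate over 50 trials is detected (power check)
  set.seed(12)
  pre2 <- matrix(rpois(50, 10 * 0.25), ncol = 1)
  post2 <- matrix(rpois(50, 30 * 0.35), ncol = 1)
  expect_true(response_significance(post2, pre2, n_comparisons = 8)$significant)

  # the exact permutation alternative agrees for small n
  set.seed(13)
  pre3 <- matrix(rpois(10, 2.5), ncol = 1)
  post3 <- matrix(rpois(10, 12), ncol = 1)
  rt <- response_significance(post3, pre3)
  rp <- response_significance(post3, pre3, method = "permutation")
  expect_equal(rt$significant, rp$significant)

  expect_error(response_significance(matrix(1), matrix(1)), "at least 2")
})

test_that("spike density has the Gaussian closed form and conserves mass", {
  tt <- seq(-0.1, 0.1, by = 0.001)
  d <- spike_density(0, tt)
  expect_equal(max(d), 1 / (0.015 * sqrt(2 * pi)), tolerance = 1e-6)
  expect_equal(tt[which.max(d)], 0)

  expect_equal(spike_density(numeric(0), tt), numeric(length(tt)))
  expect_error(spike_density(0, numeric(0)), "empty")
  expect_error(spike_density(0, seq(0, 1, by = 0.01)), "resolution")

  # mass conservation: integral ~ spikes per trial within 1%
  set.seed(44)
  spikes <- runif(200, 0.2, 0.8)
  grid <- seq(0, 1, by = 0.002)
  dens <- spike_density(spikes, grid, n_trials = 10)
  mass <- sum(dens) * 0.002
  expect_lt(abs(mass - 20) / 20, 0.01)
})
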