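# calcium_events: dF/F, event detection, activity metrics, alignment

test_that("compute_dff follows the F_min definition and gain invariance", {
  tr <- fluorescence_trace(0:3, c(100, 100, 200, 100))
  dff <- compute_dff(tr, baseline_fraction = 0.5)
  expect_equal(dff$F_min, 100)
  expect_equal(dff$dff, c(0, 0, 1, 0))
  # flat trace -> dff identically 0
  flat <- compute_dff(fluorescence_trace(0:9, rep(100, 10)))
  expect_true(all(flat$dff == 0))
  # gain invariance: scaling f_raw and f_bg by c leaves dff unchanged
  for (g in c(0.5, 5, 37)) {
    a <- compute_dff(fluorescence_trace(0:3, c(150, 150, 250, 150), 50))
    b <- compute_dff(fluorescence_trace(0:3, g * c(150, 150, 250, 150), g * 50))
    expect_equal(a$dff, b$dff, tolerance = 1e-12)
  }
  expect_error(compute_dff(fluorescence_trace(0:3, c(1, 1, 5, 1), 10)),
               class = "nm_baseline_error")
  expect_error(compute_dff(tr, baseline_fraction = 0.6),
               class = "nm_config_error")
})

test_that("detect_events: null, injected events, sub-threshold events", {
  t <- seq(0, 100, 0.1)
  # flat noiseless -> no events
  flat <- compute_dff(fluorescence_trace(t, rep(100, length(t))))
  expect_equal(nrow(detect_events(flat)), 0)
  # two injected kernels at 10 s and 70 s above noise -> exactly 2 events
  set.seed(5)
  found <- 0; close_peaks <- 0
  for (rep in 1:10) {
    noise_sd <- 0.01
    dff_true <- 0.5 * ca_kernel(t - 10) + 0.5 * ca_kernel(t - 70)
    f <- 100 * (1 + dff_true) + rnorm(length(t), 0, 100 * noise_sd)
    ev <- detect_events(compute_dff(fluorescence_trace(t, f)))
    if (nrow(ev) == 2) {
      found <- found + 1
      true_pk <- 10 + ca_kernel_peak_time()
      if (all(abs(ev$peak_t_s - c(true_pk, true_pk + 60)) <= 0.3))
        close_peaks <- close_peaks + 1
    }
  }
  expect_gte(found, 9)
  expect_gte(close_peaks, 9)
  # kernel at 1x noise SD stays undetected
  set.seed(6)
  f <- 100 * (1 + 0.01 * ca_kernel(t - 50)) + rnorm(length(t), 0, 1)
  ev <- detect_events(compute_dff(fluorescence_trace(t, f)))
  expect_equal(nrow(ev), 0)
})

test_that("max amplitude and total activity with scale invariance", {
  t <- seq(0, 30, 0.1)
  # rectangular event of dff = 1 lasting 10 s -> area 10
  f <- rep(100, length(t)); f[t >= 10 & t <= 20] <- 200
  dff <- compute_dff(fluorescence_trace(t, f), baseline_fraction = 0.5)
  ev <- detect_events(dff, smooth_s = 0)
  expect_equal(nrow(ev), 1)
  expect_equal(total_activity(dff, ev), 10, tolerance = 0.02)
  expect_equal(max_event_amplitude(ev), 1)
  # empty -> (0, 0)
  none <- ev[0, ]
  expect_equal(max_event_amplitude(none), 0)
  expect_equal(total_activity(dff, none), 0)
  # common gain scaling leaves both outputs unchanged
  dff5 <- compute_dff(fluorescence_trace(t, 5 * f), baseline_fraction = 0.5)
  ev5 <- detect_events(dff5, smooth_s = 0)
  expect_equal(total_activity(dff5, ev5), total_activity(dff, ev))
  expect_equal(max_event_amplitude(ev5), max_event_amplitude(ev))
  # additivity: totals equal the sum over events
  expect_equal(total_activity(dff, ev), sum(ev$area_dff_s))
})

test_that("align_to_stimuli windows, truncation, and responder classes", {
  proto <- stimulation_protocol(1, period_s = 30, total_duration_s = 150)
  t <- seq(0, 149.9, 0.1)
  flat <- compute_dff(fluorescence_trace(t, rep(100, length(t))))
  al <- align_to_stimuli(flat, proto)
  expect_equal(nrow(al), 5)
  expect_true(all(al$window_max_dff == 0))
  expect_false(any(al$truncated[1:4]))
  # first-dominant profile: window 1 strictly greatest
  sim <- gen_calcium_recording(proto, list(mito_spec("first-dominant")),
                               noise_sd = 0, seed = 2)
  d <- compute_dff(sim$traces[[1]])
  al1 <- align_to_stimuli(d, proto)
  expect_true(al1$window_max_dff[1] > max(al1$window_max_dff[-1]))
  # late-dominant profile: some later window dominates
  sim2 <- gen_calcium_recording(proto, list(mito_spec("late-dominant")),
                                noise_sd = 0, seed = 2)
  al2 <- align_to_stimuli(compute_dff(sim2$traces[[1]]), proto)
  expect_gt(which.max(al2$window_max_dff), 1)
  expect_error(align_to_stimuli(flat, stimulation_protocol(1, onset_times_s = c(0, 200))),
               class = "nm_validation_error")
})

test_that("normalize_group_activity maps the reference mean to 1", {
  out <- normalize_group_activity(list(ref = c(2, 2, 2), other = c(4, 4)),
                                  "ref")
  expect_equal(out$ref, c(1, 1, 1))
  expect_equal(out$other, c(2, 2))
  self <- normalize_group_activity(list(g = c(3, 5, 7)), "g")
  expect_equal(mean(self$g), 1)
  expect_error(normalize_group_activity(list(g = c(-1, 1)), "g"),
               class = "nm_normalization_error")
  # simulated groups with a true 2x activity ratio normalize to ~2
  set.seed(8)
  a <- rnorm(200, 10, 1); b <- rnorm(200, 20, 1)
  nn <- normalize_group_activity(list(ctrl = a, double = b), "ctrl")
  expect_equal(mean(nn$double), 2, tolerance = 0.05)
})
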