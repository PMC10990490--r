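# synthetic_data: camera model, generators, determinism, noise realism

test_that("render_frame: dark frame, determinism, clipping", {
  opt <- optics_model(read_noise_e = 0)
  dark <- render_frame(matrix(0, 16, 16), opt, px_um = 0.16, seed = 1)
  expect_true(all(dark == opt$offset_counts))
  opt2 <- optics_model()
  a <- render_frame(matrix(3, 16, 16), opt2, px_um = 0.16, seed = 42)
  b <- render_frame(matrix(3, 16, 16), opt2, px_um = 0.16, seed = 42)
  expect_identical(a, b)
  expect_true(all(a >= 0))
  expect_error(render_frame(matrix(-1, 4, 4), opt2, 0.16),
               class = "nm_config_error")
  expect_error(optics_model(psf_sigma_um = 0), class = "nm_config_error")
})

test_that("flat-field noise variance matches gain^2 x photons + (rn x gain)^2", {
  opt <- optics_model(photons_per_unit = 20, read_noise_e = 1.5,
                      gain_counts_per_photon = 2, offset_counts = 100)
  img <- render_frame(matrix(5, 350, 350), opt, px_um = 0.16, seed = 7)
  expect_gte(length(img), 1e5)
  expected <- opt$gain_counts_per_photon^2 * 100 +
    (opt$read_noise_e * opt$gain_counts_per_photon)^2
  expect_lt(abs(stats::var(as.vector(img)) / expected - 1), 0.05)
})

test_that("relative shot noise vanishes at high photon flux", {
  opt <- optics_model(photons_per_unit = 1e4, read_noise_e = 0,
                      offset_counts = 0)
  img <- render_frame(matrix(1, 100, 100), opt, px_um = 0.16, seed = 3)
  rel_sd <- stats::sd(img) / mean(img)
  expect_lt(rel_sd, 1.2 / sqrt(1e4) * 1.1)   # ~ sqrt(N)/N
})

test_that("gen_calcium_recording: null case, truth layout, errors", {
  proto <- stimulation_protocol(1, period_s = 30, total_duration_s = 150)
  sim <- gen_calcium_recording(proto, list(mito_spec("custom",
                                                     amplitudes = rep(0, 5))),
                               noise_sd = 0, seed = 1)
  expect_true(all(abs(sim$traces[[1]]$f_corr - 100) < 1e-12))
  sim2 <- gen_calcium_recording(proto, list(mito_spec("first-dominant")),
                                noise_sd = 0, seed = 1)
  expect_equal(nrow(sim2$truth$events), 5)   # 5 stimulus windows
  expect_error(gen_calcium_recording(proto, list(mito_spec(rise_s = 0.2)),
                                     dt_s = 0.25),
               class = "nm_sampling_error")
  expect_error(mito_spec("first-dominant", amplitudes = c(1, 2, 1)),
               class = "nm_config_error")
  expect_error(mito_spec("late-dominant", amplitudes = c(2, 1, 1)),
               class = "nm_config_error")
})

test_that("calcium kernel has unit analytic peak", {
  for (pars in list(c(0.2, 3), c(0.5, 5), c(0.1, 1))) {
    tstar <- ca_kernel_peak_time(pars[1], pars[2])
    expect_equal(ca_kernel(tstar, pars[1], pars[2]), 1, tolerance = 1e-12)
    # the analytic peak is a true maximum
    expect_lt(ca_kernel(tstar * 0.9, pars[1], pars[2]), 1)
    expect_lt(ca_kernel(tstar * 1.1, pars[1], pars[2]), 1)
  }
  expect_equal(ca_kernel(-1), 0)
})

test_that("gen_rogfp_scene: determinism and per-object substreams", {
  a <- gen_rogfp_scene(n_mito = 4, seed = 9)
  b <- gen_rogfp_scene(n_mito = 4, seed = 9)
  expect_identical(a$stack488$pages, b$stack488$pages)
  expect_identical(a$truth, b$truth)
  # adding an object does not reshuffle existing objects' truth
  c6 <- gen_rogfp_scene(n_mito = 5, seed = 9)
  expect_equal(c6$truth[1:4, c("x", "y", "z_focal", "r_true")],
               a$truth[, c("x", "y", "z_focal", "r_true")])
  expect_error(gen_rogfp_scene(n_mito = 0), class = "nm_generation_error")
})

test_that("draw_ratio_population honors mixture models", {
  uni <- draw_ratio_population(500, seed = 2)
  expect_lt(abs(mean(uni) - 0.03), 0.005)
  bi <- draw_ratio_population(500, list(means = c(0.05, 0.09),
                                        sds = c(0.002, 0.002),
                                        weights = c(0.5, 0.5)), seed = 2)
  expect_gt(mean(bi > 0.07), 0.3)
  expect_gt(mean(bi < 0.07), 0.3)
  expect_error(draw_ratio_population(10, list(means = -1, sds = 1)),
               class = "nm_config_error")
})

test_that("gen_frap_experiment: schedule and limiting cases", {
  ex <- gen_frap_experiment(seed = 1, noiseless = TRUE)
  expect_length(ex$stacks, 10)                       # pre, 0, 2..16
  expect_named(ex$stacks, c("pre", "0", as.character(seq(2, 16, 2))))
  # k -> infinity: all post-bleach timepoints at the plateau level
  sat <- gen_frap_experiment(k_per_min = 1e6, plateau_pct = 80,
                             seed = 1, noiseless = TRUE)
  s <- extract_frap_series(sat$stacks, sat$region, sat$background)
  expect_lt(diff(range(s$f[-1])) / mean(s$f[-1]), 1e-9)
  # plateau 0: immobile pool, all timepoints equal F0
  imm <- gen_frap_experiment(plateau_pct = 0, seed = 1, noiseless = TRUE)
  si <- extract_frap_series(imm$stacks, imm$region, imm$background)
  expect_lt(diff(range(si$f)) / si$f_pre, 1e-9)
  expect_error(gen_frap_experiment(plateau_pct = 101), class = "nm_config_error")
})

test_that("gen_transport_stream: kinematics, shapes, empty scene", {
  sim <- gen_transport_stream(list(particle_spec(2, 1, 5)), length_um = 40,
                              duration_s = 50, dt_s = 0.1, seed = 1,
                              noiseless = TRUE)
  expect_equal(length(sim$stream$pages), 500)
  # 2 um/s for 49.9 s from 5 um: exits the 40 um field; truth records it
  expect_equal(sim$truth$net_displacement_um, 2 * 49.9)
  empty <- gen_transport_stream(list(), length_um = 20, duration_s = 2,
                                dt_s = 0.2, seed = 1, noiseless = TRUE)
  expect_lt(diff(range(unlist(empty$stream$pages))), 1e-9)  # pure background
  fast <- gen_transport_stream(list(particle_spec(30, 1, 5)),
                               duration_s = 1, dt_s = 0.1, seed = 1,
                               noiseless = TRUE)
  expect_gt(length(attr(fast$truth, "warnings")), 0)  # undersampling recorded
})

test_that("gen_proximity_scene: guard-banded truth at all target fractions", {
  z <- gen_proximity_scene(n_mito = 10, target_fraction_within_1um = 0,
                           seed = 1, noiseless = TRUE)
  expect_true(all(z$truth$nearest_gap_um >= 1.5))
  full <- gen_proximity_scene(n_mito = 10, target_fraction_within_1um = 1,
                              seed = 1, noiseless = TRUE)
  expect_equal(sum(full$truth$proximal), 10)
  d <- gen_proximity_scene(n_mito = 100, target_fraction_within_1um = 0.61,
                           seed = 2, noiseless = TRUE)
  expect_equal(sum(d$truth$proximal), 61)
  expect_true(all(d$truth$nearest_gap_um[d$truth$proximal] < 1))
  expect_error(gen_proximity_scene(n_mito = 50, length_um = 100),
               class = "nm_placement_error")
})
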