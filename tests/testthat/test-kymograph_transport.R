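# kymograph_transport: kymograph construction, tracking, rates, velocities

test_that("kymograph shape and time-invariance for static scenes", {
  sim <- gen_transport_stream(list(particle_spec(0, 1, 10, motile = FALSE)),
                              length_um = 20, duration_s = 5, dt_s = 0.5,
                              seed = 1, noiseless = TRUE)
  kym <- build_kymograph(sim$stream, sim$path)
  expect_equal(nrow(kym$matrix), length(sim$stream$pages))
  expect_true(all(apply(kym$matrix, 2, function(col) diff(range(col))) < 1e-9))
  # path exiting the frame is a geometry error
  bad <- neurite_path(rbind(c(-5, 7), c(50, 7)))
  expect_error(build_kymograph(sim$stream, bad), class = "nm_geometry_error")
})

test_that("single-particle slope is recovered", {
  sim <- gen_transport_stream(list(particle_spec(2, 1, 5)), length_um = 40,
                              duration_s = 10, dt_s = 0.2, seed = 2,
                              noiseless = TRUE)
  kym <- build_kymograph(sim$stream, sim$path)
  ev <- detect_transport_events(kym)
  expect_length(ev, 1)
  fitv <- coef(lm(x_um ~ t_s, ev[[1]]$track))[2]
  expect_equal(unname(fitv), 2, tolerance = 1e-6)
  # noisy render stays within 5%
  simn <- gen_transport_stream(list(particle_spec(2, 1, 5)), length_um = 40,
                               duration_s = 10, dt_s = 0.2, seed = 3)
  evn <- detect_transport_events(build_kymograph(simn$stream, simn$path))
  expect_length(evn, 1)
  fitn <- coef(lm(x_um ~ t_s, evn[[1]]$track))[2]
  expect_equal(unname(fitn), 2, tolerance = 0.05)
})

test_that("motile and stationary particles are separated with directions", {
  cfg <- transport_config(11, n_motile = 3)
  sim <- gen_transport_stream(cfg$specs, length_um = cfg$length_um,
                              duration_s = cfg$duration_s, dt_s = cfg$dt_s,
                              seed = 11)
  ev <- detect_transport_events(build_kymograph(sim$stream, sim$path))
  expect_length(ev, 3)
  # match by starting position; directions must agree with truth
  for (e in ev) {
    i <- which.min(abs(cfg$starts[1:3] - e$track$x_um[1]))
    expect_equal(e$direction,
                 if (cfg$dir[i] > 0) "anterograde" else "retrograde")
  }
  expect_gte(length(attr(ev, "stationary")), 1)
  # empty kymograph
  empty <- gen_transport_stream(list(), length_um = 20, duration_s = 5,
                                dt_s = 0.5, seed = 1)
  expect_length(detect_transport_events(build_kymograph(empty$stream, empty$path)), 0)
})

test_that("reversal yields one event with both segment signs", {
  # synthetic kymograph: spot moves right 10 frames then left 10 frames
  n_f <- 19; n_x <- 60
  pos <- c(seq(10, 30, 2), seq(28, 14, -2))   # net +4 px after the reversal
  m <- matrix(10, n_f, n_x)
  for (f in seq_len(n_f))
    m[f, ] <- 10 + 100 * exp(-((seq_len(n_x) - 1 - pos[f])^2) / (2 * 1.3^2))
  kym <- structure(list(matrix = m, dt_s = 0.5, px_um = 0.2, dx_um = 0.2),
                   class = "kymograph")
  ev <- detect_transport_events(kym, min_net_displacement_um = 0.5)
  expect_length(ev, 1)
  vel <- instantaneous_velocities(ev)
  signs <- sign(vel$segments$v_um_s)
  expect_setequal(unique(signs), c(-1, 1))
})

test_that("pauses split segments and are excluded from speeds", {
  sim <- gen_transport_stream(list(particle_spec(2, 1, 3,
                                                 pauses = list(c(4, 9)))),
                              length_um = 40, duration_s = 15, dt_s = 0.25,
                              seed = 4, noiseless = TRUE)
  ev <- detect_transport_events(build_kymograph(sim$stream, sim$path))
  expect_length(ev, 1)
  vel <- instantaneous_velocities(ev)
  segs <- vel$segments
  expect_equal(nrow(segs), 2)
  expect_equal(segs$v_um_s, c(2, 2), tolerance = 0.02)
  expect_equal(vel$events$mean_speed_um_s, 2, tolerance = 0.02)
})

test_that("events_per_minute arithmetic", {
  expect_equal(events_per_minute(10, 50), 12)
  expect_equal(events_per_minute(0, 50), 0)
  expect_equal(events_per_minute(60, 60), 60)
  expect_error(events_per_minute(3, 0), class = "nm_validation_error")
  # rate linearity: pooling two equal-duration records
  expect_equal(events_per_minute(4 + 6, 50 + 50),
               (events_per_minute(4, 50) + events_per_minute(6, 50)) / 2)
})

test_that("left-right mirroring swaps directions and negates velocities", {
  cfg <- transport_config(21, n_motile = 2)
  sim <- gen_transport_stream(cfg$specs, length_um = cfg$length_um,
                              duration_s = cfg$duration_s, dt_s = cfg$dt_s,
                              seed = 21, noiseless = TRUE)
  kym <- build_kymograph(sim$stream, sim$path)
  mir <- structure(list(matrix = kym$matrix[, ncol(kym$matrix):1],
                        dt_s = kym$dt_s, px_um = kym$px_um,
                        dx_um = kym$dx_um), class = "kymograph")
  ev <- detect_transport_events(kym)
  evm <- detect_transport_events(mir)
  expect_equal(length(ev), length(evm))
  vel <- instantaneous_velocities(ev)
  velm <- instantaneous_velocities(evm)
  expect_setequal(round(velm$segments$v_um_s, 4),
                  round(-vel$segments$v_um_s, 4))
  swap <- c(anterograde = "retrograde", retrograde = "anterograde")
  expect_equal(sort(vapply(evm, `[[`, "", "direction")),
               sort(unname(swap[vapply(ev, `[[`, "", "direction")])))
  expect_equal(sort(abs(velm$segments$v_um_s)), sort(abs(vel$segments$v_um_s)),
               tolerance = 1e-6)
})
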