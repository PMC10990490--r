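# frap_analysis: extraction, normalization, recovery fit, curve
# comparison, linescan puncta areas

test_that("extract_frap_series: static sample, schedule and bounds checks", {
  ex <- gen_frap_experiment(seed = 3, noiseless = TRUE)
  static <- ex$stacks[rep("pre", 10)]
  names(static) <- names(ex$stacks)
  s <- extract_frap_series(static, ex$region, ex$background)
  expect_lt(diff(range(c(s$f_pre, s$f))), 1e-9)
  expect_error(extract_frap_series(ex$stacks[1:9], ex$region, ex$background),
               class = "nm_schedule_error")
  outside <- roi("bad", "rectangle", rbind(c(100, 10), c(130, 20)))
  expect_error(extract_frap_series(ex$stacks, outside, ex$background),
               class = "nm_geometry_error")
})

test_that("noiseless render reproduces the analytic recovery curve", {
  ex <- gen_frap_experiment(k_per_min = 0.2, plateau_pct = 80, seed = 1,
                            noiseless = TRUE)
  s <- extract_frap_series(ex$stacks, ex$region, ex$background)
  sp <- normalize_frap(s, "percent")
  expected <- 80 * (1 - exp(-0.2 * sp$t_min))
  expect_equal(sp$f_norm, expected, tolerance = 1e-6)
  expect_equal(sp$f_pre_norm, 100)
  fit <- fit_recovery(sp)
  expect_equal(fit$k_per_min, 0.2, tolerance = 1e-6)
  expect_equal(fit$plateau, 80, tolerance = 1e-6)
})

test_that("normalization endpoint identities and failure modes", {
  t_min <- seq(0, 16, 2)
  # full recovery after bleach -> percent 100 at every t > 0
  s <- frap_series("a", t_min, c(10, rep(100, 8)), f_pre = 100)
  p <- normalize_frap(s, "percent")
  expect_equal(p$f_norm[1], 0)
  expect_true(all(p$f_norm[-1] == 100))
  # no recovery -> percent and subtract identically 0
  s0 <- frap_series("a", t_min, rep(10, 9), f_pre = 100)
  expect_true(all(normalize_frap(s0, "percent")$f_norm == 0))
  expect_true(all(normalize_frap(s0, "subtract")$f_norm == 0))
  # failed bleach
  sbad <- frap_series("a", t_min, rep(100, 9), f_pre = 90)
  expect_error(normalize_frap(sbad, "percent"), class = "nm_normalization_error")
  # per-animal endpoint identity holds for arbitrary noisy series
  set.seed(3)
  for (i in 1:5) {
    f <- c(10, 10 + cumsum(abs(rnorm(8, 5))))
    pi <- normalize_frap(frap_series("x", t_min, f, f_pre = 120), "percent")
    expect_equal(pi$f_norm[1], 0)
    expect_equal(pi$f_pre_norm, 100)
  }
})

test_that("fit_recovery inverts exact data and flags degenerate input", {
  t_min <- seq(0, 16, 2)
  y <- 80 * (1 - exp(-0.2 * t_min))
  s <- frap_series("a", t_min, y, f_pre = 100, norm_mode = "percent",
                   f_norm = y)
  fit <- fit_recovery(s)
  expect_equal(fit$plateau, 80, tolerance = 1e-6)
  expect_equal(fit$k_per_min, 0.2, tolerance = 1e-6)
  expect_lt(fit$rss, 1e-12)
  # noiseless fitted curve is non-decreasing over the window
  tt <- seq(0, 16, 0.1)
  expect_true(all(diff(fit$plateau * (1 - exp(-fit$k_per_min * tt))) >= 0))
  z <- frap_series("a", t_min, rep(0, 9), f_pre = 100, norm_mode = "percent",
                   f_norm = rep(0, 9))
  fz <- fit_recovery(z)
  expect_true(fz$flagged)
  expect_lt(abs(fz$plateau), 1e-6)
  expect_error(fit_recovery(frap_series("a", c(0, 2), c(0, 1), 10)),
               class = "nm_df_error")
})

test_that("curve comparison: null identity and nested-model invariants", {
  g <- make_frap_group(4, 80, 0.2, 0)
  cmp <- compare_recovery_curves(list(a = g, b = g))
  expect_equal(cmp$F, 0, tolerance = 1e-8)
  expect_equal(cmp$p_raw, 1, tolerance = 1e-6)
  # SS_shared >= SS_separate always, F >= 0
  set.seed(9)
  for (i in 1:5) {
    ga <- make_frap_group(5, 70, 0.25, 5)
    gb <- make_frap_group(5, 50, 0.15, 5)
    cc <- compare_recovery_curves(list(a = ga, b = gb))
    expect_gte(cc$F, 0)
  }
  # control-family restriction and Bonferroni factor
  cc3 <- compare_recovery_curves(list(ctrl = make_frap_group(4, 80, 0.2, 2),
                                      g1 = make_frap_group(4, 60, 0.2, 2),
                                      g2 = make_frap_group(4, 40, 0.2, 2)),
                                 control = "ctrl")
  expect_equal(nrow(cc3), 2)
  expect_equal(cc3$p_adj, pmin(1, cc3$p_raw * 2))
  expect_error(compare_recovery_curves(list(
    a = list(frap_series("x", c(0, 2, 4), c(0, 1, 2), 10)),
    b = list(frap_series("y", c(0, 2), c(0, 1), 10)))),
    class = "nm_df_error")
})

test_that("linescan puncta areas: null profile, known areas, linearity", {
  nr <- 24; nc <- 200
  path <- neurite_path(rbind(c(2, 11), c(nc - 3, 11)), width_px = 20L)
  flat <- matrix(10, nr, nc)
  p0 <- prebleach_puncta_areas(flat, path, px_um = 0.2)
  expect_equal(nrow(p0$peaks), 0)
  expect_equal(p0$mean_area, 0)
  expect_true(p0$no_puncta)
  # two triangular puncta of known area (half-width 4 px, heights 50/30)
  tri <- function(center, h, half) {
    v <- rep(0, nc)
    for (d in -half:half) v[center + d] <- h * (1 - abs(d) / (half + 1))
    v
  }
  prof <- 10 + tri(60, 50, 4) + tri(140, 30, 4)
  img <- matrix(rep(prof, each = nr), nr, nc)
  pp <- prebleach_puncta_areas(img, path, px_um = 0.2)
  expect_equal(nrow(pp$peaks), 2)
  # expected areas: trapezoid of the sampled triangle above zero baseline
  exp_area <- function(h, half) sum(diff((-half:half) * 0.2) *
    (head(h * (1 - abs(-half:half) / (half + 1)), -1) +
     tail(h * (1 - abs(-half:half) / (half + 1)), -1)) / 2)
  expect_equal(pp$peaks$area[1], exp_area(50, 4), tolerance = 0.05)
  expect_equal(pp$peaks$area[2], exp_area(30, 4), tolerance = 0.05)
  # doubling illumination doubles areas
  pp2 <- prebleach_puncta_areas(matrix(rep(2 * prof, each = nr), nr, nc),
                                path, px_um = 0.2)
  expect_equal(pp2$peaks$area, 2 * pp$peaks$area, tolerance = 0.02)
  expect_error(prebleach_puncta_areas(flat,
    neurite_path(rbind(c(0, 5), c(1, 5))), px_um = 0.2),
    class = "nm_geometry_error")
})

test_that("frap exclusion integrates with per-timepoint outlier flags", {
  flags <- list(a1 = c(rep(TRUE, 5), rep(FALSE, 4)),
                a2 = c(rep(TRUE, 4), rep(FALSE, 5)),
                a3 = rep(FALSE, 9))
  res <- frap_exclusion(flags)
  expect_equal(res$excluded, "a1")      # 5/9 >= 0.5
  expect_setequal(res$kept, c("a2", "a3"))
})
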