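# Shared fixtures, all generated in code.

# FRAP group of n animals on the standard schedule with Gaussian noise,
# already in percent-normalized form.
make_frap_group <- function(n, plateau, k, sd, t_min = seq(0, 16, 2)) {
  lapply(seq_len(n), function(i) {
    y <- plateau * (1 - exp(-k * t_min)) + rnorm(length(t_min), 0, sd)
    frap_series(paste0("animal_", i), t_min, y, f_pre = 100,
                norm_mode = "percent", f_norm = y)
  })
}

# Analytic displacement of a particle with pauses (independent of the
# generator's internal kinematics).
particle_displacement <- function(v, d, pauses, t) {
  m <- t
  for (p in pauses) m <- m - pmin(pmax(t - p[1], 0), p[2] - p[1])
  d * v * m
}

# Build a non-crossing transport scene: particles are placed sequentially
# so every pair keeps >= 2.5 um separation at all times (the spec's
# "well separated" precondition), plus two stationary particles.
transport_config <- function(seed, duration_s = 25, dt_s = 0.25,
                             n_motile = NULL, n_stationary = 2L) {
  set.seed(seed * 7 + 1)
  n_mot <- n_motile %||% sample(3:5, 1)
  t <- seq(0, duration_s, by = dt_s)
  vs <- runif(n_mot, 0.5, 2.5)
  ds <- sample(c(-1, 1), n_mot, replace = TRUE)
  pauses <- lapply(seq_len(n_mot), function(i)
    if (runif(1) < 0.3) list(c(8, 11)) else list())
  disps <- lapply(seq_len(n_mot), function(i)
    particle_displacement(vs[i], ds[i], pauses[[i]], t))
  disps <- c(disps, rep(list(rep(0, length(t))), n_stationary))
  starts <- numeric(length(disps))
  starts[1] <- 2 + max(0, -min(disps[[1]]))
  for (i in seq_along(disps)[-1])
    starts[i] <- starts[i - 1] + max(disps[[i - 1]] - disps[[i]]) + 2.5
  len <- starts[length(starts)] + max(disps[[length(disps)]]) + 2
  specs <- c(lapply(seq_len(n_mot), function(i)
    particle_spec(vs[i], ds[i], starts[i], pauses[[i]])),
    lapply(seq_len(n_stationary), function(j)
      particle_spec(0, 1, starts[n_mot + j], motile = FALSE)))
  list(specs = specs, length_um = len, n_motile = n_mot,
       v = vs, dir = ds, starts = starts, duration_s = duration_s,
       dt_s = dt_s)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
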