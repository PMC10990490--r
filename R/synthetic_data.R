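# Synthetic-microscopy generators with recorded ground truth.
#
# Every generator takes a single seed that fans out to per-object and
# per-frame substreams (counter-based), so adding one object never
# reshuffles the noise of the others, and identical seeds reproduce
# bit-identical outputs. `noiseless = TRUE` returns the deterministic
# camera expectation (offset + gain * photons_per_unit * blur(field)),
# the baseline for the end-to-end identity tests.

#' Camera/optics model for rendering
#'
#' Emulates an EMCCD detection chain: Gaussian PSF blur, Poisson photon
#' shot noise, Gaussian read noise, camera offset and gain.
#'
#' @param psf_sigma_um Gaussian PSF sigma in microns.
#' @param photons_per_unit expected photons per model brightness unit.
#' @param read_noise_e read-noise SD in electrons (rms).
#' @param offset_counts camera baseline in counts.
#' @param gain_counts_per_photon counts per detected photon.
#' @return an `optics_model`.
#' @export
optics_model <- function(psf_sigma_um = 0.15, photons_per_unit = 10,
                         read_noise_e = 1.5, offset_counts = 100,
                         gain_counts_per_photon = 2) {
  if (psf_sigma_um <= 0 || photons_per_unit <= 0 || read_noise_e < 0 ||
      offset_counts < 0 || gain_counts_per_photon <= 0)
    nm_stop("invalid optics model parameters", "nm_config_error")
  structure(list(psf_sigma_um = psf_sigma_um,
                 photons_per_unit = photons_per_unit,
                 read_noise_e = read_noise_e,
                 offset_counts = offset_counts,
                 gain_counts_per_photon = gain_counts_per_photon),
            class = "optics_model")
}

#' Render one camera frame from a brightness field
#'
#' `output = offset + gain * Poisson(photons_per_unit * blur(field)) +
#' N(0, read_noise_e * gain)`, clipped at 0. Deterministic given `seed`;
#' `noiseless = TRUE` returns the expectation instead.
#'
#' @param field 2-D non-negative brightness matrix (model units).
#' @param optics an [optics_model()].
#' @param px_um pixel size (converts PSF sigma to pixels).
#' @param seed integer seed (NULL: use current RNG stream).
#' @param noiseless logical.
#' @return intensity matrix (counts).
#' @export
render_frame <- function(field, optics, px_um, seed = NULL, noiseless = FALSE) {
  stopifnot(inherits(optics, "optics_model"))
  if (any(!is.finite(field)) || any(field < 0))
    nm_stop("brightness field must be finite and >= 0", "nm_config_error")
  mu <- optics$photons_per_unit * blur2d(field, optics$psf_sigma_um / px_um)
  if (noiseless)
    return(optics$offset_counts + optics$gain_counts_per_photon * mu)
  with_seed(seed, {
    n <- length(mu)
    counts <- optics$offset_counts +
      optics$gain_counts_per_photon * stats::rpois(n, as.vector(mu)) +
      stats::rnorm(n, 0, optics$read_noise_e * optics$gain_counts_per_photon)
    matrix(pmax(counts, 0), nrow(mu), ncol(mu))
  })
}

## ---- calcium ---------------------------------------------------------------

#' Unit-peak calcium transient kernel (difference of exponentials)
#'
#' `K(t) = (exp(-t/decay) - exp(-t/rise)) / K_max` for `t >= 0`, 0 before;
#' normalized so the continuous maximum is exactly 1 (at
#' `t* = rise*decay/(decay-rise) * log(decay/rise)`).
#'
#' @param t_s time from event onset, seconds.
#' @param rise_s rise time constant (default 0.2 s).
#' @param decay_s decay time constant (default 3 s); must exceed `rise_s`.
#' @export
ca_kernel <- function(t_s, rise_s = 0.2, decay_s = 3) {
  if (rise_s >= decay_s) nm_stop("rise_s must be < decay_s", "nm_config_error")
  tstar <- rise_s * decay_s / (decay_s - rise_s) * log(decay_s / rise_s)
  kmax <- exp(-tstar / decay_s) - exp(-tstar / rise_s)
  ifelse(t_s < 0, 0, (exp(-t_s / decay_s) - exp(-t_s / rise_s)) / kmax)
}

#' Time of the kernel's continuous maximum
#' @inheritParams ca_kernel
#' @export
ca_kernel_peak_time <- function(rise_s = 0.2, decay_s = 3) {
  rise_s * decay_s / (decay_s - rise_s) * log(decay_s / rise_s)
}

#' Describe one simulated mitochondrion's calcium response
#'
#' @param response_class `"first-dominant"` (first stimulus evokes the
#'   strictly largest response), `"late-dominant"` (a later stimulus
#'   dominates) or `"custom"`.
#' @param amplitudes per-stimulus peak dF/F_min amplitudes; defaults are
#'   drawn per class.
#' @param n_stimuli used to build default amplitude profiles.
#' @param rise_s,decay_s kernel time constants.
#' @param baseline baseline fluorescence (a.u.).
#' @export
mito_spec <- function(response_class = c("first-dominant", "late-dominant", "custom"),
                      amplitudes = NULL, n_stimuli = 5L,
                      rise_s = 0.2, decay_s = 3, baseline = 100) {
  response_class <- match.arg(response_class)
  if (is.null(amplitudes)) {
    amplitudes <- switch(response_class,
      "first-dominant" = 1.5 * 0.65^(seq_len(n_stimuli) - 1),
      "late-dominant"  = {
        a <- 1.4 * 0.7^abs(seq_len(n_stimuli) - 3); a[1] <- min(a[1], 0.35); a
      },
      "custom" = nm_stop("custom class needs explicit amplitudes", "nm_config_error"))
  }
  if (response_class == "first-dominant" &&
      !(amplitudes[1] > max(amplitudes[-1])))
    nm_stop("first-dominant requires amplitude_1 strictly largest", "nm_config_error")
  if (response_class == "late-dominant" && which.max(amplitudes) == 1L)
    nm_stop("late-dominant requires a later amplitude largest", "nm_config_error")
  list(response_class = response_class, amplitudes = amplitudes,
       rise_s = rise_s, decay_s = decay_s, baseline = baseline)
}

#' Simulate stimulus-locked calcium recordings with ground truth
#'
#' Each trace is `baseline * (1 + sum_i amplitude_i K(t - onset_i))` plus
#' Gaussian noise of SD `noise_sd * baseline`, mimicking mitochondrial
#' GCaMP responses to periodic optogenetic stimulation.
#'
#' @param protocol a [stimulation_protocol()] fitting within `duration_s`.
#' @param mito_specs list of [mito_spec()]s.
#' @param duration_s recording length (default 150 s, a 2.5 min recording).
#' @param dt_s sampling interval (default 0.1 s); must be < rise_s.
#' @param noise_sd fractional noise SD relative to baseline (default 0.01,
#'   the shot-noise scale of a bright indicator at which the lowest-5%
#'   baseline estimator stays within 2% of the true baseline).
#' @param bg_level constant background fluorescence added to `f_raw`.
#' @param seed integer seed.
#' @return list with `traces` (list of `fluorescence_trace`) and `truth`
#'   (`$events`: one row per mito x stimulus with onset, amplitude, sampled
#'   peak dF/F and window area; `$mitos`: per-trace summary).
#' @export
gen_calcium_recording <- function(protocol, mito_specs, duration_s = 150,
                                  dt_s = 0.1, noise_sd = 0.01, bg_level = 50,
                                  seed = 1L) {
  stopifnot(inherits(protocol, "stimulation_protocol"))
  onsets <- protocol$onset_times_s
  if (max(onsets) >= duration_s)
    nm_stop("protocol does not fit within duration_s", "nm_config_error")
  t <- seq(0, duration_s - dt_s / 2, by = dt_s)
  period <- protocol$period_s %||% (duration_s - max(onsets))
  traces <- list(); ev <- list(); mt <- list()
  for (m in seq_along(mito_specs)) {
    sp <- mito_specs[[m]]
    if (dt_s >= sp$rise_s)
      nm_stop("dt_s must be smaller than the kernel rise time", "nm_sampling_error")
    amps <- rep_len(sp$amplitudes, length(onsets))
    dff_clean <- rep(0, length(t))
    for (i in seq_along(onsets))
      dff_clean <- dff_clean + amps[i] * ca_kernel(t - onsets[i], sp$rise_s, sp$decay_s)
    f_corr <- sp$baseline * (1 + dff_clean)
    if (noise_sd > 0)
      f_corr <- f_corr + with_seed(substream_seed(seed, m),
                                   stats::rnorm(length(t), 0, noise_sd * sp$baseline))
    traces[[m]] <- fluorescence_trace(t_s = t, f_raw = f_corr + bg_level,
                                      f_bg = rep(bg_level, length(t)),
                                      source_id = sprintf("mito_%02d", m))
    for (i in seq_along(onsets)) {
      win <- t >= onsets[i] & t < onsets[i] + period
      ev[[length(ev) + 1L]] <- data.frame(
        source_id = sprintf("mito_%02d", m), stimulus_index = i,
        onset_s = onsets[i], amplitude = amps[i],
        peak_dff = max(dff_clean[win]),
        peak_t_s = t[win][which.max(dff_clean[win])],
        area_dff_s = trapz(t[win], dff_clean[win]))
    }
    mt[[m]] <- data.frame(source_id = sprintf("mito_%02d", m),
                          response_class = sp$response_class,
                          baseline = sp$baseline,
                          max_dff = max(dff_clean),
                          total_activity = trapz(t, dff_clean))
  }
  list(traces = traces,
       truth = list(events = do.call(rbind, ev), mitos = do.call(rbind, mt),
                    seed = seed, dt_s = dt_s, duration_s = duration_s))
}

## ---- roGFP ratiometric scenes ---------------------------------------------

#' Draw per-mitochondrion true roGFP ratios from a population model
#'
#' @param n number of draws.
#' @param model `list(means=, sds=)` single component, or
#'   `list(means=c(m1,m2), sds=c(s1,s2), weights=c(w1,w2))` mixture.
#'   Defaults: unstimulated populations center near 0.03; activity-shifted
#'   bimodal populations near 0.05 and 0.09.
#' @param seed integer seed.
#' @export
draw_ratio_population <- function(n, model = list(means = 0.03, sds = 0.01),
                                  seed = 1L) {
  means <- model$means; sds <- model$sds
  if (any(means <= 0)) nm_stop("ratio means must be > 0", "nm_config_error")
  w <- model$weights %||% rep(1 / length(means), length(means))
  with_seed(seed, {
    comp <- sample.int(length(means), n, replace = TRUE, prob = w)
    pmax(stats::rnorm(n, means[comp], sds[comp]), 1e-4)
  })
}

#' Simulate a dual-excitation roGFP z-stack scene
#'
#' Mitochondria are rendered as elongated blobs along a neurite in both
#' excitation channels across a z-stack; the 405-channel brightness of
#' mitochondrion i is `r_i` times its 488 brightness, so the
#' background-corrected 405/488 ratio of object i is exactly `r_i` in the
#' noiseless expectation.
#'
#' @param n_mito number of mitochondria (>= 1).
#' @param ratio_model passed to [draw_ratio_population()].
#' @param n_z number of z planes (default 5).
#' @param amp_488 peak 488-channel brightness per object (model units).
#' @param bg_488,bg_405 uniform background brightness per channel.
#' @param optics an [optics_model()].
#' @param px_um pixel size (default 0.16 um/px).
#' @param dz_um plane spacing (default 0.25 um).
#' @param seed integer seed.
#' @param noiseless render expectations instead of noisy frames.
#' @return list: `stack405`, `stack488` (z-stacks), `rois` (per-object
#'   signal rectangle with linked background rectangle), `truth`
#'   (mito_id, x, y, z_focal, r_true).
#' @export
gen_rogfp_scene <- function(n_mito = 6L,
                            ratio_model = list(means = 0.03, sds = 0.01),
                            n_z = 5L, amp_488 = 60, bg_488 = 2, bg_405 = 1.5,
                            optics = optics_model(), px_um = 0.16,
                            dz_um = 0.25, seed = 1L, noiseless = FALSE) {
  if (n_mito < 1L) nm_stop("n_mito must be >= 1", "nm_generation_error")
  if (n_z < 3L) nm_stop("need >= 3 z planes", "nm_generation_error")
  spacing <- 26L; margin <- 16L
  nc <- 2L * margin + spacing * (n_mito - 1L) + 1L
  nr <- 40L
  sx <- 3; sy <- 1.6; sz <- 1.2
  # one substream per object: adding a mitochondrion never reshuffles others
  geom <- do.call(rbind, lapply(seq_len(n_mito), function(i)
    with_seed(substream_seed(seed, 300L + i), data.frame(
      mito_id = sprintf("mito_%02d", i),
      x = margin + spacing * (i - 1L) + stats::runif(1, -2, 2),
      y = (nr - 1) / 2 + stats::runif(1, -1.5, 1.5),
      z_focal = sample(2:(n_z - 1L), 1L)))))
  geom$r_true <- vapply(seq_len(n_mito), function(i)
    draw_ratio_population(1L, ratio_model, seed = substream_seed(seed, 600L + i)), 0)
  xs <- matrix(rep(0:(nc - 1), each = nr), nr, nc)
  ys <- matrix(rep(0:(nr - 1), nc), nr, nc)
  blobs <- lapply(seq_len(n_mito), function(i)
    exp(-((xs - geom$x[i])^2) / (2 * sx^2) - ((ys - geom$y[i])^2) / (2 * sy^2)))
  pages405 <- pages488 <- vector("list", n_z)
  for (z in seq_len(n_z)) {
    f488 <- matrix(bg_488, nr, nc); f405 <- matrix(bg_405, nr, nc)
    for (i in seq_len(n_mito)) {
      wz <- exp(-((z - geom$z_focal[i])^2) / (2 * sz^2))
      f488 <- f488 + amp_488 * wz * blobs[[i]]
      f405 <- f405 + amp_488 * geom$r_true[i] * wz * blobs[[i]]
    }
    pages488[[z]] <- render_frame(f488, optics, px_um,
                                  seed = substream_seed(seed, 100L + z),
                                  noiseless = noiseless)
    pages405[[z]] <- render_frame(f405, optics, px_um,
                                  seed = substream_seed(seed, 200L + z),
                                  noiseless = noiseless)
  }
  rois <- list()
  for (i in seq_len(n_mito)) {
    cx <- geom$x[i]; cy <- geom$y[i]
    rois[[2L * i - 1L]] <- roi(sprintf("mito_%02d", i), "rectangle",
                               rbind(c(cx - 6, cy - 4), c(cx + 6, cy + 4)),
                               background_id = sprintf("bg_%02d", i))
    rois[[2L * i]] <- roi(sprintf("bg_%02d", i), "rectangle",
                          rbind(c(cx - 6, 1), c(cx + 6, 9)))
  }
  mk <- function(pages, nm) image_stack(pages, "z", dz_um = dz_um, px_um = px_um,
                                        excitation_nm = nm)
  list(stack405 = mk(pages405, 405L), stack488 = mk(pages488, 488L),
       rois = rois, truth = geom, seed = seed)
}

## ---- FRAP ------------------------------------------------------------------

#' Simulate a FRAP experiment with known recovery rate and plateau
#'
#' A neurite band is rendered across a z-stack at each timepoint of the
#' schedule (pre-bleach, 0 min, then every `schedule_min` minutes). Inside
#' the bleach zone the band brightness follows
#' `F(t) = F0 + (Fpre - F0) * (plateau_pct/100) * (1 - exp(-k t))`.
#'
#' @param k_per_min recovery rate constant (> 0, per minute).
#' @param plateau_pct mobile fraction as percent of the bleached signal
#'   (0..100).
#' @param prebleach_level pre-bleach band brightness (model units).
#' @param schedule_min post-bleach acquisition times, minutes
#'   (default every 2 min out to 16 min).
#' @param bleach_frac residual fraction immediately after bleach
#'   (`F0 = bleach_frac * Fpre`).
#' @param n_z planes per stack (focal plane is brightest, so a
#'   max-intensity projection returns it exactly).
#' @param optics,px_um,dz_um rendering calibration.
#' @param seed integer seed.
#' @param noiseless render expectations.
#' @return list: `stacks` (named list, "pre", "0", then minutes), `region`
#'   and `background` ROIs, `truth` (k, plateau_pct, Fpre, F0, t_min).
#' @export
gen_frap_experiment <- function(k_per_min = 0.2, plateau_pct = 80,
                                prebleach_level = 100,
                                schedule_min = seq(2, 16, by = 2),
                                bleach_frac = 0.05, n_z = 5L,
                                optics = optics_model(), px_um = 0.16,
                                dz_um = 0.25, seed = 1L, noiseless = FALSE) {
  if (plateau_pct < 0 || plateau_pct > 100)
    nm_stop("plateau_pct must be in [0, 100]", "nm_config_error")
  if (k_per_min <= 0) nm_stop("k_per_min must be > 0", "nm_config_error")
  nr <- 30L; nc <- 120L
  band_rows <- 13:19          # 1-based rows (y = 12..18)
  bleach_x <- c(30, 89)       # 0-based inclusive column range
  if (bleach_x[2] >= nc) nm_stop("bleach region outside image", "nm_geometry_error")
  fpre <- prebleach_level; f0 <- bleach_frac * prebleach_level
  t_min <- c(NA, 0, schedule_min)            # NA marks pre-bleach
  labels <- c("pre", "0", as.character(schedule_min))
  level <- function(t) f0 + (fpre - f0) * (plateau_pct / 100) * (1 - exp(-k_per_min * t))
  zw <- exp(-((seq_len(n_z) - (n_z + 1) / 2)^2) / (2 * 1.5^2))
  zw <- zw / max(zw)
  stacks <- list()
  for (i in seq_along(labels)) {
    inside <- if (is.na(t_min[i])) fpre else level(t_min[i])
    base <- matrix(0, nr, nc)
    base[band_rows, ] <- fpre
    base[band_rows, (bleach_x[1] + 1):(bleach_x[2] + 1)] <- inside
    pages <- lapply(seq_len(n_z), function(z)
      render_frame(base * zw[z], optics, px_um,
                   seed = substream_seed(seed, 1000L * i + z),
                   noiseless = noiseless))
    stacks[[labels[i]]] <- image_stack(pages, "z", dz_um = dz_um, px_um = px_um,
                                       excitation_nm = 488L)
  }
  region <- roi("frap_region", "rectangle", rbind(c(38, 13), c(81, 17)))
  background <- roi("frap_bg", "rectangle", rbind(c(38, 0), c(81, 4)))
  list(stacks = stacks, region = region, background = background,
       truth = list(k_per_min = k_per_min, plateau_pct = plateau_pct,
                    Fpre = fpre, F0 = f0, t_min = c(0, schedule_min),
                    labels = labels, seed = seed))
}

## ---- transport streams -----------------------------------------------------

#' Describe one simulated transported particle
#'
#' @param v_um_s speed in um/s (>= 0).
#' @param direction +1 (anterograde, increasing arc length) or -1.
#' @param start_um initial arc-length position.
#' @param pauses list of `c(start_s, end_s)` intervals during which the
#'   particle does not move.
#' @param motile logical; stationary particles never move.
#' @export
particle_spec <- function(v_um_s, direction = 1, start_um = 0,
                          pauses = list(), motile = TRUE) {
  stopifnot(direction %in% c(-1, 1), v_um_s >= 0)
  list(v_um_s = v_um_s, direction = direction, start_um = start_um,
       pauses = pauses, motile = motile)
}

particle_position <- function(sp, t_s) {
  if (!sp$motile) return(rep(sp$start_um, length(t_s)))
  moving <- t_s
  for (p in sp$pauses)
    moving <- moving - pmin(pmax(t_s - p[1], 0), p[2] - p[1])
  sp$start_um + sp$direction * sp$v_um_s * moving
}

#' Simulate an image stream of particles moving along a photobleached neurite
#'
#' @param particles list of [particle_spec()]s.
#' @param length_um neurite length.
#' @param duration_s stream duration (50 s streams are the kymograph
#'   convention here).
#' @param dt_s frame interval (default 0.1 s, a 100 ms exposure stream).
#' @param amp particle peak brightness (model units).
#' @param bg_level residual background after photobleaching.
#' @param spot_sigma_px particle Gaussian radius in pixels.
#' @param optics,px_um rendering calibration.
#' @param seed integer seed.
#' @param noiseless render expectations.
#' @return list: `stream` (time-axis `image_stack`), `path`
#'   (`neurite_path` along the neurite), `truth` (per-particle kinematics;
#'   `warnings` attribute lists any undersampling concerns).
#' @export
gen_transport_stream <- function(particles, length_um = 40, duration_s = 50,
                                 dt_s = 0.1, amp = 40, bg_level = 0.5,
                                 spot_sigma_px = 1.3,
                                 optics = optics_model(psf_sigma_um = 0.05),
                                 px_um = 0.2, seed = 1L, noiseless = FALSE) {
  if (dt_s <= 0) nm_stop("dt_s must be > 0", "nm_config_error")
  nc <- round(length_um / px_um); nr <- 15L; y0 <- 7
  n_frames <- round(duration_s / dt_s)
  t <- (seq_len(n_frames) - 1L) * dt_s
  warnings <- character(0)
  for (sp in particles) {
    if (sp$start_um < 0 || sp$start_um > length_um)
      nm_stop("particle start position outside neurite", "nm_config_error")
    if (sp$motile && sp$v_um_s * dt_s > 1.0)
      warnings <- c(warnings, sprintf(
        "step %.2f um/frame exceeds the resolvable tracking step", sp$v_um_s * dt_s))
  }
  pos <- if (length(particles))
    matrix(vapply(particles, particle_position, numeric(n_frames), t_s = t),
           nrow = n_frames)
  else matrix(0, n_frames, 0L)
  gy <- exp(-((0:(nr - 1)) - y0)^2 / (2 * spot_sigma_px^2))
  xs <- 0:(nc - 1)
  pages <- vector("list", n_frames)
  for (k in seq_len(n_frames)) {
    fx <- rep(0, nc)
    if (length(particles))
      for (j in seq_along(particles)) {
        xp <- pos[k, j] / px_um
        if (xp >= -4 && xp <= nc + 3)
          fx <- fx + amp * exp(-(xs - xp)^2 / (2 * spot_sigma_px^2))
      }
    field <- bg_level + outer(gy, fx)
    pages[[k]] <- render_frame(field, optics, px_um,
                               seed = substream_seed(seed, 5000L + k),
                               noiseless = noiseless)
  }
  stream <- image_stack(pages, "time", dt_s = dt_s, px_um = px_um,
                        exposure_ms = dt_s * 1000)
  path <- neurite_path(rbind(c(0, y0), c(nc - 1, y0)), width_px = 9L)
  truth <- if (length(particles)) data.frame(
    particle = seq_along(particles),
    v_um_s = vapply(particles, `[[`, 0, "v_um_s"),
    direction = vapply(particles, `[[`, 0, "direction"),
    start_um = vapply(particles, `[[`, 0, "start_um"),
    motile = vapply(particles, `[[`, TRUE, "motile"),
    end_um = pos[n_frames, ],
    net_displacement_um = pos[n_frames, ] - pos[1, ]
  ) else data.frame()
  attr(truth, "warnings") <- warnings
  list(stream = stream, path = path, truth = truth, seed = seed)
}

## ---- proximity scenes ------------------------------------------------------

#' Simulate a two-channel mitochondria/puncta scene with controlled proximity
#'
#' Exactly `round(target_fraction_within_1um * n_mito)` mitochondria are
#' placed with a boundary-to-boundary axial gap below 1 um from a punctum
#' (drawn uniformly in 0.1..0.8 um); every other mitochondrion is kept at
#' least 1.5 um from all puncta (guard band), so the proximal fraction is
#' recoverable exactly.
#'
#' @param n_mito number of mitochondria.
#' @param n_puncta number of receptor puncta (default: one per proximal
#'   mitochondrion plus a few distant extras).
#' @param target_fraction_within_1um target proximal fraction (0 to 1).
#' @param length_um neurite length (default scales with `n_mito`).
#' @param optics,px_um rendering calibration.
#' @param seed integer seed.
#' @param noiseless render expectations.
#' @return list: `mito_stack`, `puncta_stack` (single-frame stacks),
#'   `path`, `truth` (per-mito interval, nearest-punctum gap, proximal
#'   flag), `puncta` (true punctum intervals).
#' @export
gen_proximity_scene <- function(n_mito = 100L, n_puncta = NULL,
                                target_fraction_within_1um = 0.61,
                                length_um = NULL,
                                optics = optics_model(psf_sigma_um = 0.1),
                                px_um = 0.2, seed = 1L, noiseless = FALSE) {
  tf <- target_fraction_within_1um
  if (tf < 0 || tf > 1) nm_stop("target fraction must be in [0, 1]", "nm_config_error")
  length_um <- length_um %||% max(40, 5.5 * n_mito)
  slot <- length_um / n_mito
  mito_len <- 1.2; punc_len <- 0.6
  # worst case: an extra (distant) punctum ends 3.8 um into a slot and must
  # still clear the next mitochondrion by the 1.5 um guard band
  if (slot < 5.3)
    nm_stop("infeasible object density for guard-banded placement", "nm_placement_error")
  n_prox <- round(tf * n_mito)
  prox_idx <- with_seed(substream_seed(seed, 0L),
                        sort(sample.int(n_mito, n_prox)))
  gaps <- with_seed(substream_seed(seed, 1L), stats::runif(n_mito, 0.1, 0.8))
  mito_a <- (seq_len(n_mito) - 1) * slot + 0.8
  mito_b <- mito_a + mito_len
  punc <- data.frame(a = numeric(0), b = numeric(0))
  for (i in prox_idx)
    punc <- rbind(punc, data.frame(a = mito_b[i] + gaps[i],
                                   b = mito_b[i] + gaps[i] + punc_len))
  n_puncta <- n_puncta %||% (n_prox + min(5L, n_mito - n_prox))
  if (n_puncta < n_prox)
    nm_stop("n_puncta must cover every proximal mitochondrion", "nm_placement_error")
  extra_slots <- setdiff(seq_len(n_mito), prox_idx)
  n_extra <- n_puncta - n_prox
  if (n_extra > length(extra_slots))
    nm_stop("infeasible: too many distant puncta requested", "nm_placement_error")
  for (i in utils::head(extra_slots, n_extra))
    punc <- rbind(punc, data.frame(a = mito_b[i] + 2.0,
                                   b = mito_b[i] + 2.0 + punc_len))
  # truth distances (boundary-to-boundary along the axis)
  nearest <- vapply(seq_len(n_mito), function(i) {
    if (!nrow(punc)) return(Inf)
    min(pmax(0, pmax(mito_a[i], punc$a) - pmin(mito_b[i], punc$b)))
  }, 0)
  truth <- data.frame(mito_id = sprintf("mito_%03d", seq_len(n_mito)),
                      s_start_um = mito_a, s_end_um = mito_b,
                      nearest_gap_um = nearest,
                      proximal = seq_len(n_mito) %in% prox_idx)
  stopifnot(all(truth$nearest_gap_um[truth$proximal] < 1),
            all(truth$nearest_gap_um[!truth$proximal] >= 1.5))
  # render: steep-edged boxes so thresholded extents track true intervals
  nc <- round(length_um / px_um); nr <- 12L; rows <- 6:8
  edge_um <- 0.1
  box_profile <- function(a, b) {
    x_um <- (0:(nc - 1)) * px_um
    stats::pnorm((x_um - a) / edge_um) - stats::pnorm((x_um - b) / edge_um)
  }
  field_from <- function(a_vec, b_vec, amp) {
    fx <- rep(0, nc)
    for (i in seq_along(a_vec)) fx <- fx + amp * box_profile(a_vec[i], b_vec[i])
    f <- matrix(0, nr, nc); f[rows, ] <- rep(fx, each = length(rows))
    f + 1
  }
  mito_page <- render_frame(field_from(mito_a, mito_b, 50), optics, px_um,
                            seed = substream_seed(seed, 10L), noiseless = noiseless)
  punc_page <- render_frame(field_from(punc$a, punc$b, 50), optics, px_um,
                            seed = substream_seed(seed, 11L), noiseless = noiseless)
  mk <- function(p, nm) image_stack(list(p), "time", dt_s = 0.1, px_um = px_um,
                                    excitation_nm = nm)
  path <- neurite_path(rbind(c(0, 7), c(nc - 1, 7)), width_px = 7L)
  list(mito_stack = mk(mito_page, 561L), puncta_stack = mk(punc_page, 488L),
       path = path, truth = truth,
       puncta = data.frame(s_start_um = punc$a, s_end_um = punc$b),
       seed = seed)
}
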