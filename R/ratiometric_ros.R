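# Per-mitochondrion roGFP ratiometry (405/488 excitation) with local
# background subtraction and best-Z selection, plus population-level
# unimodal/bimodal analysis via BIC-selected Gaussian mixtures.

#' Segment mitochondria in a 488-excitation z-stack
#'
#' Gaussian smoothing + Otsu threshold on the maximum-intensity projection,
#' 4-connected components with a minimum area, then for each object the
#' z-plane maximizing its mean 488 signal and an automatic nearby
#' background annulus (clipped away from every segmented object). Objects
#' touching end-to-end beyond the merge tolerance are returned merged.
#'
#' @param stack488 a z-axis `image_stack` (>= 3 planes).
#' @param smooth_sigma_px pre-threshold smoothing sigma (default 1).
#' @param min_area_px minimum object area (default 6).
#' @param annulus_gap_px,annulus_width_px background annulus geometry
#'   (defaults: ring at distance 2 px, width 3 px).
#' @return list of segments, each with `id`, `pixels` (linear indices into
#'   a page matrix), `bg_pixels`, `best_z`, `roi` (bounding rectangle);
#'   empty list (with a warning) when nothing is found.
#' @export
segment_mitochondria <- function(stack488, smooth_sigma_px = 1,
                                 min_area_px = 6L, annulus_gap_px = 2L,
                                 annulus_width_px = 3L) {
  stopifnot(inherits(stack488, "image_stack"))
  if (stack488$axis_kind != "z" || n_pages(stack488) < 3L)
    nm_stop("segmentation needs a z-stack with >= 3 planes", "nm_config_error")
  proj <- Reduce(pmax, stack488$pages)
  sm <- blur2d(proj, smooth_sigma_px)
  thr <- otsu_threshold(sm)
  mask <- sm > thr
  lab <- label_components(mask)
  k <- max(lab)
  if (k == 0L) {
    nm_warn("no objects found in 488 stack", "nm_empty_segmentation")
    return(list())
  }
  nr <- nrow(proj); nc <- ncol(proj)
  all_dil <- dilate_mask(lab > 0, annulus_gap_px)
  segs <- list()
  for (i in seq_len(k)) {
    px <- which(lab == i)
    if (length(px) < min_area_px) next
    means <- vapply(stack488$pages, function(p) mean(p[px]), 0)
    obj <- lab == i
    ring <- dilate_mask(obj, annulus_gap_px + annulus_width_px) &
      !dilate_mask(obj, annulus_gap_px) & !all_dil
    rows <- ((px - 1L) %% nr) + 1L
    cols <- ((px - 1L) %/% nr) + 1L
    segs[[length(segs) + 1L]] <- list(
      id = sprintf("mito_%02d", length(segs) + 1L),
      pixels = px, bg_pixels = which(ring),
      best_z = which.max(means),
      roi = roi(sprintf("mito_%02d", length(segs) + 1L), "rectangle",
                rbind(c(min(cols) - 1L, min(rows) - 1L),
                      c(max(cols) - 1L, max(rows) - 1L))))
  }
  if (!length(segs)) nm_warn("no objects above the minimum area", "nm_empty_segmentation")
  segs
}

# binary dilation with a square structuring element of radius r
dilate_mask <- function(mask, r) {
  out <- mask
  nr <- nrow(mask); nc <- ncol(mask)
  for (d in seq_len(r)) {
    shifted <- out
    shifted[-1, ] <- shifted[-1, ] | out[-nr, ]
    shifted[-nr, ] <- shifted[-nr, ] | out[-1, ]
    shifted[, -1] <- shifted[, -1] | out[, -nc]
    shifted[, -nc] <- shifted[, -nc] | out[, -1]
    out <- shifted
  }
  out
}

#' Measure the background-corrected 405/488 excitation ratio of one object
#'
#' Means are computed at the object's best-Z plane only, in both channels,
#' for signal and background; `f_ratio = (F405 - B405) / (F488 - B488)`.
#' The measurement is invalid (`valid = FALSE`, ratio suppressed to NA)
#' when the 488 signal above background does not exceed 3x the background
#' SD at that plane.
#'
#' @param stack405,stack488 co-registered z-stacks (identical geometry).
#' @param signal object pixels: a `roi`, or an integer vector of linear
#'   indices (as produced by [segment_mitochondria()]).
#' @param background background pixels: a `roi` or linear indices.
#' @param best_z 1-based plane index of maximal 488 signal.
#' @param mito_id identifier carried into the result.
#' @return one-row data.frame: `mito_id`, `z_index`, `F405`, `B405`,
#'   `F488`, `B488`, `f_ratio`, `valid`.
#' @export
measure_ratio <- function(stack405, stack488, signal, background, best_z,
                          mito_id = "mito") {
  stopifnot(inherits(stack405, "image_stack"), inherits(stack488, "image_stack"))
  d4 <- dim(stack405$pages[[1]]); d8 <- dim(stack488$pages[[1]])
  if (!identical(d4, d8) || n_pages(stack405) != n_pages(stack488))
    nm_stop("405/488 stacks are not co-registered", "nm_registration_error")
  nr <- d8[1]; nc <- d8[2]
  as_idx <- function(x) {
    if (inherits(x, "roi")) {
      m <- roi_mask(x, nr, nc)
      if (!any(m)) nm_stop("ROI covers no pixels", "nm_geometry_error")
      v <- x$vertices
      if (any(v[, 1] < 0 | v[, 1] > nc - 1 | v[, 2] < 0 | v[, 2] > nr - 1))
        nm_stop("ROI extends outside the image", "nm_geometry_error")
      which(m)
    } else as.integer(x)
  }
  sig <- as_idx(signal); bg <- as_idx(background)
  p405 <- stack405$pages[[best_z]]; p488 <- stack488$pages[[best_z]]
  f405 <- mean(p405[sig]); b405 <- mean(p405[bg])
  f488 <- mean(p488[sig]); b488 <- mean(p488[bg])
  noise_floor <- 3 * stats::sd(p488[bg])
  valid <- is.finite(noise_floor) && (f488 - b488) > noise_floor ||
    (stats::sd(p488[bg]) == 0 && (f488 - b488) > 0)
  data.frame(mito_id = mito_id, z_index = best_z,
             F405 = f405, B405 = b405, F488 = f488, B488 = b488,
             f_ratio = if (valid) (f405 - b405) / (f488 - b488) else NA_real_,
             valid = valid)
}

#' Measure all segmented objects of a dual-excitation scene
#'
#' Convenience wrapper: [segment_mitochondria()] on the 488 stack, then
#' [measure_ratio()] per object.
#' @param stack405,stack488 co-registered z-stacks.
#' @param ... passed to [segment_mitochondria()].
#' @return data.frame, one row per object.
#' @export
measure_scene_ratios <- function(stack405, stack488, ...) {
  segs <- segment_mitochondria(stack488, ...)
  if (!length(segs)) return(data.frame())
  do.call(rbind, lapply(segs, function(s)
    measure_ratio(stack405, stack488, s$pixels, s$bg_pixels, s$best_z,
                  mito_id = s$id)))
}

## ---- population modality ---------------------------------------------------

# log-likelihood of a 1-component normal model
ll_norm <- function(x, mu, sd) sum(stats::dnorm(x, mu, sd, log = TRUE))

# EM for a 2-component Gaussian mixture; returns NULL on failure
em_gmm2 <- function(x, mu0, sd0, w0, max_iter = 500L, tol = 1e-10) {
  mu <- mu0; sd <- pmax(sd0, 1e-8); w <- w0
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    d1 <- w[1] * stats::dnorm(x, mu[1], sd[1])
    d2 <- w[2] * stats::dnorm(x, mu[2], sd[2])
    tot <- d1 + d2
    if (any(tot <= 0) || any(!is.finite(tot))) return(NULL)
    g <- d1 / tot
    n1 <- sum(g); n2 <- length(x) - n1
    if (n1 < 1e-6 || n2 < 1e-6) return(NULL)
    mu <- c(sum(g * x) / n1, sum((1 - g) * x) / n2)
    sd <- sqrt(c(sum(g * (x - mu[1])^2) / n1,
                 sum((1 - g) * (x - mu[2])^2) / n2))
    sd <- pmax(sd, 1e-6 * stats::sd(x))
    w <- c(n1, n2) / length(x)
    ll <- sum(log(tot))
    if (abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  list(mu = mu, sd = sd, w = w, ll = ll_old)
}

#' Unimodal-versus-bimodal analysis of a ratio population
#'
#' Fits 1- and 2-component Gaussian mixtures (EM, deterministic
#' multi-start under a fixed seed) and selects the model with the lower
#' BIC. Mirrors the descriptive histogram analysis in which an
#' unstimulated population is unimodal and an activity-shifted population
#' becomes bimodal.
#'
#' @param ratios numeric vector of valid per-mitochondrion ratios (n >= 20).
#' @param n_starts random EM restarts in addition to a quantile-based start.
#' @param seed RNG seed for the restarts.
#' @return a `modality_report`: `n_components` (1 or 2),
#'   `component_means` (ascending), `component_sds`, `weights`, `bic_1`,
#'   `bic_2`.
#' @export
population_modality <- function(ratios, n_starts = 5L, seed = 1L) {
  x <- as.numeric(ratios)
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 20L) nm_stop("need >= 20 valid ratios", "nm_insufficient_data")
  if (stats::sd(x) == 0)
    nm_stop("degenerate population: zero variance", "nm_degenerate_error")
  mu1 <- mean(x); sd1 <- stats::sd(x) * sqrt((n - 1) / n)
  bic1 <- -2 * ll_norm(x, mu1, sd1) + 2 * log(n)
  starts <- list(list(mu = stats::quantile(x, c(0.25, 0.75), names = FALSE),
                      sd = rep(sd1 / 2, 2), w = c(0.5, 0.5)))
  starts <- c(starts, with_seed(seed, lapply(seq_len(n_starts), function(i) {
    m <- sort(sample(x, 2))
    list(mu = m, sd = rep(sd1 * stats::runif(1, 0.3, 1), 2), w = c(0.5, 0.5))
  })))
  best <- NULL
  for (s in starts) {
    fit <- em_gmm2(x, s$mu, s$sd, s$w)
    if (!is.null(fit) && (is.null(best) || fit$ll > best$ll)) best <- fit
  }
  if (is.null(best))
    nm_stop("EM did not converge from any start", "nm_fit_error")
  bic2 <- -2 * best$ll + 5 * log(n)
  two <- bic2 < bic1
  ord <- order(best$mu)
  structure(list(
    n_components = if (two) 2L else 1L,
    component_means = if (two) best$mu[ord] else mu1,
    component_sds = if (two) best$sd[ord] else sd1,
    weights = if (two) best$w[ord] else 1,
    bic_1 = bic1, bic_2 = bic2, n = n), class = "modality_report")
}

#' @export
print.modality_report <- function(x, ...) {
  cat(sprintf("<modality_report> %d component(s); means = %s; BIC1 = %.1f, BIC2 = %.1f\n",
              x$n_components, paste(signif(x$component_means, 3), collapse = ", "),
              x$bic_1, x$bic_2))
  invisible(x)
}
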