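# FRAP quantification: region fluorescence across the pre/0..16 min
# schedule, the two normalization schemes, one-phase recovery fitting,
# extra sum-of-squares F-test curve comparison, and pre-bleach linescan
# puncta-area analysis.

#' FRAP series for one animal
#'
#' @param animal_id identifier.
#' @param t_min post-bleach timepoints in minutes (first must be 0).
#' @param f region fluorescence at `t_min` (a.u.).
#' @param f_pre pre-bleach fluorescence (a.u.).
#' @param norm_mode `"raw"`, `"percent"` or `"subtract"`.
#' @param f_norm normalized values (set by [normalize_frap()]).
#' @return a `frap_series`.
#' @export
frap_series <- function(animal_id, t_min, f, f_pre, norm_mode = "raw",
                        f_norm = NULL) {
  if (length(t_min) != length(f))
    nm_stop("t_min and f must have equal length", "nm_validation_error")
  if (t_min[1] != 0 || any(diff(t_min) <= 0))
    nm_stop("t_min must start at 0 and increase", "nm_validation_error")
  if (any(!is.finite(c(f, f_pre))))
    nm_stop("fluorescence values must be finite", "nm_validation_error")
  structure(list(animal_id = animal_id, t_min = t_min, f = f, f_pre = f_pre,
                 norm_mode = norm_mode, f_norm = f_norm),
            class = "frap_series")
}

#' Extract a FRAP series from per-timepoint z-stacks
#'
#' Per timepoint the fluorescence is the mean within the region of the
#' maximum-intensity z-projection, minus the background mean. The first
#' stack is the pre-bleach acquisition, the second the 0 min timepoint.
#'
#' @param stacks ordered list of z-stacks (pre, 0 min, then `schedule_min`).
#' @param region,background `roi`s inside every stack.
#' @param schedule_min post-bleach minutes after the 0 min point
#'   (default every 2 min out to 16 min).
#' @param animal_id identifier.
#' @return a `frap_series` with `norm_mode = "raw"`.
#' @export
extract_frap_series <- function(stacks, region, background,
                                schedule_min = seq(2, 16, by = 2),
                                animal_id = "animal") {
  expected <- 2L + length(schedule_min)
  if (length(stacks) != expected)
    nm_stop(sprintf("schedule error: expected %d stacks (pre, 0, %s), got %d",
                    expected, paste(schedule_min, collapse = ", "),
                    length(stacks)), "nm_schedule_error")
  vals <- vapply(stacks, function(s) {
    stopifnot(inherits(s, "image_stack"))
    proj <- Reduce(pmax, s$pages)
    nr <- nrow(proj); nc <- ncol(proj)
    for (r in list(region, background)) {
      v <- r$vertices
      if (any(v[, 1] < 0 | v[, 1] > nc - 1 | v[, 2] < 0 | v[, 2] > nr - 1))
        nm_stop("ROI partially outside image", "nm_geometry_error")
    }
    mean(proj[roi_mask(region, nr, nc)]) - mean(proj[roi_mask(background, nr, nc)])
  }, 0)
  vals <- unname(vals)
  frap_series(animal_id, t_min = c(0, schedule_min), f = vals[-1],
              f_pre = vals[1])
}

#' Normalize a FRAP series
#'
#' `percent`: `f_norm(t) = 100 * (f(t) - f(0)) / (f_pre - f(0))`, so the
#' pre-bleach level maps to 100 and the 0 min point to 0 by construction.
#' `subtract`: `f_norm(t) = f(t) - f(0)` in a.u. (used when initial
#' fluorescence differs systematically between groups); the pre-bleach
#' point is not part of the recovery curve in either mode.
#'
#' @param series a `frap_series` (raw).
#' @param mode `"percent"` or `"subtract"`.
#' @return the series with `f_norm` and `norm_mode` set.
#' @export
normalize_frap <- function(series, mode = c("percent", "subtract")) {
  mode <- match.arg(mode)
  stopifnot(inherits(series, "frap_series"))
  f0 <- series$f[1]
  if (mode == "percent") {
    if (series$f_pre <= f0)
      nm_stop("normalization error: F_pre <= F_0 (bleach failed)",
              "nm_normalization_error")
    series$f_norm <- 100 * (series$f - f0) / (series$f_pre - f0)
    series$f_pre_norm <- 100          # pre-bleach level maps to 100 exactly
  } else {
    series$f_norm <- series$f - f0
    series$f_pre_norm <- series$f_pre - f0
  }
  series$norm_mode <- mode
  series
}

#' Fit a one-phase recovery curve to a group of FRAP series
#'
#' Least squares of `Y(t) = plateau * (1 - exp(-k t))` pooled over all
#' post-bleach points of the group (normalized values if present,
#' otherwise raw). The profile of k is scanned on a deterministic
#' log-spaced grid (plateau solved in closed form per k) and refined with
#' a bounded 1-D optimization, so the fit is reproducible.
#'
#' @param series_list one `frap_series` or a list of them (one group).
#' @param k_range search range for k (per minute).
#' @return a `frap_fit`: `plateau`, `k_per_min`, `rss`, `n_points`,
#'   `flagged` (TRUE when k is unidentifiable, e.g. all-zero data).
#' @export
fit_recovery <- function(series_list, k_range = c(1e-3, 30)) {
  if (inherits(series_list, "frap_series")) series_list <- list(series_list)
  t <- unlist(lapply(series_list, `[[`, "t_min"))
  y <- unlist(lapply(series_list, function(s) s$f_norm %||% s$f))
  if (length(unique(t[t > 0])) < 2L || length(t) < 3L)
    nm_stop("need >= 3 distinct post-bleach timepoints", "nm_df_error")
  fit <- fit_one_phase(t, y, k_range)
  structure(c(fit, list(n_points = length(t))), class = "frap_fit")
}

# core least-squares engine shared by fit and F-test
fit_one_phase <- function(t, y, k_range = c(1e-3, 30)) {
  rss_k <- function(k) {
    g <- 1 - exp(-k * t)
    den <- sum(g * g)
    p <- if (den > 0) sum(y * g) / den else 0
    c(rss = sum((y - p * g)^2), plateau = p)
  }
  grid <- exp(seq(log(k_range[1]), log(k_range[2]), length.out = 120))
  vals <- vapply(grid, function(k) rss_k(k)["rss"], 0)
  i <- which.min(vals)
  lo <- grid[max(1L, i - 1L)]; hi <- grid[min(length(grid), i + 1L)]
  opt <- stats::optimize(function(k) rss_k(k)["rss"], c(lo, hi), tol = 1e-10)
  best <- rss_k(opt$minimum)
  flagged <- abs(best["plateau"]) < 1e-8 * max(1, stats::sd(y)) ||
    sum(y^2) < 1e-12
  list(plateau = unname(best["plateau"]), k_per_min = opt$minimum,
       rss = unname(best["rss"]), flagged = unname(flagged))
}

#' @export
print.frap_fit <- function(x, ...) {
  cat(sprintf("<frap_fit> plateau = %.3g, k = %.4g /min, rss = %.3g (n = %d)%s\n",
              x$plateau, x$k_per_min, x$rss, x$n_points,
              if (isTRUE(x$flagged)) " [flagged]" else ""))
  invisible(x)
}

#' Compare FRAP recovery curves between groups (extra sum-of-squares F-test)
#'
#' Per pair of groups, one shared curve is fitted to the pooled points
#' (`SS_shared`) and individual curves to each group (`SS_separate`);
#' `F = ((SS_shared - SS_separate)/ddf) / (SS_separate/df_sep)` with
#' `ddf = 2` extra parameters and `df_sep = n_a + n_b - 4`. p-values come
#' from the F distribution and are Bonferroni-adjusted over the family of
#' comparisons; curves are considered different when the adjusted p is
#' below `alpha` (0.01 by convention here).
#'
#' @param groups named list; each element a list of `frap_series`.
#' @param control optional control-group name; if given the family is all
#'   group-vs-control pairs, otherwise all pairs.
#' @param alpha significance threshold on the adjusted p (default 0.01).
#' @return data.frame: `group_a`, `group_b`, `F`, `df1`, `df2`, `p_raw`,
#'   `p_adj`, `significant`.
#' @export
compare_recovery_curves <- function(groups, control = NULL, alpha = 0.01) {
  stopifnot(is.list(groups), length(groups) >= 2L, !is.null(names(groups)))
  pool <- function(gs) {
    t <- unlist(lapply(gs, `[[`, "t_min"))
    y <- unlist(lapply(gs, function(s) s$f_norm %||% s$f))
    list(t = t, y = y)
  }
  pairs <- if (is.null(control)) {
    utils::combn(names(groups), 2, simplify = FALSE)
  } else {
    if (!control %in% names(groups)) nm_stop("control group not found", "nm_validation_error")
    lapply(setdiff(names(groups), control), function(g) c(control, g))
  }
  rows <- lapply(pairs, function(pr) {
    a <- pool(groups[[pr[1]]]); b <- pool(groups[[pr[2]]])
    if (length(a$t) < 3L || length(b$t) < 3L)
      nm_stop("group has fewer points than parameters", "nm_df_error")
    ss_sep <- fit_one_phase(a$t, a$y)$rss + fit_one_phase(b$t, b$y)$rss
    ss_sh <- fit_one_phase(c(a$t, b$t), c(a$y, b$y))$rss
    df2 <- length(a$t) + length(b$t) - 4L
    f <- max(0, (ss_sh - ss_sep) / 2 / (ss_sep / df2))
    p <- stats::pf(f, 2, df2, lower.tail = FALSE)
    data.frame(group_a = pr[1], group_b = pr[2], F = f, df1 = 2L, df2 = df2,
               p_raw = p)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- pmin(1, out$p_raw * nrow(out))
  out$significant <- out$p_adj < alpha
  out
}

#' Pre-bleach linescan puncta-area analysis
#'
#' Width-averaged intensity profile along the neurite (the 20 px linescan
#' convention), a rolling-median local baseline, and peaks above
#' `baseline + k x robust SD`; each peak's area is the trapezoidal
#' integral of (intensity - local baseline) between its threshold
#' crossings.
#'
#' @param image single frame (matrix) or an `image_stack` (max projection
#'   is used).
#' @param path a [neurite_path()] inside the image.
#' @param px_um pixel size (taken from the stack when available).
#' @param baseline_window_um rolling-median window (default 4 um).
#' @param threshold_sd threshold multiplier above baseline (default 2).
#' @return a `puncta_profile`: `s_um`, `intensity`, `baseline`, and
#'   `peaks` data.frame (`position_um`, `area`, `height`); `mean_area` is
#'   0 with `no_puncta = TRUE` when the profile is flat.
#' @export
prebleach_puncta_areas <- function(image, path, px_um = NULL,
                                   baseline_window_um = 4,
                                   threshold_sd = 2) {
  if (inherits(image, "image_stack")) {
    px_um <- px_um %||% image$px_um
    image <- Reduce(pmax, image$pages)
  }
  if (is.null(px_um)) nm_stop("px_um required", "nm_config_error")
  prof <- path_profile(image, path)
  if (length(prof$s_px) < 3L)
    nm_stop("path shorter than 3 samples", "nm_geometry_error")
  s_um <- prof$s_px * px_um
  y <- prof$intensity
  w <- max(3L, round(baseline_window_um / px_um))
  if (w %% 2L == 0L) w <- w + 1L
  base <- stats::runmed(y, min(w, length(y) - (1 - length(y) %% 2)))
  resid <- y - base
  thr <- threshold_sd * max(mad_sd(resid), 1e-12)
  above <- resid > thr
  peaks <- data.frame(position_um = numeric(0), area = numeric(0),
                      height = numeric(0))
  if (any(above)) {
    r <- rle(above)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (ci in which(r$values)) {
      idx <- starts[ci]:ends[ci]
      if (length(idx) < 2L) next
      peaks <- rbind(peaks, data.frame(
        position_um = s_um[idx][which.max(resid[idx])],
        area = trapz(s_um[idx], resid[idx]),
        height = max(resid[idx])))
    }
  }
  structure(list(s_um = s_um, intensity = y, baseline = base, peaks = peaks,
                 mean_area = if (nrow(peaks)) mean(peaks$area) else 0,
                 no_puncta = nrow(peaks) == 0L),
            class = "puncta_profile")
}
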