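# Kymograph construction along a neurite path and transport quantification:
# event detection (automated surrogate for manual counting), per-minute
# event rates, and instantaneous segment velocities.

# Resample a polyline at 1 px arc-length spacing; returns positions and
# unit normals (0-based pixel coordinates).
path_samples <- function(path) {
  p <- path$points
  L <- path$length_px
  s <- seq(0, L, by = 1)
  cum <- c(0, cumsum(path$seg_len_px))
  seg <- findInterval(s, cum, rightmost.closed = TRUE)
  seg[seg >= nrow(p)] <- nrow(p) - 1L
  frac <- (s - cum[seg]) / path$seg_len_px[seg]
  x <- p[seg, 1] + frac * (p[seg + 1L, 1] - p[seg, 1])
  y <- p[seg, 2] + frac * (p[seg + 1L, 2] - p[seg, 2])
  tx <- (p[seg + 1L, 1] - p[seg, 1]) / path$seg_len_px[seg]
  ty <- (p[seg + 1L, 2] - p[seg, 2]) / path$seg_len_px[seg]
  list(s_px = s, x = x, y = y, nx = -ty, ny = tx)
}

# Precompute bilinear interpolation indices/weights for a set of points on
# an nr x nc image (coordinates clamped to the frame).
bilinear_plan <- function(x, y, nr, nc) {
  x <- pmin(pmax(x, 0), nc - 1); y <- pmin(pmax(y, 0), nr - 1)
  x0 <- pmin(floor(x), nc - 2); y0 <- pmin(floor(y), nr - 2)
  fx <- x - x0; fy <- y - y0
  i00 <- (x0) * nr + y0 + 1
  list(i00 = i00, i10 = i00 + 1, i01 = i00 + nr, i11 = i00 + nr + 1,
       w00 = (1 - fx) * (1 - fy), w10 = (1 - fx) * fy,
       w01 = fx * (1 - fy), w11 = fx * fy)
}

bilinear_eval <- function(img, plan) {
  v <- img
  plan$w00 * v[plan$i00] + plan$w10 * v[plan$i10] +
    plan$w01 * v[plan$i01] + plan$w11 * v[plan$i11]
}

# Width-averaged intensity profile of one frame along a path.
path_profile <- function(image, path) {
  nr <- nrow(image); nc <- ncol(image)
  pv <- path$points
  if (any(pv[, 1] < 0 | pv[, 1] > nc - 1 | pv[, 2] < 0 | pv[, 2] > nr - 1))
    nm_stop("path exits the frame", "nm_geometry_error")
  sm <- path_samples(path)
  offs <- seq(-(path$width_px - 1) / 2, (path$width_px - 1) / 2, by = 1)
  xs <- outer(sm$x, offs * 1, function(a, b) a) + outer(sm$nx, offs)
  ys <- outer(sm$y, offs * 1, function(a, b) a) + outer(sm$ny, offs)
  plan <- bilinear_plan(as.vector(xs), as.vector(ys), nr, nc)
  vals <- matrix(bilinear_eval(image, plan), nrow = length(sm$s_px))
  list(s_px = sm$s_px, intensity = rowMeans(vals), plan = plan,
       n_off = length(offs))
}

#' Build a kymograph from an image stream along a neurite path
#'
#' Rows are frames (time), columns are arc-length samples (distance);
#' the path is resampled at pixel spacing and each cell is the mean
#' intensity across `width_px` perpendicular to the path.
#'
#' @param stream a time-axis `image_stack` with >= 2 frames.
#' @param path a [neurite_path()] within the frame bounds.
#' @return a `kymograph`: `matrix`, `dt_s`, `dx_um`.
#' @export
build_kymograph <- function(stream, path) {
  stopifnot(inherits(stream, "image_stack"))
  if (stream$axis_kind != "time" || n_pages(stream) < 2L)
    nm_stop("kymograph needs a time-axis stream with >= 2 frames", "nm_config_error")
  first <- path_profile(stream$pages[[1]], path)
  mat <- matrix(0, n_pages(stream), length(first$s_px))
  mat[1, ] <- first$intensity
  for (k in 2:n_pages(stream)) {
    vals <- matrix(bilinear_eval(stream$pages[[k]], first$plan),
                   nrow = length(first$s_px))
    mat[k, ] <- rowMeans(vals)
  }
  structure(list(matrix = mat, dt_s = stream$dt_s, px_um = stream$px_um,
                 dx_um = stream$px_um), class = "kymograph")
}

#' @export
print.kymograph <- function(x, ...) {
  cat(sprintf("<kymograph> %d frames x %d positions (dt = %gs, dx = %gum)\n",
              nrow(x$matrix), ncol(x$matrix), x$dt_s, x$dx_um))
  invisible(x)
}

# Sub-pixel refinement of a peak at index i (1-based) of profile y with
# background already subtracted: log-parabolic when possible (exact for
# Gaussian spots), plain parabolic otherwise.
refine_peak <- function(y, i) {
  if (i <= 1L || i >= length(y)) return(i - 1)
  a <- y[i - 1L]; b <- y[i]; c <- y[i + 1L]
  d <- if (a > 0 && b > 0 && c > 0) {
    la <- log(a); lb <- log(b); lc <- log(c)
    den <- la - 2 * lb + lc
    if (den < 0) 0.5 * (la - lc) / den else 0
  } else {
    den <- a - 2 * b + c
    if (den < 0) 0.5 * (a - c) / den else 0
  }
  i - 1 + max(-1, min(1, d))
}

#' Detect transport events (motile tracks) in a kymograph
#'
#' Per frame, intensity maxima above a robust threshold are localized with
#' sub-pixel precision and linked greedily across frames within a
#' velocity-capped step. Tracks lasting at least `min_track_frames` are
#' kept; a track is a transport event (motile) when its absolute net
#' displacement reaches `min_net_displacement_um`. Direction follows the
#' sign of the net displacement along the path orientation (anterograde =
#' increasing arc length).
#'
#' @param kymo a `kymograph`.
#' @param min_net_displacement_um motility threshold (default 2 um).
#' @param max_speed_um_s linking velocity cap (default 5 um/s).
#' @param min_track_frames minimum detections per track (default 5).
#' @param threshold_sd detection threshold in robust SDs above the row
#'   median (default 4).
#' @param max_gap_frames frames a track may go undetected (default 2).
#' @param min_sep_px minimum separation between same-frame maxima.
#' @return list of events; each has `track` (data.frame `t_s`, `x_um`),
#'   `direction`, `net_displacement_um`, `motile`. Non-motile tracks are
#'   attached as `attr(, "stationary")`.
#' @export
detect_transport_events <- function(kymo, min_net_displacement_um = 2,
                                    max_speed_um_s = 5,
                                    min_track_frames = 5L,
                                    threshold_sd = 4,
                                    max_gap_frames = 2L,
                                    min_sep_px = 3L) {
  stopifnot(inherits(kymo, "kymograph"))
  m <- kymo$matrix
  n_frames <- nrow(m)
  max_step_px <- max_speed_um_s * kymo$dt_s / kymo$dx_um
  tracks <- list()     # each: list(frames=, x=, last_frame=)
  open <- integer(0)
  for (f in seq_len(n_frames)) {
    y <- m[f, ]
    bg <- stats::median(y)
    noise <- mad_sd(y)
    thr <- bg + threshold_sd * max(noise, 1e-9)
    idx <- local_maxima(y, threshold = thr, min_sep = min_sep_px)
    det_x <- vapply(idx, function(i) refine_peak(y - bg, i), 0)
    used_det <- rep(FALSE, length(det_x))
    if (length(open) && length(det_x)) {
      cand <- expand.grid(tr = open, dt = seq_along(det_x))
      cand$gap <- f - vapply(cand$tr, function(ti) tracks[[ti]]$last_frame, 0L)
      cand$dist <- abs(det_x[cand$dt] -
                         vapply(cand$tr, function(ti) tracks[[ti]]$x[length(tracks[[ti]]$x)], 0))
      cand <- cand[cand$dist <= max_step_px * cand$gap + 0.5, , drop = FALSE]
      cand <- cand[order(cand$dist), , drop = FALSE]
      used_tr <- integer(0)
      for (r in seq_len(nrow(cand))) {
        ti <- cand$tr[r]; di <- cand$dt[r]
        if (ti %in% used_tr || used_det[di]) next
        tracks[[ti]]$frames <- c(tracks[[ti]]$frames, f)
        tracks[[ti]]$x <- c(tracks[[ti]]$x, det_x[di])
        tracks[[ti]]$last_frame <- f
        used_tr <- c(used_tr, ti); used_det[di] <- TRUE
      }
    }
    for (di in which(!used_det)) {
      tracks[[length(tracks) + 1L]] <- list(frames = f, x = det_x[di],
                                            last_frame = f)
      open <- c(open, length(tracks))
    }
    open <- open[vapply(open, function(ti) f - tracks[[ti]]$last_frame <= max_gap_frames, TRUE)]
  }
  events <- list(); stationary <- list()
  for (tr in tracks) {
    if (length(tr$frames) < min_track_frames) next
    x_um <- tr$x * kymo$dx_um
    t_s <- (tr$frames - 1L) * kymo$dt_s
    net <- x_um[length(x_um)] - x_um[1]
    ev <- list(track = data.frame(t_s = t_s, x_um = x_um),
               direction = if (net >= 0) "anterograde" else "retrograde",
               net_displacement_um = net,
               motile = abs(net) >= min_net_displacement_um)
    if (ev$motile) events[[length(events) + 1L]] <- ev
    else stationary[[length(stationary) + 1L]] <- ev
  }
  attr(events, "stationary") <- stationary
  events
}

#' Transport events per minute
#'
#' `rate = count * 60 / duration_s`: 10 events in a 50 s kymograph is
#' 12 events per minute.
#' @param events list from [detect_transport_events()] (or a count).
#' @param duration_s kymograph duration in seconds (> 0).
#' @export
events_per_minute <- function(events, duration_s) {
  if (duration_s <= 0) nm_stop("duration must be > 0", "nm_validation_error")
  n <- if (is.numeric(events)) events else length(events)
  n * 60 / duration_s
}

#' Instantaneous segment velocities of transport events
#'
#' Each track is split into segments at pauses (frame-to-frame speed below
#' `pause_speed_um_s` for at least `pause_min_frames` consecutive steps)
#' and at direction reversals; each motile segment contributes
#' `velocity = dx/dt` over the segment. Pause time is excluded from all
#' summaries.
#'
#' @param events list from [detect_transport_events()].
#' @param pause_speed_um_s pause speed threshold (default 0.1 um/s).
#' @param pause_min_frames minimum steps for a pause (default 3).
#' @return list: `segments` (data.frame `event_id`, `segment_index`,
#'   `v_um_s`, `duration_s`), `events` (data.frame `event_id`,
#'   `mean_speed_um_s` = moving distance over moving time, `n_segments`,
#'   `direction`).
#' @export
instantaneous_velocities <- function(events, pause_speed_um_s = 0.1,
                                     pause_min_frames = 3L) {
  seg_rows <- list(); ev_rows <- list()
  for (e in seq_along(events)) {
    tr <- events[[e]]$track
    n <- nrow(tr)
    if (n < 2L) next
    v <- diff(tr$x_um) / diff(tr$t_s)
    slow <- abs(v) < pause_speed_um_s
    # only sustained slow runs count as pauses
    r <- rle(slow)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    is_pause <- rep(FALSE, length(v))
    for (ci in which(r$values & r$lengths >= pause_min_frames))
      is_pause[starts[ci]:ends[ci]] <- TRUE
    state <- ifelse(is_pause, 0, sign(v))
    # group consecutive steps with the same state
    grp <- cumsum(c(1, diff(state) != 0))
    k <- 0L
    for (g in unique(grp)) {
      idx <- which(grp == g)
      if (state[idx[1]] == 0) next
      i0 <- idx[1]; i1 <- idx[length(idx)] + 1L
      dt <- tr$t_s[i1] - tr$t_s[i0]
      if (dt <= 0) next
      k <- k + 1L
      seg_rows[[length(seg_rows) + 1L]] <- data.frame(
        event_id = e, segment_index = k,
        v_um_s = (tr$x_um[i1] - tr$x_um[i0]) / dt, duration_s = dt)
    }
    segs <- if (length(seg_rows)) do.call(rbind, seg_rows) else NULL
    my <- if (!is.null(segs)) segs[segs$event_id == e, , drop = FALSE] else NULL
    ev_rows[[length(ev_rows) + 1L]] <- data.frame(
      event_id = e,
      mean_speed_um_s = if (!is.null(my) && nrow(my))
        sum(abs(my$v_um_s) * my$duration_s) / sum(my$duration_s) else NA_real_,
      n_segments = k, direction = events[[e]]$direction)
  }
  list(segments = if (length(seg_rows)) do.call(rbind, seg_rows)
       else data.frame(event_id = integer(0), segment_index = integer(0),
                       v_um_s = numeric(0), duration_s = numeric(0)),
       events = if (length(ev_rows)) do.call(rbind, ev_rows)
       else data.frame(event_id = integer(0), mean_speed_um_s = numeric(0),
                       n_segments = integer(0), direction = character(0)))
}
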