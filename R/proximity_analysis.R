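# Classification of mitochondria as proximal (< 1 um boundary-to-boundary
# along the neurite axis) to receptor puncta, and the proximal fraction.

#' Axial object (interval along the neurite arc-length axis)
#'
#' @param id identifier.
#' @param channel `"mito"` or `"puncta"`.
#' @param s_start_um,s_end_um occupied interval (start < end).
#' @export
axial_object <- function(id, channel = c("mito", "puncta"),
                         s_start_um, s_end_um) {
  channel <- match.arg(channel)
  if (s_start_um >= s_end_um)
    nm_stop("interval must have s_start < s_end", "nm_validation_error")
  structure(list(id = id, channel = channel, s_start_um = s_start_um,
                 s_end_um = s_end_um), class = "axial_object")
}

# Segment a single-frame (or projected) channel image and project each
# object onto the path's arc-length axis.
segment_channel_1d <- function(image, path, px_um, min_area_px = 6L) {
  sm <- blur2d(image, 1)
  thr <- otsu_threshold(sm)
  lab <- label_components(sm > thr)
  k <- max(lab)
  if (k == 0L) return(list())
  nr <- nrow(image); nc <- ncol(image)
  samp <- path_samples(path)
  out <- list()
  for (i in seq_len(k)) {
    px <- which(lab == i)
    if (length(px) < min_area_px) next
    rows <- ((px - 1L) %% nr)          # 0-based y
    cols <- ((px - 1L) %/% nr)         # 0-based x
    # nearest path sample per pixel; candidate samples are restricted to
    # the object's bounding box (padded by the path width) for speed
    pad <- path$width_px + 2
    keep <- samp$x >= min(cols) - pad & samp$x <= max(cols) + pad &
      samp$y >= min(rows) - pad & samp$y <= max(rows) + pad
    if (!any(keep)) keep <- rep(TRUE, length(samp$x))
    cand <- list(s_px = samp$s_px[keep], x = samp$x[keep], y = samp$y[keep])
    d2 <- outer(cols, cand$x, `-`)^2 + outer(rows, cand$y, `-`)^2
    nearest <- apply(d2, 1, which.min)
    mind <- sqrt(d2[cbind(seq_along(nearest), nearest)])
    if (min(mind) > path$width_px) {
      nm_warn(sprintf("object %d farther than width_px from path; dropped", i),
              "nm_projection_warning")
      next
    }
    s_range <- range(cand$s_px[nearest]) * px_um
    out[[length(out) + 1L]] <- c(s_start_um = s_range[1], s_end_um = s_range[2])
  }
  out
}

#' Project detected objects of two channels onto the neurite axis
#'
#' Each connected object is mapped to the arc-length interval spanned by
#' its pixels' nearest path points. Objects farther than `width_px` from
#' the path are dropped with a warning.
#'
#' @param mito_image,puncta_image single-frame matrices or `image_stack`s
#'   (first page used); `puncta_image` may be NULL.
#' @param path a [neurite_path()].
#' @param px_um pixel size (taken from a stack when available).
#' @return list of [axial_object()]s.
#' @export
project_objects <- function(mito_image, puncta_image, path, px_um = NULL) {
  get_img <- function(x) {
    if (inherits(x, "image_stack")) {
      px_um <<- px_um %||% x$px_um
      x$pages[[1]]
    } else x
  }
  mi <- get_img(mito_image)
  pi <- if (!is.null(puncta_image)) get_img(puncta_image) else NULL
  if (is.null(px_um)) nm_stop("px_um required", "nm_config_error")
  objs <- list()
  mk <- function(iv_list, channel) {
    lapply(seq_along(iv_list), function(i)
      axial_object(sprintf("%s_%03d", channel, i), channel,
                   iv_list[[i]]["s_start_um"], iv_list[[i]]["s_end_um"]))
  }
  objs <- c(objs, mk(segment_channel_1d(mi, path, px_um), "mito"))
  if (!is.null(pi)) objs <- c(objs, mk(segment_channel_1d(pi, path, px_um), "puncta"))
  objs
}

#' Proximal fraction of mitochondria relative to receptor puncta
#'
#' Per mitochondrion the distance to the nearest punctum is the
#' boundary-to-boundary axial gap (0 when the intervals overlap;
#' `mode = "centroid"` uses center-to-center distance instead). A
#' mitochondrion is proximal when its distance is strictly below
#' `threshold_um`; the fraction is proximal / total.
#'
#' @param mitos,puncta lists of [axial_object()]s (or data.frames with
#'   `s_start_um`, `s_end_um`).
#' @param threshold_um proximity threshold (default 1 um, strict `<`).
#' @param mode `"edge"` (default) or `"centroid"`.
#' @return list: `fraction`, `distances` (data.frame `mito_id`,
#'   `nearest_distance_um`, `proximal`), `n_mito`, `n_puncta`,
#'   `no_puncta` flag.
#' @export
proximity_fraction <- function(mitos, puncta, threshold_um = 1.0,
                               mode = c("edge", "centroid")) {
  mode <- match.arg(mode)
  as_df <- function(x, channel) {
    if (is.data.frame(x)) {
      if (is.null(x$id)) x$id <- sprintf("%s_%03d", channel, seq_len(nrow(x)))
      x[, c("id", "s_start_um", "s_end_um")]
    } else {
      do.call(rbind, lapply(x, function(o)
        data.frame(id = o$id, s_start_um = o$s_start_um, s_end_um = o$s_end_um)))
    }
  }
  m <- as_df(mitos, "mito")
  if (is.null(m) || !nrow(m)) nm_stop("need >= 1 mitochondrion", "nm_validation_error")
  p <- if (!is.null(puncta)) as_df(puncta, "puncta") else NULL
  dist_one <- function(a1, b1) {
    if (is.null(p) || !nrow(p)) return(Inf)
    if (mode == "edge") min(pmax(0, pmax(a1, p$s_start_um) - pmin(b1, p$s_end_um)))
    else min(abs((a1 + b1) / 2 - (p$s_start_um + p$s_end_um) / 2))
  }
  d <- mapply(dist_one, m$s_start_um, m$s_end_um)
  res <- data.frame(mito_id = m$id, nearest_distance_um = d,
                    proximal = d < threshold_um)
  list(fraction = mean(res$proximal), distances = res,
       n_mito = nrow(m), n_puncta = if (is.null(p)) 0L else nrow(p),
       threshold_um = threshold_um,
       no_puncta = is.null(p) || !nrow(p))
}
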