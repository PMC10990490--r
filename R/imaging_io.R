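# Calibrated image stacks, ROIs, neurite paths, stimulation protocols,
# and their on-disk formats (baseline TIFF + JSON sidecars).
#
# Coordinate convention: pixel-centered, 0-based, x = column, y = row.
# All micron quantities derive from px_um.

#' Calibrated multi-page image stack
#'
#' The common currency of all imaging stages: an ordered list of 2-D
#' intensity matrices (rows = y, columns = x) plus spatial/temporal
#' calibration and excitation metadata.
#'
#' @param pages list of numeric matrices, identical dimensions, values >= 0.
#' @param axis_kind `"time"` (stream, `dt_s` set) or `"z"` (z-stack,
#'   `dz_um` set). Exactly one of `dt_s`/`dz_um` must be supplied.
#' @param dt_s frame interval in seconds.
#' @param dz_um plane spacing in microns.
#' @param px_um pixel size, microns per pixel (> 0).
#' @param exposure_ms exposure per page, milliseconds (optional).
#' @param excitation_nm excitation wavelength, e.g. 405 or 488 (optional).
#' @return an `image_stack` object.
#' @export
image_stack <- function(pages, axis_kind = c("time", "z"), dt_s = NULL,
                        dz_um = NULL, px_um, exposure_ms = NULL,
                        excitation_nm = NULL) {
  axis_kind <- match.arg(axis_kind)
  if (!is.list(pages) || !length(pages))
    nm_stop("pages must be a non-empty list of matrices", "nm_format_error")
  dims <- vapply(pages, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    nm_stop("all pages must share identical dimensions", "nm_format_error")
  if (any(vapply(pages, function(p) any(!is.finite(p)) || any(p < 0), TRUE)))
    nm_stop("intensities must be finite and >= 0", "nm_format_error")
  if (!is.numeric(px_um) || px_um <= 0)
    nm_stop("px_um must be > 0", "nm_config_error")
  if (axis_kind == "time") {
    if (is.null(dt_s) || !is.null(dz_um))
      nm_stop("time-axis stack needs dt_s (and no dz_um)", "nm_config_error")
    if (dt_s <= 0) nm_stop("dt_s must be > 0", "nm_config_error")
  } else {
    if (is.null(dz_um) || !is.null(dt_s))
      nm_stop("z-axis stack needs dz_um (and no dt_s)", "nm_config_error")
    if (dz_um <= 0) nm_stop("dz_um must be > 0", "nm_config_error")
  }
  structure(list(pages = pages, axis_kind = axis_kind, dt_s = dt_s,
                 dz_um = dz_um, px_um = px_um, exposure_ms = exposure_ms,
                 excitation_nm = excitation_nm),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$pages[[1]])
  cat(sprintf("<image_stack> %d page(s) of %dx%d px (%.3g um/px), axis=%s %s\n",
              length(x$pages), d[1], d[2], x$px_um, x$axis_kind,
              if (x$axis_kind == "time") sprintf("dt=%gs", x$dt_s)
              else sprintf("dz=%gum", x$dz_um)))
  invisible(x)
}

n_pages <- function(stack) length(stack$pages)

#' Axial span of a z-stack in microns
#'
#' Span = (n_pages - 1) x dz_um: the distance between the first and last
#' plane centers (21 planes at 0.25 um steps span 5.0 um).
#' @param stack a z-axis `image_stack`.
#' @return scalar microns.
#' @export
axial_span_um <- function(stack) {
  stopifnot(inherits(stack, "image_stack"))
  if (stack$axis_kind != "z") nm_stop("axial span is defined for z-stacks", "nm_config_error")
  (n_pages(stack) - 1) * stack$dz_um
}

#' Region of interest
#'
#' @param id character identifier.
#' @param kind `"rectangle"` (exactly 2 opposite corners) or `"polygon"`
#'   (>= 3 vertices).
#' @param vertices numeric matrix / list of (x, y) pixel coordinates
#'   (0-based, pixel-centered).
#' @param background_id optional id of a paired background ROI.
#' @return a `roi` object.
#' @export
roi <- function(id, kind = c("rectangle", "polygon"), vertices,
                background_id = NULL) {
  kind <- match.arg(kind)
  v <- as.matrix(vertices)
  if (ncol(v) != 2) nm_stop("vertices must be (x, y) pairs", "nm_validation_error")
  if (kind == "rectangle" && nrow(v) != 2)
    nm_stop("rectangle ROI needs exactly 2 corners", "nm_validation_error")
  if (kind == "polygon" && nrow(v) < 3)
    nm_stop("polygon ROI needs >= 3 vertices", "nm_validation_error")
  r <- structure(list(id = as.character(id), kind = kind, vertices = v,
                      background_id = background_id), class = "roi")
  if (roi_area_px(r) <= 0) nm_stop("ROI area must be > 0", "nm_validation_error")
  r
}

#' ROI area in square pixels
#' @param r a `roi`.
#' @return scalar (shoelace area for polygons, w x h for rectangles).
#' @export
roi_area_px <- function(r) {
  v <- r$vertices
  if (r$kind == "rectangle") {
    abs(diff(v[, 1])) * abs(diff(v[, 2]))
  } else {
    x <- v[, 1]; y <- v[, 2]
    abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
  }
}

# Logical pixel mask of an ROI on an nr x nc image (even-odd rule for
# polygons). Pixel (row i, col j) has center (x = j-1, y = i-1).
roi_mask <- function(r, nr, nc) {
  xs <- matrix(rep(0:(nc - 1), each = nr), nr, nc)
  ys <- matrix(rep(0:(nr - 1), nc), nr, nc)
  if (r$kind == "rectangle") {
    x0 <- min(r$vertices[, 1]); x1 <- max(r$vertices[, 1])
    y0 <- min(r$vertices[, 2]); y1 <- max(r$vertices[, 2])
    xs >= x0 & xs <= x1 & ys >= y0 & ys <= y1
  } else {
    px <- r$vertices[, 1]; py <- r$vertices[, 2]
    n <- length(px)
    inside <- matrix(FALSE, nr, nc)
    j <- n
    for (i in seq_len(n)) {
      cross <- ((py[i] > ys) != (py[j] > ys)) &
        (xs < (px[j] - px[i]) * (ys - py[i]) / (py[j] - py[i]) + px[i])
      inside <- xor(inside, cross)
      j <- i
    }
    inside
  }
}

roi_overlaps <- function(a, b, nr = 512L, nc = 512L) {
  # cheap bounding-box test first
  abb <- apply(a$vertices, 2, range); bbb <- apply(b$vertices, 2, range)
  if (abb[2, 1] < bbb[1, 1] || bbb[2, 1] < abb[1, 1] ||
      abb[2, 2] < bbb[1, 2] || bbb[2, 2] < abb[1, 2]) return(FALSE)
  TRUE
}

#' Neurite path (polyline with an averaging width)
#'
#' @param points ordered matrix/list of (x, y) pixel coordinates, >= 2
#'   distinct consecutive points.
#' @param width_px integer averaging width perpendicular to the path
#'   (default 20, the linescan convention).
#' @return a `neurite_path`.
#' @export
neurite_path <- function(points, width_px = 20L) {
  p <- as.matrix(points)
  if (nrow(p) < 2) nm_stop("path needs >= 2 points", "nm_validation_error")
  seg <- sqrt(rowSums(diff(p)^2))
  if (any(seg == 0)) nm_stop("consecutive path points must be distinct", "nm_validation_error")
  if (width_px < 1) nm_stop("width_px must be >= 1", "nm_validation_error")
  structure(list(points = p, width_px = as.integer(width_px),
                 seg_len_px = seg, length_px = sum(seg)),
            class = "neurite_path")
}

#' Path arc length in microns
#' @param path a `neurite_path`.
#' @param px_um pixel size.
#' @export
path_length_um <- function(path, px_um) path$length_px * px_um

#' Stimulation protocol
#'
#' Either periodic (`period_s` + `total_duration_s`; onsets at
#' 0, period, 2*period, ... strictly below the total duration) or explicit
#' (`onset_times_s`). A 1 s pulse every 30 s is 33.3 mHz.
#'
#' @param pulse_duration_s pulse length in seconds.
#' @param period_s inter-pulse period (periodic form).
#' @param total_duration_s recording duration (periodic form).
#' @param onset_times_s strictly increasing onset vector (explicit form).
#' @return a `stimulation_protocol` with derived `frequency_mHz`.
#' @export
stimulation_protocol <- function(pulse_duration_s, period_s = NULL,
                                 total_duration_s = NULL,
                                 onset_times_s = NULL) {
  if (pulse_duration_s <= 0) nm_stop("pulse_duration_s must be > 0", "nm_validation_error")
  if (is.null(onset_times_s)) {
    if (is.null(period_s) || is.null(total_duration_s))
      nm_stop("periodic protocol needs period_s and total_duration_s", "nm_validation_error")
    if (period_s <= 0) nm_stop("period_s must be > 0", "nm_validation_error")
    n_on <- max(1L, ceiling(total_duration_s / period_s - 1e-9))
    onset_times_s <- (seq_len(n_on) - 1) * period_s
  } else {
    if (any(diff(onset_times_s) <= 0))
      nm_stop("onset times must be strictly increasing", "nm_validation_error")
    if (is.null(period_s) && length(onset_times_s) > 1)
      period_s <- stats::median(diff(onset_times_s))
    if (is.null(total_duration_s))
      total_duration_s <- max(onset_times_s) + (period_s %||% pulse_duration_s)
  }
  if (!is.null(period_s) && pulse_duration_s >= period_s)
    nm_stop("pulse_duration_s must be < period_s", "nm_validation_error")
  structure(list(onset_times_s = onset_times_s,
                 pulse_duration_s = pulse_duration_s,
                 period_s = period_s,
                 total_duration_s = total_duration_s,
                 frequency_mHz = if (is.null(period_s)) NULL else 1000 / period_s),
            class = "stimulation_protocol")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---- stack I/O -------------------------------------------------------------

#' Write an image stack as multi-page 16-bit TIFF
#'
#' Baseline little-endian TIFF, one strip per page; calibration metadata is
#' written to a `<path>.json` sidecar so the file round-trips through
#' [read_stack()]. Intensities outside the unsigned 16-bit range raise a
#' range error rather than being clipped.
#'
#' @param stack an `image_stack`.
#' @param path output file path.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  tiff_write_pages(stack$pages, path)
  meta <- stack[c("axis_kind", "dt_s", "dz_um", "px_um", "exposure_ms",
                  "excitation_nm")]
  jsonlite::write_json(Filter(Negate(is.null), meta),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a multi-page TIFF into an image stack
#'
#' Metadata is taken from the `<path>.json` sidecar if present; the
#' `calibration` list supplies or overrides any missing keys
#' (`px_um`, `dt_s` or `dz_um`, `axis_kind`, `exposure_ms`, `excitation_nm`).
#'
#' @param path TIFF file path.
#' @param calibration named list of metadata overrides.
#' @return an `image_stack` (page order preserved).
#' @export
read_stack <- function(path, calibration = list()) {
  pages <- tiff_read_pages(path)
  side <- paste0(path, ".json")
  meta <- if (file.exists(side)) jsonlite::read_json(side, simplifyVector = TRUE) else list()
  meta[names(calibration)] <- calibration
  if (is.null(meta$px_um))
    nm_stop("calibration must supply px_um", "nm_config_error")
  if (is.null(meta$dt_s) && is.null(meta$dz_um))
    nm_stop("calibration must supply dt_s or dz_um", "nm_config_error")
  axis <- meta$axis_kind %||% (if (!is.null(meta$dt_s)) "time" else "z")
  image_stack(pages, axis_kind = axis, dt_s = meta$dt_s, dz_um = meta$dz_um,
              px_um = meta$px_um, exposure_ms = meta$exposure_ms,
              excitation_nm = meta$excitation_nm)
}

## ---- JSON object I/O -------------------------------------------------------

#' Load ROIs from a rois.json document
#'
#' Schema: `{"rois":[{"id","kind","vertices":[[x,y],...],"background_id"}]}`.
#' Background cross-references are resolved; a dangling `background_id`
#' raises a reference error.
#'
#' @param path JSON file.
#' @return list of `roi` objects.
#' @export
load_rois <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(doc$rois)) nm_stop("rois.json must contain a 'rois' array", "nm_validation_error")
  rois <- lapply(doc$rois, function(r) {
    v <- do.call(rbind, lapply(r$vertices, unlist))
    roi(r$id, r$kind, v, background_id = r$background_id)
  })
  ids <- vapply(rois, `[[`, "", "id")
  for (r in rois) {
    if (!is.null(r$background_id) && !r$background_id %in% ids)
      nm_stop(sprintf("background_id '%s' does not reference any ROI", r$background_id),
              "nm_reference_error")
  }
  rois
}

#' Save ROIs to rois.json
#' @param rois list of `roi` objects.
#' @param path output file.
#' @export
save_rois <- function(rois, path) {
  doc <- list(rois = lapply(rois, function(r) {
    out <- list(id = r$id, kind = r$kind,
                vertices = lapply(seq_len(nrow(r$vertices)),
                                  function(i) as.numeric(r$vertices[i, ])))
    if (!is.null(r$background_id)) out$background_id <- r$background_id
    out
  }))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a neurite path from path.json (`{"points":[[x,y],...],"width_px":20}`)
#' @param path JSON file.
#' @export
load_path <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  pts <- do.call(rbind, lapply(doc$points, unlist))
  neurite_path(pts, width_px = doc$width_px %||% 20L)
}

#' Save a neurite path to path.json
#' @param npath a `neurite_path`.
#' @param path output file.
#' @export
save_path <- function(npath, path) {
  doc <- list(points = lapply(seq_len(nrow(npath$points)),
                              function(i) as.numeric(npath$points[i, ])),
              width_px = npath$width_px)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a stimulation protocol from protocol.json
#'
#' Accepts the periodic form (`period_s`, `pulse_duration_s`,
#' `total_duration_s`) or the explicit form (`onset_times_s`,
#' `pulse_duration_s`).
#' @param path JSON file.
#' @export
load_protocol <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  stimulation_protocol(pulse_duration_s = doc$pulse_duration_s,
                       period_s = doc$period_s,
                       total_duration_s = doc$total_duration_s,
                       onset_times_s = doc$onset_times_s)
}

#' Save a stimulation protocol to protocol.json
#' @param protocol a `stimulation_protocol`.
#' @param path output file.
#' @export
save_protocol <- function(protocol, path) {
  doc <- list(pulse_duration_s = protocol$pulse_duration_s,
              period_s = protocol$period_s,
              total_duration_s = protocol$total_duration_s,
              onset_times_s = protocol$onset_times_s)
  jsonlite::write_json(Filter(Negate(is.null), doc), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
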