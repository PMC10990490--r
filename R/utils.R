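# Shared numerical helpers: errors, Gaussian filtering, thresholding,
# connected components, integration, RNG substreams.

nm_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "nm_error")))
}

nm_warn <- function(msg, class = "nm_warning") {
  warning(warningCondition(msg, class = c(class, "nm_warning")))
}

#' Trapezoidal integral
#'
#' @param x ordinate vector (increasing).
#' @param y values at `x`.
#' @return scalar integral.
#' @keywords internal
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((y[-1] + y[-n]) / 2 * diff(x))
}

#' Robust SD via the median absolute deviation
#' @keywords internal
mad_sd <- function(x) stats::mad(x, constant = 1.4826)

# Derive a reproducible 31-bit substream seed from a global seed and an index.
# Counter-based so adding one object never reshuffles the streams of others.
substream_seed <- function(seed, index) {
  s <- (as.double(seed) %% 2147483647) * 48271 + as.double(index) * 16807
  as.integer(s %% 2147483629) + 1L
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; restores the
# caller's RNG afterwards so generators do not perturb user code.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

gauss_kernel1d <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(4 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

# Separable Gaussian blur with replicated edges. sigma in pixels.
blur2d <- function(mat, sigma) {
  if (sigma <= 0) return(mat)
  k <- gauss_kernel1d(sigma)
  r <- (length(k) - 1L) %/% 2L
  nr <- nrow(mat); nc <- ncol(mat)
  # rows (y direction)
  out <- matrix(0, nr, nc)
  for (j in seq_along(k)) {
    off <- j - r - 1L
    idx <- pmin(pmax(seq_len(nr) + off, 1L), nr)
    out <- out + k[j] * mat[idx, , drop = FALSE]
  }
  # columns (x direction)
  out2 <- matrix(0, nr, nc)
  for (j in seq_along(k)) {
    off <- j - r - 1L
    idx <- pmin(pmax(seq_len(nc) + off, 1L), nc)
    out2 <- out2 + k[j] * out[, idx, drop = FALSE]
  }
  out2
}

# Otsu's between-class-variance threshold on a numeric matrix/vector.
otsu_threshold <- function(x, nbins = 256L) {
  x <- as.numeric(x)
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  h <- graphics::hist(x, breaks = seq(rng[1], rng[2], length.out = nbins + 1L),
                      plot = FALSE)
  w <- h$counts / length(x)
  mids <- h$mids
  omega <- cumsum(w)
  mu <- cumsum(w * mids)
  mu_t <- mu[length(mu)]
  denom <- omega * (1 - omega)
  denom[denom == 0] <- NA
  sigma_b <- (mu_t * omega - mu)^2 / denom
  mids[which.max(sigma_b)]
}

# 4-connected component labelling by iterative minimum-label propagation.
# Suited to the small scenes used here (objects tens of pixels across).
label_components <- function(mask) {
  stopifnot(is.logical(mask) || all(mask %in% c(0, 1)))
  mask <- mask != 0
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0, nr, nc)
  lab[mask] <- seq_len(sum(mask))
  if (!any(mask)) return(lab)
  big <- sum(mask) + 1
  repeat {
    padded <- function(di, dj) {
      m <- matrix(big, nr, nc)
      ri <- seq_len(nr) + di; cj <- seq_len(nc) + dj
      ok_r <- ri >= 1L & ri <= nr; ok_c <- cj >= 1L & cj <= nc
      m[ok_r, ok_c] <- lab[ri[ok_r], cj[ok_c], drop = FALSE]
      m[m == 0] <- big
      m
    }
    cand <- pmin(padded(1L, 0L), padded(-1L, 0L), padded(0L, 1L), padded(0L, -1L))
    new <- lab
    upd <- mask & cand < lab & cand < big
    new[upd] <- cand[upd]
    if (identical(new, lab)) break
    lab <- new
  }
  # compact labels to 1..K
  u <- sort(unique(lab[lab > 0]))
  lab[lab > 0] <- match(lab[lab > 0], u)
  lab
}

# Local maxima of a vector above `threshold`, with minimum separation
# `min_sep` samples (keeps the larger of two close maxima).
local_maxima <- function(v, threshold = -Inf, min_sep = 1L) {
  n <- length(v)
  if (n < 3L) return(integer(0))
  idx <- which(v[2:(n - 1L)] >= v[1:(n - 2L)] & v[2:(n - 1L)] > v[3:n] &
                 v[2:(n - 1L)] > threshold) + 1L
  if (length(idx) <= 1L || min_sep <= 1L) return(idx)
  keep <- logical(length(idx))
  ord <- order(v[idx], decreasing = TRUE)
  taken <- integer(0)
  for (i in ord) {
    if (!length(taken) || all(abs(idx[i] - taken) >= min_sep)) {
      keep[i] <- TRUE
      taken <- c(taken, idx[i])
    }
  }
  sort(idx[keep])
}

# Centered moving average with window of w samples (odd; w<=1 is identity).
moving_average <- function(v, w) {
  w <- as.integer(w)
  if (w <= 1L) return(v)
  if (w %% 2L == 0L) w <- w + 1L
  n <- length(v)
  cs <- cumsum(c(0, v))
  half <- (w - 1L) %/% 2L
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}
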