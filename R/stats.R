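# Statistical layer: ROUT outlier removal (Q budget), FRAP animal
# exclusion, one-way ANOVA with Dunnett's many-to-one comparisons,
# paired t-test, and the Pearson effect-size screen.

#' ROUT outlier detection on a list of measurements
#'
#' Robust location/scale by iteratively reweighted fitting of a constant
#' model with Lorentzian weights; scale is the robust standard deviation
#' of the residuals (the 68.27th percentile of |residuals|, adjusted by
#' N/(N-K)). Each point's two-sided tail probability under t with N-K df
#' is computed and outliers are flagged by a Benjamini-Hochberg-style
#' step-up at false-discovery rate Q on the most extreme residuals.
#'
#' @param values numeric vector (n >= 5).
#' @param Q_percent false-discovery budget in percent (default 1).
#' @return an `outlier_result`: `kept_indices`, `outlier_indices`,
#'   `Q_percent`, `method_details` (center, scale, per-point t and p).
#' @export
rout_outliers <- function(values, Q_percent = 1.0) {
  x <- as.numeric(values)
  n <- length(x)
  if (n < 5L) nm_stop("ROUT needs n >= 5", "nm_insufficient_data")
  K <- 1L
  center <- stats::median(x)
  rsdr <- rsdr_scale(x - center, n, K)
  if (rsdr == 0) {
    # degenerate scale: the bulk of the data is constant. Any point off
    # that constant is infinitely extreme; with no deviations at all there
    # is nothing to flag.
    dev <- which(x != center & Q_percent > 0)
    return(structure(list(kept_indices = setdiff(seq_len(n), dev),
                          outlier_indices = dev, Q_percent = Q_percent,
                          method_details = list(center = center, scale = 0,
                                                t = ifelse(x == center, 0, Inf),
                                                p = ifelse(x == center, 1, 0))),
                     class = "outlier_result"))
  }
  for (it in seq_len(100L)) {
    r <- x - center
    w <- 1 / (1 + (r / rsdr)^2)
    new_center <- sum(w * x) / sum(w)
    new_rsdr <- rsdr_scale(x - new_center, n, K)
    if (abs(new_center - center) < 1e-10 * (abs(center) + 1e-10) &&
        abs(new_rsdr - rsdr) < 1e-10 * rsdr) {
      center <- new_center; rsdr <- new_rsdr; break
    }
    center <- new_center; rsdr <- max(new_rsdr, 1e-300)
  }
  tvals <- (x - center) / rsdr
  p <- 2 * stats::pt(-abs(tvals), df = n - K)
  out_idx <- integer(0)
  if (Q_percent > 0) {
    ord <- order(p)                       # most extreme first
    crit <- Q_percent / 100 * seq_len(n) / n
    hits <- which(p[ord] <= crit)
    if (length(hits)) out_idx <- sort(ord[seq_len(max(hits))])
  }
  structure(list(kept_indices = setdiff(seq_len(n), out_idx),
                 outlier_indices = out_idx, Q_percent = Q_percent,
                 method_details = list(center = center, scale = rsdr,
                                       t = tvals, p = p)),
            class = "outlier_result")
}

# robust standard deviation of residuals: 68.27th percentile of |resid|
# with the N/(N-K) small-sample adjustment
rsdr_scale <- function(resid, n, K) {
  unname(stats::quantile(abs(resid), 0.6827)) * n / (n - K)
}

#' FRAP animal-exclusion rule
#'
#' An animal is excluded when 50% or more of its timepoints were flagged
#' as outliers.
#'
#' @param flags named list (one logical vector per animal, equal lengths)
#'   or a logical matrix (rows = animals).
#' @return list: `kept` (names/indices), `excluded`, `outlier_fraction`.
#' @export
frap_exclusion <- function(flags) {
  if (is.matrix(flags))
    flags <- stats::setNames(lapply(seq_len(nrow(flags)), function(i) flags[i, ]),
                             rownames(flags) %||% as.character(seq_len(nrow(flags))))
  lens <- vapply(flags, length, 0L)
  if (length(unique(lens)) != 1L)
    nm_stop("every animal must have the same timepoint count", "nm_validation_error")
  frac <- vapply(flags, mean, 0)
  excluded <- names(flags)[frac >= 0.5]
  list(kept = setdiff(names(flags), excluded), excluded = excluded,
       outlier_fraction = frac)
}

#' Monte Carlo reference sample for Dunnett's max-|T| distribution
#'
#' Null distribution of the maximum absolute many-to-one t statistic for
#' a one-way layout with group sizes `ns` (control first) and pooled
#' residual df. Fixed seed makes adjusted p-values reproducible
#' (documented Monte Carlo tolerance ~ 3/sqrt(n_draws)).
#'
#' @param ns integer vector of group sizes, control first.
#' @param df residual degrees of freedom (default sum(ns) - length(ns)).
#' @param n_draws draws (default 1e5).
#' @param seed RNG seed.
#' @return numeric vector of max-|T| draws.
#' @export
dunnett_reference <- function(ns, df = sum(ns) - length(ns),
                              n_draws = 1e5, seed = 1L) {
  k <- length(ns) - 1L
  with_seed(seed, {
    z0 <- stats::rnorm(n_draws, 0, sqrt(1 / ns[1]))
    s <- sqrt(stats::rchisq(n_draws, df) / df)
    maxT <- rep(0, n_draws)
    for (j in seq_len(k)) {
      zj <- stats::rnorm(n_draws, 0, sqrt(1 / ns[j + 1L]))
      tj <- abs(zj - z0) / (s * sqrt(1 / ns[j + 1L] + 1 / ns[1]))
      maxT <- pmax(maxT, tj)
    }
    maxT
  })
}

#' One-way ANOVA with Dunnett's many-to-one comparisons
#'
#' Homoscedastic one-way ANOVA (F, p) plus Dunnett-adjusted p-values for
#' every treatment-versus-control comparison:
#' `p_adj = P(max_j |T_j| >= |t_obs|)` under the joint null. With exactly
#' two groups this reduces analytically to the two-sided pooled t-test
#' (computed exactly); with more groups the reference distribution is a
#' fixed-seed Monte Carlo sample ([dunnett_reference()]).
#'
#' @param groups named list of numeric vectors (each n >= 2).
#' @param control name of the control group.
#' @param n_draws,seed Monte Carlo settings for k > 2.
#' @param reference optional precomputed [dunnett_reference()] sample
#'   (must match the design's group sizes and df).
#' @return list: `anova` (`F`, `df1`, `df2`, `p`), `comparisons`
#'   (data.frame `group`, `diff`, `t`, `p_unadjusted`, `p_adj`),
#'   `mc_tolerance`.
#' @export
anova_dunnett <- function(groups, control, n_draws = 1e5, seed = 1L,
                          reference = NULL) {
  stopifnot(is.list(groups), !is.null(names(groups)))
  if (!control %in% names(groups)) nm_stop("control group not found", "nm_validation_error")
  if (length(groups) < 2L) nm_stop("need >= 2 groups", "nm_validation_error")
  if (any(vapply(groups, length, 0L) < 2L))
    nm_stop("every group needs n >= 2", "nm_validation_error")
  ord <- c(control, setdiff(names(groups), control))
  groups <- groups[ord]
  ns <- vapply(groups, length, 0L)
  means <- vapply(groups, mean, 0)
  N <- sum(ns); k <- length(groups)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  if (ssw == 0) nm_stop("zero within-group variance everywhere", "nm_degenerate_error")
  df2 <- N - k
  s2 <- ssw / df2
  grand <- sum(ns * means) / N
  ssb <- sum(ns * (means - grand)^2)
  f <- (ssb / (k - 1)) / s2
  p_f <- stats::pf(f, k - 1, df2, lower.tail = FALSE)
  tstat <- (means[-1] - means[1]) / sqrt(s2 * (1 / ns[-1] + 1 / ns[1]))
  p_un <- 2 * stats::pt(-abs(tstat), df2)
  if (k == 2L) {
    p_adj <- p_un
    mc_tol <- 0
  } else {
    if (is.null(reference))
      reference <- dunnett_reference(ns, df2, n_draws, seed)
    p_adj <- vapply(tstat, function(t0) mean(reference >= abs(t0)), 0)
    p_adj <- pmax(p_adj, p_un)       # adjusted p can never beat unadjusted
    mc_tol <- 3 / sqrt(length(reference))
  }
  list(anova = list(F = f, df1 = k - 1L, df2 = df2, p = p_f),
       comparisons = data.frame(group = names(groups)[-1],
                                diff = unname(means[-1] - means[1]),
                                t = unname(tstat),
                                p_unadjusted = unname(p_un),
                                p_adj = unname(p_adj)),
       mc_tolerance = mc_tol)
}

#' Paired two-sided t-test
#'
#' @param values_a,values_b paired measurements (equal length, n >= 3).
#' @return list: `p`, `t`, `df`, `mean_difference`, `degenerate` (TRUE
#'   when the differences have zero variance).
#' @export
paired_t <- function(values_a, values_b) {
  if (length(values_a) != length(values_b))
    nm_stop("paired samples must have equal length", "nm_validation_error")
  n <- length(values_a)
  if (n < 3L) nm_stop("paired t needs n >= 3", "nm_insufficient_data")
  d <- values_a - values_b
  if (stats::sd(d) == 0) {
    return(list(p = if (mean(d) == 0) 1 else NA_real_, t = NA_real_,
                df = n - 1L, mean_difference = mean(d), degenerate = TRUE))
  }
  tt <- stats::t.test(values_a, values_b, paired = TRUE)
  list(p = tt$p.value, t = unname(tt$statistic), df = unname(tt$parameter),
       mean_difference = mean(d), degenerate = FALSE)
}

#' Post hoc Pearson effect-size screen
#'
#' Pearson r between the values and a covariate (acquisition order by
#' default); the dataset passes when `|r| < 0.3` (strict).
#'
#' @param values numeric vector (n >= 3).
#' @param covariate numeric vector of equal length (default: order).
#' @return list: `r`, `pass` (NA when r is undefined), `threshold`.
#' @export
effect_size_screen <- function(values, covariate = seq_along(values)) {
  if (length(values) != length(covariate))
    nm_stop("covariate must match values in length", "nm_validation_error")
  if (length(values) < 3L) nm_stop("need n >= 3", "nm_insufficient_data")
  if (stats::sd(values) == 0 || stats::sd(covariate) == 0)
    return(list(r = NA_real_, pass = NA, threshold = 0.3))
  r <- stats::cor(values, covariate)
  list(r = r, pass = abs(r) < 0.3, threshold = 0.3)
}
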