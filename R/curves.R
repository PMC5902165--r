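#' LOESS-smooth one expression time course
#'
#' Locally weighted linear regression (tricube weights, degree 1) of a log2
#' expression curve, evaluated both on the observed time grid and on a dense
#' grid used for derivative-based features. Deterministic.
#'
#' @param values log2 expression, one per time point.
#' @param times Sampling times in hours, strictly increasing and evenly
#'   spaced (the reference design is 25 points, 0-48 h every 2 h).
#' @param span Smoothing span as the fraction of points per local window
#'   (default 0.3, about 8 of 25 points).
#' @param dense_dt Dense-grid step in hours (default 0.5).
#' @return List with `fitted` (on `times`), `dense_times`, `dense` (on the
#'   dense grid), and the inputs.
#' @export
loess_smooth <- function(values, times, span = 0.3, dense_dt = 0.5) {
  stopifnot(length(values) == length(times), !is.unsorted(times))
  if (span * length(times) < 4)
    stop("span too small: fewer than 4 points per local window")
  if (any(!is.finite(values))) stop("curve contains missing values")
  if (stats::var(values) == 0) {
    dense_times <- seq(min(times), max(times), by = dense_dt)
    return(list(fitted = values, dense_times = dense_times,
                dense = rep(values[1], length(dense_times)),
                values = values, times = times))
  }
  fit <- stats::loess(values ~ times, span = span, degree = 1,
                      family = "gaussian",
                      control = stats::loess.control(surface = "direct"))
  dense_times <- seq(min(times), max(times), by = dense_dt)
  list(fitted = as.numeric(stats::predict(fit, data.frame(times = times))),
       dense_times = dense_times,
       dense = as.numeric(stats::predict(fit, data.frame(times = dense_times))),
       values = values, times = times)
}

# Major interior extrema of a dense smoothed curve: sign-change extrema
# whose value differs from both neighboring turning points (including the
# endpoints) by at least min_swing_frac of the curve range. Small wiggles
# that LOESS leaves in flat stretches of a noisy curve are thereby ignored.
# Used for seed selection only; the raw extremum features keep the plain
# sign-change definition.
.major_extrema <- function(dense, dtimes, min_swing_frac = 0.2) {
  rng <- diff(range(dense))
  if (rng == 0) return(numeric(0))
  thr <- min_swing_frac * rng
  nd <- length(dense)
  d <- diff(dense)
  sgn <- sign(d)
  sgn[sgn == 0] <- 1
  flips <- which(diff(sgn) != 0) + 1L
  if (length(flips) == 0) return(numeric(0))
  pts <- c(1L, flips, nd)
  vals <- dense[pts]
  keep <- vapply(seq_along(flips), function(j) {
    v <- vals[j + 1]
    min(abs(v - vals[j]), abs(v - vals[j + 2])) >= thr
  }, TRUE)
  dtimes[flips[keep]]
}

# Pearson autocorrelation of x at an index lag (not mean-centred acf:
# a plain correlation between the series and its shifted copy).
.lag_cor <- function(x, lag) {
  n <- length(x)
  if (lag >= n - 2) return(NA_real_)
  a <- x[seq_len(n - lag)]
  b <- x[seq_len(n - lag) + lag]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(0)
  stats::cor(a, b)
}

#' Shape features of one smoothed expression curve
#'
#' Computes the ten per-curve measures used by the in vitro classifier:
#' extreme slopes, the times of the first two interior extrema, the
#' min/max ratio on the linear scale, the 24-h autocorrelation, a
#' scatter measure, normalized residuals around the LOESS and around a
#' straight line, and a period estimate.
#'
#' Definitions: slopes are central differences of the dense smoothed curve
#' (log2 units/h); extremum times are the first and second sign changes of
#' that derivative (sentinel `48` when absent); `minmax_ratio` is
#' `min(2^s)/max(2^s)` of the smoothed curve; `autocorr24` is the Pearson
#' correlation of the raw series with itself shifted by `ac_lag_h`;
#' `scattering` is `mean(|diff(raw)|) / range(raw)` (a normalized total
#' variation: low for smooth curves, high for point-to-point noise);
#' `resid_loess` and
#' `resid_linear` are RMS residuals (around the LOESS fit and the
#' least-squares line) divided by `sd(raw)`; `period_est` is the lag in
#' `period_window` maximizing the dense smoothed curve's autocorrelation
#' (0 when no lag correlates positively).
#'
#' @param sm Output of [loess_smooth()].
#' @param ac_lag_h Raw autocorrelation lag in hours (default 24).
#' @param period_window Period search window in hours (default `c(16, 32)`).
#' @return Named numeric vector of the 10 features plus five auxiliaries
#'   used only for seed selection: `lin_slope` (the least-squares trend),
#'   `n_major_extrema` and `major_extremum1_t` (interior extrema surviving a
#'   prominence filter of 20% of the curve range, which ignores the small
#'   wiggles LOESS leaves in flat stretches of a noisy curve), and
#'   `harm_phase` / `harm_r2` (peak phase and variance fraction of an
#'   ordinary least-squares 24-h cosine fit to the raw curve).
#' @export
extract_features <- function(sm, ac_lag_h = 24, period_window = c(16, 32)) {
  raw <- sm$values
  times <- sm$times
  dt_raw <- times[2] - times[1]
  dense <- sm$dense
  dtimes <- sm$dense_times
  dd <- dtimes[2] - dtimes[1]

  if (stats::sd(raw) == 0) {
    return(c(max_slope = 0, min_slope = 0, extremum1_t = max(times),
             extremum2_t = max(times), minmax_ratio = 1, autocorr24 = 0,
             scattering = 0, resid_loess = 0, resid_linear = 0,
             period_est = 0, lin_slope = 0, n_major_extrema = 0,
             major_extremum1_t = max(times), harm_phase = 0, harm_r2 = 0))
  }

  # central-difference derivative on the dense grid
  nd <- length(dense)
  deriv <- (dense[c(2:nd, nd)] - dense[c(1, 1:(nd - 1))]) /
    (dtimes[c(2:nd, nd)] - dtimes[c(1, 1:(nd - 1))])

  sgn <- sign(deriv)
  sgn[sgn == 0] <- 1
  flips <- which(diff(sgn) != 0)
  ext_t <- dtimes[flips + 1]
  ext_t <- ext_t[ext_t > min(times) & ext_t < max(times)]
  extremum1_t <- if (length(ext_t) >= 1) ext_t[1] else max(times)
  extremum2_t <- if (length(ext_t) >= 2) ext_t[2] else max(times)

  lin <- stats::lm.fit(cbind(1, times), raw)
  rng <- diff(range(raw))

  # period: best positive autocorrelation peak of the dense smoothed curve
  lag_idx <- seq(ceiling(period_window[1] / dd), floor(period_window[2] / dd))
  ac <- vapply(lag_idx, function(l) .lag_cor(dense, l), 0)
  period_est <- if (all(is.na(ac)) || max(ac, na.rm = TRUE) <= 0) 0 else
    lag_idx[which.max(ac)] * dd

  major <- .major_extrema(dense, dtimes)

  # OLS 24-h cosine fit on the raw curve (seed-selection auxiliary)
  wh <- 2 * pi / ac_lag_h
  Xh <- cbind(1, cos(wh * times), sin(wh * times))
  hfit <- stats::lm.fit(Xh, raw)
  harm_phase <- (atan2(hfit$coefficients[3], hfit$coefficients[2]) *
                   ac_lag_h / (2 * pi)) %% ac_lag_h
  harm_r2 <- 1 - sum(hfit$residuals^2) / sum((raw - mean(raw))^2)

  c(max_slope = max(deriv),
    min_slope = min(deriv),
    extremum1_t = extremum1_t,
    extremum2_t = extremum2_t,
    minmax_ratio = min(2^dense) / max(2^dense),
    autocorr24 = {
      l <- round(ac_lag_h / dt_raw)
      v <- .lag_cor(raw, l)
      if (is.na(v)) 0 else v
    },
    scattering = mean(abs(diff(raw))) / rng,
    resid_loess = sqrt(mean((raw - sm$fitted)^2)) / stats::sd(raw),
    resid_linear = sqrt(mean(lin$residuals^2)) / stats::sd(raw),
    period_est = period_est,
    lin_slope = unname(lin$coefficients[2]),
    n_major_extrema = length(major),
    major_extremum1_t = if (length(major) >= 1) major[1] else max(times),
    harm_phase = unname(harm_phase),
    harm_r2 = harm_r2)
}

#' Feature table for every gene x condition curve
#'
#' Replicate measurements at the same time point are averaged, then each
#' curve is LOESS-smoothed and summarized by [extract_features()].
#'
#' @param expr log2 RPKM matrix, genes x samples.
#' @param samples Sample sheet with `sample_id`, `donor_id`, `condition`,
#'   `time_h`.
#' @param span,dense_dt Passed to [loess_smooth()].
#' @param ac_lag_h,period_window Passed to [extract_features()].
#' @return data.frame with `gene_id`, `donor_id`, `condition`, `curve_id`
#'   and the feature columns.
#' @export
curve_feature_table <- function(expr, samples, span = 0.3, dense_dt = 0.5,
                                ac_lag_h = 24, period_window = c(16, 32)) {
  stopifnot(all(colnames(expr) %in% samples$sample_id))
  samples <- samples[match(colnames(expr), samples$sample_id), ]
  key <- paste(samples$donor_id, samples$condition, sep = "|")
  rows <- list()
  for (cu in unique(key)) {
    idx <- which(key == cu)
    tt <- samples$time_h[idx]
    ut <- sort(unique(tt))
    # average replicates per time point
    agg <- vapply(ut, function(t0) rowMeans(expr[, idx[tt == t0], drop = FALSE]),
                  numeric(nrow(expr)))
    if (nrow(expr) == 1L) agg <- matrix(agg, nrow = 1)
    feats <- t(apply(agg, 1, function(v) {
      sm <- loess_smooth(v, ut, span = span, dense_dt = dense_dt)
      extract_features(sm, ac_lag_h = ac_lag_h, period_window = period_window)
    }))
    meta <- data.frame(
      gene_id = rownames(expr),
      donor_id = samples$donor_id[idx][1],
      condition = samples$condition[idx][1],
      curve_id = paste(rownames(expr), cu, sep = "|"),
      stringsAsFactors = FALSE
    )
    rows[[cu]] <- cbind(meta, as.data.frame(feats))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Linear-scale peak-to-trough amplitude of a smoothed curve
#'
#' @param sm Output of [loess_smooth()] (log2 scale).
#' @return `max(2^s) - min(2^s)` over the window; 0 for a constant curve.
#' @export
curve_amplitude <- function(sm) {
  max(2^sm$dense) - min(2^sm$dense)
}
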