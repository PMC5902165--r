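# Orthogonal rotation diagonalizing the donor random-intercept covariance.
# For Z the donor indicator matrix, tcrossprod(Z) is block diagonal; its
# eigenvectors U turn V = sigma_e^2 (I + lambda Z Z') into a diagonal matrix
# with entries sigma_e^2 (1 + lambda * e_i). Computed once per design.
.donor_rotation <- function(donor) {
  donor <- as.factor(donor)
  Z <- stats::model.matrix(~ 0 + donor)
  eg <- eigen(tcrossprod(Z), symmetric = TRUE)
  list(U = eg$vectors, e = pmax(eg$values, 0))
}

# Profile ML log-likelihood at variance ratio lambda = sigma_d^2 / sigma_e^2,
# in the rotated basis: yr = U'y, Xr = U'X. Returns loglik and the GLS pieces.
.profile_ll <- function(lambda, yr, Xr, e) {
  n <- length(yr)
  w <- 1 / (1 + lambda * e)
  Xw <- Xr * w
  beta <- solve(crossprod(Xw, Xr), crossprod(Xw, yr))
  r <- yr - Xr %*% beta
  rss <- sum(w * r^2)
  s2 <- rss / n
  ll <- -0.5 * (n * log(2 * pi * s2) + n + sum(log(1 + lambda * e)))
  list(ll = ll, beta = drop(beta), sigma_e2 = s2, sigma_d2 = lambda * s2)
}

# Maximize the profile likelihood over lambda >= 0 (log-scale search plus an
# explicit boundary evaluation at lambda = 0).
.fit_ml <- function(yr, Xr, e) {
  obj <- function(ll) .profile_ll(exp(ll), yr, Xr, e)$ll
  opt <- stats::optimize(obj, interval = c(-18, 18), maximum = TRUE,
                         tol = 1e-9)
  at0 <- .profile_ll(0, yr, Xr, e)
  if (at0$ll >= opt$objective) {
    at0$boundary <- TRUE
    return(at0)
  }
  out <- .profile_ll(exp(opt$maximum), yr, Xr, e)
  out$boundary <- out$sigma_d2 < 1e-8 * out$sigma_e2
  out
}

#' Fit the donor random-intercept harmonic model to one gene
#'
#' Fits, by maximum likelihood, `y = mu + a cos(wt) + b sin(wt) + u_donor + e`
#' with `w = 2 pi / period_h`, `u_donor ~ N(0, sigma_d^2)` iid per donor, and
#' a Gaussian residual — together with the null model without the harmonic
#' terms, on the identical observation set. ML (not REML) is used so the
#' likelihood-ratio statistic comparing the two fixed-effect structures is
#' valid. Estimation profiles the fixed effects and residual variance
#' analytically by generalized least squares in the eigenbasis of the donor
#' design, leaving a one-dimensional search over the variance ratio.
#'
#' @param y Numeric vector of log2 expression values, one per sample;
#'   non-finite entries are dropped together with their design rows.
#' @param times Numeric vector of sampling times in hours.
#' @param donor Factor or character vector of donor IDs.
#' @param period_h Oscillation period in hours (default 24).
#' @return A list with `mu`, `a`, `b`, `sigma_donor2`, `sigma_e2`,
#'   `loglik_full`, `loglik_null`, `lrt_stat`, `amplitude` (log2
#'   peak-to-trough, `2 sqrt(a^2 + b^2)`), `phase_h` (hours of the fitted
#'   peak in `[0, period_h)`), `n_obs`, `boundary` (TRUE when the donor
#'   variance was pinned at zero).
#' @export
fit_harmonic_mixed <- function(y, times, donor, period_h = 24) {
  keep <- is.finite(y)
  y <- y[keep]; times <- times[keep]; donor <- factor(donor[keep])
  if (length(y) < 6L) stop("need at least 6 usable observations")
  if (nlevels(donor) < 2L) stop("need at least 2 donors")
  tmod <- times %% period_h
  if (length(unique(tmod)) < 3L)
    stop("singular harmonic design: fewer than 3 distinct times")

  w <- 2 * pi / period_h
  X <- cbind(1, cos(w * times), sin(w * times))
  rot <- .donor_rotation(donor)
  yr <- drop(crossprod(rot$U, y))
  Xr <- crossprod(rot$U, X)

  full <- .fit_ml(yr, Xr, rot$e)
  null <- .fit_ml(yr, Xr[, 1, drop = FALSE], rot$e)
  lrt <- 2 * (full$ll - null$ll)
  if (lrt < -1e-8) stop("negative LRT statistic: ", lrt)
  lrt <- max(lrt, 0)

  ap <- amplitude_phase(full$beta[2], full$beta[3], period_h)
  list(mu = full$beta[1], a = full$beta[2], b = full$beta[3],
       sigma_donor2 = full$sigma_d2, sigma_e2 = full$sigma_e2,
       loglik_full = full$ll, loglik_null = null$ll, lrt_stat = lrt,
       amplitude = ap[["amplitude"]], phase_h = ap[["phase_h"]],
       n_obs = length(y), boundary = full$boundary)
}

#' Fit the harmonic mixed model to every gene of an expression layer
#'
#' Applies [fit_harmonic_mixed()] row-wise, dropping masked (`NA`/`-Inf`)
#' samples per gene, and appends chi-squared p-values (df = 2) and
#' Benjamini-Hochberg q-values. Genes with fewer than 6 usable samples or
#' fewer than 2 donors get an `NA` row rather than being dropped.
#'
#' @param expr log2 expression matrix, genes x samples.
#' @param samples Sample sheet with `sample_id`, `donor_id`, `time_h`
#'   matching `colnames(expr)`.
#' @param period_h Period in hours (default 24).
#' @return data.frame with one row per gene: `gene_id`, `mu`, `a`, `b`,
#'   `sigma_donor2`, `sigma_e2`, `lrt_stat`, `p`, `q`, `amplitude`,
#'   `phase_h`, `n_obs`, `boundary`.
#' @export
fit_harmonic_layer <- function(expr, samples, period_h = 24) {
  stopifnot(all(colnames(expr) %in% samples$sample_id))
  samples <- samples[match(colnames(expr), samples$sample_id), ]
  times <- samples$time_h
  donor <- factor(samples$donor_id)
  w <- 2 * pi / period_h
  X <- cbind(1, cos(w * times), sin(w * times))

  # cache the rotated design per missingness pattern (usually one pattern)
  cache <- new.env(parent = emptyenv())
  get_rot <- function(keep) {
    key <- paste(which(keep), collapse = ",")
    if (is.null(cache[[key]])) {
      rot <- .donor_rotation(donor[keep])
      rot$Xr <- crossprod(rot$U, X[keep, , drop = FALSE])
      cache[[key]] <- rot
    }
    cache[[key]]
  }

  na_row <- list(mu = NA_real_, a = NA_real_, b = NA_real_,
                 sigma_donor2 = NA_real_, sigma_e2 = NA_real_,
                 lrt_stat = NA_real_, amplitude = NA_real_,
                 phase_h = NA_real_, n_obs = 0L, boundary = NA)
  rows <- vector("list", nrow(expr))
  for (i in seq_len(nrow(expr))) {
    yi <- expr[i, ]
    keep <- is.finite(yi)
    if (sum(keep) < 6L || nlevels(droplevels(donor[keep])) < 2L) {
      rows[[i]] <- na_row
      next
    }
    rot <- get_rot(keep)
    yr <- drop(crossprod(rot$U, yi[keep]))
    full <- .fit_ml(yr, rot$Xr, rot$e)
    null <- .fit_ml(yr, rot$Xr[, 1, drop = FALSE], rot$e)
    ap <- amplitude_phase(full$beta[2], full$beta[3], period_h)
    rows[[i]] <- list(mu = full$beta[1], a = full$beta[2], b = full$beta[3],
                      sigma_donor2 = full$sigma_d2, sigma_e2 = full$sigma_e2,
                      lrt_stat = max(2 * (full$ll - null$ll), 0),
                      amplitude = ap[["amplitude"]], phase_h = ap[["phase_h"]],
                      n_obs = sum(keep), boundary = full$boundary)
  }
  out <- do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
  out <- cbind(gene_id = rownames(expr), out, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out$p <- NA_real_
  ok <- !is.na(out$lrt_stat)
  out$p[ok] <- lrt_pvalue(out$lrt_stat[ok])
  out$q <- adjust_bh(out$p)
  out[, c("gene_id", "mu", "a", "b", "sigma_donor2", "sigma_e2",
          "lrt_stat", "p", "q", "amplitude", "phase_h", "n_obs", "boundary")]
}

#' Likelihood-ratio p-value against a chi-squared(2) reference
#'
#' Two harmonic terms are removed under the null, so the LRT statistic is
#' referred to a chi-squared distribution with 2 degrees of freedom
#' (upper tail, equal to `exp(-stat/2)`).
#'
#' @param lrt_stat Non-negative statistic(s); values in `[-1e-8, 0)` are
#'   treated as 0.
#' @return p-value(s) in `[0, 1]`.
#' @export
lrt_pvalue <- function(lrt_stat) {
  if (any(lrt_stat < -1e-8, na.rm = TRUE)) stop("negative LRT statistic")
  stats::pchisq(pmax(lrt_stat, 0), df = 2, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment; `NA` p-values propagate to `NA` q-values with a
#' warning and do not enter the ranking.
#'
#' @param pvals Numeric vector of p-values in `[0, 1]` (NA allowed).
#' @return q-values, same length and order.
#' @export
adjust_bh <- function(pvals) {
  if (anyNA(pvals)) warning("NA p-values propagate to NA q-values")
  bad <- !is.na(pvals) & (pvals < 0 | pvals > 1)
  if (any(bad)) stop("p-values outside [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Classify genes by the layer(s) at which they are rhythmic
#'
#' `R-I.R-E` when both intronic and exonic q-values fall below `fdr`;
#' `R-I` (rhythmic transcription only) or `R-E` (rhythmic mRNA only) when a
#' single layer is significant — genes whose intronic layer was masked can
#' only be `R-E` or `NR` — and `NR` otherwise.
#'
#' @param q_intronic,q_exonic q-value vectors aligned gene-by-gene
#'   (NA = layer untested).
#' @param fdr Significance threshold (default 0.05).
#' @return Character vector of groups in `{R-I.R-E, R-I, R-E, NR}`.
#' @export
classify_rhythm_groups <- function(q_intronic, q_exonic, fdr = 0.05) {
  stopifnot(length(q_intronic) == length(q_exonic))
  sig_i <- !is.na(q_intronic) & q_intronic < fdr
  sig_e <- !is.na(q_exonic) & q_exonic < fdr
  ifelse(sig_i & sig_e, "R-I.R-E",
         ifelse(sig_i, "R-I", ifelse(sig_e, "R-E", "NR")))
}

#' Amplitude and peak phase of a fitted harmonic
#'
#' Amplitude is the log2 peak-to-trough `2 sqrt(a^2 + b^2)`; the phase is
#' the hour at which `a cos(wt) + b sin(wt)` peaks, in `[0, period_h)`.
#'
#' @param a,b Cosine and sine coefficients (log2 units).
#' @param period_h Period in hours.
#' @return Named numeric vector `c(amplitude =, phase_h =)`.
#' @export
amplitude_phase <- function(a, b, period_h = 24) {
  amp <- 2 * sqrt(a^2 + b^2)
  ph <- (atan2(b, a) * period_h / (2 * pi)) %% period_h
  c(amplitude = amp, phase_h = ph)
}

#' Assign phases to half-open bins
#'
#' @param phase_h Phases in `[0, period_h)`.
#' @param width_h Bin width in hours (default 4); must divide the period.
#' @param period_h Period in hours (default 24).
#' @return Integer bin indices `floor(phase / width)`, bins `[k w, (k+1) w)`.
#' @export
phase_bin <- function(phase_h, width_h = 4, period_h = 24) {
  if (period_h %% width_h != 0) stop("bin width must divide the period")
  if (any(phase_h < 0 | phase_h >= period_h, na.rm = TRUE))
    stop("phases must lie in [0, period)")
  as.integer(floor(phase_h / width_h))
}
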