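# the ten shape measures the classifier consumes (lin_slope is auxiliary)
.CURVE_FEATURES <- c("max_slope", "min_slope", "extremum1_t", "extremum2_t",
                     "minmax_ratio", "autocorr24", "scattering",
                     "resid_loess", "resid_linear", "period_est")

#' Curve categories used by the in vitro classifier
#' @export
CURVE_CATEGORIES <- c("circadian", "one_peak", "linear", "cloud")

#' Default core clock gene seed list
#' @export
CLOCK_GENES <- c("ARNTL", "NR1D1", "NR1D2", "PER1", "PER2", "PER3",
                 "CRY1", "CRY2", "NPAS2", "TEF", "BHLHE41")

# circular standard deviation of phases on a 24-h clock, in hours
.phase_sd <- function(phase_h, period_h = 24) {
  a <- 2 * pi * phase_h / period_h
  r <- sqrt(mean(sin(a))^2 + mean(cos(a))^2)
  sqrt(pmax(-2 * log(r), 0)) * period_h / (2 * pi)
}

#' Build the labeled seed set for self-training
#'
#' The circadian class is anchored by the core clock genes, whose four
#' condition-curves are all used: the knockdown curves of clock genes are
#' genuinely rhythmic but blunted, so they teach the classifier what a weak
#' rhythm looks like. The anchor is extended by a gene-level consistency
#' heuristic that exploits the fact that a curve archetype is a property of
#' the gene, observed four times (2 donors x 2 conditions): a chance
#' rhythm-like fluctuation in one curve does not reproduce in the other
#' three with a matching phase. A gene seeds the circadian class when its
#' four curves agree in 24-h cosine phase (circular SD below
#' `phase_sd_max`), each curve's cosine fit explains at least `r2_min` of
#' its variance, and every period estimate falls in `period_range`. Linear
#' seeds are genes with a consistent monotone trend (same slope sign, all
#' slopes above `trend_min` in magnitude, no major extremum, median
#' normalized linear residual below 0.6). One-peak seeds are
#' phase-coherent genes with at least three single-major-extremum curves
#' peaking within `peak_window` hours at consistent times. Cloud seeds are
#' genes whose four phases are incoherent (circular SD above
#' `cloud_phase_sd_min`); their curves include the chance rhythm-like ones,
#' which gives the classifier labeled examples on the unstructured side of
#' the rhythm boundary. All four curves of every seed gene are labeled;
#' classes are disjoint, with circadian taking precedence, then linear,
#' then one-peak.
#'
#' @param features Feature table from [curve_feature_table()].
#' @param clock_genes Character vector of circadian anchor gene IDs
#'   (default [CLOCK_GENES]); all must be present in `features`.
#' @param peak_window Admissible major-extremum window in hours for
#'   one-peak seeds (default `c(2, 24)`).
#' @param phase_sd_max Circular phase SD bound for coherent genes, hours
#'   (default 2).
#' @param r2_min Minimum per-curve cosine-fit variance fraction for
#'   circadian seed genes (default 0.25).
#' @param period_range Admissible per-curve period estimates for circadian
#'   seed genes, hours (default `c(18, 30)`).
#' @param cloud_phase_sd_min Circular phase SD above which a gene seeds the
#'   cloud class, hours (default 6).
#' @param trend_min Minimum absolute slope (log2/h) for linear seed genes
#'   (default 0.015).
#' @param min_seed_curves Error when a class gathers fewer curves than this
#'   (default 11).
#' @return data.frame `curve_id`, `label`.
#' @export
seed_training_set <- function(features, clock_genes = CLOCK_GENES,
                              peak_window = c(2, 24), phase_sd_max = 2,
                              r2_min = 0.25, period_range = c(18, 30),
                              cloud_phase_sd_min = 6, trend_min = 0.015,
                              min_seed_curves = 11) {
  if (anyDuplicated(clock_genes))
    stop("duplicated gene in clock list: ",
         paste(unique(clock_genes[duplicated(clock_genes)]), collapse = ", "))
  missing <- setdiff(clock_genes, features$gene_id)
  if (length(missing) > 0)
    stop("clock genes missing after filtering: ", paste(missing, collapse = ", "))

  per_gene <- split(features, features$gene_id)
  gs <- do.call(rbind, lapply(per_gene, function(d) {
    single <- d$n_major_extrema == 1 &
      d$major_extremum1_t >= peak_window[1] &
      d$major_extremum1_t <= peak_window[2]
    data.frame(
      gene_id = d$gene_id[1],
      phase_sd = .phase_sd(d$harm_phase),
      min_r2 = min(d$harm_r2),
      period_ok = all(d$period_est >= period_range[1] &
                        d$period_est <= period_range[2]),
      n_single_peak = sum(single),
      peak_t_sd = if (sum(single) >= 2) stats::sd(d$major_extremum1_t[single])
                  else NA_real_,
      trend_ok = (all(d$lin_slope > 0) || all(d$lin_slope < 0)) &&
        min(abs(d$lin_slope)) > trend_min,
      no_major = all(d$n_major_extrema == 0),
      med_resid_linear = stats::median(d$resid_linear),
      stringsAsFactors = FALSE
    )
  }))

  circ_g <- gs$gene_id[gs$phase_sd < phase_sd_max & gs$min_r2 > r2_min &
                         gs$period_ok]
  circ_g <- union(circ_g, clock_genes)
  lin_g <- setdiff(gs$gene_id[gs$trend_ok & gs$no_major &
                                gs$med_resid_linear < 0.6], circ_g)
  op_g <- setdiff(gs$gene_id[gs$phase_sd < phase_sd_max &
                               gs$n_single_peak >= 3 &
                               !is.na(gs$peak_t_sd) & gs$peak_t_sd < 3],
                  c(circ_g, lin_g))
  cloud_g <- setdiff(gs$gene_id[gs$phase_sd > cloud_phase_sd_min],
                     c(circ_g, lin_g, op_g))

  seed_genes <- list(circadian = circ_g, one_peak = op_g,
                     linear = lin_g, cloud = cloud_g)
  out <- do.call(rbind, lapply(names(seed_genes), function(k) {
    ids <- features$curve_id[features$gene_id %in% seed_genes[[k]]]
    if (length(ids) < min_seed_curves)
      stop("only ", length(ids), " eligible seed curves for class ", k,
           "; need ", min_seed_curves)
    data.frame(curve_id = ids, label = k, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Self-train a random-forest curve classifier
#'
#' Starting from the seed set, repeatedly trains a random forest on the
#' current labeled curves, scores all unlabeled curves, and permanently
#' admits those whose top class probability reaches `admit_score` under
#' their predicted label. Classes stop admitting once they hold
#' `target_per_class` curves; the loop ends when every class is full or an
#' iteration admits nothing. The last model is kept.
#'
#' @param features Feature table from [curve_feature_table()].
#' @param seeds Seed labels from [seed_training_set()].
#' @param admit_score Admission probability threshold (default 0.9).
#' @param target_per_class Stop growing a class at this size (default 500).
#' @param rng_seed Integer seed making the forests reproducible.
#' @param ntree Trees per forest (default 500).
#' @return List with `model` (the final randomForest), `labels`
#'   (data.frame `curve_id`, `label`, `iteration`), and `history`
#'   (per-iteration class counts).
#' @export
self_train <- function(features, seeds, admit_score = 0.9,
                       target_per_class = 500, rng_seed = 1, ntree = 500) {
  x <- as.matrix(features[, .CURVE_FEATURES])
  rownames(x) <- features$curve_id
  if (!all(seeds$curve_id %in% features$curve_id))
    stop("seed curves absent from the feature table")

  labels <- stats::setNames(seeds$label, seeds$curve_id)
  iter_of <- stats::setNames(rep(0L, length(labels)), names(labels))
  history <- list()
  model <- NULL
  iter <- 0L
  repeat {
    iter <- iter + 1L
    set.seed(rng_seed + iter)
    y <- factor(labels[names(labels)], levels = CURVE_CATEGORIES)
    model <- randomForest::randomForest(x[names(labels), , drop = FALSE], y,
                                        ntree = ntree)
    counts <- table(y)
    history[[iter]] <- as.integer(counts)
    if (all(counts >= target_per_class) || iter > 50L) break

    un <- setdiff(rownames(x), names(labels))
    if (length(un) == 0L) break
    prob <- stats::predict(model, x[un, , drop = FALSE], type = "prob")
    top <- max.col(prob, ties.method = "first")
    top_p <- prob[cbind(seq_len(nrow(prob)), top)]
    admitted <- character(0)
    for (k in seq_along(CURVE_CATEGORIES)) {
      room <- target_per_class - counts[k]
      if (room <= 0) next
      cand <- which(top == k & top_p >= admit_score)
      if (length(cand) == 0) next
      # when more curves qualify than the class has room for, keep a random
      # subset rather than the most extreme ones, so the class stays
      # representative of everything that cleared the threshold
      if (length(cand) > room) cand <- sample(cand, room)
      ids <- un[cand]
      labels[ids] <- CURVE_CATEGORIES[k]
      iter_of[ids] <- iter
      admitted <- c(admitted, ids)
    }
    if (length(admitted) == 0L) break
  }
  list(model = model,
       labels = data.frame(curve_id = names(labels),
                           label = unname(labels),
                           iteration = unname(iter_of[names(labels)]),
                           stringsAsFactors = FALSE),
       history = do.call(rbind, history))
}

#' Final per-curve category calls
#'
#' A curve is assigned the class with the highest random-forest probability
#' provided that probability exceeds 0.5 and the maximum is unique;
#' otherwise it is `"unclassified"` (and will count as non-rhythmic in the
#' model assignment).
#'
#' @param model Trained classifier from [self_train()].
#' @param features Feature table.
#' @param min_prob Call threshold (default 0.5, strict `>`).
#' @return data.frame `curve_id`, `gene_id`, `donor_id`, `condition`, the
#'   four class probabilities, and `category`.
#' @export
classify_curves <- function(model, features, min_prob = 0.5) {
  x <- as.matrix(features[, .CURVE_FEATURES])
  rownames(x) <- features$curve_id
  prob <- stats::predict(model, x, type = "prob")
  prob <- prob[, CURVE_CATEGORIES, drop = FALSE]
  cbind(features[, c("curve_id", "gene_id", "donor_id", "condition")],
        as.data.frame(prob),
        category = .call_categories(prob, min_prob),
        stringsAsFactors = FALSE)
}

# the final call rule: unique argmax strictly above min_prob, else unclassified
.call_categories <- function(prob, min_prob = 0.5) {
  best <- apply(prob, 1, max)
  n_at_best <- rowSums(prob == best)
  cat_idx <- max.col(prob, ties.method = "first")
  unname(ifelse(best > min_prob & n_at_best == 1L,
                colnames(prob)[cat_idx], "unclassified"))
}

#' Canonical mask-to-model table for the 16 rhythmicity models
#'
#' The four condition-curves are ordered (donorA-siControl, donorB-siControl,
#' donorA-siCLOCK, donorB-siCLOCK). Model 1 is rhythmic everywhere (1111),
#' models 2 and 3 drop one siCLOCK donor (1110, 1101), model 4 is rhythmic
#' in siControl only (1100); the remaining nonzero masks follow in order of
#' decreasing number of rhythmic siControl curves, then decreasing binary
#' value; model 16 is the all-zero mask.
#'
#' @return data.frame `mask` (e.g. "1100") and `model` (1-16).
#' @export
model_mask_table <- function() {
  masks <- 15:0
  bits <- t(vapply(masks, function(m) as.integer(intToBits(m))[4:1], integer(4)))
  nz <- masks != 0
  ord <- order(-(bits[nz, 1] + bits[nz, 2]), -masks[nz])
  mask_str <- apply(bits, 1, paste, collapse = "")
  data.frame(
    mask = c(mask_str[nz][ord], "0000"),
    model = 1:16,
    stringsAsFactors = FALSE
  )
}

#' Assign each gene to one of the 16 rhythmicity models
#'
#' A condition-curve counts as rhythmic when its final category is
#' `"circadian"`. The per-gene 4-bit mask over (donorA-siControl,
#' donorB-siControl, donorA-siCLOCK, donorB-siCLOCK) — donors in sorted
#' order — maps to models 1-16 via [model_mask_table()].
#'
#' @param calls Output of [classify_curves()]; every gene must have exactly
#'   four condition-curves (2 donors x 2 conditions).
#' @param control_label,kd_label Condition labels (defaults `"siControl"`,
#'   `"siCLOCK"`).
#' @return data.frame `gene_id`, `mask`, `model`.
#' @export
assign_models <- function(calls, control_label = "siControl",
                          kd_label = "siCLOCK") {
  donors <- sort(unique(calls$donor_id))
  if (length(donors) != 2L) stop("expected exactly 2 donors, got ",
                                 length(donors))
  combo <- expand.grid(condition = c(control_label, kd_label),
                       donor_id = donors, stringsAsFactors = FALSE)
  combo <- combo[order(match(combo$condition, c(control_label, kd_label)),
                       combo$donor_id), ]
  key <- paste(calls$gene_id, calls$donor_id, calls$condition, sep = "\r")
  rhythmic <- stats::setNames(calls$category == "circadian", key)

  genes <- unique(calls$gene_id)
  want <- outer(genes, paste(combo$donor_id, combo$condition, sep = "\r"),
                paste, sep = "\r")
  if (!all(want %in% key))
    stop("missing condition-curves for some genes")
  bits <- matrix(as.integer(rhythmic[want]), nrow = length(genes))
  mask <- apply(bits, 1, paste, collapse = "")

  tab <- model_mask_table()
  data.frame(gene_id = genes, mask = mask,
             model = tab$model[match(mask, tab$mask)],
             stringsAsFactors = FALSE)
}

#' Linear-scale amplitudes for every gene x condition curve
#'
#' Smooths each replicate-averaged curve and reports the peak-to-trough
#' amplitude on the linear (2^log2) scale.
#'
#' @inheritParams curve_feature_table
#' @return data.frame `gene_id`, `donor_id`, `condition`, `amplitude`.
#' @export
curve_amplitude_table <- function(expr, samples, span = 0.3, dense_dt = 0.5) {
  stopifnot(all(colnames(expr) %in% samples$sample_id))
  samples <- samples[match(colnames(expr), samples$sample_id), ]
  key <- paste(samples$donor_id, samples$condition, sep = "|")
  rows <- list()
  for (cu in unique(key)) {
    idx <- which(key == cu)
    tt <- samples$time_h[idx]
    ut <- sort(unique(tt))
    agg <- vapply(ut, function(t0) rowMeans(expr[, idx[tt == t0], drop = FALSE]),
                  numeric(nrow(expr)))
    if (nrow(expr) == 1L) agg <- matrix(agg, nrow = 1)
    amp <- apply(agg, 1, function(v)
      curve_amplitude(loess_smooth(v, ut, span = span, dense_dt = dense_dt)))
    rows[[cu]] <- data.frame(gene_id = rownames(expr),
                             donor_id = samples$donor_id[idx][1],
                             condition = samples$condition[idx][1],
                             amplitude = unname(amp),
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Paired amplitude comparison between control and knockdown
#'
#' Tests whether curve amplitudes differ between paired conditions using a
#' two-sided paired t-test on log10-transformed amplitudes (the log brings
#' the right-skewed amplitude distribution close to normal). Pairs with a
#' non-positive amplitude on either side are excluded and counted.
#'
#' @param amp_ctrl,amp_kd Positive amplitude vectors paired per gene.
#' @return List with `mean_log10_diff` (knockdown minus control), `t`,
#'   `p`, `n_used`, `n_excluded`.
#' @export
compare_amplitudes <- function(amp_ctrl, amp_kd) {
  stopifnot(length(amp_ctrl) == length(amp_kd))
  ok <- is.finite(amp_ctrl) & is.finite(amp_kd) & amp_ctrl > 0 & amp_kd > 0
  if (sum(ok) < 3) stop("fewer than 3 usable amplitude pairs")
  d <- log10(amp_kd[ok]) - log10(amp_ctrl[ok])
  if (stats::sd(d) <= 1e-10 * max(1, abs(mean(d)))) {
    # degenerate: identical pairs (t = 0, p = 1) or an exactly constant
    # ratio (effect with zero variance; p underflows)
    t_stat <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
    p <- if (mean(d) == 0) 1 else 0
  } else {
    tt <- stats::t.test(d)
    t_stat <- unname(tt$statistic)
    p <- tt$p.value
  }
  list(mean_log10_diff = mean(d), t = t_stat,
       p = p, n_used = sum(ok), n_excluded = sum(!ok))
}
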