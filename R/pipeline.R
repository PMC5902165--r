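#' Read a genes-x-samples TSV matrix
#'
#' First column is the gene ID; remaining columns are samples. `NA` marks
#' masked values.
#'
#' @param path TSV path.
#' @return Numeric matrix with gene rownames.
#' @export
read_matrix_tsv <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  storage.mode(m) <- "double"
  m
}

#' Write a genes-x-samples matrix as TSV
#' @param m Matrix with gene rownames.
#' @param path Output path.
#' @export
write_matrix_tsv <- function(m, path) {
  tab <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Default pipeline configuration
#'
#' All thresholds default to the published analysis values: count filters of
#' 2 (intronic) and 10 (exonic) mean reads, log2 RPKM floors of -2 (exonic)
#' and -3 (intronic), an in vitro expression floor of 0, a 24-h period, 5%
#' FDR, 4-h phase bins, an enrichment amplitude floor of 0.5 log2 and
#' reporting threshold p < 1e-4, LOESS span 0.3, self-training admission
#' score 0.9 with a 500-curve class target.
#'
#' @param ... Overrides of the defaults.
#' @return Named list of configuration values.
#' @export
default_config <- function(...) {
  cfg <- list(
    period_h = 24, fdr = 0.05,
    min_intronic = 2, min_exonic = 10,
    min_exonic_log2rpkm = -2, min_intronic_log2rpkm = -3,
    min_invitro_log2rpkm = 0,
    scale_method = "total",
    amp_min = 0.5, bin_width = 4,
    enrich_min_genes = 5, enrich_p_max = 1e-4,
    span = 0.3, dense_dt = 0.5,
    admit_score = 0.9, target_per_class = 500, ntree = 500,
    rng_seed = 1,
    clock_genes = CLOCK_GENES,
    model_subset = 1:4
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config keys: ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  cfg
}

.config_hash <- function(cfg) {
  s <- paste(names(cfg), vapply(cfg, function(x) paste(format(x), collapse = ","), ""),
             sep = "=", collapse = ";")
  # small deterministic fingerprint (polynomial rolling hash)
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
  sprintf("%08x", h)
}

#' Run the in vivo arm end to end
#'
#' Normalizes exonic and intronic counts to log2 RPKM (intronic layer with
#' the exonic-derived library factors), applies the expression filters, fits
#' the donor random-intercept harmonic model to both layers, classifies
#' genes into R-I.R-E / R-I / R-E / NR, computes the exon/intron half-life
#' proxy, and (when a membership table is given) runs the phase-binned motif
#' enrichment on the intronic layer.
#'
#' @param exonic_counts,intronic_counts Count matrices, genes x samples.
#' @param samples Sample sheet (`sample_id`, `donor_id`, `time_h`).
#' @param lengths data.frame `gene_id`, `exonic_length`, `intronic_length`.
#' @param memberships Optional named list of motif gene sets.
#' @param config From [default_config()].
#' @return List with `config_hash`, `expr` (both layers), `filter_report`,
#'   `fits` (both layers), `groups`, `proxy`, `enrichment` (or NULL), `log`.
#' @export
run_invivo <- function(exonic_counts, intronic_counts, samples, lengths,
                       memberships = NULL, config = default_config()) {
  log <- character(0)
  say <- function(...) log <<- c(log, sprintf(...))
  stopifnot(identical(rownames(exonic_counts), rownames(intronic_counts)))
  say("input: %d genes, %d samples", nrow(exonic_counts), ncol(exonic_counts))

  lib <- library_scale_factors(exonic_counts, method = config$scale_method)
  len_ex <- stats::setNames(lengths$exonic_length, lengths$gene_id)
  len_in <- stats::setNames(lengths$intronic_length, lengths$gene_id)
  expr_ex <- compute_log2_rpkm(exonic_counts, len_ex, lib)
  expr_in <- compute_log2_rpkm(intronic_counts, len_in, lib)

  flt <- filter_in_vivo(exonic_counts, intronic_counts, expr_ex, expr_in,
                        min_intronic = config$min_intronic,
                        min_exonic = config$min_exonic,
                        min_exonic_log2rpkm = config$min_exonic_log2rpkm,
                        min_intronic_log2rpkm = config$min_intronic_log2rpkm)
  for (i in seq_len(nrow(flt$report)))
    say("filter %s: %d genes", flt$report$rule[i], flt$report$genes_removed[i])
  say("testable genes: %d", nrow(flt$exonic_expr))
  if (nrow(flt$exonic_expr) == 0) {
    say("no testable genes")
    return(list(config_hash = .config_hash(config), expr = flt,
                filter_report = flt$report, fits = NULL, groups = NULL,
                proxy = NULL, enrichment = NULL, log = log))
  }

  fit_ex <- fit_harmonic_layer(flt$exonic_expr, samples, config$period_h)
  fit_in <- fit_harmonic_layer(flt$intronic_expr, samples, config$period_h)
  groups <- data.frame(
    gene_id = fit_ex$gene_id,
    group = classify_rhythm_groups(fit_in$q, fit_ex$q, fdr = config$fdr),
    stringsAsFactors = FALSE
  )
  say("groups: %s", paste(names(table(groups$group)), table(groups$group),
                          sep = "=", collapse = ", "))
  proxy <- exon_intron_ratio(flt$exonic_expr, flt$intronic_expr)

  enr <- NULL
  if (!is.null(memberships)) {
    fg <- select_foreground(fit_in, amp_min = config$amp_min,
                            fdr = config$fdr, bin_width = config$bin_width,
                            period_h = config$period_h)
    enr <- run_enrichment(fg, memberships, background = fit_ex$gene_id,
                          min_genes = config$enrich_min_genes,
                          p_max = config$enrich_p_max)
    say("enrichment: %d (term, bin) pairs tested", nrow(enr))
  }

  list(config_hash = .config_hash(config),
       expr = list(exonic = flt$exonic_expr, intronic = flt$intronic_expr),
       filter_report = flt$report,
       fits = list(exonic = fit_ex, intronic = fit_in),
       groups = groups, proxy = proxy, enrichment = enr, log = log)
}

#' Run the in vitro arm end to end
#'
#' Filters genes by expression, extracts LOESS shape features per
#' gene x condition curve, builds the clock-gene seed set, self-trains the
#' random-forest classifier, makes final category calls, assigns genes to
#' the 16 rhythmicity models, and compares control vs knockdown amplitudes
#' for genes rhythmic everywhere (model 1).
#'
#' @param expr log2 RPKM matrix, genes x samples.
#' @param samples Sample sheet (`sample_id`, `donor_id`, `condition`,
#'   `time_h`).
#' @param config From [default_config()].
#' @return List with `config_hash`, `kept_genes`, `features`, `seeds`,
#'   `classifier` (self-training output), `calls`, `models`, `amplitudes`,
#'   `amp_comparison` (model-1 genes; NULL when fewer than 3), `log`.
#' @export
run_invitro <- function(expr, samples, config = default_config()) {
  log <- character(0)
  say <- function(...) log <<- c(log, sprintf(...))
  say("input: %d genes, %d samples", nrow(expr), ncol(expr))

  kept <- filter_in_vitro(expr, samples,
                          min_log2rpkm = config$min_invitro_log2rpkm)
  say("expression filter kept %d/%d genes", length(kept), nrow(expr))
  expr <- expr[kept, , drop = FALSE]

  features <- curve_feature_table(expr, samples, span = config$span,
                                  dense_dt = config$dense_dt)
  seeds <- seed_training_set(features, clock_genes = config$clock_genes)
  st <- self_train(features, seeds, admit_score = config$admit_score,
                   target_per_class = config$target_per_class,
                   rng_seed = config$rng_seed, ntree = config$ntree)
  say("self-training: %d iterations, final class sizes %s",
      nrow(st$history), paste(st$history[nrow(st$history), ], collapse = "/"))

  calls <- classify_curves(st$model, features)
  models <- assign_models(calls)
  say("rhythmic genes (models 1-15): %d / %d",
      sum(models$model < 16), nrow(models))

  amps <- curve_amplitude_table(expr, samples, span = config$span,
                                dense_dt = config$dense_dt)
  amp_cmp <- NULL
  m1 <- models$gene_id[models$model == 1]
  if (length(m1) >= 3) {
    mean_by <- function(cond) {
      a <- amps[amps$condition == cond & amps$gene_id %in% m1, ]
      tapply(a$amplitude, a$gene_id, mean)[m1]
    }
    amp_cmp <- compare_amplitudes(mean_by("siControl"), mean_by("siCLOCK"))
    say("model-1 amplitude change: mean log10 diff %.3f (p = %.3g, n = %d)",
        amp_cmp$mean_log10_diff, amp_cmp$p, amp_cmp$n_used)
  }

  list(config_hash = .config_hash(config), kept_genes = kept,
       features = features, seeds = seeds, classifier = st,
       calls = calls, models = models, amplitudes = amps,
       amp_comparison = amp_cmp, log = log)
}

#' Overlap of rhythmic gene sets between the two arms
#'
#' Reports the funnel: (i) genes rhythmic in vitro (models in
#' `model_subset`), (ii) the subset also expressed (tested) in vivo,
#' (iii) the subset also rhythmic at the mRNA (exonic) level in vivo.
#'
#' @param invivo_fits_exonic Exonic fit table from [run_invivo()].
#' @param invitro_models Model table from [run_invitro()].
#' @param model_subset In vitro models counted as rhythmic (default 1:4).
#' @param fdr In vivo significance threshold (default 0.05).
#' @return List with the three gene-ID vectors (`invitro_rhythmic`,
#'   `expressed_invivo`, `rhythmic_both`) and a `counts` vector.
#' @export
compare_rhythmic_sets <- function(invivo_fits_exonic, invitro_models,
                                  model_subset = 1:4, fdr = 0.05) {
  vitro <- invitro_models$gene_id[invitro_models$model %in% model_subset]
  vivo_genes <- invivo_fits_exonic$gene_id
  if (length(intersect(vitro, vivo_genes)) == 0 && length(vitro) > 0)
    warning("no shared gene identifiers between the two arms")
  expressed <- intersect(vitro, vivo_genes)
  sig <- invivo_fits_exonic$gene_id[!is.na(invivo_fits_exonic$q) &
                                      invivo_fits_exonic$q < fdr]
  both <- intersect(expressed, sig)
  list(invitro_rhythmic = vitro, expressed_invivo = expressed,
       rhythmic_both = both,
       counts = c(invitro_rhythmic = length(vitro),
                  expressed_invivo = length(expressed),
                  rhythmic_both = length(both)))
}
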