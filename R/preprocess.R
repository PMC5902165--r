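#' Per-sample library scaling factors from exonic counts
#'
#' Returns the effective library size per sample, derived from the exonic
#' count matrix. The same factors normalize both the exonic and the intronic
#' layer, so that the two layers stay comparable within a sample. The default
#' is the total exonic count; `method = "TMM"` uses edgeR's trimmed mean of
#' M-values on top of the totals.
#'
#' @param exonic_counts Integer matrix, genes x samples.
#' @param method `"total"` (default) or `"TMM"`.
#' @return Numeric vector of effective library sizes, one per sample.
#' @export
library_scale_factors <- function(exonic_counts, method = c("total", "TMM")) {
  method <- match.arg(method)
  lib <- colSums(exonic_counts)
  if (any(lib <= 0)) stop("zero library size in sample(s): ",
                          paste(colnames(exonic_counts)[lib <= 0], collapse = ", "))
  if (method == "TMM") {
    if (!requireNamespace("edgeR", quietly = TRUE))
      stop("method 'TMM' requires the edgeR package")
    nf <- edgeR::calcNormFactors(exonic_counts, method = "TMM")
    lib <- lib * nf
  }
  lib
}

#' Convert a count matrix to log2 RPKM
#'
#' RPKM = count / (gene length in kb x effective library size in millions).
#' Zero counts map to `-Inf`, which the rest of the pipeline treats as a
#' masked value; with `pseudo_count > 0` that many reads are added to every
#' count first (useful for dense in vitro curves on the log scale).
#'
#' @param counts Matrix of non-negative counts, genes x samples, with gene
#'   IDs as rownames.
#' @param lengths Named numeric vector of region lengths in bp covering all
#'   genes in `counts`.
#' @param lib_sizes Effective library sizes from [library_scale_factors()];
#'   for the intronic layer pass the exonic-derived factors.
#' @param pseudo_count Reads added to every count before the log (default 0).
#' @return Matrix of log2 RPKM values; `-Inf` marks masked (zero-count) cells.
#' @export
compute_log2_rpkm <- function(counts, lengths, lib_sizes, pseudo_count = 0) {
  if (is.null(rownames(counts))) stop("counts must carry gene IDs as rownames")
  len <- lengths[rownames(counts)]
  if (anyNA(len)) stop("missing lengths for genes: ",
                       paste(utils::head(rownames(counts)[is.na(len)]), collapse = ", "))
  if (any(len <= 0)) stop("non-positive region lengths")
  if (any(lib_sizes <= 0)) stop("non-positive library sizes")
  rpkm <- sweep(counts + pseudo_count, 2, lib_sizes / 1e6, "/") / (len / 1e3)
  log2(rpkm)
}

# row means ignoring masked (-Inf / NA) entries; NaN when fully masked
.masked_row_means <- function(x) {
  x[!is.finite(x)] <- NA
  rowMeans(x, na.rm = TRUE)
}

#' Expression filters for the around-the-clock (in vivo) design
#'
#' Applies, in order: (i) discard genes with mean intronic count < `min_intronic`
#' or mean exonic count < `min_exonic`; (ii) discard genes with mean exonic
#' log2 RPKM below `min_exonic_log2rpkm` (strict `<`); (iii) genes with mean
#' intronic log2 RPKM below `min_intronic_log2rpkm` keep their exonic values
#' but have the whole intronic layer masked to `NA`.
#'
#' @param exonic_counts,intronic_counts Count matrices sharing a gene universe.
#' @param exonic_expr,intronic_expr Matching log2 RPKM matrices.
#' @param min_intronic,min_exonic Mean raw-count thresholds (defaults 2, 10).
#' @param min_exonic_log2rpkm,min_intronic_log2rpkm Mean log2 RPKM thresholds
#'   (defaults -2, -3).
#' @return List with filtered `exonic_expr`, `intronic_expr` (row-matched),
#'   and a `report` data.frame of genes removed/masked per rule.
#' @export
filter_in_vivo <- function(exonic_counts, intronic_counts,
                           exonic_expr, intronic_expr,
                           min_intronic = 2, min_exonic = 10,
                           min_exonic_log2rpkm = -2,
                           min_intronic_log2rpkm = -3) {
  genes <- rownames(exonic_counts)
  stopifnot(identical(genes, rownames(intronic_counts)),
            identical(genes, rownames(exonic_expr)),
            identical(genes, rownames(intronic_expr)))

  low_counts <- rowMeans(intronic_counts) < min_intronic |
    rowMeans(exonic_counts) < min_exonic
  keep1 <- !low_counts

  mean_ex <- .masked_row_means(exonic_expr)
  low_exonic <- is.nan(mean_ex) | mean_ex < min_exonic_log2rpkm
  keep2 <- keep1 & !low_exonic

  mean_in <- .masked_row_means(intronic_expr)
  mask_intron <- keep2 & (is.nan(mean_in) | mean_in < min_intronic_log2rpkm)

  ex <- exonic_expr[keep2, , drop = FALSE]
  io <- intronic_expr[keep2, , drop = FALSE]
  io[rownames(io) %in% genes[mask_intron], ] <- NA

  report <- data.frame(
    rule = c("mean_counts", "mean_exonic_log2rpkm", "intronic_masked"),
    genes_removed = c(sum(low_counts), sum(keep1 & low_exonic), sum(mask_intron)),
    stringsAsFactors = FALSE
  )
  list(exonic_expr = ex, intronic_expr = io, report = report)
}

#' Expression filter for the dense in vitro design
#'
#' Keeps genes whose mean log2 RPKM exceeds `min_log2rpkm` in every
#' condition-curve (donor x condition combination). The threshold is applied
#' to the per-curve mean over time points, so an oscillating gene that dips
#' below the cutoff at individual times is retained.
#'
#' @param expr log2 RPKM matrix, genes x samples.
#' @param samples Sample sheet data.frame with `sample_id`, `donor_id`,
#'   `condition` (and `time_h`); `sample_id` must match `colnames(expr)`.
#' @param min_log2rpkm Threshold (default 0, strict `>`).
#' @return Character vector of retained gene IDs.
#' @export
filter_in_vitro <- function(expr, samples, min_log2rpkm = 0) {
  stopifnot(all(colnames(expr) %in% samples$sample_id))
  samples <- samples[match(colnames(expr), samples$sample_id), ]
  curve <- interaction(samples$donor_id, samples$condition, drop = TRUE)
  if (nlevels(curve) < 2L) stop("need at least two condition-curves")
  ok <- rep(TRUE, nrow(expr))
  for (lev in levels(curve)) {
    m <- .masked_row_means(expr[, curve == lev, drop = FALSE])
    ok <- ok & !is.nan(m) & m > min_log2rpkm
  }
  rownames(expr)[ok]
}

#' Exon/intron ratio as an mRNA half-life proxy
#'
#' For each gene, the mean exonic log2 RPKM minus the mean intronic log2
#' RPKM over samples. At steady state the mature/nascent abundance ratio is
#' proportional to the mRNA half-life, so a higher proxy indicates a more
#' stable transcript. Genes with a fully masked intronic layer return `NA`.
#'
#' @param exonic_expr,intronic_expr log2 RPKM matrices with identical
#'   rownames; `-Inf`/`NA` entries are masked.
#' @return Named numeric vector of proxies in log2 units.
#' @export
exon_intron_ratio <- function(exonic_expr, intronic_expr) {
  stopifnot(identical(rownames(exonic_expr), rownames(intronic_expr)))
  proxy <- .masked_row_means(exonic_expr) - .masked_row_means(intronic_expr)
  proxy[is.nan(proxy)] <- NA
  names(proxy) <- rownames(exonic_expr)
  proxy
}
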