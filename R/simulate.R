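#' Simulate the around-the-clock muscle biopsy design
#'
#' Generates coupled intronic (pre-mRNA) and exonic (mRNA) expression for
#' `n_donors` donors sampled at fixed clock times, with known rhythmicity
#' ground truth. The intronic log2 signal of a rhythmic gene is
#' `mu_p + (A/2) cos(w (t - phase)) + u_donor`; the exonic signal follows the
#' steady-state solution of first-order mRNA turnover
#' `dm/dt = production - k m` with `k = ln 2 / half_life`: its oscillation is
#' attenuated by `g = k / sqrt(k^2 + w^2)` and delayed by `atan2(w, k) / w`
#' hours, and its baseline gains `log2(half_life / ln 2)` (mature abundance
#' scales with half-life at steady state). Gaussian residual noise is added
#' on the log2 scale; read counts are then drawn negative-binomially from
#' the RPKM-implied means.
#'
#' @param n_genes Number of genes.
#' @param n_donors Number of donors (default 10).
#' @param times Sampling times in hours (default `c(12, 16, 20, 24, 28, 32)`,
#'   i.e. clock times 12:00 to 08:00 at 4-h spacing).
#' @param prop_rhythmic Fraction of rhythmic genes (default 0.4).
#' @param amp_range Range of the intronic log2 peak-to-trough amplitude for
#'   rhythmic genes (default `c(0.5, 2)`).
#' @param half_life_range mRNA half-life range in hours, sampled
#'   log-uniformly (default `c(0.5, 48)`).
#' @param sigma_donor SD of the donor random intercept (default 0.5).
#' @param sigma_e Residual log2 SD (default 0.25).
#' @param dispersion Negative-binomial dispersion of the counts
#'   (default 0.05; 0 gives Poisson).
#' @param lib_size Nominal library size per sample (default 25e6).
#' @param period_h Period in hours (default 24).
#' @param rng_seed Integer seed.
#' @return List with `exonic_counts`, `intronic_counts` (integer matrices),
#'   `exonic_signal`, `intronic_signal` (noisy log2 matrices before count
#'   sampling), `samples` (sample sheet), `lengths` (per-gene exonic and
#'   intronic bp), and `truth` (per-gene generating parameters).
#' @export
gen_in_vivo <- function(n_genes, n_donors = 10,
                        times = c(12, 16, 20, 24, 28, 32),
                        prop_rhythmic = 0.4, amp_range = c(0.5, 2),
                        half_life_range = c(0.5, 48),
                        sigma_donor = 0.5, sigma_e = 0.25,
                        dispersion = 0.05, lib_size = 25e6,
                        period_h = 24, rng_seed = 1) {
  stopifnot(n_genes >= 1, n_donors >= 2, length(times) >= 2,
            prop_rhythmic >= 0, prop_rhythmic <= 1,
            all(half_life_range > 0), sigma_donor >= 0, sigma_e >= 0,
            dispersion >= 0, lib_size > 0)
  set.seed(rng_seed)
  w <- 2 * pi / period_h

  genes <- sprintf("gene%05d", seq_len(n_genes))
  rhythmic <- seq_len(n_genes) <= round(prop_rhythmic * n_genes)
  A_p <- ifelse(rhythmic, stats::runif(n_genes, amp_range[1], amp_range[2]), 0)
  phase_p <- stats::runif(n_genes, 0, period_h)
  half_life <- exp(stats::runif(n_genes, log(half_life_range[1]),
                                log(half_life_range[2])))
  k <- log(2) / half_life
  g <- k / sqrt(k^2 + w^2)
  delta <- atan2(w, k) / w
  mu_p <- stats::runif(n_genes, 0, 4)
  mu_m <- mu_p + log2(half_life / log(2))

  donors <- sprintf("donor%02d", seq_len(n_donors))
  samples <- expand.grid(time_h = times, donor_id = donors,
                         stringsAsFactors = FALSE)
  samples <- data.frame(
    sample_id = sprintf("%s_t%02d", samples$donor_id, samples$time_h),
    donor_id = samples$donor_id,
    time_h = samples$time_h %% period_h,
    condition = "none",
    stringsAsFactors = FALSE
  )
  ns <- nrow(samples)
  tt <- samples$time_h

  u_in <- matrix(stats::rnorm(n_genes * n_donors, 0, sigma_donor),
                 n_genes, n_donors, dimnames = list(genes, donors))
  u_ex <- matrix(stats::rnorm(n_genes * n_donors, 0, sigma_donor),
                 n_genes, n_donors, dimnames = list(genes, donors))
  didx <- match(samples$donor_id, donors)

  osc_in <- (A_p / 2) * cos(outer(-w * phase_p, w * tt, "+"))
  osc_ex <- (A_p * g / 2) * cos(outer(-w * (phase_p + delta), w * tt, "+"))
  intronic_signal <- mu_p + osc_in + u_in[, didx] +
    matrix(stats::rnorm(n_genes * ns, 0, sigma_e), n_genes, ns)
  exonic_signal <- mu_m + osc_ex + u_ex[, didx] +
    matrix(stats::rnorm(n_genes * ns, 0, sigma_e), n_genes, ns)
  dimnames(intronic_signal) <- dimnames(exonic_signal) <-
    list(genes, samples$sample_id)

  lengths <- data.frame(
    gene_id = genes,
    exonic_length = round(stats::runif(n_genes, 500, 5000)),
    intronic_length = round(stats::runif(n_genes, 2000, 50000)),
    stringsAsFactors = FALSE
  )

  draw_counts <- function(signal, len) {
    mu <- 2^signal * (len / 1e3) * (lib_size / 1e6)
    cnt <- if (dispersion > 0)
      stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion)
    else stats::rpois(length(mu), mu)
    matrix(cnt, nrow = nrow(signal), dimnames = dimnames(signal))
  }
  exonic_counts <- draw_counts(exonic_signal, lengths$exonic_length)
  intronic_counts <- draw_counts(intronic_signal, lengths$intronic_length)

  truth <- data.frame(
    gene_id = genes, truth_rhythmic = rhythmic, truth_amp = A_p,
    truth_phase = phase_p %% period_h, truth_half_life = half_life,
    truth_atten = g, truth_delay = delta, truth_mu_p = mu_p,
    truth_mu_m = mu_m, stringsAsFactors = FALSE
  )
  list(exonic_counts = exonic_counts, intronic_counts = intronic_counts,
       exonic_signal = exonic_signal, intronic_signal = intronic_signal,
       samples = samples, lengths = lengths, truth = truth)
}

#' Simulate the dense synchronized-myotube design
#'
#' Generates log2 RPKM curves for 2 donors x 2 conditions x 25 time points
#' (0-48 h every 2 h) with four planted curve archetypes: `circadian`
#' (damped cosine `mu + (A/2) e^(-t/tau) cos(w (t - phase))`, emulating the
#' gradual loss of population synchrony in culture; the knockdown condition
#' multiplies A by `kd_amp_factor`), `one_peak` (a Gaussian bump early in the
#' course), `linear` (a steady trend) and `cloud` (unstructured scatter).
#' The first `length(clock_genes)` genes are high-amplitude circadian genes
#' carrying the core clock gene names, so the classifier's seed set is
#' realistic. Gaussian noise of SD `noise_sd` is added to every curve.
#'
#' @param n_genes Total genes (must exceed `length(clock_genes)`).
#' @param mix Named archetype proportions summing to 1 (default
#'   `c(circadian = .1, one_peak = .1, linear = .1, cloud = .7)`).
#' @param donors Donor IDs (default `c("donorA", "donorB")`).
#' @param times Sampling times (default `seq(0, 48, 2)`).
#' @param n_rep Replicates per time point (default 2, averaged downstream).
#' @param kd_amp_factor Knockdown amplitude multiplier (default 0.4).
#' @param noise_sd Log2 noise SD (default 0.2).
#' @param tau Damping time constant in hours (default 36).
#' @param frac_low_expr Fraction of genes planted below the expression
#'   filter (baseline < 0; default 0).
#' @param clock_genes Names for the designated clock-gene analogs
#'   (default [CLOCK_GENES]).
#' @param conditions Condition labels (default siControl/siCLOCK).
#' @param period_h Period (default 24).
#' @param rng_seed Integer seed.
#' @return List with `expr` (genes x samples log2 matrix), `samples`
#'   (sample sheet), `truth` (per-gene archetype and parameters).
#' @export
gen_in_vitro <- function(n_genes,
                         mix = c(circadian = 0.10, one_peak = 0.10,
                                 linear = 0.10, cloud = 0.70),
                         donors = c("donorA", "donorB"),
                         times = seq(0, 48, by = 2), n_rep = 2,
                         kd_amp_factor = 0.4, noise_sd = 0.2, tau = 36,
                         frac_low_expr = 0, clock_genes = CLOCK_GENES,
                         conditions = c("siControl", "siCLOCK"),
                         period_h = 24, rng_seed = 1) {
  if (abs(sum(mix) - 1) > 1e-8) stop("archetype mix must sum to 1")
  if (!identical(sort(names(mix)), sort(CURVE_CATEGORIES)))
    stop("mix must be named over the four archetypes")
  nc <- length(clock_genes)
  stopifnot(n_genes > nc)
  set.seed(rng_seed)
  w <- 2 * pi / period_h

  genes <- c(clock_genes, sprintf("gene%05d", seq_len(n_genes - nc)))
  archetype <- c(rep("circadian", nc),
                 sample(names(mix), n_genes - nc, replace = TRUE, prob = mix))

  mu <- stats::runif(n_genes, 1, 6)
  low <- stats::runif(n_genes) < frac_low_expr
  mu[low] <- stats::runif(sum(low), -2, -0.2)
  A <- ifelse(seq_len(n_genes) <= nc, stats::runif(n_genes, 1.5, 2.5),
              stats::runif(n_genes, 1.0, 2.5))
  phase <- stats::runif(n_genes, 0, period_h)
  peak_c <- stats::runif(n_genes, 4, 16)
  peak_s <- stats::runif(n_genes, 2.5, 5)
  peak_h <- stats::runif(n_genes, 1, 2.5)
  slope <- sample(c(-1, 1), n_genes, replace = TRUE) *
    stats::runif(n_genes, 0.02, 0.06)
  cloud_sd <- stats::runif(n_genes, 0.4, 0.8)

  samples <- expand.grid(replicate = seq_len(n_rep), time_h = times,
                         condition = conditions, donor_id = donors,
                         stringsAsFactors = FALSE)
  samples$sample_id <- sprintf("%s_%s_t%02d_r%d", samples$donor_id,
                               samples$condition, samples$time_h,
                               samples$replicate)
  samples <- samples[, c("sample_id", "donor_id", "condition",
                         "time_h", "replicate")]
  ns <- nrow(samples)

  donor_shift <- matrix(stats::rnorm(n_genes * length(donors), 0, 0.3),
                        n_genes, length(donors))
  phase_shift <- matrix(stats::rnorm(n_genes * length(donors), 0, 0.5),
                        n_genes, length(donors))

  expr <- matrix(0, n_genes, ns, dimnames = list(genes, samples$sample_id))
  didx <- match(samples$donor_id, donors)
  kd <- samples$condition == conditions[2]
  tt <- samples$time_h
  for (i in seq_len(n_genes)) {
    base <- mu[i] + donor_shift[i, didx]
    curve <- switch(
      archetype[i],
      circadian = {
        amp <- A[i] * ifelse(kd, kd_amp_factor, 1)
        base + (amp / 2) * exp(-tt / tau) *
          cos(w * (tt - phase[i] - phase_shift[i, didx]))
      },
      one_peak = base + peak_h[i] * exp(-(tt - peak_c[i])^2 / (2 * peak_s[i]^2)),
      linear = base + slope[i] * (tt - mean(range(times))),
      cloud = base + stats::rnorm(ns, 0, cloud_sd[i])
    )
    expr[i, ] <- curve + stats::rnorm(ns, 0, noise_sd)
  }

  truth <- data.frame(
    gene_id = genes, truth_archetype = archetype, truth_amp = A,
    truth_kd_factor = ifelse(archetype == "circadian", kd_amp_factor, NA),
    truth_phase = phase, truth_tau = tau, truth_baseline = mu,
    truth_clock_gene = seq_len(n_genes) <= nc,
    stringsAsFactors = FALSE
  )
  list(expr = expr, samples = samples, truth = truth)
}

# independent per-base labeling of one gene's transcripts (oracle-grade,
# deliberately naive)
.per_base_regions <- function(tx_exons) {
  lo <- min(vapply(tx_exons, function(e) min(e$start), 0))
  hi <- max(vapply(tx_exons, function(e) max(e$end), 0))
  pos <- lo:hi
  exonic <- rep(FALSE, length(pos))
  covered <- rep(FALSE, length(pos))
  intr_all <- rep(TRUE, length(pos))
  for (e in tx_exons) {
    span <- pos >= min(e$start) & pos <= max(e$end)
    in_ex <- rep(FALSE, length(pos))
    for (j in seq_len(nrow(e)))
      in_ex <- in_ex | (pos >= e$start[j] & pos <= e$end[j])
    exonic <- exonic | in_ex
    covered <- covered | span
    intr_all <- intr_all & (!span | !in_ex)
  }
  intronic <- covered & intr_all & !exonic
  to_ir <- function(m) {
    r <- rle(m)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    IRanges::IRanges(start = pos[starts[r$values]], end = pos[ends[r$values]])
  }
  list(exonic = to_ir(exonic), intronic = to_ir(intronic))
}

#' Simulate a toy multi-transcript annotation with known regions
#'
#' Builds random genes of 1-3 transcripts with 1-5 exons each, writes GTF
#' text, and labels every base independently (naive per-base scan) to
#' produce ground-truth exonic/intronic regions for oracle tests.
#'
#' @param n_genes Number of genes.
#' @param rng_seed Integer seed.
#' @param span_bp Approximate gene span in bp (default 5000).
#' @return List with `exons` (exon table as in [read_gtf_exons()]),
#'   `gtf_lines` (character vector of GTF records), and `truth` (per-gene
#'   list of exonic/intronic [IRanges::IRanges] from the per-base scan).
#' @export
gen_toy_annotation <- function(n_genes, rng_seed = 1, span_bp = 5000) {
  set.seed(rng_seed)
  all_exons <- list()
  truth <- list()
  offset <- 1000L
  for (i in seq_len(n_genes)) {
    gid <- sprintf("toy%04d", i)
    strand <- sample(c("+", "-"), 1)
    n_tx <- sample(1:3, 1)
    tx_exons <- list()
    for (tx in seq_len(n_tx)) {
      n_ex <- sample(1:5, 1)
      # random non-overlapping exons inside the gene span
      cuts <- sort(sample(seq_len(span_bp), 2 * n_ex))
      st <- offset + cuts[seq(1, 2 * n_ex, 2)]
      en <- offset + cuts[seq(2, 2 * n_ex, 2)]
      tx_exons[[tx]] <- data.frame(start = st, end = en)
      all_exons[[paste(gid, tx)]] <- data.frame(
        gene_id = gid, transcript_id = sprintf("%s.t%d", gid, tx),
        chrom = "chr1", strand = strand, start = st, end = en,
        stringsAsFactors = FALSE
      )
    }
    truth[[gid]] <- .per_base_regions(tx_exons)
    offset <- offset + span_bp + 2000L
  }
  exons <- do.call(rbind, all_exons)
  rownames(exons) <- NULL
  gtf_lines <- sprintf(
    'chr1\ttoy\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";',
    exons$start, exons$end, exons$strand, exons$gene_id, exons$transcript_id
  )
  list(exons = exons, gtf_lines = gtf_lines, truth = truth)
}

#' Simulate motif membership tables with one planted enrichment
#'
#' Builds a membership table in which one motif preferentially contains
#' genes of a chosen phase bin (probability `p_in` inside the bin, `p_out`
#' outside), plus uniform-rate decoy motifs.
#'
#' @param gene_ids Background gene IDs.
#' @param bins Phase-bin index per gene (same length as `gene_ids`).
#' @param enriched_bin The bin carrying the planted signal.
#' @param p_in,p_out Membership probabilities inside/outside the bin
#'   (require `0 <= p_out < p_in <= 1`).
#' @param n_decoys Number of decoy motifs (default 50).
#' @param decoy_rate Uniform membership rate for decoys (default 0.1).
#' @param rng_seed Integer seed.
#' @return List with `memberships` (named list of gene vectors; planted
#'   motif is `"planted_motif"`) and `truth` (planted term and bin).
#' @export
gen_motif_memberships <- function(gene_ids, bins, enriched_bin,
                                  p_in = 0.8, p_out = 0.1, n_decoys = 50,
                                  decoy_rate = 0.1, rng_seed = 1) {
  if (!(p_out >= 0 && p_out < p_in && p_in <= 1))
    stop("need 0 <= p_out < p_in <= 1")
  stopifnot(length(gene_ids) == length(bins))
  set.seed(rng_seed)
  pr <- ifelse(bins == enriched_bin, p_in, p_out)
  planted <- gene_ids[stats::runif(length(gene_ids)) < pr]
  memberships <- list(planted_motif = planted)
  for (d in seq_len(n_decoys)) {
    memberships[[sprintf("decoy%03d", d)]] <-
      gene_ids[stats::runif(length(gene_ids)) < decoy_rate]
  }
  list(memberships = memberships,
       truth = list(term = "planted_motif", bin = enriched_bin))
}
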