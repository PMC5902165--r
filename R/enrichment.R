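#' Select the phase-binned rhythmic foreground
#'
#' From a table of harmonic fits, keeps genes rhythmic at the chosen layer
#' (q below `fdr`) with log2 peak-to-trough amplitude strictly above
#' `amp_min`, and partitions them by peak phase into half-open bins of
#' `bin_width` hours.
#'
#' @param fits data.frame from [fit_harmonic_layer()] (needs `gene_id`,
#'   `q`, `amplitude`, `phase_h`).
#' @param amp_min Amplitude cutoff in log2 units (default 0.5, strict `>`).
#' @param fdr q-value cutoff (default 0.05).
#' @param bin_width Phase bin width in hours (default 4).
#' @param period_h Period in hours (default 24).
#' @return Named list of gene-ID vectors, one per phase bin (names are bin
#'   indices as characters); empty foreground yields an empty list with a
#'   warning.
#' @export
select_foreground <- function(fits, amp_min = 0.5, fdr = 0.05,
                              bin_width = 4, period_h = 24) {
  sel <- !is.na(fits$q) & fits$q < fdr &
    !is.na(fits$amplitude) & fits$amplitude > amp_min
  if (!any(sel)) {
    warning("empty rhythmic foreground")
    return(stats::setNames(list(), character(0)))
  }
  bin <- phase_bin(fits$phase_h[sel], width_h = bin_width, period_h = period_h)
  split(fits$gene_id[sel], bin)
}

#' Upper-tail hypergeometric test
#'
#' Probability of observing `k` or more foreground genes in a term of size
#' `K`, drawing `n` genes from a background of `N`.
#'
#' @param k Foreground hits in the term.
#' @param K Term size in the background.
#' @param n Foreground size.
#' @param N Background size.
#' @return `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`.
#' @export
hypergeom_test <- function(k, K, n, N) {
  if (any(k < 0 | K < 0 | n < 0 | N < 0) || any(k > n) || any(k > K) ||
      any(n > N) || any(K > N))
    stop("inconsistent hypergeometric counts")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Phase-binned over-representation of gene-set memberships
#'
#' For every (term, phase-bin) pair, tests whether the term's genes are
#' over-represented among the bin's rhythmic genes relative to the expressed
#' background, by an upper-tail hypergeometric test. Terms absent from the
#' background are skipped. No multiple-testing correction gates the
#' reporting rule (`k >= min_genes` and `p < p_max`), but a BH column is
#' included for transparency.
#'
#' @param foreground Named list of gene vectors per bin, from
#'   [select_foreground()].
#' @param memberships Named list mapping term IDs to gene-ID vectors.
#' @param background Character vector of all expressed genes.
#' @param min_genes Minimum foreground hits to report a term (default 5).
#' @param p_max Reporting p-value threshold (default 1e-4).
#' @return data.frame `term`, `bin`, `k`, `K`, `n`, `N`, `p`, `q_bh`,
#'   `reported`, sorted by `p`.
#' @export
run_enrichment <- function(foreground, memberships, background,
                           min_genes = 5, p_max = 1e-4) {
  N <- length(unique(background))
  rows <- list()
  for (term in names(memberships)) {
    gs <- intersect(memberships[[term]], background)
    if (length(gs) == 0L) {
      message("term ", term, " absent from background; skipped")
      next
    }
    for (b in names(foreground)) {
      fg <- intersect(foreground[[b]], background)
      k <- length(intersect(gs, fg))
      rows[[paste(term, b)]] <- data.frame(
        term = term, bin = as.integer(b), k = k, K = length(gs),
        n = length(fg), N = N,
        p = hypergeom_test(k, length(gs), length(fg), N),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(data.frame(term = character(0), bin = integer(0),
                                      k = integer(0), K = integer(0),
                                      n = integer(0), N = integer(0),
                                      p = numeric(0), q_bh = numeric(0),
                                      reported = logical(0)))
  out$q_bh <- stats::p.adjust(out$p, method = "BH")
  out$reported <- out$k >= min_genes & out$p < p_max
  out <- out[order(out$p), ]
  rownames(out) <- NULL
  out
}
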