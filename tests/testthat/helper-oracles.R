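# Independent oracles used across the suite. These deliberately reimplement
# quantities by brute force (dense matrices, enumeration, per-base scans) and
# never call the code paths they check.

# Multivariate-normal log-likelihood of a random-intercept model evaluated
# directly: V = sigma_e2 * I + sigma_d2 * Z Z', GLS for the fixed effects,
# dense Cholesky. Profile over a 2-D grid of variance components, refined
# twice around the incumbent.
oracle_grid_loglik <- function(y, X, donor) {
  Z <- stats::model.matrix(~ 0 + factor(donor))
  ZZt <- tcrossprod(Z)
  n <- length(y)
  ll_at <- function(sd2, se2) {
    V <- se2 * diag(n) + sd2 * ZZt
    ch <- chol(V)
    Vi_y <- backsolve(ch, forwardsolve(t(ch), y))
    Vi_X <- backsolve(ch, forwardsolve(t(ch), X))
    beta <- solve(crossprod(X, Vi_X), crossprod(X, Vi_y))
    r <- y - X %*% beta
    Vi_r <- backsolve(ch, forwardsolve(t(ch), r))
    -0.5 * (n * log(2 * pi) + 2 * sum(log(diag(ch))) + sum(r * Vi_r))
  }
  vy <- stats::var(y)
  sd2_grid <- seq(1e-6, 2 * vy, length.out = 40)
  se2_grid <- seq(1e-6, 2 * vy, length.out = 40)
  best <- c(-Inf, NA, NA)
  for (refine in 1:6) {
    for (a in sd2_grid) for (b in se2_grid) {
      ll <- ll_at(a, b)
      if (ll > best[1]) best <- c(ll, a, b)
    }
    da <- diff(sd2_grid[1:2]); db <- diff(se2_grid[1:2])
    sd2_grid <- seq(max(1e-9, best[2] - 2 * da), best[2] + 2 * da,
                    length.out = 25)
    se2_grid <- seq(max(1e-9, best[3] - 2 * db), best[3] + 2 * db,
                    length.out = 25)
  }
  best[1]
}

# Benjamini-Hochberg by its definition: q_i = min over j with p_j >= p_i of
# n * p_j / rank_j, scanning all thresholds.
oracle_bh <- function(p) {
  n <- length(p)
  r <- rank(p, ties.method = "min")
  vapply(seq_len(n), function(i) {
    cand <- p >= p[i]
    min(1, min(n * p[cand] / rank(p, ties.method = "max")[cand]))
  }, 0)
}

# Upper-tail hypergeometric probability by direct enumeration of outcomes.
oracle_hyper <- function(k, K, n, N) {
  js <- k:min(n, K)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# Textbook paired t statistic and two-sided p.
oracle_paired_t <- function(x, y) {
  d <- x - y
  n <- length(d)
  t <- mean(d) / (stats::sd(d) / sqrt(n))
  list(t = t, p = 2 * stats::pt(-abs(t), df = n - 1))
}

# Per-base exonic/intronic labeling of one gene, looping over every base.
# tx_list: list of data.frames with start/end exon rows (1-based closed).
oracle_regions <- function(tx_list) {
  lo <- min(vapply(tx_list, function(e) min(e$start), 0))
  hi <- max(vapply(tx_list, function(e) max(e$end), 0))
  lab <- character(hi - lo + 1)
  for (i in seq_along(lab)) {
    p <- lo + i - 1
    ex <- FALSE; n_cov <- 0; n_intr <- 0
    for (e in tx_list) {
      if (p < min(e$start) || p > max(e$end)) next
      n_cov <- n_cov + 1
      in_exon <- any(p >= e$start & p <= e$end)
      if (in_exon) ex <- TRUE else n_intr <- n_intr + 1
    }
    lab[i] <- if (ex) "exonic"
      else if (n_cov > 0 && n_intr == n_cov) "intronic" else "neither"
  }
  list(positions = lo:hi, labels = lab)
}

# expand an IRanges into the set of covered integer positions
ir_positions <- function(ir) {
  if (length(ir) == 0) return(integer(0))
  unlist(Map(seq, IRanges::start(ir), IRanges::end(ir)))
}

# small in vitro simulation shared by classifier tests (kept modest so the
# default test run stays fast)
small_invitro <- function(n_genes = 600, rng_seed = 42, ...) {
  gen_in_vitro(n_genes, rng_seed = rng_seed, ...)
}
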