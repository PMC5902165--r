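w24 <- 2 * pi / 24

test_that("noiseless harmonic signal is recovered exactly", {
  times <- rep(c(0, 4, 8, 12, 16, 20), 3)
  donor <- rep(c("a", "b", "c"), each = 6)
  y <- 5 + cos(w24 * times) + rep(c(-1, 0, 1), each = 6)
  fit <- fit_harmonic_mixed(y, times, donor)
  expect_equal(fit$mu, 5, tolerance = 1e-6)
  expect_equal(fit$a, 1, tolerance = 1e-6)
  expect_equal(fit$b, 0, tolerance = 1e-6)
  expect_gt(fit$sigma_donor2, 0)
  expect_lt(fit$sigma_e2, 1e-6)
})

test_that("constant-per-donor signal gives a null LRT", {
  times <- rep(c(0, 4, 8, 12, 16, 20), 3)
  donor <- rep(c("a", "b", "c"), each = 6)
  y <- rep(c(2, 5, 8), each = 6)
  fit <- fit_harmonic_mixed(y, times, donor)
  expect_equal(fit$a, 0, tolerance = 1e-8)
  expect_equal(fit$b, 0, tolerance = 1e-8)
  expect_lt(fit$lrt_stat, 1e-6)
})

test_that("ML log-likelihood matches lme4 and the grid-profile GLS oracle", {
  skip_if_not_installed("lme4")
  set.seed(10)
  times <- rep(c(0, 4, 8, 12, 16, 20), 3)
  donor <- rep(c("a", "b", "c"), each = 6)
  X <- cbind(1, cos(w24 * times), sin(w24 * times))
  for (i in 1:10) {
    y <- 3 + rnorm(1) * cos(w24 * times) + rnorm(1) * sin(w24 * times) +
      rep(rnorm(3, 0, 0.7), each = 6) + rnorm(18, 0, 0.3)
    fit <- fit_harmonic_mixed(y, times, donor)
    m <- lme4::lmer(y ~ cos(w24 * times) + sin(w24 * times) + (1 | donor),
                    REML = FALSE)
    expect_equal(fit$loglik_full, as.numeric(stats::logLik(m)),
                 tolerance = 1e-6)
    orc <- oracle_grid_loglik(y, X, donor)
    expect_gte(fit$loglik_full, orc - 1e-4)
    expect_equal(fit$loglik_full, orc, tolerance = 1e-3)
  }
})

test_that("degenerate designs are rejected", {
  expect_error(fit_harmonic_mixed(rnorm(4), rep(0, 4), c("a", "a", "b", "b")),
               "6 usable")
  expect_error(fit_harmonic_mixed(rnorm(6), 1:6, rep("a", 6)), "2 donors")
  expect_error(fit_harmonic_mixed(rnorm(6), rep(3, 6), rep(c("a", "b"), 3)),
               "singular")
})

test_that("chi-squared(2) p-values equal the closed form", {
  expect_equal(lrt_pvalue(0), 1)
  expect_equal(lrt_pvalue(5.991), exp(-5.991 / 2), tolerance = 1e-12)
  set.seed(11)
  stats <- rexp(1000, 0.3)
  expect_equal(lrt_pvalue(stats), exp(-stats / 2), tolerance = 1e-12)
  expect_error(lrt_pvalue(-1), "negative")
})

test_that("BH adjustment matches the exhaustive threshold scan", {
  expect_equal(adjust_bh(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  set.seed(12)
  for (i in 1:5) {
    p <- runif(37)
    expect_equal(adjust_bh(p), oracle_bh(p), tolerance = 1e-12)
  }
  expect_warning(q <- adjust_bh(c(0.1, NA)), "NA")
  expect_true(is.na(q[2]))
  expect_error(adjust_bh(c(0.5, 1.2)), "outside")
})

test_that("rhythm groups partition by layer significance", {
  q_i <- c(0.01, 0.01, NA, 0.2, 0.2)
  q_e <- c(0.01, 0.20, 0.01, 0.01, 0.9)
  expect_equal(classify_rhythm_groups(q_i, q_e),
               c("R-I.R-E", "R-I", "R-E", "R-E", "NR"))
})

test_that("amplitude and phase follow the cosinor geometry", {
  ap <- amplitude_phase(1, 0)
  expect_equal(unname(ap), c(2, 0))
  ap <- amplitude_phase(0, 1, 24)
  expect_equal(unname(ap["phase_h"]), 6)
  set.seed(13)
  grid <- seq(0, 24, by = 0.01)
  for (i in 1:20) {
    a <- rnorm(1); b <- rnorm(1)
    ap <- amplitude_phase(a, b, 24)
    argmax <- grid[which.max(a * cos(w24 * grid) + b * sin(w24 * grid))]
    expect_lt(min(abs(ap[["phase_h"]] - argmax),
                  24 - abs(ap[["phase_h"]] - argmax)), 0.011)
  }
})

test_that("phase bins are half-open and near-uniform for uniform phases", {
  expect_equal(phase_bin(0), 0L)
  expect_equal(phase_bin(4), 1L)
  expect_equal(phase_bin(3.999), 0L)
  expect_error(phase_bin(1, width_h = 5), "divide")
  expect_error(phase_bin(25), "\\[0, period\\)")
  set.seed(14)
  bins <- phase_bin(runif(6000, 0, 24))
  expect_gt(chisq.test(table(bins))$p.value, 0.01)
})

test_that("shifting all times shifts the phase and nothing else", {
  set.seed(15)
  times <- rep(c(0, 4, 8, 12, 16, 20), 4)
  donor <- rep(letters[1:4], each = 6)
  y <- 2 + 0.8 * cos(w24 * (times - 7)) + rep(rnorm(4, 0, 0.5), each = 6) +
    rnorm(24, 0, 0.2)
  f0 <- fit_harmonic_mixed(y, times, donor)
  f5 <- fit_harmonic_mixed(y, times + 5, donor)
  expect_equal(f5$loglik_full, f0$loglik_full, tolerance = 1e-6)
  expect_equal(f5$amplitude, f0$amplitude, tolerance = 1e-6)
  expect_equal((f5$phase_h - f0$phase_h) %% 24, 5, tolerance = 1e-4)
})

test_that("layer-level fitting handles masked genes and reports q-values", {
  sim <- gen_in_vivo(40, n_donors = 4, prop_rhythmic = 0.5, rng_seed = 16)
  expr <- sim$intronic_signal
  expr[1, ] <- NA                       # fully masked -> NA row
  expr[2, 1:20] <- NA                   # too few usable samples (24 total)
  suppressWarnings(fit <- fit_harmonic_layer(expr, sim$samples))
  expect_equal(nrow(fit), 40)
  expect_true(is.na(fit$p[1]) && is.na(fit$p[2]))
  expect_true(all(fit$q[-(1:2)] >= fit$p[-(1:2)] - 1e-12))
  expect_true(all(fit$lrt_stat[-(1:2)] >= 0))
})
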