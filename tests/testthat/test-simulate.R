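test_that("kinetic attenuation and delay follow first-order turnover", {
  hl <- 24 * log(2) / (2 * pi)   # k equals omega
  sim <- gen_in_vivo(5, half_life_range = c(hl, hl), rng_seed = 1)
  expect_equal(sim$truth$truth_atten, rep(1 / sqrt(2), 5), tolerance = 1e-12)
  expect_equal(sim$truth$truth_delay, rep(3, 5), tolerance = 1e-12)
})

test_that("non-rhythmic genes are flat up to donor structure", {
  sim <- gen_in_vivo(10, prop_rhythmic = 0, sigma_e = 0, rng_seed = 2)
  expect_true(all(sim$truth$truth_amp == 0))
  # within a donor, the noiseless signal does not vary over time
  for (d in unique(sim$samples$donor_id)) {
    cols <- sim$samples$sample_id[sim$samples$donor_id == d]
    spread <- apply(sim$intronic_signal[, cols], 1, function(v) diff(range(v)))
    expect_true(all(spread < 1e-12))
  }
})

test_that("the closed-form mRNA cycle solves the turnover ODE", {
  # small-amplitude regime, where production in linear scale is sinusoidal
  # to first order: integrate dm/dt = p(t) - k m numerically and compare
  w <- 2 * pi / 24
  A <- 1e-3; mu_p <- 1; phase <- 5; hl <- 6
  k <- log(2) / hl
  p_fun <- function(t) 2^(mu_p + (A / 2) * cos(w * (t - phase)))
  m <- 2^(mu_p) / k    # start at the flat steady state
  dt <- 0.0005
  ts <- seq(0, 24 * 12, by = dt)  # several periods to settle on the cycle
  for (t in ts) m <- m + dt * (p_fun(t) - k * m)
  t_end <- ts[length(ts)] + dt
  g <- k / sqrt(k^2 + w^2)
  delay <- atan2(w, k) / w
  closed <- 2^(mu_p + log2(1 / k) + (A * g / 2) * cos(w * (t_end - phase - delay)))
  expect_equal(m, closed, tolerance = 1e-6)
})

test_that("measured amplitude attenuation matches k/sqrt(k^2+w^2)", {
  sim <- gen_in_vivo(60, prop_rhythmic = 1, amp_range = c(1, 1), sigma_e = 0,
                     sigma_donor = 0, dispersion = 0, rng_seed = 3)
  fit_i <- fit_harmonic_layer(sim$intronic_signal, sim$samples)
  fit_e <- fit_harmonic_layer(sim$exonic_signal, sim$samples)
  ratio <- fit_e$amplitude / fit_i$amplitude
  expect_true(all(abs(ratio - sim$truth$truth_atten) /
                    sim$truth$truth_atten < 0.05))
})

test_that("generators are reproducible under a fixed seed", {
  a <- gen_in_vivo(20, rng_seed = 4)
  b <- gen_in_vivo(20, rng_seed = 4)
  expect_identical(a, b)
  x <- gen_in_vitro(30, rng_seed = 4)
  y <- gen_in_vitro(30, rng_seed = 4)
  expect_identical(x, y)
})

test_that("a unit knockdown factor leaves conditions identical", {
  sim <- gen_in_vitro(20, kd_amp_factor = 1, noise_sd = 0, rng_seed = 5)
  s <- sim$samples
  for (d in unique(s$donor_id)) {
    ctrl <- s$sample_id[s$donor_id == d & s$condition == "siControl" &
                          s$replicate == 1]
    kd <- s$sample_id[s$donor_id == d & s$condition == "siCLOCK" &
                        s$replicate == 1]
    circ <- sim$truth$gene_id[sim$truth$truth_archetype == "circadian"]
    expect_equal(sim$expr[circ, ctrl], sim$expr[circ, kd],
                 ignore_attr = TRUE, tolerance = 1e-12)
  }
})

test_that("an undamped noiseless clock gene is an exact recoverable cosine", {
  sim <- gen_in_vitro(20, noise_sd = 0, tau = Inf, rng_seed = 6)
  s <- sim$samples
  cols <- s$sample_id[s$donor_id == "donorA" & s$condition == "siControl" &
                        s$replicate == 1]
  y <- sim$expr["ARNTL", cols]
  tt <- s$time_h[match(cols, s$sample_id)]
  ft <- extract_features(loess_smooth(y, tt))
  expect_lt(abs(ft[["period_est"]] - 24), 0.5)
  expect_gt(ft[["harm_r2"]], 0.999)
})

test_that("archetype proportions follow the requested mix", {
  mix <- c(circadian = 0.1, one_peak = 0.1, linear = 0.1, cloud = 0.7)
  sim <- gen_in_vitro(2000, mix = mix, rng_seed = 7)
  # the clock-gene analogs are forced circadian; test the sampled remainder
  sampled <- sim$truth$truth_archetype[!sim$truth$truth_clock_gene]
  tab <- table(factor(sampled, levels = names(mix)))
  expect_gt(chisq.test(tab, p = mix)$p.value, 1e-3)
  expect_error(gen_in_vitro(100, mix = mix * 2), "sum to 1")
})

test_that("toy annotation truth comes from per-base labeling", {
  toy <- gen_toy_annotation(10, rng_seed = 8, span_bp = 1500)
  # nested/overlapping transcripts: truth equals the naive oracle rerun here
  for (gid in names(toy$truth)) {
    ex <- toy$exons[toy$exons$gene_id == gid, ]
    orc <- oracle_regions(lapply(split(ex, ex$transcript_id),
                                 function(e) e[, c("start", "end")]))
    expect_setequal(ir_positions(toy$truth[[gid]]$exonic),
                    orc$positions[orc$labels == "exonic"])
    expect_setequal(ir_positions(toy$truth[[gid]]$intronic),
                    orc$positions[orc$labels == "intronic"])
  }
})

test_that("motif membership generator plants the requested structure", {
  genes <- sprintf("g%03d", 1:300)
  bins <- rep(0:5, each = 50)
  mm <- gen_motif_memberships(genes, bins, 3, p_in = 1, p_out = 0,
                              rng_seed = 9)
  expect_setequal(mm$memberships$planted_motif, genes[bins == 3])
  expect_error(gen_motif_memberships(genes, bins, 3, p_in = 0.2, p_out = 0.5),
               "p_out < p_in")
  null_mm <- gen_motif_memberships(genes, bins, 3, p_in = 0.3,
                                   p_out = 0.29999, rng_seed = 10)
  planted_rate_in <- mean(genes[bins == 3] %in% null_mm$memberships$planted_motif)
  planted_rate_out <- mean(genes[bins != 3] %in% null_mm$memberships$planted_motif)
  expect_lt(abs(planted_rate_in - planted_rate_out), 0.25)
})
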