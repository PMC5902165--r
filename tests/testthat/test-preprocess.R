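test_that("log2 RPKM follows the formula and masks zero counts", {
  counts <- matrix(c(8, 0), nrow = 1, dimnames = list("g1", c("s1", "s2")))
  expr <- compute_log2_rpkm(counts, c(g1 = 1000), c(1e6, 1e6))
  expect_equal(expr[1, "s1"], 3)          # 8 / (1 kb x 1 M) = 8 RPKM
  expect_identical(expr[1, "s2"], -Inf)   # zero count -> masked

  set.seed(1)
  cnt <- matrix(rpois(120, 50), 20, 6,
                dimnames = list(sprintf("g%02d", 1:20), sprintf("s%d", 1:6)))
  len <- setNames(runif(20, 300, 5000), rownames(cnt))
  lib <- colSums(cnt)
  expr <- compute_log2_rpkm(cnt, len, lib)
  manual <- log2(cnt[3, 5] / ((len[3] / 1e3) * (lib[5] / 1e6)))
  expect_equal(expr[3, 5], unname(manual), tolerance = 1e-12)
})

test_that("normalization is scale-equivariant", {
  set.seed(2)
  cnt <- matrix(rpois(60, 30), 10, 6, dimnames = list(sprintf("g%d", 1:10), NULL))
  len <- setNames(rep(1000, 10), rownames(cnt))
  lib <- colSums(cnt)
  expect_equal(compute_log2_rpkm(cnt, len, lib),
               compute_log2_rpkm(cnt * 2L, len, lib * 2),
               tolerance = 1e-12)
})

test_that("in vivo filters apply the documented rules and boundaries", {
  genes <- c("lowIntron", "boundary", "maskIntron", "ok")
  ns <- 6
  exc <- matrix(50, 4, ns, dimnames = list(genes, sprintf("s%d", 1:ns)))
  inc <- matrix(50, 4, ns, dimnames = dimnames(exc))
  inc["lowIntron", ] <- c(2, 2, 2, 2, 2, 1.4)   # mean 1.9 < 2 -> discarded
  ex_expr <- matrix(1, 4, ns, dimnames = dimnames(exc))
  in_expr <- matrix(1, 4, ns, dimnames = dimnames(exc))
  ex_expr["boundary", ] <- -2                    # exactly -2 -> kept (strict <)
  in_expr["maskIntron", ] <- -3.5                # intronic masked, gene kept

  flt <- filter_in_vivo(exc, inc, ex_expr, in_expr)
  expect_false("lowIntron" %in% rownames(flt$exonic_expr))
  expect_true("boundary" %in% rownames(flt$exonic_expr))
  expect_true("maskIntron" %in% rownames(flt$exonic_expr))
  expect_true(all(is.na(flt$intronic_expr["maskIntron", ])))
  expect_false(anyNA(flt$intronic_expr["ok", ]))
  expect_equal(flt$report$genes_removed,
               c(1, 0, 1))
})

test_that("count and expression filters are order-stable", {
  set.seed(3)
  n <- 50; ns <- 6
  exc <- matrix(rpois(n * ns, 30), n, ns,
                dimnames = list(sprintf("g%02d", 1:n), sprintf("s%d", 1:ns)))
  inc <- matrix(rpois(n * ns, 5), n, ns, dimnames = dimnames(exc))
  len <- setNames(runif(n, 500, 3000), rownames(exc))
  lib <- colSums(exc)
  ex_expr <- compute_log2_rpkm(exc, len, lib)
  in_expr <- compute_log2_rpkm(inc, len * 5, lib)
  joint <- filter_in_vivo(exc, inc, ex_expr, in_expr)
  # apply rule (i) first, then (ii) on the survivors
  keep1 <- rowMeans(inc) >= 2 & rowMeans(exc) >= 10
  step1 <- filter_in_vivo(exc[keep1, ], inc[keep1, ],
                          ex_expr[keep1, ], in_expr[keep1, ])
  expect_identical(rownames(joint$exonic_expr), rownames(step1$exonic_expr))
})

test_that("in vitro filter keeps genes above threshold in all four curves", {
  samples <- expand.grid(time_h = seq(0, 48, 24),
                         condition = c("siControl", "siCLOCK"),
                         donor_id = c("dA", "dB"), stringsAsFactors = FALSE)
  samples$sample_id <- sprintf("s%02d", seq_len(nrow(samples)))
  expr <- matrix(0.5, 3, nrow(samples),
                 dimnames = list(c("allAbove", "oneBelow", "allBelow"),
                                 samples$sample_id))
  below <- samples$condition == "siCLOCK" & samples$donor_id == "dB"
  expr["oneBelow", below] <- -0.1
  expr["allBelow", ] <- -0.1
  kept <- filter_in_vitro(expr, samples)
  expect_identical(kept, "allAbove")
})

test_that("planted sub-threshold genes are exactly the ones removed", {
  sim <- gen_in_vitro(300, frac_low_expr = 0.3, rng_seed = 8)
  kept <- filter_in_vitro(sim$expr, sim$samples)
  # independent recomputation of per-curve means
  key <- paste(sim$samples$donor_id, sim$samples$condition)
  ok <- rep(TRUE, nrow(sim$expr))
  for (cu in unique(key))
    ok <- ok & rowMeans(sim$expr[, key == cu, drop = FALSE]) > 0
  expect_setequal(kept, rownames(sim$expr)[ok])
  expect_gt(sum(!ok), 0)
})

test_that("exon/intron ratio behaves as a half-life proxy", {
  ex <- matrix(c(2, 2, 4, 4), 2, 2, byrow = TRUE,
               dimnames = list(c("same", "x4"), c("s1", "s2")))
  io <- matrix(2, 2, 2, dimnames = dimnames(ex))
  proxy <- exon_intron_ratio(ex, io)
  expect_equal(unname(proxy["same"]), 0)
  expect_equal(unname(proxy["x4"]), 2)   # 4-fold linear = 2 in log2

  sim <- gen_in_vivo(200, prop_rhythmic = 0.3, sigma_e = 0.25, rng_seed = 4)
  proxy <- exon_intron_ratio(sim$exonic_signal, sim$intronic_signal)
  rho <- cor(proxy, sim$truth$truth_half_life, method = "spearman")
  expect_gt(rho, 0.8)
})

test_that("fully masked intronic layer yields a missing proxy", {
  ex <- matrix(1, 1, 3, dimnames = list("g", NULL))
  io <- matrix(NA_real_, 1, 3, dimnames = list("g", NULL))
  expect_true(is.na(exon_intron_ratio(ex, io)["g"]))
})
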