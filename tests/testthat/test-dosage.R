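# Normalisation, ancestral inference, fixed-median tests, balance, TSI.

test_that("median scaling equalises shared-set medians and is idempotent", {
  set.seed(3)
  mat <- matrix(rexp(200, 0.1) + 1, nrow = 20,
                dimnames = list(paste0("g", 1:20), paste0("s", 1:10)))
  shared <- paste0("g", 1:10)
  norm1 <- median_scale_normalize(mat, shared)
  med <- apply(norm1[shared, ], 2, median)
  expect_true(all(abs(med - med[1]) < 1e-9))
  norm2 <- median_scale_normalize(norm1, shared)
  expect_equal(unclass(norm2), unclass(norm1), ignore_attr = TRUE)
  # rescaling a sample before normalisation leaves the output unchanged
  # (scale the sample with the highest shared median so the grand median,
  # an order statistic of the others, stays put)
  top <- which.max(apply(mat[shared, ], 2, median))
  mat2 <- mat; mat2[, top] <- mat2[, top] * 2
  norm3 <- median_scale_normalize(mat2, shared)
  expect_equal(unclass(norm3), unclass(norm1), ignore_attr = TRUE,
               tolerance = 1e-9)
  expect_error(median_scale_normalize(mat, character(0)),
               class = "xy_config_error")
})

test_that("scale factors follow the closed form g / sample_median", {
  mat <- rbind(g1 = c(10, 20), g2 = c(10, 20), g3 = c(10, 20))
  colnames(mat) <- c("s1", "s2")
  norm <- median_scale_normalize(mat, c("g1", "g2", "g3"))
  g <- median(c(10, 20))
  expect_equal(unname(attr(norm, "scale_factors")), c(g / 10, g / 20))
})

test_that("ancestral expression is the halved outgroup median", {
  expect_equal(infer_ancestral_expression(c(10, 14)), 6)
  expect_equal(infer_ancestral_expression(7), 3.5)
  expect_true(is.na(infer_ancestral_expression(numeric(0))))
  m <- rbind(g1 = c(10, 14), g2 = c(NA, 8), g3 = c(NA, NA))
  expect_equal(unname(infer_ancestral_expression(m)), c(6, 4, NA))
})

test_that("ratio test handles the degenerate all-equal case and needs 5 ratios", {
  expect_equal(ratio_test(rep(-1, 10), -1)$p, 1)
  expect_error(ratio_test(c(0, 0.1, -0.2), 0), class = "xy_config_error")
  set.seed(4)
  r <- rnorm(500, 0, 0.5)
  expect_gt(ratio_test(r, 0)$p, 0.001)
  expect_lt(ratio_test(r, -1)$p, 1e-10)
})

test_that("dosage calls follow the two-test decision rule", {
  tr <- expression_truth(200, 400)
  run <- function(model) {
    cfg <- sim_config(dosage_model = model, tissues = c("liver", "brain"))
    dosage_calls(simulate_expression(tr, cfg, seed = 44))
  }
  full <- run("full")
  expect_true(all(full$call == "BALANCED"))
  none <- run("none")
  expect_true(all(none$call == "UNCOMPENSATED"))
  part <- run("partial:1.5")
  expect_true(all(part$call == "INTERMEDIATE"))
  # INTERMEDIATE iff both tests reject
  expect_true(all(part$p_vs_0 < 0.05 & part$p_vs_minus1 < 0.05))
  expect_true(all(none$p_vs_minus1 >= 0.05))
  expect_equal(attr(part, "consensus"), "INTERMEDIATE")
})

test_that("gametologue balance behaves at the reference points", {
  # x_male + y_male = x_female -> ~0 with the pseudocount
  expect_lt(abs(gametologue_balance(3, 2, 5)), 0.02)
  expect_equal(gametologue_balance(5, 5, 10), 0)
  # silenced Y with half male X -> about -1
  expect_equal(gametologue_balance(5, 0, 10), log2(5.1 / 10.1),
               tolerance = 1e-9)
  expect_lt(gametologue_balance(5, 0, 10), -0.9)
})

test_that("balanced gametologues show balance ~0 while X-only M/F is ~-1", {
  tr <- expression_truth(100, 300, n_y_retained = 300)
  cfg <- sim_config(dosage_model = "none", tissues = "liver")
  es <- simulate_expression(tr, cfg, seed = 46)
  g <- es$genes
  x_ids <- g$gene_id[g$class == "X"][1:300]
  y_ids <- paste0(x_ids, "_Y")
  m <- es$values[, "focal_male_liver"]
  f <- es$values[, "focal_female_liver"]
  bal <- gametologue_balance(m[x_ids], m[y_ids], f[x_ids])
  x_only <- log2((m[x_ids] + 0.1) / (f[x_ids] + 0.1))
  expect_lt(abs(median(bal)), 0.1)
  expect_lt(abs(median(x_only) - (-1)), 0.1)
})

test_that("TSI spans 1/T for uniform to 1 for single-tissue expression", {
  expect_equal(tsi(c(5, 0, 0, 0, 0, 0, 0)), 1.0)
  expect_equal(tsi(rep(3, 7)), 1 / 7)
  expect_true(is.na(tsi(rep(0, 7))))
  expect_error(tsi(5), class = "xy_config_error")
  # bounds property over random genes
  set.seed(9)
  m <- matrix(rexp(70), nrow = 10)
  v <- tsi(m)
  expect_true(all(v >= 1 / 7 - 1e-12 & v <= 1))
})

test_that("current/ancestral ratios recover the simulated regimes", {
  tr <- expression_truth(100, 300)
  cfg <- sim_config(dosage_model = "none", tissues = "liver")
  es <- simulate_expression(tr, cfg, seed = 47,
                            outgroup_species = c("outA", "outB"))
  out_cols <- es$samples$sample_id[es$samples$species != "focal"]
  anc <- infer_ancestral_expression(es$values[, out_cols])
  # females keep the ancestral diploid level (current ~ 2 x per-allele),
  # uncompensated males sit at the per-allele level; the median-of-two-
  # outgroups estimator carries a small common multiplicative bias, so the
  # one-fold separation between the sexes is the sharp signature
  f_ratio <- current_ancestral_ratios(es, "liver", "female", anc)
  m_ratio <- current_ancestral_ratios(es, "liver", "male", anc)
  expect_lt(abs(median(f_ratio) - 1), 0.35)
  expect_lt(abs(median(m_ratio)), 0.35)
  expect_lt(abs((median(f_ratio) - median(m_ratio)) - 1), 0.15)
})
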