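test_that("log2-CPM normalization satisfies its closed forms", {
  m <- matrix(c(0, 10, 90,
                0, 50, 50), nrow = 3,
              dimnames = list(paste0("g", 1:3), c("s1", "s2")))
  nm <- normalize_cpm_log(m)
  expect_equal(nm$values["g1", "s1"], 0)                     # log2(1) = 0
  expect_equal(nm$values["g2", "s1"], log2(1 + 1e6 * 0.1))
  # a count equal to the whole library gives log2(1 + 1e6)
  one <- matrix(c(5, 0), 2, 1, dimnames = list(c("a", "b"), "s"))
  expect_equal(normalize_cpm_log(one)$values["a", "s"], log2(1 + 1e6))
  # scale invariance within a sample
  expect_equal(normalize_cpm_log(m * 2)$values, nm$values)
  # zero-total samples are named in the error
  bad <- matrix(c(1, 1, 0, 0), 2, 2, dimnames = list(NULL, c("ok", "empty")))
  expect_error(normalize_cpm_log(bad), "empty")
})

test_that("per-gene ANOVA matches stats::aov and handles degenerate genes", {
  set.seed(31)
  states <- rep(c("NEGATIVE", "RED_G1", "GREEN_SG2M"), each = 3)
  x <- matrix(rnorm(20 * 9, mean = 5), nrow = 20,
              dimnames = list(sprintf("g%02d", 1:20), NULL))
  x[1, ] <- 7                                   # flat gene
  x[2, ] <- rep(c(0, 0, 3), each = 3)           # perfect separation
  de <- de_one_way(x, states)

  expect_equal(de$F[1], 0)
  expect_equal(de$p[1], 1)
  expect_lt(de$p[2], 1e-10)

  # independent oracle: aov per gene
  for (g in 3:8) {
    fit <- summary(aov(x[g, ] ~ factor(states)))[[1]]
    expect_equal(de$F[g], fit[["F value"]][1], tolerance = 1e-10)
    expect_equal(de$p[g], fit[["Pr(>F)"]][1], tolerance = 1e-10)
  }
  expect_true(all(de$q >= de$p))
  expect_true(all(de$q <= 1))
  expect_error(de_one_way(x, rep(c("NEGATIVE", "RED_G1", "GREEN_SG2M"),
                                 c(1, 4, 4))), ">= 2 replicates")
})

test_that("ANOVA F keeps nominal type-I error on balanced null data", {
  set.seed(32)
  states <- rep(c("NEGATIVE", "RED_G1", "GREEN_SG2M"), each = 3)
  x <- matrix(rnorm(10000 * 9), nrow = 10000)
  de <- de_one_way(x, states)
  rate <- mean(de$p < 0.05)
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.07)
  # and p-values are uniform enough for BH to stay silent under the null
  expect_equal(sum(de$q < 0.05), 0)
})

test_that("BH adjustment follows the step-up formula and permutes with input", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(bh_adjust(0.013), 0.013)
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")

  # independent oracle: direct application of q_(i) = min_{j>=i} p_(j) m / j
  set.seed(33)
  p <- runif(50)
  o <- order(p)
  m <- length(p)
  q_sorted <- rev(cummin(rev(p[o] * m / seq_len(m))))
  q_oracle <- numeric(m); q_oracle[o] <- pmin(q_sorted, 1)
  expect_equal(bh_adjust(p), q_oracle, tolerance = 1e-12)

  # monotone in sorted order; permutation equivariance
  expect_true(all(diff(bh_adjust(p)[o]) >= -1e-12))
  perm <- sample(m)
  expect_equal(bh_adjust(p[perm]), bh_adjust(p)[perm])
})

test_that("signature extraction applies the q/argmax/lfc rule", {
  de <- data.frame(gene = c("up_red", "flat", "weak_lfc", "up_green"),
                   mean_negative = c(2, 5, 3.0, 1),
                   mean_red = c(5, 5, 3.4, 1),
                   mean_green = c(2, 5, 3.0, 4),
                   lfc_negative = c(-1.5, 0, -0.2, -1.5),
                   lfc_red = c(3, 0, 0.4, -1.5),
                   lfc_green = c(-1.5, 0, -0.2, 3),
                   F = c(30, 0, 8, 30),
                   p = c(1e-5, 1, 0.01, 1e-5),
                   q = c(0.01, 1, 0.2, 0.01))
  class(de) <- c("de_result", "data.frame")
  expect_warning(
    sig <- extract_state_signatures(de, q_threshold = 0.05, lfc_threshold = 0.5),
    "genes_negative")
  expect_identical(sig$genes_red, "up_red")
  expect_identical(sig$genes_green, "up_green")
  # q = 0.2 gene excluded regardless of its means; lists disjoint
  expect_length(sig$genes_negative, 0)
  expect_length(intersect(sig$genes_red, sig$genes_green), 0)
})

test_that("planted state signatures are recovered from simulated bulk", {
  cfg <- small_config(n_genes = 5000, n_state_genes_per_state = 100,
                      n_arterial_genes = 50, n_venous_genes = 50,
                      n_tgf_genes = 20, n_bmp_genes = 20,
                      delta_state = 1, bulk_depth = 1e6, seed = 3)
  panel <- make_gene_panel(cfg)
  bulk <- simulate_bulk_sorted(cfg, panel)
  sig <- extract_state_signatures(de_one_way(normalize_cpm_log(bulk),
                                             bulk$sample_state))
  truth <- list(genes_negative = panel$state_negative,
                genes_red = panel$state_red,
                genes_green = panel$state_green)
  for (s in names(truth)) {
    hits <- intersect(sig[[s]], truth[[s]])
    precision <- length(hits) / length(sig[[s]])
    recall <- length(hits) / length(truth[[s]])
    expect_gte(precision, 0.8)
    expect_gte(recall, 0.6)
  }
})

test_that("null bulk simulations rarely yield any significant signature gene", {
  states <- NULL
  hits <- vapply(1:50, function(s) {
    cfg <- small_config(n_genes = 1000, n_state_genes_per_state = 30,
                        n_arterial_genes = 10, n_venous_genes = 10,
                        n_tgf_genes = 5, n_bmp_genes = 5,
                        delta_state = 0, bulk_depth = 2e5, seed = 100 + s)
    bulk <- simulate_bulk_sorted(cfg)
    de <- de_one_way(normalize_cpm_log(bulk), bulk$sample_state)
    sum(de$q < 0.05)
  }, numeric(1))
  # under a global null BH rejects at least one gene with probability alpha,
  # so the expected clean fraction is 1 - 0.05 = 0.95; allow ~2 binomial SE
  # around that expectation over 50 seeds
  expect_gte(mean(hits == 0), 0.89)
  expect_lte(mean(hits > 0), 0.11)
})
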