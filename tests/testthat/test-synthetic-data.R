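test_that("gene panels are disjoint, deterministic, and lead with canonical markers", {
  cfg <- small_config(n_arterial_genes = 7, n_venous_genes = 6)
  panel <- make_gene_panel(cfg)

  expect_identical(panel$arterial[1], "Efnb2")
  expect_identical(panel$venous[1], "Ephb4")
  expect_identical(panel$arterial[1:7],
                   c("Efnb2", "Gja4", "Gja5", "Sox17", "Bmx", "Jag1", "Hey1"))

  lists <- panel[c("arterial", "venous", "state_negative", "state_red",
                   "state_green", "tgf", "bmp", "housekeeping")]
  all_genes <- unlist(lists, use.names = FALSE)
  expect_false(anyDuplicated(all_genes) > 0)
  expect_setequal(all_genes, panel$gene_names)
  expect_length(panel$gene_names, cfg$n_genes)

  expect_identical(panel, make_gene_panel(cfg))
})

test_that("all-zero panel sizes give empty lists and an all-housekeeping index", {
  cfg <- small_config(n_arterial_genes = 0, n_venous_genes = 0,
                      n_state_genes_per_state = 0, n_tgf_genes = 0,
                      n_bmp_genes = 0)
  panel <- make_gene_panel(cfg)
  expect_length(panel$arterial, 0)
  expect_length(panel$state_red, 0)
  expect_length(panel$housekeeping, cfg$n_genes)
})

test_that("oversized panels are rejected with the offending field named", {
  expect_error(small_config(n_genes = 100, n_state_genes_per_state = 50),
               "n_state_genes_per_state")
  expect_error(small_config(bulk_depth = 0), "bulk_depth")
  expect_error(small_config(nb_dispersion = -1), "nb_dispersion")
  expect_error(small_config(bulk_replicates = 1), "bulk_replicates")
})

test_that("identical configs reproduce bitwise-identical datasets", {
  cfg <- small_config(seed = 11)
  sc1 <- simulate_single_cells(cfg)
  sc2 <- simulate_single_cells(cfg)
  expect_identical(sc1, sc2)
  expect_identical(simulate_bulk_sorted(cfg), simulate_bulk_sorted(cfg))
  expect_false(identical(sc1$counts,
                         simulate_single_cells(small_config(seed = 12))$counts))
})

test_that("beta = 0 decouples state from axis position", {
  cfg <- small_config(n_cells = 5000, n_genes = 200,
                      n_state_genes_per_state = 20, n_arterial_genes = 10,
                      n_venous_genes = 10, n_tgf_genes = 5, n_bmp_genes = 5,
                      beta_coupling = 0, seed = 3)
  sc <- simulate_single_cells(cfg)
  side <- factor(sc$av_position >= 0, labels = c("venous", "arterial"))
  p <- suppressWarnings(chisq.test(table(side, sc$state)))$p.value
  expect_gt(p, 0.01)
})

test_that("null effect sizes give flat per-gene means up to library size", {
  cfg <- small_config(n_cells = 5000, n_genes = 300,
                      n_state_genes_per_state = 30, n_arterial_genes = 15,
                      n_venous_genes = 15, n_tgf_genes = 5, n_bmp_genes = 5,
                      delta_state = 0, delta_av = 0, gene_logmean_sd = 0,
                      seed = 4)
  sc <- simulate_single_cells(cfg)
  gm <- colMeans(sc$counts)
  expect_true(all(gm / mean(gm) > 0.9 & gm / mean(gm) < 1.1))
})

test_that("axis position predicts FUCCI-Red membership under coupling", {
  # Monte-Carlo floor pre-computed from the softmax model: at beta = 1.5 the
  # a vs indicator(RED_G1) Spearman correlation concentrates near 0.55
  cfg <- small_config(n_cells = 2000, n_genes = 300,
                      n_state_genes_per_state = 30, n_arterial_genes = 15,
                      n_venous_genes = 15, n_tgf_genes = 5, n_bmp_genes = 5,
                      beta_coupling = 1.5, seed = 1)
  sc <- simulate_single_cells(cfg)
  rho <- cor(sc$av_position, as.numeric(sc$state == "RED_G1"),
             method = "spearman")
  expect_gt(rho, 0.3)
})

test_that("softmax state fractions match the closed form when uncoupled", {
  cfg <- small_config(n_cells = 8000, n_genes = 100,
                      n_state_genes_per_state = 10, n_arterial_genes = 5,
                      n_venous_genes = 5, n_tgf_genes = 5, n_bmp_genes = 5,
                      beta_coupling = 0, p_green_base = 0.2, seed = 9)
  sc <- simulate_single_cells(cfg)
  odds_g <- cfg$p_green_base / (1 - cfg$p_green_base)
  p_green <- odds_g / (2 + odds_g)
  p_other <- 1 / (2 + odds_g)
  frac <- as.numeric(table(sc$state)) / cfg$n_cells
  tol <- 4 * sqrt(0.25 / cfg$n_cells)  # ~4 binomial SDs
  expect_lt(abs(frac[1] - p_other), tol)
  expect_lt(abs(frac[2] - p_other), tol)
  expect_lt(abs(frac[3] - p_green), tol)
})

test_that("single-cell counts honour the NB mean-variance relation", {
  cfg <- small_config(n_cells = 5000, n_genes = 400,
                      n_state_genes_per_state = 0, n_arterial_genes = 0,
                      n_venous_genes = 0, n_tgf_genes = 0, n_bmp_genes = 0,
                      nb_dispersion = 0.5, libsize_logsd = 0, seed = 5)
  sc <- simulate_single_cells(cfg)
  mu <- colMeans(sc$counts)
  v <- apply(sc$counts, 2L, var)
  # Var = mu + phi mu^2  =>  regression of (v - mu) on mu^2 recovers phi
  phi_hat <- sum((v - mu) * mu^2) / sum(mu^4)
  expect_gt(phi_hat, 0.5 * 0.8)
  expect_lt(phi_hat, 0.5 * 1.2)
})

test_that("bulk design has 3 states x replicates samples with planted fold changes", {
  cfg <- small_config(n_genes = 5000, n_state_genes_per_state = 100,
                      n_arterial_genes = 50, n_venous_genes = 50,
                      n_tgf_genes = 20, n_bmp_genes = 20,
                      bulk_replicates = 3, bulk_depth = 1e6, delta_state = 1,
                      seed = 7)
  bulk <- simulate_bulk_sorted(cfg)
  expect_equal(ncol(bulk$counts), 9L)
  expect_equal(as.numeric(table(bulk$sample_state)), c(3, 3, 3))

  # planted RED genes run ~2x higher in RED samples (NB mean arithmetic,
  # shrunk slightly by per-state renormalization)
  panel <- make_gene_panel(cfg)
  red <- bulk$sample_state == "RED_G1"
  m_red <- rowMeans(bulk$counts[panel$state_red, red])
  m_oth <- rowMeans(bulk$counts[panel$state_red, !red])
  ratio <- mean(m_red / m_oth)
  expect_gt(ratio, 1.7)
  expect_lt(ratio, 2.3)
})

test_that("a null bulk simulation centres between-state log-ratios at zero", {
  cfg <- small_config(n_genes = 5000, n_state_genes_per_state = 100,
                      n_arterial_genes = 50, n_venous_genes = 50,
                      n_tgf_genes = 20, n_bmp_genes = 20, delta_state = 0,
                      bulk_depth = 1e6, seed = 8)
  bulk <- simulate_bulk_sorted(cfg)
  red <- bulk$sample_state == "RED_G1"
  lr <- log2(rowMeans(bulk$counts[, red]) + 0.5) -
        log2(rowMeans(bulk$counts[, !red]) + 0.5)
  expect_lt(abs(median(lr)), 0.05)
})

test_that("nuclear image fixture stores a ground truth equal to direct summation", {
  img <- simulate_nuclear_image(small_config(seed = 5))
  expect_true(all(img$image >= 0))
  expect_false(any(img$nuclear_mask & !img$vessel_mask))
  direct <- 100 * sum(img$image[img$nuclear_mask]) / sum(img$image[img$vessel_mask])
  expect_equal(img$truth_fraction, direct, tolerance = 1e-12)

  flat <- simulate_nuclear_image(small_config(seed = 6), uniform = TRUE)
  expect_equal(flat$truth_fraction,
               100 * sum(flat$nuclear_mask) / sum(flat$vessel_mask),
               tolerance = 1e-12)

  expect_error(simulate_nuclear_image(small_config(), uniform = TRUE,
                                      intensity_scale = 0),
               "zero")
})
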