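test_that("module score vanishes when controls carry the same signal", {
  # every gene identical within a bin: control mean cancels the signature mean
  n_cells <- 40; n_bins <- 5; per_bin <- 20
  vals <- seq_len(n_bins)
  m <- do.call(cbind, lapply(vals, function(v) matrix(v, n_cells, per_bin)))
  dimnames(m) <- list(sprintf("c%02d", 1:n_cells),
                      sprintf("g%03d", seq_len(n_bins * per_bin)))
  sig <- c("g001", "g025", "g045", "g085")
  sc <- module_score(m, sig, module_score_params(n_bins = n_bins, n_ctrl = 10, seed = 2))
  expect_true(all(abs(sc) < 1e-12))
})

test_that("module scores are shift-invariant and seed-deterministic", {
  m <- toy_matrix(30, 200, seed = 51, fn = function(n) rlnorm(n))
  sig <- colnames(m)[c(3, 50, 120)]
  p <- module_score_params(n_bins = 10, n_ctrl = 15, seed = 7)
  s1 <- module_score(m, sig, p)
  expect_equal(module_score(m + 3.7, sig, p), s1, tolerance = 1e-12)
  expect_identical(module_score(m, sig, p), s1)
  # a different seed redraws controls
  expect_false(identical(module_score(m, sig, module_score_params(10, 15, seed = 8)), s1))
  expect_error(module_score(m, c("nope1", "nope2"), p), "nope1")
  expect_warning(module_score(m, c(sig, "ghost"), p), "ghost")
  expect_error(module_score(m, sig, module_score_params(n_bins = 300)), "n_bins")
})

test_that("random gene sets score near zero on null data", {
  m <- toy_matrix(300, 1000, seed = 52, fn = function(n) rlnorm(n, sdlog = 1))
  set.seed(53)
  grand <- vapply(1:100, function(i) {
    sig <- sample(colnames(m), 50)
    mean(module_score(m, sig, module_score_params(seed = i)))
  }, numeric(1))
  expect_gt(mean(grand), -0.05)
  expect_lt(mean(grand), 0.05)
})

test_that("planted state programs raise in-state module scores", {
  cfg <- small_config(n_cells = 800, n_genes = 2000,
                      n_state_genes_per_state = 100, delta_state = 1, seed = 1)
  panel <- make_gene_panel(cfg)
  sc <- simulate_single_cells(cfg, panel)
  expr <- lognorm_cells(sc)
  s_red <- module_score(expr, panel$state_red, module_score_params(seed = 1))
  gap <- mean(s_red[sc$state == "RED_G1"]) - mean(s_red[sc$state != "RED_G1"])
  expect_gt(gap, 0.2)

  sig <- list(genes_negative = panel$state_negative,
              genes_red = panel$state_red, genes_green = panel$state_green)
  cc <- cellcycle_scores(expr, sig, module_score_params(seed = 1))
  gap_rn <- mean(cc$score_red[sc$state == "RED_G1"]) -
            mean(cc$score_red[sc$state == "NEGATIVE"])
  expect_gt(gap_rn, 0.1)
  expect_error(cellcycle_scores(expr, list(genes_negative = character(0),
                                           genes_red = "a", genes_green = "b")),
               "genes_negative")
})

test_that("signaling scores track the arterial axis through the TGF panel", {
  cfg <- small_config(n_cells = 1000, n_genes = 2000,
                      n_state_genes_per_state = 50, n_tgf_genes = 20,
                      n_bmp_genes = 20, delta_av = 1, seed = 1)
  panel <- make_gene_panel(cfg)
  sc <- simulate_single_cells(cfg, panel)
  expr <- lognorm_cells(sc)
  expect_length(tgf_signaling_genes(), 7)
  expect_length(bmp_signaling_genes(), 3)
  sg <- signaling_scores(expr, tgf_genes = panel$tgf, bmp_genes = panel$bmp,
                         params = module_score_params(seed = 1))
  expect_gt(cor(sg$tgf_score, sc$av_position), 0.3)
  expect_lt(cor(sg$bmp_score, sc$av_position), -0.3)
})

test_that("constant matrices give zero scores everywhere", {
  m <- matrix(4, 20, 60,
              dimnames = list(sprintf("c%02d", 1:20), sprintf("g%02d", 1:60)))
  p <- module_score_params(n_bins = 4, n_ctrl = 5, seed = 3)
  expect_true(all(abs(module_score(m, c("g01", "g30"), p)) < 1e-12))
  sg <- signaling_scores(m, tgf_genes = c("g01", "g02"), bmp_genes = c("g03"),
                         params = p)
  expect_true(all(abs(unlist(sg)) < 1e-12))
})

test_that("av scores are z-based, antisymmetric, and recover the axis", {
  m <- toy_matrix(100, 40, seed = 55)
  art <- colnames(m)[1:10]; ven <- colnames(m)[11:20]
  av <- av_scores(m, art, ven)
  expect_equal(av$av_score, av$arterial_score - av$venous_score)
  swapped <- av_scores(m, ven, art)
  expect_equal(swapped$av_score, -av$av_score, tolerance = 1e-12)

  # identical arterial and venous profiles cancel exactly
  m2 <- m
  m2[, 11:20] <- m2[, 1:10]
  expect_true(all(abs(av_scores(m2, art, ven)$av_score) < 1e-12))

  # z-scores across cells have mean 0 and variance 1
  z <- scale(m[, art])
  expect_true(all(abs(colMeans(z)) < 1e-12))
  expect_true(all(abs(apply(z, 2, var) - 1) < 1e-12))

  # a cell sitting at +1 SD on every arterial and -1 SD on every venous gene
  # scores exactly 2: columns (1, -1, 0) have mean 0 and sd 1, so cell 1's
  # z is exactly +1 on arterial and -1 on venous genes
  base <- cbind(a1 = c(1, -1, 0), a2 = c(1, 0, -1),
                v1 = c(-1, 1, 0), v2 = c(-1, 0, 1))
  rownames(base) <- c("hi", "x", "y")
  av2 <- av_scores(base, c("a1", "a2"), c("v1", "v2"))
  expect_equal(av2$av_score[1], 2, tolerance = 1e-12)

  expect_error(av_scores(m, c("zzz"), ven), "arterial")
  const <- m; const[, 1:10] <- 1
  expect_error(av_scores(const, art, ven), "zero variance")
})

test_that("relative G1 score is an exact antisymmetric difference", {
  expect_equal(relative_g1(0.5, 0.2), 0.3)
  expect_equal(relative_g1(c(1, 2), c(1, 2)), c(0, 0))
  a <- c(0.3, -0.1, 2); b <- c(1, 0.4, -2)
  expect_equal(relative_g1(a, b), -relative_g1(b, a))
  expect_error(relative_g1(1:3, 1:2), "equal length")
})

test_that("imputed AV score recovers the latent axis end to end", {
  cfg <- small_config(n_cells = 600, n_genes = 1500,
                      n_state_genes_per_state = 60, n_arterial_genes = 40,
                      n_venous_genes = 40, beta_coupling = 1.5, delta_av = 1,
                      seed = 1)
  panel <- make_gene_panel(cfg)
  sc <- simulate_single_cells(cfg, panel)
  expr <- lognorm_cells(sc)
  expressed <- colSums(sc$counts) > 0
  op <- build_operator(expr[, expressed], t = 4)
  imp <- impute(expr[, expressed], op)
  av <- av_scores(imp, panel$arterial, panel$venous)
  expect_gt(cor(av$av_score, sc$av_position), 0.5)
})
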