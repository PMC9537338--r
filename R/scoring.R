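#' Canonical TGF-beta signaling gene list
#'
#' Default TGF-beta pathway panel used for signaling scores: Smad3, Tgfbr1,
#' Tgfbr2, Smad6, Acvrl1, Tgfb1, Tgfb2. An extended variant adding Smad2 and
#' Smad7 (and dropping Smad6) circulates in the literature and is available
#' via `variant = "extended"`.
#'
#' @param variant `"default"` (7 genes) or `"extended"` (8 genes).
#' @return Character vector of gene symbols.
#' @export
tgf_signaling_genes <- function(variant = c("default", "extended")) {
  switch(match.arg(variant),
         default = c("Smad3", "Tgfbr1", "Tgfbr2", "Smad6", "Acvrl1", "Tgfb1", "Tgfb2"),
         extended = c("Smad2", "Smad3", "Tgfbr1", "Tgfbr2", "Acvrl1", "Tgfb1",
                      "Tgfb2", "Smad7"))
}

#' Canonical BMP signaling gene list
#'
#' Default BMP pathway panel: Smad1, Smad5, Bmpr2. The extended variant adds
#' the type-I receptors Bmpr1a and Bmpr1b.
#'
#' @param variant `"default"` (3 genes) or `"extended"` (5 genes).
#' @return Character vector of gene symbols.
#' @export
bmp_signaling_genes <- function(variant = c("default", "extended")) {
  switch(match.arg(variant),
         default = c("Smad1", "Smad5", "Bmpr2"),
         extended = c("Smad1", "Smad5", "Bmpr2", "Bmpr1a", "Bmpr1b"))
}

#' Parameters for expression-bin-matched module scoring
#'
#' @param n_bins Number of equal-frequency expression bins (default 24).
#' @param n_ctrl Control genes drawn per signature gene (default 100).
#' @param seed Seed for the control draws.
#' @return A list of class `"module_score_params"`.
#' @export
module_score_params <- function(n_bins = 24L, n_ctrl = 100L, seed = 0L) {
  if (!is_number(n_bins) || n_bins < 2) stop_bad("'n_bins' must be >= 2")
  if (!is_number(n_ctrl) || n_ctrl < 1) stop_bad("'n_ctrl' must be >= 1")
  if (!is_number(seed)) stop_bad("'seed' must be a finite number")
  structure(list(n_bins = as.integer(n_bins), n_ctrl = as.integer(n_ctrl),
                 seed = as.integer(seed)),
            class = "module_score_params")
}

#' Per-cell gene-set module score with bin-matched controls
#'
#' Genes are ranked by mean expression across cells and cut into `n_bins`
#' equal-frequency bins. For each signature gene, `n_ctrl` control genes are
#' drawn (seeded, without replacement) from the same bin; the score of a cell
#' is its mean expression over the signature genes minus its mean over the
#' pooled control multiset. Subtracting expression-matched controls removes
#' the component of the signal driven by overall expression level, so scores
#' of a random gene set are centred at zero.
#'
#' @param expr_lognorm Cells x genes matrix of log-normalized expression with
#'   gene column names.
#' @param gene_set Character vector of signature genes; members missing from
#'   the matrix are dropped with a warning.
#' @param params A [module_score_params()].
#' @return Numeric per-cell score vector (named by rownames of the matrix).
#' @export
module_score <- function(expr_lognorm, gene_set, params = module_score_params()) {
  stopifnot(inherits(params, "module_score_params"))
  if (!is.matrix(expr_lognorm) || is.null(colnames(expr_lognorm)))
    stop_bad("'expr_lognorm' must be a cells x genes matrix with gene names")
  genes <- colnames(expr_lognorm)
  if (params$n_bins > length(genes))
    stop_bad("'n_bins' (%d) exceeds the number of genes (%d)",
             params$n_bins, length(genes))
  gene_set <- unique(gene_set)
  missing <- setdiff(gene_set, genes)
  present <- intersect(gene_set, genes)
  if (!length(present))
    stop_bad("no gene of the set is present in the matrix; missing: %s",
             paste(missing, collapse = ", "))
  if (length(missing))
    warning("dropping gene(s) absent from the matrix: ",
            paste(missing, collapse = ", "))

  avg <- colMeans(expr_lognorm)
  ord <- rank(avg, ties.method = "first")
  bin <- ceiling(ord * params$n_bins / length(genes))

  ctrl <- with_seed(params$seed, {
    unlist(lapply(present, function(g) {
      pool <- which(bin == bin[[match(g, genes)]])
      sample(pool, min(params$n_ctrl, length(pool)))
    }), use.names = FALSE)
  })
  rowMeans(expr_lognorm[, present, drop = FALSE]) -
    rowMeans(expr_lognorm[, ctrl, drop = FALSE])
}

#' TGF-beta and BMP signaling scores
#'
#' Module scores ([module_score()]) of the TGF-beta and BMP pathway panels.
#'
#' @param expr_lognorm Cells x genes log-normalized matrix.
#' @param tgf_genes,bmp_genes Gene lists; default to [tgf_signaling_genes()]
#'   and [bmp_signaling_genes()].
#' @param params A [module_score_params()].
#' @return A data.frame with columns `tgf_score`, `bmp_score`.
#' @export
signaling_scores <- function(expr_lognorm,
                             tgf_genes = tgf_signaling_genes(),
                             bmp_genes = bmp_signaling_genes(),
                             params = module_score_params()) {
  data.frame(tgf_score = module_score(expr_lognorm, tgf_genes, params),
             bmp_score = module_score(expr_lognorm, bmp_genes, params))
}

#' FUCCI cell-cycle-state scores
#'
#' One module score per state signature (derived from sorted-population bulk
#' RNA-seq via [extract_state_signatures()]).
#'
#' @param expr_lognorm Cells x genes log-normalized matrix.
#' @param signatures A [extract_state_signatures()] result (or any list with
#'   `genes_negative`, `genes_red`, `genes_green`).
#' @param params A [module_score_params()].
#' @return A data.frame with columns `score_negative`, `score_red`,
#'   `score_green`.
#' @export
cellcycle_scores <- function(expr_lognorm, signatures,
                             params = module_score_params()) {
  for (s in c("genes_negative", "genes_red", "genes_green"))
    if (!length(signatures[[s]]))
      stop_bad("signature '%s' is empty", s)
  data.frame(
    score_negative = module_score(expr_lognorm, signatures$genes_negative, params),
    score_red = module_score(expr_lognorm, signatures$genes_red, params),
    score_green = module_score(expr_lognorm, signatures$genes_green, params))
}

#' Arterial, venous and arterial-vs-venous scores
#'
#' Computes "average relative expression" on an imputed matrix: every gene is
#' z-scored across cells (genes with zero variance contribute 0), the arterial
#' score of a cell is the mean z over the arterial list, the venous score the
#' mean z over the venous list, and the arterial-vs-venous score their
#' difference.
#'
#' @param expr_imputed Cells x genes matrix, typically the output of
#'   [impute()].
#' @param arterial_genes,venous_genes Gene lists (intersected with the matrix;
#'   missing genes dropped with a warning).
#' @return A data.frame with columns `arterial_score`, `venous_score`,
#'   `av_score` (`av_score == arterial_score - venous_score` exactly).
#' @export
av_scores <- function(expr_imputed, arterial_genes, venous_genes) {
  if (!is.matrix(expr_imputed) || is.null(colnames(expr_imputed)))
    stop_bad("'expr_imputed' must be a cells x genes matrix with gene names")
  mean_z <- function(gene_list, label) {
    present <- intersect(unique(gene_list), colnames(expr_imputed))
    if (!length(present)) stop_bad("no %s gene present in the matrix", label)
    missing <- setdiff(unique(gene_list), present)
    if (length(missing))
      warning("dropping ", label, " gene(s) absent from the matrix: ",
              paste(missing, collapse = ", "))
    sub <- expr_imputed[, present, drop = FALSE]
    sds <- apply(sub, 2L, stats::sd)
    if (all(sds == 0))
      stop_bad("all %s genes have zero variance across cells", label)
    z <- scale(sub)
    z[, sds == 0] <- 0
    rowMeans(z)
  }
  s_art <- mean_z(arterial_genes, "arterial")
  s_ven <- mean_z(venous_genes, "venous")
  data.frame(arterial_score = s_art, venous_score = s_ven,
             av_score = s_art - s_ven)
}

#' Relative G1 score
#'
#' `delta_G1 = score_red - score_negative` per cell: positions each cell
#' between the early-G1 (FUCCI-Negative) and late-G1 (FUCCI-Red)
#' transcriptional states.
#'
#' @param score_red,score_negative Aligned per-cell score vectors.
#' @return Numeric vector of the same length.
#' @export
relative_g1 <- function(score_red, score_negative) {
  if (length(score_red) != length(score_negative))
    stop_bad("score vectors must have equal length")
  score_red - score_negative
}

#' Log-normalize single-cell counts
#'
#' Per-cell `log2(1 + 1e6 * count / cell_total)` for a cells x genes count
#' matrix. Genes expressed in no cell can optionally be dropped.
#'
#' @param counts Cells x genes nonnegative matrix (or a
#'   `single_cell_dataset`).
#' @param drop_unexpressed Drop all-zero genes (default FALSE).
#' @return Cells x genes matrix of log2-CPM values.
#' @export
lognorm_cells <- function(counts, drop_unexpressed = FALSE) {
  if (inherits(counts, "single_cell_dataset")) counts <- counts$counts
  if (!is.matrix(counts) || any(!is.finite(counts)) || any(counts < 0))
    stop_bad("'counts' must be a finite nonnegative cells x genes matrix")
  tot <- rowSums(counts)
  if (any(tot <= 0)) stop_bad("%d cell(s) have zero total counts", sum(tot <= 0))
  x <- log2(1 + counts / tot * 1e6)
  if (drop_unexpressed) x <- x[, colSums(counts) > 0, drop = FALSE]
  x
}

#' Full per-cell score table
#'
#' Convenience wrapper computing every score of the analysis on one dataset:
#' cell-cycle-state module scores and the relative G1 score on log-normalized
#' counts, TGF-beta/BMP signaling scores, and arterial/venous/AV scores on the
#' diffusion-imputed matrix.
#'
#' @param expr_lognorm Cells x genes log-normalized matrix.
#' @param expr_imputed Imputed matrix from [impute()] (same cells).
#' @param signatures A [extract_state_signatures()] result.
#' @param arterial_genes,venous_genes Arterial/venous identity gene lists.
#' @param tgf_genes,bmp_genes Signaling panels.
#' @param params A [module_score_params()].
#' @return A data.frame (one row per cell) with columns `score_negative`,
#'   `score_red`, `score_green`, `relative_g1`, `tgf_score`, `bmp_score`,
#'   `arterial_score`, `venous_score`, `av_score`.
#' @export
score_cells <- function(expr_lognorm, expr_imputed, signatures,
                        arterial_genes, venous_genes,
                        tgf_genes = tgf_signaling_genes(),
                        bmp_genes = bmp_signaling_genes(),
                        params = module_score_params()) {
  cc <- cellcycle_scores(expr_lognorm, signatures, params)
  sg <- signaling_scores(expr_lognorm, tgf_genes, bmp_genes, params)
  av <- av_scores(expr_imputed, arterial_genes, venous_genes)
  out <- cbind(cc,
               relative_g1 = relative_g1(cc$score_red, cc$score_negative),
               sg, av)
  rownames(out) <- rownames(expr_lognorm)
  out
}
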