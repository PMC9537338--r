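#' Simulation configuration for synthetic FUCCI endothelial datasets
#'
#' Bundles every parameter of the synthetic-data generator: dataset sizes,
#' planted gene-program sizes and effect sizes, the coupling between the
#' arterial-venous axis and cell-cycle-state propensity, negative-binomial
#' noise, library-size variation, and per-state reporter fluorescence.
#'
#' The generator emulates two data structures: droplet scRNA-seq of retinal
#' endothelial cells spread along a latent venous-to-arterial axis
#' `a in [-1, 1]`, and bulk RNA-seq of FACS-sorted FUCCI-Negative /
#' FUCCI-Red G1 / FUCCI-Green S/G2/M populations with paired replicates.
#'
#' @param n_cells Number of single cells.
#' @param n_genes Number of genes.
#' @param n_arterial_genes,n_venous_genes Sizes of the planted arterial and
#'   venous gene programs.
#' @param n_state_genes_per_state Planted cell-cycle-state signature genes per
#'   FUCCI state.
#' @param n_tgf_genes,n_bmp_genes Sizes of the planted TGF-beta (co-scales with
#'   the arterial program) and BMP (co-scales with the venous program) panels.
#' @param delta_state log2 fold-change gained by a state-signature gene in its
#'   own state.
#' @param delta_av log2 fold-change span of arterial/venous program genes
#'   across the arterial-venous axis.
#' @param beta_coupling Strength of the softmax coupling between axis position
#'   and cell-cycle-state propensity (0 = no coupling).
#' @param nb_dispersion Negative-binomial dispersion `phi` for single-cell
#'   counts (`Var = mu + phi * mu^2`).
#' @param bulk_dispersion Negative-binomial dispersion for bulk samples.
#'   Sorted-population bulk libraries from paired replicates are far less
#'   dispersed than droplet data.
#' @param gene_logmean_sd SD of the log-normal baseline gene-abundance
#'   distribution. 0 gives a flat expression profile; the default 1 gives the
#'   heavy-tailed abundance spread real data show, which is what makes
#'   expression-bin-matched control genes meaningful.
#' @param libsize_logmean,libsize_logsd Log-normal parameters of the expected
#'   per-cell library size `l_i` (defaults: median 5000 counts, 0.3 log-SD).
#' @param bulk_replicates Replicates per FUCCI state in the bulk design.
#' @param bulk_depth Expected counts per bulk sample.
#' @param fluor_logmeans 3 x 2 matrix of log-intensity means, rows
#'   NEGATIVE/RED_G1/GREEN_SG2M, columns mCherry/mVenus.
#' @param fluor_logsd Log-SD of reporter intensities (all states/channels).
#' @param p_green_base Baseline S/G2/M probability at axis position 0.
#' @param seed Integer seed; identical configs give bitwise-identical datasets.
#' @return A validated list of class `"sim_config"`.
#' @examples
#' cfg <- sim_config(n_cells = 200, n_genes = 500, seed = 1)
#' @export
sim_config <- function(n_cells = 2000,
                       n_genes = 5000,
                       n_arterial_genes = 50,
                       n_venous_genes = 50,
                       n_state_genes_per_state = 100,
                       n_tgf_genes = 20,
                       n_bmp_genes = 20,
                       delta_state = 1,
                       delta_av = 1,
                       beta_coupling = 1.5,
                       nb_dispersion = 0.5,
                       bulk_dispersion = 0.01,
                       gene_logmean_sd = 1,
                       libsize_logmean = log(5000),
                       libsize_logsd = 0.3,
                       bulk_replicates = 3,
                       bulk_depth = 1e6,
                       fluor_logmeans = rbind(NEGATIVE   = c(mcherry = log(10),   mvenus = log(10)),
                                              RED_G1     = c(mcherry = log(1000), mvenus = log(10)),
                                              GREEN_SG2M = c(mcherry = log(10),   mvenus = log(1000))),
                       fluor_logsd = 0.5,
                       p_green_base = 0.2,
                       seed = 1L) {
  cfg <- list(n_cells = n_cells, n_genes = n_genes,
              n_arterial_genes = n_arterial_genes, n_venous_genes = n_venous_genes,
              n_state_genes_per_state = n_state_genes_per_state,
              n_tgf_genes = n_tgf_genes, n_bmp_genes = n_bmp_genes,
              delta_state = delta_state, delta_av = delta_av,
              beta_coupling = beta_coupling,
              nb_dispersion = nb_dispersion, bulk_dispersion = bulk_dispersion,
              gene_logmean_sd = gene_logmean_sd,
              libsize_logmean = libsize_logmean, libsize_logsd = libsize_logsd,
              bulk_replicates = bulk_replicates, bulk_depth = bulk_depth,
              fluor_logmeans = fluor_logmeans, fluor_logsd = fluor_logsd,
              p_green_base = p_green_base, seed = seed)
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  for (f in c("n_cells", "n_genes")) {
    if (!is_number(cfg[[f]]) || cfg[[f]] < 1 || cfg[[f]] != round(cfg[[f]]))
      stop_bad("'%s' must be a positive integer, got %s", f, format(cfg[[f]]))
  }
  for (f in c("n_arterial_genes", "n_venous_genes", "n_state_genes_per_state",
              "n_tgf_genes", "n_bmp_genes")) {
    if (!is_number(cfg[[f]]) || cfg[[f]] < 0 || cfg[[f]] != round(cfg[[f]]))
      stop_bad("'%s' must be a nonnegative integer", f)
  }
  for (f in c("delta_state", "delta_av", "beta_coupling", "gene_logmean_sd",
              "libsize_logmean", "libsize_logsd", "fluor_logsd")) {
    if (!is_number(cfg[[f]])) stop_bad("'%s' must be a finite number", f)
  }
  if (!is_number(cfg$nb_dispersion) || cfg$nb_dispersion <= 0)
    stop_bad("'nb_dispersion' must be > 0")
  if (!is_number(cfg$bulk_dispersion) || cfg$bulk_dispersion <= 0)
    stop_bad("'bulk_dispersion' must be > 0")
  if (!is_number(cfg$bulk_replicates) || cfg$bulk_replicates < 2)
    stop_bad("'bulk_replicates' must be >= 2")
  if (!is_number(cfg$bulk_depth) || cfg$bulk_depth <= 0)
    stop_bad("'bulk_depth' must be > 0")
  if (!is_number(cfg$p_green_base) || cfg$p_green_base < 0 || cfg$p_green_base > 1)
    stop_bad("'p_green_base' must be in [0, 1]")
  if (!is.matrix(cfg$fluor_logmeans) || !all(dim(cfg$fluor_logmeans) == c(3, 2)) ||
      !all(is.finite(cfg$fluor_logmeans)))
    stop_bad("'fluor_logmeans' must be a finite 3 x 2 matrix (states x channels)")
  if (!is_number(cfg$seed)) stop_bad("'seed' must be a finite number")
  panel_total <- cfg$n_arterial_genes + cfg$n_venous_genes +
    3 * cfg$n_state_genes_per_state + cfg$n_tgf_genes + cfg$n_bmp_genes
  if (panel_total > cfg$n_genes)
    stop_bad(paste0("gene panels need %d genes but 'n_genes' is %d; reduce ",
                    "'n_arterial_genes'/'n_venous_genes'/'n_state_genes_per_state'/",
                    "'n_tgf_genes'/'n_bmp_genes'"),
             panel_total, cfg$n_genes)
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_cells, "cells x", x$n_genes, "genes;",
      x$bulk_replicates, "bulk replicates/state @", format(x$bulk_depth), "counts\n")
  cat("  planted programs: arterial", x$n_arterial_genes, "| venous", x$n_venous_genes,
      "| state", x$n_state_genes_per_state, "/state | tgf", x$n_tgf_genes,
      "| bmp", x$n_bmp_genes, "\n")
  cat("  effects: delta_state", x$delta_state, "| delta_av", x$delta_av,
      "| beta", x$beta_coupling, "| phi_sc", x$nb_dispersion,
      "| phi_bulk", x$bulk_dispersion, "| seed", x$seed, "\n")
  invisible(x)
}

# canonical FUCCI state labels, in fixed order
fucci_states <- function() c("NEGATIVE", "RED_G1", "GREEN_SG2M")
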