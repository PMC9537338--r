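#' Build the planted gene panel for a simulation
#'
#' Assigns disjoint gene panels (arterial, venous, per-state cell-cycle
#' signatures, TGF-beta, BMP, housekeeping) over the gene index of a
#' [sim_config()]. The leading members of the arterial and venous panels carry
#' the canonical mouse marker names (Efnb2, Gja4, Gja5, Sox17, Bmx, Jag1, Hey1
#' and Ephb4, Nrp2, Nr2f2, Ptgs1, Apoe, Slc38a5), and the TGF/BMP panels lead
#' with the canonical pathway genes; remaining slots get synthetic names.
#'
#' @param config A [sim_config()].
#' @return A list of class `"gene_panel"` with character vectors `arterial`,
#'   `venous`, `state_negative`, `state_red`, `state_green`, `tgf`, `bmp`,
#'   `housekeeping`, and `gene_names` (the full gene index, in order).
#' @examples
#' panel <- make_gene_panel(sim_config(n_cells = 100, n_genes = 600))
#' head(panel$arterial)
#' @export
make_gene_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)

  named <- list(
    arterial = c("Efnb2", "Gja4", "Gja5", "Sox17", "Bmx", "Jag1", "Hey1"),
    venous   = c("Ephb4", "Nrp2", "Nr2f2", "Ptgs1", "Apoe", "Slc38a5"),
    tgf      = tgf_signaling_genes(),
    bmp      = bmp_signaling_genes()
  )
  sizes <- c(arterial = config$n_arterial_genes,
             venous = config$n_venous_genes,
             state_negative = config$n_state_genes_per_state,
             state_red = config$n_state_genes_per_state,
             state_green = config$n_state_genes_per_state,
             tgf = config$n_tgf_genes,
             bmp = config$n_bmp_genes)
  prefix <- c(arterial = "Art", venous = "Ven", state_negative = "StNeg",
              state_red = "StRed", state_green = "StGrn", tgf = "Tgfx",
              bmp = "Bmpx")

  panel <- list()
  for (p in names(sizes)) {
    n <- sizes[[p]]
    real <- if (p %in% names(named)) named[[p]] else character(0)
    nm <- c(real[seq_len(min(n, length(real)))],
            if (n > length(real))
              sprintf("%s%03d", prefix[[p]], seq_len(n - length(real))))
    panel[[p]] <- nm
  }
  used <- sum(sizes)
  panel$housekeeping <- sprintf("Gene%05d", seq_len(config$n_genes - used))
  panel$gene_names <- unlist(panel[c("arterial", "venous", "state_negative",
                                     "state_red", "state_green", "tgf", "bmp",
                                     "housekeeping")], use.names = FALSE)
  stopifnot(!anyDuplicated(panel$gene_names),
            length(panel$gene_names) == config$n_genes)
  class(panel) <- "gene_panel"
  panel
}

# per-gene baseline log2 relative abundance, shared machinery for both
# single-cell and bulk generators (drawn inside each generator's seeded stream)
baseline_log2_weights <- function(config) {
  stats::rnorm(config$n_genes, mean = 0, sd = config$gene_logmean_sd / log(2))
}

# indices of each panel within the gene index
panel_index <- function(panel) {
  lapply(panel[c("arterial", "venous", "state_negative", "state_red",
                 "state_green", "tgf", "bmp")],
         function(g) match(g, panel$gene_names))
}

#' Simulate droplet single-cell RNA-seq along the arterial-venous continuum
#'
#' Each cell gets a latent axis position `a ~ Uniform(-1, 1)` (venous at -1,
#' arterial at +1). Cell-cycle state is drawn from a three-way softmax with
#' logits `-beta * a` (NEGATIVE), `+beta * a` (RED_G1), and
#' `logit(p_green_base) - beta * a` (GREEN_SG2M), so the late-G1 propensity
#' rises toward the arterial side and both early-G1 and S/G2/M toward the
#' venous side. Arterial program genes scale as `2^(delta_av * max(a, 0))`,
#' venous as `2^(delta_av * max(-a, 0))`; TGF genes co-scale with the arterial
#' and BMP genes with the venous program; each state-signature gene gains
#' `2^delta_state` in its own state. Per-cell relative abundances are
#' renormalized, multiplied by a log-normal library size, and counts drawn as
#' NB(mu, phi) with `Var = mu + phi mu^2`. Reporter fluorescence is log-normal
#' per state (RED_G1 high mCherry, GREEN_SG2M high mVenus, NEGATIVE dim).
#'
#' @param config A [sim_config()].
#' @param panel A [make_gene_panel()] result for the same config.
#' @return A list of class `"single_cell_dataset"` with `counts` (cells x
#'   genes integer matrix, dimnames set), `gene_names`, `cell_ids`,
#'   `av_position`, `state` (factor), `mcherry`, `mvenus`.
#' @examples
#' cfg <- sim_config(n_cells = 100, n_genes = 600, seed = 7)
#' sc <- simulate_single_cells(cfg, make_gene_panel(cfg))
#' table(sc$state)
#' @export
simulate_single_cells <- function(config, panel = make_gene_panel(config)) {
  stopifnot(inherits(config, "sim_config"), inherits(panel, "gene_panel"))
  validate_sim_config(config)
  if (length(panel$gene_names) != config$n_genes)
    stop_bad("panel was built for %d genes, config has %d",
             length(panel$gene_names), config$n_genes)
  idx <- panel_index(panel)
  n <- config$n_cells
  g <- config$n_genes

  with_seed(stage_seed(config$seed, "single_cells"), {
    a <- stats::runif(n, -1, 1)

    logit_g <- stats::qlogis(min(max(config$p_green_base, 1e-12), 1 - 1e-12))
    logits <- cbind(NEGATIVE = -config$beta_coupling * a,
                    RED_G1 = config$beta_coupling * a,
                    GREEN_SG2M = logit_g - config$beta_coupling * a)
    pr <- exp(logits - apply(logits, 1L, max))
    pr <- pr / rowSums(pr)
    u <- stats::runif(n)
    state_i <- 1L + (u > pr[, 1L]) + (u > pr[, 1L] + pr[, 2L])
    state <- factor(fucci_states()[state_i], levels = fucci_states())

    # per-cell log2 expression weights: baseline + planted programs
    w0 <- baseline_log2_weights(config)
    lw <- matrix(w0, nrow = n, ncol = g, byrow = TRUE)
    art_boost <- config$delta_av * pmax(a, 0)
    ven_boost <- config$delta_av * pmax(-a, 0)
    for (p in c("arterial", "tgf")) if (length(idx[[p]]))
      lw[, idx[[p]]] <- lw[, idx[[p]]] + art_boost
    for (p in c("venous", "bmp")) if (length(idx[[p]]))
      lw[, idx[[p]]] <- lw[, idx[[p]]] + ven_boost
    state_panels <- c(NEGATIVE = "state_negative", RED_G1 = "state_red",
                      GREEN_SG2M = "state_green")
    for (s in fucci_states()) {
      cols <- idx[[state_panels[[s]]]]
      rows <- state == s
      if (length(cols) && any(rows))
        lw[rows, cols] <- lw[rows, cols] + config$delta_state
    }

    w <- 2^lw
    libsize <- stats::rlnorm(n, config$libsize_logmean, config$libsize_logsd)
    mu <- (w / rowSums(w)) * libsize
    counts <- matrix(stats::rnbinom(n * g, mu = mu, size = 1 / config$nb_dispersion),
                     nrow = n, ncol = g)

    fl <- config$fluor_logmeans
    mcherry <- stats::rlnorm(n, fl[state_i, 1L], config$fluor_logsd)
    mvenus <- stats::rlnorm(n, fl[state_i, 2L], config$fluor_logsd)

    cell_ids <- sprintf("cell_%05d", seq_len(n))
    dimnames(counts) <- list(cell_ids, panel$gene_names)
    structure(list(counts = counts, gene_names = panel$gene_names,
                   cell_ids = cell_ids, av_position = a, state = state,
                   mcherry = mcherry, mvenus = mvenus),
              class = "single_cell_dataset")
  })
}

#' @export
print.single_cell_dataset <- function(x, ...) {
  cat("single_cell_dataset:", nrow(x$counts), "cells x", ncol(x$counts), "genes\n")
  print(table(state = x$state))
  invisible(x)
}

#' Simulate bulk RNA-seq of FACS-sorted FUCCI populations
#'
#' For each FUCCI state and replicate, gene counts are drawn NB with mean
#' proportional to the state's expression program (baseline abundances with
#' each state-signature panel up `2^delta_state` in its own state), scaled so
#' every sample expects `bulk_depth` total counts. The default design of 3
#' replicates x 3 states yields nine samples.
#'
#' @param config A [sim_config()].
#' @param panel A [make_gene_panel()] result for the same config.
#' @return A list of class `"bulk_dataset"`: `counts` (genes x samples integer
#'   matrix), `sample_state` (factor), `replicate` (integer), `gene_names`.
#' @examples
#' cfg <- sim_config(n_cells = 10, n_genes = 600, seed = 2)
#' bk <- simulate_bulk_sorted(cfg, make_gene_panel(cfg))
#' table(bk$sample_state)
#' @export
simulate_bulk_sorted <- function(config, panel = make_gene_panel(config)) {
  stopifnot(inherits(config, "sim_config"), inherits(panel, "gene_panel"))
  validate_sim_config(config)
  if (length(panel$gene_names) != config$n_genes)
    stop_bad("panel was built for %d genes, config has %d",
             length(panel$gene_names), config$n_genes)
  idx <- panel_index(panel)
  g <- config$n_genes
  reps <- config$bulk_replicates
  states <- fucci_states()
  state_panels <- c(NEGATIVE = "state_negative", RED_G1 = "state_red",
                    GREEN_SG2M = "state_green")

  with_seed(stage_seed(config$seed, "bulk_sorted"), {
    w0 <- baseline_log2_weights(config)
    n_samples <- length(states) * reps
    counts <- matrix(0L, nrow = g, ncol = n_samples)
    sample_state <- character(n_samples)
    replicate <- integer(n_samples)
    j <- 0L
    for (s in states) {
      lw <- w0
      cols <- idx[[state_panels[[s]]]]
      if (length(cols)) lw[cols] <- lw[cols] + config$delta_state
      w <- 2^lw
      mu <- config$bulk_depth * w / sum(w)
      for (r in seq_len(reps)) {
        j <- j + 1L
        counts[, j] <- stats::rnbinom(g, mu = mu, size = 1 / config$bulk_dispersion)
        sample_state[j] <- s
        replicate[j] <- r
      }
    }
    sample_ids <- sprintf("%s_rep%d", sample_state, replicate)
    dimnames(counts) <- list(panel$gene_names, sample_ids)
    structure(list(counts = counts,
                   sample_state = factor(sample_state, levels = states),
                   replicate = replicate, gene_names = panel$gene_names),
              class = "bulk_dataset")
  })
}

#' @export
print.bulk_dataset <- function(x, ...) {
  cat("bulk_dataset:", nrow(x$counts), "genes x", ncol(x$counts), "samples (",
      paste(levels(x$sample_state), collapse = "/"), ")\n")
  invisible(x)
}

#' Simulate a toy vessel image with nuclear and vessel masks
#'
#' Produces a speckled nonnegative intensity field over a rectangular image,
#' a vessel mask (a horizontal band) and a nuclear mask (disks inside the
#' vessel), together with the ground-truth nuclear fraction
#' `100 * sum(image[nuclear]) / sum(image[vessel])` used to validate the
#' nuclear-localization statistic.
#'
#' @param config A [sim_config()] (only its seed is used).
#' @param nrow,ncol Image dimensions in pixels.
#' @param n_nuclei Number of nuclear disks planted inside the vessel band.
#' @param uniform If `TRUE`, intensity is 1 everywhere (a flat field);
#'   otherwise seeded log-normal speckle.
#' @param intensity_scale Multiplier on the intensity field; a zero scale gives
#'   a zero image, which the generator refuses (the fraction is undefined).
#' @return A list of class `"nuclear_image"`: `image`, `nuclear_mask`,
#'   `vessel_mask`, and `truth_fraction` (percent).
#' @export
simulate_nuclear_image <- function(config, nrow = 64, ncol = 64, n_nuclei = 5,
                                   uniform = FALSE, intensity_scale = 1) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(stage_seed(config$seed, "nuclear_image"), {
    img <- if (uniform) matrix(1, nrow, ncol)
           else matrix(stats::rlnorm(nrow * ncol, 0, 0.5), nrow, ncol)
    img <- img * intensity_scale

    vessel <- matrix(FALSE, nrow, ncol)
    band <- seq(floor(nrow * 0.3), ceiling(nrow * 0.7))
    vessel[band, ] <- TRUE

    nuclear <- matrix(FALSE, nrow, ncol)
    rad <- max(2, floor(nrow * 0.04))
    cx <- sample(band[(rad + 1):(length(band) - rad)], n_nuclei, replace = TRUE)
    cy <- sample((rad + 1):(ncol - rad), n_nuclei, replace = TRUE)
    rr <- row(img); cc <- col(img)
    for (i in seq_len(n_nuclei))
      nuclear <- nuclear | ((rr - cx[i])^2 + (cc - cy[i])^2 <= rad^2)
    nuclear <- nuclear & vessel

    if (any(nuclear & !vessel))
      stop_bad("nuclear mask extends outside the vessel mask")
    vtot <- sum(img[vessel])
    if (vtot <= 0)
      stop_bad("total vessel intensity is zero; nuclear fraction undefined")
    structure(list(image = img, nuclear_mask = nuclear, vessel_mask = vessel,
                   truth_fraction = 100 * sum(img[nuclear]) / vtot),
              class = "nuclear_image")
  })
}
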