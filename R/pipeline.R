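#' Read an expression matrix
#'
#' Supports two dialects by extension: Matrix Market (`.mtx`, 1-based triplet,
#' accompanied by `genes.tsv` and `barcodes.tsv` in the same directory) and
#' dense TSV (header row of gene names, first column `cell_id`). Both
#' round-trip losslessly through [write_expression()].
#'
#' @param path Path to a `.mtx` or `.tsv` file.
#' @return A cells x genes matrix with cell and gene names.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stop_bad("no such file: %s", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "mtx") {
    m <- tryCatch(Matrix::readMM(path),
                  error = function(e) stop_bad("malformed MTX '%s': %s",
                                               path, conditionMessage(e)))
    genes <- read_name_column(file.path(dirname(path), "genes.tsv"))
    cells <- read_name_column(file.path(dirname(path), "barcodes.tsv"))
    m <- as.matrix(m)
    if (nrow(m) != length(cells) || ncol(m) != length(genes))
      stop_bad("MTX is %d x %d but barcodes/genes list %d cells and %d genes",
               nrow(m), ncol(m), length(cells), length(genes))
    dimnames(m) <- list(cells, genes)
    storage.mode(m) <- "double"
    m
  } else if (ext == "tsv") {
    df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    if (!ncol(df) || names(df)[1] != "cell_id")
      stop_bad("dense TSV '%s' must have 'cell_id' as its first column", path)
    if (anyDuplicated(df$cell_id)) stop_bad("duplicate cell ids in %s", path)
    if (anyDuplicated(names(df)[-1])) stop_bad("duplicate gene names in %s", path)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df$cell_id
    storage.mode(m) <- "double"
    m
  } else stop_bad("unsupported extension '.%s' (use .mtx or .tsv)", ext)
}

read_name_column <- function(path) {
  if (!file.exists(path)) stop_bad("missing companion file: %s", path)
  nm <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)[[1]]
  if (anyDuplicated(nm)) stop_bad("duplicate names in %s", path)
  nm
}

#' Write an expression matrix
#'
#' Inverse of [read_expression()]: `.mtx` writes a 1-based Matrix Market
#' triplet plus `genes.tsv`/`barcodes.tsv`; `.tsv` writes a dense
#' tab-separated table with a `cell_id` first column.
#'
#' @param matrix Cells x genes matrix with dimnames.
#' @param path Destination `.mtx` or `.tsv` path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(matrix, path) {
  if (!is.matrix(matrix) || is.null(rownames(matrix)) || is.null(colnames(matrix)))
    stop_bad("'matrix' must be a cells x genes matrix with dimnames")
  if (anyDuplicated(rownames(matrix)) || anyDuplicated(colnames(matrix)))
    stop_bad("duplicate cell or gene names")
  ext <- tolower(tools::file_ext(path))
  if (ext == "mtx") {
    Matrix::writeMM(methods::as(methods::as(Matrix::Matrix(matrix, sparse = TRUE),
                                            "generalMatrix"), "CsparseMatrix"),
                    path)
    writeLines(colnames(matrix), file.path(dirname(path), "genes.tsv"))
    writeLines(rownames(matrix), file.path(dirname(path), "barcodes.tsv"))
  } else if (ext == "tsv") {
    df <- data.frame(cell_id = rownames(matrix), matrix,
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else stop_bad("unsupported extension '.%s' (use .mtx or .tsv)", ext)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' @param path GMT path (tab-separated: set name, description, genes...).
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop_bad("no such file: %s", path)
  fgsea::gmtPathways(path)
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of character gene vectors.
#' @param path Destination path.
#' @param description Second-column description (recycled).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, description = "avcycle") {
  if (!is.list(sets) || is.null(names(sets)) || any(!nzchar(names(sets))))
    stop_bad("'sets' must be a named list of gene vectors")
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, description, sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Run the full analysis end to end
#'
#' Orchestrates simulate -> gate -> signatures -> impute -> score ->
#' associate on synthetic data and writes every artefact to `out_dir`:
#' `matrix.mtx`/`genes.tsv`/`barcodes.tsv` and `truth.tsv` (single cells),
#' `bulk_counts.tsv`/`bulk_samples.tsv`, `labels.tsv`, `fractions.tsv`,
#' `de_results.tsv`, `signatures.gmt`, `imputed.tsv`, `scores.tsv`,
#' `associations.json` and `manifest.json`. Every stage is seeded from the
#' global seed through [stage_seed()], so a rerun with the same config
#' reproduces identical file checksums.
#'
#' @param config A [sim_config()]; its `seed` is the global seed.
#' @param out_dir Output directory (created if missing).
#' @param t Diffusion steps for imputation (default 4).
#' @param q_threshold,lfc_threshold Signature extraction thresholds.
#' @param score_params A [module_score_params()].
#' @param write_imputed Write the dense imputed matrix (default FALSE; it is
#'   the largest artefact and recomputable).
#' @return The manifest, invisibly: config hash, seeds, file checksums,
#'   package version, per-stage timings, and the association table.
#' @export
run_end_to_end <- function(config = sim_config(), out_dir, t = 4L,
                           q_threshold = 0.05, lfc_threshold = 0.5,
                           score_params = module_score_params(seed = stage_seed(config$seed, "scoring")),
                           write_imputed = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  timings <- c()
  tic <- function() proc.time()[["elapsed"]]
  stage <- function(name, code) {
    t0 <- tic()
    res <- tryCatch(force(code), error = function(e) {
      writeLines(paste("FAILED at stage:", name), file.path(out_dir, "FAILED"))
      stop_bad("stage '%s' failed: %s", name, conditionMessage(e))
    })
    timings[[name]] <<- round(tic() - t0, 3)
    res
  }

  panel <- stage("panel", make_gene_panel(config))
  sc <- stage("simulate_single_cells", simulate_single_cells(config, panel))
  bulk <- stage("simulate_bulk", simulate_bulk_sorted(config, panel))

  stage("write_datasets", {
    write_expression(sc$counts, file.path(out_dir, "matrix.mtx"))
    utils::write.table(
      data.frame(cell_id = sc$cell_ids, av_position = sc$av_position,
                 state = sc$state, mcherry = sc$mcherry, mvenus = sc$mvenus),
      file.path(out_dir, "truth.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(gene = rownames(bulk$counts), bulk$counts, check.names = FALSE),
      file.path(out_dir, "bulk_counts.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(sample_id = colnames(bulk$counts), state = bulk$sample_state,
                 replicate = bulk$replicate),
      file.path(out_dir, "bulk_samples.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    write_gmt(list(ARTERIAL = panel$arterial, VENOUS = panel$venous,
                   TGF_SIGNALING = panel$tgf, BMP_SIGNALING = panel$bmp),
              file.path(out_dir, "panels.gmt"))
  })

  labels <- stage("gate", {
    thr <- auto_thresholds(
      sc$mcherry[sc$state == "NEGATIVE"], sc$mvenus[sc$state == "NEGATIVE"])
    lab <- assign_fucci_state(sc$mcherry, sc$mvenus, thr)
    utils::write.table(data.frame(cell_id = sc$cell_ids, label = lab),
                       file.path(out_dir, "labels.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      state_fractions(lab, ifelse(sc$av_position >= 0, "arterial_side", "venous_side")),
      file.path(out_dir, "fractions.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    lab
  })

  signatures <- stage("signatures", {
    de <- de_one_way(normalize_cpm_log(bulk), bulk$sample_state)
    utils::write.table(de, file.path(out_dir, "de_results.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    sig <- extract_state_signatures(de, q_threshold, lfc_threshold)
    write_gmt(list(FUCCI_NEGATIVE = sig$genes_negative,
                   FUCCI_RED_G1 = sig$genes_red,
                   FUCCI_GREEN_SG2M = sig$genes_green),
              file.path(out_dir, "signatures.gmt"))
    sig
  })

  lognorm <- stage("lognorm", lognorm_cells(sc))
  imputed <- stage("impute", {
    expressed <- colSums(sc$counts) > 0
    op <- build_operator(lognorm[, expressed, drop = FALSE], t = t)
    imp <- impute(lognorm[, expressed, drop = FALSE], op)
    if (write_imputed) write_expression(imp, file.path(out_dir, "imputed.tsv"))
    imp
  })

  scores <- stage("score", {
    sc_scores <- score_cells(lognorm, imputed, signatures,
                             arterial_genes = panel$arterial,
                             venous_genes = panel$venous,
                             params = score_params)
    utils::write.table(cbind(cell_id = sc$cell_ids, sc_scores),
                       file.path(out_dir, "scores.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    sc_scores
  })

  associations <- stage("associate", {
    assoc <- associate_scores(scores, x = "relative_g1",
                              y = c("arterial_score", "venous_score",
                                    "tgf_score", "bmp_score"))
    jsonlite::write_json(assoc, file.path(out_dir, "associations.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
    assoc
  })

  files <- c("matrix.mtx", "genes.tsv", "barcodes.tsv", "truth.tsv",
             "bulk_counts.tsv", "bulk_samples.tsv", "panels.gmt", "labels.tsv",
             "fractions.tsv", "de_results.tsv", "signatures.gmt", "scores.tsv",
             "associations.json")
  checksums <- tools::md5sum(file.path(out_dir, files))
  names(checksums) <- files
  manifest <- list(
    config_hash = unname(tools::md5sum(local({
      f <- tempfile(); dput(unclass(config), f); f
    }))),
    global_seed = config$seed,
    stage_seeds = vapply(c("single_cells", "bulk_sorted", "scoring"),
                         function(tg) stage_seed(config$seed, tg), integer(1)),
    package_version = as.character(utils::packageVersion("avcycle")),
    timings_sec = as.list(timings),
    checksums = as.list(checksums),
    associations = associations)
  json <- jsonlite::toJSON(manifest[setdiff(names(manifest), "timings_sec")],
                           auto_unbox = TRUE, digits = NA, dataframe = "rows")
  writeLines(json, file.path(out_dir, "manifest.json"))
  invisible(manifest)
}

#' In-memory pipeline: simulate, derive signatures, score, associate
#'
#' The computational core of [run_end_to_end()] without any file I/O:
#' simulates single-cell and bulk data from `config`, derives state
#' signatures from the bulk arm, computes all per-cell scores (imputing with
#' `t` diffusion steps for the arterial/venous scores), and regresses each
#' response score on the relative G1 score.
#'
#' @param config A [sim_config()].
#' @param t Diffusion steps (default 4).
#' @param q_threshold,lfc_threshold Signature thresholds.
#' @return A list: `scores` (per-cell score table), `signatures`,
#'   `associations` (the regression table from [associate_scores()]), and the
#'   simulated `sc` dataset.
#' @export
pipeline_associations <- function(config, t = 4L, q_threshold = 0.05,
                                  lfc_threshold = 0.5) {
  panel <- make_gene_panel(config)
  sc <- simulate_single_cells(config, panel)
  bulk <- simulate_bulk_sorted(config, panel)
  sig <- extract_state_signatures(de_one_way(normalize_cpm_log(bulk),
                                             bulk$sample_state),
                                  q_threshold, lfc_threshold)
  lognorm <- lognorm_cells(sc)
  expressed <- colSums(sc$counts) > 0
  op <- build_operator(lognorm[, expressed, drop = FALSE], t = t)
  imputed <- impute(lognorm[, expressed, drop = FALSE], op)
  scores <- score_cells(lognorm, imputed, sig,
                        arterial_genes = panel$arterial,
                        venous_genes = panel$venous,
                        params = module_score_params(seed = stage_seed(config$seed, "scoring")))
  assoc <- associate_scores(scores, x = "relative_g1",
                            y = c("arterial_score", "venous_score",
                                  "tgf_score", "bmp_score"))
  list(scores = scores, signatures = sig, associations = assoc, sc = sc)
}

#' Regress scores against a predictor score
#'
#' Runs [ols_simple()] of each response score on the predictor, optionally on
#' a cell subset (e.g. specified clusters only).
#'
#' @param scores Data.frame from [score_cells()] (or any frame holding the
#'   named columns).
#' @param x Predictor column name (default `"relative_g1"`).
#' @param y Response column names.
#' @param subset Optional logical/integer cell filter.
#' @return A data.frame: one row per response with `x`, `y`, `slope`,
#'   `intercept`, `r_squared`, `p_value`, `n`.
#' @export
associate_scores <- function(scores, x = "relative_g1",
                             y = c("arterial_score", "venous_score"),
                             subset = NULL) {
  miss <- setdiff(c(x, y), names(scores))
  if (length(miss))
    stop_bad("column(s) not in the score table: %s", paste(miss, collapse = ", "))
  if (!is.null(subset)) scores <- scores[subset, , drop = FALSE]
  do.call(rbind, lapply(y, function(v) {
    fit <- ols_simple(scores[[x]], scores[[v]])
    data.frame(x = x, y = v, slope = fit$slope, intercept = fit$intercept,
               r_squared = fit$r_squared, p_value = fit$p_value, n = fit$n,
               stringsAsFactors = FALSE)
  }))
}
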