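#' Log2 counts-per-million normalization
#'
#' Converts a genes x samples count matrix (or a `bulk_dataset`) to
#' `log2(1 + 1e6 * count / library_size)`. A zero count maps to exactly 0 and
#' scaling all counts of a sample leaves its values unchanged.
#'
#' @param counts A nonnegative genes x samples matrix, or a
#'   [simulate_bulk_sorted()] result.
#' @return A list of class `"normalized_matrix"`: `values` (genes x samples,
#'   log2-CPM) and `library_sizes`.
#' @examples
#' m <- matrix(c(0, 10, 90, 0, 50, 50), nrow = 3,
#'             dimnames = list(paste0("g", 1:3), c("s1", "s2")))
#' normalize_cpm_log(m)$values
#' @export
normalize_cpm_log <- function(counts) {
  if (inherits(counts, "bulk_dataset")) counts <- counts$counts
  if (!is.matrix(counts) || any(!is.finite(counts)) || any(counts < 0))
    stop_bad("'counts' must be a finite nonnegative genes x samples matrix")
  libs <- colSums(counts)
  bad <- which(libs <= 0)
  if (length(bad))
    stop_bad("sample(s) with zero total counts: %s",
             paste(colnames(counts)[bad] %||% bad, collapse = ", "))
  values <- log2(1 + sweep(counts, 2L, libs, "/") * 1e6)
  structure(list(values = values, library_sizes = libs),
            class = "normalized_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-gene one-way ANOVA across FUCCI states
#'
#' Tests each gene for differential expression across the three FUCCI states
#' with a fixed-effects one-way ANOVA on log2-CPM values, and reports per-state
#' means, the log2 fold-change of every state against the mean of the other
#' two, F, p, and Benjamini-Hochberg q-values over all tested genes. Genes with
#' zero total variance get F = 0, p = 1; genes separated with zero
#' within-group variance get p = 0.
#'
#' @param norm A [normalize_cpm_log()] result (or a genes x samples matrix of
#'   log2-CPM values).
#' @param states FUCCI state label per sample; all three states must be
#'   present with at least two replicates each.
#' @return A data.frame of class `"de_result"` with columns `gene`,
#'   `mean_negative`, `mean_red`, `mean_green`, `lfc_negative`, `lfc_red`,
#'   `lfc_green`, `F`, `p`, `q`.
#' @export
de_one_way <- function(norm, states) {
  x <- if (inherits(norm, "normalized_matrix")) norm$values else norm
  if (!is.matrix(x) || any(!is.finite(x)))
    stop_bad("'norm' must be a finite genes x samples matrix")
  states <- factor(states, levels = fucci_states())
  if (length(states) != ncol(x))
    stop_bad("'states' must have one label per sample")
  if (anyNA(states))
    stop_bad("'states' must use labels %s", paste(fucci_states(), collapse = "/"))
  cnt <- table(states)
  if (any(cnt < 2))
    stop_bad("every state needs >= 2 replicates, got %s",
             paste(sprintf("%s=%d", names(cnt), cnt), collapse = ", "))

  n <- ncol(x)
  k <- 3L
  means <- sapply(fucci_states(), function(s)
    rowMeans(x[, states == s, drop = FALSE]))
  grand <- rowMeans(x)
  ssb <- as.vector(means^2 %*% as.numeric(cnt)) - n * grand^2
  sst <- rowSums(x^2) - n * grand^2
  ssw <- pmax(sst - ssb, 0)
  ssb <- pmax(ssb, 0)

  Fstat <- (ssb / (k - 1)) / (ssw / (n - k))
  p <- stats::pf(Fstat, k - 1, n - k, lower.tail = FALSE)
  # degenerate cases: no variance at all -> null; separation with zero
  # within-group variance -> limiting p of 0
  tol <- 1e-12 * pmax(rowSums(x^2), 1)
  flat <- sst <= tol
  sep <- !flat & ssw <= tol
  Fstat[flat] <- 0; p[flat] <- 1
  Fstat[sep] <- Inf; p[sep] <- 0

  out <- data.frame(
    gene = rownames(x) %||% sprintf("gene_%d", seq_len(nrow(x))),
    mean_negative = means[, "NEGATIVE"],
    mean_red = means[, "RED_G1"],
    mean_green = means[, "GREEN_SG2M"],
    lfc_negative = means[, "NEGATIVE"] - (means[, "RED_G1"] + means[, "GREEN_SG2M"]) / 2,
    lfc_red = means[, "RED_G1"] - (means[, "NEGATIVE"] + means[, "GREEN_SG2M"]) / 2,
    lfc_green = means[, "GREEN_SG2M"] - (means[, "NEGATIVE"] + means[, "RED_G1"]) / 2,
    F = Fstat, p = p,
    row.names = NULL, stringsAsFactors = FALSE)
  out$q <- bh_adjust(out$p)
  class(out) <- c("de_result", "data.frame")
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment:
#' `q_(i) = min_(j >= i) p_(j) * m / j`, capped at 1, returned in the input
#' order.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return q-values, same length and order as the input.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
bh_adjust <- function(pvalues) {
  if (!is.numeric(pvalues) || anyNA(pvalues) ||
      any(pvalues < 0) || any(pvalues > 1))
    stop_bad("p-values must be numbers in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Extract per-state upregulated gene signatures
#'
#' A gene joins the signature of the state where it is most highly expressed
#' if (i) its q-value is below `q_threshold`, (ii) that state's mean log2-CPM
#' is the strict maximum over the three states, and (iii) its log2 fold-change
#' against the mean of the other two states is at least `lfc_threshold`.
#' Assignment to the argmax state makes the three lists disjoint by
#' construction.
#'
#' @param de A [de_one_way()] result.
#' @param q_threshold FDR threshold (default 0.05).
#' @param lfc_threshold Minimum log2 fold-change vs the other states (0.5).
#' @return A list of class `"signature_set"`: `genes_negative`, `genes_red`,
#'   `genes_green`, plus the thresholds and a `source` description.
#' @export
extract_state_signatures <- function(de, q_threshold = 0.05, lfc_threshold = 0.5) {
  stopifnot(inherits(de, "de_result"))
  if (!nrow(de)) stop_bad("'de' has no genes")
  means <- as.matrix(de[, c("mean_negative", "mean_red", "mean_green")])
  lfc <- as.matrix(de[, c("lfc_negative", "lfc_red", "lfc_green")])
  top <- max.col(means, ties.method = "first")
  strict <- means[cbind(seq_len(nrow(de)), top)] >
    apply(means, 1L, function(r) max(r[-which.max(r)]))
  pass <- de$q < q_threshold & strict &
    lfc[cbind(seq_len(nrow(de)), top)] >= lfc_threshold
  pick <- function(s) de$gene[pass & top == s]
  sig <- structure(list(genes_negative = pick(1L),
                        genes_red = pick(2L),
                        genes_green = pick(3L),
                        q_threshold = q_threshold,
                        lfc_threshold = lfc_threshold,
                        source = "one-way ANOVA on log2-CPM, BH-adjusted"),
                   class = "signature_set")
  if (any(lengths(sig[1:3]) == 0))
    warning("empty signature list(s): ",
            paste(names(sig)[1:3][lengths(sig[1:3]) == 0], collapse = ", "))
  sig
}

#' @export
print.signature_set <- function(x, ...) {
  cat(sprintf("signature_set (q < %g, lfc >= %g): NEGATIVE %d | RED_G1 %d | GREEN_SG2M %d genes\n",
              x$q_threshold, x$lfc_threshold, length(x$genes_negative),
              length(x$genes_red), length(x$genes_green)))
  invisible(x)
}
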