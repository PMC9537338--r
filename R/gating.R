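#' FUCCI gating thresholds
#'
#' A pair of channel thresholds plus a policy for mCherry+/mVenus+ double
#' positives (the G1/S overlap of FUCCI reporters). `AS_GREEN` (default)
#' assigns them to S/G2/M because Geminin presence marks S-phase entry;
#' `SEPARATE` keeps them as their own `DOUBLE_POSITIVE` class; `EXCLUDE`
#' drops them (label `NA`).
#'
#' @param tau_red mCherry intensity threshold (> 0).
#' @param tau_green mVenus intensity threshold (> 0).
#' @param double_positive_policy One of `"AS_GREEN"`, `"SEPARATE"`, `"EXCLUDE"`.
#' @return A list of class `"gating_thresholds"`.
#' @export
gating_thresholds <- function(tau_red, tau_green,
                              double_positive_policy = c("AS_GREEN", "SEPARATE", "EXCLUDE")) {
  double_positive_policy <- match.arg(double_positive_policy)
  if (!is_number(tau_red) || tau_red <= 0) stop_bad("'tau_red' must be > 0")
  if (!is_number(tau_green) || tau_green <= 0) stop_bad("'tau_green' must be > 0")
  structure(list(tau_red = tau_red, tau_green = tau_green,
                 double_positive_policy = double_positive_policy),
            class = "gating_thresholds")
}

#' Assign FUCCI cell-cycle states from reporter intensities
#'
#' Implements the two-channel gate: mCherry-/mVenus- cells are FUCCI-Negative
#' (early G1), mCherry+/mVenus- are FUCCI-Red G1 (late G1), mCherry-/mVenus+
#' are FUCCI-Green S/G2/M; double positives follow the thresholds' policy.
#' A channel is "+" when its intensity is at or above its threshold.
#'
#' @param mcherry,mvenus Nonnegative intensity vectors of equal length.
#' @param thresholds A [gating_thresholds()].
#' @return A factor with levels `NEGATIVE`, `RED_G1`, `GREEN_SG2M`,
#'   `DOUBLE_POSITIVE` (the last only populated under the `SEPARATE` policy;
#'   `EXCLUDE` yields `NA` for double positives).
#' @examples
#' assign_fucci_state(c(2, 50, 2), c(2, 2, 50), gating_thresholds(10, 10))
#' @export
assign_fucci_state <- function(mcherry, mvenus, thresholds) {
  stopifnot(inherits(thresholds, "gating_thresholds"))
  if (length(mcherry) != length(mvenus))
    stop_bad("'mcherry' and 'mvenus' must have equal length")
  if (any(!is.finite(mcherry)) || any(!is.finite(mvenus)) ||
      any(mcherry < 0) || any(mvenus < 0))
    stop_bad("intensities must be finite and >= 0")
  red <- mcherry >= thresholds$tau_red
  grn <- mvenus >= thresholds$tau_green
  lab <- ifelse(!red & !grn, "NEGATIVE",
         ifelse(red & !grn, "RED_G1",
         ifelse(!red & grn, "GREEN_SG2M",
                switch(thresholds$double_positive_policy,
                       AS_GREEN = "GREEN_SG2M",
                       SEPARATE = "DOUBLE_POSITIVE",
                       EXCLUDE = NA_character_))))
  factor(lab, levels = c(fucci_states(), "DOUBLE_POSITIVE"))
}

#' Derive gating thresholds from a reporter-negative control
#'
#' Sets each channel's threshold to an empirical quantile of its
#' reporter-negative control intensities, using the deterministic nearest-rank
#' definition: the `ceiling(q * n)`-th order statistic (the minimum at
#' `q = 0`).
#'
#' @param negative_control_mcherry,negative_control_mvenus Nonempty control
#'   intensity vectors.
#' @param quantile Quantile in `[0, 1]`, default 0.99.
#' @param double_positive_policy Passed to [gating_thresholds()].
#' @return A [gating_thresholds()].
#' @examples
#' auto_thresholds(1:100, 1:100)$tau_red  # 99
#' @export
auto_thresholds <- function(negative_control_mcherry, negative_control_mvenus,
                            quantile = 0.99,
                            double_positive_policy = "AS_GREEN") {
  if (!length(negative_control_mcherry) || !length(negative_control_mvenus))
    stop_bad("control samples must be non-empty")
  if (!is_number(quantile) || quantile < 0 || quantile > 1)
    stop_bad("'quantile' must be in [0, 1]")
  nearest_rank <- function(x, q) {
    x <- sort(x)
    x[max(1L, ceiling(q * length(x)))]
  }
  gating_thresholds(nearest_rank(negative_control_mcherry, quantile),
                    nearest_rank(negative_control_mvenus, quantile),
                    double_positive_policy)
}

#' Per-group FUCCI state fractions
#'
#' Tabulates, within each group, the percentage of (non-excluded) cells in
#' each gated state. Percentages within a group sum to 100; raw counts are
#' reported alongside. Groups with no labelled cells are omitted with a
#' warning.
#'
#' @param labels Factor from [assign_fucci_state()] (NA = excluded).
#' @param groups Group identifier per cell (same length as `labels`); a single
#'   group is assumed when omitted.
#' @return A data.frame with columns `group`, `state`, `n`, `percent`.
#' @export
state_fractions <- function(labels, groups = rep("all", length(labels))) {
  if (length(labels) != length(groups))
    stop_bad("'labels' and 'groups' must have equal length")
  keep <- !is.na(labels)
  labels <- droplevels(factor(labels)[keep])
  groups_all <- factor(groups)
  groups <- groups_all[keep]
  empty <- levels(groups_all)[tabulate(groups, nbins = nlevels(groups_all)) == 0L]
  if (length(empty)) {
    warning("omitting empty group(s): ", paste(empty, collapse = ", "))
    groups <- droplevels(groups)
  }
  tab <- table(group = groups, state = labels)
  out <- as.data.frame(tab, responseName = "n", stringsAsFactors = FALSE)
  tot <- rowSums(tab)
  out$percent <- 100 * out$n / tot[out$group]
  out <- out[order(out$group, out$state), , drop = FALSE]
  rownames(out) <- NULL
  out
}
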