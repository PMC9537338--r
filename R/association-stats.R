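#' Simple linear regression
#'
#' Closed-form least squares of `y` on `x` with the usual two-sided t-test on
#' the slope (`n - 2` degrees of freedom).
#'
#' @param x,y Numeric vectors of equal length `n >= 3`; `x` must vary.
#' @return A list of class `"regression_result"`: `slope`, `intercept`,
#'   `r_squared`, `slope_se`, `t_statistic`, `p_value`, `n`.
#' @examples
#' ols_simple(0:2, c(0, 1, 2))$slope  # 1
#' @export
ols_simple <- function(x, y) {
  if (length(x) != length(y)) stop_bad("'x' and 'y' must have equal length")
  n <- length(x)
  if (n < 3) stop_bad("need n >= 3 observations, got %d", n)
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop_bad("'x' and 'y' must be finite")
  sxx <- sum((x - mean(x))^2)
  if (sxx <= 0) stop_bad("'x' has zero variance")
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  resid <- y - intercept - slope * x
  rss <- sum(resid^2)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - rss / tss else 1
  se <- sqrt(rss / (n - 2) / sxx)
  tstat <- if (se > 0) slope / se else sign(slope) * Inf
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  structure(list(slope = slope, intercept = intercept, r_squared = r2,
                 slope_se = se, t_statistic = tstat, p_value = p, n = n),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("slope %.4g (se %.3g), intercept %.4g, R^2 %.3f, t %.3g, p %.3g, n %d\n",
              x$slope, x$slope_se, x$intercept, x$r_squared, x$t_statistic,
              x$p_value, x$n))
  invisible(x)
}

#' One-way ANOVA with Tukey HSD post hoc comparisons
#'
#' Fixed-effects one-way ANOVA across groups followed by all-pairs Tukey
#' honestly-significant-difference tests using the studentized-range
#' distribution with pooled within-group variance; unequal group sizes use
#' the Tukey-Kramer standard error.
#'
#' @param groups List of numeric vectors, one per group (named or not), at
#'   least 2 groups with `n >= 2` each.
#' @param alpha Nominal level recorded on the result (default 0.05).
#' @return A list of class `"anova_tukey_result"`: `F`, `p`, `df`, `means`,
#'   `n`, and `tukey` (a data.frame with one row per unordered pair: `group1`,
#'   `group2`, `diff`, `q`, `p_adj`).
#' @export
anova_tukey <- function(groups, alpha = 0.05) {
  if (!is.list(groups) || length(groups) < 2)
    stop_bad("'groups' must be a list of >= 2 numeric vectors")
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    names(groups) <- sprintf("group%d", seq_along(groups))
  ns <- lengths(groups)
  if (any(ns < 2)) stop_bad("every group needs n >= 2, got %s",
                            paste(ns, collapse = ", "))
  if (any(!vapply(groups, function(g) all(is.finite(g)), logical(1))))
    stop_bad("group values must be finite")
  k <- length(groups)
  N <- sum(ns)
  means <- vapply(groups, mean, numeric(1))
  grand <- sum(ns * means) / N
  ssb <- sum(ns * (means - grand)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  df1 <- k - 1; df2 <- N - k
  msw <- ssw / df2
  if (msw <= 0) {
    Fstat <- if (ssb > 0) Inf else 0
    p <- if (ssb > 0) 0 else 1
  } else {
    Fstat <- (ssb / df1) / msw
    p <- stats::pf(Fstat, df1, df2, lower.tail = FALSE)
  }

  pairs <- utils::combn(k, 2)
  tukey <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    d <- means[i2] - means[i1]
    se <- sqrt(msw / 2 * (1 / ns[i1] + 1 / ns[i2]))
    q <- if (se > 0) abs(d) / se else if (abs(d) > 0) Inf else 0
    p_adj <- if (is.infinite(q)) 0
             else stats::ptukey(q, nmeans = k, df = df2, lower.tail = FALSE)
    data.frame(group1 = names(groups)[i1], group2 = names(groups)[i2],
               diff = unname(d), q = unname(q), p_adj = unname(p_adj),
               stringsAsFactors = FALSE)
  }))
  structure(list(F = Fstat, p = p, df = c(df1, df2), means = means, n = ns,
                 alpha = alpha, tukey = tukey),
            class = "anova_tukey_result")
}

#' @export
print.anova_tukey_result <- function(x, ...) {
  cat(sprintf("one-way ANOVA: F(%d, %d) = %.4g, p = %.3g\n",
              x$df[1], x$df[2], x$F, x$p))
  print(x$tukey, row.names = FALSE)
  invisible(x)
}

#' Welch two-sample t-test
#'
#' Two-sided Welch statistic with Satterthwaite degrees of freedom. Samples
#' with zero variance get their variance floored at 1e-12 (with a warning)
#' rather than producing NaN.
#'
#' @param a,b Numeric vectors with `n >= 2` each.
#' @return A list with `t`, `df`, `p` (two-sided), and the group means.
#' @export
welch_t <- function(a, b) {
  if (length(a) < 2 || length(b) < 2)
    stop_bad("each sample needs n >= 2")
  if (any(!is.finite(a)) || any(!is.finite(b)))
    stop_bad("samples must be finite")
  va <- stats::var(a); vb <- stats::var(b)
  if (va <= 0 || vb <= 0) {
    warning("zero-variance sample; flooring variance at 1e-12")
    va <- max(va, 1e-12); vb <- max(vb, 1e-12)
  }
  na <- length(a); nb <- length(b)
  se2 <- va / na + vb / nb
  tstat <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(abs(tstat), df = df, lower.tail = FALSE)
  list(t = tstat, df = df, p = p, mean_a = mean(a), mean_b = mean(b))
}

#' Delta-delta-Ct fold change
#'
#' Relative qPCR quantification: `ddCt = (Ct_target,treated - Ct_ref,treated)
#' - (Ct_target,control - Ct_ref,control)`; fold change `2^(-ddCt)`.
#'
#' @param ct_target_treated,ct_ref_treated,ct_target_control,ct_ref_control
#'   Finite cycle-threshold values (vectorized).
#' @return Fold change(s) relative to the control condition.
#' @examples
#' ddct_fold_change(20, 18, 22, 18)  # 4
#' @export
ddct_fold_change <- function(ct_target_treated, ct_ref_treated,
                             ct_target_control, ct_ref_control) {
  vals <- c(ct_target_treated, ct_ref_treated, ct_target_control, ct_ref_control)
  if (any(!is.finite(vals))) stop_bad("Ct values must be finite")
  ddct <- (ct_target_treated - ct_ref_treated) -
    (ct_target_control - ct_ref_control)
  2^(-ddct)
}

#' Nuclear localization percentage
#'
#' `100 * sum(image[nuclear_mask]) / sum(image[vessel_mask])`: the fraction of
#' a vessel's fluorescent intensity that falls inside nuclei.
#'
#' @param image Nonnegative 2-D intensity matrix (or a
#'   [simulate_nuclear_image()] result, in which case masks default to its
#'   own).
#' @param nuclear_mask,vessel_mask Logical matrices of the image's shape with
#'   `nuclear_mask` contained in `vessel_mask`.
#' @return Percentage in `[0, 100]`.
#' @export
nuclear_localization <- function(image, nuclear_mask = NULL, vessel_mask = NULL) {
  if (inherits(image, "nuclear_image")) {
    nuclear_mask <- nuclear_mask %||% image$nuclear_mask
    vessel_mask <- vessel_mask %||% image$vessel_mask
    image <- image$image
  }
  if (!is.matrix(image) || any(!is.finite(image)) || any(image < 0))
    stop_bad("'image' must be a finite nonnegative matrix")
  if (!identical(dim(image), dim(nuclear_mask)) ||
      !identical(dim(image), dim(vessel_mask)))
    stop_bad("mask shapes must equal the image shape")
  if (any(nuclear_mask & !vessel_mask))
    stop_bad("nuclear mask must be contained in the vessel mask")
  vtot <- sum(image[vessel_mask])
  if (vtot <= 0) stop_bad("total vessel intensity must be > 0")
  100 * sum(image[nuclear_mask]) / vtot
}
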