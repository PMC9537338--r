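#' Construct a diffusion operator from raw pieces
#'
#' Low-level constructor validating a row-stochastic Markov matrix; mostly
#' useful for worked examples and tests. Use [build_operator()] to derive an
#' operator from expression data.
#'
#' @param markov Row-stochastic square matrix (rows sum to 1 within 1e-9,
#'   entries >= 0).
#' @param t Number of diffusion steps (nonnegative integer, default 4).
#' @param k,ka,embedding_dims Optional metadata on how the kernel was built.
#' @return A list of class `"diffusion_operator"`.
#' @export
diffusion_operator <- function(markov, t = 4L, k = NA_integer_,
                               ka = NA_integer_, embedding_dims = NA_integer_) {
  if (!is.matrix(markov) || nrow(markov) != ncol(markov) ||
      any(!is.finite(markov)) || any(markov < 0))
    stop_bad("'markov' must be a square nonnegative matrix")
  if (any(abs(rowSums(markov) - 1) > 1e-9))
    stop_bad("'markov' rows must sum to 1 within 1e-9")
  if (!is_number(t) || t < 0 || t != round(t))
    stop_bad("'t' must be a nonnegative integer")
  structure(list(markov = markov, t = as.integer(t), k = k, ka = ka,
                 embedding_dims = embedding_dims),
            class = "diffusion_operator")
}

# PC scores of the top `d` components of a cells x genes matrix, via the
# eigendecomposition of the centered Gram matrix (cheap when cells << genes)
pc_scores <- function(x, d) {
  xc <- sweep(x, 2L, colMeans(x))
  d <- min(d, nrow(x) - 1L, ncol(x))
  if (d < 1L) return(xc)
  eg <- eigen(tcrossprod(xc), symmetric = TRUE)
  ev <- pmax(eg$values[seq_len(d)], 0)
  eg$vectors[, seq_len(d), drop = FALSE] %*% diag(sqrt(ev), d)
}

#' Build a kNN adaptive-Gaussian Markov diffusion operator
#'
#' Computes cell-cell distances in a truncated principal-component embedding
#' of the log-normalized expression matrix, forms the adaptive Gaussian
#' affinity `A_ij = exp(-(d_ij / sigma_i)^2)` over each cell's `k` nearest
#' neighbours (self included) with bandwidth `sigma_i` equal to the distance
#' to the `ka`-th neighbour, symmetrizes `A <- (A + t(A)) / 2`, and
#' row-normalizes to a Markov matrix. Powering this operator smooths
#' expression along the phenotypic manifold (MAGIC-style imputation).
#'
#' @param expr_lognorm Cells x genes matrix of log-normalized expression.
#' @param k Neighbours per cell (default 15; must exceed `ka`).
#' @param ka Index of the adaptive-bandwidth neighbour (default 4).
#' @param embedding_dims Principal components used for distances (default 20).
#' @param t Diffusion steps stored on the operator (default 4).
#' @return A [diffusion_operator()].
#' @export
build_operator <- function(expr_lognorm, k = 15L, ka = 4L,
                           embedding_dims = 20L, t = 4L) {
  if (!is.matrix(expr_lognorm) || any(!is.finite(expr_lognorm)))
    stop_bad("'expr_lognorm' must be a finite cells x genes matrix")
  n <- nrow(expr_lognorm)
  if (k <= ka) stop_bad("'k' (%d) must be greater than 'ka' (%d)", k, ka)
  if (n <= k) stop_bad("need more cells (%d) than neighbours k = %d", n, k)

  dmat <- as.matrix(stats::dist(pc_scores(expr_lognorm, embedding_dims)))
  # neighbour distances exclude self; sigma_i = distance to ka-th neighbour
  ord <- apply(dmat, 1L, function(r) order(r)[seq_len(k + 1L)])  # (k+1) x n, incl self
  sigma <- vapply(seq_len(n), function(i) sort(dmat[i, -i])[ka], numeric(1))
  zero_sigma <- sigma <= 0
  if (any(zero_sigma)) {
    warning("duplicate cells give zero adaptive bandwidth for ",
            sum(zero_sigma), " cell(s); flooring sigma")
    floor_val <- max(.Machine$double.eps, min(sigma[!zero_sigma], 1) * 1e-8)
    sigma[zero_sigma] <- floor_val
  }
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    nb <- ord[, i]
    A[i, nb] <- exp(-(dmat[i, nb] / sigma[i])^2)
  }
  A <- (A + t(A)) / 2
  M <- A / rowSums(A)
  diffusion_operator(M, t = t, k = as.integer(k), ka = as.integer(ka),
                     embedding_dims = as.integer(embedding_dims))
}

#' Diffusion-impute an expression matrix
#'
#' Returns `M^t %*% expr` for the operator's Markov matrix `M`: each imputed
#' value is a convex combination of the gene's values over the cell's
#' diffusion neighbourhood, so per-gene values stay within the observed range
#' and constant genes are preserved exactly. `t = 0` returns the input
#' unchanged.
#'
#' @param expr Cells x genes matrix (same cells as the operator).
#' @param op A [diffusion_operator()] or [build_operator()] result.
#' @param t Diffusion steps; defaults to the operator's own `t`.
#' @return The imputed cells x genes matrix (dimnames preserved).
#' @examples
#' M <- rbind(c(.5, .5, 0), c(.25, .5, .25), c(0, .5, .5))
#' op <- diffusion_operator(M, t = 1)
#' impute(cbind(x = c(0, 0, 4)), op)  # (0, 1, 2)
#' @export
impute <- function(expr, op, t = op$t) {
  stopifnot(inherits(op, "diffusion_operator"))
  if (is.vector(expr)) expr <- cbind(expr)
  if (!is.matrix(expr) || any(!is.finite(expr)))
    stop_bad("'expr' must be a finite cells x genes matrix")
  if (nrow(expr) != nrow(op$markov))
    stop_bad("operator is for %d cells but 'expr' has %d rows",
             nrow(op$markov), nrow(expr))
  if (!is_number(t) || t < 0 || t != round(t))
    stop_bad("'t' must be a nonnegative integer")
  if (t == 0) return(expr)
  out <- expr
  for (s in seq_len(t)) out <- op$markov %*% out
  dimnames(out) <- dimnames(expr)
  out
}
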