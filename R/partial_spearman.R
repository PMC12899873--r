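#' Partial Spearman correlation
#'
#' Rank-based partial correlation between two intake vectors, adjusted for a
#' set of covariates (typically total energy intake and sex). All variables
#' are rank-transformed (average ranks for ties), the ranked `x` and `y` are
#' residualized on the ranked covariates plus an intercept by least squares,
#' and the Pearson correlation of the residuals is returned together with a
#' two-sided p-value from the t reference distribution with
#' `df = n - 2 - k` where `k` is the number of covariates.
#'
#' @param x,y Numeric vectors of equal length.
#' @param covariates Optional numeric matrix or data frame of covariates
#'   (same number of rows as `length(x)`). `NULL` gives the plain Spearman
#'   rank correlation.
#' @return A tibble with columns `r`, `p`, `df`, `n`.
#' @examples
#' partial_spearman(1:5, c(2, 4, 6, 8, 10))
#' @export
partial_spearman <- function(x, y, covariates = NULL) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) != length(y)) {
    stop_dccn("`x` and `y` must have equal length.", "dccn_length_error")
  }
  cov_mat <- prepare_covariates(covariates, length(x))
  k <- ncol(cov_mat)
  n <- length(x)
  if (n < k + 4) {
    stop_dccn(
      sprintf("Need at least %d observations for %d covariates; got %d.",
              k + 4, k, n),
      "dccn_length_error"
    )
  }
  rx <- rank(x)
  ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0) {
    stop_dccn(
      "Degenerate input: zero variance after ranking (constant vector).",
      "dccn_degenerate_error"
    )
  }
  design <- matrix(1, n, 1)
  if (k > 0) design <- cbind(design, apply(cov_mat, 2, rank))
  qr_d <- qr(design)
  res_x <- qr.resid(qr_d, rx)
  res_y <- qr.resid(qr_d, ry)
  # tolerance absorbs QR round-off on exactly collinear columns
  if (sd(res_x) < n * 1e-10 || sd(res_y) < n * 1e-10) {
    stop_dccn(
      "Degenerate input: ranks are fully explained by the covariates.",
      "dccn_degenerate_error"
    )
  }
  r <- cor(res_x, res_y)
  df <- n - 2 - k
  tibble::tibble(r = r, p = r_to_p(r, df), df = df, n = n)
}

prepare_covariates <- function(covariates, n) {
  if (is.null(covariates)) {
    return(matrix(numeric(0), nrow = n, ncol = 0))
  }
  cov_mat <- as.matrix(as.data.frame(covariates))
  storage.mode(cov_mat) <- "double"
  if (nrow(cov_mat) != n) {
    stop_dccn("Covariates must have one row per observation.",
              "dccn_length_error")
  }
  cov_mat
}

# Two-sided p from the t reference for a (partial rank) correlation.
r_to_p <- function(r, df) {
  r <- pmin(pmax(r, -1), 1)
  tstat <- abs(r) * sqrt(df / pmax(1 - r^2, .Machine$double.eps))
  2 * pt(tstat, df = df, lower.tail = FALSE)
}

# Partial Spearman correlation matrix of all columns of `mat`, adjusted for
# `covariates`, on the rows `idx`. One rank + QR + cor per call, shared by
# every food pair: identical to calling partial_spearman() pairwise on the
# same rows, but with a single regression instead of one per pair.
partial_spearman_matrix <- function(mat, covariates, idx = seq_len(nrow(mat))) {
  sub <- mat[idx, , drop = FALSE]
  m <- nrow(sub)
  cov_sub <- covariates[idx, , drop = FALSE]
  k <- ncol(cov_sub)
  ranked <- apply(sub, 2, rank)
  design <- matrix(1, m, 1)
  if (k > 0) design <- cbind(design, apply(cov_sub, 2, rank))
  resid <- qr.resid(qr(design), ranked)
  sds <- apply(resid, 2, sd)
  degenerate <- sds < m * 1e-10
  if (any(degenerate)) {
    # constant foods stay in the matrix with NA correlations (kept as isolates)
    resid[, degenerate] <- NA_real_
  }
  r <- suppressWarnings(cor(resid))
  diag(r) <- 1
  list(r = r, df = m - 2 - k, degenerate = degenerate)
}
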