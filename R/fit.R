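# Per-group least-squares deconvolution.
#
# Model, per gene j within one study group:
#   y_j = X beta_j + eps,   eps ~ N(0, sigma^2 I)
# with y_j the bulk expression across the group's M samples and X the M x P
# matrix of measured cell proportions. There is no intercept: zero cell
# content implies zero bulk signal. The coefficient estimates betahat_kj are
# the cell type-specific expression estimates.

#' Fit cell type-specific expression for one study group
#'
#' Solves the no-intercept least-squares problem `y_j ~ X` for every gene of
#' one group, sharing a single QR factorisation of `X` across genes. The
#' residual variance estimate is `s2 = RSS / (M - P)` and the coefficient
#' covariance is `s2 * (X'X)^{-1}`, whose diagonal gives the per-cell
#' variance of the expression estimates. `(X'X)^{-1}` is materialised once
#' per group because the covariance and the downstream Welch test need it;
#' the coefficient solve itself goes through the QR factorisation, which is
#' numerically preferable when the proportion matrix is ill-conditioned.
#'
#' @param Y numeric matrix, genes x samples (the group's bulk expression).
#' @param X numeric matrix, samples x cell types (the group's proportions).
#' @param group label stored with the fit, e.g. `"controls"`.
#' @return An object of class `lrcde_groupfit`: list with `betas`
#'   (genes x cells), `fitted`, `residuals` (genes x samples), `mse`
#'   (per-gene `s2`), `coef_var` (genes x cells, diagonal of the coefficient
#'   covariance), `xtx_inv`, `m_samples`, `p_cells`, `df = M - P`, and the
#'   [condition_number()] report of `X`.
#' @examples
#' X <- cbind(a = c(0.7, 0.6, 0.5, 0.4), b = c(0.3, 0.4, 0.5, 0.6))
#' Y <- rbind(g1 = c(1, 2, 3, 4))
#' fit <- fit_cell_type_expression(Y, X)
#' fit$betas
#' @export
fit_cell_type_expression <- function(Y, X, group = "controls") {
  stopifnot_numeric_matrix(Y, "expression")
  stopifnot_numeric_matrix(X, "proportions")
  M <- ncol(Y)
  P <- ncol(X)
  if (nrow(X) != M)
    stop("expression has ", M, " samples but proportions have ", nrow(X))
  if (M <= P)
    stop("insufficient degrees of freedom: M = ", M, " samples, P = ", P,
         " cell types; need M > P")
  cond <- condition_number(X)
  if (cond$singular)
    stop("proportion matrix is singular or numerically near-singular ",
         "(condition number ", format(cond$cd, digits = 4), "); ",
         "a least-squares solution cannot be obtained")
  qx <- qr(X)
  betas <- t(qr.coef(qx, t(Y)))              # genes x cells
  fitted <- betas %*% t(X)                   # genes x samples
  resid <- Y - fitted
  mse <- mse_per_gene(resid, M, P)
  xtx_inv <- chol2inv(chol(crossprod(X)))
  dimnames(xtx_inv) <- list(colnames(X), colnames(X))
  coef_var <- outer(mse, pmax(diag(xtx_inv), 0))
  dimnames(coef_var) <- dimnames(betas) <- list(rownames(Y), colnames(X))
  structure(list(group = group, betas = betas, fitted = fitted,
                 residuals = resid, mse = mse, coef_var = coef_var,
                 xtx_inv = xtx_inv, m_samples = M, p_cells = P,
                 df = M - P, condition = cond),
            class = "lrcde_groupfit")
}

#' @export
print.lrcde_groupfit <- function(x, ...) {
  cat("Group least-squares deconvolution fit (", x$group, ")\n", sep = "")
  cat("  genes:", nrow(x$betas), " cell types:", x$p_cells,
      " samples:", x$m_samples, " df:", x$df, "\n")
  cat("  condition number of X'X:", format(x$condition$cd, digits = 4), "\n")
  invisible(x)
}

#' Per-gene mean squared error
#'
#' Residual sum of squares divided by the residual degrees of freedom
#' `M - P`; the unbiased estimate of the residual variance `sigma^2`.
#'
#' @param residuals numeric matrix genes x samples, or a vector for one gene.
#' @param M number of samples.
#' @param P number of fitted coefficients (cell types).
#' @return Numeric vector of per-gene MSE values.
#' @export
mse_per_gene <- function(residuals, M, P) {
  if (M <= P) stop("M must exceed P to estimate residual variance")
  if (is.null(dim(residuals))) residuals <- matrix(residuals, nrow = 1L)
  if (ncol(residuals) != M)
    stop("residual matrix has ", ncol(residuals), " columns, expected M = ", M)
  rowSums(residuals^2) / (M - P)
}

#' Coefficient covariance matrix for one gene
#'
#' The estimated covariance of the cell type-specific expression estimates:
#' `s2 * (X'X)^{-1}`, with the per-cell variances on the diagonal.
#'
#' @param mse_j the gene's residual variance estimate (scalar, `>= 0`).
#' @param xtx_inv the group's `(X'X)^{-1}` matrix.
#' @return A P x P covariance matrix.
#' @export
coef_covariance <- function(mse_j, xtx_inv) {
  if (length(mse_j) != 1L || mse_j < 0)
    stop("mse_j must be a single non-negative value")
  mse_j * xtx_inv
}
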