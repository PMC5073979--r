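# Condition diagnostics of the cell-proportion design matrix.
#
# Because complete cell proportions sum to 1 across cell types, the columns
# of X are strongly multicollinear and X'X can be near-singular. The
# condition number used throughout is the eigenvalue ratio of X'X (the
# square of the SVD-based condition number of X itself).

# Eigenvalue ratio below which X'X is treated as numerically singular,
# relative to machine epsilon.
.SINGULAR_RTOL <- 1e3 * .Machine$double.eps

# Condition numbers above this are flagged: coefficient estimates become
# unstable under small perturbations of the proportions.
.HIGH_CD <- 1000

#' Condition number of the squared proportion matrix
#'
#' Eigendecomposes the symmetric matrix `X'X` and reports the ratio of the
#' absolute values of its largest to smallest eigenvalues. A matrix is
#' flagged `singular` when the smallest eigenvalue magnitude falls below
#' `1e3 * .Machine$double.eps` times the largest (scale-free tolerance);
#' `high` when the condition number exceeds 1000, the regime in which cell
#' type-specific expression estimates become unreliable.
#'
#' @param X numeric matrix (samples x cell types), or an `lrcde_data`
#'   object whose proportions are used.
#' @return An object of class `condition_report`: list with `eigenvalues`
#'   (descending), `vectors` (matching eigenvectors of `X'X`), `cd`,
#'   `singular`, `high`.
#' @examples
#' condition_number(diag(2))$cd                     # orthonormal: 1
#' condition_number(diag(c(2, 1)))$cd               # X'X = diag(4, 1): 4
#' @export
condition_number <- function(X) {
  if (inherits(X, "lrcde_data")) X <- X$proportions
  stopifnot_numeric_matrix(X, "proportions")
  e <- eigen(crossprod(X), symmetric = TRUE)
  ev <- e$values
  amax <- max(abs(ev))
  amin <- min(abs(ev))
  cd <- if (amin == 0) Inf else amax / amin
  structure(list(eigenvalues = ev, vectors = e$vectors, cd = cd,
                 singular = amin <= .SINGULAR_RTOL * amax,
                 high = cd > .HIGH_CD),
            class = "condition_report")
}

#' @export
print.condition_report <- function(x, ...) {
  cat("Condition report of X'X\n")
  cat("  eigenvalues:", paste(format(x$eigenvalues, digits = 4),
                              collapse = " "), "\n")
  cat("  condition number:", format(x$cd, digits = 6),
      if (x$singular) "(singular)" else if (x$high) "(high, > 1000)" else "",
      "\n")
  invisible(x)
}

#' Is the proportion matrix numerically singular?
#'
#' A least-squares solution cannot be obtained when the predictor matrix is
#' singular; this is the gate used by [fit_cell_type_expression()].
#'
#' @inheritParams condition_number
#' @return `TRUE` iff `X'X` is numerically singular.
#' @export
singularity_check <- function(X) {
  condition_number(X)$singular
}

#' Drop the cell types with the lowest mean proportions
#'
#' Multicollinearity remedy: removes the `k` columns with the smallest means
#' (ties broken by input order, earliest column dropped first). Remaining
#' rows are deliberately not renormalised — the retained proportions are
#' kept as measured, so the retained coefficients keep their interpretation;
#' the result is flagged `reduced` and no longer sums to 1. Set
#' `renormalize = TRUE` to rescale rows back to sum 1 instead.
#'
#' @param X numeric proportion matrix, samples x cell types.
#' @param k number of cell types to drop, `0 <= k <= P - 2` (at least two
#'   predictors must remain).
#' @param renormalize rescale remaining rows to sum 1 (off by default).
#' @return A list with `proportions` (the reduced matrix) and `plan`, a list
#'   recording `dropped_cells` (ascending-mean order), `retained_mass`
#'   (mean retained row total before any renormalisation), `cd_before`,
#'   `cd_after`.
#' @export
drop_lowest_mean_cells <- function(X, k, renormalize = FALSE) {
  stopifnot_numeric_matrix(X, "proportions")
  P <- ncol(X)
  if (k < 0 || k > P - 2L)
    stop("k must be between 0 and P - 2 = ", P - 2L,
         " (at least two cell types must remain)")
  cd_before <- condition_number(X)$cd
  if (k == 0L) {
    plan <- list(dropped_cells = character(0L), retained_mass = 1,
                 cd_before = cd_before, cd_after = cd_before)
    return(list(proportions = X, plan = plan))
  }
  ord <- order(colMeans(X))            # stable: ties keep input order
  drop_idx <- ord[seq_len(k)]
  kept <- X[, -drop_idx, drop = FALSE]
  retained <- mean(rowSums(kept)) / mean(rowSums(X))
  if (renormalize) kept <- kept / rowSums(kept)
  attr(kept, "reduced") <- !renormalize
  plan <- list(dropped_cells = colnames(X)[drop_idx],
               retained_mass = retained,
               cd_before = cd_before,
               cd_after = condition_number(kept)$cd)
  list(proportions = kept, plan = plan)
}
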