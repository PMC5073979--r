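# Main model-fitting interface.

#' Cell type-specific differential expression by deconvolution
#'
#' Fits the two-group linear-regression deconvolution model: within each
#' group, bulk expression of every gene is regressed (no intercept) on the
#' measured cell proportions, yielding cell type-specific expression
#' estimates. The per-cell effect size is the difference of the case and
#' control estimates, tested gene-by-gene with a Welch t-test whose
#' variances come from the regression coefficient covariance — so genes
#' with precise estimates are judged on their own variability rather than a
#' global cutoff. Per-test detection power is computed from the observed
#' t-statistic ([detection_power()]).
#'
#' @param data an `lrcde_data` object from [align_study()], or a genes x
#'   samples expression matrix (then `proportions` and `groups` must be
#'   supplied and are passed through [align_study()]).
#' @param proportions,groups see [align_study()]; ignored when `data` is
#'   already an `lrcde_data`.
#' @param alpha two-sided significance level used for the power calculation
#'   and reported significance counts.
#' @param adjust multiple-testing adjustment across the full gene x cell
#'   table: `"bonferroni"` (default) or `"none"`.
#' @param transform optional `log2(x + 1)` transform of the expression
#'   matrix before fitting (`"none"` or `"log2p1"`).
#' @return An object of class `lrcde`: list with
#'   \describe{
#'     \item{table}{data frame, one row per gene x cell type: `gene`,
#'       `cell`, `beta_controls`, `beta_cases`, `delta`, `se_delta`, `t`,
#'       `df`, `p`, `p_adj`, `power`, `mse_controls`, `mse_cases`,
#'       `neg_beta`, `high_cd`.}
#'     \item{fits}{the two `lrcde_groupfit` objects.}
#'     \item{condition}{[condition_number()] report of the full proportion
#'       matrix.}
#'     \item{alpha, adjust, transform, data, call}{inputs as supplied.}
#'   }
#' @examples
#' sim <- assemble_study(sim_config(n_genes = 50, n_per_group = 10, seed = 7))
#' fit <- lrcde(sim$dataset)
#' head(fit$table)
#' @seealso [summary.lrcde()], [run_perm_fdr()] for the permutation-FDR
#'   comparator, [assemble_study()] for simulated input.
#' @export
lrcde <- function(data, proportions = NULL, groups = NULL, alpha = 0.05,
                  adjust = c("bonferroni", "none"),
                  transform = c("none", "log2p1")) {
  adjust <- match.arg(adjust)
  transform <- match.arg(transform)
  if (!inherits(data, "lrcde_data")) {
    if (is.null(proportions) || is.null(groups))
      stop("supply an lrcde_data object or expression + proportions + groups")
    data <- align_study(data, proportions, groups)
  }
  expr <- data$expression
  if (transform == "log2p1") expr <- log2(expr + 1)
  X <- data$proportions
  g <- data$groups
  cond <- condition_number(X)
  if (cond$high && !cond$singular)
    warning("high condition number of the proportion matrix (",
            format(cond$cd, digits = 4),
            " > 1000): cell type-specific estimates may be unreliable")
  fit_ctrl <- fit_cell_type_expression(expr[, g == "controls", drop = FALSE],
                                       X[g == "controls", , drop = FALSE],
                                       group = "controls")
  fit_case <- fit_cell_type_expression(expr[, g == "cases", drop = FALSE],
                                       X[g == "cases", , drop = FALSE],
                                       group = "cases")
  delta <- effect_sizes(fit_case, fit_ctrl)
  w <- welch_statistic(as.vector(fit_case$betas), as.vector(fit_case$coef_var),
                       fit_case$df,
                       as.vector(fit_ctrl$betas), as.vector(fit_ctrl$coef_var),
                       fit_ctrl$df)
  p <- t_p_value(w$t, w$df)
  genes <- rownames(expr)
  cells <- colnames(X)
  J <- length(genes)
  P <- length(cells)
  tab <- data.frame(
    gene = rep(genes, times = P),
    cell = rep(cells, each = J),
    beta_controls = as.vector(fit_ctrl$betas),
    beta_cases = as.vector(fit_case$betas),
    delta = as.vector(delta),
    se_delta = sqrt(as.vector(fit_case$coef_var) +
                      as.vector(fit_ctrl$coef_var)),
    t = w$t,
    df = w$df,
    p = p,
    p_adj = adjust_p(p, adjust),
    power = detection_power(w$t, w$df, alpha),
    mse_controls = rep(fit_ctrl$mse, times = P),
    mse_cases = rep(fit_case$mse, times = P),
    neg_beta = as.vector(fit_ctrl$betas) < 0 | as.vector(fit_case$betas) < 0,
    high_cd = cond$high,
    stringsAsFactors = FALSE
  )
  structure(list(table = tab, fits = list(controls = fit_ctrl,
                                          cases = fit_case),
                 condition = cond, alpha = alpha, adjust = adjust,
                 transform = transform, data = data, call = match.call()),
            class = "lrcde")
}

#' Effect sizes between two group fits
#'
#' Elementwise difference of the case and control cell type-specific
#' expression estimates.
#'
#' @param fit_cases,fit_controls `lrcde_groupfit` objects sharing gene and
#'   cell names.
#' @return A genes x cells matrix of effect sizes.
#' @export
effect_sizes <- function(fit_cases, fit_controls) {
  if (!identical(dim(fit_cases$betas), dim(fit_controls$betas)))
    stop("group fits have mismatched dimensions")
  if (!identical(dimnames(fit_cases$betas), dimnames(fit_controls$betas)))
    stop("group fits have mismatched gene or cell names")
  fit_cases$betas - fit_controls$betas
}

#' @export
print.lrcde <- function(x, ...) {
  tab <- x$table
  cat("Cell type-specific differential expression fit\n")
  cat("  genes:", length(unique(tab$gene)),
      " cell types:", length(unique(tab$cell)),
      " samples:", ncol(x$data$expression), "\n")
  cat("  condition number of X'X:", format(x$condition$cd, digits = 6),
      if (x$condition$high) "(high, > 1000)" else "", "\n")
  cat("  significant at adjusted p <", x$alpha, ":",
      sum(tab$p_adj < x$alpha), "of", nrow(tab), "tests\n")
  invisible(x)
}

#' Summarise a deconvolution differential-expression fit
#'
#' @param object an `lrcde` fit.
#' @param n number of top rows (by p-value) to retain for printing.
#' @param ... unused.
#' @return A `summary.lrcde` object: per-cell significance counts, the `n`
#'   smallest-p rows, and the condition report.
#' @export
summary.lrcde <- function(object, n = 10L, ...) {
  tab <- object$table
  per_cell <- aggregate(cbind(n_sig = tab$p_adj < object$alpha),
                        by = list(cell = tab$cell), FUN = sum)
  top <- tab[order(tab$p), , drop = FALSE]
  structure(list(per_cell = per_cell, top = utils::head(top, n),
                 condition = object$condition, alpha = object$alpha,
                 adjust = object$adjust, n_tests = nrow(tab)),
            class = "summary.lrcde")
}

#' @export
print.summary.lrcde <- function(x, ...) {
  cat("Significant gene x cell tests (", x$adjust, "-adjusted p < ", x$alpha,
      ") out of ", x$n_tests, ":\n", sep = "")
  print(x$per_cell, row.names = FALSE)
  cat("\nTop tests by p-value:\n")
  print(x$top, row.names = FALSE, digits = 4)
  cat("\n")
  print(x$condition)
  invisible(x)
}

#' Extract cell type-specific expression estimates
#'
#' @param object an `lrcde` fit.
#' @param group `"both"` (list of two matrices), `"controls"` or `"cases"`.
#' @param ... unused.
#' @return Genes x cells matrix (or list of two).
#' @export
coef.lrcde <- function(object, group = c("both", "controls", "cases"), ...) {
  group <- match.arg(group)
  if (group == "both")
    list(controls = object$fits$controls$betas,
         cases = object$fits$cases$betas)
  else object$fits[[group]]$betas
}

#' Predicted bulk expression from a fitted deconvolution model
#'
#' Reconstructs bulk expression as the proportion-weighted sum of the
#' fitted cell type-specific estimates, optionally for new proportions.
#'
#' @param object an `lrcde` fit.
#' @param newprops optional samples x cells proportion matrix; defaults to
#'   the group's own proportions (giving the fitted values).
#' @param group which group's estimates to use.
#' @param ... unused.
#' @return Genes x samples matrix of predicted bulk expression.
#' @export
predict.lrcde <- function(object, newprops = NULL,
                          group = c("controls", "cases"), ...) {
  group <- match.arg(group)
  fit <- object$fits[[group]]
  if (is.null(newprops)) return(fit$fitted)
  stopifnot_numeric_matrix(newprops, "proportions")
  if (ncol(newprops) != fit$p_cells)
    stop("newprops must have ", fit$p_cells, " cell-type columns")
  fit$betas %*% t(newprops)
}

#' @export
residuals.lrcde <- function(object, group = c("controls", "cases"), ...) {
  group <- match.arg(group)
  object$fits[[group]]$residuals
}

#' @export
fitted.lrcde <- function(object, group = c("controls", "cases"), ...) {
  group <- match.arg(group)
  object$fits[[group]]$fitted
}

#' Volcano plot of cell type-specific differential expression
#'
#' Effect size against `-log10(p)`, one colour per cell type, with the
#' significance level drawn as a horizontal line.
#'
#' @param x an `lrcde` fit.
#' @param use_adjusted plot adjusted p-values instead of raw ones.
#' @param ... passed to [graphics::plot()].
#' @export
plot.lrcde <- function(x, use_adjusted = FALSE, ...) {
  tab <- x$table
  p <- if (use_adjusted) tab$p_adj else tab$p
  p <- pmax(p, .Machine$double.xmin)
  cells <- unique(tab$cell)
  cols <- grDevices::hcl.colors(max(3L, length(cells)), "Dark 3")
  graphics::plot(tab$delta, -log10(p),
                 col = cols[match(tab$cell, cells)], pch = 16, cex = 0.6,
                 xlab = "effect size (cases - controls)",
                 ylab = if (use_adjusted) "-log10 adjusted p" else "-log10 p",
                 ...)
  graphics::abline(h = -log10(x$alpha), lty = 2)
  graphics::legend("topright", legend = cells, col = cols[seq_along(cells)],
                   pch = 16, cex = 0.8, bty = "n")
  invisible(x)
}

#' Simulate bulk expression from a fitted deconvolution model
#'
#' Parametric simulation: new bulk matrices are drawn as
#' `betas %*% t(X) + noise`, with per-gene Gaussian noise variance equal to
#' the gene's estimated residual variance, per group.
#'
#' @param object an `lrcde` fit.
#' @param nsim number of replicate datasets.
#' @param seed integer seed.
#' @param ... unused.
#' @return A list of `nsim` `lrcde_data` objects.
#' @export
simulate.lrcde <- function(object, nsim = 1, seed = 1, ...) {
  d <- object$data
  g <- d$groups
  out <- vector("list", nsim)
  for (i in seq_len(nsim)) {
    expr <- d$expression
    for (grp in c("controls", "cases")) {
      fit <- object$fits[[grp]]
      noise <- with_seed(derive_seed(seed, 2L * i + (grp == "cases")),
                         matrix(stats::rnorm(length(fit$fitted),
                                             sd = rep(sqrt(fit$mse),
                                                      fit$m_samples)),
                                nrow(fit$fitted), ncol(fit$fitted)))
      expr[, g == grp] <- fit$fitted + noise
    }
    out[[i]] <- align_study(expr, d$proportions, g)
  }
  out
}
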