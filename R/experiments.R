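# Reproducible simulation experiments: sensitivity (TPR) curves against
# significance thresholds, the condition-number perturbation study, the
# cell-dropping study, and the Welch-p vs permutation-FDR comparison.

#' True positive rate at a significance threshold
#'
#' Fraction of truly changed genes whose score (p-value or FDR) falls
#' strictly below the threshold.
#'
#' @param scores per-gene scores (smaller = more significant), aligned with
#'   `truth`.
#' @param truth per-gene true effect sizes (zero for unchanged genes); at
#'   least one nonzero entry required.
#' @param threshold scalar threshold; detection is `score < threshold`.
#' @return The TPR in `[0, 1]`.
#' @export
tpr_at_threshold <- function(scores, truth, threshold) {
  if (length(scores) != length(truth))
    stop("scores and truth must have equal length")
  changed <- truth != 0
  if (!any(changed)) stop("truth contains no changed genes")
  mean(scores[changed] < threshold)
}

#' Sensitivity curve over a threshold grid
#'
#' @inheritParams tpr_at_threshold
#' @param thresholds vector of thresholds.
#' @param method label stored with the curve (`"welch_p"` or `"perm_fdr"`).
#' @return A data frame with columns `method`, `threshold`, `tpr`.
#' @export
sensitivity_curve <- function(scores, truth, thresholds,
                              method = "welch_p") {
  data.frame(method = method, threshold = thresholds,
             tpr = vapply(thresholds,
                          function(th) tpr_at_threshold(scores, truth, th),
                          numeric(1L)))
}

#' Default significance-threshold grids
#'
#' p-values are thresholded up to 0.1 (the two-sided `1 - alpha` range)
#' and FDRs up to the conventional liberal 0.3 cutoff.
#'
#' @param n number of evenly spaced grid points.
#' @return Numeric vector of thresholds starting at 0.
#' @export
p_threshold_grid <- function(n = 101L) seq(0, 0.1, length.out = n)

#' @rdname p_threshold_grid
#' @export
fdr_threshold_grid <- function(n = 101L) seq(0, 0.3, length.out = n)

# Target-cell scores and truth for one simulated study, both methods.
.curves_for_study <- function(sim, data = sim$dataset, methods, n_perm,
                              n_cuts, seed, p_grid, fdr_grid,
                              target_cell_name = NULL) {
  cfg <- sim$config
  tc <- target_cell_name %||%
    colnames(sim$dataset$proportions)[cfg$target_cell]
  truth <- sim$truth[, cfg$target_cell]
  out <- list()
  if ("welch_p" %in% methods) {
    fit <- lrcde(data, adjust = "none")
    tab <- fit$table
    p_tc <- tab$p[tab$cell == tc]
    names(p_tc) <- tab$gene[tab$cell == tc]
    out$welch_p <- sensitivity_curve(p_tc[names(truth)], truth, p_grid,
                                     "welch_p")
    out$welch_fit <- fit
  }
  if ("perm_fdr" %in% methods) {
    fdr_tab <- run_perm_fdr(data, n_perm = n_perm, n_cuts = n_cuts,
                            seed = seed)
    f_tc <- fdr_tab$fdr[fdr_tab$cell == tc]
    names(f_tc) <- fdr_tab$gene[fdr_tab$cell == tc]
    out$perm_fdr <- sensitivity_curve(f_tc[names(truth)], truth, fdr_grid,
                                      "perm_fdr")
    out$fdr_table <- fdr_tab
  }
  out
}

#' Parameter sweep of detection sensitivity
#'
#' Reruns the simulator and both detection methods for each value of one
#' varied parameter, holding the rest of the configuration fixed: the
#' sample-size, proportion-SD, MSE and transform comparisons. Each value
#' gets its own derived seed, so values are independent replicates of the
#' same conditions apart from the varied parameter.
#'
#' @param base a [sim_config()] giving the held-fixed configuration.
#' @param vary one of `"n_per_group"`, `"target_sd"`, `"mse_target"`,
#'   `"transform"`.
#' @param values values to sweep (for `"transform"`: `"none"`,
#'   `"log2p1"`).
#' @param methods which methods to run.
#' @param n_perm,n_cuts permutation-FDR settings.
#' @param p_grid,fdr_grid threshold grids for the two methods.
#' @return An object of class `lrcde_sweep`: list of per-value entries
#'   (`value`, `curves`, `achieved_sd`, `achieved_cd`), plus `vary` and
#'   `base`.
#' @export
parameter_sweep <- function(base, vary, values,
                            methods = c("welch_p", "perm_fdr"),
                            n_perm = 200L, n_cuts = 100L,
                            p_grid = p_threshold_grid(),
                            fdr_grid = fdr_threshold_grid()) {
  stopifnot(inherits(base, "sim_config"))
  vary <- match.arg(vary, c("n_per_group", "target_sd", "mse_target",
                            "transform"))
  methods <- match.arg(methods, several.ok = TRUE)
  entries <- vector("list", length(values))
  for (i in seq_along(values)) {
    cfg_args <- unclass(base)
    cfg_args$seed <- derive_seed(base$seed, 1000L + i)
    if (vary != "transform") cfg_args[[vary]] <- values[[i]]
    cfg <- do.call(sim_config, cfg_args)
    sim <- assemble_study(cfg)
    data <- sim$dataset
    if (vary == "transform" && values[[i]] == "log2p1")
      data$expression <- log2(data$expression + 1)
    cv <- .curves_for_study(sim, data, methods, n_perm, n_cuts,
                            derive_seed(cfg$seed, 5000L), p_grid, fdr_grid)
    entries[[i]] <- list(value = values[[i]],
                         curves = cv[intersect(names(cv),
                                               c("welch_p", "perm_fdr"))],
                         achieved_sd = sim$achieved_sd,
                         achieved_cd = sim$achieved_cd)
  }
  structure(list(vary = vary, entries = entries, base = base),
            class = "lrcde_sweep")
}

#' @export
print.lrcde_sweep <- function(x, ...) {
  cat("Sensitivity sweep over", x$vary, "\n")
  for (e in x$entries) {
    cat("  ", x$vary, "=", format(e$value), ": ")
    for (m in names(e$curves))
      cat(m, "max TPR", format(max(e$curves[[m]]$tpr), digits = 3), " ")
    cat("\n")
  }
  invisible(x)
}

#' Plot sensitivity curves from a parameter sweep
#'
#' TPR against the significance threshold, one line per swept value, one
#' panel per method.
#'
#' @param x an `lrcde_sweep` object.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.lrcde_sweep <- function(x, ...) {
  methods <- names(x$entries[[1L]]$curves)
  oldpar <- graphics::par(mfrow = c(1L, length(methods)))
  on.exit(graphics::par(oldpar))
  for (m in methods) {
    tpr <- sapply(x$entries, function(e) e$curves[[m]]$tpr)
    graphics::matplot(x$entries[[1L]]$curves[[m]]$threshold, tpr,
                      type = "l", lty = 1L,
                      xlab = if (m == "welch_p") "p-value threshold"
                             else "FDR threshold",
                      ylab = "TPR", main = m, ...)
    graphics::legend("bottomright",
                     legend = paste(x$vary, "=",
                                    sapply(x$entries, `[[`, "value")),
                     lty = 1L, col = seq_along(x$entries), bty = "n")
  }
  invisible(x)
}

#' Condition-number perturbation experiment
#'
#' Stability of detection sensitivity under small perturbations of the
#' proportion matrix: `n_iter` studies are simulated at a fixed target-cell
#' SD and target condition number, each with a freshly drawn proportion
#' matrix (seeds derived from the master seed), and a scalar sensitivity is
#' recorded per iteration. High condition numbers make this sensitivity
#' fluctuate across iterations even though SD and condition number are held
#' fixed.
#'
#' @param target_cd target condition number of `X'X`.
#' @param n_iter number of perturbed iterations.
#' @param config base [sim_config()]; its `target_cd` is overridden.
#' @param summary per-iteration scalar: `"power"` (mean of
#'   [detection_power()] over changed genes in the target cell) or `"tpr"`
#'   ([tpr_at_threshold()] of the Welch p-values at `tpr_threshold`).
#' @param alpha significance level for the power calculation.
#' @param tpr_threshold threshold for the `"tpr"` summary.
#' @return An object of class `cd_perturbation`: list with `target_cd`,
#'   `sensitivity` (length `n_iter`), `min`, `max`, `achieved_cd`,
#'   `summary`, `config`.
#' @export
cd_perturbation_experiment <- function(target_cd, n_iter = 100L, config,
                                       summary = c("power", "tpr"),
                                       alpha = 0.05,
                                       tpr_threshold = alpha) {
  stopifnot(inherits(config, "sim_config"))
  summary <- match.arg(summary)
  sens <- numeric(n_iter)
  acd <- numeric(n_iter)
  for (i in seq_len(n_iter)) {
    cfg_args <- unclass(config)
    cfg_args$target_cd <- target_cd
    cfg_args$seed <- derive_seed(config$seed, i)
    cfg <- do.call(sim_config, cfg_args)
    sim <- assemble_study(cfg)
    fit <- lrcde(sim$dataset, alpha = alpha, adjust = "none")
    tc <- colnames(sim$dataset$proportions)[cfg$target_cell]
    tab <- fit$table[fit$table$cell == tc, ]
    tab <- tab[match(rownames(sim$truth), tab$gene), ]
    truth <- sim$truth[, cfg$target_cell]
    sens[i] <- if (summary == "power")
      mean(tab$power[truth != 0])
    else tpr_at_threshold(tab$p, truth, tpr_threshold)
    acd[i] <- sim$achieved_cd
  }
  structure(list(target_cd = target_cd, sensitivity = sens,
                 min = min(sens), max = max(sens), achieved_cd = acd,
                 summary = summary, config = config),
            class = "cd_perturbation")
}

#' @export
print.cd_perturbation <- function(x, ...) {
  cat("Condition-number perturbation experiment (target CD ", x$target_cd,
      ", ", length(x$sensitivity), " iterations, ", x$summary,
      " summary)\n", sep = "")
  cat("  sensitivity min/median/max: ",
      paste(format(c(x$min, stats::median(x$sensitivity), x$max),
                   digits = 4), collapse = " / "), "\n")
  invisible(x)
}

#' Cell-dropping experiment
#'
#' Simulates one study at the base configuration (typically with a high
#' condition number), then reruns both detection methods after dropping the
#' `k` lowest-mean cell types, for each `k` in `drops`. Dropping reduces
#' the multicollinearity of the proportion matrix; the experiment records
#' the condition reports and sensitivity curves per `k`.
#'
#' @param config a [sim_config()] object.
#' @param drops integer vector of drop counts (each in `0..P-2`).
#' @inheritParams parameter_sweep
#' @return An object of class `lrcde_dropping`: list of per-`k` entries
#'   (`k`, `plan`, `cd`, `curves`), plus the simulated study `sim`.
#' @export
cell_dropping_experiment <- function(config, drops = c(0L, 1L, 3L),
                                     methods = c("welch_p", "perm_fdr"),
                                     n_perm = 200L, n_cuts = 100L,
                                     p_grid = p_threshold_grid(),
                                     fdr_grid = fdr_threshold_grid()) {
  stopifnot(inherits(config, "sim_config"))
  methods <- match.arg(methods, several.ok = TRUE)
  sim <- assemble_study(config)
  tc_name <- colnames(sim$dataset$proportions)[config$target_cell]
  entries <- vector("list", length(drops))
  for (i in seq_along(drops)) {
    k <- drops[i]
    dropped <- drop_lowest_mean_cells(sim$dataset$proportions, k)
    if (tc_name %in% dropped$plan$dropped_cells)
      stop("dropping k = ", k, " cells would remove the target cell type")
    data_k <- sim$dataset
    data_k$proportions <- dropped$proportions
    cv <- .curves_for_study(sim, data_k, methods, n_perm, n_cuts,
                            derive_seed(config$seed, 7000L + i),
                            p_grid, fdr_grid, target_cell_name = tc_name)
    entries[[i]] <- list(k = k, plan = dropped$plan,
                         cd = dropped$plan$cd_after,
                         curves = cv[intersect(names(cv),
                                               c("welch_p", "perm_fdr"))])
  }
  structure(list(entries = entries, sim = sim, config = config),
            class = "lrcde_dropping")
}

#' @export
print.lrcde_dropping <- function(x, ...) {
  cat("Cell-dropping experiment (base condition number ",
      format(x$sim$achieved_cd, digits = 5), ")\n", sep = "")
  for (e in x$entries) {
    cat("  k =", e$k, ": CD", format(e$cd, digits = 5),
        " retained mass", format(e$plan$retained_mass, digits = 3), " ")
    for (m in names(e$curves))
      cat(m, "max TPR", format(max(e$curves[[m]]$tpr), digits = 3), " ")
    cat("\n")
  }
  invisible(x)
}
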