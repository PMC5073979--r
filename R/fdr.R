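# Permutation cut-point false discovery rate comparator.
#
# The comparator method estimates, per cell type, an FDR for each gene's
# effect size by permuting group labels, refitting the two deconvolution
# regressions, and comparing observed exceedance counts over a grid of cut
# points with the average exceedance under permutation.

#' Effect sizes under permuted group labels
#'
#' For each of `n_perm` seeded permutations of the group labels (group
#' sizes preserved), refits both group regressions and records the
#' permuted effect-size matrix. Permutations whose regression fails (e.g. a
#' singular subset design) are skipped and counted.
#'
#' @param data an `lrcde_data` object.
#' @param n_perm number of permutations.
#' @param seed integer seed for the permutation sequence.
#' @param perms optional list of explicit permutations (integer vectors of
#'   length `2M`) overriding the seeded draw; e.g. `list(seq_len(2 * M))`
#'   forces the identity permutation.
#' @return A genes x cells x permutations array with attribute
#'   `n_failed` counting skipped permutations.
#' @export
permuted_deltas <- function(data, n_perm = 200L, seed = 1L, perms = NULL) {
  stopifnot(inherits(data, "lrcde_data"))
  if (is.null(perms)) {
    if (n_perm < 1L) stop("n_perm must be >= 1")
    n_samp <- ncol(data$expression)
    perms <- with_seed(seed, lapply(seq_len(n_perm),
                                    function(i) sample.int(n_samp)))
  }
  g <- data$groups
  expr <- data$expression
  X <- data$proportions
  out <- array(NA_real_,
               dim = c(nrow(expr), ncol(X), length(perms)),
               dimnames = list(rownames(expr), colnames(X), NULL))
  n_failed <- 0L
  for (b in seq_along(perms)) {
    gp <- g[perms[[b]]]
    d_b <- try({
      f_ctrl <- fit_cell_type_expression(expr[, gp == "controls",
                                              drop = FALSE],
                                         X[gp == "controls", , drop = FALSE],
                                         "controls")
      f_case <- fit_cell_type_expression(expr[, gp == "cases", drop = FALSE],
                                         X[gp == "cases", , drop = FALSE],
                                         "cases")
      f_case$betas - f_ctrl$betas
    }, silent = TRUE)
    if (inherits(d_b, "try-error")) n_failed <- n_failed + 1L
    else out[, , b] <- d_b
  }
  if (n_failed > 0L) {
    warning(n_failed, " of ", length(perms),
            " permutations failed and were skipped")
    out <- out[, , !is.na(out[1L, 1L, ]), drop = FALSE]
  }
  attr(out, "n_failed") <- n_failed
  out
}

# FDR assignment for one cell and one sign class.
.fdr_one_class <- function(obs_mag, perm_mag, n_perm_eff, n_cuts, cuts) {
  if (is.null(cuts)) cuts <- seq(0, max(obs_mag), length.out = n_cuts)
  calls <- vapply(cuts, function(cc) sum(obs_mag > cc), numeric(1L))
  exceed <- vapply(cuts, function(cc) sum(perm_mag > cc), numeric(1L)) /
    n_perm_eff
  raw <- ifelse(calls == 0, ifelse(exceed == 0, 0, 1),
                pmin(1, exceed / calls))
  # running minimum in ascending cut order: the assigned FDR is
  # non-increasing in the cut point (and hence in |delta|)
  mono <- cummin(raw)
  # each magnitude takes the FDR of the greatest cut point strictly below it
  idx <- findInterval(obs_mag, cuts, left.open = TRUE)
  list(fdr = mono[pmax(idx, 1L)],
       info = data.frame(cut = cuts, calls = calls, mean_exceed = exceed,
                         fdr_raw = raw, fdr = mono))
}

#' Cut-point FDR from observed and permuted effect sizes
#'
#' Per cell type (and, by default, separately for positive and negative
#' effects), builds `n_cuts` evenly spaced cut points between zero and the
#' largest observed effect magnitude. At each cut point, the number of
#' observed effects exceeding it ("calls") is compared with the average
#' number of permuted effects exceeding it; their ratio (capped at 1) is
#' the raw FDR, made non-increasing in the cut point by a running minimum
#' in ascending cut order. Each gene receives the FDR of the greatest
#' cut point smaller than its effect magnitude. Genes with an exactly zero
#' effect get FDR 1.
#'
#' @param observed genes x cells matrix of observed effect sizes.
#' @param permuted genes x cells x permutations array
#'   (see [permuted_deltas()]).
#' @param n_cuts number of cut points (>= 2).
#' @param cuts optional explicit cut-point vector overriding the grid.
#' @param sign_classes process positive and negative effects as separate
#'   classes (default); `FALSE` pools magnitudes.
#' @return A data frame (`gene`, `cell`, `delta`, `fdr`) with attribute
#'   `cutinfo`, a per cell/class list of cut-point tables.
#' @examples
#' obs <- matrix(c(0.9, 0.5, 0.1), dimnames = list(paste0("g", 1:3), "c1"))
#' perm <- array(c(0.55, 0.25, 0.05), c(3, 1, 1))
#' fdr_from_cutpoints(obs, perm, cuts = c(0, 0.3, 0.6))
#' @export
fdr_from_cutpoints <- function(observed, permuted, n_cuts = 100L,
                               cuts = NULL, sign_classes = TRUE) {
  if (is.null(dim(observed))) observed <- as.matrix(observed)
  if (length(dim(permuted)) == 2L)
    permuted <- array(permuted, c(dim(permuted), 1L))
  if (!all(dim(permuted)[1:2] == dim(observed)))
    stop("observed and permuted arrays do not conform")
  if (is.null(cuts) && n_cuts < 2L) stop("n_cuts must be >= 2")
  J <- nrow(observed); P <- ncol(observed)
  B <- dim(permuted)[3L]
  fdr <- matrix(1, J, P)
  cutinfo <- list()
  for (k in seq_len(P)) {
    obs_k <- observed[, k]
    perm_k <- as.vector(permuted[, k, ])
    perm_k <- perm_k[!is.na(perm_k)]
    classes <- if (sign_classes)
      list(pos = obs_k > 0, neg = obs_k < 0)
    else list(all = obs_k != 0)
    for (cl in names(classes)) {
      in_cl <- classes[[cl]]
      if (!any(in_cl)) next
      perm_cl <- switch(cl,
                        pos = perm_k[perm_k > 0],
                        neg = perm_k[perm_k < 0],
                        all = perm_k[perm_k != 0])
      res <- .fdr_one_class(abs(obs_k[in_cl]), abs(perm_cl), B, n_cuts, cuts)
      fdr[in_cl, k] <- res$fdr
      cutinfo[[paste0(colnames(observed)[k] %||% paste0("cell_", k),
                      ".", cl)]] <- res$info
    }
  }
  out <- data.frame(
    gene = rep(rownames(observed) %||% paste0("gene_", seq_len(J)),
               times = P),
    cell = rep(colnames(observed) %||% paste0("cell_", seq_len(P)),
               each = J),
    delta = as.vector(observed),
    fdr = as.vector(fdr),
    stringsAsFactors = FALSE)
  attr(out, "cutinfo") <- cutinfo
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Permutation cut-point FDR for a two-group study
#'
#' Convenience wrapper: fits the two group regressions for the observed
#' labels, computes permuted effect sizes, and assigns cut-point FDRs.
#'
#' @inheritParams permuted_deltas
#' @inheritParams fdr_from_cutpoints
#' @return The [fdr_from_cutpoints()] data frame, with the observed effect
#'   matrix attached as attribute `observed`.
#' @export
run_perm_fdr <- function(data, n_perm = 200L, n_cuts = 100L, seed = 1L,
                         sign_classes = TRUE) {
  stopifnot(inherits(data, "lrcde_data"))
  g <- data$groups
  f_ctrl <- fit_cell_type_expression(
    data$expression[, g == "controls", drop = FALSE],
    data$proportions[g == "controls", , drop = FALSE], "controls")
  f_case <- fit_cell_type_expression(
    data$expression[, g == "cases", drop = FALSE],
    data$proportions[g == "cases", , drop = FALSE], "cases")
  observed <- f_case$betas - f_ctrl$betas
  perm <- permuted_deltas(data, n_perm = n_perm, seed = seed)
  out <- fdr_from_cutpoints(observed, perm, n_cuts = n_cuts,
                            sign_classes = sign_classes)
  attr(out, "observed") <- observed
  out
}
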