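# Readers, writers and dataset assembly.
#
# File conventions: delimited text (TSV by default, CSV by ".csv" extension),
# one header row and one header column. Expression files are genes x samples;
# proportion files are samples x cell types.

.sep_for <- function(path, sep = NULL) {
  if (!is.null(sep)) return(sep)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

# Read a delimited numeric matrix with row and column headers, validating
# completeness, numeric type and id uniqueness.
.read_matrix <- function(path, sep = NULL, what = "matrix") {
  sep <- .sep_for(path, sep)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          quote = "\"", comment.char = "")
  if (ncol(df) < 2L) stop(what, " file ", path, " has no data columns")
  row_ids <- as.character(df[[1L]])
  body <- df[, -1L, drop = FALSE]
  col_ids <- colnames(body)
  if (anyDuplicated(row_ids))
    stop(what, " file ", path, ": duplicate row id '",
         row_ids[anyDuplicated(row_ids)], "'")
  if (anyDuplicated(col_ids))
    stop(what, " file ", path, ": duplicate column id '",
         col_ids[anyDuplicated(col_ids)], "'")
  for (j in seq_along(body)) {
    if (!is.numeric(body[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(body[[j]]))))[1L]
      stop(what, " file ", path, ": non-numeric value in column '",
           col_ids[j], "', row '", row_ids[if (is.na(bad)) 1L else bad], "'")
    }
    if (anyNA(body[[j]]))
      stop(what, " file ", path, ": missing value in column '", col_ids[j],
           "', row '", row_ids[which(is.na(body[[j]]))[1L]], "'")
  }
  m <- as.matrix(body)
  dimnames(m) <- list(row_ids, col_ids)
  m
}

#' Read a heterogeneous expression matrix
#'
#' Reads a genes x samples delimited text file (first row sample ids, first
#' column gene ids). Optionally applies the variance-stabilising transform
#' `log2(x + 1)`; the `+1` offset maps zero counts to zero and keeps the
#' transform monotone and invertible.
#'
#' @param path path to a TSV (default) or CSV file.
#' @param transform `"none"` to keep values as stored, `"log2p1"` for
#'   `log2(x + 1)`.
#' @param sep field separator override; inferred from the extension if `NULL`.
#' @return A numeric matrix, genes in rows, samples in columns, with attribute
#'   `scale_tag` set to `"linear"` or `"log2"`.
#' @seealso [read_proportions()], [align_study()]
#' @export
read_expression <- function(path, transform = c("none", "log2p1"), sep = NULL) {
  transform <- match.arg(transform)
  m <- .read_matrix(path, sep, "expression")
  if (ncol(m) < 2L) stop("expression matrix needs at least two samples")
  if (transform == "log2p1") {
    if (any(m < -1)) stop("log2p1 transform requires values > -1")
    m <- log2(m + 1)
    attr(m, "scale_tag") <- "log2"
  } else {
    attr(m, "scale_tag") <- "linear"
  }
  m
}

#' Read a cell-proportion matrix
#'
#' Reads a samples x cell types delimited text file of cell fractions.
#' Negative entries are an error. Rows are expected to sum to 1 (the
#' biological constraint on complete cell proportions); deviations beyond
#' `1e-3` raise a warning rather than an error because measured
#' flow-cytometry fractions rarely sum exactly to 1.
#'
#' @inheritParams read_expression
#' @return A numeric matrix, samples in rows, cell types in columns, with
#'   attribute `reduced = FALSE` (see [drop_lowest_mean_cells()]).
#' @export
read_proportions <- function(path, sep = NULL) {
  m <- .read_matrix(path, sep, "proportions")
  if (any(m < 0)) {
    bad <- which(m < 0, arr.ind = TRUE)[1L, ]
    stop("proportions: negative entry for sample '", rownames(m)[bad[1L]],
         "', cell '", colnames(m)[bad[2L]], "'")
  }
  rs <- rowSums(m)
  off <- abs(rs - 1) > 1e-3
  if (any(off))
    warning("proportions: ", sum(off), " row(s) deviate from sum 1 by > 1e-3",
            " (first: '", rownames(m)[which(off)[1L]], "', sum ",
            format(rs[which(off)[1L]]), ")")
  attr(m, "reduced") <- FALSE
  m
}

#' Read two-group sample labels
#'
#' Reads a two-column delimited file (`sample_id`, `group`). Exactly two
#' distinct group labels must be present; labels other than
#' `controls`/`cases` are mapped onto those levels in sort order, the first
#' becoming `controls`.
#'
#' @inheritParams read_expression
#' @return A named factor with levels `c("controls", "cases")`.
#' @export
read_group_labels <- function(path, sep = NULL) {
  sep <- .sep_for(path, sep)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("group label file must have two columns")
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids))
    stop("group label file: duplicate sample id '", ids[anyDuplicated(ids)], "'")
  as_group_factor(df[[2L]], ids)
}

#' Assemble and align a two-group deconvolution dataset
#'
#' Checks that the expression matrix, proportion matrix and group labels
#' cover the same samples, reorders proportions and labels to the expression
#' column order (the canonical order), and validates that each group keeps
#' more samples than there are cell types, without which the residual
#' degrees of freedom `M - P` of the per-group regression would vanish.
#'
#' @param expression numeric matrix, genes x samples.
#' @param proportions numeric matrix, samples x cell types.
#' @param groups named factor/character of group labels, or an unnamed vector
#'   ordered like the expression columns.
#' @return An object of class `lrcde_data`: a list with elements
#'   `expression`, `proportions`, `groups`, sample-aligned.
#' @export
align_study <- function(expression, proportions, groups) {
  stopifnot_numeric_matrix(expression, "expression")
  stopifnot_numeric_matrix(proportions, "proportions")
  samples <- colnames(expression)
  if (is.null(samples)) stop("expression matrix must have sample column names")
  if (is.null(rownames(proportions)))
    stop("proportion matrix must have sample row names")
  if (is.null(names(groups))) {
    if (length(groups) != length(samples))
      stop("unnamed group labels must match the number of expression samples")
    names(groups) <- samples
  }
  g <- as_group_factor(groups)
  for (piece in list(proportions = rownames(proportions),
                     groups = names(g))) {
    missing_here <- setdiff(samples, piece)
    extra_here <- setdiff(piece, samples)
    if (length(missing_here) || length(extra_here))
      stop("sample id mismatch; missing: [",
           paste(missing_here, collapse = ", "), "], extra: [",
           paste(extra_here, collapse = ", "), "]")
  }
  props <- proportions[samples, , drop = FALSE]
  attr(props, "reduced") <- isTRUE(attr(proportions, "reduced"))
  g <- g[samples]
  P <- ncol(props)
  m_g <- table(g)
  if (any(m_g <= P))
    stop("insufficient degrees of freedom: group sizes (",
         paste(m_g, collapse = ", "), ") must exceed the number of cell ",
         "types (", P, ")")
  structure(list(expression = expression, proportions = props, groups = g),
            class = "lrcde_data")
}

#' @export
print.lrcde_data <- function(x, ...) {
  cat("Two-group deconvolution dataset\n")
  cat("  genes:     ", nrow(x$expression), "\n")
  cat("  samples:   ", ncol(x$expression), " (",
      paste(table(x$groups), collapse = " controls / "), " cases)\n", sep = "")
  cat("  cell types:", ncol(x$proportions),
      paste0("(", paste(colnames(x$proportions), collapse = ", "), ")"), "\n")
  invisible(x)
}

.cde_columns <- c("gene", "cell", "beta_controls", "beta_cases", "delta",
                  "se_delta", "t", "df", "p", "p_adj", "power",
                  "mse_controls", "mse_cases")

#' Write a cell type-specific differential expression table
#'
#' Writes one row per gene x cell type, at full double precision (15
#' significant digits) so that a read/write round trip preserves values.
#'
#' @param table a data frame as produced by [lrcde()] (`$table`).
#' @param path output path; TSV by default, CSV for a `.csv` extension.
#' @param sep field separator override.
#' @export
write_cde_table <- function(table, path, sep = NULL) {
  sep <- .sep_for(path, sep)
  miss <- setdiff(.cde_columns, colnames(table))
  if (length(miss))
    stop("CDE table is missing columns: ", paste(miss, collapse = ", "))
  out <- table[, .cde_columns, drop = FALSE]
  num <- vapply(out, is.numeric, logical(1L))
  out[num] <- lapply(out[num], function(x) format(x, digits = 15L,
                                                  trim = TRUE))
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a cell type-specific differential expression table
#'
#' @inheritParams read_expression
#' @return A data frame with the columns written by [write_cde_table()].
#' @export
read_cde_table <- function(path, sep = NULL) {
  sep <- .sep_for(path, sep)
  utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                    stringsAsFactors = FALSE)
}
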