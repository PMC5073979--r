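# Internal helpers shared across the package.

#' Derive a reproducible sub-seed from a master seed
#'
#' Repeated experiments (simulation replicates, permutations, sweeps) each
#' need their own RNG stream, all reproducible from one master seed. Sub-seeds
#' are derived by a fixed affine map modulo a prime below 2^31 so that any
#' integer master seed and counter yield a valid `set.seed()` argument.
#'
#' @param seed integer master seed.
#' @param counter non-negative integer stream index.
#' @return An integer seed in `[0, 2^31)`.
#' @export
derive_seed <- function(seed, counter) {
  as.integer((as.numeric(seed) %% 2147483629 * 48271 + counter) %% 2147483629)
}

# Evaluate code under a given seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Normalize a two-group label vector to a factor with levels
# c("controls", "cases"). Labels already named controls/cases are kept;
# otherwise the first label in sort order becomes "controls".
as_group_factor <- function(groups, sample_ids = names(groups)) {
  g <- as.character(groups)
  lev <- sort(unique(g))
  if (length(lev) != 2L)
    stop("group labels must contain exactly two distinct values, found: ",
         paste(lev, collapse = ", "))
  if (setequal(lev, c("controls", "cases"))) {
    f <- factor(g, levels = c("controls", "cases"))
  } else {
    f <- factor(ifelse(g == lev[1L], "controls", "cases"),
                levels = c("controls", "cases"))
  }
  names(f) <- sample_ids
  f
}

stopifnot_numeric_matrix <- function(x, what) {
  if (!is.matrix(x) || !is.numeric(x))
    stop(what, " must be a numeric matrix")
  if (anyNA(x)) {
    bad <- which(is.na(x), arr.ind = TRUE)[1L, ]
    stop(what, " contains missing values (first at row ", bad[1L],
         ", column ", bad[2L], ")")
  }
  invisible(x)
}
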