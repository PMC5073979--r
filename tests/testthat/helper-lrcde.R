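# Shared fixtures, built in code.

# Small fully-specified two-group dataset with known structure.
toy_study <- function(J = 6L, M = 8L, P = 2L, seed = 1L) {
  set.seed(seed)
  X <- matrix(runif(M * P, 0.2, 0.8), M, P)
  X <- X / rowSums(X)
  dimnames(X) <- list(paste0("s", seq_len(M)), paste0("c", seq_len(P)))
  B <- matrix(runif(J * P, 5, 10), J, P,
              dimnames = list(paste0("g", seq_len(J)), colnames(X)))
  Y <- B %*% t(X) + matrix(rnorm(J * M, sd = 0.1), J, M)
  colnames(Y) <- rownames(X)
  g <- factor(rep(c("controls", "cases"), length.out = M),
              levels = c("controls", "cases"))
  names(g) <- rownames(X)
  list(expression = Y, proportions = X, groups = g, betas = B)
}

write_matrix_file <- function(m, path, sep = "\t", header_col = "id") {
  df <- data.frame(rownames(m), m, check.names = FALSE)
  colnames(df) <- c(header_col, colnames(m))
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  path
}
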