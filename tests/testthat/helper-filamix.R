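# Shared fixtures and independent oracles.

# Small expression matrix built in code: one condition, three sample types,
# `reps` replicates, values supplied or drawn reproducibly.
toy_matrix <- function(values = NULL, n_genes = 10, condition = "P",
                       reps = 3, seed = 42) {
  keys <- as.vector(outer(c("F", "V", "Ht"), seq_len(reps),
                          function(st, r) paste(condition, st, r, sep = "_")))
  if (is.null(values)) {
    set.seed(seed)
    values <- matrix(rlnorm(n_genes * length(keys), log(500), 1),
                     nrow = n_genes)
  }
  rownames(values) <- sprintf("g%02d", seq_len(nrow(values)))
  colnames(values) <- keys
  ExpressionMatrix(values)
}

# Mean-of-order-statistics quantile normalization, independent of the
# implementation path (no ties expected in continuous random input).
qn_oracle <- function(m) {
  ref <- rowMeans(apply(m, 2, sort))
  out <- m
  for (j in seq_len(ncol(m))) out[order(m[, j]), j] <- ref
  out
}

# Welch's t-test from first principles: statistic, Welch-Satterthwaite df,
# two-tailed p from the t distribution.
welch_oracle <- function(x, y) {
  v1 <- var(x) / length(x)
  v2 <- var(y) / length(y)
  t_stat <- (mean(x) - mean(y)) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (length(x) - 1) + v2^2 / (length(y) - 1))
  list(t_stat = t_stat, df = df, p = 2 * pt(-abs(t_stat), df))
}
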