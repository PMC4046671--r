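#' Reduce a dataset before mixture modeling
#'
#' Applies the two data-reduction filters for one growth condition, in
#' order: (1) remove genes whose mean signal across the condition's samples
#' (all sample types and replicates) is below `mean_floor`; (2) among the
#' survivors, remove genes whose replicate coefficient of variation exceeds
#' `cv_threshold` within any sample-type group (a concrete surrogate for
#' "high variability between biological replicates").
#'
#' @param em an [ExpressionMatrix].
#' @param condition condition label present in `em`.
#' @param mean_floor SIU floor on the across-sample mean (default 128).
#' @param cv_threshold maximal tolerated within-group replicate CV (default
#'   0.5); `Inf` disables the filter.
#' @return list with `matrix` (the reduced [ExpressionMatrix], restricted to
#'   the condition's samples) and `report` (a `ReductionReport` data frame:
#'   counts in/removed/out and the parameters used).
#' @export
reduce_dataset <- function(em, condition, mean_floor = 128,
                           cv_threshold = 0.5) {
  idx <- sample_columns(em, condition = condition)
  if (!length(idx)) stop("condition '", condition, "' absent from matrix")
  sub <- em[, idx]
  vals <- sub$values

  genes_in <- nrow(vals)
  keep_signal <- rowMeans(vals) >= mean_floor
  removed_low <- sum(!keep_signal)

  high_cv <- rep(FALSE, genes_in)
  if (is.finite(cv_threshold)) {
    for (st in unique(sub$samples$sample_type)) {
      g <- vals[, sample_columns(sub, sample_type = st), drop = FALSE]
      if (ncol(g) < 2) next
      cv <- apply(g, 1, stats::sd) / rowMeans(g)
      cv[is.na(cv)] <- 0
      high_cv <- high_cv | cv > cv_threshold
    }
  }
  removed_var <- sum(keep_signal & high_cv)
  keep <- keep_signal & !high_cv

  report <- data.frame(
    condition = condition,
    genes_in = genes_in,
    genes_removed_low_signal = removed_low,
    genes_removed_variability = removed_var,
    genes_out = sum(keep),
    mean_floor = mean_floor,
    cv_threshold = cv_threshold,
    stringsAsFactors = FALSE
  )
  stopifnot(report$genes_out ==
              report$genes_in - removed_low - removed_var)
  list(matrix = sub[which(keep), ], report = report)
}

#' Per-gene sample-type means for one condition
#'
#' Convenience extractor: replicate means of the filament (F), vegetative
#' (V) and heterocyst (Ht) groups, aligned by gene.
#'
#' @param em an [ExpressionMatrix].
#' @param condition condition label.
#' @return data frame with `gene_id`, `f_mean`, `v_mean`, `ht_mean`.
#' @export
condition_means <- function(em, condition) {
  grp <- function(st) {
    cols <- sample_columns(em, condition = condition, sample_type = st)
    if (!length(cols))
      stop("no ", st, " samples for condition '", condition, "'")
    rowMeans(em$values[, cols, drop = FALSE])
  }
  data.frame(
    gene_id = em$genes$gene_id,
    f_mean = grp("F"), v_mean = grp("V"), ht_mean = grp("Ht"),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Fit the two-component filament mixing model
#'
#' Fits the no-intercept linear model `F = a*V + b*Ht`, where F, V and Ht
#' are per-gene replicate means in filaments, vegetative cells and
#' heterocysts, and a and b reflect the relative abundance of the two cell
#' types in the filament. Two estimators are offered:
#'
#' * `ols`: least squares through the origin on (V, Ht) -> F;
#' * `grid`: exhaustive lattice search minimizing the sum of squared
#'   weighted residuals (each residual divided by the Euclidean length of
#'   the gene's (V, Ht, F) vector), so the search objective matches the
#'   outlier statistic;
#' * `tls`: orthogonal (total) least squares on the norm-scaled points
#'   (V, Ht, F)/|(V, Ht, F)|: the plane through the origin minimizing the
#'   orthogonal scatter of the scale-normalized gene vectors. Because V, Ht
#'   and F all carry the same relative measurement noise, the response-only
#'   estimators are either tail-dominated (`ols`) or attenuated by regressor
#'   noise (`grid`); `tls` treats the three coordinates symmetrically and is
#'   the recommended estimator on noisy data.
#'
#' Coefficients are unconstrained in sign: values a > 1 or b < 0 can and do
#' occur on real data and are diagnostically meaningful. Optional bootstrap:
#' genes are resampled with replacement `n_boot` times and percentile 95%
#' intervals reported.
#'
#' @param v_means,ht_means,f_means aligned per-gene replicate means (SIU).
#' @param method `"ols"` or `"grid"`.
#' @param grid_a,grid_b lattice ranges for the grid search.
#' @param grid_step lattice step (default 0.001).
#' @param n_boot number of bootstrap resamples (0 = none).
#' @param seed seed for the bootstrap.
#' @return a `MixtureFit` list: `a`, `b`, `method`, `sse` (sum of squared
#'   weighted residuals at the estimate), `n_genes`, and when bootstrapped
#'   `bootstrap_ci_a`, `bootstrap_ci_b`, `n_boot`, `seed`.
#' @examples
#' v <- c(100, 200, 400); ht <- c(50, 300, 10)
#' f <- 0.92 * v + 0.08 * ht
#' fit_mixture(v, ht, f)[c("a", "b")]
#' @export
fit_mixture <- function(v_means, ht_means, f_means,
                        method = c("ols", "grid", "tls"),
                        grid_a = c(0, 1.5), grid_b = c(-0.3, 0.5),
                        grid_step = 0.001,
                        n_boot = 0, seed = 1L) {
  method <- match.arg(method)
  n <- length(f_means)
  if (n == 0) stop("empty input")
  if (length(v_means) != n || length(ht_means) != n)
    stop("v_means, ht_means and f_means must be aligned by gene")
  if (n < 3) stop("need at least 3 genes to fit the mixture")
  v <- as.numeric(v_means); ht <- as.numeric(ht_means); f <- as.numeric(f_means)

  est <- function(v, ht, f) {
    switch(method,
           ols = .fit_ols(v, ht, f),
           grid = .fit_grid(v, ht, f, grid_a, grid_b, grid_step),
           tls = .fit_tls(v, ht, f))
  }
  ab <- est(v, ht, f)
  norm2 <- v^2 + ht^2 + f^2
  r <- (f - ab[1] * v - ab[2] * ht) / sqrt(norm2)
  fit <- list(a = ab[1], b = ab[2], method = method,
              sse = sum(r^2), n_genes = n)
  if (n_boot > 0) {
    set.seed(seed)
    boots <- matrix(NA_real_, n_boot, 2)
    for (i in seq_len(n_boot)) {
      idx <- sample.int(n, n, replace = TRUE)
      boots[i, ] <- tryCatch(est(v[idx], ht[idx], f[idx]),
                             error = function(e) c(NA_real_, NA_real_))
    }
    fit$bootstrap_ci_a <- unname(stats::quantile(boots[, 1], c(0.025, 0.975),
                                                 na.rm = TRUE))
    fit$bootstrap_ci_b <- unname(stats::quantile(boots[, 2], c(0.025, 0.975),
                                                 na.rm = TRUE))
    fit$n_boot <- n_boot
    fit$seed <- seed
  }
  class(fit) <- "MixtureFit"
  fit
}

.fit_ols <- function(v, ht, f) {
  X <- cbind(V = v, Ht = ht)
  qr_x <- qr(X)
  if (qr_x$rank < 2)
    stop("singular fit: V and Ht columns are collinear")
  unname(qr.coef(qr_x, f))
}

# Exhaustive lattice search on the weighted-residual objective. The
# objective is quadratic in (a, b), so it is evaluated on the full lattice
# from six sufficient statistics rather than by looping over genes.
.fit_grid <- function(v, ht, f, grid_a, grid_b, grid_step) {
  w <- 1 / (v^2 + ht^2 + f^2)
  if (any(!is.finite(w))) stop("gene with V = Ht = F = 0: weight undefined")
  s_vv <- sum(w * v * v); s_hh <- sum(w * ht * ht); s_vh <- sum(w * v * ht)
  s_vf <- sum(w * v * f); s_hf <- sum(w * ht * f); s_ff <- sum(w * f * f)
  a_seq <- seq(grid_a[1], grid_a[2], by = grid_step)
  b_seq <- seq(grid_b[1], grid_b[2], by = grid_step)
  # SSE(a,b) = s_ff + a^2 s_vv + b^2 s_hh + 2ab s_vh - 2a s_vf - 2b s_hf
  sse <- outer(a_seq^2 * s_vv - 2 * a_seq * s_vf,
               b_seq^2 * s_hh - 2 * b_seq * s_hf, "+") +
    2 * outer(a_seq, b_seq) * s_vh + s_ff
  best <- arrayInd(which.min(sse), dim(sse))
  c(a_seq[best[1]], b_seq[best[2]])
}

# Orthogonal regression through the origin on norm-scaled gene vectors:
# the smallest-eigenvalue direction of the scaled points' scatter defines
# the plane u . (V, Ht, F) = 0, giving F = -(u1/u3) V - (u2/u3) Ht.
.fit_tls <- function(v, ht, f) {
  norm <- sqrt(v^2 + ht^2 + f^2)
  if (any(norm == 0)) stop("gene with V = Ht = F = 0: norm undefined")
  X <- cbind(v, ht, f) / norm
  e <- eigen(crossprod(X), symmetric = TRUE)
  u <- e$vectors[, 3]
  if (abs(u[3]) < sqrt(.Machine$double.eps))
    stop("singular fit: plane normal orthogonal to the F axis")
  c(-u[1] / u[3], -u[2] / u[3])
}

#' @export
print.MixtureFit <- function(x, ...) {
  cat(sprintf("MixtureFit (%s): a = %.4f, b = %.4f, sse = %.4g, n = %d\n",
              x$method, x$a, x$b, x$sse, x$n_genes))
  if (!is.null(x$n_boot))
    cat(sprintf("  bootstrap 95%% CI (n_boot = %d): a [%.4f, %.4f], b [%.4f, %.4f]\n",
                x$n_boot, x$bootstrap_ci_a[1], x$bootstrap_ci_a[2],
                x$bootstrap_ci_b[1], x$bootstrap_ci_b[2]))
  invisible(x)
}

#' Weighted residuals of the mixing model
#'
#' For each gene computes the predicted filament signal
#' `F_calc = a*V + b*Ht` and the weighted residual
#' `r = (F - F_calc) / sqrt(V^2 + Ht^2 + F^2)`: the raw residual divided by
#' the Euclidean length of the gene's (V, Ht, F) vector in three-dimensional
#' space, i.e. the deviation as a proportion of the gene's overall
#' transcript level. Large positive residuals flag transcripts
#' under-represented in the isolated cell fractions relative to filaments
#' (the degradation signature); genes with V = Ht = F = 0 have an undefined
#' norm and are excluded with a warning.
#'
#' @param fit a `MixtureFit` (or any list with elements `a` and `b`).
#' @param v_means,ht_means,f_means aligned per-gene replicate means.
#' @param gene_ids optional gene ids; defaults to names of `f_means` or a
#'   running index.
#' @return data frame of `ResidualRecord`s: `gene_id`, `f_mean`, `v_mean`,
#'   `ht_mean`, `f_calc`, `vector_norm`, `r`, and `rank` (1-based by |r|
#'   descending, ties broken by gene id).
#' @export
weighted_residuals <- function(fit, v_means, ht_means, f_means,
                               gene_ids = NULL) {
  n <- length(f_means)
  if (length(v_means) != n || length(ht_means) != n)
    stop("mean vectors must be aligned by gene")
  if (is.null(gene_ids))
    gene_ids <- if (!is.null(names(f_means))) names(f_means) else
      sprintf("gene_%d", seq_len(n))
  v <- as.numeric(v_means); ht <- as.numeric(ht_means); f <- as.numeric(f_means)
  norm <- sqrt(v^2 + ht^2 + f^2)
  bad <- norm == 0
  if (any(bad)) {
    warning("excluding ", sum(bad), " gene(s) with V = Ht = F = 0: ",
            paste(gene_ids[bad], collapse = ", "))
    v <- v[!bad]; ht <- ht[!bad]; f <- f[!bad]
    norm <- norm[!bad]; gene_ids <- gene_ids[!bad]
  }
  f_calc <- fit$a * v + fit$b * ht
  r <- (f - f_calc) / norm
  rec <- data.frame(
    gene_id = gene_ids, f_mean = f, v_mean = v, ht_mean = ht,
    f_calc = f_calc, vector_norm = norm, r = r,
    stringsAsFactors = FALSE
  )
  ord <- order(-abs(rec$r), rec$gene_id)
  rec$rank <- NA_integer_
  rec$rank[ord] <- seq_len(nrow(rec))
  rec
}

#' Rank outlier genes by weighted residual
#'
#' Orders genes by their weighted residual and returns the top k: the
#' points farthest from the plane `F = a*V + b*Ht`. Direction `f_high`
#' ranks by signed r descending (genes with F >> a*V + b*Ht, the
#' degraded-in-isolation signature), `f_low` by signed r ascending, and
#' `both` by |r| descending. Ties are broken by gene id.
#'
#' @param records data frame from [weighted_residuals()].
#' @param k number of genes to return (0 gives an empty list).
#' @param direction `"both"`, `"f_high"` or `"f_low"`.
#' @return the top-k rows of `records`, re-ranked 1..k.
#' @export
rank_outliers <- function(records, k, direction = c("both", "f_high", "f_low")) {
  direction <- match.arg(direction)
  if (k < 0) stop("k must be >= 0")
  if (nrow(records) == 0) stop("no residual records")
  if (k > nrow(records)) stop("k exceeds the number of records")
  ord <- switch(direction,
    both = order(-abs(records$r), records$gene_id),
    f_high = order(-records$r, records$gene_id),
    f_low = order(records$r, records$gene_id)
  )
  out <- records[ord[seq_len(k)], , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
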