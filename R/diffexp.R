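#' Per-gene group means and fold changes
#'
#' Replicate means of the vegetative (V) and heterocyst (Ht) groups in one
#' condition, plus the fold change of the means (default orientation
#' Ht over V) and its log2. Means below the positivity floor `eps` are
#' clamped to `eps` before taking the ratio and flagged.
#'
#' @param em an [ExpressionMatrix].
#' @param condition condition label.
#' @param eps positivity floor, SIU (default 1, below background
#'   resolution).
#' @return data frame: `gene_id`, `v_mean`, `ht_mean`, `fold`
#'   (ht_mean / v_mean after clamping), `log2fc`, `clamped`.
#' @export
group_means_and_fold <- function(em, condition, eps = 1) {
  v_cols <- sample_columns(em, condition = condition, sample_type = "V")
  ht_cols <- sample_columns(em, condition = condition, sample_type = "Ht")
  if (length(v_cols) < 2 || length(ht_cols) < 2)
    stop("need at least 2 V and 2 Ht replicates for condition '",
         condition, "'")
  v_mean <- rowMeans(em$values[, v_cols, drop = FALSE])
  ht_mean <- rowMeans(em$values[, ht_cols, drop = FALSE])
  v_c <- pmax(v_mean, eps)
  ht_c <- pmax(ht_mean, eps)
  data.frame(
    gene_id = em$genes$gene_id,
    v_mean = v_mean, ht_mean = ht_mean,
    fold = ht_c / v_c, log2fc = log2(ht_c / v_c),
    clamped = v_mean < eps | ht_mean < eps,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Welch's unequal-variance t-test
#'
#' Two-tailed t-test with unequal variances (Welch) between two replicate
#' groups, by default on log2-transformed signals (variance stabilization
#' for multiplicative noise). Degenerate inputs follow fixed conventions:
#' two constant equal groups give p = 1, constant groups with unequal means
#' give p = 0, both with a warning.
#'
#' @param group1,group2 numeric replicate signals, at least 2 values each.
#' @param log_transform test on log2 signals (default `TRUE`); raw-scale
#'   values must then be positive.
#' @return list with `t_stat`, `df` (Welch--Satterthwaite) and two-tailed
#'   `p`.
#' @examples
#' welch_test(c(10, 12, 11), c(20, 22, 21), log_transform = FALSE)
#' @export
welch_test <- function(group1, group2, log_transform = TRUE) {
  if (length(group1) < 2 || length(group2) < 2)
    stop("need at least 2 values per group")
  x <- as.numeric(group1); y <- as.numeric(group2)
  if (log_transform) {
    if (any(x <= 0) || any(y <= 0))
      stop("log transform requires positive signals")
    x <- log2(x); y <- log2(y)
  }
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (mean(x) == mean(y)) {
      warning("both groups constant and equal; p = 1 by convention")
      return(list(t_stat = 0, df = NA_real_, p = 1))
    }
    warning("zero variance with unequal means; p = 0 limit")
    return(list(t_stat = sign(mean(x) - mean(y)) * Inf, df = NA_real_, p = 0))
  }
  tt <- stats::t.test(x, y, var.equal = FALSE, alternative = "two.sided")
  list(t_stat = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value)
}

#' Volcano classification of differential-expression records
#'
#' Classifies each gene as `up_in_Ht` (fold Ht/V strictly above the
#' threshold and p strictly below alpha), `up_in_V` (the mirror condition)
#' or `ns`, and counts genes per direction. The classes are mutually
#' exclusive. The thresholds default to the study's criterion of more than
#' a 2-fold difference with p < 0.01 (raw p: no multiplicity correction
#' drives the classification).
#'
#' @param de_records data frame with columns `fold` (Ht over V) and `p`,
#'   e.g. from [de_table()].
#' @param fold_threshold fold-change threshold (strict, default 2).
#' @param alpha p-value threshold (strict, default 0.01).
#' @return list with `records` (input plus `volcano_class`) and `counts`
#'   (named vector `up_in_Ht`, `up_in_V`).
#' @export
volcano_classify <- function(de_records, fold_threshold = 2, alpha = 0.01) {
  if (nrow(de_records) == 0) {
    de_records$volcano_class <- character(0)
    return(list(records = de_records,
                counts = c(up_in_Ht = 0L, up_in_V = 0L)))
  }
  up_ht <- de_records$fold > fold_threshold & de_records$p < alpha
  up_v <- de_records$fold < 1 / fold_threshold & de_records$p < alpha
  cls <- rep("ns", nrow(de_records))
  cls[up_ht] <- "up_in_Ht"
  cls[up_v] <- "up_in_V"
  de_records$volcano_class <- cls
  list(records = de_records,
       counts = c(up_in_Ht = sum(up_ht), up_in_V = sum(up_v)))
}

#' Full differential-expression table for one condition
#'
#' Combines [group_means_and_fold()], per-gene [welch_test()]s and
#' [volcano_classify()] into one table, and adds an informational
#' Benjamini--Hochberg FDR column (`fdr`) that never drives the
#' classification.
#'
#' @param em an [ExpressionMatrix].
#' @param condition condition label.
#' @param fold_threshold,alpha see [volcano_classify()].
#' @param log_transform see [welch_test()].
#' @param eps see [group_means_and_fold()].
#' @return list with `records` (gene_id, v_mean, ht_mean, fold, log2fc,
#'   t_stat, df, p, fdr, volcano_class) and `counts`.
#' @export
de_table <- function(em, condition, fold_threshold = 2, alpha = 0.01,
                     log_transform = TRUE, eps = 1) {
  base <- group_means_and_fold(em, condition, eps = eps)
  v_cols <- sample_columns(em, condition = condition, sample_type = "V")
  ht_cols <- sample_columns(em, condition = condition, sample_type = "Ht")
  vm <- em$values[, v_cols, drop = FALSE]
  hm <- em$values[, ht_cols, drop = FALSE]
  n <- nrow(base)
  t_stat <- df <- p <- numeric(n)
  n_degenerate <- 0L
  for (i in seq_len(n)) {
    w <- withCallingHandlers(
      welch_test(hm[i, ], vm[i, ], log_transform = log_transform),
      warning = function(cnd) {
        n_degenerate <<- n_degenerate + 1L
        invokeRestart("muffleWarning")
      }
    )
    t_stat[i] <- w$t_stat; df[i] <- w$df; p[i] <- w$p
  }
  if (n_degenerate > 0)
    warning(n_degenerate, " gene(s) with degenerate (constant) replicate ",
            "groups; conventional p-values assigned")
  base$t_stat <- t_stat; base$df <- df; base$p <- p
  base$fdr <- stats::p.adjust(p, method = "BH")
  out <- volcano_classify(base, fold_threshold = fold_threshold, alpha = alpha)
  out$records <- out$records[, c("gene_id", "v_mean", "ht_mean", "fold",
                                 "log2fc", "t_stat", "df", "p", "fdr",
                                 "volcano_class")]
  out
}

#' Volcano plot coordinates
#'
#' Exports the (log2 fold change, -log10 p) pairs used for volcano plots.
#'
#' @param de_records records from [de_table()].
#' @return data frame: `gene_id`, `log2fc`, `neg_log10_p`, `volcano_class`.
#' @export
volcano_coordinates <- function(de_records) {
  data.frame(
    gene_id = de_records$gene_id,
    log2fc = de_records$log2fc,
    neg_log10_p = -log10(pmax(de_records$p, .Machine$double.xmin)),
    volcano_class = de_records$volcano_class,
    stringsAsFactors = FALSE
  )
}
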