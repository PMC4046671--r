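#' Sample-level principal component analysis
#'
#' PCA with samples as observations and genes as variables (gene-centered;
#' gene-scaled when `scale_genes` is set). Scores and loadings come from the
#' singular value decomposition of the centered data. The sign of each
#' component is fixed so that its largest-magnitude loading entry is
#' positive, making outputs deterministic.
#'
#' @param em an [ExpressionMatrix] with at least 2 samples.
#' @param k number of components, at most `min(genes, samples)`.
#' @param scale_genes divide each gene by its standard deviation.
#' @return a `PCAResult` list: `scores` (samples x k), `loadings`
#'   (genes x k), `variance_explained` (fractions, non-increasing).
#' @export
pca_samples <- function(em, k = 2, scale_genes = FALSE) {
  vals <- if (is.matrix(em)) em else em$values
  if (ncol(vals) < 2) stop("need at least 2 samples")
  if (k > min(dim(vals))) stop("k exceeds min(genes, samples)")
  x <- t(vals)  # samples x genes
  if (all(apply(x, 2, stats::sd) == 0))
    stop("constant matrix: no variance to decompose")
  if (scale_genes) {
    sds <- apply(x, 2, stats::sd)
    if (any(sds == 0)) stop("cannot scale zero-variance genes")
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = scale_genes)
  k_use <- min(k, ncol(pc$rotation))
  scores <- pc$x[, seq_len(k_use), drop = FALSE]
  loadings <- pc$rotation[, seq_len(k_use), drop = FALSE]
  # deterministic sign: largest |loading| entry positive per component
  for (j in seq_len(k_use)) {
    i_max <- which.max(abs(loadings[, j]))
    if (loadings[i_max, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  structure(
    list(scores = scores, loadings = loadings,
         variance_explained = ve[seq_len(k_use)]),
    class = "PCAResult"
  )
}

#' Functional-category transcript-share profile
#'
#' For one sample group (e.g. phototrophic heterocysts), computes each
#' functional category's share of total transcripts: 100 times the sum of
#' its genes' group-mean signals divided by the sum over all genes. Shares
#' sum to 100.
#'
#' @param em an [ExpressionMatrix]; every gene must carry a category.
#' @param condition condition label.
#' @param sample_type sample-type label.
#' @param per_replicate compute one profile per replicate instead of the
#'   replicate-mean profile.
#' @return data frame with `category` and `percent` (plus `replicate` when
#'   `per_replicate`).
#' @export
category_profile <- function(em, condition, sample_type,
                             per_replicate = FALSE) {
  if (anyNA(em$genes$category) || any(!nzchar(em$genes$category)))
    stop("unannotated gene(s): ",
         paste(em$genes$gene_id[is.na(em$genes$category) |
                                  !nzchar(em$genes$category)], collapse = ", "))
  cols <- sample_columns(em, condition = condition, sample_type = sample_type)
  if (!length(cols))
    stop("no samples for ", condition, "/", sample_type)
  one <- function(sig) {
    tot <- tapply(sig, em$genes$category, sum)
    data.frame(category = names(tot),
               percent = 100 * as.numeric(tot) / sum(sig),
               stringsAsFactors = FALSE)
  }
  if (!per_replicate)
    return(one(rowMeans(em$values[, cols, drop = FALSE])))
  out <- lapply(cols, function(j) {
    d <- one(em$values[, j])
    d$replicate <- em$samples$replicate[j]
    d
  })
  do.call(rbind, out)
}

#' The seven-level expression-intensity bin scale
#'
#' Ordered signal-intensity bins used to describe transcription levels:
#' background (<= 150 SIU), just-above-background (151--200), very-low
#' (201--600), low (601--2,000), moderate (2,001--6,000), high
#' (6,001--20,000), very-high (20,001--60,000; values above 60,000 are
#' clamped into this bin). The background / just-above-background
#' distinction is somewhat arbitrary; both labels are emitted and merging
#' is a presentation choice.
#'
#' @return data frame with `label`, `lower`, `upper` (upper bounds
#'   inclusive).
#' @export
bin_scale <- function() {
  data.frame(
    label = c("background", "just-above-background", "very-low", "low",
              "moderate", "high", "very-high"),
    lower = c(0, 151, 201, 601, 2001, 6001, 20001),
    upper = c(150, 200, 600, 2000, 6000, 20000, Inf),
    stringsAsFactors = FALSE
  )
}

#' Classify a signal intensity into an expression bin
#'
#' Total monotone step function on `[0, Inf)`: each value maps to the bin of
#' [bin_scale()] whose range contains it, with bin upper bounds inclusive
#' (150 is background, 151 just-above-background, 2,000 low) and values
#' above 60,000 mapped to very-high.
#'
#' @param value numeric signal intensities, >= 0 (vectorized).
#' @return character vector of bin labels, as an ordered factor.
#' @examples
#' classify_bin(c(0, 150, 151, 601, 20001, 75000))
#' @export
classify_bin <- function(value) {
  if (any(value < 0)) stop("signal intensities must be >= 0")
  scale <- bin_scale()
  idx <- findInterval(value, c(scale$lower[-1], Inf)) + 1L
  factor(scale$label[idx], levels = scale$label, ordered = TRUE)
}

#' Percent-of-maximum transcript level
#'
#' A gene's group-mean signal as a percentage of the maximal group-mean
#' signal over all genes in the same sample group (e.g. "44% of the
#' strongest heterocyst signal").
#'
#' @param em an [ExpressionMatrix].
#' @param gene_id gene of interest.
#' @param condition condition label.
#' @param sample_type sample-type label.
#' @return a single percentage.
#' @export
percent_of_max <- function(em, gene_id, condition, sample_type) {
  i <- match(gene_id, em$genes$gene_id)
  if (is.na(i)) stop("gene '", gene_id, "' not in matrix")
  cols <- sample_columns(em, condition = condition, sample_type = sample_type)
  if (!length(cols)) stop("no samples for ", condition, "/", sample_type)
  means <- rowMeans(em$values[, cols, drop = FALSE])
  if (max(means) == 0) stop("all-zero sample group")
  unname(100 * means[i] / max(means))
}
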