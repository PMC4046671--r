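#' Read an expression table from TSV
#'
#' Reads the canonical tab-separated dialect: a UTF-8 header row with columns
#' `gene_id`, `product`, `category`, followed by one column per sample named
#' by its sample key (`{P|M|H}_{F|V|Ht}_{replicate}`). Values are
#' non-negative signal intensities; missing values are rejected (imputation
#' is out of scope).
#'
#' @param path path to a TSV file.
#' @param sample_map optional named character vector mapping foreign column
#'   headers to canonical sample keys, for files that use other naming.
#' @return an [ExpressionMatrix].
#' @seealso [write_expression_table()]
#' @export
read_expression_table <- function(path, sample_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = NA, na.strings = "NA")
  need <- c("gene_id", "product", "category")
  if (!all(need %in% names(df)))
    stop("header must declare columns: ", paste(need, collapse = ", "))
  sample_cols <- setdiff(names(df), need)
  if (!is.null(sample_map)) {
    hit <- sample_cols %in% names(sample_map)
    sample_cols_keys <- ifelse(hit, sample_map[sample_cols], sample_cols)
  } else {
    sample_cols_keys <- sample_cols
  }
  dup <- df$gene_id[duplicated(df$gene_id)]
  if (length(dup))
    stop("duplicated locus tag(s): ", paste(unique(dup), collapse = ", "))
  samples <- do.call(rbind, lapply(sample_cols_keys, parse_sample_key))
  vals <- as.matrix(df[, sample_cols, drop = FALSE])
  storage.mode(vals) <- "double"
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1, ]
    stop("missing/non-numeric value at row ", bad[1], ", column '",
         sample_cols[bad[2]], "'")
  }
  if (any(vals < 0)) {
    bad <- which(vals < 0, arr.ind = TRUE)[1, ]
    stop("negative value at row ", bad[1], ", column '",
         sample_cols[bad[2]], "'")
  }
  ExpressionMatrix(
    vals,
    genes = data.frame(gene_id = df$gene_id, product = df$product,
                       category = df$category, stringsAsFactors = FALSE),
    samples = samples
  )
}

#' Write an expression table to TSV
#'
#' Inverse of [read_expression_table()]: the written file round-trips to an
#' identical matrix, preserving gene and sample order.
#'
#' @param em an [ExpressionMatrix].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(em, path) {
  validate_expression_matrix(em)
  df <- data.frame(
    gene_id = em$genes$gene_id,
    product = em$genes$product,
    category = em$genes$category,
    stringsAsFactors = FALSE,
    check.names = FALSE
  )
  vals <- as.data.frame(em$values)
  names(vals) <- em$samples$key
  df <- cbind(df, vals)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Quantile-normalize an expression matrix
#'
#' Forces every sample column to share the same value distribution: the value
#' at each rank is replaced by the mean of that rank's order statistics
#' across columns. Tied values within a column receive the mean of the
#' reference quantiles their ranks span, so the transform is deterministic.
#' The operation is idempotent.
#'
#' @param em an [ExpressionMatrix] (or bare numeric matrix) with at least two
#'   sample columns.
#' @return object of the same type with normalized values.
#' @export
quantile_normalize <- function(em) {
  bare <- is.matrix(em)
  vals <- if (bare) em else em$values
  if (ncol(vals) < 2)
    stop("quantile normalization needs at least 2 samples")
  out <- limma::normalizeQuantiles(vals, ties = TRUE)
  dimnames(out) <- dimnames(vals)
  if (bare) return(out)
  em$values <- out
  validate_expression_matrix(em)
  em
}

#' Pairwise sample correlation matrix
#'
#' Computes all pairwise sample-sample correlations, as either the squared
#' Pearson coefficient of determination (R^2, the replicate-reproducibility
#' statistic) or Spearman's rank correlation.
#'
#' @param em an [ExpressionMatrix] with at least two genes.
#' @param statistic `"r2"` (squared Pearson) or `"spearman"`.
#' @return symmetric numeric matrix with sample keys as dimnames and unit
#'   diagonal.
#' @export
correlation_matrix <- function(em, statistic = c("r2", "spearman")) {
  statistic <- match.arg(statistic)
  vals <- if (is.matrix(em)) em else em$values
  if (nrow(vals) < 2) stop("need at least 2 genes to correlate samples")
  sds <- apply(vals, 2, stats::sd)
  if (any(sds == 0))
    stop("zero-variance sample column(s): ",
         paste(colnames(vals)[sds == 0], collapse = ", "))
  if (statistic == "r2") {
    out <- stats::cor(vals, method = "pearson")^2
  } else {
    out <- stats::cor(vals, method = "spearman")
  }
  diag(out) <- 1
  out
}

#' Read a GEO series-matrix text file
#'
#' Minimal loader for the uncompressed `*_series_matrix.txt` dialect: `!`
#' prefixed metadata lines are skipped and the table between
#' `!series_matrix_table_begin` and `!series_matrix_table_end` is read. An
#' optional platform table maps array feature ids to locus tags; sample
#' titles (or a user mapping) supply the canonical sample keys.
#'
#' @param path path to a series-matrix text file.
#' @param id_map optional named character vector mapping feature ids
#'   (`ID_REF`) to locus tags; unmapped features are dropped.
#' @param sample_map named character vector mapping GSM accessions (the table
#'   header) to canonical sample keys. Required when headers are accessions.
#' @return an [ExpressionMatrix] with placeholder annotation.
#' @export
read_geo_series_matrix <- function(path, id_map = NULL, sample_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  beg <- grep("^!series_matrix_table_begin", lines)
  end <- grep("^!series_matrix_table_end", lines)
  if (length(beg) != 1 || length(end) != 1 || end <= beg)
    stop("no series-matrix table found in ", path)
  tab <- lines[(beg + 1):(end - 1)]
  df <- utils::read.delim(text = paste(tab, collapse = "\n"),
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "ID_REF") stop("expected first table column ID_REF")
  ids <- as.character(df$ID_REF)
  vals <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(vals) <- "double"
  if (!is.null(id_map)) {
    keep <- ids %in% names(id_map)
    vals <- vals[keep, , drop = FALSE]
    ids <- unname(id_map[ids[keep]])
  }
  headers <- colnames(vals)
  if (!is.null(sample_map)) {
    miss <- setdiff(headers, names(sample_map))
    if (length(miss))
      stop("sample_map lacks entries for: ", paste(miss, collapse = ", "))
    headers <- unname(sample_map[headers])
  }
  rownames(vals) <- ids
  colnames(vals) <- headers
  ExpressionMatrix(vals)
}
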