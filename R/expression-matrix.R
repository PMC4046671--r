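#' Expression matrix with sample metadata and gene annotation
#'
#' An `ExpressionMatrix` bundles a genes x samples signal-intensity matrix
#' (SIU, signal intensity units) with per-gene annotation (product string and
#' one of sixteen functional categories) and per-sample metadata. Samples are
#' identified by a key of the form `{condition}_{sample_type}_{replicate}`,
#' e.g. `P_V_1` for the first vegetative-cell replicate grown
#' phototrophically. Conditions are `P` (phototrophic), `M` (mixotrophic) and
#' `H` (heterotrophic); sample types are `F` (whole filament), `V`
#' (vegetative cells) and `Ht` (heterocysts).
#'
#' @param values numeric matrix, genes in rows, samples in columns. Row names
#'   are taken as gene ids if `genes` is missing; column names must be
#'   parseable sample keys if `samples` is missing.
#' @param genes data frame with columns `gene_id`, `product`, `category`,
#'   one row per row of `values`.
#' @param samples data frame with columns `key`, `condition`, `sample_type`,
#'   `replicate`, one row per column of `values`.
#' @return an object of class `ExpressionMatrix`.
#' @examples
#' vals <- matrix(100, 2, 2, dimnames = list(c("g1", "g2"), c("P_V_1", "P_V_2")))
#' em <- ExpressionMatrix(vals)
#' dim(em)
#' @export
ExpressionMatrix <- function(values, genes = NULL, samples = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(genes)) {
    if (is.null(rownames(values)))
      stop("`values` must have row names (gene ids) when `genes` is missing")
    genes <- data.frame(
      gene_id = rownames(values),
      product = "unknown",
      category = "Unknown",
      stringsAsFactors = FALSE
    )
  }
  if (is.null(samples)) {
    if (is.null(colnames(values)))
      stop("`values` must have column names (sample keys) when `samples` is missing")
    samples <- do.call(rbind, lapply(colnames(values), parse_sample_key))
  }
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  rownames(genes) <- NULL
  rownames(samples) <- NULL
  rownames(values) <- genes$gene_id
  colnames(values) <- samples$key
  em <- structure(
    list(values = values, genes = genes, samples = samples),
    class = "ExpressionMatrix"
  )
  validate_expression_matrix(em)
  em
}

validate_expression_matrix <- function(em) {
  v <- em$values
  g <- em$genes
  s <- em$samples
  need_g <- c("gene_id", "product", "category")
  if (!all(need_g %in% names(g)))
    stop("gene annotation must have columns: ", paste(need_g, collapse = ", "))
  need_s <- c("key", "condition", "sample_type", "replicate")
  if (!all(need_s %in% names(s)))
    stop("sample metadata must have columns: ", paste(need_s, collapse = ", "))
  if (nrow(g) != nrow(v))
    stop("gene annotation has ", nrow(g), " rows but matrix has ", nrow(v))
  if (nrow(s) != ncol(v))
    stop("sample metadata has ", nrow(s), " rows but matrix has ", ncol(v), " columns")
  dup <- g$gene_id[duplicated(g$gene_id)]
  if (length(dup))
    stop("duplicate gene ids: ", paste(unique(dup), collapse = ", "))
  dup <- s$key[duplicated(s$key)]
  if (length(dup))
    stop("duplicate sample keys: ", paste(unique(dup), collapse = ", "))
  if (anyNA(v) || any(!is.finite(v)))
    stop("expression values must be finite and non-missing")
  if (any(v < 0))
    stop("expression values must be non-negative")
  if (anyNA(g$category) || any(!nzchar(g$category)))
    stop("every gene needs a functional category")
  invisible(em)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat("ExpressionMatrix:", nrow(x$values), "genes x", ncol(x$values), "samples\n")
  cat("conditions:", paste(unique(x$samples$condition), collapse = " "),
      "| sample types:", paste(unique(x$samples$sample_type), collapse = " "), "\n")
  invisible(x)
}

#' @export
`[.ExpressionMatrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$values))
  if (missing(j)) j <- seq_len(ncol(x$values))
  if (is.character(i)) i <- match(i, x$genes$gene_id)
  if (is.character(j)) j <- match(j, x$samples$key)
  ExpressionMatrix(
    x$values[i, j, drop = FALSE],
    genes = x$genes[i, , drop = FALSE],
    samples = x$samples[j, , drop = FALSE]
  )
}

#' Build or parse a sample key
#'
#' Sample keys follow the canonical `{condition}_{sample_type}_{replicate}`
#' naming, e.g. `M_Ht_2`.
#'
#' @param condition one of `P`, `M`, `H`.
#' @param sample_type one of `F`, `V`, `Ht`.
#' @param replicate 1-based replicate index.
#' @return `sample_key()` returns the key string; `parse_sample_key()`
#'   returns a one-row data frame with columns `key`, `condition`,
#'   `sample_type`, `replicate`.
#' @examples
#' sample_key("P", "V", 1)
#' parse_sample_key("P_V_1")
#' @export
sample_key <- function(condition, sample_type, replicate) {
  paste(condition, sample_type, as.integer(replicate), sep = "_")
}

#' @rdname sample_key
#' @param key sample key string to parse.
#' @export
parse_sample_key <- function(key) {
  parts <- strsplit(key, "_", fixed = TRUE)[[1]]
  ok <- length(parts) == 3 &&
    parts[1] %in% c("P", "M", "H") &&
    parts[2] %in% c("F", "V", "Ht") &&
    grepl("^[0-9]+$", parts[3])
  if (!ok)
    stop("unparseable sample key '", key,
         "': expected {P|M|H}_{F|V|Ht}_{replicate}")
  data.frame(
    key = key, condition = parts[1], sample_type = parts[2],
    replicate = as.integer(parts[3]), stringsAsFactors = FALSE
  )
}

#' Select the sample columns of one condition / sample type
#'
#' @param em an [ExpressionMatrix].
#' @param condition condition label, or `NULL` for all.
#' @param sample_type sample-type label, or `NULL` for all.
#' @return integer vector of column indices.
#' @keywords internal
sample_columns <- function(em, condition = NULL, sample_type = NULL) {
  keep <- rep(TRUE, nrow(em$samples))
  if (!is.null(condition)) keep <- keep & em$samples$condition == condition
  if (!is.null(sample_type)) keep <- keep & em$samples$sample_type == sample_type
  which(keep)
}

#' Default functional categories
#'
#' The sixteen functional categories used to annotate genes, including the
#' catch-all `Other` and `Unknown` categories.
#'
#' @return character vector of length 16.
#' @export
functional_categories <- function() {
  c("N2 fixation", "Photosynthesis", "Phycobilisome",
    "CO2 uptake and fixation", "Electron transfer and respiration",
    "Amino acid metabolism", "Carbohydrate metabolism",
    "Lipid and cell envelope", "Cofactor and vitamin biosynthesis",
    "Nucleotide metabolism", "Transcription and translation",
    "Replication and repair", "Transport", "Signal transduction",
    "Other", "Unknown")
}
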