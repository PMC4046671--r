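#' Simulation parameters for a synthetic filament-transcriptome experiment
#'
#' Defines the ground-truth structure the pipeline assumes: two latent
#' cell-type expression profiles (right-skewed, lognormal-like, spanning
#' roughly 50--60,000 SIU), whole-filament samples formed as the linear
#' mixture `F = mix_a * V + mix_b * Ht`, multiplicative lognormal replicate
#' noise with a given coefficient of variation, a background floor, a
#' configurable set of differentially expressed genes, and a configurable
#' set of transcripts degraded specifically in isolated-heterocyst samples
#' (emulating rapid transcript degradation during heterocyst isolation).
#'
#' @param n_genes number of genes.
#' @param conditions character vector of condition labels (subset of
#'   `P`, `M`, `H`). The latent profiles are shared across conditions.
#' @param n_replicates biological replicates per sample type and condition.
#' @param mix_a vegetative-cell weight in the filament mixture (default
#'   0.92, the relative abundance of vegetative cells).
#' @param mix_b heterocyst weight (default 0.08).
#' @param lognormal_meanlog,lognormal_sdlog shape of the baseline log-normal
#'   expression distribution (natural-log scale).
#' @param noise_cv replicate coefficient of variation of the multiplicative
#'   noise (0 = noiseless).
#' @param background_floor minimum reportable signal, SIU.
#' @param de_fraction fraction of genes differentially expressed between the
#'   two cell types (half up in each direction).
#' @param de_log2fc_range interval from which absolute log2 fold changes of
#'   DE genes are drawn uniformly.
#' @param degraded_gene_count number of transcripts degraded in
#'   isolated-heterocyst samples only.
#' @param degradation_factor multiplier in (0, 1] applied to degraded genes'
#'   heterocyst signal; the filament keeps the undegraded contribution.
#' @param saturation_ceiling maximum signal, SIU (scanner saturation);
#'   `NULL` disables the ceiling.
#' @param seed integer seed; same parameters and seed give identical output.
#' @return a `SimulationParams` list, validated.
#' @export
sim_params <- function(n_genes = 4000,
                       conditions = "P",
                       n_replicates = 3,
                       mix_a = 0.92,
                       mix_b = 0.08,
                       lognormal_meanlog = log(500),
                       lognormal_sdlog = 1.2,
                       noise_cv = 0.1,
                       background_floor = 50,
                       de_fraction = 0.1,
                       de_log2fc_range = c(1, 4),
                       degraded_gene_count = 0,
                       degradation_factor = 1,
                       saturation_ceiling = 60000,
                       seed = 1L) {
  p <- list(
    n_genes = n_genes, conditions = conditions, n_replicates = n_replicates,
    mix_a = mix_a, mix_b = mix_b,
    lognormal_meanlog = lognormal_meanlog, lognormal_sdlog = lognormal_sdlog,
    noise_cv = noise_cv, background_floor = background_floor,
    de_fraction = de_fraction, de_log2fc_range = de_log2fc_range,
    degraded_gene_count = degraded_gene_count,
    degradation_factor = degradation_factor,
    saturation_ceiling = saturation_ceiling, seed = as.integer(seed)
  )
  chk <- function(ok, field, msg) if (!ok) stop("invalid `", field, "`: ", msg)
  chk(is.numeric(n_genes) && n_genes >= 1, "n_genes", "must be a positive count")
  chk(all(conditions %in% c("P", "M", "H")), "conditions",
      "labels must be among P, M, H")
  chk(n_replicates >= 1, "n_replicates", "must be a positive count")
  chk(mix_a > 0, "mix_a", "must be > 0")
  chk(mix_b >= 0, "mix_b", "must be >= 0")
  chk(noise_cv >= 0, "noise_cv", "must be >= 0")
  chk(background_floor >= 0, "background_floor", "must be >= 0")
  chk(de_fraction >= 0 && de_fraction <= 1, "de_fraction", "must be in [0, 1]")
  chk(degraded_gene_count >= 0 && degraded_gene_count <= n_genes,
      "degraded_gene_count", "must be in [0, n_genes]")
  chk(degradation_factor > 0 && degradation_factor <= 1,
      "degradation_factor", "must be in (0, 1]")
  chk(is.null(saturation_ceiling) || saturation_ceiling > background_floor,
      "saturation_ceiling", "must exceed background_floor")
  class(p) <- "SimulationParams"
  p
}

#' Degrade selected transcripts
#'
#' Multiplies the listed genes' signals by a degradation factor, leaving all
#' other genes unchanged. Models transcripts targeted for rapid degradation
#' in heterocysts during their isolation from filaments.
#'
#' @param ht_values named numeric vector of per-gene signals.
#' @param gene_ids gene ids to degrade; must exist in `names(ht_values)`.
#' @param factor multiplier in (0, 1].
#' @return the degraded signal vector.
#' @export
degrade_transcripts <- function(ht_values, gene_ids, factor) {
  if (!(factor > 0 && factor <= 1))
    stop("degradation factor must be in (0, 1]")
  unknown <- setdiff(gene_ids, names(ht_values))
  if (length(unknown))
    stop("unknown gene id(s): ", paste(unknown, collapse = ", "))
  ht_values[gene_ids] <- ht_values[gene_ids] * factor
  ht_values
}

#' Draw noisy biological replicates
#'
#' Each replicate is `expected` times multiplicative lognormal noise with
#' unit mean and coefficient of variation `cv` (microarray intensities are
#' positive and right-skewed), clamped below at `floor` and above at
#' `ceiling` when given.
#'
#' @param expected non-negative per-gene expected signals.
#' @param n number of replicates.
#' @param cv coefficient of variation of the noise (>= 0).
#' @param floor background floor, SIU.
#' @param ceiling optional saturation ceiling, SIU.
#' @param seed optional integer seed; `NULL` uses the current RNG stream.
#' @return matrix with `length(expected)` rows and `n` columns.
#' @export
sample_replicates <- function(expected, n, cv, floor = 0, ceiling = NULL,
                              seed = NULL) {
  if (any(expected < 0)) stop("expected signals must be non-negative")
  if (cv < 0) stop("cv must be >= 0")
  if (n < 1) stop("n must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  m <- length(expected)
  if (cv == 0) {
    out <- matrix(rep(expected, n), nrow = m)
  } else {
    sdlog <- sqrt(log(1 + cv^2))
    noise <- matrix(stats::rlnorm(m * n, meanlog = -sdlog^2 / 2, sdlog = sdlog),
                    nrow = m)
    out <- expected * noise
  }
  out <- pmax(out, floor)
  if (!is.null(ceiling)) out <- pmin(out, ceiling)
  rownames(out) <- names(expected)
  out
}

#' Simulate a filament-transcriptome dataset with known ground truth
#'
#' Draws two latent cell-type profiles, plants differential expression and
#' heterocyst-specific degradation, forms whole-filament expectations as
#' `mix_a * V + mix_b * Ht`, and adds replicate noise. Degradation is applied
#' to the isolated-heterocyst samples only, after mixing: the filament keeps
#' the undegraded heterocyst contribution, which is exactly the discrepancy
#' the weighted-residual outlier statistic detects.
#'
#' @param params a [sim_params()] object.
#' @return a list with elements `matrix` (an [ExpressionMatrix]) and `truth`
#'   (a `SyntheticTruth` list: `true_v`, `true_ht` noiseless profiles,
#'   `de_genes` with true log2 fold changes, `degraded_genes`, `mix_a`,
#'   `mix_b`).
#' @examples
#' sim <- simulate_dataset(sim_params(n_genes = 100, seed = 7))
#' dim(sim$matrix)
#' @export
simulate_dataset <- function(params) {
  if (!inherits(params, "SimulationParams"))
    params <- do.call(sim_params, params)
  p <- params
  set.seed(p$seed)
  n <- p$n_genes
  ids <- sprintf("gene_%0*d", max(4, nchar(n)), seq_len(n))

  base <- stats::rlnorm(n, p$lognormal_meanlog, p$lognormal_sdlog)
  base <- pmax(base, p$background_floor)
  if (!is.null(p$saturation_ceiling)) base <- pmin(base, p$saturation_ceiling)
  true_v <- true_ht <- stats::setNames(base, ids)

  # DE genes: half up in V, half up in Ht, keeping normalization plausible
  n_de <- round(p$de_fraction * n)
  de_ids <- character(0)
  de_lfc <- numeric(0)
  if (n_de > 0) {
    de_ids <- sample(ids, n_de)
    mag <- stats::runif(n_de, p$de_log2fc_range[1], p$de_log2fc_range[2])
    up_ht <- seq_len(n_de) <= n_de / 2
    de_lfc <- ifelse(up_ht, mag, -mag)  # log2(Ht/V)
    true_ht[de_ids[up_ht]] <- true_ht[de_ids[up_ht]] * 2^mag[up_ht]
    true_v[de_ids[!up_ht]] <- true_v[de_ids[!up_ht]] * 2^mag[!up_ht]
    names(de_lfc) <- de_ids
  }
  if (!is.null(p$saturation_ceiling)) {
    true_v <- pmin(true_v, p$saturation_ceiling)
    true_ht <- pmin(true_ht, p$saturation_ceiling)
  }

  degraded <- character(0)
  if (p$degraded_gene_count > 0) {
    # degraded transcripts are heterocyst-specific by construction: the
    # degradation-in-isolation phenomenon concerns transcripts strongly
    # upregulated in heterocysts (nif-like), so candidates are the
    # Ht-upregulated DE genes with the largest Ht/V ratio, supplemented by
    # the most Ht-abundant remaining genes if that pool is too small
    ratio <- true_ht / true_v
    cand <- de_ids[de_lfc > 0]
    cand <- cand[order(-ratio[cand], cand)]
    degraded <- utils::head(cand, p$degraded_gene_count)
    if (length(degraded) < p$degraded_gene_count) {
      rest <- setdiff(ids, degraded)
      rest <- rest[order(-true_ht[rest], rest)]
      degraded <- c(degraded,
                    utils::head(rest, p$degraded_gene_count - length(degraded)))
    }
  }

  true_f <- p$mix_a * true_v + p$mix_b * true_ht
  ht_obs <- degrade_transcripts(true_ht, degraded, p$degradation_factor)

  cols <- list()
  meta <- list()
  for (cond in p$conditions) {
    for (st in c("F", "V", "Ht")) {
      expected <- switch(st, F = true_f, V = true_v, Ht = ht_obs)
      reps <- sample_replicates(expected, p$n_replicates, p$noise_cv,
                                floor = p$background_floor,
                                ceiling = p$saturation_ceiling)
      for (r in seq_len(p$n_replicates)) {
        key <- sample_key(cond, st, r)
        cols[[key]] <- reps[, r]
        meta[[key]] <- data.frame(key = key, condition = cond,
                                  sample_type = st, replicate = r,
                                  stringsAsFactors = FALSE)
      }
    }
  }
  vals <- do.call(cbind, cols)
  rownames(vals) <- ids
  genes <- data.frame(
    gene_id = ids,
    product = "simulated protein",
    category = sample(functional_categories(), n, replace = TRUE),
    stringsAsFactors = FALSE
  )
  em <- ExpressionMatrix(vals, genes = genes, samples = do.call(rbind, meta))
  truth <- structure(
    list(true_v = true_v, true_ht = true_ht,
         de_genes = de_lfc, degraded_genes = degraded,
         mix_a = p$mix_a, mix_b = p$mix_b, params = p),
    class = "SyntheticTruth"
  )
  list(matrix = em, truth = truth)
}

#' Write a simulated dataset to disk
#'
#' Writes the expression TSV, a `truth.tsv` table (`gene_id`, `true_v`,
#' `true_ht`, `is_de`, `true_log2fc`, `is_degraded`) and a `params.yaml`
#' run-parameters file.
#'
#' @param sim result of [simulate_dataset()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_simulated_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression_table(sim$matrix, file.path(dir, "expression.tsv"))
  tr <- sim$truth
  ids <- names(tr$true_v)
  truth_df <- data.frame(
    gene_id = ids,
    true_v = unname(tr$true_v),
    true_ht = unname(tr$true_ht),
    is_de = ids %in% names(tr$de_genes),
    true_log2fc = unname(tr$de_genes[ids]),
    is_degraded = ids %in% tr$degraded_genes,
    stringsAsFactors = FALSE
  )
  truth_df$true_log2fc[is.na(truth_df$true_log2fc)] <- 0
  utils::write.table(truth_df, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  p <- tr$params
  p_flat <- lapply(unclass(p), function(x) if (is.null(x)) "null" else x)
  writeLines(
    paste0(names(p_flat), ": ",
           vapply(p_flat, function(x) paste(format(x), collapse = ", "), "")),
    file.path(dir, "params.yaml")
  )
  invisible(dir)
}
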