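#' Fit an RT-qPCR standard curve
#'
#' Least-squares line of threshold cycle (Ct) on log10(input amount) over a
#' dilution series (e.g. pools of 1--250 pg cDNA). A valid assay has a
#' negative slope; the amplification efficiency is `10^(-1/slope) - 1`
#' (1.0 = perfect doubling per cycle, slope -3.3219).
#'
#' @param amounts input amounts (pg), all > 0, at least 3 dilution points.
#' @param cts threshold cycles, aligned with `amounts`.
#' @return a `StandardCurve` list: `slope` (Ct per log10 amount),
#'   `intercept` (Ct at 1 unit amount), `r2`, `amplification_efficiency`.
#' @examples
#' fit_standard_curve(c(1, 10, 100), c(30, 26.678, 23.356))
#' @export
fit_standard_curve <- function(amounts, cts) {
  if (length(amounts) < 3) stop("need at least 3 dilution points")
  if (length(cts) != length(amounts)) stop("amounts and cts must be aligned")
  if (any(amounts <= 0)) stop("amounts must be positive")
  fit <- stats::lm(cts ~ log10(amounts))
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  if (is.na(slope)) stop("degenerate dilution series (single amount)")
  if (slope >= 0)
    stop("invalid assay: standard-curve slope must be negative (got ",
         signif(slope, 4), ")")
  r2 <- suppressWarnings(summary(fit)$r.squared)  # exact fits are legitimate
  structure(
    list(slope = slope, intercept = intercept, r2 = r2,
         amplification_efficiency = 10^(-1 / slope) - 1),
    class = "StandardCurve"
  )
}

#' @export
print.StandardCurve <- function(x, ...) {
  cat(sprintf("StandardCurve: Ct = %.4f + %.4f * log10(amount), R2 = %.4f, efficiency = %.1f%%\n",
              x$intercept, x$slope, x$r2, 100 * x$amplification_efficiency))
  invisible(x)
}

#' Relative quantification from a standard curve
#'
#' Interpolates a quantity from the standard curve,
#' `quantity = 10^((intercept - ct) / |slope|)`, and divides by the
#' reference quantity (the constitutively expressed reference gene, e.g.
#' rnpB, measured in the same sample) to give a normalized relative level.
#'
#' @param ct threshold cycle(s).
#' @param curve a [fit_standard_curve()] result.
#' @param reference_quantity reference-gene quantity from the same sample
#'   (> 0); default 1 returns the raw interpolated quantity.
#' @return relative transcript level(s).
#' @examples
#' curve <- fit_standard_curve(c(1, 10, 100), c(30, 26.678, 23.356))
#' quantify_relative(25, curve)   # 5 cycles below intercept ~ 2^5 = 32 pg
#' @export
quantify_relative <- function(ct, curve, reference_quantity = 1) {
  if (!inherits(curve, "StandardCurve")) stop("curve must be a StandardCurve")
  if (reference_quantity <= 0) stop("reference_quantity must be > 0")
  quantity <- 10^((curve$intercept - ct) / abs(curve$slope))
  quantity / reference_quantity
}

#' Estimate cell specificity of an RNA preparation
#'
#' A marker gene fully specific to the *other* cell type should give no
#' signal in a pure preparation; its observed cross signal, as a percentage
#' of its signal in its home preparation, measures contamination. Cell
#' specificity is 100 minus the cross-signal percentage. Signals must
#' already be normalized to the reference gene; a cross signal exceeding
#' the home signal indicates assay failure and is rejected.
#'
#' @param marker_home_signal marker's reference-normalized signal in its
#'   home cell-type preparation (> 0).
#' @param marker_cross_signal marker's signal in the opposite preparation.
#' @param target_cell_type label of the preparation being assessed
#'   (optional).
#' @param marker_gene marker name (optional).
#' @return a `SpecificityEstimate` list: `target_cell_type`, `marker_gene`,
#'   `cross_signal_percent`, `specificity_percent`.
#' @examples
#' # rbcL signal in heterocyst RNA at 6.9% of vegetative-cell RNA
#' estimate_specificity(1, 0.069)$specificity_percent  # 93.1
#' @export
estimate_specificity <- function(marker_home_signal, marker_cross_signal,
                                 target_cell_type = NA_character_,
                                 marker_gene = NA_character_) {
  if (marker_home_signal <= 0) stop("home signal must be > 0")
  if (marker_cross_signal < 0) stop("cross signal must be >= 0")
  if (marker_cross_signal > marker_home_signal)
    stop("assay failure: cross signal exceeds home signal")
  cross_pct <- 100 * marker_cross_signal / marker_home_signal
  structure(
    list(target_cell_type = target_cell_type, marker_gene = marker_gene,
         cross_signal_percent = cross_pct,
         specificity_percent = 100 - cross_pct),
    class = "SpecificityEstimate"
  )
}

#' Check reference-gene stability across samples
#'
#' The reference gene is assumed constitutively expressed; its Ct values
#' should vary little across samples. Emits a warning (not an error) when
#' the relative Ct range exceeds the tolerance.
#'
#' @param cts reference-gene Ct values across samples.
#' @param tolerance maximal tolerated relative range (default 0.05, i.e.
#'   5%).
#' @return `TRUE` if stable, `FALSE` (with a warning) otherwise.
#' @export
check_reference_stability <- function(cts, tolerance = 0.05) {
  rel_range <- (max(cts) - min(cts)) / mean(cts)
  if (rel_range > tolerance) {
    warning(sprintf(
      "reference-gene Ct varies by %.1f%% (> %.1f%%): constitutive-expression assumption questionable",
      100 * rel_range, 100 * tolerance))
    return(FALSE)
  }
  TRUE
}
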