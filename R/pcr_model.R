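#' Expression level under the exponential qPCR model
#'
#' The quantity of template behind a threshold cycle is `A = I / E^Ct`:
#' `I` is the fluorescence threshold, `E` the per-cycle amplification factor
#' and `Ct` the cycle at which the reaction crosses `I`. Computed in the log
#' domain to stay exact for large Ct.
#'
#' @param ct Ct value(s), cycles.
#' @param efficiency amplification factor `E` (> 1), recycled against `ct`.
#' @param threshold fluorescence threshold `I` (> 0).
#' @return Expression level(s) `A`, strictly decreasing in Ct.
#' @export
expression_from_ct <- function(ct, efficiency, threshold = 1) {
  if (any(!is.finite(efficiency)) || any(efficiency <= 1))
    rs_computation_error("efficiency must be > 1")
  if (!is.numeric(threshold) || any(threshold <= 0))
    rs_computation_error("threshold must be positive")
  exp(log(threshold) - ct * log(efficiency))
}

#' Amplification efficiency from a dilution series
#'
#' Fits mean Ct per dilution against log10 of the relative template
#' concentration (`-log10(dilution factor)`) by least squares and converts
#' the slope with `E = 10^(-1/slope)`. A valid assay has a negative slope
#' (about -3.32 for perfect doubling); a non-negative slope is returned with
#' `valid = FALSE` rather than an error so batch calibrations can proceed.
#'
#' @param series a [dilution_series()].
#' @param per_replicate if `TRUE`, fit all replicate Cts instead of
#'   per-dilution means. With balanced replicates the slope (and hence `E`)
#'   is identical; only the r-squared changes.
#' @return A list of class `EfficiencyFit`: `E`, `slope`, `r_squared`,
#'   `valid`.
#' @export
efficiency_from_dilution <- function(series, per_replicate = FALSE) {
  if (!inherits(series, "DilutionSeries"))
    rs_validation_error("series must be a DilutionSeries")
  if (per_replicate) {
    x <- -log10(series$ct$dilution)
    y <- series$ct$ct
  } else {
    means <- tapply(series$ct$ct, series$ct$dilution, mean)
    x <- -log10(as.numeric(names(means)))
    y <- as.numeric(means)
  }
  if (length(unique(x)) < 2L || stats::var(x) == 0)
    rs_computation_error("zero variance in log10(dilution); cannot fit")
  fit <- stats::lm(y ~ x)
  slope <- unname(stats::coef(fit)[2L])
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - sum(stats::residuals(fit)^2) / sst else NA_real_
  valid <- is.finite(slope) && slope < 0
  if (!valid)
    warning("non-negative dilution slope: invalid assay")
  structure(list(E = 10^(-1 / slope), slope = slope, r_squared = r2,
                 valid = valid),
            class = "EfficiencyFit")
}

#' @export
print.EfficiencyFit <- function(x, ...) {
  cat(sprintf("EfficiencyFit: E = %.4f (slope %.4f, r^2 %.4f)%s\n",
              x$E, x$slope, x$r_squared,
              if (!x$valid) " [INVALID ASSAY]" else ""))
  invisible(x)
}

#' Collapse or pass through replicate Ct values
#'
#' `policy = "mean"` collapses the run-by-replicate grid to one mean Ct per
#' gene/sample pair (the input contract of the comparative delta-Ct and
#' geNorm measures); `policy = "per_replicate"` passes every value through
#' (the Haller measure needs the replicate spread). Note the order of
#' operations matters on the expression scale: the expression of a mean Ct
#' equals the geometric mean of per-replicate expressions only when all
#' replicates agree, because `E^-mean(Ct) = geomean(E^-Ct)` exactly, while
#' an arithmetic mean of expressions does not commute with the Ct mean.
#'
#' @param ct_tbl a [ct_table()].
#' @param policy `"mean"` or `"per_replicate"`.
#' @return A `CtTable`; for `"mean"` each gene/sample pair holds one value
#'   at replicate slot (1, 1).
#' @export
replicate_aggregate <- function(ct_tbl, policy = c("mean", "per_replicate")) {
  policy <- match.arg(policy)
  if (policy == "per_replicate") return(ct_tbl)
  d <- ct_tbl$data
  agg <- stats::aggregate(ct ~ gene + sample, data = d, FUN = mean)
  agg$run <- 1L
  agg$rep <- 1L
  ct_table(agg[c("gene", "sample", "run", "rep", "ct")],
           efficiencies = ct_tbl$efficiencies, groups = ct_tbl$groups,
           threshold = ct_tbl$threshold)
}

#' Mean-Ct matrix of a CtTable
#'
#' @param ct_tbl a [ct_table()].
#' @return Numeric matrix, genes x samples, of per-pair mean Ct.
#' @export
ct_mean_matrix <- function(ct_tbl) {
  genes <- ct_genes(ct_tbl)
  samples <- ct_samples(ct_tbl)
  d <- ct_tbl$data
  m <- tapply(d$ct, list(factor(d$gene, genes), factor(d$sample, samples)),
              mean)
  if (anyNA(m))
    rs_computation_error("missing Ct for some gene/sample pair")
  m
}

#' Expression matrix of a CtTable under the exponential model
#'
#' Collapses replicates to mean Ct per gene/sample and converts with each
#' gene's own efficiency: `A = I / E^Ct`.
#'
#' @param ct_tbl a [ct_table()].
#' @return Numeric matrix, genes x samples, of expression levels `A`.
#' @export
ct_expression_matrix <- function(ct_tbl) {
  m <- ct_mean_matrix(ct_tbl)
  e <- ct_tbl$efficiencies[rownames(m)]
  a <- exp(log(ct_tbl$threshold) - m * log(e))
  dimnames(a) <- dimnames(m)
  a
}
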