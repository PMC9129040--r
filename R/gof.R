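#' Quantile-quantile comparison of two incidence surfaces
#'
#' Compares the statistical distribution of a predicted surface against a
#' reference surface over their shared unmasked cells: paired quantiles at
#' configurable probabilities plus a Kolmogorov-style maximum gap between
#' the two empirical distribution functions. The gap is also expressed
#' relative to the reference interquartile range, the scale the adequacy
#' rule in [select_model()] uses.
#'
#' @param predicted,reference aligned continuous `sgrid`s (or equal-shape
#'   matrices/vectors).
#' @param probs probabilities at which quantile pairs are reported.
#' @return List with `quantiles` (data frame: `prob`, `predicted`,
#'   `reference`), `ks_gap` (max ECDF gap, in `[0, 1]`), `max_quantile_gap`
#'   (largest absolute quantile difference), and `gap_over_iqr` (that gap
#'   over the reference IQR).
#' @export
qq_compare <- function(predicted, reference, probs = seq(0.01, 0.99, 0.01)) {
  pv <- if (is_sgrid(predicted)) predicted$values[!predicted$mask]
        else as.vector(predicted)
  rv <- if (is_sgrid(reference)) reference$values[!reference$mask]
        else as.vector(reference)
  if (is_sgrid(predicted) && is_sgrid(reference)) {
    if (!is_aligned(predicted, reference)) stop("grids are not aligned")
    shared <- !predicted$mask & !reference$mask
    if (!any(shared)) stop("no shared unmasked cells")
    pv <- predicted$values[shared]; rv <- reference$values[shared]
  }
  if (!length(pv) || !length(rv)) stop("no shared unmasked cells")
  qp <- stats::quantile(pv, probs, names = FALSE)
  qr <- stats::quantile(rv, probs, names = FALSE)
  # two-sample Kolmogorov statistic: max ECDF gap over the pooled support
  pool <- sort(unique(c(pv, rv)))
  gap <- max(abs(stats::ecdf(pv)(pool) - stats::ecdf(rv)(pool)))
  iqr <- stats::IQR(rv)
  mqg <- max(abs(qp - qr))
  list(quantiles = data.frame(prob = probs, predicted = qp, reference = qr),
       ks_gap = gap, max_quantile_gap = mqg,
       gap_over_iqr = if (iqr > 0) mqg / iqr else Inf)
}

#' Residual surface and stratified RMSE
#'
#' Cellwise residuals `observed - predicted` (predictions are typically the
#' posterior-median surface) plus the root-mean-square error per stratum
#' (land-cover class, district, or any labelling). Without stratum labels
#' only the global RMSE is returned, with a warning.
#'
#' @param predicted,observed aligned continuous `sgrid`s.
#' @param strata optional stratum labels: a categorical `sgrid` or a
#'   character matrix/vector matching the grids' cells.
#' @return List with `residuals` (`sgrid`), `rmse` (named vector per
#'   stratum) and `global_rmse`.
#' @export
residual_surface <- function(predicted, observed, strata = NULL) {
  stopifnot(is_sgrid(predicted), is_sgrid(observed))
  if (!is_aligned(predicted, observed)) stop("grids are not aligned")
  shared <- !predicted$mask & !observed$mask
  res_vals <- observed$values - predicted$values
  res <- grid_like(observed, res_vals, mask = !shared)
  rv <- res_vals[shared]
  global <- sqrt(mean(rv^2))
  if (is.null(strata)) {
    warning("no stratum labels supplied; returning global RMSE only")
    return(list(residuals = res, rmse = c(global = global),
                global_rmse = global))
  }
  lab <- if (is_sgrid(strata)) strata$labels[strata$values] else strata
  lab <- matrix(lab, nrow(res_vals), ncol(res_vals))[shared]
  rmse <- tapply(rv, lab, function(v) sqrt(mean(v^2)))
  rmse <- stats::setNames(as.numeric(rmse), names(rmse))
  list(residuals = res, rmse = rmse[!is.na(rmse)], global_rmse = global)
}
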