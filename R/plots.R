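#' Trace plots of posterior draws
#'
#' One panel per parameter (up to `max_par`), chains overlaid, for a quick
#' visual check of mixing alongside [gelman_rubin()] and [geweke()].
#'
#' @param x a `posterior_samples`.
#' @param parameters which parameters to show (default: first `max_par`).
#' @param max_par panel cap.
#' @param ... passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.posterior_samples <- function(x, parameters = NULL, max_par = 6, ...) {
  pars <- parameters %||% utils::head(x$par_names, max_par)
  pars <- intersect(pars, x$par_names)
  old <- graphics::par(mfrow = grDevices::n2mfrow(length(pars)),
                       mar = c(2.5, 2.5, 2, 0.5), mgp = c(1.5, 0.5, 0))
  on.exit(graphics::par(old))
  for (p in pars) {
    j <- match(p, x$par_names)
    tr <- sapply(x$chains, function(m) m[, j])
    graphics::matplot(tr, type = "l", lty = 1, xlab = "retained draw",
                      ylab = "", main = p, ...)
  }
  invisible(x)
}

#' Diagnostic plots for a fitted model
#'
#' Residual surface and predicted-vs-observed quantile plot, the two
#' visual checks the selection criteria lean on. Requires the report to
#' have been built with an `observed` layer.
#'
#' @param x a [fit_report()].
#' @param ... unused.
#' @return `x`, invisibly.
#' @export
plot.fit_report <- function(x, ...) {
  if (is.null(x$predicted))
    stop("fit_report was built without an observed layer")
  old <- graphics::par(mfrow = c(1, 2), mar = c(3, 3, 2, 1),
                       mgp = c(1.8, 0.6, 0))
  on.exit(graphics::par(old))
  plot(x$residuals, main = paste0(x$label, ": observed - predicted"))
  qp <- stats::quantile(grid_values(x$predicted), seq(0.01, 0.99, 0.01))
  qo <- stats::quantile(x$residuals$values + x$predicted$values,
                        seq(0.01, 0.99, 0.01), na.rm = TRUE)
  graphics::plot(qo, qp, xlab = "observed quantiles",
                 ylab = "predicted quantiles",
                 main = sprintf("QQ (gap/IQR = %.2f)",
                                x$qq_gap_over_iqr %||% NA))
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}
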