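#' Correlation test corrected for spatial autocorrelation
#'
#' Pearson correlation between two aligned grids with a Clifford-Richardson
#' modified t-test: the variance of the sample correlation is inflated by
#' the sum over spatial lags of the product of the two fields' sample
#' autocorrelations, giving an effective sample size `M` (and effective
#' degrees of freedom `M - 2`) smaller than the number of cells whenever
#' both fields are spatially structured. The autocorrelation products are
#' accumulated over all cell-pair displacement lags up to half the grid
#' extent in each axis.
#'
#' @param x,y aligned continuous `sgrid`s (or plain matrices) with at least
#'   10 shared unmasked cells.
#' @return List with `r` (Pearson correlation), `n` (shared cells),
#'   `effective_df`, and `p` (two-sided, from t with the effective df).
#' @export
spatial_corrected_correlation <- function(x, y) {
  xm <- if (is_sgrid(x)) x else sgrid(as.matrix(x))
  ym <- if (is_sgrid(y)) y else sgrid(as.matrix(y))
  if (!all(dim(xm) == dim(ym)))
    stop("grids are not aligned")
  if (is_sgrid(x) && is_sgrid(y) && !is_aligned(xm, ym))
    stop("grids are not aligned")
  shared <- !xm$mask & !ym$mask
  n <- sum(shared)
  if (n < 10) stop("need at least 10 shared unmasked cells")
  xv <- xm$values; yv <- ym$values
  xv[!shared] <- NA; yv[!shared] <- NA
  if (stats::sd(xv[shared]) == 0 || stats::sd(yv[shared]) == 0)
    stop("correlation undefined for a constant field")
  r <- stats::cor(xv[shared], yv[shared])

  nr <- nrow(xv); nc <- ncol(xv)
  max_dr <- floor(nr / 2); max_dc <- floor(nc / 2)
  cx <- grid_autocorr(xv, shared, max_dr, max_dc)
  cy <- grid_autocorr(yv, shared, max_dr, max_dc)
  npairs <- cx$npairs
  # var(r) ~ (1/n^2) * sum_lags N_lag * rho_x(lag) * rho_y(lag), the zero
  # lag contributing n * 1 * 1
  var_r <- (n + sum(npairs * cx$rho * cy$rho)) / n^2
  M <- max(1 / var_r, 3)  # effective sample size
  eff_df <- M - 2
  tstat <- r * sqrt(eff_df / max(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = eff_df)
  list(r = r, n = n, effective_df = eff_df, p = p)
}

# Sample spatial autocorrelations by displacement lag (dr, dc), pooling
# (dc, -dc) symmetry; returns pair counts and autocorrelations for all
# nonzero lags up to the given extents. (Internal.)
grid_autocorr <- function(v, ok, max_dr, max_dc) {
  mu <- mean(v[ok]); s2 <- stats::var(v[ok])
  vc <- v - mu
  vc[!ok] <- 0
  w <- ok * 1
  nr <- nrow(vc); nc <- ncol(vc)
  rho <- c(); npairs <- c()
  for (dr in 0:max_dr) {
    for (dc in (-max_dc):max_dc) {
      if (dr == 0 && dc <= 0) next  # count each unordered displacement once
      r1 <- seq_len(nr - dr)
      c1 <- if (dc >= 0) seq_len(nc - dc) else (1 - dc):nc
      r2 <- r1 + dr
      c2 <- c1 + dc
      a <- vc[r1, c1, drop = FALSE] * vc[r2, c2, drop = FALSE]
      m <- w[r1, c1, drop = FALSE] * w[r2, c2, drop = FALSE]
      np <- sum(m)
      if (np == 0) next
      rho <- c(rho, sum(a) / (np * s2))
      npairs <- c(npairs, 2 * np)  # both orientations of the displacement
    }
  }
  list(rho = rho, npairs = npairs)
}
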