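#' Aggregate a continuous grid by block summation
#'
#' Coarsens a continuous grid by an integer factor, each output cell holding
#' the sum of its `factor` x `factor` input block. This is the exact upscaling
#' rule for per-cell counts and abundances: the global unmasked total is
#' conserved. Masked cells contribute 0 to their block; a block whose cells
#' are all masked stays masked. Grids whose dimensions are not divisible by
#' `factor` are padded with masked cells on the top/right edge; the padding is
#' recorded in the output's `meta$padded` field.
#'
#' @param g a continuous `sgrid`.
#' @param factor positive integer aggregation factor.
#' @return An `sgrid` with cell size `factor` times coarser.
#' @export
#' @examples
#' g <- sgrid(matrix(1, 10, 10))
#' aggregate_sum(g, 5)$values  # every cell 25
aggregate_sum <- function(g, factor) {
  stopifnot(is_sgrid(g))
  if (g$kind != "continuous")
    stop("aggregation by sum undefined for categories")
  factor <- as.integer(factor)
  if (length(factor) != 1 || is.na(factor) || factor < 1)
    stop("`factor` must be a positive integer")
  if (factor == 1L) return(g)
  p <- pad_to_multiple(g$values, g$mask, factor)
  vals <- p$values
  vals[p$mask] <- 0
  nr <- nrow(vals) %/% factor
  nc <- ncol(vals) %/% factor
  # block sums via two aggregation matrices: out = R v C
  R <- block_indicator(nr, factor)
  C <- block_indicator(nc, factor)
  out_vals <- R %*% vals %*% t(C)
  out_mask <- (R %*% (!p$mask) %*% t(C)) == 0
  out <- sgrid(out_vals, cell_size = g$cell_size * factor, origin = g$origin,
               mask = out_mask, kind = "continuous")
  out$meta$padded <- p$padded
  out
}

# nr_out x (nr_out*f) block indicator matrix
block_indicator <- function(n_out, f) {
  M <- matrix(0, n_out, n_out * f)
  M[cbind(rep(seq_len(n_out), each = f), seq_len(n_out * f))] <- 1
  M
}

pad_to_multiple <- function(values, mask, f) {
  nr <- nrow(values); nc <- ncol(values)
  pr <- (f - nr %% f) %% f
  pc <- (f - nc %% f) %% f
  if (pr == 0 && pc == 0)
    return(list(values = values, mask = mask, padded = c(rows = 0L, cols = 0L)))
  v <- matrix(0, nr + pr, nc + pc)
  m <- matrix(TRUE, nr + pr, nc + pc)
  v[seq_len(nr), seq_len(nc)] <- values
  m[seq_len(nr), seq_len(nc)] <- mask
  list(values = v, mask = m, padded = c(rows = pr, cols = pc))
}

#' Resample a continuous grid by bilinear interpolation
#'
#' Interpolates a continuous grid onto a new geometry. Each output cell value
#' is the bilinear interpolation of the four input cell centres surrounding
#' the output cell centre; masked neighbours are dropped and the remaining
#' weights renormalised, and an output cell with no unmasked neighbour is
#' masked. Output centres outside the input centre lattice are clamped to the
#' edge (nearest-edge extension). Intended for intensive quantities such as
#' incidence rates; totals are not conserved (use [aggregate_sum()] for
#' counts).
#'
#' @param g a continuous `sgrid`.
#' @param target an `sgrid` or [grid_geometry()] list giving the output
#'   geometry.
#' @return An `sgrid` on the target geometry.
#' @export
resample_bilinear <- function(g, target) {
  stopifnot(is_sgrid(g))
  if (g$kind != "continuous")
    stop("bilinear resampling undefined for categorical grids")
  geo <- if (is_sgrid(target)) grid_geometry(target) else target
  if (!all(c("nrow", "ncol", "cell_size", "origin") %in% names(geo)))
    stop("`target` must be an sgrid or a grid_geometry() list")
  if (geo$nrow < 1 || geo$ncol < 1) stop("target geometry has zero cells")

  nr <- nrow(g$values); nc <- ncol(g$values)
  # output cell centres in fractional input row/col units (1-based centres)
  ox <- geo$origin[1] + (seq_len(geo$ncol) - 0.5) * geo$cell_size
  oy <- geo$origin[2] + (seq_len(geo$nrow) - 0.5) * geo$cell_size
  fc <- (ox - g$origin[1]) / g$cell_size + 0.5
  fr <- (oy - g$origin[2]) / g$cell_size + 0.5
  fc <- pmin(pmax(fc, 1), nc)
  fr <- pmin(pmax(fr, 1), nr)

  c0 <- pmin(floor(fc), nc - 1L); c0 <- pmax(c0, 1L); c1 <- c0 + 1L
  r0 <- pmin(floor(fr), nr - 1L); r0 <- pmax(r0, 1L); r1 <- r0 + 1L
  if (nc == 1L) { c0 <- c1 <- rep(1L, length(fc)) }
  if (nr == 1L) { r0 <- r1 <- rep(1L, length(fr)) }
  wc <- if (nc == 1L) rep(0, length(fc)) else fc - c0
  wr <- if (nr == 1L) rep(0, length(fr)) else fr - r0

  # expand to the full output lattice
  R0 <- matrix(r0, geo$nrow, geo$ncol); R1 <- matrix(r1, geo$nrow, geo$ncol)
  C0 <- matrix(c0, geo$nrow, geo$ncol, byrow = TRUE)
  C1 <- matrix(c1, geo$nrow, geo$ncol, byrow = TRUE)
  WR <- matrix(wr, geo$nrow, geo$ncol)
  WC <- matrix(wc, geo$nrow, geo$ncol, byrow = TRUE)

  v <- g$values; v[g$mask] <- 0
  ok <- !g$mask
  idx <- function(R, C) cbind(as.vector(R), as.vector(C))
  w00 <- (1 - WR) * (1 - WC); w01 <- (1 - WR) * WC
  w10 <- WR * (1 - WC);       w11 <- WR * WC
  gv <- function(R, C) matrix(v[idx(R, C)], geo$nrow, geo$ncol)
  gm <- function(R, C) matrix(ok[idx(R, C)], geo$nrow, geo$ncol)
  num <- w00 * gv(R0, C0) * gm(R0, C0) + w01 * gv(R0, C1) * gm(R0, C1) +
         w10 * gv(R1, C0) * gm(R1, C0) + w11 * gv(R1, C1) * gm(R1, C1)
  den <- w00 * gm(R0, C0) + w01 * gm(R0, C1) +
         w10 * gm(R1, C0) + w11 * gm(R1, C1)
  out_mask <- den <= 0
  vals <- ifelse(out_mask, NA_real_, num / pmax(den, .Machine$double.eps))
  sgrid(vals, cell_size = geo$cell_size, origin = geo$origin,
        mask = out_mask, kind = "continuous")
}

#' Upscale a categorical grid by majority vote
#'
#' Coarsens a categorical grid by an integer factor; each output cell takes
#' the modal class of its `factor` x `factor` block, ignoring masked cells.
#' Ties break deterministically to the class earliest in the label set; the
#' number of tied blocks is recorded in `meta$ties`. Fully masked blocks stay
#' masked; non-divisible shapes are padded with masked cells (recorded in
#' `meta$padded`).
#'
#' @param g a categorical `sgrid`.
#' @param factor positive integer upscaling factor.
#' @return A categorical `sgrid` with the same label set.
#' @export
upscale_majority <- function(g, factor) {
  stopifnot(is_sgrid(g))
  if (g$kind != "categorical")
    stop("majority-vote upscaling undefined for continuous grids")
  factor <- as.integer(factor)
  if (length(factor) != 1 || is.na(factor) || factor < 1)
    stop("`factor` must be a positive integer")
  if (factor == 1L) return(g)
  p <- pad_to_multiple(g$values, g$mask, factor)
  nr <- nrow(p$values) %/% factor
  nc <- ncol(p$values) %/% factor
  out <- matrix(NA_integer_, nr, nc)
  ties <- 0L
  nlab <- length(g$labels)
  for (i in seq_len(nr)) {
    ri <- ((i - 1L) * factor + 1L):(i * factor)
    for (j in seq_len(nc)) {
      ci <- ((j - 1L) * factor + 1L):(j * factor)
      codes <- p$values[ri, ci][!p$mask[ri, ci]]
      if (length(codes) == 0) next
      tab <- tabulate(codes, nbins = nlab)
      win <- which(tab == max(tab))
      if (length(win) > 1L) ties <- ties + 1L
      out[i, j] <- win[1L]  # lowest label-set index on ties
    }
  }
  res <- sgrid(out, cell_size = g$cell_size * factor, origin = g$origin,
               mask = is.na(out), kind = "categorical", labels = g$labels)
  res$meta$ties <- ties
  res$meta$padded <- p$padded
  res
}
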