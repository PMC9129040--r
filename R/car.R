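#' Queen-neighbourhood adjacency for a grid
#'
#' Builds the symmetric queen (8-neighbour) adjacency of an `nr` x `nc` grid
#' as an edge list over unique pairs, plus per-cell neighbour counts. Cells
#' are indexed column-major (R matrix order). Interior cells have 8
#' neighbours, edges 5, corners 3.
#'
#' @param nr,nc grid dimensions.
#' @param mask optional logical matrix; masked cells are excluded from the
#'   neighbourhood graph.
#' @return List with `pairs` (2-column matrix of unique neighbour index
#'   pairs), `n_neighbours` (per cell), `n` (number of cells) and `dim`.
#' @export
car_adjacency <- function(nr, nc, mask = NULL) {
  if (nr < 1 || nc < 1) stop("grid dimensions must be positive")
  idx <- matrix(seq_len(nr * nc), nr, nc)
  if (!is.null(mask)) idx[mask] <- NA_integer_
  pairs_list <- list()
  shift <- function(di, dj) {
    ri <- seq_len(nr - abs(di)); ci <- seq_len(nc - abs(dj))
    a <- idx[ri + max(di, 0), ci + max(dj, 0), drop = FALSE]
    b <- idx[ri - min(di, 0), ci - min(dj, 0), drop = FALSE]
    ok <- !is.na(a) & !is.na(b)
    cbind(as.vector(a[ok]), as.vector(b[ok]))
  }
  # unique offsets covering the queen neighbourhood once
  offs <- list(c(1, 0), c(0, 1), c(1, 1), c(1, -1))
  pairs <- do.call(rbind, lapply(offs, function(o) shift(o[1], o[2])))
  nn <- tabulate(c(pairs[, 1], pairs[, 2]), nbins = nr * nc)
  list(pairs = pairs, n_neighbours = nn, n = sum(!is.na(idx)),
       dim = c(nr, nc))
}

#' Intrinsic CAR log density
#'
#' Log density of an intrinsic conditional autoregressive field, in which
#' each cell value is normally distributed about the mean of its queen
#' neighbours: up to the rank-deficiency constant,
#' `((n-1)/2) log(tau) - (tau/2) * sum_(i~j) (rho_i - rho_j)^2` over unique
#' neighbour pairs. The field is improper (constant shifts are unpenalised);
#' identification comes from sum-to-zero centring. With `normalised = TRUE`
#' the exact log density on the sum-to-zero subspace is returned (adds the
#' pseudo-determinant of the structure matrix and the `2*pi` constant, at the
#' cost of an eigendecomposition).
#'
#' @param rho numeric field (vector or matrix, column-major cell order).
#' @param adjacency a [car_adjacency()].
#' @param tau precision (> 0).
#' @param normalised include the constant terms (exact subspace density).
#' @return Log density (a scalar).
#' @export
car_logdensity <- function(rho, adjacency, tau, normalised = FALSE) {
  rho <- as.numeric(rho)
  if (length(rho) != prod(adjacency$dim))
    stop("`rho` length does not match the adjacency grid")
  if (!is.finite(tau) || tau <= 0) stop("`tau` must be > 0")
  pr <- adjacency$pairs
  if (!is.matrix(pr) || ncol(pr) != 2 || any(pr < 1 | pr > length(rho)) ||
      any(pr[, 1] == pr[, 2]) || anyDuplicated(rbind(pr, pr[, 2:1])))
    stop("adjacency is not a symmetric relation over unique pairs")
  quad <- sum((rho[pr[, 1]] - rho[pr[, 2]])^2)
  n <- adjacency$n
  out <- ((n - 1) / 2) * log(tau) - (tau / 2) * quad
  if (normalised) {
    Q <- car_structure_matrix(adjacency)
    ev <- eigen(Q, symmetric = TRUE, only.values = TRUE)$values
    ev <- ev[ev > max(ev) * 1e-10]
    out <- out + 0.5 * sum(log(ev)) - ((n - 1) / 2) * log(2 * pi)
  }
  out
}

# Dense structure matrix D - W of the intrinsic CAR (internal; small grids).
car_structure_matrix <- function(adjacency) {
  n <- prod(adjacency$dim)
  Q <- matrix(0, n, n)
  pr <- adjacency$pairs
  Q[pr] <- -1
  Q[pr[, 2:1]] <- -1
  diag(Q) <- adjacency$n_neighbours
  Q
}

#' Simulate an intrinsic CAR field
#'
#' Draws one realisation of the centred intrinsic CAR field by spectral
#' decomposition of the structure matrix: suitable for the small grids the
#' synthetic scenarios use (the decomposition is dense).
#'
#' @param adjacency a [car_adjacency()].
#' @param tau precision (> 0).
#' @return A numeric matrix with the adjacency's dimensions, summing to ~0.
#' @export
simulate_car <- function(adjacency, tau) {
  if (!is.finite(tau) || tau <= 0) stop("`tau` must be > 0")
  Q <- car_structure_matrix(adjacency)
  e <- eigen(Q, symmetric = TRUE)
  keep <- e$values > max(e$values) * 1e-10
  z <- stats::rnorm(sum(keep), sd = 1 / sqrt(tau * e$values[keep]))
  x <- e$vectors[, keep, drop = FALSE] %*% z
  x <- x - mean(x)
  matrix(x, adjacency$dim[1], adjacency$dim[2])
}
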