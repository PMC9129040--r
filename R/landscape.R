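#' Land-cover label set
#'
#' The five land-cover classes the contact models stratify over, in their
#' canonical order (the order also fixes the majority-vote tie-break).
#' @export
LAND_COVER_CLASSES <- c("agriculture", "degraded", "forest", "tea", "urban")

#' Assemble an aligned grid landscape
#'
#' Bundles the model's input layers — human population density, per-species
#' snake abundance, categorical land cover, and optional observed bite and
#' envenoming counts — after validating that all layers share one geometry,
#' that counts are non-negative integers, that cells with no humans have no
#' cases, and that the land-cover labels are the canonical five classes.
#'
#' @param human_density continuous `sgrid`, people per cell.
#' @param snake_abundance named list of continuous `sgrid`s, one per species,
#'   individuals per cell.
#' @param land_cover categorical `sgrid` over [LAND_COVER_CLASSES].
#' @param bite_counts,envenoming_counts optional count `sgrid`s.
#' @param bite_incidence,envenoming_incidence optional rate `sgrid`s (cases
#'   per person per year); kept as-is, not validated against counts.
#' @return An object of class `landscape`.
#' @export
grid_landscape <- function(human_density, snake_abundance, land_cover,
                           bite_counts = NULL, envenoming_counts = NULL,
                           bite_incidence = NULL, envenoming_incidence = NULL) {
  if (missing(human_density) || !is_sgrid(human_density))
    stop("a human density layer is required")
  if (missing(land_cover) || !is_sgrid(land_cover))
    stop("a land-cover layer is required")
  if (land_cover$kind != "categorical" ||
      !identical(land_cover$labels, LAND_COVER_CLASSES))
    stop("land cover must be categorical over the canonical five classes")
  if (!is.list(snake_abundance) || length(snake_abundance) == 0 ||
      is.null(names(snake_abundance)) || any(names(snake_abundance) == ""))
    stop("`snake_abundance` must be a named list of grids, one per species")
  layers <- c(list(human_density = human_density, land_cover = land_cover),
              snake_abundance,
              list(bite_counts = bite_counts,
                   envenoming_counts = envenoming_counts,
                   bite_incidence = bite_incidence,
                   envenoming_incidence = envenoming_incidence))
  layers <- Filter(Negate(is.null), layers)
  for (nm in names(layers)) {
    if (!is_sgrid(layers[[nm]])) stop("layer `", nm, "` is not an sgrid")
    if (!is_aligned(human_density, layers[[nm]]))
      stop("layer `", nm, "` is not aligned with human density")
  }
  check_nonneg <- function(g, nm) {
    v <- g$values[!g$mask]
    if (any(v < 0)) stop("layer `", nm, "` has negative values")
  }
  check_nonneg(human_density, "human_density")
  for (nm in names(snake_abundance)) check_nonneg(snake_abundance[[nm]], nm)
  check_counts <- function(g, nm) {
    if (is.null(g)) return(invisible())
    check_nonneg(g, nm)
    v <- g$values[!g$mask]
    if (any(abs(v - round(v)) > 1e-8))
      stop("layer `", nm, "` must hold integer counts")
    h <- human_density$values[!g$mask & !human_density$mask]
    vv <- g$values[!g$mask & !human_density$mask]
    if (any(vv > 0 & h == 0))
      stop("layer `", nm, "` has cases in cells with zero humans")
  }
  check_counts(bite_counts, "bite_counts")
  check_counts(envenoming_counts, "envenoming_counts")
  structure(list(
    human_density = human_density,
    snake_abundance = snake_abundance,
    land_cover = land_cover,
    bite_counts = bite_counts,
    envenoming_counts = envenoming_counts,
    bite_incidence = bite_incidence,
    envenoming_incidence = envenoming_incidence
  ), class = "landscape")
}

#' @export
print.landscape <- function(x, ...) {
  d <- dim(x$human_density)
  cat(sprintf("<landscape> %d x %d cells, %d snake species\n",
              d[1], d[2], length(x$snake_abundance)))
  cat("  species:", paste(names(x$snake_abundance), collapse = ", "), "\n")
  opt <- c("bite_counts", "envenoming_counts", "bite_incidence",
           "envenoming_incidence")
  have <- opt[!vapply(x[opt], is.null, logical(1))]
  if (length(have)) cat("  observed layers:", paste(have, collapse = ", "), "\n")
  invisible(x)
}

#' Species listed in a landscape
#' @param landscape a `landscape`.
#' @return Character vector of species names.
#' @export
landscape_species <- function(landscape) names(landscape$snake_abundance)

#' Align raw layers onto a common grid
#'
#' Brings a set of differently gridded layers onto one geometry using the
#' formatting rules of the analysis: extensive layers (counts, abundances,
#' population) are coarsened by block summation, intensive layers (incidence
#' rates) by bilinear resampling, and categorical land cover by majority
#' vote. The target geometry is the human layer's geometry after applying its
#' own rule; every other layer is then converted to it.
#'
#' @param human_density continuous `sgrid` (rule: sum).
#' @param snake_abundance named list of continuous `sgrid`s (rule: sum).
#' @param land_cover categorical `sgrid` (rule: majority).
#' @param factor integer aggregation factor applied to sum/majority layers
#'   (the analysis default, 5, takes 1-unit cells to 5-unit cells).
#' @param bite_counts,envenoming_counts optional count layers (rule: sum).
#' @param bite_incidence,envenoming_incidence optional rate layers (rule:
#'   bilinear onto the target geometry).
#' @return A [grid_landscape()] whose layers are mutually aligned.
#' @export
align_landscape <- function(human_density, snake_abundance, land_cover,
                            factor = 5,
                            bite_counts = NULL, envenoming_counts = NULL,
                            bite_incidence = NULL, envenoming_incidence = NULL) {
  if (missing(human_density)) stop("a human density layer is required")
  if (missing(land_cover)) stop("a land-cover layer is required")
  h <- aggregate_sum(human_density, factor)
  target <- grid_geometry(h)
  agg <- function(g) if (is.null(g)) NULL else {
    out <- aggregate_sum(g, factor)
    if (!is_aligned(h, out)) stop("layer failed to align after aggregation")
    out
  }
  res <- function(g) if (is.null(g)) NULL else resample_bilinear(g, target)
  snakes <- lapply(snake_abundance, agg)
  lc <- upscale_majority(land_cover, factor)
  bc <- agg(bite_counts)
  ec <- agg(envenoming_counts)
  if (!is.null(bc)) bc$values <- round(bc$values)
  if (!is.null(ec)) ec$values <- round(ec$values)
  grid_landscape(h, snakes, lc,
                 bite_counts = bc, envenoming_counts = ec,
                 bite_incidence = res(bite_incidence),
                 envenoming_incidence = res(envenoming_incidence))
}
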