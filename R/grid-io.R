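#' Write a grid to the plain-text CSV dialect
#'
#' Serialises a grid as a CSV with header `x,y,value`, one row per unmasked
#' cell (cell-centre coordinates), plus a JSON sidecar `<path>.json` holding
#' the geometry, the kind, and the label set for categorical grids. The pair
#' round-trips bit-identically through [read_grid()].
#'
#' @param g an `sgrid`.
#' @param path output CSV path; the sidecar is written next to it.
#' @return `path`, invisibly.
#' @export
write_grid <- function(g, path) {
  stopifnot(is_sgrid(g))
  cc <- cell_centres(g)
  keep <- which(!g$mask, arr.ind = TRUE)
  df <- data.frame(x = cc$x[keep[, 2]], y = cc$y[keep[, 1]],
                   value = g$values[keep])
  df <- df[order(df$y, df$x), ]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  side <- list(nrow = nrow(g$values), ncol = ncol(g$values),
               cell_size = g$cell_size, origin = g$origin, kind = g$kind)
  if (!is.null(g$labels)) side$labels <- g$labels
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a grid from the CSV dialect
#'
#' @param path CSV path written by [write_grid()]; expects the JSON sidecar
#'   `<path>.json` next to it.
#' @return An `sgrid`.
#' @export
read_grid <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  df <- utils::read.csv(path)
  vals <- matrix(if (side$kind == "categorical") NA_integer_ else NA_real_,
                 side$nrow, side$ncol)
  j <- round((df$x - side$origin[1]) / side$cell_size + 0.5)
  i <- round((df$y - side$origin[2]) / side$cell_size + 0.5)
  if (any(i < 1 | i > side$nrow | j < 1 | j > side$ncol))
    stop("cell coordinates outside the sidecar geometry")
  vals[cbind(i, j)] <- df$value
  sgrid(vals, cell_size = side$cell_size, origin = side$origin,
        mask = is.na(vals), kind = side$kind,
        labels = if (side$kind == "categorical") side$labels else NULL)
}

#' Write a landscape to a directory
#'
#' One CSV+sidecar pair per layer plus a `landscape.json` manifest naming the
#' layers and species.
#'
#' @param landscape a `landscape`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_landscape <- function(landscape, dir) {
  stopifnot(inherits(landscape, "landscape"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(species = landscape_species(landscape), layers = list())
  wr <- function(g, nm) {
    if (is.null(g)) return(invisible())
    write_grid(g, file.path(dir, paste0(nm, ".csv")))
    manifest$layers[[nm]] <<- paste0(nm, ".csv")
  }
  wr(landscape$human_density, "human_density")
  wr(landscape$land_cover, "land_cover")
  for (sp in landscape_species(landscape))
    wr(landscape$snake_abundance[[sp]], paste0("snake_", sp))
  wr(landscape$bite_counts, "bite_counts")
  wr(landscape$envenoming_counts, "envenoming_counts")
  wr(landscape$bite_incidence, "bite_incidence")
  wr(landscape$envenoming_incidence, "envenoming_incidence")
  jsonlite::write_json(manifest, file.path(dir, "landscape.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a landscape from a directory written by [write_landscape()]
#'
#' @param dir directory holding the layer CSVs and `landscape.json`.
#' @return A `landscape`.
#' @export
read_landscape <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "landscape.json"),
                                  simplifyVector = TRUE)
  rd <- function(nm) {
    f <- manifest$layers[[nm]]
    if (is.null(f)) NULL else read_grid(file.path(dir, f))
  }
  snakes <- lapply(manifest$species, function(sp) rd(paste0("snake_", sp)))
  names(snakes) <- manifest$species
  grid_landscape(rd("human_density"), snakes, rd("land_cover"),
                 bite_counts = rd("bite_counts"),
                 envenoming_counts = rd("envenoming_counts"),
                 bite_incidence = rd("bite_incidence"),
                 envenoming_incidence = rd("envenoming_incidence"))
}
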