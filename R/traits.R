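#' The seven medically relevant species of the reference system
#' @export
SNAKE_SPECIES <- c("B_caeruleus", "B_ceylonicus", "D_russelii", "E_carinatus",
                   "Hypnale_spp", "N_naja", "T_trigonocephalus")

#' Per-species contact-rate traits
#'
#' Builds the trait table the contact-rate decomposition consumes: a
#' contact-rate scale `B_s` (>= 0), an aggressiveness index `A_s` in (0, 1]
#' and an envenoming-severity index `E_s` in (0, 1] per species. The
#' effective weight of a species is `B_s * A_s` at the snakebite stage and
#' `B_s * A_s * E_s` at the envenoming stage.
#'
#' @param species_id character vector of species names.
#' @param B_s non-negative contact-rate scales.
#' @param A_s aggressiveness indices in (0, 1].
#' @param E_s envenoming-severity indices in (0, 1].
#' @return A `data.frame` of class `species_traits`.
#' @export
#' @examples
#' species_traits(c("N_naja", "D_russelii"), B_s = c(2, 1),
#'                A_s = c(0.8, 0.6), E_s = c(0.9, 1))
species_traits <- function(species_id, B_s, A_s, E_s) {
  n <- length(species_id)
  if (anyDuplicated(species_id)) stop("duplicated species_id")
  if (length(B_s) != n || length(A_s) != n || length(E_s) != n)
    stop("trait vectors must match the number of species")
  if (any(!is.finite(B_s)) || any(B_s < 0)) stop("B_s must be >= 0")
  if (any(!is.finite(A_s)) || any(A_s <= 0) || any(A_s > 1))
    stop("A_s must lie in (0, 1]")
  if (any(!is.finite(E_s)) || any(E_s <= 0) || any(E_s > 1))
    stop("E_s must lie in (0, 1]")
  structure(data.frame(species_id = as.character(species_id),
                       B_s = B_s, A_s = A_s, E_s = E_s,
                       stringsAsFactors = FALSE),
            class = c("species_traits", "data.frame"))
}

#' Read species traits from CSV
#'
#' Expects columns `species_id,B_s,A_s,E_s`. The package ships a synthetic
#' placeholder table for the seven reference species at
#' `system.file("extdata", "species_traits_synthetic.csv",
#' package = "snakespill")`; its index values are illustrative, not field
#' estimates.
#'
#' @param path CSV path.
#' @return A [species_traits()] table.
#' @export
read_species_traits <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species_id", "B_s", "A_s", "E_s")
  if (!all(need %in% names(df)))
    stop("traits CSV needs columns ", paste(need, collapse = ", "))
  species_traits(df$species_id, df$B_s, df$A_s, df$E_s)
}

#' Species-decomposed effective snake abundance
#'
#' Collapses per-species abundance layers into the single effective abundance
#' the contact forms consume: `S_t = sum_s w_s * S_s`, with `w_s = B_s * A_s`
#' for the snakebite stage and `w_s = B_s * A_s * E_s` for the envenoming
#' stage.
#'
#' @param snake_abundance named list of aligned continuous `sgrid`s (or plain
#'   matrices) keyed by species.
#' @param traits a [species_traits()] table covering every supplied species.
#' @param stage `"snakebite"` or `"envenoming"`.
#' @return An object of the same type as the inputs (`sgrid` or matrix)
#'   holding `S_t`, non-negative everywhere.
#' @export
effective_abundance <- function(snake_abundance, traits,
                                stage = c("snakebite", "envenoming")) {
  stage <- match.arg(stage)
  stopifnot(inherits(traits, "species_traits"))
  sp <- names(snake_abundance)
  if (is.null(sp)) stop("snake abundance layers must be named by species")
  missing_sp <- setdiff(sp, traits$species_id)
  if (length(missing_sp))
    stop("traits missing for species: ", paste(missing_sp, collapse = ", "))
  w <- species_weights(traits, stage)[sp]
  first <- snake_abundance[[1]]
  as_mat <- function(g) if (is_sgrid(g)) g$values else g
  acc <- as_mat(first) * w[[1]]
  mask <- if (is_sgrid(first)) first$mask else NULL
  for (k in seq_along(sp)[-1]) {
    g <- snake_abundance[[k]]
    m <- as_mat(g)
    if (!all(dim(m) == dim(acc))) stop("species grids are not aligned")
    if (is_sgrid(g) && is_sgrid(first) && !is_aligned(first, g))
      stop("species grids are not aligned")
    acc <- acc + m * w[[k]]
    if (is_sgrid(g)) mask <- mask | g$mask
  }
  if (is_sgrid(first)) grid_like(first, acc, mask = mask) else acc
}

species_weights <- function(traits, stage) {
  w <- traits$B_s * traits$A_s
  if (stage == "envenoming") w <- w * traits$E_s
  stats::setNames(w, traits$species_id)
}
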