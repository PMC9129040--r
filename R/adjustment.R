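#' Human-impact adjustment of snake abundance
#'
#' Humans depress snake abundance; the models absorb that into a strictly
#' positive multiplier `beta(H, l)` of effective snake abundance, stratified
#' by land-cover class `l` (or global). Four functional forms are supported,
#' all exponentials of a polynomial in human density so the multiplier stays
#' positive while its coefficients are free reals:
#'
#' * `linear_H`:      `exp(b0 + b1 * H)`
#' * `H_squared`:     `exp(b0 + b1 * H^2)`
#' * `H_plus_H2`:     `exp(b0 + b1 * H + b2 * H^2)`
#' * `log_H_squared`: `exp(b0 + b1 * log(H + 1)^2)`
#'
#' The log form (the form selected for the reference analysis) uses
#' `log(H + 1)` so that empty cells are finite and evaluate exactly to
#' `exp(b0)`.
#'
#' @param form one of the four names above.
#' @param coefficients a data frame with a `class` column naming land-cover
#'   classes (or the single value `"global"`) and columns `b0`, `b1` (and
#'   `b2` for `H_plus_H2`).
#' @return An object of class `abundance_adjustment`.
#' @export
#' @examples
#' adj <- abundance_adjustment("log_H_squared",
#'   data.frame(class = c("agriculture", "forest"),
#'              b0 = c(-0.2, 0.2), b1 = c(-0.01, -0.03)))
#' abundance_multiplier(1, "agriculture", adj)  # exp(b0): log(1+... )
abundance_adjustment <- function(form = c("linear_H", "H_squared",
                                          "H_plus_H2", "log_H_squared"),
                                 coefficients) {
  form <- match.arg(form)
  if (!is.data.frame(coefficients) || !"class" %in% names(coefficients))
    stop("`coefficients` must be a data frame with a `class` column")
  need <- if (form == "H_plus_H2") c("b0", "b1", "b2") else c("b0", "b1")
  if (!all(need %in% names(coefficients)))
    stop("coefficients need columns ", paste(need, collapse = ", "))
  if (anyDuplicated(coefficients$class)) stop("duplicated coefficient class")
  if (any(!is.finite(as.matrix(coefficients[need]))))
    stop("coefficients must be finite")
  structure(list(form = form,
                 coefficients = coefficients[, c("class", need)],
                 stratified = !identical(coefficients$class, "global")),
            class = "abundance_adjustment")
}

#' Evaluate the human-impact multiplier beta(H, l)
#'
#' @param H human density (people per cell), any shape; must be >= 0.
#' @param land_cover land-cover class labels, recycled against `H` (ignored
#'   for a global adjustment).
#' @param adjustment an [abundance_adjustment()].
#' @return Strictly positive multiplier with the shape of `H`.
#' @export
abundance_multiplier <- function(H, land_cover, adjustment) {
  stopifnot(inherits(adjustment, "abundance_adjustment"))
  Hv <- if (is_sgrid(H)) H$values else H
  if (any(Hv < 0, na.rm = TRUE)) stop("human density must be >= 0")
  co <- adjustment$coefficients
  if (adjustment$stratified) {
    lc <- if (is_sgrid(land_cover)) land_cover$labels[land_cover$values]
          else land_cover
    idx <- match(lc, co$class)
    if (any(is.na(idx) & !is.na(lc)))
      stop("unknown land-cover class: ",
           paste(unique(lc[is.na(idx) & !is.na(lc)]), collapse = ", "))
  } else {
    idx <- rep(1L, length(Hv))
  }
  b0 <- co$b0[idx]; b1 <- co$b1[idx]
  eta <- switch(adjustment$form,
    linear_H      = b0 + b1 * Hv,
    H_squared     = b0 + b1 * Hv^2,
    H_plus_H2     = b0 + b1 * Hv + co$b2[idx] * Hv^2,
    log_H_squared = b0 + b1 * log1p(Hv)^2)
  out <- exp(eta)
  if (is_sgrid(H)) grid_like(H, matrix(out, nrow(Hv), ncol(Hv)),
                             mask = H$mask)
  else if (is.matrix(Hv)) matrix(out, nrow(Hv), ncol(Hv))
  else as.numeric(out)
}
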