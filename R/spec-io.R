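#' Write and read a contact model specification as YAML
#'
#' Serialises the relationship name, its shape parameters, the observation
#' family, the stage, the trait table and the adjustment block. `NA` shape
#' parameters (free, to be estimated) round-trip as nulls tagged free.
#'
#' @param spec a [contact_model_spec()].
#' @param path YAML file path.
#' @return `path`, invisibly.
#' @export
write_contact_spec <- function(spec, path) {
  stopifnot(inherits(spec, "contact_spec"))
  num_or_free <- function(x) {
    if (is.null(x)) NULL else if (is.na(x)) "free" else as.numeric(x)
  }
  out <- list(
    relationship = spec$relationship,
    beta = spec$beta,
    parameters = Filter(Negate(is.null), list(
      p = num_or_free(spec$p), q = num_or_free(spec$q),
      q_h = num_or_free(spec$q_h), q_s = num_or_free(spec$q_s),
      epsilon = num_or_free(spec$epsilon),
      c_half = num_or_free(spec$c_half))),
    asymptote_on = spec$asymptote_on,
    family = spec$family,
    r = if (is.null(spec$r)) NULL else as.list(spec$r),
    stage = spec$stage,
    traits = if (!is.null(spec$traits)) lapply(
      seq_len(nrow(spec$traits)), function(i) as.list(spec$traits[i, ])),
    adjustment = if (!is.null(spec$adjustment)) list(
      form = spec$adjustment$form,
      coefficients = lapply(seq_len(nrow(spec$adjustment$coefficients)),
                            function(i)
                              as.list(spec$adjustment$coefficients[i, ])))
  )
  yaml::write_yaml(Filter(Negate(is.null), out), path)
  invisible(path)
}

#' @rdname write_contact_spec
#' @return For `read_contact_spec()`, a `contact_spec`.
#' @export
read_contact_spec <- function(path) {
  y <- yaml::read_yaml(path)
  free_or_num <- function(x) {
    if (is.null(x)) NULL else if (identical(x, "free")) NA_real_
    else as.numeric(x)
  }
  traits <- if (!is.null(y$traits)) {
    df <- do.call(rbind, lapply(y$traits, as.data.frame))
    species_traits(df$species_id, df$B_s, df$A_s, df$E_s)
  }
  adjustment <- if (!is.null(y$adjustment)) {
    co <- do.call(rbind, lapply(y$adjustment$coefficients, as.data.frame))
    abundance_adjustment(y$adjustment$form, co)
  }
  r <- if (!is.null(y$r)) unlist(y$r)
  pr <- y$parameters %||% list()
  contact_model_spec(y$relationship, beta = y$beta %||% 1,
                     p = free_or_num(pr[["p"]]), q = free_or_num(pr[["q"]]),
                     q_h = free_or_num(pr[["q_h"]]),
                     q_s = free_or_num(pr[["q_s"]]),
                     epsilon = free_or_num(pr[["epsilon"]]),
                     c_half = free_or_num(pr[["c_half"]]),
                     asymptote_on = y$asymptote_on %||% "S",
                     traits = traits, adjustment = adjustment,
                     family = y$family %||% "poisson", r = r,
                     stage = y$stage %||% "snakebite")
}

#' Write a scenario's generating truth to JSON
#'
#' Records every generating parameter of a synthetic scenario — grid shape,
#' field marginals and ranges, land-cover composition, the true contact
#' spec, envenoming model and CAR settings — next to simulated outputs, so
#' recovery experiments can always recompute the forward pass from stored
#' truth.
#'
#' @param cfg a [scenario_config()].
#' @param path JSON path (conventionally `truth.json` in the output dir).
#' @return `path`, invisibly.
#' @export
write_truth <- function(cfg, path) {
  stopifnot(inherits(cfg, "scenario"))
  env <- cfg$env_model
  out <- list(
    grid = list(nrow = cfg$nrow, ncol = cfg$ncol),
    abundance = list(meanlog = cfg$abundance_meanlog,
                     sdlog = cfg$abundance_sdlog,
                     range = cfg$abundance_range),
    human = list(meanlog = cfg$human_meanlog, sdlog = cfg$human_sdlog,
                 range = cfg$human_range, hotspots = cfg$hotspots,
                 hotspot_amp = cfg$hotspot_amp,
                 hotspot_width = cfg$hotspot_width),
    land_cover = list(proportions = as.list(cfg$lc_props),
                      patch = cfg$lc_patch),
    traits = cfg$traits,
    contact = list(relationship = cfg$spec$relationship,
                   beta = cfg$spec$beta, family = cfg$spec$family,
                   r = cfg$spec$r,
                   adjustment = if (!is.null(cfg$spec$adjustment))
                     list(form = cfg$spec$adjustment$form,
                          coefficients = cfg$spec$adjustment$coefficients)),
    envenoming = if (!is.null(env))
      list(B_s = as.list(env$B_s), E_s = as.list(env$E_s),
           B_LC = as.list(env$B_LC)),
    car = list(on = cfg$car_on, tau = cfg$tau),
    seed = cfg$seed)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' Write a fit report as JSON
#'
#' Serialises the selection-relevant scalars (DIC, pD, convergence,
#' adequacy, spatially corrected correlation), the per-parameter posterior
#' summary, and the stratified RMSE table. Grids (residual and predicted
#' surfaces) are written separately through [write_grid()] if a directory
#' is supplied.
#'
#' @param report a [fit_report()].
#' @param path JSON path.
#' @param grids_dir optional directory for the residual/predicted grids.
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(report, path, grids_dir = NULL) {
  stopifnot(inherits(report, "fit_report"))
  out <- list(label = report$label, DIC = report$DIC, pD = report$pD,
              max_rhat = report$max_rhat, converged = report$converged,
              geweke_z = report$geweke_z,
              qq_gap_over_iqr = report$qq_gap_over_iqr,
              correlation = report$correlation,
              correlation_df = report$correlation_df,
              correlation_p = report$correlation_p,
              rmse = if (!is.null(report$rmse)) as.list(report$rmse),
              summary = report$summary)
  jsonlite::write_json(Filter(Negate(is.null), out), path,
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       na = "null")
  if (!is.null(grids_dir)) {
    dir.create(grids_dir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(report$residuals))
      write_grid(report$residuals, file.path(grids_dir, "residuals.csv"))
    if (!is.null(report$predicted))
      write_grid(report$predicted, file.path(grids_dir, "predicted.csv"))
  }
  invisible(path)
}
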