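# Pipeline drivers binding the stages: fit every species, derive niche
# statistics, run the meta-analysis.

#' Fit quantile models for every species in a survey table
#'
#' @param surveys stacked survey data frame (`species_id`, `cell_id`,
#'   `detections`, `n_transects`).
#' @param field temperature field data frame.
#' @param taus quantile levels.
#' @param sd_denominator passed to [standardize_predictors()].
#' @return Named list of `"species_fit"` objects, in survey order.
#' @export
fit_community <- function(surveys, field, taus = c(0.50, 0.75, 0.90, 0.95),
                          sd_denominator = "sample") {
  ids <- unique(surveys$species_id)
  fits <- lapply(ids, function(sid) {
    fit_species(surveys[surveys$species_id == sid, ], field, taus,
                sd_denominator = sd_denominator)
  })
  names(fits) <- ids
  fits
}

#' Pseudo-R-squared matrix across quantile levels
#'
#' Reshapes a model table into the species x quantile-level matrix consumed
#' by [trend_contrast()].
#'
#' @param models model table data frame (see [model_table()]).
#' @return Numeric matrix, rownames species, colnames quantile levels.
#' @export
pseudo_r2_matrix <- function(models) {
  taus <- sort(unique(models$tau))
  ids <- unique(models$species_id)
  mat <- matrix(NA_real_, length(ids), length(taus),
                dimnames = list(ids, format_tau(taus)))
  for (i in seq_len(nrow(models))) {
    mat[as.character(models$species_id[i]),
        format_tau(models$tau[i])] <- models$pseudo_r2[i]
  }
  mat
}

#' Run the full analysis pipeline in memory
#'
#' Applies the species inclusion filter, fits the quantile models, derives
#' the species-parameter table and runs the across-species meta-analysis,
#' following a [pipeline_config()].
#'
#' @param surveys stacked survey data frame.
#' @param field temperature field data frame.
#' @param config a `"pipeline_config"`.
#' @return list with `retained` (species ids), `fits`, `models` (model
#'   table), `params` (species-parameter table), `tmean_tests` and `report`
#'   (a `"meta_report"`).
#' @export
run_pipeline <- function(surveys, field, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  retained <- species_filter(surveys, config$min_cells, config$min_max_freq)
  if (length(retained) == 0L) stop("no species pass the inclusion filter")
  surveys <- surveys[surveys$species_id %in% retained, ]
  fits <- fit_community(surveys, field, config$quantiles)
  models <- model_table(fits)
  params <- niche_table(fits, surveys, field,
                        domain_lo = config$domain[1],
                        domain_hi = config$domain[2])
  regional <- if (is.null(config$regional_mean)) mean(field$temp_c)
              else config$regional_mean
  tm <- per_species_tmean_tests(surveys, field, regional_mean = regional,
                                alpha = config$alpha)
  report <- meta_report(params, regional_mean = regional,
                        pseudo_r2_matrix = pseudo_r2_matrix(models),
                        delta_aic_cutoff = config$delta_aic_cutoff,
                        alpha = config$alpha)
  list(retained = retained, fits = fits, models = models, params = params,
       tmean_tests = tm, report = report)
}
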