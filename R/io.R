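# Delimited-text readers and writers (comma-separated, header row, UTF-8,
# "." decimal) and the pipeline configuration.

#' Read a temperature field table
#'
#' @param path CSV file with columns `cell_id`, `temp_c`.
#' @return Validated temperature field data frame.
#' @export
read_field <- function(path) {
  dat <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "temp_c")
  miss <- setdiff(need, names(dat))
  if (length(miss)) {
    stop(sprintf("field table %s is missing columns: %s", path,
                 paste(miss, collapse = ", ")))
  }
  bad <- which(!is.finite(dat$temp_c))
  if (length(bad)) {
    stop(sprintf("non-finite temperature in %s at row(s) %s", path,
                 paste(utils::head(bad, 5), collapse = ", ")))
  }
  if (anyDuplicated(dat$cell_id)) stop("duplicate cell_id in field table")
  dat
}

#' Read a species survey table
#'
#' @param path CSV file with columns `species_id`, `cell_id`, `detections`,
#'   `n_transects` (an existing `relative_abundance` column is recomputed).
#' @return Validated survey data frame with `relative_abundance`.
#' @export
read_survey <- function(path) {
  dat <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species_id", "cell_id", "detections", "n_transects")
  miss <- setdiff(need, names(dat))
  if (length(miss)) {
    stop(sprintf("survey table %s is missing columns: %s", path,
                 paste(miss, collapse = ", ")))
  }
  bad <- which(!is.finite(dat$detections) |
                 dat$detections != round(dat$detections) |
                 dat$detections < 0)
  if (length(bad)) {
    stop(sprintf("non-integer or negative detections in %s at row(s) %s",
                 path, paste(utils::head(bad, 5), collapse = ", ")))
  }
  bad <- which(dat$detections > dat$n_transects)
  if (length(bad)) {
    stop(sprintf("detections exceed n_transects in %s at row(s) %s", path,
                 paste(utils::head(bad, 5), collapse = ", ")))
  }
  dat$relative_abundance <- dat$detections / dat$n_transects
  dat
}

#' Write pipeline tables
#'
#' Plain CSV writers (no row names, "." decimal) for the interchange tables:
#' temperature field, survey, fitted-model table and species-parameter
#' table.
#'
#' @param x data frame to write.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' Write and read a ground-truth manifest
#'
#' The simulation ground truth (per-species potential-curve coefficients,
#' archetypes and true niche statistics, plus the generating configuration)
#' is stored as YAML.
#'
#' @param community result of [generate_community()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_truth_manifest <- function(community, path) {
  cfg <- community$config
  obj <- list(
    config = unclass(cfg),
    species = lapply(seq_len(nrow(community$manifest)), function(i) {
      as.list(community$manifest[i, ])
    })
  )
  yaml::write_yaml(obj, path, precision = 15L)
  invisible(path)
}

#' @rdname write_truth_manifest
#' @export
read_truth_manifest <- function(path) {
  obj <- yaml::read_yaml(path)
  obj$manifest <- do.call(rbind, lapply(obj$species, as.data.frame))
  obj
}

#' Pipeline configuration
#'
#' Collects every tunable threshold of the analysis with the conventional
#' defaults: quantile levels 0.50/0.75/0.90/0.95, integration domain
#' `[-2, 10]` degrees Celsius, inclusion filters (50 occupied cells, maximum
#' frequency 0.05), model-support cutoff `-2 log(1000)` (printed -13.82),
#' breadth class cutoffs 0.33/0.90, preference class cutoffs 0/5 degrees
#' Celsius, `alpha = 0.05`. The regional mean temperature defaults to the
#' mean of the supplied field and can be pinned (e.g. to 2.55 degrees
#' Celsius for replication against a published species table).
#'
#' @param quantiles quantile levels, strictly inside (0, 1).
#' @param domain integration window, `c(lo, hi)`.
#' @param min_cells,min_max_freq species inclusion filters.
#' @param delta_aic_cutoff model-support cutoff.
#' @param breadth_cutoffs,pref_cutoffs classification boundaries.
#' @param regional_mean fixed regional mean temperature or `NULL` (compute
#'   from the field).
#' @param alpha significance level.
#' @param seed integer seed for simulation stages.
#' @return list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(quantiles = c(0.50, 0.75, 0.90, 0.95),
                            domain = c(-2, 10),
                            min_cells = 50L, min_max_freq = 0.05,
                            delta_aic_cutoff = delta_aic_for_evidence(1000),
                            breadth_cutoffs = c(0.33, 0.90),
                            pref_cutoffs = c(0, 5),
                            regional_mean = NULL,
                            alpha = 0.05, seed = 1L) {
  if (any(quantiles <= 0 | quantiles >= 1)) {
    stop("quantile levels must be strictly between 0 and 1")
  }
  if (is.unsorted(quantiles, strictly = TRUE)) {
    stop("quantile levels must be strictly increasing")
  }
  if (length(domain) != 2 || domain[1] >= domain[2]) {
    stop("domain must be c(lo, hi) with lo < hi")
  }
  structure(
    list(quantiles = quantiles, domain = as.numeric(domain),
         min_cells = as.integer(min_cells), min_max_freq = min_max_freq,
         delta_aic_cutoff = delta_aic_cutoff,
         breadth_cutoffs = breadth_cutoffs, pref_cutoffs = pref_cutoffs,
         regional_mean = regional_mean, alpha = alpha,
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' @rdname pipeline_config
#' @param path YAML file to write to / read from.
#' @param config a `"pipeline_config"`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  obj <- yaml::read_yaml(path)
  do.call(pipeline_config, obj[!vapply(obj, is.null, TRUE)])
}
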