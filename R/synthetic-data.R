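# Synthetic survey generator: wedge-shaped abundance-temperature point
# clouds with known ground truth. The data-generating process is
#   potential(T) = clip(a0 + b0*T + c0*T^2, 0, 1)   (maximum potential abundance)
#   p_cell      = U_cell * potential(T_cell)        (U: unmeasured limiting factors)
#   detections  ~ Binomial(n_transects, p_cell)
# so the upper edge of the point cloud traces the potential curve while most
# points fall below it.

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Generate a per-cell temperature field
#'
#' Draws one mean minimum winter temperature per grid cell. The default
#' uniform distribution over `[-2, 10]` degrees Celsius matches the thermal
#' span used for niche integration; the empirical distribution of a real
#' atlas grid can be substituted by reading a field table instead.
#'
#' @param n_cells number of grid cells (at least 3, so that a quadratic is
#'   identifiable).
#' @param range_lo,range_hi temperature range bounds (degrees Celsius).
#' @param seed optional integer seed; fixing it makes the output
#'   bit-identical across calls.
#' @return data frame with columns `cell_id` (integer) and `temp_c`.
#' @export
generate_temperature_field <- function(n_cells, range_lo = -2, range_hi = 10,
                                       seed = NULL) {
  if (!is.numeric(n_cells) || n_cells < 3) {
    stop("n_cells must be at least 3 (quadratic fit identifiability)")
  }
  if (range_lo >= range_hi) stop("range_lo must be below range_hi")
  n_cells <- as.integer(n_cells)
  temp <- with_seed(seed, stats::runif(n_cells, range_lo, range_hi))
  data.frame(cell_id = seq_len(n_cells), temp_c = temp)
}

#' Define the ground truth for one simulated species
#'
#' The potential-abundance curve is the quadratic
#' `a0 + b0*T + c0*T^2` on the Celsius scale, clipped to `[0, 1]`
#' (probability units). Observed abundance is thinned below the curve by a
#' multiplicative suppression factor representing unmeasured limiting
#' factors.
#'
#' @param species_id species label.
#' @param a0,b0,c0 quadratic coefficients of the potential curve on the
#'   original Celsius scale.
#' @param suppression `"uniform"` (factor drawn per cell from Uniform(0, 1),
#'   the default wedge mechanism) or `"none"` (no thinning; oracle mode).
#' @param n_transects transects per cell (the detection denominator).
#' @return An object of class `"species_truth"`.
#' @export
species_truth <- function(species_id, a0, b0, c0,
                          suppression = c("uniform", "none"),
                          n_transects = 60L) {
  suppression <- match.arg(suppression)
  stopifnot(is.numeric(a0), is.numeric(b0), is.numeric(c0),
            n_transects >= 1)
  structure(
    list(species_id = species_id, a0 = a0, b0 = b0, c0 = c0,
         suppression = suppression, n_transects = as.integer(n_transects)),
    class = "species_truth"
  )
}

#' Potential abundance of a simulated species
#'
#' Evaluates the species' potential-abundance curve, clipped to `[0, 1]`.
#'
#' @param truth a `"species_truth"`.
#' @param temperature numeric vector (degrees Celsius).
#' @return Potential abundance in `[0, 1]`.
#' @export
potential_abundance <- function(truth, temperature) {
  stopifnot(inherits(truth, "species_truth"))
  pmin(pmax(truth$a0 + truth$b0 * temperature + truth$c0 * temperature^2, 0), 1)
}

#' Simulate a detection survey for one species
#'
#' For every cell, the detection probability is the potential abundance at
#' the cell temperature multiplied by a suppression factor, and the number of
#' transects with detection is binomial.
#'
#' @param field temperature field data frame (see
#'   [generate_temperature_field()]).
#' @param truth a `"species_truth"`.
#' @param seed optional integer seed.
#' @return data frame with columns `species_id`, `cell_id`, `detections`,
#'   `n_transects`, `relative_abundance`.
#' @export
generate_species_survey <- function(field, truth, seed = NULL) {
  stopifnot(inherits(truth, "species_truth"), is.data.frame(field),
            nrow(field) >= 1)
  pot <- potential_abundance(truth, field$temp_c)
  if (all(pot <= 0)) {
    stop("degenerate species: potential curve is zero over the whole field")
  }
  n <- nrow(field)
  detections <- with_seed(seed, {
    u <- switch(truth$suppression,
                uniform = stats::runif(n),
                none = rep.int(1, n))
    stats::rbinom(n, size = truth$n_transects, prob = u * pot)
  })
  data.frame(
    species_id = truth$species_id,
    cell_id = field$cell_id,
    detections = detections,
    n_transects = truth$n_transects,
    relative_abundance = detections / truth$n_transects
  )
}

#' Configuration for a simulated community
#'
#' Collects the study conditions for a multi-species simulation: the survey
#' design (1,689 cells, 60 transects per cell, thermal span `[-2, 10]`
#' degrees Celsius by default) and the ranges from which species archetypes
#' are drawn. Archetypes are `"cold"` and `"warm"` hump-shaped species with
#' vertices drawn from `vertex_cold` / `vertex_warm`, and `"flat"`
#' temperature-independent species.
#'
#' @param n_cells,temperature_range,n_transects survey design.
#' @param n_species number of species; archetypes are recycled over
#'   `archetypes` in order.
#' @param archetypes character vector drawn from `"cold"`, `"warm"`,
#'   `"flat"`.
#' @param peak_range range of the peak potential abundance.
#' @param halfwidth_range range of the half-width (degrees Celsius) at which
#'   the hump-shaped potential curve reaches zero.
#' @param vertex_cold,vertex_warm vertex (preferred temperature) ranges for
#'   the two hump-shaped archetypes.
#' @param suppression suppression law applied to every species.
#' @param seed integer seed; the whole community is deterministic given it.
#' @return An object of class `"community_config"` (a validated list).
#' @export
community_config <- function(n_cells = 1689L,
                             temperature_range = c(-2, 10),
                             n_species = 12L,
                             archetypes = c("cold", "warm", "flat"),
                             n_transects = 60L,
                             peak_range = c(0.25, 0.85),
                             halfwidth_range = c(4, 10),
                             vertex_cold = c(-2, 0),
                             vertex_warm = c(5, 9),
                             suppression = "uniform",
                             seed = 1L) {
  stopifnot(n_cells >= 3, n_species >= 1, n_transects >= 1,
            length(temperature_range) == 2,
            temperature_range[1] < temperature_range[2],
            all(archetypes %in% c("cold", "warm", "flat")),
            peak_range[1] > 0, peak_range[2] <= 1)
  structure(
    list(n_cells = as.integer(n_cells),
         temperature_range = as.numeric(temperature_range),
         n_species = as.integer(n_species),
         archetypes = archetypes,
         n_transects = as.integer(n_transects),
         peak_range = peak_range, halfwidth_range = halfwidth_range,
         vertex_cold = vertex_cold, vertex_warm = vertex_warm,
         suppression = suppression, seed = as.integer(seed)),
    class = "community_config"
  )
}

# Draw one species truth for an archetype under a config (RNG already seeded).
draw_truth <- function(config, species_id, archetype) {
  pk <- stats::runif(1, config$peak_range[1], config$peak_range[2])
  if (archetype == "flat") {
    return(species_truth(species_id, a0 = pk, b0 = 0, c0 = 0,
                         suppression = config$suppression,
                         n_transects = config$n_transects))
  }
  v <- switch(archetype,
              cold = stats::runif(1, config$vertex_cold[1], config$vertex_cold[2]),
              warm = stats::runif(1, config$vertex_warm[1], config$vertex_warm[2]))
  w <- stats::runif(1, config$halfwidth_range[1], config$halfwidth_range[2])
  k <- pk / w^2
  # pk - k (T - v)^2 expanded into a0 + b0 T + c0 T^2
  species_truth(species_id, a0 = pk - k * v^2, b0 = 2 * k * v, c0 = -k,
                suppression = config$suppression,
                n_transects = config$n_transects)
}

#' Simulate a whole community
#'
#' Generates one temperature field and, for each species, a ground-truth
#' potential curve and a detection survey. The truth manifest records, per
#' species, the quadratic coefficients and the implied true niche statistics
#' (preferred temperature and thermal breadth of the clipped potential
#' curve over the temperature range).
#'
#' @param config a `"community_config"`.
#' @return list with `field`, `surveys` (one stacked data frame), `truths`
#'   (list of `"species_truth"`), `manifest` (data frame of ground-truth
#'   parameters) and `config`.
#' @export
generate_community <- function(config) {
  stopifnot(inherits(config, "community_config"))
  with_seed(config$seed, {
    field <- generate_temperature_field(
      config$n_cells, config$temperature_range[1], config$temperature_range[2]
    )
    arch <- rep_len(config$archetypes, config$n_species)
    ids <- sprintf("sp%03d", seq_len(config$n_species))
    truths <- vector("list", config$n_species)
    surveys <- vector("list", config$n_species)
    manifest <- vector("list", config$n_species)
    lo <- config$temperature_range[1]
    hi <- config$temperature_range[2]
    for (i in seq_len(config$n_species)) {
      tr <- draw_truth(config, ids[i], arch[i])
      truths[[i]] <- tr
      surveys[[i]] <- generate_species_survey(field, tr)
      manifest[[i]] <- data.frame(
        species_id = ids[i], archetype = arch[i],
        a0 = tr$a0, b0 = tr$b0, c0 = tr$c0,
        suppression = tr$suppression, n_transects = tr$n_transects,
        t_pref_true = true_preferred_temperature(tr, lo, hi),
        t_breadth_true = true_thermal_breadth(tr, lo, hi)
      )
    }
    list(field = field, surveys = do.call(rbind, surveys), truths = truths,
         manifest = do.call(rbind, manifest), config = config)
  })
}

#' True preferred temperature of a simulated species
#'
#' Argmax of the clipped potential curve over the temperature range; for a
#' flat species the range midpoint is returned.
#'
#' @param truth a `"species_truth"`.
#' @param lo,hi temperature range (degrees Celsius).
#' @return Temperature of maximum potential abundance.
#' @export
true_preferred_temperature <- function(truth, lo = -2, hi = 10) {
  if (truth$b0 == 0 && truth$c0 == 0) return((lo + hi) / 2)
  cand <- c(lo, hi)
  if (truth$c0 < 0) {
    v <- -truth$b0 / (2 * truth$c0)
    if (v > lo && v < hi) cand <- c(cand, v)
  }
  cand[which.max(potential_abundance(truth, cand))]
}

#' True thermal breadth of a simulated species
#'
#' Normalized area under the clipped potential curve over the temperature
#' range (numerical quadrature of the clipped quadratic, which may saturate
#' at 1).
#'
#' @inheritParams true_preferred_temperature
#' @return Breadth in `(0, 1]`.
#' @export
true_thermal_breadth <- function(truth, lo = -2, hi = 10) {
  f <- function(t) potential_abundance(truth, t)
  pk <- max(f(seq(lo, hi, length.out = 2001)))
  if (pk <= 0) stop("degenerate species: no positive potential abundance")
  stats::integrate(f, lo, hi, subdivisions = 500L,
                   rel.tol = 1e-9)$value / (pk * (hi - lo))
}
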