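# Thermal-niche statistics derived from the fitted 95%-quantile model and
# the raw survey: preferred temperature (vertex of the fitted curve), mean
# distribution temperature (abundance-weighted mean of occupied-cell
# temperatures) and thermal breadth (normalized area under the fitted curve).

#' Back-transform fitted beta coefficients to the Celsius scale
#'
#' The model is fitted on standardized predictors `z1 = (T - mu1)/sigma1` and
#' `z2 = (T^2 - mu2)/sigma2`; substituting these into
#' `a + b z1 + c z2` gives the curve `alpha + beta T + gamma T^2` with
#' `alpha = a - b mu1/sigma1 - c mu2/sigma2`, `beta = b/sigma1`,
#' `gamma = c/sigma2`.
#'
#' @param model a `"quantile_model"` carrying standardization constants.
#' @return Named numeric vector `alpha`, `beta`, `gamma`.
#' @export
curve_coefficients <- function(model) {
  stopifnot(inherits(model, "quantile_model"))
  std <- model$std
  if (is.null(std)) stop("model carries no standardization constants")
  a <- model$coef[["a"]]; b <- model$coef[["b"]]; c <- model$coef[["c"]]
  c(alpha = a - b * std$mu1 / std$sigma1 - c * std$mu2 / std$sigma2,
    beta = b / std$sigma1,
    gamma = c / std$sigma2)
}

#' Environmental preferred temperature
#'
#' The temperature at which the fitted upper-quantile abundance curve is
#' maximal within the thermal span of the study region, obtained by setting
#' the curve's derivative to zero. When the quadratic opens downward and its
#' vertex lies inside the domain, the vertex is returned unflagged; for
#' monotone or upward-opening fits the maximizing endpoint is returned with
#' `boundary = TRUE`. A fully flat fitted curve returns the domain midpoint
#' with `flat = TRUE`.
#'
#' @param model a `"quantile_model"` (conventionally the `tau = 0.95` fit).
#' @param domain_lo,domain_hi thermal span (degrees Celsius); defaults to the
#'   `[-2, 10]` integration window.
#' @return list with `t_pref`, `boundary` (logical), `flat` (logical).
#' @export
preferred_temperature <- function(model, domain_lo = -2, domain_hi = 10) {
  stopifnot(domain_lo < domain_hi)
  co <- curve_coefficients(model)
  beta <- co[["beta"]]; gamma <- co[["gamma"]]
  if (beta == 0 && gamma == 0) {
    return(list(t_pref = (domain_lo + domain_hi) / 2,
                boundary = FALSE, flat = TRUE))
  }
  if (gamma < 0) {
    v <- -beta / (2 * gamma)
    if (v >= domain_lo && v <= domain_hi) {
      return(list(t_pref = v, boundary = FALSE, flat = FALSE))
    }
  }
  # argmax over the endpoints; exact ties resolved to the colder endpoint
  f <- function(t) co[["alpha"]] + beta * t + gamma * t^2
  t_pref <- if (f(domain_hi) > f(domain_lo)) domain_hi else domain_lo
  list(t_pref = t_pref, boundary = TRUE, flat = FALSE)
}

#' Mean distribution temperature
#'
#' Abundance-weighted mean of cell temperatures over the cells where the
#' species was detected at least once, with weights equal to the relative
#' abundance (frequency of detection). Identical to weighting by raw
#' detection counts when the transect effort is constant.
#'
#' @param survey one species' survey data frame (`cell_id`, `detections`,
#'   `n_transects`).
#' @param field temperature field data frame (`cell_id`, `temp_c`).
#' @return Weighted mean temperature (degrees Celsius).
#' @export
mean_distribution_temperature <- function(survey, field) {
  dat <- merge(survey, field[, c("cell_id", "temp_c")], by = "cell_id")
  occ <- dat[dat$detections >= 1, ]
  if (nrow(occ) == 0L) stop("species has no occupied cells")
  w <- occ$detections / occ$n_transects
  sum(w * occ$temp_c) / sum(w)
}

# Antiderivative of alpha + beta t + gamma t^2.
quad_antideriv <- function(t, alpha, beta, gamma) {
  alpha * t + beta * t^2 / 2 + gamma * t^3 / 3
}

# Exact integral of max(alpha + beta t + gamma t^2, 0) over [lo, hi]:
# piecewise-polynomial integration between the real roots of the quadratic.
quad_positive_integral <- function(alpha, beta, gamma, lo, hi) {
  f <- function(t) alpha + beta * t + gamma * t^2
  F <- function(t) quad_antideriv(t, alpha, beta, gamma)
  cuts <- numeric(0)
  if (gamma == 0) {
    if (beta != 0) cuts <- -alpha / beta
  } else {
    disc <- beta^2 - 4 * gamma * alpha
    if (disc > 0) cuts <- sort((-beta + c(-1, 1) * sqrt(disc)) / (2 * gamma))
  }
  pts <- sort(unique(c(lo, hi, cuts[cuts > lo & cuts < hi])))
  total <- 0
  for (i in seq_len(length(pts) - 1L)) {
    mid <- (pts[i] + pts[i + 1L]) / 2
    if (f(mid) > 0) total <- total + F(pts[i + 1L]) - F(pts[i])
  }
  total
}

#' Thermal breadth
#'
#' Area under the fitted upper-quantile abundance curve over the thermal
#' span, normalized so that every species' maximal predicted abundance is 1
#' and divided by the span width; ranges in `(0, 1]`, with 1 a flat
#' (temperature-independent) response and small values a narrow thermal
#' specialist. By default negative predicted abundances are clipped to zero
#' before integration (abundance cannot be negative); the unclipped signed
#' integral is available for sensitivity checks via `clip = FALSE`.
#'
#' @inheritParams preferred_temperature
#' @param clip clip negative predicted abundances at zero (default `TRUE`).
#' @return Thermal breadth (dimensionless).
#' @export
thermal_breadth <- function(model, domain_lo = -2, domain_hi = 10,
                            clip = TRUE) {
  stopifnot(domain_lo < domain_hi)
  co <- curve_coefficients(model)
  alpha <- co[["alpha"]]; beta <- co[["beta"]]; gamma <- co[["gamma"]]
  f <- function(t) alpha + beta * t + gamma * t^2
  cand <- c(domain_lo, domain_hi)
  if (gamma < 0) {
    v <- -beta / (2 * gamma)
    if (v > domain_lo && v < domain_hi) cand <- c(cand, v)
  }
  a_max <- max(f(cand))
  if (a_max <= 0) {
    stop("fitted curve has no positive predicted abundance on the domain")
  }
  integral <- if (clip) {
    quad_positive_integral(alpha, beta, gamma, domain_lo, domain_hi)
  } else {
    quad_antideriv(domain_hi, alpha, beta, gamma) -
      quad_antideriv(domain_lo, alpha, beta, gamma)
  }
  integral / (a_max * (domain_hi - domain_lo))
}

#' Classify species by thermal breadth and preferred temperature
#'
#' Threshold labels: thermal specialists have breadth below 0.33 and thermal
#' generalists above 0.90; cold-preferring species have a preferred
#' temperature below 0 degrees Celsius and warm-preferring above 5.
#' Inequalities are strict, so boundary values fall in the middle classes.
#'
#' @param params data frame with columns `t_breadth` and `t_pref` (e.g. from
#'   [niche_table()]).
#' @param breadth_cutoffs,pref_cutoffs class boundaries.
#' @return `params` with columns `class_thermal`
#'   (specialist/intermediate/generalist) and `class_pref` (cold/mid/warm).
#' @export
classify_species <- function(params, breadth_cutoffs = c(0.33, 0.90),
                             pref_cutoffs = c(0, 5)) {
  stopifnot(is.data.frame(params),
            all(c("t_breadth", "t_pref") %in% names(params)))
  params$class_thermal <- ifelse(params$t_breadth < breadth_cutoffs[1],
                                 "specialist",
                                 ifelse(params$t_breadth > breadth_cutoffs[2],
                                        "generalist", "intermediate"))
  params$class_pref <- ifelse(params$t_pref < pref_cutoffs[1], "cold",
                              ifelse(params$t_pref > pref_cutoffs[2],
                                     "warm", "mid"))
  params
}

#' Species-parameter table from fitted models
#'
#' Builds one row per species combining the `tau = 0.95` model coefficients
#' and screening statistics with the derived niche statistics, in the layout
#' of a per-species supplementary table: `species_id`, `b`, `c`,
#' `delta_aic`, `pseudo_r2`, `t_pref`, `t_pref_boundary`, `t_mean`,
#' `t_breadth` plus class labels.
#'
#' @param fits list of `"species_fit"` objects (or a model table data frame
#'   as written by the `fit` stage).
#' @param surveys stacked survey data frame for all species.
#' @param field temperature field data frame.
#' @param domain_lo,domain_hi integration window (degrees Celsius).
#' @param tau quantile level whose model defines the niche statistics
#'   (default 0.95).
#' @param clip_breadth passed to [thermal_breadth()].
#' @return Classified species-parameter data frame.
#' @export
niche_table <- function(fits, surveys, field, domain_lo = -2, domain_hi = 10,
                        tau = 0.95, clip_breadth = TRUE) {
  models <- extract_tau_models(fits, tau)
  rows <- lapply(names(models), function(sid) {
    m <- models[[sid]]
    pref <- preferred_temperature(m, domain_lo, domain_hi)
    sv <- surveys[surveys$species_id == sid, ]
    data.frame(
      species_id = sid,
      b = m$coef[["b"]], c = m$coef[["c"]],
      pseudo_r2 = m$pseudo_r2, delta_aic = m$delta_aic,
      model_support = classify_model_support(m$delta_aic),
      t_pref = pref$t_pref, t_pref_boundary = pref$boundary | pref$flat,
      t_mean = mean_distribution_temperature(sv, field),
      t_breadth = thermal_breadth(m, domain_lo, domain_hi,
                                  clip = clip_breadth)
    )
  })
  classify_species(do.call(rbind, rows))
}

# Normalize fits input (list of species_fit or model_table data frame) to a
# named list of quantile_model objects at the requested tau.
extract_tau_models <- function(fits, tau) {
  if (is.data.frame(fits)) {
    sub <- fits[abs(fits$tau - tau) < 1e-9, ]
    if (nrow(sub) == 0L) stop(sprintf("no fitted models at tau = %g", tau))
    out <- lapply(seq_len(nrow(sub)), function(i) model_from_row(sub[i, ]))
    names(out) <- sub$species_id
    return(out)
  }
  if (inherits(fits, "species_fit")) fits <- list(fits)
  key <- format_tau(tau)
  out <- lapply(fits, function(f) {
    m <- f$models[[key]]
    if (is.null(m)) stop(sprintf("species %s has no model at tau = %g",
                                 f$species_id, tau))
    m
  })
  names(out) <- vapply(fits, function(f) as.character(f$species_id), "")
  out
}
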