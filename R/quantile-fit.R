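#' Standardize temperature predictors
#'
#' Builds the two predictors of the quadratic abundance--temperature model:
#' temperature and squared temperature, each standardized to mean 0 and
#' standard deviation 1 so that the fitted coefficients are beta
#' (standardized) coefficients and directly comparable in magnitude. The
#' squared term is standardized from \eqn{T^2} itself, not from the square of
#' the standardized temperature.
#'
#' @param temperatures numeric vector of cell temperatures (degrees Celsius).
#' @param sd_denominator `"sample"` (divisor `n - 1`, the default) or
#'   `"population"` (divisor `n`). Recorded in the output because the
#'   back-transformation of fitted coefficients to the Celsius scale depends
#'   on it.
#' @return An object of class `"std_predictors"`: a list with `z1`, `z2`
#'   (standardized predictors) and the constants `mu1`, `sigma1`, `mu2`,
#'   `sigma2` needed to map fitted curves back to the original scale.
#' @examples
#' sp <- standardize_predictors(c(-1, 0, 1, 3, 7))
#' mean(sp$z1)  # 0
#' sd(sp$z1)    # 1
#' @export
standardize_predictors <- function(temperatures,
                                   sd_denominator = c("sample", "population")) {
  sd_denominator <- match.arg(sd_denominator)
  t <- as.numeric(temperatures)
  if (anyNA(t) || any(!is.finite(t))) {
    stop("temperatures must be finite and non-missing")
  }
  if (length(unique(t)) < 3L) {
    stop("at least 3 distinct temperatures are required to identify a quadratic")
  }
  sdev <- function(v) {
    if (sd_denominator == "sample") stats::sd(v)
    else sqrt(mean((v - mean(v))^2))
  }
  t2 <- t^2
  mu1 <- mean(t); sigma1 <- sdev(t)
  mu2 <- mean(t2); sigma2 <- sdev(t2)
  if (sigma1 <= 0 || sigma2 <= 0) {
    stop("zero variance in temperature or squared temperature; cannot standardize")
  }
  structure(
    list(z1 = (t - mu1) / sigma1, z2 = (t2 - mu2) / sigma2,
         mu1 = mu1, sigma1 = sigma1, mu2 = mu2, sigma2 = sigma2,
         sd_denominator = sd_denominator),
    class = "std_predictors"
  )
}

#' Total pinball (check-function) loss
#'
#' The asymmetric absolute loss whose minimization defines the conditional
#' quantile at level `tau`: residuals above the fitted value are weighted by
#' `tau`, residuals below by `1 - tau`.
#'
#' @param residuals numeric vector of residuals (observed minus fitted).
#' @param tau quantile level, strictly between 0 and 1.
#' @return Total loss, a nonnegative scalar.
#' @examples
#' pinball_loss(c(1, -1), 0.5)   # 1
#' pinball_loss(1, 0.95)         # 0.95
#' @export
pinball_loss <- function(residuals, tau) {
  check_tau(tau)
  r <- as.numeric(residuals)
  sum(r * (tau - (r < 0)))
}

check_tau <- function(tau) {
  if (!is.numeric(tau) || length(tau) != 1L || !is.finite(tau) ||
      tau <= 0 || tau >= 1) {
    stop("tau must be a single number strictly between 0 and 1")
  }
  invisible(tau)
}

# Step length to the boundary along a direction, for interior-point iterates.
# Returns min(1, factor * max feasible step) keeping v + a*dv > 0.
ip_step <- function(v1, dv1, v2, dv2, factor = 0.99995) {
  neg <- dv1 < 0
  a1 <- if (any(neg)) min(-v1[neg] / dv1[neg]) else Inf
  neg <- dv2 < 0
  a2 <- if (any(neg)) min(-v2[neg] / dv2[neg]) else Inf
  min(1, factor * min(a1, a2))
}

# Frisch-Newton interior-point solver for the quantile-regression linear
# program, in its bounded-variable dual form:
#   max y'a  s.t.  X'a = (1 - tau) X'1,  a in [0, 1]^n,
# whose equality multipliers are (minus) the regression coefficients.
# Mehrotra predictor-corrector steps; afterwards the solution is polished to
# an exact LP vertex by refitting the plane through the p observations with
# the smallest absolute residuals (the optimal basis, generically).
rq_fit_ip <- function(X, y, tau, tol = 1e-11, maxit = 200L) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("length of response must match rows of design")
  if (n < p + 1L) stop(sprintf("need at least %d observations for %d parameters", p + 1L, p))
  if (qr(X)$rank < p) stop("design matrix is rank deficient")
  check_tau(tau)

  cc <- -y
  x <- rep.int(1 - tau, n)
  s <- rep.int(tau, n)
  b_eq <- drop(crossprod(X, x))
  nu <- qr.coef(qr(X), cc)
  nu[is.na(nu)] <- 0
  dlt <- cc - drop(X %*% nu)
  shift <- max(1e-3, 0.5 * mean(abs(dlt)))
  z <- pmax(dlt, 0) + shift
  w <- z - dlt
  yscale <- 1 + sum(abs(y))

  solve_kkt <- function(M, rhs) {
    out <- tryCatch(solve(M, rhs), error = function(e) NULL)
    if (is.null(out)) {
      out <- solve(M + diag(1e-10 * max(diag(M)), ncol(M)), rhs)
    }
    out
  }

  for (it in seq_len(maxit)) {
    gap <- sum(x * z) + sum(s * w)
    if (gap < tol * yscale) break
    d <- 1 / (z / x + w / s)
    rp <- b_eq - drop(crossprod(X, x))
    rd <- cc - drop(X %*% nu) - z + w
    M <- crossprod(X, X * d)

    # affine (predictor) direction
    rho <- rd + z - w
    dnu <- solve_kkt(M, rp + drop(crossprod(X, d * rho)))
    dx <- d * (drop(X %*% dnu) - rho)
    dz <- -z - (z / x) * dx
    dw <- -w + (w / s) * dx
    ap <- ip_step(x, dx, s, -dx)
    ad <- ip_step(z, dz, w, dw)
    gap_aff <- sum((x + ap * dx) * (z + ad * dz)) +
      sum((s - ap * dx) * (w + ad * dw))
    mu <- max((gap_aff / gap)^3 * gap / (2 * n), 0)

    # corrector direction with centering
    g1 <- mu / x - z - dx * dz / x
    g2 <- mu / s - w + dx * dw / s
    rho <- rd - g1 + g2
    dnu <- solve_kkt(M, rp + drop(crossprod(X, d * rho)))
    dx <- d * (drop(X %*% dnu) - rho)
    dz <- g1 - (z / x) * dx
    dw <- g2 + (w / s) * dx
    ap <- ip_step(x, dx, s, -dx)
    ad <- ip_step(z, dz, w, dw)

    x <- x + ap * dx
    s <- s - ap * dx
    nu <- nu + ad * dnu
    z <- z + ad * dz
    w <- w + ad * dw
  }

  beta <- -nu
  loss <- pinball_loss(y - drop(X %*% beta), tau)

  # vertex polish: the exact optimum interpolates p observations
  r <- y - drop(X %*% beta)
  m <- min(n, p + 4L)
  cand <- order(abs(r))[seq_len(m)]
  for (idx in utils::combn(cand, p, simplify = FALSE)) {
    B <- X[idx, , drop = FALSE]
    bc <- tryCatch(solve(B, y[idx]), error = function(e) NULL)
    if (is.null(bc)) next
    lc <- pinball_loss(y - drop(X %*% bc), tau)
    if (lc < loss) {
      loss <- lc
      beta <- bc
    }
  }
  list(coefficients = beta, loss = loss, iterations = it)
}

# Exact intercept-only quantile fit: the tau-th sample quantile minimizes the
# pinball loss; the lower order statistic of the minimizing interval is taken.
rq_fit_null <- function(y, tau) {
  check_tau(tau)
  n <- length(y)
  a <- sort(y)[max(1L, ceiling(n * tau))]
  list(coefficients = a, loss = pinball_loss(y - a, tau))
}

#' Fit a quadratic quantile-regression model
#'
#' Minimizes the total pinball loss of `abundance ~ 1 + z1 + z2` at quantile
#' level `tau`. The problem is a convex linear program solved exactly by an
#' interior-point method with a vertex-polish step; the recorded loss is the
#' global minimum.
#'
#' @param z1,z2 standardized temperature and standardized squared temperature
#'   (see [standardize_predictors()]).
#' @param abundance response: relative abundance in `[0, 1]` (any numeric
#'   response is accepted).
#' @param tau quantile level in (0, 1).
#' @param std optional `"std_predictors"` object; its standardization
#'   constants are stored in the model and are required for back-transforming
#'   the fitted curve to the Celsius scale.
#' @return An object of class `"quantile_model"`: coefficients `a` (intercept),
#'   `b` (linear beta), `c` (quadratic beta), the minimized loss `loss`, `tau`,
#'   `n`, `k` and the standardization constants.
#' @seealso [fit_species()] for the per-species driver, [pseudo_r2()],
#'   [delta_aic()] for screening.
#' @export
fit_quantile <- function(z1, z2, abundance, tau, std = NULL) {
  y <- as.numeric(abundance)
  n <- length(y)
  if (length(z1) != n || length(z2) != n) {
    stop("z1, z2 and abundance must have equal length")
  }
  if (n < 4L) stop("need at least 4 observations for the 3-parameter model")
  X <- cbind(intercept = 1, z1 = z1, z2 = z2)
  fit <- rq_fit_ip(X, y, tau)
  new_quantile_model(
    coef = c(a = unname(fit$coefficients[1]), b = unname(fit$coefficients[2]),
             c = unname(fit$coefficients[3])),
    tau = tau, loss = fit$loss, n = n, k = 3L, std = std
  )
}

#' Fit an intercept-only (null) quantile model
#'
#' The null model against which the temperature model is screened: its fitted
#' value is the `tau`-th sample quantile of abundance.
#'
#' @inheritParams fit_quantile
#' @return A `"quantile_model"` with `k = 1`.
#' @export
fit_null <- function(abundance, tau, std = NULL) {
  y <- as.numeric(abundance)
  if (length(y) < 2L) stop("need at least 2 observations")
  fit <- rq_fit_null(y, tau)
  new_quantile_model(
    coef = c(a = fit$coefficients, b = 0, c = 0),
    tau = tau, loss = fit$loss, n = length(y), k = 1L, std = std
  )
}

new_quantile_model <- function(coef, tau, loss, n, k, std = NULL,
                               pseudo_r2 = NA_real_, delta_aic = NA_real_,
                               null_loss = NA_real_) {
  structure(
    list(coef = coef, tau = tau, loss = loss, n = n, k = k,
         std = std, pseudo_r2 = pseudo_r2, delta_aic = delta_aic,
         null_loss = null_loss, aic = quantile_aic_value(loss, n, k)),
    class = "quantile_model"
  )
}

#' @export
print.quantile_model <- function(x, ...) {
  cat(sprintf("Quantile regression model (tau = %g, n = %d, k = %d)\n",
              x$tau, x$n, x$k))
  print(round(x$coef, 6))
  cat(sprintf("pinball loss %.6g; AIC %.6g", x$loss, x$aic))
  if (!is.na(x$pseudo_r2)) cat(sprintf("; pseudo-R2 %.4f", x$pseudo_r2))
  if (!is.na(x$delta_aic)) cat(sprintf("; delta AIC %.2f", x$delta_aic))
  cat("\n")
  invisible(x)
}

#' Predict abundance from a fitted quantile model
#'
#' Evaluates the fitted curve at temperatures on the original Celsius scale,
#' using the standardization constants stored in the model.
#'
#' @param object a `"quantile_model"` with standardization constants.
#' @param temperature numeric vector of temperatures (degrees Celsius).
#' @param ... unused.
#' @return Predicted abundance at each temperature (not clipped to `[0, 1]`).
#' @export
predict.quantile_model <- function(object, temperature, ...) {
  co <- curve_coefficients(object)
  co[["alpha"]] + co[["beta"]] * temperature + co[["gamma"]] * temperature^2
}

#' Koenker--Machado pseudo-R-squared
#'
#' Goodness of fit of a quantile model relative to the intercept-only model at
#' the same quantile: `1 - loss(full) / loss(null)`. Because the null model is
#' nested in the full model, the value lies in `[0, 1]`.
#'
#' @param full,null `"quantile_model"` objects fitted at the same `tau` on the
#'   same data.
#' @return Pseudo-R-squared in `[0, 1]`.
#' @export
pseudo_r2 <- function(full, null) {
  stopifnot(inherits(full, "quantile_model"), inherits(null, "quantile_model"))
  if (full$tau != null$tau || full$n != null$n) {
    stop("full and null models must share tau and data")
  }
  if (null$loss <= 0) {
    stop("null model has zero loss (degenerate response); pseudo-R2 undefined")
  }
  max(0, min(1, 1 - full$loss / null$loss))
}

quantile_aic_value <- function(loss, n, k) {
  if (loss <= 0) return(-Inf)
  2 * k + 2 * n * log(loss / n)
}

#' AIC of a quantile model
#'
#' Information criterion based on the asymmetric-Laplace working likelihood
#' with the scale parameter profiled out: `AIC = 2k + 2n log(V/n)` up to an
#' additive constant that does not depend on the model and therefore cancels
#' in AIC differences. A model with zero loss returns `-Inf` (infinite
#' likelihood sentinel).
#'
#' @param model a `"quantile_model"`.
#' @return AIC value (possibly `-Inf`).
#' @export
aic_quantile <- function(model) {
  stopifnot(inherits(model, "quantile_model"))
  quantile_aic_value(model$loss, model$n, model$k)
}

#' AIC difference between the temperature model and the null model
#'
#' `delta_aic = AIC(full) - AIC(null)`; strongly negative values favour the
#' temperature model. The screening convention treats a model as supported
#' when the difference is at or below `-2 log(1000) = -13.8155` (evidence
#' ratio of 1,000).
#'
#' @inheritParams pseudo_r2
#' @return AIC difference (negative favours the full model).
#' @export
delta_aic <- function(full, null) {
  stopifnot(inherits(full, "quantile_model"), inherits(null, "quantile_model"))
  if (full$tau != null$tau || full$n != null$n) {
    stop("full and null models must share tau and data")
  }
  aic_quantile(full) - aic_quantile(null)
}

#' Evidence ratio for an AIC difference
#'
#' `exp(-delta_aic / 2)`: how many times better the model is than the null in
#' an information-theoretic sense. A difference of `-13.8155` corresponds to
#' an evidence ratio of 1,000.
#'
#' @param delta_aic AIC difference (full minus null).
#' @return Evidence ratio.
#' @export
evidence_ratio <- function(delta_aic) exp(-0.5 * delta_aic)

#' AIC difference corresponding to a given evidence ratio
#'
#' Inverse of [evidence_ratio()]: `-2 log(ratio)`.
#'
#' @param ratio evidence ratio (> 0).
#' @return The AIC difference (negative for ratios above 1).
#' @export
delta_aic_for_evidence <- function(ratio) {
  stopifnot(is.numeric(ratio), all(ratio > 0))
  -2 * log(ratio)
}

#' Classify model support from the AIC difference
#'
#' Three-way screen of the temperature model against the null:
#' `"supported"` at or below the evidence-ratio-1000 cutoff (printed -13.82),
#' `"weak"` between the cutoff and -6, `"unsupported"` above -6.
#'
#' @param delta_aic numeric vector of AIC differences (full minus null).
#' @param cutoff support cutoff (default `-2 log(1000)`).
#' @param weak_cutoff weak-evidence boundary (default -6).
#' @return Character vector of class labels.
#' @export
classify_model_support <- function(delta_aic,
                                   cutoff = delta_aic_for_evidence(1000),
                                   weak_cutoff = -6) {
  ifelse(delta_aic <= cutoff, "supported",
         ifelse(delta_aic <= weak_cutoff, "weak", "unsupported"))
}

#' Fit quantile models for one species at several quantile levels
#'
#' Merges a species survey with the temperature field, standardizes the
#' temperature predictors once over the species' cell set, and fits the full
#' quadratic model and the intercept-only null at each requested quantile.
#' Pseudo-R-squared and the AIC difference against the null are stored in
#' each full model.
#'
#' @param survey data frame with columns `cell_id`, `detections`,
#'   `n_transects` (one species; a `species_id` column, if present, must hold
#'   a single value). `relative_abundance` is recomputed as
#'   `detections / n_transects`.
#' @param field data frame with columns `cell_id`, `temp_c`.
#' @param taus quantile levels; default the four levels 0.50, 0.75, 0.90,
#'   0.95 used for upper-boundary abundance modelling.
#' @param sd_denominator passed to [standardize_predictors()].
#' @return An object of class `"species_fit"`: a list with `species_id`,
#'   `std`, and `models`, a list of `"quantile_model"` objects named by
#'   quantile level.
#' @export
fit_species <- function(survey, field, taus = c(0.50, 0.75, 0.90, 0.95),
                        sd_denominator = "sample") {
  stopifnot(is.data.frame(survey), is.data.frame(field))
  for (tau in taus) check_tau(tau)
  if (anyDuplicated(taus)) stop("duplicate quantile levels")
  sid <- if ("species_id" %in% names(survey)) unique(survey$species_id) else NA
  if (length(sid) != 1L) stop("fit_species expects a single species")
  dat <- merge(survey, field[, c("cell_id", "temp_c")], by = "cell_id")
  if (nrow(dat) < 4L) stop("fewer than 4 cells shared between survey and field")
  y <- dat$detections / dat$n_transects
  std <- standardize_predictors(dat$temp_c, sd_denominator = sd_denominator)
  models <- lapply(taus, function(tau) {
    full <- fit_quantile(std$z1, std$z2, y, tau, std = std)
    null <- fit_null(y, tau, std = std)
    full$null_loss <- null$loss
    full$pseudo_r2 <- pseudo_r2(full, null)
    full$delta_aic <- delta_aic(full, null)
    full
  })
  names(models) <- format_tau(taus)
  structure(list(species_id = sid, std = std, models = models, taus = taus),
            class = "species_fit")
}

format_tau <- function(taus) formatC(taus, format = "g")

#' @export
print.species_fit <- function(x, ...) {
  cat(sprintf("Quantile fits for species %s at %d levels\n",
              as.character(x$species_id), length(x$models)))
  print(model_table(list(x)))
  invisible(x)
}

#' Tabulate fitted quantile models
#'
#' Flattens a list of `"species_fit"` objects into one row per species and
#' quantile level, in the layout written by the `fit` pipeline stage.
#'
#' @param fits list of `"species_fit"` objects (a single object is accepted).
#' @return data frame with columns `species_id`, `tau`, `a`, `b`, `c`,
#'   `loss`, `null_loss`, `pseudo_r2`, `delta_aic`, `n`, and the
#'   standardization constants `mu1`, `sigma1`, `mu2`, `sigma2`.
#' @export
model_table <- function(fits) {
  if (inherits(fits, "species_fit")) fits <- list(fits)
  rows <- lapply(fits, function(f) {
    do.call(rbind, lapply(f$models, function(m) {
      data.frame(species_id = f$species_id, tau = m$tau,
                 a = m$coef[["a"]], b = m$coef[["b"]], c = m$coef[["c"]],
                 loss = m$loss, null_loss = m$null_loss,
                 pseudo_r2 = m$pseudo_r2, delta_aic = m$delta_aic,
                 n = m$n, mu1 = m$std$mu1, sigma1 = m$std$sigma1,
                 mu2 = m$std$mu2, sigma2 = m$std$sigma2)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Rebuild a minimal quantile_model from a model_table row (used by pipeline
# stages that read fitted models back from disk).
model_from_row <- function(row) {
  std <- structure(
    list(z1 = NULL, z2 = NULL, mu1 = row$mu1, sigma1 = row$sigma1,
         mu2 = row$mu2, sigma2 = row$sigma2, sd_denominator = "sample"),
    class = "std_predictors"
  )
  new_quantile_model(
    coef = c(a = row$a, b = row$b, c = row$c),
    tau = row$tau, loss = row$loss, n = row$n, k = 3L, std = std,
    pseudo_r2 = row$pseudo_r2, delta_aic = row$delta_aic,
    null_loss = row$null_loss
  )
}
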