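# Independent oracles used across the suite.

# Exact quantile-regression oracle by vertex enumeration: an optimal solution
# of the pinball-loss LP interpolates p observations (for a design in general
# position), so the global minimum is the best interpolating p-subset.
brute_force_rq_loss <- function(X, y, tau) {
  X <- as.matrix(X)
  p <- ncol(X)
  best <- Inf
  for (idx in utils::combn(nrow(X), p, simplify = FALSE)) {
    B <- X[idx, , drop = FALSE]
    beta <- tryCatch(solve(B, y[idx]), error = function(e) NULL)
    if (is.null(beta)) next
    loss <- pinball_loss(y - drop(X %*% beta), tau)
    if (loss < best) best <- loss
  }
  best
}

# Holm step-down correction, straight from its definition: order the
# p-values, compare the i-th smallest against alpha / (m - i + 1), and stop
# rejecting at the first failure.
brute_force_holm <- function(p, alpha = 0.05) {
  m <- length(p)
  ord <- order(p)
  reject <- logical(m)
  for (i in seq_len(m)) {
    if (p[ord[i]] <= alpha / (m - i + 1)) {
      reject[ord[i]] <- TRUE
    } else {
      break
    }
  }
  reject
}

# A quantile_model with identity standardization: coefficients are then on
# the original Celsius scale, convenient for closed-form niche checks.
identity_model <- function(a, b, c, tau = 0.95) {
  std <- structure(
    list(z1 = NULL, z2 = NULL, mu1 = 0, sigma1 = 1, mu2 = 0, sigma2 = 1,
         sd_denominator = "sample"),
    class = "std_predictors"
  )
  winterniche:::new_quantile_model(
    coef = c(a = a, b = b, c = c), tau = tau, loss = 0, n = 10L, k = 3L,
    std = std
  )
}

# A quantile_model with random standardization constants and coefficients,
# exercising the back-transformation path.
random_model <- function() {
  temps <- stats::runif(30, -2, 10)
  std <- standardize_predictors(temps)
  winterniche:::new_quantile_model(
    coef = c(a = stats::rnorm(1), b = stats::rnorm(1, sd = 3),
             c = stats::rnorm(1, sd = 3)),
    tau = 0.95, loss = 1, n = 30L, k = 3L, std = std
  )
}

# Noiseless survey whose relative abundance equals the potential curve
# exactly (up to the transect-count rounding), for limit checks.
noiseless_survey <- function(field, truth) {
  pot <- potential_abundance(truth, field$temp_c)
  det <- round(pot * truth$n_transects)
  data.frame(species_id = truth$species_id, cell_id = field$cell_id,
             detections = det, n_transects = truth$n_transects,
             relative_abundance = det / truth$n_transects)
}
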