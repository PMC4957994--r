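# Across-species meta-analysis: the statistical battery applied to a
# species-parameter table (t tests on coefficients, paired tests, a
# repeated-measures linear contrast on pseudo-R2 across quantile levels,
# per-species tests of the mean distribution temperature with Holm
# correction, correlations and the summary table).

meta_result <- function(test, statistic, df, p_value, n, estimate = NA_real_,
                        extra = NULL) {
  structure(
    c(list(test = test, statistic = unname(statistic), df = unname(df),
           p_value = unname(p_value), n = n, estimate = unname(estimate)),
      extra),
    class = "meta_result"
  )
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, df = %s, p = %.4g (n = %d)\n",
              x$test, x$statistic, paste(x$df, collapse = ","),
              x$p_value, x$n))
  invisible(x)
}

#' Filter species by survey coverage
#'
#' Retains species detected in at least `min_cells` cells and whose maximum
#' recorded relative abundance reaches `min_max_freq` (species below either
#' threshold are too rare or too hard to detect for a stable upper-quantile
#' fit). Both comparisons follow the printed conventions: species in fewer
#' than 50 cells are excluded, and only a maximum frequency strictly lower
#' than 0.05 excludes.
#'
#' @param surveys stacked survey data frame (`species_id`, `cell_id`,
#'   `detections`, `n_transects`).
#' @param min_cells minimum number of occupied cells (default 50).
#' @param min_max_freq minimum maximum relative abundance (default 0.05,
#'   i.e. 3 of 60 transects).
#' @return Character vector of retained species ids.
#' @export
species_filter <- function(surveys, min_cells = 50L, min_max_freq = 0.05) {
  stopifnot(is.data.frame(surveys))
  occ <- tapply(surveys$detections >= 1, surveys$species_id, sum)
  maxf <- tapply(surveys$detections / surveys$n_transects,
                 surveys$species_id, max)
  ids <- names(occ)[occ >= min_cells & maxf >= min_max_freq]
  ids[order(match(ids, unique(surveys$species_id)))]
}

#' One-sample t test
#'
#' Classical one-sample t statistic of `values` against the reference mean
#' `mu0`, with a two-sided p-value.
#'
#' @param values numeric vector, at least 2 values with nonzero variance.
#' @param mu0 reference mean.
#' @param label test label carried in the result.
#' @return A `"meta_result"` with `statistic`, `df`, `p_value`, `estimate`
#'   (the sample mean).
#' @export
one_sample_t <- function(values, mu0 = 0, label = "one-sample t") {
  v <- as.numeric(values)
  v <- v[!is.na(v)]
  n <- length(v)
  if (n < 2L) stop("need at least 2 values")
  s <- stats::sd(v)
  if (s == 0) {
    # all values identical: t = 0/0 unless they sit exactly at mu0
    if (mean(v) == mu0) {
      return(meta_result(label, 0, n - 1L, 1, n, mean(v)))
    }
    stop("zero variance; t statistic undefined")
  }
  t_stat <- (mean(v) - mu0) / (s / sqrt(n))
  meta_result(label, t_stat, n - 1L,
              2 * stats::pt(-abs(t_stat), n - 1L), n, mean(v))
}

#' Paired t test
#'
#' One-sample t test of the differences `x - y` against zero.
#'
#' @param x,y paired numeric vectors of equal length.
#' @param label test label.
#' @return A `"meta_result"`; `estimate` is the mean difference.
#' @export
paired_t <- function(x, y, label = "paired t") {
  if (length(x) != length(y)) stop("x and y must have equal length")
  one_sample_t(x - y, 0, label = label)
}

#' Repeated-measures linear contrast across quantile levels
#'
#' Tests for a monotone trend of a per-species statistic (typically
#' pseudo-R-squared) across ordered quantile levels: each species' values are
#' collapsed to a contrast score `sum(w * x)` and the scores are tested
#' against zero; `F = t^2` on `(1, n - 1)` degrees of freedom. Default
#' weights are the quantile levels centered on their mean, so unevenly
#' spaced levels (0.50, 0.75, 0.90, 0.95) are weighted by their spacing; an
#' equally spaced variant uses centered ranks.
#'
#' @param mat numeric matrix, species in rows and ordered quantile levels in
#'   columns.
#' @param levels numeric quantile levels (default parsed from column names,
#'   falling back to 0.50, 0.75, 0.90, 0.95).
#' @param weights contrast weights summing to zero; default
#'   `levels - mean(levels)`.
#' @param spacing `"level"` (weights from the levels themselves) or
#'   `"equal"` (centered ranks).
#' @return A `"meta_result"` with the F statistic and `df = c(1, n - 1)`.
#' @export
trend_contrast <- function(mat, levels = NULL, weights = NULL,
                           spacing = c("level", "equal")) {
  spacing <- match.arg(spacing)
  mat <- as.matrix(mat)
  if (anyNA(mat)) stop("contrast requires a complete matrix")
  if (is.null(levels)) {
    levels <- suppressWarnings(as.numeric(colnames(mat)))
    if (anyNA(levels)) levels <- c(0.50, 0.75, 0.90, 0.95)[seq_len(ncol(mat))]
  }
  if (is.null(weights)) {
    weights <- switch(spacing,
                      level = levels - mean(levels),
                      equal = seq_along(levels) - mean(seq_along(levels)))
  }
  if (length(weights) != ncol(mat)) stop("one weight per column required")
  if (abs(sum(weights)) > 1e-12) stop("contrast weights must sum to zero")
  scores <- drop(mat %*% weights)
  n <- length(scores)
  if (stats::sd(scores) == 0) {
    return(meta_result("linear contrast (repeated measures)", 0,
                       c(1L, n - 1L), 1, n, 0,
                       extra = list(degenerate = TRUE)))
  }
  tt <- one_sample_t(scores, 0)
  meta_result("linear contrast (repeated measures)", tt$statistic^2,
              c(1L, n - 1L),
              stats::pf(tt$statistic^2, 1, n - 1L, lower.tail = FALSE),
              n, mean(scores))
}

#' Per-species tests of the mean distribution temperature
#'
#' For every species with at least 2 occupied cells, tests whether the
#' temperatures of its occupied cells differ from the regional mean
#' temperature, then applies the Holm step-down (sequential Bonferroni)
#' correction across species. The default test is an unweighted one-sample t
#' over occupied-cell temperatures; `weighted = TRUE` uses
#' abundance-weighted mean and variance with frequency weights normalized to
#' the occupied-cell count.
#'
#' @param surveys stacked survey data frame.
#' @param field temperature field data frame.
#' @param regional_mean reference temperature (degrees Celsius); by default
#'   the mean of the supplied field.
#' @param alpha family-wise significance level (default 0.05).
#' @param weighted use abundance-weighted mean and variance.
#' @return list of class `"tmean_tests"`: `table` (per-species statistics,
#'   Holm-adjusted p-values, significance and direction), `counts`
#'   (significantly colder / warmer, nonsignificant, skipped), `alpha`,
#'   `regional_mean`.
#' @export
per_species_tmean_tests <- function(surveys, field, regional_mean = NULL,
                                    alpha = 0.05, weighted = FALSE) {
  if (is.null(regional_mean)) regional_mean <- mean(field$temp_c)
  ids <- unique(surveys$species_id)
  rows <- lapply(ids, function(sid) {
    sv <- surveys[surveys$species_id == sid, ]
    dat <- merge(sv, field[, c("cell_id", "temp_c")], by = "cell_id")
    occ <- dat[dat$detections >= 1, ]
    n <- nrow(occ)
    if (n < 2L || stats::sd(occ$temp_c) == 0) {
      return(data.frame(species_id = sid, n_cells = n, t_mean = NA_real_,
                        statistic = NA_real_, df = NA_real_, p = NA_real_))
    }
    w <- if (weighted) {
      f <- occ$detections / occ$n_transects
      n * f / sum(f)
    } else rep.int(1, n)
    m <- sum(w * occ$temp_c) / sum(w)
    s2 <- sum(w * (occ$temp_c - m)^2) / (n - 1)
    t_stat <- (m - regional_mean) / sqrt(s2 / n)
    data.frame(species_id = sid, n_cells = n, t_mean = m,
               statistic = t_stat, df = n - 1,
               p = 2 * stats::pt(-abs(t_stat), n - 1))
  })
  tab <- do.call(rbind, rows)
  tested <- !is.na(tab$p)
  tab$p_holm <- NA_real_
  tab$p_holm[tested] <- stats::p.adjust(tab$p[tested], method = "holm")
  tab$significant <- !is.na(tab$p_holm) & tab$p_holm < alpha
  tab$direction <- ifelse(!tested, "skipped",
                          ifelse(!tab$significant, "nonsignificant",
                                 ifelse(tab$t_mean < regional_mean,
                                        "colder", "warmer")))
  if (any(!tested)) {
    warning(sprintf("%d species with < 2 occupied cells skipped",
                    sum(!tested)))
  }
  counts <- c(colder = sum(tab$direction == "colder"),
              warmer = sum(tab$direction == "warmer"),
              nonsignificant = sum(tab$direction == "nonsignificant"),
              skipped = sum(tab$direction == "skipped"))
  structure(list(table = tab, counts = counts, alpha = alpha,
                 regional_mean = regional_mean, weighted = weighted),
            class = "tmean_tests")
}

#' @export
print.tmean_tests <- function(x, ...) {
  cat(sprintf(
    "Per-species mean-temperature tests vs %.3f C (Holm, alpha = %g)\n",
    x$regional_mean, x$alpha))
  print(x$counts)
  invisible(x)
}

#' Pearson correlation with test
#'
#' Pearson correlation coefficient with the usual t-based two-sided test.
#'
#' @param x,y numeric vectors of equal length (n >= 3).
#' @param label test label.
#' @return A `"meta_result"`; `estimate` is `r`.
#' @export
pearson_corr <- function(x, y, label = "Pearson correlation") {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- !(is.na(x) | is.na(y))
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance")
  r <- sum((x - mean(x)) * (y - mean(y))) /
    ((n - 1) * stats::sd(x) * stats::sd(y))
  t_stat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  meta_result(label, t_stat, n - 2L,
              if (abs(r) >= 1) 0 else 2 * stats::pt(-abs(t_stat), n - 2L),
              n, r)
}

#' Summary table of niche parameters across species
#'
#' Mean, standard deviation, range and species count for each derived
#' parameter: the standardized coefficients `b`, `c` and the preferred
#' temperature over the species with supported temperature models
#' (`delta_aic` at or below the cutoff), and the mean distribution
#' temperature and thermal breadth over all species (they do not depend on
#' model support).
#'
#' @param species_table species-parameter data frame (see [niche_table()]);
#'   needs columns `b`, `c`, `t_pref`, `t_mean`, `t_breadth`, `delta_aic`.
#' @param delta_aic_cutoff support cutoff (default `-2 log(1000)`, printed
#'   as -13.82).
#' @return data frame with one row per parameter: `parameter`, `mean`, `sd`,
#'   `min`, `max`, `n`.
#' @export
summarize_table1 <- function(species_table,
                             delta_aic_cutoff = delta_aic_for_evidence(1000)) {
  stopifnot(is.data.frame(species_table), nrow(species_table) >= 1)
  sig <- species_table[!is.na(species_table$delta_aic) &
                         species_table$delta_aic <= delta_aic_cutoff, ]
  one <- function(name, v) {
    v <- v[!is.na(v)]
    data.frame(parameter = name, mean = mean(v),
               sd = if (length(v) > 1) stats::sd(v) else NA_real_,
               min = min(v), max = max(v), n = length(v))
  }
  out <- rbind(
    one("b", sig$b), one("c", sig$c), one("t_pref", sig$t_pref),
    one("t_mean", species_table$t_mean),
    one("t_breadth", species_table$t_breadth)
  )
  rownames(out) <- NULL
  out
}

#' Across-species meta-analysis report
#'
#' Runs the full statistical battery on a species-parameter table: t tests of
#' the standardized linear and quadratic coefficients against zero and the
#' paired comparison of their absolute magnitudes (supported-model species);
#' the t test of the preferred temperature against the regional mean
#' temperature, the correlation and paired comparison of preferred vs mean
#' distribution temperature (supported-model species); counts of
#' cold-/warm-preferring and specialist/generalist species; and the summary
#' table. If a matrix of pseudo-R-squared values across quantile levels is
#' supplied, the repeated-measures linear contrast of the increase from the
#' lowest to the highest level is included.
#'
#' @param species_table species-parameter data frame (see [niche_table()]).
#' @param regional_mean regional mean temperature (degrees Celsius);
#'   required for the preferred-temperature test.
#' @param pseudo_r2_matrix optional species x quantile-level matrix of
#'   pseudo-R-squared values.
#' @param delta_aic_cutoff model-support cutoff.
#' @param alpha significance level recorded in the report.
#' @return list of class `"meta_report"` with elements `tests` (named list
#'   of `"meta_result"`), `counts`, `summary` and the settings used.
#' @export
meta_report <- function(species_table, regional_mean,
                        pseudo_r2_matrix = NULL,
                        delta_aic_cutoff = delta_aic_for_evidence(1000),
                        alpha = 0.05) {
  stopifnot(is.data.frame(species_table))
  sig <- species_table[!is.na(species_table$delta_aic) &
                         species_table$delta_aic <= delta_aic_cutoff, ]
  tests <- list()
  if (nrow(sig) >= 2) {
    tests$b_vs_zero <- one_sample_t(sig$b, 0, "b vs 0")
    tests$c_vs_zero <- one_sample_t(sig$c, 0, "c vs 0")
    tests$abs_b_vs_abs_c <- paired_t(abs(sig$b), abs(sig$c), "|b| vs |c|")
    tests$t_pref_vs_regional <- one_sample_t(sig$t_pref, regional_mean,
                                             "t_pref vs regional mean")
    tests$t_pref_vs_t_mean <- paired_t(sig$t_pref, sig$t_mean,
                                       "t_pref vs t_mean")
  }
  if (nrow(sig) >= 3) {
    tests$corr_t_pref_t_mean <- pearson_corr(sig$t_pref, sig$t_mean,
                                             "r(t_pref, t_mean)")
  }
  if (!is.null(pseudo_r2_matrix)) {
    tests$pseudo_r2_trend <- trend_contrast(pseudo_r2_matrix)
  }
  counts <- c(
    n_species = nrow(species_table),
    n_significant = nrow(sig),
    n_pref_cold = sum(sig$t_pref < 0),
    n_pref_warm = sum(sig$t_pref > 5),
    n_specialist = sum(species_table$t_breadth < 0.33),
    n_generalist = sum(species_table$t_breadth > 0.90)
  )
  structure(
    list(tests = tests, counts = counts,
         summary = summarize_table1(species_table, delta_aic_cutoff),
         regional_mean = regional_mean, delta_aic_cutoff = delta_aic_cutoff,
         alpha = alpha),
    class = "meta_report"
  )
}

#' @export
print.meta_report <- function(x, ...) {
  cat("Across-species meta-analysis\n")
  cat(sprintf("  regional mean temperature: %.3f C; delta-AIC cutoff %.3f\n",
              x$regional_mean, x$delta_aic_cutoff))
  cat("Counts:\n")
  print(x$counts)
  cat("Tests:\n")
  for (t in x$tests) print(t)
  cat("Parameter summary:\n")
  print(x$summary, digits = 4)
  invisible(x)
}
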