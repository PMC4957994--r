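make_survey_rows <- function(sid, n_occupied, n_zero, det = 6L,
                             n_transects = 60L) {
  n <- n_occupied + n_zero
  data.frame(species_id = sid, cell_id = seq_len(n),
             detections = c(rep(det, n_occupied), rep(0L, n_zero)),
             n_transects = n_transects)
}

test_that("species filter applies the coverage and frequency thresholds", {
  surveys <- rbind(
    make_survey_rows("few_cells", 49, 10, det = 30),   # excluded: < 50 cells
    make_survey_rows("boundary", 60, 0, det = 3),      # retained: 3/60 = 0.05
    make_survey_rows("too_rare", 60, 0, det = 2),      # excluded: max 0.033
    make_survey_rows("common", 80, 20, det = 12)       # retained
  )
  expect_equal(species_filter(surveys), c("boundary", "common"))

  # enumeration oracle on a random toy community
  set.seed(61)
  ids <- sprintf("s%02d", 1:20)
  toy <- do.call(rbind, lapply(ids, function(sid) {
    make_survey_rows(sid, sample(30:80, 1), sample(0:30, 1),
                     det = sample(1:10, 1))
  }))
  expected <- ids[vapply(ids, function(sid) {
    g <- toy[toy$species_id == sid, ]
    sum(g$detections >= 1) >= 50 && max(g$detections / g$n_transects) >= 0.05
  }, TRUE)]
  expect_equal(species_filter(toy), expected)
})

test_that("one-sample t matches the closed form and stats::t.test", {
  expect_equal(one_sample_t(c(1, 2, 3), 2)$statistic, 0)
  r <- one_sample_t(c(0, 2), 0)
  expect_equal(r$statistic, 1)  # mean 1, se 1
  expect_equal(r$df, 1)

  set.seed(67)
  for (i in 1:50) {
    v <- rnorm(sample(5:40, 1), sd = runif(1, 0.5, 3))
    mu0 <- rnorm(1)
    mine <- one_sample_t(v, mu0)
    ref <- t.test(v, mu = mu0)
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-10)
  }
  expect_error(one_sample_t(rep(2, 5), 0), "zero variance")
  expect_error(one_sample_t(1, 0), "at least 2")
})

test_that("paired t is the one-sample t on differences", {
  x <- rnorm(20); y <- rnorm(20)
  a <- paired_t(x, y)
  b <- one_sample_t(x - y, 0)
  expect_equal(a$statistic, b$statistic)
  expect_equal(a$p_value, b$p_value)
  ref <- t.test(x, y, paired = TRUE)
  expect_equal(a$statistic, unname(ref$statistic), tolerance = 1e-10)

  expect_equal(paired_t(x, x)$statistic, 0)
  expect_error(paired_t(c(3, 4, 5), c(2, 3, 4)), "zero variance")
  expect_error(paired_t(x, y[1:5]), "equal length")
})

test_that("trend contrast reduces to the squared t of the scores", {
  taus <- c(0.5, 0.75, 0.9, 0.95)
  # identical values across levels: every score 0
  mat <- matrix(0.3, nrow = 6, ncol = 4, dimnames = list(NULL, taus))
  r <- trend_contrast(mat)
  expect_equal(r$statistic, 0)

  # two species with opposite scores: mean 0, F = 0
  w <- taus - mean(taus)
  m2 <- rbind(w / sum(w^2), -w / sum(w^2))
  colnames(m2) <- taus
  expect_equal(trend_contrast(m2)$statistic, 0, tolerance = 1e-12)

  set.seed(71)
  mat <- matrix(runif(40 * 4), 40, 4, dimnames = list(NULL, taus))
  r <- trend_contrast(mat)
  scores <- drop(mat %*% (taus - mean(taus)))
  tt <- one_sample_t(scores, 0)
  expect_equal(r$statistic, tt$statistic^2, tolerance = 1e-12)
  expect_equal(r$df, c(1, 39))
  # rising pseudo-R2 across levels comes out strongly positive
  rising <- matrix(rep(c(0.03, 0.05, 0.07, 0.09), each = 30), 30, 4,
                   dimnames = list(NULL, taus)) + runif(120, 0, 0.01)
  expect_gt(trend_contrast(rising)$statistic, 10)
  expect_error(trend_contrast(mat, weights = c(1, 1, 1, 1)), "sum to zero")
})

test_that("Holm flags match the brute-force step-down definition", {
  set.seed(73)
  for (i in 1:200) {
    m <- sample(2:30, 1)
    p <- runif(m)^sample(1:3, 1)
    flags <- p.adjust(p, method = "holm") < 0.05
    expect_identical(flags, brute_force_holm(p, 0.05))
  }
  # hand case: 0.01 < 0.05/2, then 0.04 < 0.05
  expect_identical(brute_force_holm(c(0.01, 0.04)), c(TRUE, TRUE))
  expect_identical(p.adjust(c(0.01, 0.04), "holm") < 0.05, c(TRUE, TRUE))
  # monotone: any p below a significant one is significant
  for (i in 1:50) {
    p <- runif(8)
    sig <- p.adjust(p, "holm") < 0.05
    if (any(sig)) expect_true(all(sig[p <= max(p[sig])]))
  }
})

test_that("per-species mean-temperature tests count directions and partition", {
  set.seed(79)
  field <- generate_temperature_field(600, -2, 10, seed = 79)
  mk_shifted <- function(sid, center, spread) {
    sel <- which(abs(field$temp_c - center) < spread)
    data.frame(species_id = sid, cell_id = field$cell_id,
               detections = ifelse(field$cell_id %in% sel, 5L, 0L),
               n_transects = 60L)
  }
  surveys <- rbind(
    mk_shifted("cold_sp", 0, 1.5),
    mk_shifted("warm_sp", 8, 1.5),
    mk_shifted("wide_sp", 4, 6.5),
    make_survey_rows("lonely", 1, 599)  # single occupied cell: skipped
  )
  res <- suppressWarnings(
    per_species_tmean_tests(surveys, field, regional_mean = 4)
  )
  tab <- res$table
  expect_equal(sum(res$counts), length(unique(surveys$species_id)))
  expect_equal(tab$direction[tab$species_id == "cold_sp"], "colder")
  expect_equal(tab$direction[tab$species_id == "warm_sp"], "warmer")
  expect_equal(tab$direction[tab$species_id == "lonely"], "skipped")
  expect_warning(per_species_tmean_tests(surveys, field, regional_mean = 4),
                 "skipped")
  # per-species statistics agree with stats::t.test on occupied temps
  occ <- field$temp_c[surveys$detections[surveys$species_id == "cold_sp"] >= 1]
  ref <- t.test(occ, mu = 4)
  expect_equal(tab$statistic[tab$species_id == "cold_sp"],
               unname(ref$statistic), tolerance = 1e-10)
  # weighted variant runs and reports the abundance-weighted mean
  resw <- suppressWarnings(
    per_species_tmean_tests(surveys, field, regional_mean = 4,
                            weighted = TRUE)
  )
  expect_equal(sum(resw$counts), 4)
})

test_that("null species show about the nominal family-wise error after Holm", {
  set.seed(83)
  field <- generate_temperature_field(400, -2, 10, seed = 83)
  n_rep <- 40
  any_sig <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    surveys <- do.call(rbind, lapply(1:8, function(i) {
      data.frame(species_id = sprintf("s%d", i), cell_id = field$cell_id,
                 detections = rbinom(400, 60, 0.08), n_transects = 60L)
    }))
    res <- per_species_tmean_tests(surveys, field,
                                   regional_mean = mean(field$temp_c))
    any_sig[r] <- any(res$table$significant)
  }
  # family-wise error under the null stays near alpha; binomial 99% bound
  expect_lte(mean(any_sig), 0.05 + 3 * sqrt(0.05 * 0.95 / n_rep))
})

test_that("Pearson correlation matches oracle and stats::cor.test", {
  x <- rnorm(30)
  expect_equal(pearson_corr(x, 2 * x + 1)$estimate, 1)
  expect_equal(pearson_corr(x, 2 * x + 1)$p_value, 0)
  y <- rnorm(30)
  y_orth <- y - x * sum(x * (y - mean(y))) / sum(x * (x - mean(x)))
  # construct exact orthogonality in the centered sense
  xc <- x - mean(x)
  y_orth <- y - xc * sum(xc * y) / sum(xc^2)
  expect_equal(pearson_corr(x, y_orth)$estimate, 0, tolerance = 1e-12)

  set.seed(89)
  for (i in 1:30) {
    a <- rnorm(25); b <- rnorm(25)
    mine <- pearson_corr(a, b)
    cov_oracle <- sum((a - mean(a)) * (b - mean(b))) / 24 / (sd(a) * sd(b))
    expect_equal(mine$estimate, cov_oracle, tolerance = 1e-12)
    ref <- cor.test(a, b)
    expect_equal(mine$estimate, unname(ref$estimate), tolerance = 1e-10)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-10)
  }
  expect_error(pearson_corr(rep(1, 5), rnorm(5)), "zero variance")
  expect_error(pearson_corr(1:2, 1:2), "at least 3")
})

test_that("summary table splits supported and all-species parameters", {
  tab <- data.frame(
    species_id = c("a", "b", "c"),
    b = c(1, 2, 6), c = c(-1, -2, -3),
    t_pref = c(0, 4, 8), t_mean = c(1, 2, 3), t_breadth = c(0.3, 0.6, 0.9),
    delta_aic = c(-20, -15, -5)  # third species not supported
  )
  out <- summarize_table1(tab)
  sig <- out[out$parameter == "b", ]
  expect_equal(sig$mean, 1.5)
  expect_equal(sig$sd, sd(c(1, 2)))
  expect_equal(sig$n, 2)
  expect_equal(out[out$parameter == "t_pref", "max"], 4)
  allr <- out[out$parameter == "t_mean", ]
  expect_equal(allr$mean, 2)
  expect_equal(allr$n, 3)
  expect_equal(out[out$parameter == "t_breadth", "min"], 0.3)

  single <- summarize_table1(tab[1, ])
  expect_true(is.na(single$sd[1]))
  expect_equal(single$mean[1], 1)
})

test_that("meta report assembles the full battery coherently", {
  set.seed(97)
  n <- 30
  tab <- data.frame(
    species_id = sprintf("s%02d", 1:n),
    b = rnorm(n, 3, 5), c = rnorm(n, -1, 3),
    t_pref = runif(n, -2, 10), t_mean = runif(n, -0.2, 5.5),
    t_breadth = runif(n, 0.26, 1),
    delta_aic = c(rep(-30, 25), rep(-8, 5))
  )
  r2mat <- matrix(runif(n * 4, 0, 0.3), n, 4,
                  dimnames = list(tab$species_id, c(0.5, 0.75, 0.9, 0.95)))
  rep <- meta_report(tab, regional_mean = 2.55, pseudo_r2_matrix = r2mat)
  expect_s3_class(rep, "meta_report")
  sig <- tab[tab$delta_aic <= delta_aic_for_evidence(1000), ]
  expect_equal(rep$counts[["n_significant"]], nrow(sig))
  expect_equal(rep$tests$b_vs_zero$statistic,
               one_sample_t(sig$b, 0)$statistic)
  expect_equal(rep$tests$t_pref_vs_t_mean$statistic,
               paired_t(sig$t_pref, sig$t_mean)$statistic)
  expect_equal(rep$tests$corr_t_pref_t_mean$estimate,
               pearson_corr(sig$t_pref, sig$t_mean)$estimate)
  expect_equal(rep$counts[["n_pref_cold"]], sum(sig$t_pref < 0))
  expect_equal(rep$counts[["n_pref_warm"]], sum(sig$t_pref > 5))
  flat <- meta_report_table(rep)
  expect_true(all(c("name", "statistic", "p_value") %in% names(flat)))
  expect_gte(nrow(flat), length(rep$tests) + length(rep$counts))
})
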