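test_that("zero_probability follows its logistic climate model", {
  m <- reference_zinb_model()
  base <- data.frame(tmax = 24, precip = 0.4)
  logodds <- function(cells) qlogis(zero_probability(m, cells))
  # published per-unit climate effects on the structural-zero log odds
  expect_equal(logodds(transform(base, tmax = 25)) - logodds(base),
               -0.1287, tolerance = 1e-12)
  expect_equal(round(logodds(transform(base, tmax = 25)) - logodds(base), 2),
               -0.13)
  expect_equal(logodds(transform(base, precip = 1.4)) - logodds(base),
               0.2679, tolerance = 1e-12)
  expect_equal(round(logodds(transform(base, precip = 1.4)) - logodds(base), 2),
               0.27)
  # logistic symmetry at gamma + delta'w = 0
  m0 <- zinb_model(0, c(tmax = 0.5), 0, c(slope = 0), 1)
  expect_equal(zero_probability(m0, data.frame(tmax = 0)), 0.5)
  expect_error(zero_probability(m, data.frame(tmax = 24)), "missing covariate")
})

test_that("expected_fires reproduces the published multiplicative effects", {
  m <- reference_zinb_model()
  cell <- function(phys, slope = 2) {
    data.frame(tmax = 24, precip = 0.38, slope = slope,
               physiographic_class = phys)
  }
  e <- function(phys, slope = 2, occ = 10) {
    expected_fires(m, cell(phys, slope), occ)
  }
  # xeric and mesic sites relative to the hydric reference
  expect_equal(e("xeric") / e("hydric"), exp(0.7621), tolerance = 1e-12)
  expect_equal(round(e("xeric") / e("hydric"), 2), 2.14)
  expect_equal(e("mesic") / e("hydric"), exp(0.7114), tolerance = 1e-12)
  expect_equal(round(e("mesic") / e("hydric"), 2), 2.04)
  # 4 percent decrease per degree of slope
  expect_equal(e("mesic", slope = 3) / e("mesic", slope = 2), exp(-0.0405))
  expect_equal(round(1 - e("mesic", slope = 3) / e("mesic", slope = 2), 2),
               0.04)
  # 1.05x per percent privet occupancy
  expect_equal(e("mesic", occ = 11) / e("mesic", occ = 10), exp(0.0444))
  expect_equal(round(e("mesic", occ = 11) / e("mesic", occ = 10), 2), 1.05)

  # multiplicative invariant holds at arbitrary baselines, exactly
  withr::with_seed(3, {
    cells <- data.frame(
      tmax = rnorm(20, 24), precip = runif(20, 0.2, 0.6),
      slope = runif(20, 0, 10),
      physiographic_class = sample(c("xeric", "mesic", "hydric"), 20, TRUE)
    )
  })
  occ <- runif(20, 0, 80)
  delta <- 2.5
  bumped <- transform(cells, slope = slope + delta)
  expect_equal(expected_fires(m, bumped, occ) / expected_fires(m, cells, occ),
               rep(exp(-0.0405 * delta), 20), tolerance = 1e-12)
  # zero inflation only shrinks the count-model mean
  mu <- exp(m$count_intercept +
              as.matrix(data.frame(
                slope = cells$slope,
                xeric = as.numeric(cells$physiographic_class == "xeric"),
                mesic = as.numeric(cells$physiographic_class == "mesic"),
                privet_percent = occ
              )) %*% m$count_coefficients)
  ef <- expected_fires(m, cells, occ)
  expect_true(all(ef >= 0 & ef <= mu + 1e-12))

  expect_error(expected_fires(m, cells, rep(150, 20)), "\\[0, 100\\]")
  bad <- cells
  bad$physiographic_class[1] <- "alpine"
  expect_error(expected_fires(m, bad, occ), "physiographic")
})

test_that("fit_zinb recovers generating parameters within 3 SE at n = 8000", {
  truth <- reference_zinb_model()
  g <- generate_grid(8000, generator_config(), seed = 61)
  withr::with_seed(62, occ <- runif(8000, 0, 60))
  counts <- generate_fire_counts(g, occ, truth, seed = 63)
  fit <- fit_zinb(counts, g$cells, occ, select = FALSE)
  expect_equal(fit$convergence, 0)
  rep <- fit$report
  true_val <- function(part, term) {
    switch(paste(part, term),
      "zero (Intercept)" = truth$zero_intercept,
      "zero tmax" = truth$zero_coefficients[["tmax"]],
      "zero precip" = truth$zero_coefficients[["precip"]],
      "count (Intercept)" = truth$count_intercept,
      "count slope" = truth$count_coefficients[["slope"]],
      "count xeric" = truth$count_coefficients[["xeric"]],
      "count mesic" = truth$count_coefficients[["mesic"]],
      "count privet_percent" = truth$count_coefficients[["privet_percent"]],
      "dispersion log_theta" = log(truth$dispersion)
    )
  }
  for (i in seq_len(nrow(rep))) {
    tv <- true_val(rep$part[i], rep$term[i])
    expect_lt(abs(rep$estimate[i] - tv), 3 * rep$std_error[i],
              label = paste(rep$part[i], rep$term[i]))
  }
  # fitted likelihood at the ML estimate is at least that of the truth
  ll_truth <- zinb_loglik(truth, counts, g$cells, occ)
  expect_gte(fit$loglik, ll_truth - 1e-6)
})

test_that("fit_zinb degenerates gracefully toward plain NB and Poisson", {
  g <- generate_grid(4000, generator_config(), seed = 71)
  withr::with_seed(72, occ <- runif(4000, 0, 60))

  # no zero inflation in truth: ZINB's AIC is no better than plain NB's
  truth_nb <- zinb_model(-50, c(tmax = 0), -0.8,
                         c(slope = -0.04, privet_percent = 0.04),
                         dispersion = 1.5)
  counts <- generate_fire_counts(g, occ, truth_nb, seed = 73)
  fit_z <- fit_zinb(counts, g$cells, occ,
                    count_candidates = c("slope", "privet_percent"),
                    select = FALSE)
  fit_nb <- fit_zinb(counts, g$cells, occ,
                     count_candidates = c("slope", "privet_percent"),
                     select = FALSE, zero_part = FALSE)
  expect_gte(fit_z$aic, fit_nb$aic - 2)

  # huge dispersion: near-Poisson counts, mean structure still recovered
  truth_pois <- zinb_model(-50, c(tmax = 0), -0.5,
                           c(slope = -0.04, privet_percent = 0.04),
                           dispersion = 1e6)
  counts_p <- generate_fire_counts(g, occ, truth_pois, seed = 74)
  fit_p <- fit_zinb(counts_p, g$cells, occ,
                    count_candidates = c("slope", "privet_percent"),
                    select = FALSE, zero_part = FALSE)
  rp <- fit_p$report
  expect_lt(abs(rp$estimate[rp$term == "slope"] + 0.04),
            3 * rp$std_error[rp$term == "slope"])
  expect_lt(abs(rp$estimate[rp$term == "privet_percent"] - 0.04),
            3 * rp$std_error[rp$term == "privet_percent"])

  expect_error(fit_zinb(rep(0L, 100), g$cells[1:100, ], occ[1:100]),
               "all counts are zero")
})

test_that("fit_zinb count part cross-checks against MASS::glm.nb", {
  skip_if_not_installed("MASS")
  g <- generate_grid(4000, generator_config(), seed = 81)
  withr::with_seed(82, occ <- runif(4000, 0, 60))
  truth_nb <- zinb_model(-50, c(tmax = 0), -0.8,
                         c(slope = -0.04, privet_percent = 0.04),
                         dispersion = 1.5)
  counts <- generate_fire_counts(g, occ, truth_nb, seed = 83)
  ours <- fit_zinb(counts, g$cells, occ,
                   count_candidates = c("slope", "privet_percent"),
                   select = FALSE, zero_part = FALSE)
  df <- data.frame(y = counts, slope = g$cells$slope, privet = occ)
  ref <- MASS::glm.nb(y ~ slope + privet, data = df)
  rp <- ours$report
  # different optimizers (joint BFGS vs glm.nb's alternating IRLS); agreement
  # to ~1e-3 absolute is the expected convergence-tolerance scale
  expect_lt(abs(rp$estimate[rp$term == "(Intercept)" & rp$part == "count"] -
                  coef(ref)[[1]]), 5e-3)
  expect_lt(abs(rp$estimate[rp$term == "slope"] - coef(ref)[["slope"]]), 1e-3)
  expect_lt(abs(rp$estimate[rp$term == "privet_percent"] -
                  coef(ref)[["privet"]]), 1e-3)
  expect_lt(abs(exp(rp$estimate[rp$term == "log_theta"]) - ref$theta), 0.05)
  # and our joint optimum is no worse in likelihood
  expect_gte(ours$loglik, as.numeric(stats::logLik(ref)) - 1e-3)
})

test_that("bin_frequencies uses lower-exclusive, upper-inclusive 0.125 bins", {
  b <- bin_frequencies(c(0, 0.125, 0.2, 0.25, 0.26, 0.375, 0.5))
  expect_equal(as.character(b),
               c("0", "(0,0.125]", "(0.125,0.25]", "(0.125,0.25]",
                 "(0.25,0.375]", "(0.25,0.375]", "(0.375,0.5]"))
  expect_true(is.ordered(b))
  expect_error(bin_frequencies(-0.1), ">= 0")
})
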