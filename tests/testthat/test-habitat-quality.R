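test_that("predict_hq evaluates the logistic form and its odds-ratio identity", {
  m0 <- hq_model(0, c(slope = 0, tmax = 0))
  cell <- data.frame(slope = 12, tmax = 30)
  expect_equal(predict_hq(m0, cell), 0.5)  # logistic symmetry

  # all covariates zero under the published coefficients:
  # logistic(-8.2364) = exp(-8.2364)/(1 + exp(-8.2364)), frozen by hand
  ref <- reference_hq_model()
  zero_cell <- as.data.frame(as.list(setNames(
    rep(0, length(ref$coefficients)), names(ref$coefficients)
  )))
  expect_equal(predict_hq(ref, zero_cell), 2.647658e-4, tolerance = 1e-6)

  # odds ratio of a unit increase in any covariate is exp(beta), exactly
  base <- data.frame(slope = 3, water_adjacent = 1, tmax = 24, stand_age = 40,
                     site_productivity = 4, artificial_regen = 0,
                     road_distance = 2, fire_disturbance = 0,
                     private_ownership = 1)
  odds <- function(p) p / (1 - p)
  for (cv in names(ref$coefficients)) {
    bumped <- base
    bumped[[cv]] <- bumped[[cv]] + 1
    expect_equal(
      odds(predict_hq(ref, bumped)) / odds(predict_hq(ref, base)),
      exp(ref$coefficients[[cv]]),
      tolerance = 1e-8
    )
  }
  # unit increase in site productivity multiplies odds by 1.388
  bumped <- base
  bumped$site_productivity <- bumped$site_productivity + 1
  expect_equal(odds(predict_hq(ref, bumped)) / odds(predict_hq(ref, base)),
               1.388, tolerance = 1e-3)

  # output strictly in (0,1); invariant to covariate column order
  g <- generate_grid(200, seed = 31)
  p <- predict_hq(ref, g$cells)
  expect_true(all(p > 0 & p < 1))
  shuffled <- g$cells[sample(names(g$cells))]
  expect_equal(predict_hq(ref, shuffled), p)

  expect_error(predict_hq(ref, data.frame(slope = 1)), "missing covariate")
})

test_that("fit_logistic recovers generating coefficients and drops noise by AIC", {
  truth <- hq_model(-1, c(tmax = 0.8, slope = -0.3, stand_age = -0.02))
  g <- generate_grid(5000, generator_config(), seed = 11)
  # standardize so the intercept is on a sane scale for this truth
  cells <- data.frame(
    tmax = scale(g$cells$tmax)[, 1],
    slope = scale(g$cells$slope)[, 1],
    stand_age = scale(g$cells$stand_age)[, 1],
    noise_cov = rnorm(5000)
  )
  p <- plogis(-1 + as.matrix(cells[names(truth$coefficients)]) %*%
                truth$coefficients)
  withr::with_seed(12, y <- rbinom(5000, 1, p))
  fit <- fit_logistic(cells, y, c(names(truth$coefficients), "noise_cov"))
  rep <- fit$report
  for (cv in names(truth$coefficients)) {
    row <- rep[rep$term == cv, ]
    expect_equal(nrow(row), 1)
    expect_lt(abs(row$estimate - truth$coefficients[[cv]]),
              3 * row$std_error)
  }

  # a pure-noise covariate is dropped by stepwise AIC in most seeds
  dropped <- 0L
  for (s in 1:10) {
    withr::with_seed(100 + s, {
      nc <- rnorm(5000)
      y2 <- rbinom(5000, 1, p)
    })
    cells$noise_cov <- nc
    f <- fit_logistic(cells, y2, c(names(truth$coefficients), "noise_cov"))
    if (!"noise_cov" %in% f$report$term) dropped <- dropped + 1L
  }
  expect_gte(dropped, 8)
})

test_that("fit_logistic flags degenerate inputs", {
  x <- c(rnorm(25, -3), rnorm(25, 3))
  y <- as.integer(x > 0)
  expect_error(fit_logistic(data.frame(x = x), y, "x"), "separation")
  expect_error(fit_logistic(data.frame(x = rnorm(10)), rep(1, 10), "x"),
               "at least 2")
  expect_error(
    fit_logistic(data.frame(x = rep(1, 20)), rep(c(0, 1), 10), "x"),
    "constant"
  )

  # balanced covariate with no effect: slope near zero (or dropped by AIC)
  withr::with_seed(7, {
    x <- rep(c(0, 1), each = 250)
    y <- rbinom(500, 1, 0.5)
  })
  f <- fit_logistic(data.frame(x = x), y, "x")
  row <- f$report[f$report$term == "x", ]
  if (nrow(row) == 1) {
    expect_lt(abs(row$estimate), 3 * row$std_error)
  } else {
    succeed("null covariate dropped by AIC")
  }
})

test_that("refits on regenerated data stay within 3 SE of truth (property)", {
  truth_beta <- c(tmax = 0.6, slope = -0.4)
  within <- 0L
  n_rep <- 10
  for (s in 1:n_rep) {
    withr::with_seed(500 + s, {
      cells <- data.frame(tmax = rnorm(2500), slope = rnorm(2500))
      p <- plogis(-0.5 + as.matrix(cells) %*% truth_beta)
      y <- rbinom(2500, 1, p)
    })
    f <- suppressWarnings(glm(y ~ tmax + slope, binomial(), data = cells))
    cf <- summary(f)$coefficients
    ok <- abs(cf["tmax", 1] - 0.6) < 3 * cf["tmax", 2] &&
      abs(cf["slope", 1] + 0.4) < 3 * cf["slope", 2] &&
      abs(cf["(Intercept)", 1] + 0.5) < 3 * cf["(Intercept)", 2]
    within <- within + ok
  }
  expect_gte(within, n_rep - 1)
})

test_that("hosmer_lemeshow matches hand tabulation and is calibrated", {
  # perfect calibration: every decile's mean prediction equals its event rate
  p <- rep(seq(0.1, 1.0, by = 0.1), each = 10)
  y <- unlist(lapply(1:10, function(k) c(rep(1, k), rep(0, 10 - k))))
  hl <- hosmer_lemeshow(p, y, groups = 10)
  expect_equal(hl$statistic, 0, tolerance = 1e-12)
  expect_equal(hl$p_value, 1)

  # 20-record fixture, 2 groups, hand-tabulated chi-square:
  # group 1: p = 0.1 x10, 2 events -> (2-1)^2/1 + (8-9)^2/9
  # group 2: p = 0.7 x10, 6 events -> (6-7)^2/7 + (4-3)^2/3
  p2 <- c(rep(0.1, 10), rep(0.7, 10))
  y2 <- c(rep(1, 2), rep(0, 8), rep(1, 6), rep(0, 4))
  hl2 <- hosmer_lemeshow(p2, y2, groups = 2)
  expect_equal(hl2$statistic, 1 + 1 / 9 + 1 / 7 + 1 / 3, tolerance = 1e-12)

  # under a well-specified fitted model, p-values are approximately uniform
  n_rep <- 200
  pv <- numeric(n_rep)
  for (s in 1:n_rep) {
    withr::with_seed(900 + s, {
      x <- rnorm(400)
      y3 <- rbinom(400, 1, plogis(-0.3 + 0.8 * x))
    })
    f <- glm(y3 ~ x, binomial())
    pv[s] <- hosmer_lemeshow(fitted(f), y3)$p_value
  }
  rej <- mean(pv < 0.05)
  expect_lt(abs(rej - 0.05), 3.5 * sqrt(0.05 * 0.95 / n_rep) + 0.02)
  expect_gt(mean(pv), 0.35)
  expect_lt(mean(pv), 0.65)
})

test_that("classification_accuracy counts threshold agreements", {
  expect_equal(classification_accuracy(c(1, 0, 1), c(1, 0, 1)), 1)
  expect_equal(classification_accuracy(rep(0.4, 5), rep(1, 5)), 0)
  # 10-record fixture scored by hand: 6 of 10 agree at threshold 0.5
  p <- c(0.9, 0.8, 0.6, 0.55, 0.5, 0.45, 0.4, 0.3, 0.2, 0.1)
  y <- c(1, 0, 1, 1, 0, 1, 0, 0, 1, 0)
  expect_equal(classification_accuracy(p, y), 0.6)
  expect_error(classification_accuracy(numeric(0), numeric(0)), "empty")
  expect_error(classification_accuracy(0.5, 1, threshold = 1), "threshold")
})
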