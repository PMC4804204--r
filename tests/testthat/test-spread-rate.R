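test_that("estimate_r applies the log-ratio formula and the exclusion rules", {
  sp <- make_survey_pair(P1 = c(10, 15, 30, 0, 5, 20),
                         P2 = c(20, 15, 20, 10, 0, 40),
                         excluded = c(NA, NA, NA, NA, NA, "site_prep"))
  est <- estimate_r(sp)
  expect_equal(est$r[1], log(2) / 5)           # closed-form hand value
  expect_equal(est$r[2], 0)                    # no change -> r = 0
  expect_true(est$excluded[3])
  expect_equal(est$reason[3], "decline")       # P_t1 > P_t2
  expect_equal(est$reason[4], "zero_occupancy")
  expect_equal(est$reason[5], "zero_occupancy")
  expect_equal(est$reason[6], "site_prep")     # pre-flagged cells stay flagged
  expect_true(all(is.na(est$r[est$excluded])))

  # translation invariance in time: shifting both survey years changes nothing
  sp_shift <- make_survey_pair(P1 = sp$P_t1, P2 = sp$P_t2,
                               t1 = 1990, t2 = 1995,
                               excluded = sp$excluded)
  expect_equal(estimate_r(sp_shift)$r, est$r)
})

test_that("fit_r_hq recovers a noiseless generating family exactly", {
  hq <- seq(0.05, 0.95, length.out = 25)
  r <- 0.3815 * exp(0.8611 * hq)
  fit <- fit_r_hq(r, hq)
  expect_equal(fit$best, "exp_linear")
  m <- fit$best_model
  expect_equal(m$a, 0.3815, tolerance = 1e-10)
  expect_equal(m$b, 0.8611, tolerance = 1e-10)
  expect_equal(m$r_squared, 1, tolerance = 1e-10)
  # most favourable habitat: r at HQ = 0.95 rounds to 0.86
  expect_equal(round(predict(m, 0.95), 2), 0.86)

  # every family wins on its own noiseless data
  defs <- list(
    linear = function(h) 0.25 + 0.39 * h,
    logarithmic = function(h) 0.95 + 0.94 * log(h),
    inverse_power = function(h) 0.91 - 0.004 / h,
    quadratic_power = function(h) 0.08 + 0.58 * h^2,
    exp_linear = function(h) 0.38 * exp(0.86 * h),
    exp_quadratic = function(h) 0.42 * exp(0.76 * h^2)
  )
  for (fam in names(defs)) {
    f <- fit_r_hq(defs[[fam]](hq), hq)
    expect_equal(f$best, fam, info = fam)
    expect_equal(f$models[[fam]]$r_squared, 1, tolerance = 1e-8, info = fam)
  }
})

test_that("fit_r_hq least-squares estimates match a brute-force oracle", {
  # 6-point fixture; oracle: direct optimisation of each family's objective
  hq <- c(0.1, 0.25, 0.4, 0.6, 0.8, 0.95)
  withr::with_seed(21, r <- 0.3 * exp(0.9 * hq) * exp(rnorm(6, 0, 0.05)))
  fit <- fit_r_hq(r, hq)
  transforms <- list(
    linear = list(g = function(h) h, log = FALSE),
    logarithmic = list(g = function(h) log(h), log = FALSE),
    inverse_power = list(g = function(h) 1 / h, log = FALSE),
    quadratic_power = list(g = function(h) h^2, log = FALSE),
    exp_sqrt = list(g = function(h) sqrt(h), log = TRUE),
    exp_linear = list(g = function(h) h, log = TRUE),
    exp_quadratic = list(g = function(h) h^2, log = TRUE)
  )
  for (fam in names(transforms)) {
    tr <- transforms[[fam]]
    y <- if (tr$log) log(r) else r
    x <- tr$g(hq)
    sse <- function(par) sum((y - par[1] - par[2] * x)^2)
    o <- optim(c(0, 0), sse, method = "BFGS",
               control = list(reltol = 1e-14))
    a_oracle <- if (tr$log) exp(o$par[1]) else o$par[1]
    m <- fit$models[[fam]]
    expect_equal(m$a, a_oracle, tolerance = 1e-6, info = fam)
    expect_equal(m$b, o$par[2], tolerance = 1e-6, info = fam)
  }
})

test_that("fit_r_hq handles degenerate and invalid inputs", {
  hq <- seq(0.1, 0.9, length.out = 10)
  # constant rates: all families collapse to the constant
  fit <- fit_r_hq(rep(0.5, 10), hq)
  expect_equal(fit$models$linear$b, 0, tolerance = 1e-12)
  for (fam in names(fit$models)) {
    expect_equal(predict(fit$models[[fam]], hq), rep(0.5, 10),
                 tolerance = 1e-8, info = fam)
  }
  # HQ = 0 skips the families whose transform is undefined there
  fit0 <- fit_r_hq(c(0.2, 0.3, 0.4, 0.5), c(0, 0.3, 0.6, 0.9))
  expect_false("inverse_power" %in% names(fit0$models))
  expect_true(any(grepl("inverse_power", fit0$notes)))
  expect_error(fit_r_hq(c(1, 2), c(0.1, 0.2)), "at least 3")
  expect_error(fit_r_hq(c(1, 2, 3), c(0.1, 0.2, 1.4)), "\\[0, 1\\]")
})

test_that("impute_r fills unsurveyed cells and keeps direct estimates", {
  m <- reference_spread_rate_model()
  hq <- c(0.2, 0.5, 0.95)
  r_direct <- c(0.4, NA, NA)
  out <- impute_r(m, hq, r_direct)
  expect_equal(out[1], 0.4)                        # surveyed cell unchanged
  expect_equal(out[2], 0.3815 * exp(0.8611 * 0.5))
  expect_equal(round(out[3], 2), 0.86)
  # intercept limit: exp_linear at HQ = 0 gives a
  expect_equal(unname(predict(m, 0)), 0.3815)
  # monotone in HQ for b > 0
  hs <- seq(0, 1, by = 0.01)
  expect_true(all(diff(impute_r(m, hs)) > 0))
  expect_error(impute_r(m, 1.2), "\\[0, 1\\]")
})
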