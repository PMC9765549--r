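test_that("exponential-rate regression recovers closed-form slopes", {
  t <- 0:4
  f <- suppressWarnings(fit_exponential_rate(t, 1e4 * exp(0.5 * t)))
  expect_equal(f$mu, 0.5, tolerance = 1e-10)
  expect_equal(f$n_points, 5L)

  flat <- suppressWarnings(fit_exponential_rate(0:5, rep(1e4, 6)))
  expect_equal(flat$mu, 0)

  decline <- suppressWarnings(
    fit_exponential_rate(0:5, 1e4 * exp(-0.2 * (0:5))))
  expect_equal(decline$mu, 0)

  expect_error(fit_exponential_rate(0:1, c(1, 2)), "at least 3")
  expect_error(fit_exponential_rate(0:3, c(1, -2, 3, 4)), "positive")
  expect_error(fit_exponential_rate(c(0, 0, 1), c(1, 2, 3)),
               "strictly increasing")
})

test_that("an explicit window restricts the regression", {
  t <- 0:8
  n <- pmin(1e4 * exp(0.6 * t), 1e6)   # plateau from t ~ 7.7
  f <- suppressWarnings(fit_exponential_rate(t, n, window = c(0, 6)))
  expect_equal(f$mu, 0.6, tolerance = 1e-10)
  # the automatic window also finds the exponential phase
  fa <- suppressWarnings(fit_exponential_rate(t, n))
  expect_equal(fa$mu, 0.6, tolerance = 1e-6)
})

test_that("the rate estimator is unbiased under lognormal noise", {
  set.seed(20)
  mus <- vapply(1:500, function(i) {
    t <- seq(0, 3.5, by = 0.5)
    n <- 1e4 * exp(0.8 * t) * rlnorm(length(t), 0, 0.05)
    fit_exponential_rate(t, n, window = c(0, 3.5))$mu
  }, numeric(1))
  expect_lt(abs(mean(mus) - 0.8), 0.02)
})

test_that("the CTMI takes mu_opt at Topt, vanishes outside, and matches hand values", {
  expect_equal(ctmi_mu(24, 0, 24, 28, 1), 1)
  expect_equal(ctmi_mu(29, 0, 24, 28, 1), 0)
  expect_equal(ctmi_mu(-1, 0, 24, 28, 1), 0)
  expect_equal(ctmi_mu(20, 0, 24, 28, 1), 0.83333333, tolerance = 1e-7)
  expect_error(ctmi_mu(20, 24, 10, 28, 1), "Tmin < Topt < Tmax")
  expect_error(ctmi_mu(20, 0, 24, 28, -1), "non-negative")

  set.seed(21)
  for (i in 1:200) {
    p <- random_cardinal()
    expect_equal(ctmi_mu(p$Topt, p$Tmin, p$Topt, p$Tmax, p$mu_opt),
                 p$mu_opt, tolerance = 1e-9)
    expect_equal(ctmi_mu(p$Tmax + runif(1, 0, 10), p$Tmin, p$Topt, p$Tmax,
                         p$mu_opt), 0)
  }
})

test_that("the CTMI approaches zero continuously at both cardinal bounds", {
  p <- list(Tmin = 2, Topt = 24, Tmax = 28, mu_opt = 0.9)
  eps <- 10^-(3:7)
  near_max <- ctmi_mu(p$Tmax - eps, p$Tmin, p$Topt, p$Tmax, p$mu_opt)
  near_min <- ctmi_mu(p$Tmin + eps, p$Tmin, p$Topt, p$Tmax, p$mu_opt)
  expect_true(all(abs(near_max) < 1e-2))
  expect_true(all(abs(near_min) < 1e-5))
  expect_true(all(diff(abs(near_max)) < 0))
})

test_that("fit_ctmi recovers noiseless parameters and is scale-equivariant", {
  temps <- 10:33
  mu <- ctmi_mu(temps, 2, 24, 28, 0.9)
  fit <- fit_ctmi(temps, mu)
  cf <- coef(fit)
  expect_lt(abs(cf[["Topt"]] - 24), 0.1)
  expect_lt(abs(cf[["Tmax"]] - 28), 0.1)
  expect_lt(abs(cf[["mu_opt"]] - 0.9), 0.01)

  fit2 <- fit_ctmi(temps, 2 * mu)
  expect_equal(coef(fit2)[["Topt"]], cf[["Topt"]], tolerance = 0.05)
  expect_equal(coef(fit2)[["mu_opt"]], 2 * cf[["mu_opt"]], tolerance = 0.02)

  expect_error(fit_ctmi(temps, rep(0, length(temps))), "unfittable")
  expect_error(fit_ctmi(c(10, 12, 14, 16), c(0.1, 0.2, 0.3, 0.2)),
               "5 distinct")
})

test_that("Topt/Tmax stay identified when the data cannot constrain Tmin", {
  temps <- 10:33
  mu <- ctmi_mu(temps, -5, 24, 28, 0.9)
  cf <- coef(fit_ctmi(temps, mu))
  expect_lt(abs(cf[["Topt"]] - 24), 0.5)
  expect_lt(abs(cf[["Tmax"]] - 28), 0.5)
})

test_that("fit_ctmi ignores observation order and is seed-deterministic", {
  r <- simulate_rates(list(Tmin = 2, Topt = 24, Tmax = 28, mu_opt = 0.9),
                      seed = 30)
  f1 <- fit_ctmi(r, seed = 7)
  f2 <- fit_ctmi(r[sample(nrow(r)), ], seed = 7)
  expect_identical(coef(f1), coef(f2))
  expect_identical(coef(fit_ctmi(r, seed = 7))[["Topt"]],
                   coef(f1)[["Topt"]])
})

test_that("ctmi methods predict, residual and report consistently", {
  r <- simulate_rates(list(Tmin = 2, Topt = 24, Tmax = 28, mu_opt = 0.9),
                      seed = 31)
  fit <- fit_ctmi(r)
  expect_equal(length(fitted(fit)), nrow(fit$fitted_data))
  expect_equal(fit$rss, sum(residuals(fit)^2), tolerance = 1e-10)
  expect_equal(predict(fit, 50), 0)
  expect_output(print(fit), "Cardinal Temperature")
})

test_that("bootstrap CIs collapse on noiseless data and reject invalid B", {
  temps <- seq(10, 31, by = 3)
  mu <- ctmi_mu(temps, 2, 24, 28, 0.9)
  fit <- fit_ctmi(temps, mu)
  expect_error(ctmi_confidence_intervals(fit, B = 0), "positive")
  ci <- ctmi_confidence_intervals(fit, B = 50, seed = 3)
  expect_lt(ci["Topt", "upper"] - ci["Topt", "lower"], 0.2)
  expect_lt(ci["Tmax", "upper"] - ci["Tmax", "lower"], 0.2)
  cf <- coef(fit)
  expect_gte(cf[["Topt"]] + 1e-4, ci["Topt", "lower"])
  expect_lte(cf[["Topt"]] - 1e-4, ci["Topt", "upper"])
})

test_that("growth_fit_report tabulates measured vs model preferenda", {
  r1 <- simulate_rates(list(Tmin = 2, Topt = 24, Tmax = 28, mu_opt = 0.9),
                       seed = 40)
  r2 <- simulate_rates(list(Tmin = 5, Topt = 28, Tmax = 32, mu_opt = 0.6),
                       seed = 41)
  rates <- rbind(data.frame(strain = "A", r1), data.frame(strain = "B", r2))
  rep <- growth_fit_report(rates, B = 30, seed = 1)
  expect_equal(rep$strain, c("A", "B"))
  expect_lt(abs(rep$Topt_model[1] - 24), 1.5)
  expect_lt(abs(rep$Tmax_model[2] - 32), 1.5)
  expect_true(all(rep$Topt_lo <= rep$Topt_hi))
})
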