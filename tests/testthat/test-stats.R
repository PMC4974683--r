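test_that("the quadratic dP-Q fit reproduces frozen oracle values", {
  q <- c(30, 42, 54)
  f40 <- dpq_fit(q, c(22.53, 35.50, 52.66))
  # frozen from the independent normal-equations oracle
  expect_equal(unname(coef(f40)), c(0.450894, 0.009648), tolerance = 1e-5)
  expect_equal(f40$rmse, 0.585345, tolerance = 1e-5)
  f55 <- dpq_fit(q, c(30.54, 49.61, 74.16))
  expect_equal(unname(coef(f55)), c(0.557719, 0.015055), tolerance = 1e-5)
  expect_equal(f55$rmse, 0.474590, tolerance = 1e-5)
  f70 <- dpq_fit(q, c(36.03, 57.72, 85.98))
  expect_equal(unname(coef(f70)), c(0.687121, 0.016685), tolerance = 1e-5)
  expect_equal(f70$rmse, 0.731919, tolerance = 1e-5)
  # steeper-curve ordering with angle: both coefficients grow
  expect_gt(coef(f70)["A"], coef(f40)["A"])
  expect_gt(coef(f70)["B"], coef(f40)["B"])
  expect_gt(coef(f55)["A"], coef(f40)["A"])
})

test_that("the fit equals the normal-equations oracle on random inputs", {
  set.seed(314)
  for (i in 1:25) {
    n <- sample(3:12, 1)
    q <- sort(runif(n, 5, 100))
    dp <- 0.5 * q + 0.02 * q^2 + rnorm(n, 0, 2)
    fit <- dpq_fit(q, dp)
    orc <- fit_dpq_oracle(q, dp)
    expect_lt(abs(coef(fit)["A"] - orc$A), 1e-10)
    expect_lt(abs(coef(fit)["B"] - orc$B), 1e-10)
    expect_lt(abs(fit$rmse - orc$rmse), 1e-10)
    # noiseless data are recovered exactly
    fit0 <- dpq_fit(q, 1.0 * q + 0.02 * q^2)
    expect_equal(unname(coef(fit0)), c(1.0, 0.02), tolerance = 1e-9)
    expect_lt(fit0$rmse, 1e-9)
  }
})

test_that("fitted curves are monotone on q > 0 when both coefficients are", {
  fit <- dpq_fit(c(30, 42, 54), c(22.53, 35.50, 52.66))
  qq <- seq(0.1, 100, length.out = 50)
  expect_true(all(diff(predict(fit, qq)) > 0))
})

test_that("degenerate fits are flagged or rejected", {
  expect_warning(f2 <- dpq_fit(c(30, 54), c(20, 50)), "RMSE undefined")
  expect_true(is.na(f2$rmse))
  expect_length(coef(f2), 2)
  expect_error(dpq_fit(c(30, 30), c(10, 12)), "singular|distinct")
  expect_error(dpq_fit(30, 10), "at least 2")
  expect_error(dpq_fit(c(-5, 30), c(1, 2)), "positive")
})

test_that("model methods are coherent", {
  fit <- dpq_fit(c(30, 42, 54), c(22.53, 35.50, 52.66))
  expect_equal(fit$fitted.values + fit$residuals, fit$data$dp)
  expect_equal(predict(fit), fit$fitted.values)
  expect_equal(predict(fit, 0), 0)  # through the origin by construction
  s <- summary(fit)
  expect_s3_class(s, "summary.dpq_fit")
  expect_output(print(fit), "A = 0.451")
  sims <- simulate(fit, nsim = 5, seed = 3, sigma = 0.1)
  expect_equal(dim(sims), c(3, 5))
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})

test_that("RMSE follows its degrees-of-freedom definition", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(0, 2), c(0, 0), m = 1), 2)
  # translation invariance and linear scaling
  y <- c(1, 4, 9, 16); yh <- c(1.2, 3.7, 9.4, 15.6)
  expect_equal(rmse(y + 10, yh + 10), rmse(y, yh))
  expect_equal(rmse(3 * y, 3 * yh), 3 * rmse(y, yh))
  expect_error(rmse(c(1, 2), c(1, 2), m = 2), "n > m")
})

test_that("linear regression with r2 behaves like OLS", {
  x <- 1:10
  f <- linear_fit_r2(x, 3 + 2 * x)
  expect_equal(f$slope, 2)
  expect_equal(f$intercept, 3)
  expect_equal(f$r2, 1)
  # y independent of x: r2 ~ 0 at large n
  set.seed(99)
  xr <- runif(1000); yr <- 5 + rnorm(1000)
  f0 <- linear_fit_r2(xr, yr)
  expect_lt(f0$r2, 0.02)
  expect_true(f0$r2 >= 0)
  # parameter recovery within 2 SE
  set.seed(4)
  x2 <- runif(200, 0, 10); y2 <- 1 + 0.8 * x2 + rnorm(200, 0, 0.5)
  f2 <- linear_fit_r2(x2, y2)
  se <- 0.5 / sqrt(sum((x2 - mean(x2))^2))
  expect_lt(abs(f2$slope - 0.8), 2 * se)
  expect_error(linear_fit_r2(rep(1, 5), 1:5), "zero variance")
  expect_error(linear_fit_r2(1:2, 1:2), "at least 3")
})

test_that("angle-difference table reproduces the published entries", {
  ref <- reference_results()
  adt <- angle_difference_table(ref)
  get <- function(sten, fl) adt$diff[adt$sb_stenosis_pct == sten & adt$sb_flow_pct == fl]
  expect_equal(get(80, 45), 0.33)
  expect_equal(get(80, 35), 0.22)
  expect_equal(get(80, 25), 0.13)
  expect_equal(get(60, 45), 0.05)
  expect_equal(get(60, 35), 0.04)
  expect_equal(get(60, 25), 0.03)
  expect_equal(unname(get(40, 25)), 0.02)
  # identical FFR columns give an all-zero table
  same <- ref; same$ffr_sb <- 0.5
  expect_true(all(angle_difference_table(same)$diff == 0))
  # missing pairings are reported by name
  expect_error(angle_difference_table(ref[ref$alpha_deg != 70 | ref$sb_stenosis_pct != 80, ]),
               "missing angle pairing")
})

test_that("fit report JSON is well formed", {
  fits <- list(`40` = dpq_fit(c(30, 42, 54), c(22.53, 35.50, 52.66)))
  path <- withr::local_tempfile(fileext = ".json")
  write_fit_report(fits, path)
  rep_ <- jsonlite::read_json(path)
  expect_equal(rep_[[1]]$angle, "40")
  expect_equal(round(rep_[[1]]$A, 3), 0.451)
  expect_equal(rep_[[1]]$n, 3)
})
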