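test_that("Michaelis-Menten fit recovers exact parameters on exact data", {
  S <- c(0.25, 0.5, 1, 2, 5, 10) * 1e-6
  fit <- fit_mm(S, 2 * S / (1e-6 + S))
  expect_equal(fit$Km, 1e-6, tolerance = 1e-6)
  expect_equal(fit$Vmax, 2, tolerance = 1e-6)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  expect_equal(unname(coef(fit)), c(fit$Km, fit$Vmax))
  expect_equal(predict(fit, 1e-6), fit$Vmax / 2, tolerance = 1e-6)
})

test_that("Michaelis-Menten fit rejects sparse or narrow designs", {
  expect_error(fit_mm(c(1, 2, 4) * 1e-6, c(1, 2, 3)), "4 distinct")
  expect_error(fit_mm(c(1, 1.5, 2, 3) * 1e-6, c(1, 2, 3, 4)), "4-fold")
})

test_that("Km is recovered within 15% under seeded 5% relative noise", {
  # tolerance pre-registered from a 100-replicate pilot at this design
  S <- c(0.25, 0.5, 1, 2, 5, 10) * 1e-6
  truth <- 2 * S / (1e-6 + S)
  kms <- withr::with_seed(101, {
    vapply(1:100, function(i) {
      v <- truth * (1 + rnorm(length(S), 0, 0.05))
      fit_mm(S, v)$Km
    }, numeric(1))
  })
  expect_lt(median(abs(kms - 1e-6) / 1e-6), 0.15)
  expect_gt(mean(abs(kms - 1e-6) / 1e-6 < 0.15), 0.75)
})

test_that("4PL fit recovers a generative IC50 of 10 uM exactly", {
  d <- 10^seq(log10(0.1), log10(1000), length.out = 8) * 1e-6
  act <- 1 / (1 + d / 1e-5)
  fit <- fit_4pl(d, act)
  expect_equal(fit$ic50, 1e-5, tolerance = 1e-6)
  expect_equal(fit$hill, 1, tolerance = 1e-6)
  expect_equal(fit$top, 1, tolerance = 1e-6)
  expect_equal(fit$bottom, 0, tolerance = 1e-6)
})

test_that("4PL curve evaluated at the fitted IC50 is the half response", {
  d <- 10^seq(-7, -3, length.out = 9)
  withr::with_seed(5, {
    act <- 0.1 + 0.9 / (1 + (d / 3e-5)^1.3) + rnorm(9, 0, 0.02)
  })
  fit <- fit_4pl(d, act)
  mid <- predict(fit, fit$ic50)
  expect_equal(mid, (fit$top + fit$bottom) / 2, tolerance = 1e-6)
})

test_that("flat dose response raises an undefined-IC50 error", {
  d <- 10^seq(-7, -3, length.out = 6)
  expect_error(fit_4pl(d, rep(5, 6)), "undefined IC50")
  expect_error(fit_4pl(d[1:4], c(1, .8, .5, .2)), ">= 5 doses")
})

test_that("zero doses anchor the top two decades below the smallest dose", {
  d <- c(0, 1e-6, 1e-5, 1e-4, 1e-3)
  act <- c(1, 1 / (1 + d[-1] / 1e-5))
  fit <- fit_4pl(d, act)
  expect_equal(fit$zero_dose_anchor, 1e-8)
  expect_equal(fit$ic50, 1e-5, tolerance = 1e-3)
})

test_that("4PL optimum matches a brute-force grid search oracle", {
  d <- 10^seq(log10(0.1), log10(1000), length.out = 8) * 1e-6
  act <- 1 / (1 + d / 1e-5)
  fit <- fit_4pl(d, act)
  # grid over (ic50, hill); top/bottom profiled out by linear least squares
  ic_grid <- 10^seq(-7, -3, length.out = 200)
  hill_grid <- 10^seq(log10(0.2), log10(5), length.out = 50)
  sse <- function(ic, h) {
    f <- 1 / (1 + (d / ic)^h)
    co <- stats::lm.fit(cbind(1, f), act)$coefficients
    sum((act - co[1] - co[2] * f)^2)
  }
  obj <- outer(ic_grid, hill_grid, Vectorize(sse))
  best <- which(obj == min(obj), arr.ind = TRUE)[1, ]
  step <- diff(log10(ic_grid))[1]
  expect_lt(abs(log10(ic_grid[best[1]]) - log10(fit$ic50)), step * 1.5)
  # the fit is no worse than the best grid point
  fit_sse <- sum((act - predict(fit))^2)
  expect_lte(fit_sse, min(obj) + 1e-8)
})

test_that("fitted activity is non-increasing in dose on noise-free series", {
  d <- 10^seq(-7, -3, length.out = 10)
  act <- 0.05 + 0.95 / (1 + (d / 1e-5)^1.7)
  fit <- fit_4pl(d, act)
  curve <- predict(fit, sort(d))
  expect_true(all(diff(curve) <= 1e-12))
})

test_that("relative inhibition is 0% at control and 100% at the reference", {
  a <- c(control = 10, vanadate = 0.2, tungstate = 9.51, molybdate = 3.14)
  tab <- relative_inhibition(a, "control", "vanadate")
  expect_equal(tab$pct_inhibition[tab$condition == "control"], 0)
  expect_equal(tab$pct_of_reference[tab$condition == "vanadate"], 100)
  expect_equal(tab$pct_inhibition[tab$condition == "vanadate"], 98)

  expect_error(relative_inhibition(c(control = 0, x = 1), "control", "x"),
               "positive")
  none <- relative_inhibition(c(control = 10, x = 10, y = 5), "control", "x")
  expect_true(none$reference_undefined[1])
  expect_true(all(is.na(none$pct_of_reference)))
})

test_that("pH optimum: symmetric profiles, exact recovery, boundary flag", {
  ph <- seq(4, 8, by = 0.5)
  sym <- exp(-(ph - 6)^2 / (2 * 0.8^2))
  fit <- estimate_ph_optimum(ph, sym)
  expect_equal(fit$optimum, 6, tolerance = 1e-6)
  expect_false(fit$boundary)
  expect_equal(fit$method, "fit")

  rising <- estimate_ph_optimum(ph, ph^2)
  expect_true(rising$boundary)
  expect_error(estimate_ph_optimum(ph[1:4], sym[1:4]), ">= 5 points")
})

test_that("thermal midpoint: step interval midpoint, exact logistic, flags", {
  step <- estimate_thermal_midpoint(c(37, 40, 45, 50, 60, 65, 70),
                                    c(1, 1, 1, 1, 0, 0, 0))
  expect_equal(step$optimum, 55, tolerance = 0.5)

  temps <- seq(37, 70, by = 2.5)
  act <- 1 / (1 + exp((temps - 55) / 2))
  fit <- estimate_thermal_midpoint(temps, act)
  expect_equal(fit$midpoint, 55, tolerance = 1e-6)
  expect_false(fit$boundary)

  flat <- estimate_thermal_midpoint(temps, rep(3, length(temps)))
  expect_true(flat$boundary)
})

test_that("profile fits match dense grid-search optima on noise-free data", {
  # pH bell: grid over (mu, s), amplitude profiled out
  ph <- seq(4, 8, by = 0.5)
  y_ph <- 0.8 * exp(-(ph - 6)^2 / (2 * 0.8^2))
  fit_ph <- estimate_ph_optimum(ph, y_ph)
  mu_grid <- seq(4, 8, length.out = 120)
  s_grid <- seq(0.2, 3, length.out = 80)
  sse_ph <- function(mu, s) {
    f <- exp(-(ph - mu)^2 / (2 * s^2))
    a <- sum(f * y_ph) / sum(f * f)
    sum((y_ph - a * f)^2)
  }
  best_ph <- min(outer(mu_grid, s_grid, Vectorize(sse_ph)))
  res_ph <- sum((y_ph - fit_ph$parameters[["A"]] *
                   exp(-(ph - fit_ph$optimum)^2 /
                         (2 * fit_ph$parameters[["s"]]^2)))^2)
  expect_lte(res_ph, best_ph + 1e-8)

  # thermal logistic: grid over (Tm, w)
  temps <- seq(37, 70, by = 2.5)
  y_th <- 2.5 / (1 + exp((temps - 55) / 2))
  fit_th <- estimate_thermal_midpoint(temps, y_th)
  tm_grid <- seq(40, 68, length.out = 120)
  w_grid <- seq(0.5, 8, length.out = 80)
  sse_th <- function(tm, w) {
    f <- 1 / (1 + exp((temps - tm) / w))
    a <- sum(f * y_th) / sum(f * f)
    sum((y_th - a * f)^2)
  }
  best_th <- min(outer(tm_grid, w_grid, Vectorize(sse_th)))
  res_th <- sum((y_th - fit_th$parameters[["A"]] /
                   (1 + exp((temps - fit_th$midpoint) /
                              fit_th$parameters[["w"]])))^2)
  expect_lte(res_th, best_th + 1e-8)
})
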