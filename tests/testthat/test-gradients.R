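rec3 <- function(values, d = c(0, 10, 20)) {
  tibble::tibble(station = paste0("S", seq_along(values)),
                 distance_km = d, value = values)
}

test_that("an exact exponential transect is fitted exactly", {
  gf <- fit_exponential_gradient(rec3(c(5, 15, 45)))
  expect_equal(gf$growth_rate, log(3) / 10)
  expect_equal(gf$r2, 1)
  expect_equal(gf$intercept, 5)
})

test_that("constant transects give zero growth and zero r2", {
  gf <- fit_exponential_gradient(rec3(c(7, 7, 7)))
  expect_equal(gf$growth_rate, 0)
  expect_equal(gf$r2, 0)
  expect_true(is.na(gf$p_slope))
  expect_false(gf$significant)
})

test_that("a perturbed transect matches the closed-form OLS solution", {
  rec <- rec3(c(5, 16, 45))
  gf <- fit_exponential_gradient(rec)
  x <- rec$distance_km
  y <- log(rec$value)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  r2 <- stats::cor(x, y)^2
  expect_equal(gf$growth_rate, slope)
  expect_equal(gf$r2, r2)
  expect_lt(gf$r2, 1)
  # slope bounded by the exact-fit slopes of the two unperturbed series
  # (with 3 equally spaced stations OLS reproduces the endpoint slope, so
  # the bound is attained, not strict)
  s1 <- log(45 / 5) / 20                 # through stations 1 and 3
  s2 <- log(16 / 5) / 10                 # forced through the perturbed point
  expect_gte(gf$growth_rate, min(s1, s2) - 1e-12)
  expect_lte(gf$growth_rate, max(s1, s2) + 1e-12)
})

test_that("the fit is invariant to rescaling all values", {
  rec <- rec3(c(4, 13, 52))
  a <- fit_exponential_gradient(rec)
  rec$value <- rec$value * 7.3
  b <- fit_exponential_gradient(rec)
  expect_equal(b$growth_rate, a$growth_rate)
  expect_equal(b$r2, a$r2)
  expect_equal(b$intercept, a$intercept * 7.3)
})

test_that("non-positive values are rejected naming the station", {
  rec <- rec3(c(5, -1, 45))
  expect_error(fit_exponential_gradient(rec), "S2")
  expect_error(fit_exponential_gradient(rec3(c(1, 2, 3))[1:2, ]),
               "at least 3")
})

test_that("the log-linear estimator is unbiased under log-normal noise", {
  truth <- log(9) / 30
  d <- seq(0, 30, by = 5)
  set.seed(2024)
  slopes <- sapply(1:200, function(i) {
    rec <- tibble::tibble(
      station = paste0("S", seq_along(d)), distance_km = d,
      value = 5 * exp(truth * d) * exp(stats::rnorm(length(d), 0, 0.3))
    )
    fit_exponential_gradient(rec)$growth_rate
  })
  se <- stats::sd(slopes) / sqrt(length(slopes))
  expect_lt(abs(mean(slopes) - truth), 2 * se)
})

test_that("station subsets can flip the significance verdict", {
  # a strong near-head gradient flattened beyond 20 km by a side-fjord input,
  # with mild scatter: significant only when the outer stations are excluded
  d <- c(0, 5, 10, 15, 20, 25, 30)
  v <- c(5, 11, 20, 47, 16, 11, 28)
  rec <- tibble::tibble(station = paste0("S", 1:7), distance_km = d, value = v)
  full <- fit_exponential_gradient(rec)
  inner <- fit_exponential_gradient(rec, subset = paste0("S", 1:4))
  expect_false(full$significant)
  expect_true(inner$significant)
  expect_equal(inner$n, 4)
})

test_that("fold change is the far/near ratio", {
  expect_equal(fold_change(5, 45), 9)
  expect_equal(fold_change(3, 3), 1)
  expect_equal(fold_change(2, 0), 0)
  expect_error(fold_change(0, 4), "> 0")
  rec <- rec3(c(5, 15, 45))
  expect_equal(transect_fold_change(rec), 9)
  expect_equal(transect_fold_change(rec, subset = c("S1", "S2")), 3)
})
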