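test_that("plateau rule fixes M0 from the observed maximum with a stability flag", {
  cv <- dissolution_curve(c(0, 60, 120, 180, 240, 300),
                          c(0, 5, 9, 10, 10, 10), 0.5, 0.1)
  est <- estimate_m0(cv)
  expect_equal(est$m0, 10)
  expect_true(est$stable)
  expect_equal(est$t_plateau, 180) # earliest time the maximum is reached

  rising <- dissolution_curve(c(0, 60, 120, 180, 240, 300),
                              c(0, 4, 7, 9.0, 9.5, 10.2), 0.5, 0.1)
  est2 <- estimate_m0(rising)
  expect_false(est2$stable)
  expect_equal(est2$m0, 10.2)

  est3 <- estimate_m0(cv, rule = "tail_mean")
  expect_equal(est3$m0, 10)
  expect_error(estimate_m0(dissolution_curve(c(0, 1), c(0, 1), 1, 1)),
               "at least 3")
})

test_that("plateau estimate on a noiseless model curve equals the end-of-run release", {
  cv <- make_model_curve(30, 5000, 1.5)
  est <- estimate_m0(cv)
  p <- rcm_params(30, 5000, 1.5)
  expect_equal(est$m0, rcm_dissolved(p, max(cv$times)))
  expect_lt(abs(est$m0 - 30) / 30, 0.02) # within 2% of the asymptotic amount
  expect_true(est$stable)
})

test_that("noiseless curves on the field schedule recover a and v", {
  for (truth in list(c(30, 5000, 1.5), c(8, 2e4, 0.8), c(90, 1e3, 3))) {
    cv <- make_model_curve(truth[1], truth[2], truth[3])
    fit <- fit_rcm(cv, m0 = truth[1])
    expect_true(fit$converged)
    expect_lt(abs(fit$params$a - truth[2]) / truth[2], 0.005)
    expect_lt(abs(fit$params$v - truth[3]) / truth[3], 0.005)
    expect_lt(max(abs(fit$residuals)), 1e-8)
  }
})

test_that("refitting from recovered parameters reproduces them (idempotence)", {
  cv <- make_model_curve(30, 5000, 1.5)
  f1 <- fit_rcm(cv, m0 = 30)
  sch <- cv$times
  cv2 <- dissolution_curve(sch, rcm_dissolved(f1$params, sch), 0.5, 0.1)
  f2 <- fit_rcm(cv2, m0 = 30)
  expect_equal(f2$params$a, f1$params$a, tolerance = 1e-8)
  expect_equal(f2$params$v, f1$params$v, tolerance = 1e-8)
})

test_that("the NLS fit agrees with an exhaustive grid-search minimizer", {
  cases <- list(c(30, 5000, 1.5), c(10, 500, 0.7), c(60, 5e4, 2.5))
  for (truth in cases) {
    cv <- make_model_curve(truth[1], truth[2], truth[3])
    fit <- fit_rcm(cv, m0 = truth[1])
    gs <- grid_search_rcm(cv, m0 = truth[1])
    # (a, v) trade off along a correlated valley, so the discrete argmin can
    # sit one cell off diagonally: agree to within 1.5 grid steps per
    # log-coordinate, and the fit must be at least as good as any grid point
    expect_lt(abs(log(fit$params$a) - log(gs$a)), 1.5 * gs$step_la)
    expect_lt(abs(log(fit$params$v) - log(gs$v)), 1.5 * gs$step_lv)
    expect_lte(fit$rss, gs$ss + 1e-12)
  }
})

test_that("fit is deterministic and reports residuals per point", {
  tab <- simulate_dissolution(rcm_params(30, 5000, 1.5), noise_sd = 0.05,
                              seed = 99)
  cv <- build_dissolution_curve(tab$time_s, tab$conc_uM, volume = 0.1,
                                dry_mass = 0.75)
  f1 <- fit_rcm(cv)
  f2 <- fit_rcm(cv)
  expect_identical(f1$params, f2$params)
  expect_length(f1$residuals, f1$n_points)
  expect_match(f1$m0_source, "plateau")
  expect_true(is.finite(f1$se_a) && is.finite(f1$se_v))
})

test_that("degenerate and undersized curves are rejected", {
  z <- dissolution_curve(c(0, 60, 120, 180), c(0, 0, 0, 0), 1, 0.1)
  expect_error(fit_rcm(z, m0 = 1), "degenerate")
  short <- dissolution_curve(c(0, 60, 120), c(0, 1, 2), 1, 0.1)
  expect_error(fit_rcm(short, m0 = 3), "at least 4")
})

test_that("rcm_parameter_table summarises one row per vessel", {
  curves <- list(make_model_curve(30, 5000, 1.5), make_model_curve(10, 2000, 1))
  tab <- rcm_parameter_table(curves)
  expect_equal(nrow(tab), 2)
  expect_true(all(tab$converged))
  expect_equal(tab$lability, tab$reducibility * tab$m0)
  expect_equal(tab$composition, 1 + 1 / tab$v)
})
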