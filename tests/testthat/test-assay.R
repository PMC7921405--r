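test_that("linear calibration matches closed-form OLS", {
  two <- calibrate_linear(c(0, 100), c(0, 0.5))
  expect_equal(two$slope, 0.005)
  expect_equal(two$intercept, 0)
  expect_equal(two$r2, 1)

  three <- calibrate_linear(c(0, 50, 100), c(0.01, 0.26, 0.51))
  expect_equal(three$slope, 0.005)
  expect_equal(three$intercept, 0.01)
  expect_equal(three$n_standards, 3)

  expect_error(calibrate_linear(c(10, 10), c(0.1, 0.2)), "distinct")
})

test_that("absorbance inverts through the calibration (round trip)", {
  cal <- calibrate_linear(c(0, 100), c(0, 0.5))
  expect_equal(absorbance_to_conc(cal, 0.25)$conc, 50)
  expect_equal(absorbance_to_conc(cal, 0.25, dilution_factor = 10)$conc, 500)
  set.seed(5)
  cal2 <- calibrate_linear(c(0, 20, 50, 100), 0.004 * c(0, 20, 50, 100) + 0.02)
  for (c0 in runif(5, 0, 200)) {
    got <- absorbance_to_conc(cal2, cal2$slope * c0 + cal2$intercept)
    expect_equal(got$conc, c0)
    expect_false(got$clipped)
  }
  below <- absorbance_to_conc(cal2, 0.01)
  expect_equal(below$conc, 0)
  expect_true(below$clipped)
  expect_error(absorbance_to_conc(cal, 0.1, dilution_factor = 0.5), ">= 1")
})

test_that("curve building converts concentration to per-gram-dry-weight", {
  cv <- build_dissolution_curve(c(0, 300), c(0, 50), volume = 0.1,
                                dry_mass = 0.5)
  expect_equal(cv$cumulative_fe, c(0, 10))
  zero <- build_dissolution_curve(c(0, 300, 600), c(0, 0, 0), 0.1, 0.5)
  expect_true(all(zero$cumulative_fe == 0))
  expect_error(build_dissolution_curve(c(0, 300, 300), c(0, 1, 1), 0.1, 0.5),
               "duplicate")
})

test_that("curve building is homogeneous in dry mass and concentration", {
  t <- c(0, 300, 600)
  conc <- c(0, 20, 40)
  base <- build_dissolution_curve(t, conc, 0.1, 0.5)$cumulative_fe
  expect_equal(build_dissolution_curve(t, conc, 0.1, 1.0)$cumulative_fe,
               base / 2)
  expect_equal(build_dissolution_curve(t, 3 * conc, 0.1, 0.5)$cumulative_fe,
               3 * base)
})

test_that("withdrawal correction follows the aliquot mass balance", {
  t <- c(0, 3600)
  conc <- c(40, 60)
  V <- 0.1; w <- 0.001; m <- 0.5
  un <- build_dissolution_curve(t, conc, V, m, correct = FALSE)
  co <- build_dissolution_curve(t, conc, V, m, withdrawal = w, correct = TRUE)
  # at t2: Fe in vessel = c2 * (V - w); Fe carried out at t1 = c1 * w
  expect_equal(co$cumulative_fe[2], (conc[2] * (V - w) + conc[1] * w) / m)
  expect_equal(co$cumulative_fe[2] - un$cumulative_fe[2],
               (conc[1] - conc[2]) * w / m)
  expect_error(
    build_dissolution_curve(t, conc, 0.001, m, withdrawal = 0.001,
                            correct = TRUE),
    "exceed"
  )
})

test_that("sequential HCl speciation books Fe(III) by difference", {
  sp <- hcl_speciation(c(fe2 = 40, fe_total = 100),
                       c(fe2 = 100, fe_total = 500))
  expect_equal(sp$fe3, c(60, 400))
  expect_equal(total_hcl(sp), 600)
  expect_false(any(sp$clipped))
  expect_equal(sp$fe2 + sp$fe3, sp$fe_total)

  clip <- hcl_speciation(c(fe2 = 52, fe_total = 50),
                         c(fe2 = 10, fe_total = 30))
  expect_equal(clip$fe3[1], 0)
  expect_true(clip$clipped[1])
  expect_equal(total_hcl(clip), 80) # totals are always the step-total sum

  zero <- hcl_speciation(c(fe2 = 0, fe_total = 0), c(fe2 = 0, fe_total = 0))
  expect_equal(total_hcl(zero), 0)
  expect_error(hcl_speciation(c(fe2 = 1), c(fe2 = 1, fe_total = 2)), "0.5 M")
})

test_that("porosity and water content come from drying weight loss", {
  pp <- physical_props(15, 10, 10)
  expect_equal(pp$porosity, 0.5)
  expect_equal(pp$water_content, 1 / 3)
  expect_equal(physical_props(10, 10, 10)$porosity, 0)
  expect_error(physical_props(25, 10, 10), "porosity")
  expect_error(physical_props(5, 10, 10), "wet_mass")
  # monotone in wet mass at fixed dry mass and volume
  por <- sapply(seq(10, 18, by = 2), function(w) physical_props(w, 10, 10)$porosity)
  expect_true(all(diff(por) > 0))
})

test_that("replicates aggregate to mean/sd with the control kept apart", {
  agg <- aggregate_replicates(c(30, 32, 28))
  expect_equal(agg$mean, 30)
  expect_equal(agg$sd, 2)
  expect_equal(agg$n, 3)
  one <- aggregate_replicates(12)
  expect_equal(one$mean, 12)
  expect_true(is.na(one$sd))
  withc <- aggregate_replicates(c(10, 10, 10), control_value = 2)
  expect_equal(withc$mean, 10) # control reported alongside, never subtracted
  expect_equal(withc$control, 2)
})
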