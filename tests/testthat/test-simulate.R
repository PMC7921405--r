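test_that("the sampling schedule follows the field cadence", {
  expect_equal(extraction_schedule(3600), c(0, 300, 600, 1200, 1800, 3000))
  expect_equal(extraction_schedule(300), c(0, 300))
  for (dur in c(1800, 3 * 3600, 32 * 3600)) {
    s <- extraction_schedule(dur)
    expect_true(all(diff(s) > 0))
    expect_equal(s[1], 0)
    expect_lte(max(s), dur)
  }
  full <- extraction_schedule()
  expect_gte(max(full), 30 * 3600) # runs into the second day
  expect_true(all(diff(full) <= 2 * 3600)) # never sparser than 2 h
  expect_error(extraction_schedule(33 * 3600), "cap")
})

test_that("noiseless simulated tables invert to the exact model curve", {
  truth <- rcm_params(30, 5000, 1.5)
  tab <- simulate_dissolution(truth, noise_sd = 0)
  cv <- build_dissolution_curve(tab$time_s, tab$conc_uM,
                                volume = tab$volume_l[1],
                                dry_mass = tab$dry_mass_g[1])
  expect_equal(cv$cumulative_fe, rcm_dissolved(truth, tab$time_s),
               tolerance = 1e-12)
  expect_identical(attr(tab, "truth"), truth)
})

test_that("simulation is deterministic under a fixed seed", {
  truth <- rcm_params(30, 5000, 1.5)
  a <- simulate_dissolution(truth, noise_sd = 0.05, seed = 123)
  b <- simulate_dissolution(truth, noise_sd = 0.05, seed = 123)
  expect_identical(a, b)
  c <- simulate_dissolution(truth, noise_sd = 0.05, seed = 124)
  expect_false(identical(a$conc_uM, c$conc_uM))
})

test_that("noisy curves still recover the apparent rate constant", {
  truth <- rcm_params(30, 5000, 1.5)
  errs <- sapply(1:100, function(s) {
    tab <- simulate_dissolution(truth, noise_sd = 0.05, seed = s)
    cv <- build_dissolution_curve(tab$time_s, tab$conc_uM, volume = 0.1,
                                  dry_mass = 0.75)
    f <- fit_rcm(cv)
    abs(f$params$v / f$params$a - 3e-4) / 3e-4
  })
  expect_lt(stats::median(errs), 0.2)
})

test_that("transect bundles realise the configured gradients exactly", {
  cfg <- scenario_config(stations = c("H", "M"), distances_km = c(0, 30),
                         noise_sd = 0, seed = 5)
  b <- simulate_transect(cfg)
  tr <- b$truth[b$truth$extraction == "chemical", ]
  expect_equal(tr$m0[tr$station == "M"] / tr$m0[tr$station == "H"], 9)
  expect_equal(attr(b$truth, "growth_m0"), log(9) / 30)
  # microbial pool doubled, control a fixed fraction of it
  mi <- b$truth[b$truth$station == "H" & b$truth$extraction == "microbial", ]
  expect_equal(unique(mi$m0[!mi$is_control]), 2 * tr$m0[tr$station == "H"])
  expect_equal(mi$m0[mi$is_control],
               0.15 * unique(mi$m0[!mi$is_control]))
})

test_that("subsurface-peak mode puts the true maximum below the surface", {
  cfg <- scenario_config(depth_mode = "subsurface_peak", noise_sd = 0,
                         seed = 5)
  b <- simulate_transect(cfg)
  chem <- b$truth[b$truth$extraction == "chemical", ]
  for (stn in unique(chem$station)) {
    g <- chem[chem$station == stn, ]
    expect_gt(g$depth_top[which.max(g$m0)], min(g$depth_top))
  }
})

test_that("bundles are byte-identical under a fixed seed", {
  cfg <- scenario_config(seed = 17)
  expect_identical(simulate_transect(cfg), simulate_transect(cfg))
})
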