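# Shared fixtures and independent oracles, built in code at test time.

# Noiseless model curve on the standard sampling schedule.
make_model_curve <- function(m0, a, v, duration_s = 32 * 3600) {
  p <- rcm_params(m0, a, v)
  sch <- extraction_schedule(duration_s)
  dissolution_curve(sch, rcm_dissolved(p, sch), dry_mass = 0.5, volume = 0.1)
}

# Brute-force oracle for the RCM fit: exhaustive search of the residual sum
# of squares over an n x n log-spaced (a, v) grid, independent of the
# Levenberg-Marquardt path.
grid_search_rcm <- function(curve, m0, a_range = c(10, 1e6),
                            v_range = c(0.1, 10), n = 200) {
  la <- seq(log(a_range[1]), log(a_range[2]), length.out = n)
  lv <- seq(log(v_range[1]), log(v_range[2]), length.out = n)
  t <- curve$times
  y <- curve$cumulative_fe
  best <- c(Inf, NA, NA)
  ev <- exp(lv)
  for (i in seq_len(n)) {
    a <- exp(la[i])
    pred <- m0 * (1 - outer(a / (a + t), ev, `^`))
    ss <- colSums((pred - y)^2)
    j <- which.min(ss)
    if (ss[j] < best[1]) best <- c(ss[j], la[i], lv[j])
  }
  list(a = exp(best[2]), v = exp(best[3]), ss = best[1],
       step_la = diff(la[1:2]), step_lv = diff(lv[1:2]))
}

# Central finite difference of f at x with near-optimal step.
central_diff <- function(f, x, scale = abs(x) + 1) {
  h <- scale * .Machine$double.eps^(1 / 3)
  (f(x + h) - f(x - h)) / (2 * h)
}
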