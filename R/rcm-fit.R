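#' Estimate the total extractable amount M0 from a curve's plateau
#'
#' The extractions are run until the Fe(II) concentration stabilises, and the
#' total extractable amount M0 is fixed from the data rather than fitted: the
#' default rule takes the maximum cumulative Fe observed by the end of the
#' extraction. The alternative `"tail_mean"` rule averages the final `k`
#' points. A stability flag reports whether the final `k` points lie within a
#' relative `window` of each other, i.e. whether the curve actually reached a
#' plateau under the stopping criterion.
#'
#' @param curve A [dissolution_curve] with at least 3 points.
#' @param rule `"max"` (default; maximum observed cumulative Fe) or
#'   `"tail_mean"` (mean of the final `k` points).
#' @param window Relative range within which the final `k` points must lie for
#'   the curve to count as stable. Default 0.05 (5%).
#' @param k Number of tail points used for the stability check and the
#'   `"tail_mean"` rule. Default 3.
#' @return A list with `m0` (micromol per g dry weight), `stable` (logical),
#'   `t_plateau` (earliest time at which the maximum was observed, seconds)
#'   and `rule`.
#' @examples
#' cv <- dissolution_curve(c(0, 60, 120, 180, 240, 300),
#'                         c(0, 5, 9, 10, 10, 10), 0.5, 0.1)
#' estimate_m0(cv)
#' @export
estimate_m0 <- function(curve, rule = c("max", "tail_mean"),
                        window = 0.05, k = 3) {
  stopifnot(inherits(curve, "dissolution_curve"))
  rule <- match.arg(rule)
  y <- curve$cumulative_fe
  n <- length(y)
  if (n < 3L) stop("curve must have at least 3 points", call. = FALSE)
  k <- min(k, n)
  tail_y <- y[(n - k + 1L):n]
  hi <- max(tail_y)
  stable <- if (hi == 0) TRUE else (hi - min(tail_y)) / hi <= window
  m0 <- switch(rule, max = max(y), tail_mean = mean(tail_y))
  # earliest time at which the observed maximum occurs
  t_plateau <- curve$times[which(y >= max(y) * (1 - 1e-12))[1]]
  list(m0 = m0, stable = stable, t_plateau = t_plateau, rule = rule)
}

#' Options controlling the RCM least-squares fit
#'
#' @param a_init Initial value for `a`, seconds. Default: the median positive
#'   sampling time of the curve (set at fit time when `NULL`).
#' @param v_init Initial value for `v`. Default 1.
#' @param a_bounds,v_bounds Lower/upper bounds; the fit works on
#'   `log(a)`, `log(v)` for conditioning, so bounds must be positive.
#' @param weighting `"none"` (plain least squares, default) or `"relative"`
#'   (weights `1/max(y, floor)^2`, giving each point roughly equal relative
#'   influence).
#' @param max_iter Maximum Levenberg-Marquardt iterations.
#' @param tol Convergence tolerance passed to the optimiser.
#' @return A list of class `rcm_fit_options`.
#' @export
fit_options <- function(a_init = NULL, v_init = 1,
                        a_bounds = c(1, 1e9), v_bounds = c(1e-3, 1e3),
                        weighting = c("none", "relative"),
                        max_iter = 200, tol = 1e-10) {
  weighting <- match.arg(weighting)
  stopifnot(all(a_bounds > 0), all(v_bounds > 0),
            a_bounds[1] < a_bounds[2], v_bounds[1] < v_bounds[2])
  structure(
    list(a_init = a_init, v_init = v_init, a_bounds = a_bounds,
         v_bounds = v_bounds, weighting = weighting,
         max_iter = max_iter, tol = tol),
    class = "rcm_fit_options"
  )
}

#' Fit the reactive continuum model to a dissolution curve
#'
#' With M0 fixed (from [estimate_m0] or supplied), fits the time-scale
#' parameter `a` and heterogeneity exponent `v` of the cumulative release
#' curve \eqn{Fe_d(t) = M_0 (1 - (a/(a+t))^v)} by Levenberg-Marquardt
#' nonlinear least squares on the log-transformed parameters. Noisy,
#' non-monotone cumulative data are fitted as-is (no isotonic smoothing),
#' so residuals remain unbiased.
#'
#' @param curve A [dissolution_curve] with at least 4 points.
#' @param m0 Fixed total extractable amount, micromol per g dry weight.
#'   `NULL` (default) applies [estimate_m0] with its default rule.
#' @param options An [fit_options] list.
#' @return An object of class `rcm_fit` with elements `params`
#'   ([rcm_params]), `m0_source`, `residuals` (model minus data, per point),
#'   `converged`, `se_a`, `se_v` (delta-method standard errors on the natural
#'   scale; `NA` if unavailable), `n_points`, `rss` and `stable`.
#' @examples
#' truth <- rcm_params(30, 5000, 1.5)
#' cv <- dissolution_curve(extraction_schedule(),
#'                         rcm_dissolved(truth, extraction_schedule()),
#'                         0.5, 0.1)
#' fit_rcm(cv, m0 = 30)
#' @export
fit_rcm <- function(curve, m0 = NULL, options = fit_options()) {
  stopifnot(inherits(curve, "dissolution_curve"),
            inherits(options, "rcm_fit_options"))
  t <- curve$times
  y <- curve$cumulative_fe
  if (length(t) < 4L) stop("curve must have at least 4 points", call. = FALSE)
  if (all(y == 0)) stop("degenerate curve: all cumulative Fe values are zero",
                        call. = FALSE)
  stable <- NA
  if (is.null(m0)) {
    est <- estimate_m0(curve)
    m0 <- est$m0
    stable <- est$stable
    m0_source <- paste0("plateau:", est$rule)
  } else {
    m0_source <- "fixed"
  }
  if (!is.numeric(m0) || m0 <= 0) stop("`m0` must be > 0", call. = FALSE)

  a0 <- options$a_init %||% max(stats::median(t[t > 0]), options$a_bounds[1])
  v0 <- options$v_init
  a0 <- min(max(a0, options$a_bounds[1]), options$a_bounds[2])
  v0 <- min(max(v0, options$v_bounds[1]), options$v_bounds[2])
  w <- switch(options$weighting,
    none = rep(1, length(y)),
    relative = 1 / pmax(y, max(y) * 1e-3)^2
  )
  dat <- data.frame(t = t, y = y, w = w)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ m0 * (1 - (exp(la) / (exp(la) + t))^exp(lv)),
      data = dat,
      start = list(la = log(a0), lv = log(v0)),
      lower = log(c(options$a_bounds[1], options$v_bounds[1])),
      upper = log(c(options$a_bounds[2], options$v_bounds[2])),
      weights = w,
      control = minpack.lm::nls.lm.control(
        maxiter = options$max_iter, ftol = options$tol, ptol = options$tol
      )
    ),
    error = function(e) e
  )

  if (inherits(fit, "error")) {
    params <- rcm_params(m0, a0, v0)
    res <- rcm_dissolved(params, t) - y
    out <- list(params = params, m0_source = m0_source, residuals = res,
                converged = FALSE, se_a = NA_real_, se_v = NA_real_,
                n_points = length(t), rss = sum(res^2), stable = stable,
                message = conditionMessage(fit))
    return(structure(out, class = "rcm_fit"))
  }

  cf <- stats::coef(fit)
  a_hat <- exp(cf[["la"]])
  v_hat <- exp(cf[["lv"]])
  params <- rcm_params(m0, a_hat, v_hat)
  res <- rcm_dissolved(params, t) - y
  conv <- fit$convInfo$isConv %||% TRUE
  se <- tryCatch(sqrt(diag(stats::vcov(fit))), error = function(e) c(NA, NA))
  structure(
    list(
      params = params, m0_source = m0_source, residuals = res,
      converged = isTRUE(conv),
      se_a = a_hat * se[[1]], se_v = v_hat * se[[2]],  # delta method
      n_points = length(t), rss = sum(res^2), stable = stable
    ),
    class = "rcm_fit"
  )
}

#' @export
print.rcm_fit <- function(x, ...) {
  p <- x$params
  cat(sprintf(
    "<rcm_fit>%s M0 = %.4g (source: %s), a = %.4g s, v = %.4g\n  n = %d, RSS = %.3g, v/a = %.3g /s, 1+1/v = %.3g\n",
    if (x$converged) "" else " [NOT CONVERGED]",
    p$m0, x$m0_source, p$a, p$v, x$n_points, x$rss, p$v / p$a, 1 + 1 / p$v
  ))
  invisible(x)
}

#' Per-vessel RCM parameter table
#'
#' Runs the plateau rule, the RCM fit and the derived-parameter algebra on a
#' list of dissolution curves and returns one tidy row per vessel — the
#' standard summary emitted by the pipeline for chemical and microbial
#' extractions alike.
#'
#' @param curves A list of [dissolution_curve] objects.
#' @param options An [fit_options] list.
#' @param rule,window Plateau rule arguments passed to [estimate_m0].
#' @return A tibble with columns `label`, `is_control`, `m0`, `a`, `v`,
#'   `reducibility`, `composition`, `lability`, `converged`, `stable`,
#'   `n_points`, `rss`.
#' @export
rcm_parameter_table <- function(curves, options = fit_options(),
                                rule = "max", window = 0.05) {
  stopifnot(is.list(curves))
  rows <- lapply(curves, function(cv) {
    est <- estimate_m0(cv, rule = rule, window = window)
    fit <- fit_rcm(cv, m0 = est$m0, options = options)
    p <- fit$params
    tibble::tibble(
      label = cv$label, is_control = cv$is_control,
      m0 = p$m0, a = p$a, v = p$v,
      reducibility = p$v / p$a, composition = 1 + 1 / p$v,
      lability = (p$v / p$a) * p$m0,
      converged = fit$converged, stable = est$stable,
      n_points = fit$n_points, rss = fit$rss
    )
  })
  dplyr::bind_rows(rows)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
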