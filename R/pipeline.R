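#' Configuration of a full pipeline run
#'
#' Exactly one of `input_dir` (a directory of input tables, see [readers])
#' and `scenario` (a [scenario_config] to simulate first) must be given.
#'
#' @param input_dir Directory holding `dissolution.tsv`, `hcl.tsv`,
#'   `tracer.tsv`, `stations.tsv`.
#' @param scenario A [scenario_config]; the simulated input tables are
#'   written to `out_dir/inputs` so the run is traceable.
#' @param out_dir Output directory.
#' @param seed Integer seed echoed into the scenario (ignored for file
#'   inputs, which carry no randomness).
#' @param plateau_rule `"max"` or `"tail_mean"` (see [estimate_m0]).
#' @param withdrawal_correct Apply the aliquot mass-balance correction in
#'   [build_dissolution_curve]?
#' @param subsets Optional named list of station-id vectors; each entry adds
#'   a filtered gradient fit (e.g. excluding stations under a side-fjord's
#'   influence).
#' @param alpha Significance level for gradient flags.
#' @param max_depth Integration bound for depth-integrated SRR, cm
#'   (default: all slices).
#' @param verbosity 0 (silent), 1 (progress messages).
#' @return A list of class `run_config`.
#' @export
run_config <- function(input_dir = NULL, scenario = NULL, out_dir,
                       seed = 1L, plateau_rule = "max",
                       withdrawal_correct = FALSE, subsets = NULL,
                       alpha = 0.05, max_depth = Inf, verbosity = 0) {
  if (is.null(input_dir) == is.null(scenario)) {
    stop("exactly one of `input_dir` and `scenario` must be given",
         call. = FALSE)
  }
  if (!is.null(scenario)) {
    stopifnot(inherits(scenario, "scenario_config"))
    scenario$seed <- as.integer(seed)
  }
  structure(
    list(input_dir = input_dir, scenario = scenario, out_dir = out_dir,
         seed = as.integer(seed), plateau_rule = plateau_rule,
         withdrawal_correct = withdrawal_correct, subsets = subsets,
         alpha = alpha, max_depth = max_depth, verbosity = verbosity),
    class = "run_config"
  )
}

log_line <- function(lines, level, msg, verbosity) {
  line <- sprintf("[%s] %s", level, msg)
  if (verbosity > 0) message(line)
  c(lines, line)
}

#' Run the full benthic iron-cycling pipeline
#'
#' Orchestrates reading (or simulating) the input tables, building per-vessel
#' dissolution curves, fixing M0 from the plateau, fitting the reactive
#' continuum model, replicate aggregation, sequential-HCl speciation, tracer
#' rate calculation with depth integration, and exponential transect-gradient
#' analysis. All result tables, a run log and a config echo are written to
#' `config$out_dir`; the run is deterministic given the config and seed, and
#' every output row carries the station/depth/vessel keys of the rows it came
#' from.
#'
#' @param config A [run_config].
#' @return Invisibly, a list of class `fjordfe_results` with tibbles
#'   `parameters`, `replicate_summary`, `speciation`, `srr_rates`,
#'   `srr_integrated`, `gradients`, plus `log`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  lg <- character()
  lg <- log_line(lg, "INFO",
                 paste0("fjordfe ", as.character(utils::packageVersion("fjordfe")),
                        ", seed ", config$seed),
                 config$verbosity)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  if (!is.null(config$scenario)) {
    bundle <- simulate_transect(config$scenario)
    write_bundle(bundle, file.path(config$out_dir, "inputs"))
    tabs <- bundle[c("stations", "dissolution", "hcl", "tracer")]
    lg <- log_line(lg, "INFO", "simulated scenario inputs", config$verbosity)
  } else {
    tabs <- read_bundle_dir(config$input_dir)
    lg <- log_line(lg, "INFO", paste("read inputs from", config$input_dir),
                   config$verbosity)
  }

  # --- per-vessel curves and RCM fits -------------------------------------
  keys <- unique(tabs$dissolution[c("station", "depth_top", "extraction",
                                    "vessel")])
  rows <- vector("list", nrow(keys))
  for (i in seq_len(nrow(keys))) {
    k <- keys[i, ]
    sub <- dplyr::inner_join(tabs$dissolution, k,
                             by = c("station", "depth_top", "extraction",
                                    "vessel"))
    sub <- sub[order(sub$time_s), ]
    cv <- build_dissolution_curve(
      sub$time_s, sub$conc_uM, volume = sub$volume_l[1],
      dry_mass = sub$dry_mass_g[1], correct = config$withdrawal_correct,
      label = k$vessel, is_control = isTRUE(as.logical(sub$is_control[1]))
    )
    est <- estimate_m0(cv, rule = config$plateau_rule)
    fit <- fit_rcm(cv, m0 = est$m0)
    dp <- derive_params(fit$params)
    rows[[i]] <- tibble::tibble(
      station = k$station, depth_top = k$depth_top,
      extraction = k$extraction, vessel = k$vessel,
      is_control = cv$is_control,
      m0 = fit$params$m0, a = fit$params$a, v = fit$params$v,
      reducibility = dp$reducibility, composition = dp$composition,
      lability = dp$lability,
      converged = fit$converged, stable = est$stable,
      n_points = fit$n_points, rss = fit$rss
    )
  }
  parameters <- dplyr::bind_rows(rows)
  n_bad <- sum(!parameters$converged)
  lg <- log_line(lg, if (n_bad > 0) "WARN" else "INFO",
                 sprintf("fitted %d vessels (%d non-converged)",
                         nrow(parameters), n_bad), config$verbosity)

  # --- replicate aggregation (controls kept separate) ---------------------
  micr <- parameters[parameters$extraction == "microbial", ]
  replicate_summary <- tibble::tibble()
  if (nrow(micr) > 0) {
    grp <- unique(micr[c("station", "depth_top")])
    srows <- lapply(seq_len(nrow(grp)), function(i) {
      g <- dplyr::inner_join(micr, grp[i, ], by = c("station", "depth_top"))
      inoc <- g[!g$is_control, ]
      ctrl <- g[g$is_control, ]
      agg_m0 <- aggregate_replicates(
        inoc$m0, if (nrow(ctrl)) ctrl$m0[1] else NULL)
      agg_lab <- aggregate_replicates(
        inoc$lability, if (nrow(ctrl)) ctrl$lability[1] else NULL)
      tibble::tibble(
        station = grp$station[i], depth_top = grp$depth_top[i],
        n = agg_m0$n,
        m0_mean = agg_m0$mean, m0_sd = agg_m0$sd, m0_control = agg_m0$control,
        lability_mean = agg_lab$mean, lability_sd = agg_lab$sd,
        lability_control = agg_lab$control
      )
    })
    replicate_summary <- dplyr::bind_rows(srows)
  }

  # --- sequential HCl speciation ------------------------------------------
  hkeys <- unique(tabs$hcl[c("station", "depth_top")])
  hrows <- lapply(seq_len(nrow(hkeys)), function(i) {
    h <- dplyr::inner_join(tabs$hcl, hkeys[i, ], by = c("station", "depth_top"))
    s05 <- h[h$step == "0.5 M HCl", ]
    s6 <- h[h$step == "6 M HCl", ]
    if (nrow(s05) != 1L || nrow(s6) != 1L) {
      stop("speciation at station ", hkeys$station[i],
           " needs exactly one 0.5 M and one 6 M HCl step", call. = FALSE)
    }
    sp <- hcl_speciation(c(fe2 = s05$fe2, fe_total = s05$fe_total),
                         c(fe2 = s6$fe2, fe_total = s6$fe_total))
    dplyr::mutate(tibble::as_tibble(sp),
                  station = hkeys$station[i], depth_top = hkeys$depth_top[i],
                  total_hcl = total_hcl(sp), .before = 1)
  })
  speciation <- dplyr::bind_rows(hrows)

  # --- sulfate reduction rates --------------------------------------------
  tr <- tabs$tracer
  tr$rate <- srr_from_tracer(tr$sulfate_mM, tr$porosity, tr$a_tris, tr$a_so4,
                             tr$t_days)
  srr_rates <- tr[c("station", "depth_top", "thickness", "rate")]
  irows <- lapply(split(srr_rates, srr_rates$station), function(g) {
    tibble::tibble(
      station = g$station[1],
      integrated = depth_integrate(
        rate_profile(g$depth_top, g$thickness, g$rate),
        max_depth = config$max_depth
      )
    )
  })
  srr_integrated <- dplyr::bind_rows(irows)
  srr_integrated <- srr_integrated[order(match(srr_integrated$station,
                                               tabs$stations$station)), ]

  # --- transect gradients of surface FeA amount and lability --------------
  surf <- parameters[parameters$extraction == "chemical" &
                       parameters$depth_top == min(parameters$depth_top), ]
  surf <- dplyr::inner_join(surf, tabs$stations, by = "station")
  gradients <- tibble::tibble()
  grad_one <- function(metric, values, subset_name, subset) {
    rec <- tibble::tibble(station = surf$station,
                          distance_km = surf$distance_km, value = values)
    gf <- fit_exponential_gradient(rec, subset = subset, alpha = config$alpha)
    fc <- transect_fold_change(rec, subset = subset)
    tibble::tibble(
      metric = metric, subset = subset_name, n = gf$n,
      growth_rate = gf$growth_rate, intercept = gf$intercept,
      r2 = gf$r2, p_slope = gf$p_slope, significant = gf$significant,
      fold_change = fc
    )
  }
  if (nrow(surf) >= 3) {
    gradients <- dplyr::bind_rows(
      grad_one("m0", surf$m0, "all", NULL),
      grad_one("lability", surf$lability, "all", NULL)
    )
    for (nm in names(config$subsets)) {
      gradients <- dplyr::bind_rows(
        gradients,
        grad_one("m0", surf$m0, nm, config$subsets[[nm]]),
        grad_one("lability", surf$lability, nm, config$subsets[[nm]])
      )
    }
    lg <- log_line(lg, "INFO",
                   sprintf("gradient fits: %d", nrow(gradients)),
                   config$verbosity)
  } else {
    lg <- log_line(lg, "WARN", "fewer than 3 surface stations; gradient fits skipped",
                   config$verbosity)
  }

  results <- structure(
    list(parameters = parameters, replicate_summary = replicate_summary,
         speciation = speciation, srr_rates = srr_rates,
         srr_integrated = srr_integrated, gradients = gradients, log = lg),
    class = "fjordfe_results"
  )

  readr::write_tsv(parameters, file.path(config$out_dir, "parameters.tsv"))
  readr::write_tsv(replicate_summary,
                   file.path(config$out_dir, "replicate_summary.tsv"))
  readr::write_tsv(speciation, file.path(config$out_dir, "speciation.tsv"))
  readr::write_tsv(srr_rates, file.path(config$out_dir, "srr_rates.tsv"))
  readr::write_tsv(srr_integrated,
                   file.path(config$out_dir, "srr_integrated.tsv"))
  readr::write_tsv(gradients, file.path(config$out_dir, "gradients.tsv"))
  writeLines(lg, file.path(config$out_dir, "run_log.txt"))
  echo <- config
  echo$version <- as.character(utils::packageVersion("fjordfe"))
  yaml::write_yaml(unclass_deep(echo), file.path(config$out_dir, "config_echo.yaml"))
  invisible(results)
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}

#' Human-readable run summary
#'
#' A pure function of the result tables: per-transect gradient lines,
#' fit-convergence counts, and SRR totals.
#'
#' @param results A `fjordfe_results` list from [run_pipeline].
#' @return A character vector of report lines (empty for empty results),
#'   returned invisibly and printed.
#' @export
pipeline_report <- function(results) {
  stopifnot(inherits(results, "fjordfe_results"))
  out <- character()
  if (nrow(results$parameters) > 0) {
    n_bad <- sum(!results$parameters$converged)
    out <- c(out, sprintf("RCM fits: %d vessels, %d converged, %d flagged",
                          nrow(results$parameters),
                          sum(results$parameters$converged), n_bad))
  }
  if (nrow(results$gradients) > 0) {
    for (i in seq_len(nrow(results$gradients))) {
      g <- results$gradients[i, ]
      out <- c(out, sprintf(
        "gradient %s [%s]: %.3g /km, r2 = %.3f, fold change %.3g, %ssignificant",
        g$metric, g$subset, g$growth_rate, g$r2, g$fold_change,
        if (isTRUE(g$significant)) "" else "not "
      ))
    }
  }
  if (nrow(results$srr_integrated) > 0) {
    out <- c(out, sprintf(
      "depth-integrated SRR: %.4g-%.4g nmol cm-2 d-1 across %d stations",
      min(results$srr_integrated$integrated),
      max(results$srr_integrated$integrated), nrow(results$srr_integrated)
    ))
  }
  if (length(out)) cat(out, sep = "\n")
  invisible(out)
}
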