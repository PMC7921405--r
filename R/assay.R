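#' Linear calibration of a colorimetric assay
#'
#' Ordinary least-squares calibration line for the ferrozine (Fe(II), 562 nm)
#' or formaldoxime (Mn, 450 nm) assay: absorbance = slope * concentration +
#' intercept.
#'
#' @param concentration Standard concentrations, micromolar; at least two
#'   distinct values.
#' @param absorbance Measured absorbances of the standards.
#' @return An object of class `calibration_line` with elements `slope`
#'   (absorbance per micromolar, > 0), `intercept`, `r2`, `n_standards`.
#' @examples
#' calibrate_linear(c(0, 50, 100), c(0.01, 0.26, 0.51))
#' @export
calibrate_linear <- function(concentration, absorbance) {
  concentration <- as.numeric(concentration)
  absorbance <- as.numeric(absorbance)
  if (length(concentration) != length(absorbance)) {
    stop("standards must pair one absorbance with each concentration", call. = FALSE)
  }
  if (length(unique(concentration)) < 2L) {
    stop("calibration needs at least 2 distinct standard concentrations",
         call. = FALSE)
  }
  fit <- stats::lm(absorbance ~ concentration)
  slope <- unname(stats::coef(fit)[2])
  if (!is.finite(slope) || slope <= 0) {
    stop("calibration slope must be positive", call. = FALSE)
  }
  # r2 of a simple OLS line; suppressWarnings covers zero-variance absorbance
  r2 <- suppressWarnings(stats::cor(concentration, absorbance)^2)
  structure(
    list(slope = slope, intercept = unname(stats::coef(fit)[1]),
         r2 = if (is.finite(r2)) r2 else 1, n_standards = length(concentration)),
    class = "calibration_line"
  )
}

#' @export
print.calibration_line <- function(x, ...) {
  cat(sprintf(
    "<calibration_line> A = %.5g * c + %.5g (r2 = %.4f, n = %d)\n",
    x$slope, x$intercept, x$r2, x$n_standards
  ))
  invisible(x)
}

#' Convert absorbance to concentration via a calibration line
#'
#' Inverts the calibration (`(A - intercept)/slope`) and applies the dilution
#' factor. Values that invert to below zero (absorbance under the blank) are
#' clipped to 0 and flagged, keeping concentrations physically non-negative.
#'
#' @param cal A [calibrate_linear] result.
#' @param absorbance Measured absorbance(s).
#' @param dilution_factor Dilution applied before measurement (>= 1).
#' @return A tibble with columns `conc` (micromolar) and `clipped` (logical).
#' @export
absorbance_to_conc <- function(cal, absorbance, dilution_factor = 1) {
  stopifnot(inherits(cal, "calibration_line"))
  if (any(dilution_factor < 1)) {
    stop("`dilution_factor` must be >= 1", call. = FALSE)
  }
  conc <- (as.numeric(absorbance) - cal$intercept) / cal$slope * dilution_factor
  clipped <- conc < 0
  conc[clipped] <- 0
  tibble::tibble(conc = conc, clipped = clipped)
}

#' Sequential-HCl iron speciation accounting
#'
#' Books the two sequential end-point leaches — 0.5 M HCl (1 h, 20 C; the
#' poorly crystalline pool) and 6 M HCl (24 h, 70 C; the crystalline pool) —
#' into the standard speciation table. Fe(III) is obtained by difference
#' (total Fe after hydroxylamine reduction minus Fe(II)); a negative
#' difference is clipped to zero and flagged. `total_hcl` is the sum of the
#' two step totals.
#'
#' @param hcl05 Named numeric `c(fe2 = , fe_total = )` for the 0.5 M HCl
#'   step, micromol per g dry weight.
#' @param hcl6 Same for the 6 M HCl step.
#' @return An object of class `hcl_speciation`: a tibble with columns `step`,
#'   `fe2`, `fe_total`, `fe3`, `clipped`, and attribute `total_hcl`.
#' @examples
#' hcl_speciation(c(fe2 = 40, fe_total = 100), c(fe2 = 100, fe_total = 500))
#' @export
hcl_speciation <- function(hcl05, hcl6) {
  one <- function(x, nm) {
    if (is.null(x) || !all(c("fe2", "fe_total") %in% names(x))) {
      stop("step `", nm, "` must supply named values fe2 and fe_total",
           call. = FALSE)
    }
    x <- as.numeric(x[c("fe2", "fe_total")])
    if (any(!is.finite(x)) || any(x < 0)) {
      stop("step `", nm, "` values must be finite and non-negative", call. = FALSE)
    }
    x
  }
  s05 <- one(hcl05, "0.5 M HCl")
  s6 <- one(hcl6, "6 M HCl")
  fe2 <- c(s05[1], s6[1])
  fe_total <- c(s05[2], s6[2])
  diff3 <- fe_total - fe2
  clipped <- diff3 < 0
  out <- tibble::tibble(
    step = c("0.5 M HCl", "6 M HCl"),
    fe2 = fe2, fe_total = fe_total,
    fe3 = pmax(diff3, 0), clipped = clipped
  )
  attr(out, "total_hcl") <- sum(fe_total)
  class(out) <- c("hcl_speciation", class(out))
  out
}

#' Total HCl-extractable iron of a speciation result
#' @param x An [hcl_speciation] result.
#' @return Micromol per g dry weight.
#' @export
total_hcl <- function(x) {
  stopifnot(inherits(x, "hcl_speciation"))
  attr(x, "total_hcl")
}

#' Porosity and water content from drying a known sediment volume
#'
#' Weight loss of a known volume of wet sediment after drying to constant
#' weight at 105 C gives the water content (wet-mass basis) and, via the
#' water density, the porosity (porewater volume fraction) needed to scale
#' porewater rates to whole sediment.
#'
#' @param wet_mass Wet sediment mass, g (`>= dry_mass`).
#' @param dry_mass Dry sediment mass, g (> 0).
#' @param sample_volume Sampled sediment volume, cm^3 (> 0).
#' @param water_density Porewater density, g per cm^3 (default 1.0).
#' @return A list with `porosity` and `water_content`, both in [0, 1).
#' @export
physical_props <- function(wet_mass, dry_mass, sample_volume,
                           water_density = 1.0) {
  if (!(dry_mass > 0) || wet_mass < dry_mass) {
    stop("need wet_mass >= dry_mass > 0", call. = FALSE)
  }
  if (!(sample_volume > 0)) stop("`sample_volume` must be > 0", call. = FALSE)
  porosity <- ((wet_mass - dry_mass) / water_density) / sample_volume
  if (porosity > 1) {
    stop("computed porosity > 1: inconsistent mass/volume inputs", call. = FALSE)
  }
  list(porosity = porosity, water_content = (wet_mass - dry_mass) / wet_mass)
}

#' Aggregate replicate vessels, keeping the uninoculated control separate
#'
#' Microbial extractions run in triplicate plus an uninoculated control that
#' measures the native iron-reducer population's activity. The control is a
#' measurement in its own right, not a blank: it is reported alongside the
#' replicate mean, never pooled with it and never subtracted.
#'
#' @param values Per-replicate parameter values (inoculated vessels), n >= 1.
#' @param control_value Optional control-vessel value.
#' @return A list with `mean`, `sd` (`NA` for a single replicate), `n`, and
#'   `control` (`NA` if none).
#' @examples
#' aggregate_replicates(c(30, 32, 28), control_value = 2)
#' @export
aggregate_replicates <- function(values, control_value = NULL) {
  values <- as.numeric(values)
  if (length(values) < 1L) stop("need at least one replicate", call. = FALSE)
  list(
    mean = mean(values),
    sd = if (length(values) > 1L) stats::sd(values) else NA_real_,
    n = length(values),
    control = if (is.null(control_value)) NA_real_ else as.numeric(control_value)
  )
}
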