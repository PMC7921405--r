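#' Dissolution curve for one extraction vessel
#'
#' A cumulative Fe-released time series, normalised to micromol per g dry
#' weight, for a single chemical (ascorbate) or microbial extraction vessel.
#' The canonical unit throughout the package is micromol per g dry weight;
#' times are seconds since extraction start.
#'
#' @param times Seconds since extraction start; strictly increasing, first
#'   value 0 (a sample is drawn immediately after the extraction solution is
#'   added).
#' @param cumulative_fe Cumulative Fe released, micromol per g dry weight.
#'   The first value may be positive (instantaneous release of loosely bound
#'   Fe); all values must be non-negative.
#' @param dry_mass Sediment dry mass in the vessel, g.
#' @param volume Extraction fluid volume, litres.
#' @param label Vessel/replicate identifier.
#' @param is_control Logical; `TRUE` for an uninoculated control vessel.
#'
#' @return An object of class `dissolution_curve`.
#' @export
dissolution_curve <- function(times, cumulative_fe, dry_mass, volume,
                              label = "vessel", is_control = FALSE) {
  times <- as.numeric(times)
  cumulative_fe <- as.numeric(cumulative_fe)
  if (length(times) != length(cumulative_fe)) {
    stop("`times` and `cumulative_fe` must have the same length", call. = FALSE)
  }
  if (any(!is.finite(times)) || any(diff(times) <= 0)) {
    stop("`times` must be finite and strictly increasing", call. = FALSE)
  }
  if (times[1] != 0) {
    stop("`times` must start at 0 (seconds since extraction start)",
         call. = FALSE)
  }
  if (any(!is.finite(cumulative_fe)) || any(cumulative_fe < 0)) {
    stop("`cumulative_fe` must be finite and non-negative", call. = FALSE)
  }
  if (!is.numeric(dry_mass) || dry_mass <= 0) stop("`dry_mass` must be > 0", call. = FALSE)
  if (!is.numeric(volume) || volume <= 0) stop("`volume` must be > 0", call. = FALSE)
  structure(
    list(
      times = times, cumulative_fe = cumulative_fe,
      dry_mass = as.numeric(dry_mass), volume = as.numeric(volume),
      label = as.character(label), is_control = isTRUE(is_control)
    ),
    class = "dissolution_curve"
  )
}

#' @export
print.dissolution_curve <- function(x, ...) {
  cat(sprintf(
    "<dissolution_curve> '%s'%s: %d points over %.2f h, max %.3g umol/g dw\n",
    x$label, if (x$is_control) " (control)" else "", length(x$times),
    max(x$times) / 3600, max(x$cumulative_fe)
  ))
  invisible(x)
}

#' @export
as.data.frame.dissolution_curve <- function(x, ...) {
  data.frame(time_s = x$times, cumulative_umol_per_gdw = x$cumulative_fe)
}

#' Build a dissolution curve from timed concentration measurements
#'
#' Converts the Fe(II) concentrations measured in aliquots drawn from an
#' extraction vessel into a cumulative per-gram-dry-weight release curve:
#' `cumulative_fe[i] = conc[i] * volume / dry_mass`. With
#' `correct = TRUE` the running mass balance accounts for the aliquots
#' themselves: Fe currently in the vessel is `conc[i]` times the fluid volume
#' remaining after earlier withdrawals, and Fe carried out in earlier aliquots
#' is credited back, so
#' `cumulative_fe[i] = (conc[i] * V_i + sum_(j<i) conc[j] * w_j) / dry_mass`
#' with `V_i = volume - sum_(j<i) w_j`. The default is no correction:
#' aliquots (a few mL via a rhizon sampler) are small relative to the 100 mL
#' vessel.
#'
#' @param times Sampling times, seconds; strictly increasing from 0.
#' @param conc Measured Fe(II) concentration in each aliquot, micromolar.
#' @param volume Initial extraction fluid volume, litres.
#' @param dry_mass Sediment dry mass, g.
#' @param withdrawal Volume removed per sample, litres; scalar or one value
#'   per sample. Only used when `correct = TRUE`.
#' @param correct Apply the withdrawal mass-balance correction?
#' @inheritParams dissolution_curve
#' @return A [dissolution_curve].
#' @examples
#' build_dissolution_curve(c(0, 300), c(0, 50), volume = 0.1, dry_mass = 0.5)
#' @export
build_dissolution_curve <- function(times, conc, volume, dry_mass,
                                    withdrawal = 0, correct = FALSE,
                                    label = "vessel", is_control = FALSE) {
  times <- as.numeric(times)
  if (anyDuplicated(times)) stop("duplicate timestamps in `times`", call. = FALSE)
  if (is.unsorted(times)) stop("`times` must be non-decreasing", call. = FALSE)
  conc <- as.numeric(conc)
  if (length(conc) != length(times)) {
    stop("`conc` and `times` must have the same length", call. = FALSE)
  }
  if (!correct) {
    cum <- conc * volume / dry_mass
  } else {
    w <- rep_len(as.numeric(withdrawal), length(times))
    removed_before <- c(0, cumsum(conc * w)[-length(times)])   # umol carried out
    vol_remaining <- volume - c(0, cumsum(w)[-length(times)])  # L left in vessel
    if (any(vol_remaining <= 0)) {
      stop("withdrawals exceed the extraction volume", call. = FALSE)
    }
    cum <- (conc * vol_remaining + removed_before) / dry_mass
  }
  dissolution_curve(times, cum, dry_mass = dry_mass, volume = volume,
                    label = label, is_control = is_control)
}
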