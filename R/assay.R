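# Reporter and growth-assay arithmetic: dual-luciferase normalization,
# fold changes versus control, area under growth curves, and percent
# inhibition of spheroid areas.

#' Relative luciferase activity
#'
#' Firefly-luciferase activity divided by Renilla-luciferase activity (the
#' co-transfected Renilla reporter controls for transfection efficiency).
#'
#' @param firefly,renilla positive readings
#' @return ratio
#' @export
relative_luciferase <- function(firefly, renilla) {
  if (any(renilla <= 0)) stop("Renilla reading must be > 0")
  firefly / renilla
}

#' Fold change versus a control value
#'
#' @param value measurement
#' @param control positive control measurement
#' @return `value / control`
#' @export
fold_change_vs_control <- function(value, control) {
  if (any(control <= 0)) stop("control must be > 0")
  value / control
}

#' Area under a growth curve
#'
#' Trapezoidal integral of a time series over its full span. Points are
#' used raw (no smoothing or regridding).
#'
#' @param times strictly ascending times (hours)
#' @param values non-negative readings (confluence, area, counts)
#' @return area
#' @export
auc <- function(times, values) {
  if (length(times) < 2) stop("need at least 2 time points")
  if (length(times) != length(values)) stop("times/values length mismatch")
  if (any(diff(times) <= 0)) stop("times must be strictly ascending")
  pracma::trapz(times, values)
}

#' Percent inhibition relative to control
#'
#' `100 * (1 - treated / control)`: 0 when treatment has no effect, 100 at
#' complete inhibition; negative values indicate growth above control.
#'
#' @param treated non-negative measurement under treatment
#' @param control positive control measurement
#' @return percent
#' @export
percent_inhibition <- function(treated, control) {
  if (any(control <= 0)) stop("control must be > 0")
  100 * (1 - treated / control)
}
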