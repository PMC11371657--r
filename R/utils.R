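# Shared numerical helpers. Units throughout the package: lengths in um,
# time in min, concentration in mM, angles in radians; image x rightward,
# y downward, origin at the top-left pixel corner.

#' Error function
#'
#' `erf(z)` as used by the diffusive concentration profiles.
#'
#' @param z numeric vector.
#' @return numeric vector of the same length.
#' @keywords internal
erf <- function(z) 2 * stats::pnorm(z * sqrt(2)) - 1

## stop unless every argument is finite numeric
check_finite <- function(...) {
  args <- list(...)
  nm <- names(args)
  for (i in seq_along(args)) {
    if (!is.numeric(args[[i]]) || any(!is.finite(args[[i]]))) {
      stop(sprintf("'%s' must be finite numeric", nm[i]), call. = FALSE)
    }
  }
  invisible(TRUE)
}

## unit vector for a gradient axis given as "x"/"y" or a length-2 vector
axis_unit_vector <- function(axis) {
  if (is.character(axis)) {
    axis <- match.arg(axis, c("y", "x"))
    return(if (axis == "x") c(1, 0) else c(0, 1))
  }
  stopifnot(is.numeric(axis), length(axis) == 2)
  n <- sqrt(sum(axis^2))
  if (n == 0) stop("gradient axis vector must be non-zero")
  axis / n
}

## wrap an angle to the axial range [0, pi)
wrap_axial <- function(theta) {
  out <- theta %% pi
  out[out < 0] <- out[out < 0] + pi
  out
}

#' Unwrap an axial (mod-pi) angle series to a continuous signal
#'
#' Rod-shaped cells have a body axis, not a direction, so measured
#' orientations live on \[0, pi). Differences between consecutive frames are
#' mapped to (-pi/2, pi/2\] and accumulated, yielding a continuous series
#' suitable for smoothing and differentiation.
#'
#' @param theta numeric vector of axial angles (radians).
#' @return numeric vector, continuous unwrapped angles.
#' @export
unwrap_axial <- function(theta) {
  if (length(theta) < 2) return(theta)
  d <- diff(theta)
  d <- d - round(d / pi) * pi
  cumsum(c(theta[1], d))
}
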