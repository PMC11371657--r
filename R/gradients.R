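# Microfluidic concentration-field models and gradient-design arithmetic.
#
# Three scenario geometries are covered:
#  * taylor_aris  - a sigmoidal solute front, pre-stretched by shear-enhanced
#    (Taylor-Aris) dispersion along a long inlet tube, advected past the cells
#    at the mean flow speed U. Cells experience a slow, smooth temporal change
#    with a vanishingly small spatial gradient.
#  * dual_flow    - two co-flowing streams in a Y-shaped channel; molecular
#    diffusion forms a steady erf-shaped gradient across the channel width.
#  * switching    - abrupt exchange of the whole medium between two
#    concentrations, smoothed over a transition timescale tau.

#' Microfluidic gradient design parameters
#'
#' Container for the scenario parameters from which every reproduced design
#' number derives: the endpoint concentrations `C_max`/`C_min` (mM), the
#' transition timescale `tau` (min), the mean flow / front speed `U` (um/min),
#' the reference cell speed `V_C` (um/min), the longitudinal gradient length
#' scale `L` (um, derived as `U * tau` when not supplied), a reference spatial
#' gradient `dCdx_ref` (mM/um, the dual-flow value the other designs are
#' compared against) and the cross-channel gradient length scale
#' `width_scale` (um).
#'
#' @param C_max,C_min endpoint concentrations (mM); `C_max > C_min >= 0`.
#' @param tau transition timescale (min).
#' @param U mean flow / front speed (um/min).
#' @param V_C reference cell speed (um/min).
#' @param L longitudinal gradient length scale (um); default `U * tau`.
#' @param dCdx_ref reference spatial gradient (mM/um).
#' @param width_scale cross-channel gradient length scale (um).
#' @return an object of class `gradient_design`.
#' @examples
#' gradient_design(C_max = 1.16, C_min = 0.84, tau = 60, U = 27000)
#' @export
gradient_design <- function(C_max, C_min, tau = NULL, U = NULL, V_C = NULL,
                            L = NULL, dCdx_ref = NULL, width_scale = 100) {
  check_finite(C_max = C_max, C_min = C_min)
  if (!(C_max > C_min && C_min >= 0)) stop("need C_max > C_min >= 0")
  if (!is.null(tau)) { check_finite(tau = tau); if (tau <= 0) stop("tau must be > 0") }
  if (!is.null(U)) { check_finite(U = U); if (U <= 0) stop("U must be > 0") }
  if (is.null(L) && !is.null(U) && !is.null(tau)) L <- U * tau
  if (!is.null(L) && L <= 0) stop("L must be > 0")
  if (width_scale <= 0) stop("width_scale must be > 0")
  structure(list(C_max = C_max, C_min = C_min, tau = tau, U = U, V_C = V_C,
                 L = L, dCdx_ref = dCdx_ref, width_scale = width_scale),
            class = "gradient_design")
}

#' @export
print.gradient_design <- function(x, ...) {
  cat("Gradient design (mM, min, um):\n")
  for (f in names(x)) if (!is.null(x[[f]])) cat(sprintf("  %-12s %g\n", f, x[[f]]))
  invisible(x)
}

#' Temporal gradient experienced by a moving cell
#'
#' A cell moving at speed `V_C` through a static spatial gradient `dCdx`
#' experiences the temporal gradient `dC/dt = V_C * dC/dx`. Signs are
#' preserved, so movement down-gradient yields a negative rate.
#'
#' @param V_C cell speed (um/min).
#' @param dCdx spatial concentration gradient (mM/um).
#' @return temporal gradient (mM/min).
#' @examples
#' temporal_gradient_from_motion(0.2, 0.02) # 0.004 mM/min
#' @export
temporal_gradient_from_motion <- function(V_C, dCdx) {
  check_finite(V_C = V_C, dCdx = dCdx)
  V_C * dCdx
}

#' Advected Taylor-Aris dispersion front
#'
#' Concentration at longitudinal position `x` and time `t` for a sigmoidal
#' front of length scale `L` advected at speed `U`:
#' `C = C_min + (C_max - C_min) * S((x - U t) / L)` with
#' `S(z) = (1 + erf(sqrt(pi) z)) / 2`. The `sqrt(pi)` slope normalisation
#' makes the mid-front spatial gradient exactly `(C_max - C_min) / L`, so the
#' quoted design value `dC/dx = (C_max - C_min)/L` is the literal mid-front
#' slope of the model field.
#'
#' @param design a [gradient_design()] with `L` (or `U` and `tau`) set.
#' @param x longitudinal position (um).
#' @param t time (min).
#' @return concentration (mM), vectorised over `x` and `t`.
#' @export
taylor_aris_front <- function(design, x, t) {
  stopifnot(inherits(design, "gradient_design"))
  if (is.null(design$L) || design$L <= 0) stop("design must carry L > 0")
  U <- if (is.null(design$U)) 0 else design$U
  z <- (x - U * t) / design$L
  design$C_min + (design$C_max - design$C_min) * 0.5 * (1 + erf(sqrt(pi) * z))
}

#' Steady dual-flow cross-channel concentration profile
#'
#' erf-shaped diffusive profile between 0 and `C_source` across the channel
#' width, centred at `y_mid`. The mid-channel slope magnitude is exactly
#' `C_source / width_scale` (same slope normalisation as
#' [taylor_aris_front()]), so a 2 mM source over a 100 um length scale gives
#' the reference spatial gradient 0.02 mM/um. `epoch_sign = +1` places the
#' high-concentration side at large `y`; `-1` mirrors the profile.
#'
#' @param C_source source-stream concentration (mM).
#' @param y cross-channel position (um).
#' @param width_scale gradient length scale (um).
#' @param epoch_sign +1 or -1, the current gradient orientation.
#' @param y_mid centreline position (um).
#' @return concentration (mM), vectorised over `y`.
#' @export
dualflow_profile <- function(C_source, y, width_scale = 100, epoch_sign = 1,
                             y_mid = 0) {
  check_finite(C_source = C_source, y = y)
  if (width_scale <= 0) stop("width_scale must be > 0")
  stopifnot(epoch_sign %in% c(-1, 1))
  C_source * 0.5 * (1 + epoch_sign * erf(sqrt(pi) * (y - y_mid) / width_scale))
}

#' Smooth concentration switch between two media
#'
#' Concentration over time when the supplied medium is exchanged at
#' `t_switch`, smoothed over the transition timescale `tau`. The ramp is a
#' C1 sinusoidal smoothstep that starts and completes exactly `tau/2` before
#' and after `t_switch`, so the mean `|dC/dt|` over the ramp is exactly
#' `(C_max - C_min) / tau`.
#'
#' @param design a [gradient_design()] with `tau` set.
#' @param t time (min), vectorised.
#' @param t_switch switch time (min).
#' @param direction `"up"` (C_min to C_max) or `"down"`.
#' @return concentration (mM).
#' @export
switching_profile <- function(design, t, t_switch, direction = c("up", "down")) {
  stopifnot(inherits(design, "gradient_design"))
  direction <- match.arg(direction)
  if (is.null(design$tau) || design$tau <= 0) stop("design must carry tau > 0")
  u <- (t - t_switch) / design$tau
  ramp <- ifelse(u <= -0.5, -1, ifelse(u >= 0.5, 1, sin(pi * u)))
  if (direction == "down") ramp <- -ramp
  mid <- (design$C_max + design$C_min) / 2
  mid + (design$C_max - design$C_min) / 2 * ramp
}

#' Gradient-design arithmetic report
#'
#' Computes the headline design numbers for a scenario: the mean temporal
#' gradient `dCdt`, the longitudinal length scale `L`, the spatial gradient
#' `dCdx`, the mean concentration, and fold ratios against the dual-flow
#' reference gradient `dCdx_ref`, against the cross-channel length scale
#' `width_scale`, and (optionally) against a second design's `dCdt`.
#'
#' For `scenario_kind = "dual_flow"` the temporal gradient is the one a
#' moving cell manufactures for itself, `V_C * dCdx_ref`; for the other
#' scenarios it is the rate imposed by the changing field,
#' `(C_max - C_min) / tau`.
#'
#' @param design a [gradient_design()].
#' @param scenario_kind `"dual_flow"`, `"taylor_aris"` or `"switching"`.
#' @param reference optional second [design_report()] (or design) whose
#'   `dCdt` the fold ratio `fold_dCdt_vs_reference` is taken against.
#' @return an object of class `design_report` (named list of numbers).
#' @examples
#' dual <- gradient_design(1.16, 0.84, V_C = 0.2, dCdx_ref = 0.02)
#' design_report(dual, "dual_flow")$dCdt # 0.004 mM/min
#' @export
design_report <- function(design,
                          scenario_kind = c("taylor_aris", "dual_flow", "switching"),
                          reference = NULL) {
  stopifnot(inherits(design, "gradient_design"))
  scenario_kind <- match.arg(scenario_kind)
  dC <- design$C_max - design$C_min
  out <- list(scenario_kind = scenario_kind,
              mean_C = (design$C_max + design$C_min) / 2)
  if (scenario_kind == "dual_flow") {
    if (is.null(design$V_C) || is.null(design$dCdx_ref)) {
      stop("dual_flow report needs V_C and dCdx_ref")
    }
    out$dCdt <- temporal_gradient_from_motion(design$V_C, design$dCdx_ref)
    out$dCdx <- design$dCdx_ref
    out$L <- design$width_scale
  } else {
    if (is.null(design$tau)) stop("report needs tau")
    out$dCdt <- dC / design$tau
    if (is.null(design$L)) stop("report needs L (or U and tau)")
    out$L <- design$L
    out$dCdx <- dC / design$L
  }
  if (out$dCdx == 0) stop("division by zero: dCdx is 0")
  if (!is.null(design$dCdx_ref)) {
    out$fold_dCdx_vs_ref <- design$dCdx_ref / out$dCdx
  }
  out$fold_L_vs_width_scale <- out$L / design$width_scale
  if (!is.null(reference)) {
    ref_dCdt <- if (inherits(reference, "design_report")) reference$dCdt
                else design_report(reference)$dCdt
    if (ref_dCdt == 0) stop("division by zero: reference dCdt is 0")
    out$fold_dCdt_vs_reference <- out$dCdt / ref_dCdt
  }
  structure(out, class = "design_report")
}

#' @export
print.design_report <- function(x, ...) {
  cat(sprintf("Design report (%s):\n", x$scenario_kind))
  lab <- c(mean_C = "mean C [mM]", dCdt = "dC/dt [mM/min]",
           dCdx = "dC/dx [mM/um]", L = "L [um]",
           fold_dCdx_vs_ref = "fold dC/dx vs reference",
           fold_L_vs_width_scale = "fold L vs width scale",
           fold_dCdt_vs_reference = "fold dC/dt vs reference")
  for (f in names(lab)) {
    if (!is.null(x[[f]])) cat(sprintf("  %-26s %.4g\n", lab[f], x[[f]]))
  }
  invisible(x)
}

#' Write a design report as machine-readable key-value text
#'
#' @param report a [design_report()].
#' @param path output file; one `key<TAB>value` pair per line.
#' @return `path`, invisibly.
#' @export
write_design_report <- function(report, path) {
  stopifnot(inherits(report, "design_report"))
  keys <- setdiff(names(report), "scenario_kind")
  lines <- c(paste0("scenario_kind\t", report$scenario_kind),
             sprintf("%s\t%.15g", keys, unlist(report[keys])))
  writeLines(lines, path)
  invisible(path)
}

#' Map dye pixel intensity to concentration
#'
#' Inverts the affine intensity calibration `intensity = gain * C + offset`
#' (the dye used to visualise the gradients has a linear intensity-to-
#' concentration response). Values falling outside `[0, C_max]` are clipped
#' with a warning.
#'
#' @param intensity pixel intensities (a.u.).
#' @param gain,offset calibration coefficients; `gain != 0`.
#' @param C_max optional upper clip (mM).
#' @return concentrations (mM).
#' @export
dye_to_concentration <- function(intensity, gain, offset, C_max = NULL) {
  check_finite(intensity = intensity, gain = gain, offset = offset)
  if (gain == 0) stop("gain must be non-zero")
  conc <- (intensity - offset) / gain
  hi <- if (is.null(C_max)) Inf else C_max
  n_out <- sum(conc < 0 | conc > hi)
  if (n_out > 0) {
    warning(sprintf("%d intensities map outside [0, %s] mM; clipped",
                    n_out, format(hi)))
    conc <- pmin(pmax(conc, 0), hi)
  }
  conc
}

#' Space-time concentration field for a scenario
#'
#' Bundles a [gradient_design()] with a scenario geometry into an evaluator
#' `C(position, t)` where `position` is the coordinate along the gradient
#' axis (um). For `"alternating_gradient"` the dual-flow profile flips
#' orientation at each entry of `swap_times`; the epoch sign starts at +1
#' (high concentration at large coordinate).
#'
#' @param design a [gradient_design()].
#' @param kind `"alternating_gradient"`, `"taylor_aris"` or `"switching"`.
#' @param swap_times gradient swap / medium switch times (min), increasing.
#' @param mid centreline position along the gradient axis (um).
#' @return object of class `concentration_field` with elements
#'   `evaluate(position, t)`, `epoch_sign(t)`, `swap_times`, `design`, `kind`.
#' @export
concentration_field <- function(design,
                                kind = c("alternating_gradient", "taylor_aris",
                                         "switching"),
                                swap_times = numeric(), mid = 0) {
  stopifnot(inherits(design, "gradient_design"))
  kind <- match.arg(kind)
  if (is.unsorted(swap_times, strictly = TRUE) && length(swap_times) > 1) {
    stop("swap_times must be strictly increasing")
  }
  epoch_sign <- function(t) {
    ifelse(findInterval(t, swap_times) %% 2 == 0, 1, -1)
  }
  evaluate <- switch(kind,
    alternating_gradient = function(position, t) {
      design$C_max * 0.5 *
        (1 + epoch_sign(t) * erf(sqrt(pi) * (position - mid) /
                                   design$width_scale))
    },
    taylor_aris = function(position, t) taylor_aris_front(design, position, t),
    switching = function(position, t) {
      # medium starts at C_max; each swap alternates direction
      if (length(swap_times) == 0) {
        return(rep(design$C_max, length.out = max(length(position), length(t))))
      }
      k <- findInterval(t, swap_times)  # number of swaps already begun
      C <- numeric(length(t))
      for (i in seq_along(t)) {
        ki <- max(k[i], 1)
        dir <- if (ki %% 2 == 1) "down" else "up"
        C[i] <- switching_profile(design, t[i], swap_times[ki], dir)
      }
      C
    })
  structure(list(evaluate = evaluate, epoch_sign = epoch_sign,
                 swap_times = swap_times, design = design, kind = kind,
                 mid = mid),
            class = "concentration_field")
}
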