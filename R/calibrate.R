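#' Calibrate the inlet waveform against a hemodynamic target
#'
#' Adjusts the inlet pressure waveform of a scenario so that a simulated
#' hemodynamic outcome matches a printed clinical anchor, using a
#' safeguarded secant/bisection iteration on a single scale parameter with
#' closed-loop re-simulation at every iterate.
#'
#' Two adjustment modes exist. `"scale"` (default) multiplies the whole
#' inlet excess over the outlet pressure -- mean drive and pulse together --
#' by a factor `beta` (see [scale_waveform()]); the response is monotone in
#' `beta` and vanishes as `beta -> 0`, so any achievable target can be
#' bracketed. `"amplitude"` adjusts only the pulse amplitude at fixed mean;
#' with a fixed mean drive the zero-amplitude response is a floor, and
#' targets below it (or above the largest achievable response) raise a
#' calibration-failure error with diagnostics.
#'
#' Targets: `"peak_probe_dp"` is the cycle maximum of the anterior-minus-
#' posterior probe pressure difference (Pa); `"peak_throat_velocity"` is
#' the cycle maximum of the axis velocity at the throat (m/s).
#'
#' @param scenario A [scenario()] whose waveform is to be calibrated.
#' @param target Positive target value (Pa or m/s depending on `metric`).
#' @param metric Which simulated outcome to match.
#' @param mode Adjustment mode, see Details.
#' @param grid Grid for the calibration runs (defaults to the scenario's
#'   reference grid; a coarser grid makes calibration much cheaper).
#' @param config Solver configuration for the calibration runs; defaults to
#'   the scenario's with 2 cycles (1 discarded).
#' @param tol Relative tolerance on the matched outcome (default 2%).
#' @param max_iters Iteration cap (each iteration is one cyclic simulation).
#' @param probe_offset Probe offset passed to [probe_series()].
#' @param beta_init Starting scale factor for the search (a good physical
#'   guess saves simulations; the result does not depend on it).
#' @return The calibrated `steno_scenario`; the iteration log (a data frame
#'   of `beta`, `value`), the achieved value and convergence flag are
#'   attached as `attr(, "calibration")`.
#' @export
calibrate_inlet_waveform <- function(scenario, target,
                                     metric = c("peak_probe_dp",
                                                "peak_throat_velocity"),
                                     mode = c("scale", "amplitude"),
                                     grid = NULL, config = NULL,
                                     tol = 0.02, max_iters = 25L,
                                     probe_offset = NULL, beta_init = 1) {
  metric <- match.arg(metric)
  mode <- match.arg(mode)
  stopifnot(inherits(scenario, "steno_scenario"))
  if (!(target > 0)) stop("`target` must be positive")
  if (is.null(config)) {
    config <- scenario$solver
    config$cycles_total <- 2L
    config$cycles_discarded <- 1L
  }
  if (is.null(probe_offset)) probe_offset <- 2 * scenario$geometry$inlet_radius
  base_wf <- scenario$inlet_waveform
  pout <- scenario$outlet_pressure

  apply_beta <- function(beta) {
    sc <- scenario
    sc$inlet_waveform <- if (mode == "scale") {
      scale_waveform(base_wf, beta, pout)
    } else {
      synthesize_inlet_waveform(base_wf$mean_pressure,
                                beta * base_wf$pulse_amplitude,
                                base_wf$period, base_wf$systolic_peak_time,
                                base_wf$n_samples)
    }
    sc
  }
  log <- data.frame(beta = numeric(), value = numeric())
  measure <- function(beta) {
    rec <- suppressWarnings(solve_cycles(apply_beta(beta), config, grid))
    pr <- probe_series(rec, probe_offset = probe_offset)
    val <- if (metric == "peak_probe_dp") {
      max(pr$dp_anterior_posterior)
    } else {
      max(pr$u_center)
    }
    log <<- rbind(log, data.frame(beta = beta, value = val))
    val
  }

  ok <- function(val) abs(val - target) <= tol * target

  b1 <- beta_init; f1 <- measure(b1)
  if (!ok(f1)) {
    # bracket the target (response is monotone increasing in beta)
    if (f1 < target) {
      blo <- b1; flo <- f1; bhi <- b1
      for (k in seq_len(14L)) {
        bhi <- bhi * 2; fhi <- measure(bhi)
        if (ok(fhi)) { b1 <- bhi; f1 <- fhi; break }
        if (fhi >= target) break
        blo <- bhi; flo <- fhi
        if (k == 14L || (mode == "amplitude" && fhi < target &&
                           abs(fhi - flo) <= 1e-6 * target)) {
          stop(sprintf(
            "calibration failure: target %.4g not achievable (best %.4g at beta = %.4g)",
            target, fhi, bhi))
        }
      }
    } else {
      bhi <- b1; fhi <- f1; blo <- b1
      fprev <- f1
      repeat {
        blo <- blo / 2; flo <- measure(blo)
        if (ok(flo)) { b1 <- blo; f1 <- flo; break }
        if (flo <= target) break
        # amplitude mode has a response floor at zero amplitude: detect the
        # plateau instead of halving forever
        if (mode == "amplitude" &&
            (abs(fprev - flo) <= 5e-3 * flo || blo < 1e-4)) {
          stop(sprintf(
            "calibration failure: target %.4g below the zero-amplitude response (~%.4g); the mean drive alone exceeds the target",
            target, flo))
        }
        bhi <- blo; fhi <- flo; fprev <- flo
        if (blo < 1e-8) {
          stop("calibration failure: could not bracket the target from above")
        }
      }
    }
    # safeguarded secant within [blo, bhi]
    if (!ok(f1)) {
      it <- nrow(log)
      while (it < max_iters) {
        bs <- if (abs(fhi - flo) > 0) {
          blo + (target - flo) * (bhi - blo) / (fhi - flo)
        } else {
          (blo + bhi) / 2
        }
        if (!(bs > blo && bs < bhi)) bs <- (blo + bhi) / 2
        fs <- measure(bs)
        if (ok(fs)) { b1 <- bs; f1 <- fs; break }
        if (fs < target) { blo <- bs; flo <- fs } else { bhi <- bs; fhi <- fs }
        it <- nrow(log)
      }
      if (!ok(f1)) {
        stop(sprintf(
          "calibration failure: no convergence to %.4g within %d runs (last %.4g)",
          target, nrow(log), f1))
      }
    }
  }

  out <- apply_beta(b1)
  attr(out, "calibration") <- list(
    mode = mode, metric = metric, target = target,
    beta = b1, achieved = f1, tol = tol,
    iterations = log, converged = TRUE
  )
  out
}

#' Calibrate the inlet pulse amplitude to a probe pressure-difference target
#'
#' Shorthand for [calibrate_inlet_waveform()] with `metric =
#' "peak_probe_dp"` and `mode = "amplitude"`: only the pulse amplitude is
#' adjusted, at fixed mean inlet pressure.
#'
#' @inheritParams calibrate_inlet_waveform
#' @param target_peak_probe_dp Target peak anterior-minus-posterior probe
#'   pressure difference, Pa.
#' @return The calibrated scenario (see [calibrate_inlet_waveform()]).
#' @export
calibrate_inlet_amplitude <- function(scenario, target_peak_probe_dp,
                                      grid = NULL, config = NULL,
                                      tol = 0.02, max_iters = 25L) {
  calibrate_inlet_waveform(scenario, target_peak_probe_dp,
                           metric = "peak_probe_dp", mode = "amplitude",
                           grid = grid, config = config,
                           tol = tol, max_iters = max_iters)
}
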