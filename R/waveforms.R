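#' Synthesize a cardiac-cycle inlet pressure waveform
#'
#' Builds a smooth, periodic, biphasic pressure waveform emulating a
#' clinically measured proximal coronary pressure trace: a raised-cosine
#' systolic bump (peaking at `systolic_peak_time`) plus a smaller dicrotic
#' (diastolic) raised-cosine wave on a constant baseline. The closed form is
#' \deqn{p(t) = \bar p + A \,\frac{s(t) - \bar s}{1 - \bar s}, \qquad
#'       s(t) = b(t; t_p, w_s) + 0.25\, b(t; t_p + 0.3T, 0.25T)}
#' where \eqn{b(t; c, w) = \tfrac12\left[1 + \cos\frac{2\pi(t-c)}{w}\right]}
#' on `|t - c| <= w/2` (zero elsewhere) and \eqn{w_s = T/2}. By construction
#' the time average over one period equals `mean_pressure` exactly, and the
#' maximum `mean_pressure + pulse_amplitude` is attained at
#' `systolic_peak_time`.
#'
#' The default peak time 0.4 s with period 0.8 s (75 bpm) places peak
#' systole mid-cycle.
#'
#' @param mean_pressure Time-averaged pressure over one period, Pa.
#' @param pulse_amplitude Peak pressure above the mean, Pa (>= 0).
#' @param period Cardiac period T, s.
#' @param systolic_peak_time Instant of peak systole, s, in `(0, period)`.
#' @param n_samples Number of samples covering `[0, period]` inclusive
#'   (>= 16).
#' @return An object of class `pressure_waveform` carrying the closed-form
#'   parameters and a `samples` data frame (`time`, `pressure`).
#' @examples
#' wf <- synthesize_inlet_waveform(9300, 1500)
#' wf$samples$time[which.max(wf$samples$pressure)]  # 0.4
#' @export
synthesize_inlet_waveform <- function(mean_pressure, pulse_amplitude = 0,
                                      period = 0.8,
                                      systolic_peak_time = 0.4,
                                      n_samples = 101L) {
  if (pulse_amplitude < 0) stop("`pulse_amplitude` must be >= 0")
  if (!(systolic_peak_time > 0 && systolic_peak_time < period)) {
    stop("require 0 < systolic_peak_time < period")
  }
  if (n_samples < 16L) stop("`n_samples` must be >= 16")
  T <- period
  tp <- systolic_peak_time
  # systolic bump width: T/2 when the peak sits mid-cycle, shrunk if the
  # peak is close to either end so the support stays strictly inside (0, T)
  ws <- min(0.5 * T, 1.9 * min(tp, T - tp))
  td <- tp + 0.3 * T
  wd <- 0.25 * T
  dic <- if (td + wd / 2 < T) 0.25 else 0  # drop dicrotic wave if it won't fit
  sbar <- (ws / 2 + dic * wd / 2) / T      # analytic mean of the unit shape

  wf <- structure(
    list(
      period = T,
      systolic_peak_time = tp,
      mean_pressure = mean_pressure,
      pulse_amplitude = pulse_amplitude,
      ws = ws, td = td, wd = wd, dic = dic, sbar = sbar,
      n_samples = as.integer(n_samples)
    ),
    class = "pressure_waveform"
  )
  t <- seq(0, T, length.out = n_samples)
  wf$samples <- data.frame(time = t, pressure = waveform_pressure(wf, t))
  wf
}

#' @export
print.pressure_waveform <- function(x, ...) {
  cat(sprintf(
    "<pressure_waveform> mean %.5g Pa, pulse amplitude %.5g Pa, period %.3g s, peak at %.3g s\n",
    x$mean_pressure, x$pulse_amplitude, x$period, x$systolic_peak_time))
  invisible(x)
}

raised_cosine <- function(t, center, width) {
  out <- numeric(length(t))
  inside <- abs(t - center) <= width / 2
  out[inside] <- 0.5 * (1 + cos(2 * pi * (t[inside] - center) / width))
  out
}

#' Evaluate a pressure waveform at arbitrary times
#'
#' Continuous (closed-form) evaluation with periodic wrapping; used by the
#' solver to impose the inlet pressure at every sub-step instant.
#'
#' @param waveform A [synthesize_inlet_waveform()] object.
#' @param t Time(s), s; wrapped into `[0, period)`.
#' @return Pressure(s), Pa.
#' @export
waveform_pressure <- function(waveform, t) {
  stopifnot(inherits(waveform, "pressure_waveform"))
  tt <- t %% waveform$period
  s <- raised_cosine(tt, waveform$systolic_peak_time, waveform$ws) +
    waveform$dic * raised_cosine(tt, waveform$td, waveform$wd)
  waveform$mean_pressure + waveform$pulse_amplitude *
    (s - waveform$sbar) / (1 - waveform$sbar)
}

#' Rescale a waveform about a reference pressure
#'
#' Returns a waveform whose excess over `reference` is multiplied by
#' `scale`: the mean becomes `reference + scale * (mean - reference)` and
#' the pulse amplitude becomes `scale * amplitude`. This is the one-knob
#' adjustment used when calibrating a scenario's transstenotic pressure
#' drive.
#'
#' @param waveform A `pressure_waveform`.
#' @param scale Positive scale factor.
#' @param reference Reference pressure held fixed (Pa), typically the
#'   scenario outlet pressure.
#' @return A new `pressure_waveform`.
#' @export
scale_waveform <- function(waveform, scale, reference) {
  stopifnot(inherits(waveform, "pressure_waveform"), scale > 0)
  synthesize_inlet_waveform(
    mean_pressure = reference + scale * (waveform$mean_pressure - reference),
    pulse_amplitude = scale * waveform$pulse_amplitude,
    period = waveform$period,
    systolic_peak_time = waveform$systolic_peak_time,
    n_samples = waveform$n_samples
  )
}

#' Printed outlet pressures for the six-severity scenario bank
#'
#' Clinically measured mean distal pressures used as constant outlet
#' boundary conditions for the 30%--80% stenosis cases: 8843, 8041, 7819,
#' 7446, 7377 and 7229 Pa respectively.
#'
#' @param severity One of 0.3, 0.4, 0.5, 0.6, 0.7, 0.8.
#' @return Outlet pressure, Pa.
#' @export
outlet_pressure_for <- function(severity) {
  bank <- c("0.3" = 8843, "0.4" = 8041, "0.5" = 7819,
            "0.6" = 7446, "0.7" = 7377, "0.8" = 7229)
  key <- sprintf("%.1f", severity)
  if (length(severity) != 1L || is.na(match(key, names(bank))) ||
      abs(severity - as.numeric(key)) > 1e-12) {
    stop("no clinical outlet pressure for severity ", severity,
         "; supply your own outlet_pressure")
  }
  unname(bank[key])
}

#' Fractional flow reserve (pressure-ratio surrogate)
#'
#' FFR quantifies the hemodynamic significance of a stenosis; clinically it
#' is operationalized as the ratio of mean distal to mean proximal pressure
#' during hyperemia, `Pd / Pa`.
#'
#' @param mean_distal Mean pressure distal to the stenosis, Pa.
#' @param mean_proximal Mean pressure proximal to the stenosis, Pa (> 0).
#' @return The dimensionless ratio `mean_distal / mean_proximal`.
#' @export
compute_ffr <- function(mean_distal, mean_proximal) {
  if (any(mean_proximal <= 0)) stop("`mean_proximal` must be positive")
  mean_distal / mean_proximal
}

#' Export waveform samples to CSV
#'
#' Two-column CSV (`time` s, `pressure` Pa).
#'
#' @param waveform A `pressure_waveform`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
waveform_to_csv <- function(waveform, path) {
  stopifnot(inherits(waveform, "pressure_waveform"))
  utils::write.csv(waveform$samples, path, row.names = FALSE)
  invisible(path)
}
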