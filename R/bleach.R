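#' Photobleaching trace
#'
#' Integrated band intensity versus illumination time, built from a spectral
#' time series of one pixel.
#'
#' @param times_s Sampling times, s.
#' @param intensity Integrated intensity per frame, a.u.
#' @param window The [filter_channel()] used for integration.
#' @param normalized Logical; `TRUE` after [minmax_normalize()].
#' @return An object of class `bleach_trace`.
#' @export
bleach_trace <- function(times_s, intensity, window = NULL,
                         normalized = FALSE) {
  stopifnot(length(times_s) == length(intensity), length(times_s) >= 1L,
            !is.unsorted(times_s, strictly = TRUE))
  if (normalized &&
      (abs(max(intensity) - 1) > 1e-9 || abs(min(intensity)) > 1e-9)) {
    stop("a normalized trace must span exactly [0, 1]")
  }
  structure(list(times_s = as.numeric(times_s),
                 intensity = as.numeric(intensity),
                 window = window, normalized = isTRUE(normalized)),
            class = "bleach_trace")
}

#' @export
print.bleach_trace <- function(x, ...) {
  cat(sprintf("<bleach_trace> %d frames over %.0f s%s\n",
              length(x$times_s), max(x$times_s) - min(x$times_s),
              if (x$normalized) ", normalized to [0, 1]" else ""))
  invisible(x)
}

#' @export
plot.bleach_trace <- function(x, ..., xlab = "time / s",
                              ylab = if (x$normalized)
                                "normalized intensity" else
                                  "integrated intensity / a.u.",
                              type = "b") {
  plot(x$times_s, x$intensity, type = type, xlab = xlab, ylab = ylab, ...)
}

#' Default integration window for a dye's bleaching trace
#'
#' The conventions of the model system's bleaching analysis: the full
#' spectrum for F18, 578--817 nm for MitoTracker Red, and 567--817 nm for
#' ATTO647N.
#'
#' @param dye Dye name, or `"full"`.
#' @param wavelength Axis used to bound the full-spectrum window.
#' @return A [filter_channel()].
#' @export
default_bleach_window <- function(dye = "full",
                                  wavelength = default_wavelength_grid()) {
  full <- filter_channel("full", min(wavelength), max(wavelength))
  switch(dye,
         "F18" = full,
         "full" = full,
         "MitoTracker Red" = filter_channel("578-817", 578, 817),
         "ATTO647N" = filter_channel("567-817", 567, 817),
         stop("no default bleach window for '", dye, "'"))
}

#' Build a bleaching trace from a spectral time series
#'
#' Integrates every frame of the series over the window ([integrate_band()]).
#' All frames must share one wavelength axis.
#'
#' @param series List of [emission_spectrum()] frames (e.g. from
#'   [simulate_bleach_series()]).
#' @param window A [filter_channel()]; `NULL` integrates the full axis.
#' @param times_s Frame times; defaults to `attr(series, "times_s")` or
#'   0, 1, 2, ... s.
#' @return A [bleach_trace()].
#' @export
trace_from_series <- function(series, window = NULL, times_s = NULL) {
  stopifnot(is.list(series), length(series) >= 1L)
  wl <- series[[1]]$wavelength
  for (f in series) {
    stopifnot(inherits(f, "emission_spectrum"))
    if (!isTRUE(all.equal(f$wavelength, wl))) {
      stop("all frames of a bleach series must share one wavelength axis")
    }
  }
  if (is.null(window)) window <- default_bleach_window("full", wl)
  if (is.null(times_s)) {
    times_s <- attr(series, "times_s")
    if (is.null(times_s)) times_s <- seq_along(series) - 1
  }
  intensity <- vapply(series, integrate_band, numeric(1), channel = window)
  bleach_trace(times_s, intensity, window = window)
}

#' Min-max normalize a trace to [0, 1]
#'
#' The affine rescaling `(I - min) / (max - min)` used to present bleaching
#' curves; idempotent, and invariant to affine transforms of the input.
#' A constant trace has no dynamic range and is an error.
#'
#' @param trace A [bleach_trace()].
#' @return A normalized [bleach_trace()].
#' @export
minmax_normalize <- function(trace) {
  stopifnot(inherits(trace, "bleach_trace"))
  lo <- min(trace$intensity)
  hi <- max(trace$intensity)
  if (hi <= lo) stop("trace has zero dynamic range; cannot normalize")
  bleach_trace(trace$times_s, (trace$intensity - lo) / (hi - lo),
               window = trace$window, normalized = TRUE)
}

#' Fraction of intensity lost by time t
#'
#' `1 - I(t) / I(0)` with I linearly interpolated between frames; intended
#' for normalized traces, where I(0) is the first recorded frame.
#'
#' @param trace A [bleach_trace()] (normalize first for the standard 0--1
#'   presentation).
#' @param t_s Time, s; must lie within the sampled range.
#' @return Fraction lost.
#' @export
#' @examples
#' tr <- bleach_trace(0:99, exp(-(0:99) / 10))
#' fraction_lost(tr, 10)  # 1 - exp(-1)
fraction_lost <- function(trace, t_s) {
  stopifnot(inherits(trace, "bleach_trace"))
  if (t_s < min(trace$times_s) || t_s > max(trace$times_s)) {
    stop("t = ", t_s, " s is outside the sampled range [",
         min(trace$times_s), ", ", max(trace$times_s), "] s")
  }
  i0 <- trace$intensity[1]
  if (i0 <= 0) stop("trace starts at non-positive intensity")
  it <- approx(trace$times_s, trace$intensity, xout = t_s)$y
  1 - it / i0
}

#' Fit an exponential decay to a bleaching trace
#'
#' Nonlinear least squares of `sum_i a_i exp(-t / tau_i) + b` with
#' nonnegative amplitudes, time constants and baseline
#' (Levenberg-Marquardt, [minpack.lm::nlsLM()]).  Initialization is fixed
#' and documented for determinism: equal amplitudes, baseline at the trace
#' minimum, and time constants log-spaced over
#' `(t_max / 50, t_max / 2)` (their geometric mean for a single component).
#'
#' @param trace A [bleach_trace()].
#' @param n_components 1 or 2 exponential components.
#' @return List: `amplitudes`, `taus` (ascending), `baseline`,
#'   `residual` (root-mean-square), `fit` (the `nls` object).
#' @export
#' @examples
#' tr <- bleach_trace(0:99, exp(-(0:99) / 10))
#' fit_decay(tr, n_components = 1)$taus  # 10
fit_decay <- function(trace, n_components = 2) {
  stopifnot(inherits(trace, "bleach_trace"),
            n_components %in% c(1L, 2L))
  n_par <- 2L * n_components + 1L
  if (length(trace$times_s) < 3L * n_par) {
    stop("fit needs at least ", 3L * n_par, " samples for ",
         n_components, " component(s)")
  }
  t <- trace$times_s
  I <- trace$intensity
  tmax <- max(t) - min(t)
  tau0 <- if (n_components == 1L) {
    sqrt((tmax / 50) * (tmax / 2))
  } else {
    exp(seq(log(tmax / 50), log(tmax / 2), length.out = n_components))
  }
  amp0 <- rep((max(I) - min(I)) / n_components, n_components)
  start <- as.list(c(setNames(amp0, paste0("a", seq_len(n_components))),
                     setNames(tau0, paste0("tau", seq_len(n_components))),
                     b = min(I)))
  rhs <- paste(
    paste0("a", seq_len(n_components), " * exp(-t / tau",
           seq_len(n_components), ")", collapse = " + "),
    "+ b")
  form <- stats::as.formula(paste("I ~", rhs))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      form, data = data.frame(t = t, I = I), start = start,
      lower = rep(c(0, 1e-6, 0), c(n_components, n_components, 1L)),
      control = minpack.lm::nls.lm.control(maxiter = 500)
    ),
    error = function(e) {
      stop("fit_decay failed to converge (", conditionMessage(e),
           "); last start was: ",
           paste(names(start), signif(unlist(start), 4), sep = "=",
                 collapse = ", "), call. = FALSE)
    }
  )
  cf <- coef(fit)
  taus <- cf[paste0("tau", seq_len(n_components))]
  amps <- cf[paste0("a", seq_len(n_components))]
  ord <- order(taus)
  list(amplitudes = unname(amps[ord]), taus = unname(taus[ord]),
       baseline = unname(cf["b"]),
       residual = sqrt(mean(stats::residuals(fit)^2)), fit = fit)
}
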