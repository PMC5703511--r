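#' Reference neon emission lines
#'
#' Wavelengths (nm, air) of bright Ne I emission lines in the visible,
#' the standard low-pressure lamp reference for calibrating the wavelength
#' axis of a CCD spectrometer.
#'
#' @format Numeric vector, nm.
#' @export
neon_lines_nm <- c(
  585.249, 588.190, 594.483, 603.000, 607.434, 614.306, 621.728,
  626.650, 633.443, 640.225, 650.653, 659.895, 667.828, 692.947, 703.241
)

#' Wavelength calibration from lamp reference lines
#'
#' Least-squares polynomial fit mapping detector pixel index to wavelength in
#' nm, from the measured pixel positions of known reference lines (e.g. a
#' neon lamp, [neon_lines_nm]).
#'
#' @param peak_pixel_positions Detector pixel indices of the line peaks.
#' @param reference_lines_nm Known line wavelengths, nm (same length).
#' @param degree Polynomial degree; must be `< length(reference_lines_nm)`.
#' @return An object of class `calibration_fit` with fields
#'   `coefficients` (ascending powers), `residuals` (nm, per line),
#'   `max_abs_residual_nm`, `degree`.  Use [predict()] to apply the fit.
#' @export
#' @examples
#' px <- (neon_lines_nm - 400) / 0.5
#' fit <- calibrate_wavelength(px, neon_lines_nm, degree = 1)
#' fit$coefficients  # intercept 400, slope 0.5
calibrate_wavelength <- function(peak_pixel_positions, reference_lines_nm,
                                 degree = 1L) {
  x <- as.numeric(peak_pixel_positions)
  y <- as.numeric(reference_lines_nm)
  if (length(x) != length(y)) {
    stop("positions and reference lines must have the same length")
  }
  degree <- as.integer(degree)
  if (degree < 1L) stop("degree must be >= 1")
  if (length(y) < degree + 1L) {
    stop("underdetermined calibration: polynomial degree ", degree,
         " needs at least ", degree + 1L, " reference lines, got ", length(y))
  }
  fit <- lm(y ~ stats::poly(x, degree, raw = TRUE))
  cf <- unname(coef(fit))
  res <- unname(y - fitted(fit))
  structure(
    list(coefficients = cf, residuals = res,
         max_abs_residual_nm = max(abs(res)), degree = degree),
    class = "calibration_fit"
  )
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf("<calibration_fit> degree %d, max |residual| = %.3g nm\n",
              x$degree, x$max_abs_residual_nm))
  cat("coefficients (ascending powers):",
      paste(signif(x$coefficients, 8), collapse = ", "), "\n")
  invisible(x)
}

#' Apply a wavelength calibration
#'
#' @param object A `calibration_fit`.
#' @param newdata Detector pixel indices.
#' @param ... Unused.
#' @return Wavelengths in nm.
#' @export
predict.calibration_fit <- function(object, newdata, ...) {
  x <- as.numeric(newdata)
  out <- numeric(length(x))
  for (p in seq_along(object$coefficients)) {
    out <- out + object$coefficients[p] * x^(p - 1)
  }
  out
}
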