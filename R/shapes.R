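#' Emitter spectral shapes
#'
#' Two shape families cover every emitter in the model system:
#'
#' * `broad_dye_shape()` — the smooth, asymmetric emission band of an organic
#'   fluorophore, modelled as the log-normal lineshape commonly fitted to dye
#'   spectra: peak position `peak_nm`, full width at half maximum `fwhm_nm`,
#'   and an asymmetry factor `asymmetry` > 1 skewing the band to the red.
#' * `lanthanide_line_shape()` — the sharp f-f emission lines of a
#'   lanthanide(III) ion: a list of (center, FWHM, relative intensity)
#'   Gaussian lines.  Line FWHMs are at most 10 nm; it is these uniquely
#'   narrow peaks that let zeolite pixels be told apart from the broad dye
#'   features.
#'
#' Shapes are densities: [shape_values()] with `normalize = "area"` integrates
#' to 1 over the axis it is evaluated on.
#'
#' @param peak_nm Emission maximum, nm.
#' @param fwhm_nm Full width at half maximum, nm.
#' @param asymmetry Red-tail asymmetry factor (1 = symmetric Gaussian).
#' @return An object of class `emitter_shape`.
#' @export
#' @examples
#' wl <- default_wavelength_grid()
#' f18 <- broad_dye_shape(517, 35)
#' wl[which.max(shape_values(f18, wl))]  # 517
broad_dye_shape <- function(peak_nm, fwhm_nm, asymmetry = 1.3) {
  stopifnot(fwhm_nm > 0, asymmetry > 0)
  structure(list(kind = "broad_dye", peak_nm = peak_nm, fwhm_nm = fwhm_nm,
                 asymmetry = asymmetry),
            class = "emitter_shape")
}

#' @param lines Data frame with columns `center_nm`, `fwhm_nm`,
#'   `relative_intensity`.
#' @rdname broad_dye_shape
#' @export
lanthanide_line_shape <- function(lines) {
  stopifnot(is.data.frame(lines),
            all(c("center_nm", "fwhm_nm", "relative_intensity") %in%
                  names(lines)))
  if (any(lines$fwhm_nm > 10)) {
    stop("lanthanide lines must be narrow (FWHM <= 10 nm)")
  }
  if (any(lines$relative_intensity < 0) || any(lines$fwhm_nm <= 0)) {
    stop("line intensities must be >= 0 and FWHMs > 0")
  }
  structure(list(kind = "lanthanide_lines", lines = lines),
            class = "emitter_shape")
}

#' Dominant emission wavelength of a shape
#' @param shape An `emitter_shape`.
#' @return Peak wavelength, nm.
#' @export
shape_peak_nm <- function(shape) {
  stopifnot(inherits(shape, "emitter_shape"))
  if (shape$kind == "broad_dye") {
    shape$peak_nm
  } else {
    shape$lines$center_nm[which.max(shape$lines$relative_intensity)]
  }
}

## Siano-Metzler log-normal lineshape, peak value 1 at `peak`, FWHM `fwhm`,
## asymmetry r (> 1 skews to +x).  Zero outside its support.
lognormal_line <- function(x, peak, fwhm, r) {
  if (abs(r - 1) < 1e-9) {
    return(exp(-4 * log(2) * (x - peak)^2 / fwhm^2))
  }
  arg <- 1 + (x - peak) * (r^2 - 1) / (r * fwhm)
  v <- numeric(length(x))
  ok <- arg > 0
  v[ok] <- exp(-(log(2) / log(r)^2) * log(arg[ok])^2)
  v
}

#' Evaluate an emitter shape on a wavelength grid
#'
#' @param shape An `emitter_shape`.
#' @param wavelength Wavelength grid, nm.
#' @param normalize `"area"` (density integrating to 1 on this grid, the
#'   default), `"peak"` (maximum 1), or `"none"`.
#' @return Numeric vector of shape values.
#' @export
shape_values <- function(shape, wavelength,
                         normalize = c("area", "peak", "none")) {
  stopifnot(inherits(shape, "emitter_shape"))
  normalize <- match.arg(normalize)
  check_wavelength_axis(wavelength)
  v <- if (shape$kind == "broad_dye") {
    lognormal_line(wavelength, shape$peak_nm, shape$fwhm_nm, shape$asymmetry)
  } else {
    out <- numeric(length(wavelength))
    for (i in seq_len(nrow(shape$lines))) {
      ln <- shape$lines[i, ]
      out <- out + ln$relative_intensity *
        exp(-4 * log(2) * (wavelength - ln$center_nm)^2 / ln$fwhm_nm^2)
    }
    out
  }
  switch(normalize,
         none = v,
         peak = v / max(v),
         area = v / trapz(wavelength, v))
}

## ---- packaged default shapes ------------------------------------------------

## Emission shapes: peaks from the packaged photophysical table; widths chosen
## to mimic the published spectra of these dyes (the table lists only maxima).
default_emission_shape <- function(name) {
  switch(name,
    "F18" = broad_dye_shape(517, 35),
    "MitoTracker Red" = broad_dye_shape(598, 45),
    "ATTO647N" = broad_dye_shape(664, 50),
    ## Standard Tb(III) 5D4 -> 7F6..3 transition positions; 544 nm dominant.
    "Tb" = lanthanide_line_shape(data.frame(
      center_nm = c(490, 544, 585, 620),
      fwhm_nm = 8,
      relative_intensity = c(0.55, 1.00, 0.35, 0.15))),
    ## Standard Eu(III) 5D0 -> 7F1..4 positions; 616 nm (5D0 -> 7F2) dominant.
    "Eu" = lanthanide_line_shape(data.frame(
      center_nm = c(592, 616, 650, 700),
      fwhm_nm = 8,
      relative_intensity = c(0.50, 1.00, 0.40, 0.15))),
    stop("no default emission shape for '", name, "'")
  )
}

## Excitation shapes (for molar-absorptivity interpolation between laser
## lines): a mirrored log-normal band peaking at the absorption maximum with
## its tail to the blue, the generic profile of a dye excitation spectrum.
## Lanthanides have no broad band (their f-f lines are tabulated directly).
default_excitation_shape <- function(name) {
  switch(name,
    "F18" = structure(list(kind = "mirrored_dye", peak_nm = 500,
                           fwhm_nm = 90, asymmetry = 1.3),
                      class = "emitter_shape"),
    "MitoTracker Red" = structure(list(kind = "mirrored_dye", peak_nm = 578,
                                       fwhm_nm = 90, asymmetry = 1.3),
                                  class = "emitter_shape"),
    "ATTO647N" = structure(list(kind = "mirrored_dye", peak_nm = 646,
                                fwhm_nm = 80, asymmetry = 1.3),
                           class = "emitter_shape"),
    NULL
  )
}

## Peak-normalized excitation-shape value (mirrored log-normal).
excitation_shape_value <- function(shape, wavelength) {
  stopifnot(inherits(shape, "emitter_shape"))
  if (shape$kind == "mirrored_dye") {
    lognormal_line(2 * shape$peak_nm - wavelength, shape$peak_nm,
                   shape$fwhm_nm, shape$asymmetry)
  } else {
    v <- shape_values(shape, seq(min(wavelength) - 1, max(wavelength) + 1,
                                 by = 0.5), normalize = "peak")
    approx(seq(min(wavelength) - 1, max(wavelength) + 1, by = 0.5), v,
           wavelength, rule = 2)$y
  }
}
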