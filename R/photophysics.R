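#' Photophysical record of one emitter
#'
#' One row of the model system's photophysical constants: quantum yield,
#' molar absorptivity at the absorption maximum and at the four laser lines
#' (465, 488, 560, 633 nm), emission maximum, excited-state lifetime, and the
#' spectral shapes used to interpolate between the tabulated wavelengths.
#'
#' @param name Emitter label.
#' @param qy Fluorescence quantum yield in \[0, 1\].
#' @param eps_max Molar absorptivity at the absorption maximum, 1/(M cm).
#' @param eps_max_wavelength Wavelength of the absorption maximum, nm.
#' @param eps_at Named numeric vector mapping excitation wavelength (nm, as
#'   names) to molar absorptivity; entries here take precedence over shape
#'   interpolation.
#' @param emission_max_nm Emission maximum, nm (must lie on the default grid).
#' @param excited_state_lifetime_ns Excited-state lifetime, ns.
#' @param excitation_shape,emission_shape `emitter_shape` objects (or `NULL`
#'   excitation shape for line absorbers whose `eps_at` table is exhaustive).
#' @return An object of class `photophys_record`.
#' @seealso [dye_record()] for the packaged emitters, [photophys_table()].
#' @export
photophys_record <- function(name, qy, eps_max, eps_max_wavelength,
                             eps_at = numeric(), emission_max_nm,
                             excited_state_lifetime_ns,
                             excitation_shape = NULL,
                             emission_shape = NULL) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!(qy >= 0 && qy <= 1)) stop("quantum yield must be in [0, 1]")
  if (eps_max < 0 || any(eps_at < 0)) stop("molar absorptivities must be >= 0")
  if (length(eps_at) && any(eps_at > eps_max + 1e-9)) {
    stop("eps_at entries cannot exceed eps_max")
  }
  if (length(eps_at) && is.null(names(eps_at))) {
    stop("eps_at must be named by excitation wavelength in nm")
  }
  grid <- default_wavelength_grid()
  if (emission_max_nm < min(grid) || emission_max_nm > max(grid)) {
    stop("emission_max_nm must lie within the working wavelength range")
  }
  if (excited_state_lifetime_ns <= 0) stop("lifetime must be > 0")
  if (!is.null(emission_shape) &&
      abs(shape_peak_nm(emission_shape) - emission_max_nm) > 0.5) {
    stop("emission shape peak (", shape_peak_nm(emission_shape),
         " nm) disagrees with emission_max_nm (", emission_max_nm, " nm)")
  }
  structure(
    list(name = name, qy = qy, eps_max = eps_max,
         eps_max_wavelength = eps_max_wavelength, eps_at = eps_at,
         emission_max_nm = emission_max_nm,
         excited_state_lifetime_ns = excited_state_lifetime_ns,
         excitation_shape = excitation_shape,
         emission_shape = emission_shape),
    class = "photophys_record"
  )
}

#' @export
print.photophys_record <- function(x, ...) {
  cat(sprintf(
    "<photophys_record> %s: QY %.3g, eps_max %.4g /(M cm) at %.0f nm, em max %.0f nm, tau %.4g ns\n",
    x$name, x$qy, x$eps_max, x$eps_max_wavelength, x$emission_max_nm,
    x$excited_state_lifetime_ns))
  invisible(x)
}

## Packaged constants.  QY, eps values and emission maxima are the measured
## properties of the three dyes and two lanthanide ions of the model system;
## the F18 (~5 ns) and Eu(III) (~500,000 ns) lifetimes are the values the
## photon-budget comparison rests on, the remaining lifetimes are typical
## class values (rhodamine / carborhodamine / Tb(III)) and configurable.
packaged_photophysics <- function() {
  list(
    "F18" = list(qy = 0.97, eps_max = 92300, eps_max_wavelength = 500,
                 eps_at = c("465" = 34645, "488" = 71371,
                            "560" = 0, "633" = 0),
                 emission_max_nm = 517, excited_state_lifetime_ns = 5),
    "MitoTracker Red" = list(qy = 0.43, eps_max = 117000,
                             eps_max_wavelength = 578,
                             eps_at = c("465" = 1671, "488" = 3882,
                                        "560" = 54764, "633" = 0),
                             emission_max_nm = 598,
                             excited_state_lifetime_ns = 1.7),
    "ATTO647N" = list(qy = 0.65, eps_max = 150000, eps_max_wavelength = 646,
                      eps_at = c("465" = 750, "488" = 900,
                                 "560" = 10650, "633" = 103500),
                      emission_max_nm = 664, excited_state_lifetime_ns = 3.5),
    "Eu" = list(qy = 0.052, eps_max = 2.8, eps_max_wavelength = 390,
                eps_at = c("465" = 0.37, "488" = 0.035,
                           "560" = 0, "633" = 0),
                emission_max_nm = 616, excited_state_lifetime_ns = 5e5),
    "Tb" = list(qy = 0.27, eps_max = 320, eps_max_wavelength = 220,
                eps_at = c("465" = 0, "488" = 0.071, "560" = 0, "633" = 0),
                emission_max_nm = 544, excited_state_lifetime_ns = 1.8e6)
  )
}

#' Packaged emitter records
#'
#' Builds the [photophys_record()] of one of the model system's emitters:
#' `"F18"`, `"MitoTracker Red"`, `"ATTO647N"`, `"Eu"`, `"Tb"`.  Note the Eu
#' emission maximum is stored as 616 nm (the tabulated value; the 5D0 -> 7F2
#' line is sometimes quoted at 615 nm).
#'
#' @param name Emitter name (partial matching not supported).
#' @param ... Overrides passed to [photophys_record()] (e.g. a measured
#'   `excited_state_lifetime_ns` or custom shapes).
#' @return A [photophys_record()].
#' @export
#' @examples
#' brightness(dye_record("F18"), 488)
dye_record <- function(name, ...) {
  tab <- packaged_photophysics()
  if (!name %in% names(tab)) {
    stop("unknown emitter '", name, "'; packaged: ",
         paste(names(tab), collapse = ", "))
  }
  args <- tab[[name]]
  args$name <- name
  args$excitation_shape <- default_excitation_shape(name)
  args$emission_shape <- default_emission_shape(name)
  args <- modifyList(args, list(...))
  do.call(photophys_record, args)
}

#' The packaged photophysical constants as a table
#'
#' @return A data.frame with one row per emitter: quantum yield, molar
#'   absorptivity at the absorption maximum and at each laser line,
#'   emission maximum, excited-state lifetime.
#' @export
photophys_table <- function() {
  tab <- packaged_photophysics()
  do.call(rbind, lapply(names(tab), function(nm) {
    r <- tab[[nm]]
    data.frame(name = nm, qy = r$qy, eps_max = r$eps_max,
               eps_max_wavelength_nm = r$eps_max_wavelength,
               eps_465 = unname(r$eps_at["465"]),
               eps_488 = unname(r$eps_at["488"]),
               eps_560 = unname(r$eps_at["560"]),
               eps_633 = unname(r$eps_at["633"]),
               emission_max_nm = r$emission_max_nm,
               excited_state_lifetime_ns = r$excited_state_lifetime_ns,
               stringsAsFactors = FALSE)
  }))
}

#' Load a photophysical table from TSV or JSON
#'
#' Reads records in the column layout of [photophys_table()] and validates
#' the invariants (QY in \[0, 1\], eps >= 0, eps at laser lines <= eps_max).
#' Emitters whose name matches a packaged one inherit its default shapes.
#'
#' @param path TSV (`.tsv`/`.txt`) or JSON file.
#' @return Named list of [photophys_record()] objects.
#' @export
load_photophys_table <- function(path) {
  d <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  } else {
    read.table(path, sep = "\t", header = TRUE, comment.char = "#",
               check.names = TRUE, stringsAsFactors = FALSE)
  }
  need <- c("name", "qy", "eps_max", "eps_max_wavelength_nm",
            "emission_max_nm", "excited_state_lifetime_ns")
  if (!all(need %in% names(d))) {
    stop("photophysics table must contain columns: ",
         paste(need, collapse = ", "))
  }
  recs <- lapply(seq_len(nrow(d)), function(i) {
    row <- d[i, ]
    eps_cols <- grep("^eps_[0-9]+$", names(d), value = TRUE)
    eps_at <- unlist(row[eps_cols])
    names(eps_at) <- sub("^eps_", "", eps_cols)
    eps_at <- eps_at[!is.na(eps_at)]
    known <- row$name %in% names(packaged_photophysics())
    photophys_record(
      name = row$name, qy = row$qy, eps_max = row$eps_max,
      eps_max_wavelength = row$eps_max_wavelength_nm, eps_at = eps_at,
      emission_max_nm = row$emission_max_nm,
      excited_state_lifetime_ns = row$excited_state_lifetime_ns,
      excitation_shape = if (known) default_excitation_shape(row$name),
      emission_shape = if (known) default_emission_shape(row$name)
    )
  })
  names(recs) <- d$name
  recs
}

#' Molar absorptivity at a wavelength
#'
#' Tabulated laser-line values take precedence; at the absorption maximum the
#' tabulated `eps_max` is returned; anywhere else the normalized excitation
#' shape scales `eps_max`.  Outside the excitation-shape support (shape value
#' below 1e-6 of the peak) the absorptivity is 0 and a warning is raised.
#'
#' @param record A [photophys_record()].
#' @param wavelength_nm Excitation wavelength, nm.
#' @return Molar absorptivity in 1/(M cm).
#' @export
#' @examples
#' epsilon_at(dye_record("F18"), 488)  # 71371, the tabulated value
epsilon_at <- function(record, wavelength_nm) {
  stopifnot(inherits(record, "photophys_record"), length(wavelength_nm) == 1L)
  if (length(record$eps_at)) {
    hit <- which(abs(as.numeric(names(record$eps_at)) - wavelength_nm) < 0.25)
    if (length(hit)) return(unname(record$eps_at[hit[1]]))
  }
  if (abs(wavelength_nm - record$eps_max_wavelength) < 0.25) {
    return(record$eps_max)
  }
  if (!is.null(record$excitation_shape)) {
    v <- excitation_shape_value(record$excitation_shape, wavelength_nm)
    if (v >= 1e-6) return(record$eps_max * v)
  }
  warning(record$name, ": wavelength ", wavelength_nm,
          " nm is outside the tabulated points and the excitation-shape ",
          "support; returning 0")
  0
}

#' Fluorophore brightness
#'
#' The product of the quantum yield and the molar absorptivity at the
#' excitation wavelength: the standard figure of merit predicting per-molecule
#' emission under non-saturating excitation.
#'
#' @inheritParams epsilon_at
#' @return Brightness in 1/(M cm).
#' @export
#' @examples
#' brightness(dye_record("F18"), 488)  # ~70,000
#' brightness(dye_record("Tb"), 488)   # ~0.02: forbidden f-f absorption
brightness <- function(record, wavelength_nm) {
  record$qy * epsilon_at(record, wavelength_nm)
}

#' Per-molecule photon-budget ratio
#'
#' How many more photons per second emitter `a` can emit than emitter `b` at
#' equal concentration: the ratio of their brightnesses multiplied by the
#' ratio of excited-state turnover rates (inverse lifetimes).  For F18 against
#' directly excited Eu(III) this exceeds 1e11 — brightness ~1e5 vs ~0.02
#' combined with lifetimes of ~5 ns vs ~500,000 ns.
#'
#' @param a,b [photophys_record()] objects.
#' @param wavelength_a,wavelength_b Excitation wavelengths for each, nm.
#' @return Dimensionless ratio (photon rate of `a` / photon rate of `b`).
#' @export
#' @examples
#' photon_budget_ratio(dye_record("F18"), dye_record("Eu"), 488, 465)
photon_budget_ratio <- function(a, b, wavelength_a, wavelength_b) {
  ba <- brightness(a, wavelength_a)
  bb <- brightness(b, wavelength_b)
  if (bb <= 0) stop("reference emitter has zero brightness at ",
                    wavelength_b, " nm")
  if (ba <= 0) stop("emitter '", a$name, "' has zero brightness at ",
                    wavelength_a, " nm")
  if (a$excited_state_lifetime_ns <= 0 || b$excited_state_lifetime_ns <= 0) {
    stop("lifetimes must be > 0")
  }
  (ba / bb) *
    (b$excited_state_lifetime_ns / a$excited_state_lifetime_ns)
}

#' Stain configuration
#'
#' One emitter at its concentration in the film.  Packaged defaults follow
#' the model system: 150 uM F18, 0.1 uM MitoTracker Red, 0.1 uM ATTO647N.
#'
#' @param record A [photophys_record()].
#' @param concentration_uM Concentration in the film, uM (>= 0).
#' @return An object of class `stain_config`.
#' @export
stain_config <- function(record, concentration_uM) {
  stopifnot(inherits(record, "photophys_record"))
  if (concentration_uM < 0) stop("concentration must be >= 0")
  structure(list(record = record, concentration_uM = concentration_uM),
            class = "stain_config")
}

#' Default film concentration of a packaged dye (uM)
#' @param name Dye name.
#' @return Concentration in uM.
#' @export
default_concentration_uM <- function(name) {
  switch(name,
         "F18" = 150,
         "MitoTracker Red" = 0.1,
         "ATTO647N" = 0.1,
         stop("no default film concentration for '", name, "'"))
}

#' Concentration ratio of two stains
#'
#' @param a,b [stain_config()] objects.
#' @return `a`'s concentration over `b`'s (dimensionless); 1500 for the
#'   default F18 : MitoTracker Red loading.
#' @export
concentration_ratio <- function(a, b) {
  stopifnot(inherits(a, "stain_config"), inherits(b, "stain_config"))
  if (b$concentration_uM <= 0) {
    stop("reference stain has zero concentration")
  }
  a$concentration_uM / b$concentration_uM
}

#' Estimated dye-loading advantage of Eu(III) zeolites
#'
#' The model system's zeolite carriers concentrate Eu(III) locally; the
#' study-level estimate of the resulting loading advantage over the film dye
#' is a factor of ~300.  The number is an estimate carried as a documented
#' constant, not a computed quantity.
#'
#' @format Scalar.
#' @export
eu_loading_advantage <- 300
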