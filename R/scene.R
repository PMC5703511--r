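#' Photobleaching model
#'
#' Empirical bi-exponential decay of a fluorophore's emission under constant
#' illumination: a fast and a slow component plus a non-bleaching baseline
#' fraction,
#' \deqn{f(t) = a_1 e^{-t/\tau_1} + a_2 e^{-t/\tau_2} + b,}
#' with \eqn{a_1 + a_2 + b = 1} so that \eqn{f(0) = 1}.
#'
#' @param a1,a2 Component amplitudes (>= 0).
#' @param tau1,tau2 Time constants, s (> 0; `tau2` ignored when `a2 = 0`).
#' @param baseline Non-bleaching fraction; defaults to `1 - a1 - a2`.
#' @return An object of class `bleach_model`.
#' @export
#' @examples
#' m <- bleach_model(a1 = 0.7, tau1 = 4, a2 = 0.3, tau2 = 25)
#' bleach_factor(m, 10)
bleach_model <- function(a1, tau1, a2 = 0, tau2 = Inf,
                         baseline = 1 - a1 - a2) {
  if (a1 < 0 || a2 < 0 || baseline < -1e-9) {
    stop("bleach amplitudes and baseline must be >= 0")
  }
  if (tau1 <= 0 || tau2 <= 0) stop("bleach time constants must be > 0")
  if (abs(a1 + a2 + baseline - 1) > 1e-6) {
    stop("amplitudes and baseline must sum to 1")
  }
  structure(list(a1 = a1, tau1 = tau1, a2 = a2, tau2 = tau2,
                 baseline = max(baseline, 0)),
            class = "bleach_model")
}

#' Surviving intensity fraction after illumination time t
#' @param model A [bleach_model()], or `NULL` for a non-bleaching emitter.
#' @param t_s Illumination time, s.
#' @return Fraction of the initial emission intensity remaining.
#' @export
bleach_factor <- function(model, t_s) {
  if (is.null(model)) return(rep(1, length(t_s)))
  stopifnot(inherits(model, "bleach_model"))
  model$a1 * exp(-t_s / model$tau1) +
    model$a2 * exp(-t_s / model$tau2) + model$baseline
}

#' Default per-dye bleaching parameters
#'
#' Shipped kinetics calibrated to the observed single-pixel behaviour of the
#' model system: F18 loses about 70% of its intensity within the first 10 s
#' and then levels out at the background; MitoTracker Red and ATTO647N both
#' have a fast 5--10 s component losing about half the intensity, with
#' MitoTracker Red fully bleached by ~40 s and ATTO647N surviving until
#' ~100 s.  The lanthanide dopants do not bleach (`NULL` entries).
#'
#' @return Named list of [bleach_model()] objects (or `NULL`).
#' @export
default_bleach_models <- function() {
  list(
    "F18" = bleach_model(a1 = 0.7, tau1 = 4, a2 = 0.3, tau2 = 25),
    "MitoTracker Red" = bleach_model(a1 = 0.5, tau1 = 7, a2 = 0.5, tau2 = 15),
    "ATTO647N" = bleach_model(a1 = 0.5, tau1 = 7, a2 = 0.5, tau2 = 40),
    "Eu" = NULL,
    "Tb" = NULL
  )
}

#' Default four-laser excitation plan
#'
#' The quadrant imaging scheme of the model system: each of the four laser
#' lines images its own corner area around the anchor zeolite (so no area is
#' illuminated twice, minimizing bleaching).  Powers are the instrument
#' settings of the benchmark: 2 / 7.2 / 1.2 / 2.9 uW for 465 / 488 / 560 /
#' 633 nm.
#'
#' @return Data frame with columns `excitation_nm`, `power_uW`, `quadrant`.
#' @export
default_excitation_plan <- function() {
  data.frame(
    excitation_nm = c(465, 488, 560, 633),
    power_uW = c(2, 7.2, 1.2, 2.9),
    quadrant = c("NE", "NW", "SW", "SE"),
    stringsAsFactors = FALSE
  )
}

#' Emission-path long-pass edge for an excitation line
#'
#' The long-pass filters that block scattered excitation light impose a hard
#' short-wavelength cutoff on the recorded emission: the 532 nm long-pass
#' used with 465/488 nm excitation only becomes transparent around 539 nm
#' (which is why the green filter windows start at 539 nm); the 561 nm and
#' 647 nm long-pass filters open around 566 and 652 nm.
#'
#' @param excitation_nm One of 465, 488, 560, 633.
#' @return Cut-on wavelength, nm.
#' @export
lp_edge_nm <- function(excitation_nm) {
  edges <- c("465" = 539, "488" = 539, "560" = 566, "633" = 652)
  key <- as.character(round(excitation_nm))
  if (!key %in% names(edges)) {
    stop("unknown excitation wavelength ", excitation_nm,
         " nm; the model system uses 465, 488, 560, 633")
  }
  unname(edges[key])
}

#' Synthetic scene configuration
#'
#' The full description of one synthetic model-system sample: film stains,
#' zeolite particles, scan geometry, excitation plan, noise, bleaching, and
#' the seed.  All downstream stages are simulated from this object.
#'
#' Geometry: sample coordinates are in um with the anchor (the zeolite used
#' for the quadrant scheme) at `anchor_um`.  Each plan entry scans an
#' `nx x ny` window in its quadrant so that the anchor sits at one image
#' corner.
#'
#' Intensity model: a pixel's expected spectrum is
#' `background_level + sum_species gain * amount * eps(ex) * QY * power * time
#'  * bleach * shape(lambda)`, with the emission-path long-pass edge applied
#' as a hard cutoff to the emitted shapes (not to the detector background).
#' `gain` maps these arbitrary units to pseudo-counts on which Poisson noise
#' acts, followed by additive Gaussian read noise.
#'
#' @param nx,ny Scan size in pixels.
#' @param pixel_size_um Pixel pitch, um.
#' @param wavelength Emission wavelength grid, nm.
#' @param film_stains Named list of [stain_config()] (film dyes).
#' @param zeolites List of zeolite descriptions: `center_um` (length-2),
#'   `radius_um`, `dopant` ([photophys_record()]), `loading` (effective local
#'   dopant concentration, uM), `rim_fraction` (the annulus
#'   `[rim_fraction * radius, radius]` carries full loading — doped zeolites
#'   light up at the edges while the center stays darker), `core_loading`
#'   (loading fraction inside the rim).
#' @param background_level Constant detector/autofluorescence floor,
#'   a.u. per nm.
#' @param excitation_plan See [default_excitation_plan()].
#' @param noise `list(poisson = TRUE, read_sigma = 2)`.
#' @param bleach_params Named list of [bleach_model()] per emitter name.
#' @param gain Global scale constant k (a.u. per uM per 1/(M cm) per uW per s).
#' @param anchor_um Sample-frame position of the quadrant-scheme anchor.
#' @param seed Default RNG seed for simulations from this scene.
#' @return An object of class `scene_config`.
#' @seealso [scene_model_system()] for the paper-default builder.
#' @export
scene_config <- function(nx = 10, ny = 10, pixel_size_um = 0.5,
                         wavelength = default_wavelength_grid(),
                         film_stains = list(), zeolites = list(),
                         background_level = 20,
                         excitation_plan = default_excitation_plan(),
                         noise = list(poisson = TRUE, read_sigma = 2),
                         bleach_params = default_bleach_models(),
                         gain = 1, anchor_um = c(0, 0), seed = 1L) {
  stopifnot(nx >= 1, ny >= 1, pixel_size_um > 0, background_level >= 0,
            gain >= 0)
  check_wavelength_axis(wavelength)
  for (st in film_stains) stopifnot(inherits(st, "stain_config"))
  for (z in zeolites) {
    stopifnot(is.numeric(z$center_um), length(z$center_um) == 2L,
              z$radius_um > 0, inherits(z$dopant, "photophys_record"),
              z$loading >= 0)
  }
  stopifnot(all(c("excitation_nm", "power_uW", "quadrant") %in%
                  names(excitation_plan)),
            all(excitation_plan$quadrant %in% c("NE", "NW", "SW", "SE")))
  structure(
    list(nx = as.integer(nx), ny = as.integer(ny),
         pixel_size_um = pixel_size_um, wavelength = wavelength,
         film_stains = film_stains, zeolites = zeolites,
         background_level = background_level,
         excitation_plan = excitation_plan, noise = noise,
         bleach_params = bleach_params, gain = gain,
         anchor_um = as.numeric(anchor_um),
         integration_time_s = 1, seed = as.integer(seed)),
    class = "scene_config"
  )
}

#' Zeolite particle description
#'
#' One lanthanide-doped LTA zeolite in the scene.  The dopant emits from an
#' annular rim (`[rim_fraction * radius, radius]`) at full `loading` and from
#' the interior at `core_loading * loading` — doped zeolites light up at the
#' edges while the center appears dark.
#'
#' @param center_um Particle center in sample coordinates, um.
#' @param dopant A [photophys_record()] (normally `dye_record("Eu")` or
#'   `"Tb"`).
#' @param loading Effective local dopant concentration, uM (the default 2e5
#'   corresponds to ~0.2 M exchanged lanthanide).
#' @param radius_um Particle radius, um.
#' @param rim_fraction Inner edge of the bright rim as a fraction of the
#'   radius.
#' @param core_loading Loading fraction in the darker core.
#' @return A list consumed by [scene_config()].
#' @export
zeolite_spec <- function(center_um, dopant, loading = 2e5, radius_um = 1.5,
                         rim_fraction = 0.6, core_loading = 0.2) {
  list(center_um = as.numeric(center_um), radius_um = radius_um,
       dopant = dopant, loading = loading, rim_fraction = rim_fraction,
       core_loading = core_loading)
}

#' Paper-default model-system scene
#'
#' Builds the benchmark sample: a PVA film carrying the requested dyes at
#' their default concentrations (150 uM F18, 0.1 uM MitoTracker Red, 0.1 uM
#' ATTO647N), an Eu(III)-doped zeolite at the anchor corner shared by the
#' four quadrant scans, and a Tb(III)-doped zeolite inside the 488 nm
#' quadrant.  Scan geometry: 10 x 10 pixels over 5 x 5 um at 1 s per pixel.
#'
#' The default zeolite `loading` (2e5 uM, i.e. ~0.2 M local lanthanide
#' concentration from the ion exchange) makes the zeolite counts the same
#' order of magnitude as the dye-film counts, matching the model system's
#' measured behaviour despite the tiny lanthanide brightness.
#'
#' @param dyes Character vector of film dyes (subset of the packaged three).
#' @param zeolites Character vector among `"Eu"`, `"Tb"`.
#' @param seed RNG seed stored in the scene.
#' @param ... Further overrides passed to [scene_config()].
#' @return A [scene_config()].
#' @export
#' @examples
#' sc <- scene_model_system("F18", seed = 7)
#' cube <- simulate_scan(sc, excitation_nm = 488)
scene_model_system <- function(dyes = c("F18", "MitoTracker Red", "ATTO647N"),
                               zeolites = c("Eu", "Tb"), seed = 1L, ...) {
  stains <- lapply(dyes, function(d) {
    stain_config(dye_record(d), default_concentration_uM(d))
  })
  names(stains) <- dyes
  zeos <- list()
  if ("Eu" %in% zeolites) {
    zeos <- c(zeos, list(zeolite_spec(c(0, 0), dye_record("Eu"))))
  }
  if ("Tb" %in% zeolites) {
    ## interior of the NW (488 nm) scan window
    zeos <- c(zeos, list(zeolite_spec(c(-3.0, 2.2), dye_record("Tb"))))
  }
  scene_config(film_stains = stains, zeolites = zeos, seed = seed, ...)
}

#' @export
print.scene_config <- function(x, ...) {
  cat(sprintf("<scene_config> %d x %d px (%.2f um/px), %d stains, %d zeolites, seed %d\n",
              x$nx, x$ny, x$pixel_size_um, length(x$film_stains),
              length(x$zeolites), x$seed))
  invisible(x)
}

#' Dye-free reference scene
#'
#' Copy of a scene with every stain concentration and zeolite loading set to
#' zero while the detector background is retained — the "sample without
#' fluorophores, with undoped zeolites" used to record background data.
#' Idempotent.
#'
#' @param scene A [scene_config()].
#' @return A [scene_config()] rendering to pure background.
#' @export
background_scene <- function(scene) {
  stopifnot(inherits(scene, "scene_config"))
  scene$film_stains <- lapply(scene$film_stains, function(st) {
    st$concentration_uM <- 0
    st
  })
  scene$zeolites <- lapply(scene$zeolites, function(z) {
    z$loading <- 0
    z
  })
  scene
}

## Lower-left corner (sample um) of the scan window for a quadrant, so the
## anchor sits at one image corner (the quadrant scheme).
quadrant_origin <- function(scene, quadrant) {
  W <- scene$nx * scene$pixel_size_um
  H <- scene$ny * scene$pixel_size_um
  off <- switch(quadrant,
                NE = c(0, 0), NW = c(-W, 0), SW = c(-W, -H), SE = c(0, -H),
                stop("quadrant must be one of NE, NW, SW, SE"))
  scene$anchor_um + off
}

plan_entry <- function(scene, excitation_nm) {
  plan <- scene$excitation_plan
  i <- which(abs(plan$excitation_nm - excitation_nm) < 0.25)
  if (!length(i)) {
    stop("excitation ", excitation_nm, " nm is not in the scene's plan (",
         paste(plan$excitation_nm, collapse = ", "), ")")
  }
  plan[i[1], ]
}

## Pixel-center sample coordinates for a quadrant window; rows follow the
## raster order (x fastest, y slowest), matching array linear indexing.
pixel_centers <- function(scene, quadrant) {
  o <- quadrant_origin(scene, quadrant)
  xs <- o[1] + (seq_len(scene$nx) - 0.5) * scene$pixel_size_um
  ys <- o[2] + (seq_len(scene$ny) - 0.5) * scene$pixel_size_um
  cbind(x = rep(xs, times = scene$ny), y = rep(ys, each = scene$nx))
}

## Per-pixel amount of each species at the pixel centers.  A zeolite displaces
## the film, so film stains are absent inside a zeolite disk; the dopant sits
## at full loading in the rim annulus and at core_loading inside it.
## Returns list(species = list(record, bleach, amounts)).
species_amounts <- function(scene, centers) {
  npx <- nrow(centers)
  inside_any <- rep(FALSE, npx)
  zeo_entries <- list()
  for (z in scene$zeolites) {
    d <- sqrt((centers[, 1] - z$center_um[1])^2 +
                (centers[, 2] - z$center_um[2])^2)
    inside <- d <= z$radius_um
    rim <- inside & d >= z$rim_fraction * z$radius_um
    amounts <- numeric(npx)
    amounts[rim] <- z$loading
    amounts[inside & !rim] <- z$loading * z$core_loading
    inside_any <- inside_any | inside
    if (any(amounts > 0)) {
      zeo_entries[[length(zeo_entries) + 1L]] <-
        list(record = z$dopant, bleach = NULL, amounts = amounts)
    }
  }
  film_entries <- lapply(scene$film_stains, function(st) {
    amounts <- rep(st$concentration_uM, npx)
    amounts[inside_any] <- 0
    list(record = st$record,
         bleach = scene$bleach_params[[st$record$name]],
         amounts = amounts)
  })
  c(unname(film_entries), zeo_entries)
}

## Spectral emission vector (a.u. per nm) of one species per unit amount,
## at one excitation setting, with the long-pass edge applied.
species_spectrum_unit <- function(scene, record, excitation_nm, power_uW) {
  eps <- suppressWarnings(epsilon_at(record, excitation_nm))
  if (eps <= 0) return(numeric(length(scene$wavelength)))
  shp <- shape_values(record$emission_shape, scene$wavelength,
                      normalize = "area")
  shp[scene$wavelength < lp_edge_nm(excitation_nm)] <- 0
  scene$gain * eps * record$qy * power_uW * scene$integration_time_s * shp
}

#' Expected emission spectrum of one scene pixel
#'
#' The noise-free forward model: detector background plus, for every species
#' present at the pixel, `gain * amount * eps(excitation) * QY * power *
#' integration_time * bleach_factor(elapsed) * emission_shape(lambda)`, with
#' the emission-path long-pass cutoff applied to the emitted light.
#'
#' @param scene A [scene_config()].
#' @param x,y 1-based pixel indices in the scan window.
#' @param excitation_nm Excitation line (must be in the plan).
#' @param power_uW Laser power; defaults to the plan entry's.
#' @param elapsed_s Prior illumination time of this spot, s (drives
#'   bleaching).
#' @param quadrant Scan quadrant; defaults to the plan entry's.
#' @return An [emission_spectrum()].
#' @export
pixel_spectrum <- function(scene, x, y, excitation_nm, power_uW = NULL,
                           elapsed_s = 0, quadrant = NULL) {
  stopifnot(inherits(scene, "scene_config"),
            x >= 1, x <= scene$nx, y >= 1, y <= scene$ny)
  entry <- plan_entry(scene, excitation_nm)
  if (is.null(power_uW)) power_uW <- entry$power_uW
  if (is.null(quadrant)) quadrant <- entry$quadrant
  centers <- pixel_centers(scene, quadrant)
  p <- (y - 1L) * scene$nx + x
  species <- species_amounts(scene, centers[p, , drop = FALSE])
  intensity <- rep(scene$background_level, length(scene$wavelength))
  for (sp in species) {
    if (sp$amounts[1] <= 0) next
    unit <- species_spectrum_unit(scene, sp$record, excitation_nm, power_uW)
    intensity <- intensity +
      sp$amounts[1] * bleach_factor(sp$bleach, elapsed_s) * unit
  }
  emission_spectrum(scene$wavelength, intensity)
}

## Expected (noise-free) cube for one plan entry: npx x n_wavelength matrix.
render_expected <- function(scene, excitation_nm, power_uW, quadrant,
                            t0 = 0, bleach_mode = "fresh") {
  centers <- pixel_centers(scene, quadrant)
  npx <- nrow(centers)
  nwl <- length(scene$wavelength)
  E <- matrix(scene$background_level, nrow = npx, ncol = nwl)
  species <- species_amounts(scene, centers)
  for (sp in species) {
    if (!any(sp$amounts > 0)) next
    unit <- species_spectrum_unit(scene, sp$record, excitation_nm, power_uW)
    if (!any(unit > 0)) next
    fac <- if (identical(bleach_mode, "cumulative")) {
      bleach_factor(sp$bleach,
                    t0 + (seq_len(npx) - 1) * scene$integration_time_s)
    } else {
      rep(bleach_factor(sp$bleach, t0), npx)
    }
    E <- E + (sp$amounts * fac) %o% unit
  }
  E
}

## Poisson pseudo-count noise followed by Gaussian read noise; negative
## samples are clamped at zero (a CCD reports nonnegative counts).
apply_noise <- function(E, noise) {
  out <- E
  if (isTRUE(noise$poisson)) {
    out[] <- rpois(length(E), lambda = pmax(E, 0))
  }
  sigma <- noise$read_sigma
  if (!is.null(sigma) && sigma > 0) {
    out <- out + rnorm(length(E), sd = sigma)
  }
  pmax(out, 0)
}

#' Simulate one raster scan
#'
#' Renders the expected spectrum of every pixel of the plan entry's quadrant
#' window and applies Poisson pseudo-count noise followed by Gaussian read
#' noise.  Deterministic given the seed.
#'
#' Within a single scan each raster position is a fresh, previously
#' unilluminated spot, so by default (`bleach_mode = "fresh"`) bleaching
#' enters only through `t0`, the prior illumination time of the whole area
#' (use it for repeated imaging of one quadrant).
#' `bleach_mode = "cumulative"` instead advances the bleach clock by one
#' dwell time per raster pixel, emulating a stationary wide-field exposure.
#'
#' @param scene A [scene_config()].
#' @param excitation_nm Excitation line selecting the plan entry.
#' @param seed RNG seed (defaults to the scene's).
#' @param t0 Prior illumination time of the area, s.
#' @param noise `FALSE` disables all noise; or a list as in [scene_config()].
#' @param bleach_mode `"fresh"` (default) or `"cumulative"`.
#' @return A [spectral_cube()].
#' @export
simulate_scan <- function(scene, excitation_nm, seed = scene$seed, t0 = 0,
                          noise = scene$noise,
                          bleach_mode = c("fresh", "cumulative")) {
  stopifnot(inherits(scene, "scene_config"))
  bleach_mode <- match.arg(bleach_mode)
  entry <- plan_entry(scene, excitation_nm)
  E <- render_expected(scene, entry$excitation_nm, entry$power_uW,
                       entry$quadrant, t0 = t0, bleach_mode = bleach_mode)
  if (isFALSE(noise) || is.null(noise)) {
    D <- E
  } else {
    D <- with_seed(seed, apply_noise(E, noise))
  }
  data <- array(D, dim = c(scene$nx, scene$ny, length(scene$wavelength)))
  spectral_cube(data, scene$wavelength,
                pixel_size_um = scene$pixel_size_um,
                excitation_nm = entry$excitation_nm,
                excitation_power_uW = entry$power_uW,
                integration_time_s = scene$integration_time_s,
                meta = list(quadrant = entry$quadrant, t0 = t0, seed = seed,
                            bleach_mode = bleach_mode))
}

#' Simulate a single-pixel bleaching series
#'
#' Holds the beam on one pixel and records its emission spectrum in `dt`
#' intervals for `n_frames` frames (default: 1 s intervals for 100 s, the
#' accelerated single-pixel bleaching protocol).  Frame `f` samples the decay
#' at elapsed time `(f - 1) * dt`.
#'
#' @param scene A [scene_config()].
#' @param pixel Length-2 vector `c(x, y)` of 1-based pixel indices.
#' @param excitation_nm Excitation line selecting the plan entry.
#' @param n_frames Number of frames.
#' @param dt Frame interval, s.
#' @param seed RNG seed (defaults to the scene's).
#' @param noise `FALSE` disables all noise; or a list as in [scene_config()].
#' @param quadrant Scan quadrant; defaults to the plan entry's.
#' @return List of `n_frames` [emission_spectrum()] objects; frame times
#'   (s) in `attr(x, "times_s")`.
#' @export
simulate_bleach_series <- function(scene, pixel = c(1, 1), excitation_nm,
                                   n_frames = 100, dt = 1,
                                   seed = scene$seed, noise = scene$noise,
                                   quadrant = NULL) {
  stopifnot(inherits(scene, "scene_config"), length(pixel) == 2L,
            n_frames >= 1, dt > 0)
  entry <- plan_entry(scene, excitation_nm)
  if (is.null(quadrant)) quadrant <- entry$quadrant
  centers <- pixel_centers(scene, quadrant)
  p <- (pixel[2] - 1L) * scene$nx + pixel[1]
  stopifnot(p >= 1, p <= nrow(centers))
  species <- species_amounts(scene, centers[p, , drop = FALSE])
  nwl <- length(scene$wavelength)
  times <- (seq_len(n_frames) - 1) * dt
  E <- matrix(scene$background_level, nrow = n_frames, ncol = nwl)
  for (sp in species) {
    if (sp$amounts[1] <= 0) next
    unit <- species_spectrum_unit(scene, sp$record, entry$excitation_nm,
                                  entry$power_uW)
    if (!any(unit > 0)) next
    E <- E + (sp$amounts[1] * bleach_factor(sp$bleach, times)) %o% unit
  }
  D <- if (isFALSE(noise) || is.null(noise)) E else
    with_seed(seed, apply_noise(E, noise))
  out <- lapply(seq_len(n_frames), function(f) {
    emission_spectrum(scene$wavelength, D[f, ])
  })
  attr(out, "times_s") <- times
  out
}

## ---- scene io ---------------------------------------------------------------

#' Write / read a scene configuration as JSON
#'
#' Emitters are stored by name and rebuilt from the packaged records on
#' reading, so the file stays small and text-only.
#'
#' @param scene A [scene_config()].
#' @param path JSON path.
#' @return `write_scene_config()` returns `path` invisibly;
#'   `read_scene_config()` a [scene_config()].
#' @export
write_scene_config <- function(scene, path) {
  stopifnot(inherits(scene, "scene_config"))
  obj <- list(
    nx = scene$nx, ny = scene$ny, pixel_size_um = scene$pixel_size_um,
    wavelength = list(from = min(scene$wavelength),
                      to = max(scene$wavelength),
                      step = scene$wavelength[2] - scene$wavelength[1]),
    film_stains = lapply(unname(scene$film_stains), function(st) {
      list(name = st$record$name, concentration_uM = st$concentration_uM)
    }),
    zeolites = lapply(unname(scene$zeolites), function(z) {
      list(dopant = z$dopant$name, center_um = z$center_um,
           radius_um = z$radius_um, loading = z$loading,
           rim_fraction = z$rim_fraction, core_loading = z$core_loading)
    }),
    background_level = scene$background_level,
    excitation_plan = scene$excitation_plan,
    noise = scene$noise, gain = scene$gain, anchor_um = scene$anchor_um,
    seed = scene$seed
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_scene_config
#' @export
read_scene_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  stains <- lapply(seq_len(NROW(obj$film_stains)), function(i) {
    stain_config(dye_record(obj$film_stains$name[i]),
                 obj$film_stains$concentration_uM[i])
  })
  if (length(stains)) names(stains) <- obj$film_stains$name
  zeos <- lapply(seq_len(NROW(obj$zeolites)), function(i) {
    z <- obj$zeolites[i, ]
    zeolite_spec(unlist(z$center_um), dye_record(z$dopant),
                 loading = z$loading, radius_um = z$radius_um,
                 rim_fraction = z$rim_fraction, core_loading = z$core_loading)
  })
  scene_config(
    nx = obj$nx, ny = obj$ny, pixel_size_um = obj$pixel_size_um,
    wavelength = seq(obj$wavelength$from, obj$wavelength$to,
                     by = obj$wavelength$step),
    film_stains = stains, zeolites = zeos,
    background_level = obj$background_level,
    excitation_plan = as.data.frame(obj$excitation_plan),
    noise = as.list(obj$noise), gain = obj$gain,
    anchor_um = as.numeric(obj$anchor_um), seed = obj$seed
  )
}
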