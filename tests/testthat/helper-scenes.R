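# Shared fixtures and independent oracles used across the suite.

# Fine-grid Riemann-sum oracle for band integration (independent of the
# package's trapezoid-with-snapped-endpoints rule).
riemann_band <- function(f, lo, hi, step = 0.01) {
  x <- seq(lo, hi, by = step)
  sum(f(x)) * step
}

# Trapezoid on a stored grid, written independently of the package internals.
trapz_oracle <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

default_scene <- function(dye = "F18", seed = 1L, ...) {
  scene_model_system(dyes = dye, seed = seed, ...)
}

# Noise-free single-dye film scene without zeolites: the analytic forward
# model is then exactly conc * eps * QY * power * time * gain * shape_cut.
film_only_scene <- function(dye = "F18", seed = 1L, conc = NULL) {
  sc <- scene_model_system(dyes = dye, zeolites = character(), seed = seed)
  if (!is.null(conc)) sc$film_stains[[dye]]$concentration_uM <- conc
  sc
}

# Expected film-pixel band signal from first principles (used as the oracle
# against channel_signal_table).
analytic_band_signal <- function(dye, excitation_nm, power_uW, lo, hi,
                                 conc = default_concentration_uM(dye),
                                 wl = default_wavelength_grid()) {
  rec <- dye_record(dye)
  shp <- shape_values(rec$emission_shape, wl, normalize = "area")
  shp[wl < lp_edge_nm(excitation_nm)] <- 0
  eps <- suppressWarnings(epsilon_at(rec, excitation_nm))
  w <- zeobench:::band_weights(wl, lo, hi)
  conc * eps * rec$qy * power_uW * sum(w * shp)
}

# Pixel-center sample coordinates computed independently of the package
# geometry code (anchor at origin).
oracle_pixel_center <- function(scene, quadrant, ix, iy) {
  W <- scene$nx * scene$pixel_size_um
  H <- scene$ny * scene$pixel_size_um
  origin <- switch(quadrant, NE = c(0, 0), NW = c(-W, 0),
                   SW = c(-W, -H), SE = c(0, -H)) + scene$anchor_um
  origin + (c(ix, iy) - 0.5) * scene$pixel_size_um
}

# Pixels whose center lies in a zeolite's full-loading rim annulus.
rim_pixels <- function(scene, zeolite, quadrant) {
  out <- NULL
  for (ix in seq_len(scene$nx)) {
    for (iy in seq_len(scene$ny)) {
      p <- oracle_pixel_center(scene, quadrant, ix, iy)
      d <- sqrt(sum((p - zeolite$center_um)^2))
      if (d <= zeolite$radius_um && d >= zeolite$rim_fraction * zeolite$radius_um) {
        out <- rbind(out, c(ix, iy))
      }
    }
  }
  out
}

# One noisy realization of an expected spectrum (Poisson + read noise),
# mirroring the generator's noise model but written independently.
noisy_spectrum <- function(expected, read_sigma = 2) {
  v <- rpois(length(expected$intensity), pmax(expected$intensity, 0)) +
    rnorm(length(expected$intensity), sd = read_sigma)
  emission_spectrum(expected$wavelength, pmax(v, 0))
}

# Paper-default single-dye scenes, four-excitation cubes and backgrounds for
# the crosstalk stages (seeded, shared across tests via lazy memoization).
crosstalk_fixture <- local({
  cache <- NULL
  function(noise = TRUE) {
    key <- if (noise) "noisy" else "clean"
    if (!is.null(cache[[key]])) return(cache[[key]])
    dyes <- c("F18", "MitoTracker Red", "ATTO647N")
    plan <- default_excitation_plan()
    scenes <- lapply(dyes, default_scene, seed = 42L)
    names(scenes) <- dyes
    cubes_by_dye <- lapply(seq_along(dyes), function(i) {
      lapply(seq_len(nrow(plan)), function(j) {
        simulate_scan(scenes[[i]], plan$excitation_nm[j],
                      seed = 5000L + 10L * i + j,
                      noise = if (noise) scenes[[i]]$noise else FALSE)
      })
    })
    names(cubes_by_dye) <- dyes
    bg_scene <- background_scene(scenes[[1]])
    background_cubes <- lapply(seq_len(nrow(plan)), function(j) {
      simulate_scan(bg_scene, plan$excitation_nm[j], seed = 6000L + j,
                    noise = if (noise) bg_scene$noise else FALSE)
    })
    res <- list(scenes = scenes, cubes_by_dye = cubes_by_dye,
                background_cubes = background_cubes, plan = plan)
    cache[[key]] <<- res
    res
  }
})
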