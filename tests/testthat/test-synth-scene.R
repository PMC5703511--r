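test_that("packaged emission shapes are unit-area densities peaking at the tabulated maxima", {
  wl <- default_wavelength_grid()
  for (nm in c("F18", "MitoTracker Red", "ATTO647N", "Eu", "Tb")) {
    rec <- dye_record(nm)
    v <- shape_values(rec$emission_shape, wl)
    expect_equal(trapz_oracle(wl, v), 1, tolerance = 1e-9)
    expect_equal(wl[which.max(v)], rec$emission_max_nm)
  }
  # line FWHMs above 10 nm are not lanthanide lines
  expect_error(lanthanide_line_shape(data.frame(
    center_nm = 616, fwhm_nm = 12, relative_intensity = 1)), "narrow")
})

test_that("pixel spectra follow the linear forward model", {
  sc <- film_only_scene("F18")
  # all concentrations zero -> constant background
  sc0 <- background_scene(sc)
  sp0 <- pixel_spectrum(sc0, 3, 3, 488)
  expect_true(all(sp0$intensity == sc$background_level))
  # single dye: spectrum - background proportional to the cut emission shape,
  # and exactly linear in concentration
  sp1 <- pixel_spectrum(sc, 3, 3, 488)
  sc2 <- film_only_scene("F18", conc = 300)
  sp2 <- pixel_spectrum(sc2, 3, 3, 488)
  net1 <- sp1$intensity - sc$background_level
  net2 <- sp2$intensity - sc$background_level
  expect_equal(net2, 2 * net1, tolerance = 1e-12)
  expect_true(all(net1[sp1$wavelength < 539] == 0))  # long-pass edge
  shp <- shape_values(dye_record("F18")$emission_shape, sp1$wavelength)
  above <- sp1$wavelength >= 539 & shp > 0
  ratio <- net1[above] / shp[above]
  expect_lt(diff(range(ratio)) / mean(ratio), 1e-8)
  # unknown excitation line is an error
  expect_error(pixel_spectrum(sc, 3, 3, 532), "not in the scene's plan")
})

test_that("an Eu zeolite pixel at 465 nm peaks at the 616 nm line", {
  sc <- scene_model_system(dyes = character(), zeolites = "Eu", seed = 1)
  sp <- pixel_spectrum(sc, 2, 3, 465)  # rim pixel of the corner zeolite
  expect_equal(sp$wavelength[which.max(sp$intensity)], 616)
  expect_gt(max(sp$intensity), 5 * sc$background_level)
})

test_that("noise-free scans equal the per-pixel forward-model oracle", {
  sc <- default_scene("F18", seed = 9)
  cube <- simulate_scan(sc, 465, noise = FALSE)
  for (px in list(c(1, 1), c(2, 3), c(7, 2), c(10, 10))) {
    expect_equal(cube$data[px[1], px[2], ],
                 pixel_spectrum(sc, px[1], px[2], 465)$intensity,
                 tolerance = 1e-12)
  }
})

test_that("scans are deterministic given the seed", {
  sc <- default_scene("F18", seed = 5)
  c1 <- simulate_scan(sc, 488, seed = 123)
  c2 <- simulate_scan(sc, 488, seed = 123)
  c3 <- simulate_scan(sc, 488, seed = 124)
  expect_identical(c1$data, c2$data)
  expect_false(identical(c1$data, c3$data))
  s1 <- simulate_bleach_series(sc, c(7, 7), 488, n_frames = 5, seed = 9)
  s2 <- simulate_bleach_series(sc, c(7, 7), 488, n_frames = 5, seed = 9)
  expect_identical(s1[[3]]$intensity, s2[[3]]$intensity)
})

test_that("noisy scans converge to the noise-free expectation", {
  # small film-only scene; Monte-Carlo mean of a band integral per pixel
  sc <- scene_model_system(dyes = "MitoTracker Red", zeolites = character(),
                           nx = 2, ny = 2, seed = 1)
  clean <- simulate_scan(sc, 560, noise = FALSE)
  ch <- filter_channel("win", 578, 700)
  ref <- extract_channel_image(clean, ch)
  n <- 300
  acc <- matrix(0, 2, 2)
  acc2 <- matrix(0, 2, 2)
  for (k in seq_len(n)) {
    img <- extract_channel_image(simulate_scan(sc, 560, seed = 40000 + k), ch)
    acc <- acc + img
    acc2 <- acc2 + img^2
  }
  mu <- acc / n
  se <- sqrt(pmax(acc2 / n - mu^2, 0) / n)
  expect_true(all(abs(mu - ref) < 3 * se + 1e-9))
})

test_that("the dye-free reference scene renders pure background", {
  sc <- default_scene("ATTO647N", seed = 2)
  bg <- background_scene(sc)
  expect_identical(background_scene(bg), bg)  # idempotent
  clean <- simulate_scan(bg, 633, noise = FALSE)
  expect_true(all(clean$data == sc$background_level))
  # Monte-Carlo mean of noisy background ~ background level
  vals <- vapply(1:50, function(k) {
    mean(simulate_scan(bg, 633, seed = 700 + k)$data)
  }, numeric(1))
  expect_lt(abs(mean(vals) - sc$background_level),
            3 * sd(vals) / sqrt(length(vals)) + 0.2)
})

test_that("a zeolite inside one quadrant appears only in that quadrant's scan", {
  sc <- scene_model_system(dyes = character(), zeolites = character(), seed = 1)
  sc$zeolites <- list(zeolite_spec(c(2.5, 2.5), dye_record("Eu")))
  eu_line <- filter_channel("eu", 610, 622)
  bgl <- sc$background_level * (622 - 610)
  excess <- vapply(default_excitation_plan()$excitation_nm, function(ex) {
    img <- extract_channel_image(simulate_scan(sc, ex, noise = FALSE), eu_line)
    max(img) - bgl
  }, numeric(1))
  names(excess) <- default_excitation_plan()$quadrant
  expect_gt(excess[["NE"]], 100)     # 465 nm scans the NE quadrant
  expect_equal(unname(excess[c("NW", "SW", "SE")]), c(0, 0, 0),
               tolerance = 1e-9)
})

test_that("the anchor zeolite sits at a corner of every quadrant scan", {
  sc <- scene_model_system(dyes = character(), zeolites = "Eu", seed = 1)
  eu_line <- filter_channel("eu", 610, 622)
  bgl <- sc$background_level * (622 - 610)
  corner_of <- list(NE = c(1, 1), NW = c(10, 1), SW = c(10, 10), SE = c(1, 10))
  plan <- default_excitation_plan()
  # Eu absorbs at 465 and (weakly) 488; check those scans light up the
  # anchor-adjacent corner region and nowhere else
  for (i in which(plan$excitation_nm %in% c(465, 488))) {
    img <- extract_channel_image(simulate_scan(sc, plan$excitation_nm[i],
                                               noise = FALSE), eu_line)
    net <- img - bgl
    corner <- corner_of[[plan$quadrant[i]]]
    d <- sqrt(outer((1:10 - corner[1])^2, (1:10 - corner[2])^2, `+`))
    expect_gt(max(net[d <= 3]), 10)
    expect_equal(max(abs(net[d > 4])), 0, tolerance = 1e-9)
  }
})

test_that("bleach series follow the configured decay exactly when noise is off", {
  sc <- film_only_scene("F18")
  # no bleaching -> constant series
  sc_const <- sc
  sc_const$bleach_params[["F18"]] <- NULL
  ser <- simulate_bleach_series(sc_const, c(3, 3), 488, n_frames = 20,
                                noise = FALSE)
  tr <- trace_from_series(ser)
  expect_lt(diff(range(tr$intensity)), 1e-9)
  # single-exponential model -> closed form on the background-free part
  tau <- 12
  sc_exp <- sc
  sc_exp$background_level <- 0
  sc_exp$bleach_params[["F18"]] <- bleach_model(a1 = 1, tau1 = tau)
  tr2 <- trace_from_series(simulate_bleach_series(sc_exp, c(3, 3), 488,
                                                  n_frames = 50,
                                                  noise = FALSE))
  expect_equal(tr2$intensity / tr2$intensity[1],
               exp(-tr2$times_s / tau), tolerance = 1e-12)
})

test_that("bleach model construction enforces the unit decomposition", {
  expect_error(bleach_model(0.7, 4, 0.5, 25, baseline = 0.3), "sum to 1")
  expect_error(bleach_model(-0.1, 4), ">= 0")
  expect_error(bleach_model(0.5, -1, 0.5, 10), "> 0")
  m <- bleach_model(0.6, 5, 0.3, 50)
  expect_equal(bleach_factor(m, 0), 1)
  expect_equal(bleach_factor(NULL, c(0, 10, 100)), c(1, 1, 1))
})

test_that("scene configurations round-trip through JSON", {
  sc <- default_scene("MitoTracker Red", seed = 77)
  path <- tempfile(fileext = ".json")
  write_scene_config(sc, path)
  sc2 <- read_scene_config(path)
  expect_equal(sc2$film_stains[["MitoTracker Red"]]$concentration_uM, 0.1)
  expect_equal(length(sc2$zeolites), length(sc$zeolites))
  expect_equal(sc2$seed, 77L)
  # identical scenes render identically
  expect_equal(simulate_scan(sc2, 560, noise = FALSE)$data,
               simulate_scan(sc, 560, noise = FALSE)$data, tolerance = 1e-12)
})
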