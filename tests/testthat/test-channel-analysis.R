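test_that("the two-pixel signal statistic does the stated arithmetic", {
  est <- fluorescent_signal(c(10, 12), c(4, 4))
  expect_equal(est$mean, 7)
  expect_equal(est$sd, sqrt(2))
  # with n = 2 the sample sd equals |net1 - net2| / sqrt(2)
  expect_equal(est$sd, abs((10 - 4) - (12 - 4)) / sqrt(2))
  # signal equal to background -> zero
  expect_equal(fluorescent_signal(c(5, 5), c(5, 5))$mean, 0)
  # shift invariance
  est2 <- fluorescent_signal(c(10, 12) + 100, c(4, 4) + 100)
  expect_equal(est2$mean, est$mean)
  expect_equal(est2$sd, est$sd)
  # single signal pixel: sd undefined
  expect_true(is.na(fluorescent_signal(10, c(4, 4))$sd))
  expect_error(fluorescent_signal(numeric(), 1), "non-empty")
  expect_error(fluorescent_signal(1, numeric()), "non-empty")
})

test_that("noise-only pixels give a null net signal", {
  set.seed(31)
  n <- 50
  noise <- function(m) rnorm(m, mean = 100, sd = 3)
  net <- fluorescent_signal(noise(n), noise(n))
  expect_lt(abs(net$mean), 3 * net$sd / sqrt(n))
})

test_that("dye-free scenes give near-zero channel signals everywhere", {
  sc <- background_scene(default_scene("F18", seed = 13))
  cubes <- list(blank = simulate_scan(sc, 488, seed = 201))
  bg <- simulate_scan(sc, 488, seed = 202)
  tab <- channel_signal_table(cubes, list(bg), filter_set_preset("edmund"))
  # noise floor: a band net signal is ~ sqrt(2 * width * background) counts
  expect_true(all(abs(tab$mean) < 5 * sqrt(2 * (tab$hi_nm - tab$lo_nm) *
                                             sc$background_level)))
})

test_that("noise-off channel signals equal the analytic forward model", {
  for (cfg in list(list(dye = "F18", ex = 488, pw = 7.2),
                   list(dye = "MitoTracker Red", ex = 560, pw = 1.2),
                   list(dye = "ATTO647N", ex = 633, pw = 2.9))) {
    sc <- film_only_scene(cfg$dye)
    cube <- simulate_scan(sc, cfg$ex, noise = FALSE)
    bg <- simulate_scan(background_scene(sc), cfg$ex, noise = FALSE)
    tab <- channel_signal_table(setNames(list(cube), cfg$dye), list(bg),
                                list(filter_set_preset("edmund"),
                                     filter_set_preset("chroma")))
    for (i in seq_len(nrow(tab))) {
      expect_equal(
        tab$mean[i],
        analytic_band_signal(cfg$dye, cfg$ex, cfg$pw, tab$lo_nm[i],
                             tab$hi_nm[i]),
        tolerance = 1e-6)
    }
    expect_true(all(tab$sd < 1e-9))  # identical pixels, no noise
  }
})

test_that("channel signals scale linearly with concentration and power", {
  band <- function(sc, ex) {
    cube <- simulate_scan(sc, ex, noise = FALSE)
    bg <- simulate_scan(background_scene(sc), ex, noise = FALSE)
    img <- extract_channel_image(cube, filter_channel("w", 578, 700))
    bimg <- extract_channel_image(bg, filter_channel("w", 578, 700))
    fluorescent_signal(img[c(1, 2)], bimg[c(1, 2)])$mean
  }
  s1 <- band(film_only_scene("MitoTracker Red", conc = 0.1), 560)
  s2 <- band(film_only_scene("MitoTracker Red", conc = 0.4), 560)
  expect_equal(s2, 4 * s1, tolerance = 1e-9)
  sc_p <- film_only_scene("MitoTracker Red", conc = 0.1)
  sc_p$excitation_plan$power_uW[sc_p$excitation_plan$excitation_nm == 560] <- 3.6
  expect_equal(band(sc_p, 560), 3 * s1, tolerance = 1e-9)
  # across dyes at one excitation, slopes stand in the ratio of
  # brightness x transmitted-emission-fraction
  s_atto <- band(film_only_scene("ATTO647N", conc = 0.1), 560)
  frac <- function(dye) {
    wl <- default_wavelength_grid()
    shp <- shape_values(dye_record(dye)$emission_shape, wl)
    shp[wl < lp_edge_nm(560)] <- 0
    w <- zeobench:::band_weights(wl, 578, 700)
    sum(w * shp)
  }
  b_ratio <- brightness(dye_record("MitoTracker Red"), 560) /
    brightness(dye_record("ATTO647N"), 560)
  expect_equal(s1 / s_atto, b_ratio * frac("MitoTracker Red") /
                 frac("ATTO647N"), tolerance = 1e-9)
})

test_that("pure line and pure band spectra classify by construction", {
  wl <- default_wavelength_grid()
  eu <- emission_spectrum(wl, shape_values(dye_record("Eu")$emission_shape,
                                           wl))
  expect_equal(as.character(classify_pixel(eu)), "zeolite")
  f18 <- emission_spectrum(wl, shape_values(
    dye_record("F18")$emission_shape, wl))
  expect_equal(as.character(classify_pixel(f18)), "film")
  expect_warning(lab <- classify_pixel(emission_spectrum(wl, rep(0, length(wl)))),
                 "no positive intensity")
  expect_equal(as.character(lab), "film")
})

test_that("the classifier reaches 95% accuracy on labelled synthetic pixels", {
  sc_eu <- scene_model_system(dyes = "ATTO647N", zeolites = "Eu", seed = 1)
  sc_tb <- scene_model_system(dyes = "F18", zeolites = "Tb", seed = 1)
  tb_zeo <- sc_tb$zeolites[[1]]
  tb_rim <- rim_pixels(sc_tb, tb_zeo, "NW")
  exp_eu <- pixel_spectrum(sc_eu, 2, 3, 465)          # Eu rim, 465 nm scan
  exp_tb <- pixel_spectrum(sc_tb, tb_rim[1, 1], tb_rim[1, 2], 488)
  films <- list(
    list(sp = pixel_spectrum(film_only_scene("F18"), 9, 9, 488), ex = 488),
    list(sp = pixel_spectrum(film_only_scene("MitoTracker Red"), 9, 9, 560),
         ex = 560),
    list(sp = pixel_spectrum(film_only_scene("ATTO647N"), 9, 9, 633),
         ex = 633))
  set.seed(97)
  truth <- character(0)
  pred <- character(0)
  for (k in 1:50) {
    for (case in list(list(sp = exp_eu, ex = 465, lab = "zeolite"),
                      list(sp = exp_tb, ex = 488, lab = "zeolite"))) {
      truth <- c(truth, case$lab)
      pred <- c(pred, as.character(classify_pixel(
        noisy_spectrum(case$sp), min_nm = lp_edge_nm(case$ex))))
    }
    fc <- films[[1 + (k %% 3)]]
    truth <- c(truth, "film", "film")
    pred <- c(pred,
              as.character(classify_pixel(noisy_spectrum(fc$sp),
                                          min_nm = lp_edge_nm(fc$ex))),
              as.character(classify_pixel(
                noisy_spectrum(films[[1 + ((k + 1) %% 3)]]$sp),
                min_nm = lp_edge_nm(films[[1 + ((k + 1) %% 3)]]$ex))))
  }
  expect_length(truth, 200)
  expect_gte(mean(pred == truth), 0.95)
})

test_that("classification degrades as the line width approaches the dye width", {
  # replace the Eu emission with a single 616 nm Gaussian of growing FWHM
  sc0 <- scene_model_system(dyes = "ATTO647N", zeolites = "Eu", seed = 1)
  widths <- c(8, 16, 24, 35)
  set.seed(55)
  detect <- vapply(widths, function(w) {
    rec <- dye_record("Eu", emission_shape = broad_dye_shape(616, w, 1))
    sc <- sc0
    sc$zeolites[[1]]$dopant <- rec
    expd <- pixel_spectrum(sc, 2, 3, 465)
    mean(vapply(1:30, function(k) {
      identical(as.character(classify_pixel(noisy_spectrum(expd),
                                            min_nm = lp_edge_nm(465))),
                "zeolite")
    }, logical(1)))
  }, numeric(1))
  expect_true(all(diff(detect) <= 0.05))      # monotone within noise
  expect_gt(detect[1], detect[length(detect)])  # strictly worse at dye width
})

test_that("contrast follows its defining ratio and flags a dark surround", {
  img <- matrix(c(10, 10, 5, 5), 2, 2)
  expect_equal(contrast(img, c(1, 2), c(3, 4)), 2)
  expect_equal(contrast(img, c(3, 4), c(3, 4)), 1)
  suppressWarnings(
    expect_equal(contrast(img, c(1, 2), c(3, 4), background = 5), Inf,
                 ignore_attr = TRUE))
  expect_warning(v <- contrast(img, c(1, 2), c(3, 4), background = 6),
                 "infinite")
  expect_error(contrast(img, integer(), c(1, 2)), "non-empty")
})

test_that("an Eu corner zeolite shows red but not green contrast over an F18 film", {
  sc <- scene_model_system(dyes = "F18", zeolites = "Eu", seed = 1)
  cube <- simulate_scan(sc, 465, noise = FALSE)
  zeo <- c(which(outer(1:10, 1:10, function(x, y) x == 2 & y == 3)),
           which(outer(1:10, 1:10, function(x, y) x == 3 & y == 2)))
  film <- c(which(outer(1:10, 1:10, function(x, y) x == 9 & y == 9)),
            which(outer(1:10, 1:10, function(x, y) x == 8 & y == 9)))
  red <- extract_channel_image(cube, filter_channel("TexasRed", 604, 644))
  green <- extract_channel_image(cube, filter_channel("FITC", 539, 556))
  bg_red <- sc$background_level * (644 - 604)
  bg_green <- sc$background_level * (556 - 539)
  c_red <- contrast(red, zeo, film, background = bg_red)
  c_green <- contrast(green, zeo, film, background = bg_green)
  expect_gt(c_red, 1.5)    # Eu line emission beats the F18 red tail
  expect_lt(c_green, 0.1)  # no Eu lines in the green window
  # hand computation of the red contrast from the forward model
  zeo_net <- mean(red[zeo]) - bg_red
  film_net <- mean(red[film]) - bg_red
  expect_equal(c_red, zeo_net / film_net, tolerance = 1e-12)
})
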