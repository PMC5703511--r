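test_that("cross-excitation panels vanish for dye-free scenes and red-edge excitation", {
  sc <- film_only_scene("MitoTracker Red")
  bg <- background_scene(sc)
  plan <- default_excitation_plan()
  clean <- function(scene) {
    lapply(plan$excitation_nm, function(ex) {
      simulate_scan(scene, ex, noise = FALSE)
    })
  }
  panel <- cross_excitation_panel(clean(sc), clean(bg))
  # 633 nm lies beyond the red edge of the MitoTracker Red absorption band
  expect_equal(max(abs(panel[["633"]]$intensity)), 0, tolerance = 1e-9)
  expect_gt(max(panel[["560"]]$intensity), 1)
  blank <- cross_excitation_panel(clean(bg), clean(bg))
  for (p in blank) expect_equal(max(abs(p$intensity)), 0, tolerance = 1e-9)
})

test_that("MitoTracker Red cross-excitation at 488 vs 560 nm follows the absorptivity ratio", {
  sc <- film_only_scene("MitoTracker Red")
  bg <- background_scene(sc)
  cubes <- lapply(c(488, 560), function(ex) simulate_scan(sc, ex, noise = FALSE))
  bgc <- lapply(c(488, 560), function(ex) simulate_scan(bg, ex, noise = FALSE))
  panel <- cross_excitation_panel(cubes, bgc)
  full <- filter_channel("full", 400, 820)
  i488 <- integrate_band(panel[["488"]], full)
  i560 <- integrate_band(panel[["560"]], full)
  # forward-model closed form: eps and power scale the spectrum; the two
  # long-pass edges transmit slightly different emission fractions
  wl <- default_wavelength_grid()
  shp <- shape_values(dye_record("MitoTracker Red")$emission_shape, wl)
  area_above <- function(edge) trapz_oracle(wl, ifelse(wl < edge, 0, shp))
  expected <- (3882 * 7.2 * area_above(539)) / (54764 * 1.2 * area_above(566))
  expect_equal(i488 / i560, expected, tolerance = 1e-9)
  # and approximately the plain absorptivity x power ratio
  expect_equal(i488 / i560, (3882 * 7.2) / (54764 * 1.2), tolerance = 0.1)
})

test_that("zero-concentration scenes yield an all-zero crosstalk matrix", {
  fx <- crosstalk_fixture(noise = FALSE)
  bg_scene <- background_scene(fx$scenes[[1]])
  cubes <- list(blank = lapply(fx$plan$excitation_nm, function(ex) {
    simulate_scan(bg_scene, ex, noise = FALSE)
  }))
  m <- build_crosstalk_matrix(
    cubes, fx$background_cubes |> lapply(\(cb) {
      simulate_scan(bg_scene, cb$excitation_nm, noise = FALSE)
    }),
    designated = data.frame(set = "edmund", channel = "FITC",
                            dye = "blank", excitation_nm = 488))
  expect_true(all(abs(m$table$mean) < 1e-9))
})

test_that("scaling one dye's concentration scales exactly its rows", {
  sc1 <- film_only_scene("ATTO647N", conc = 0.1)
  sc3 <- film_only_scene("ATTO647N", conc = 0.3)
  bgc <- lapply(c(560, 633), function(ex) {
    simulate_scan(background_scene(sc1), ex, noise = FALSE)
  })
  mk <- function(sc) {
    build_crosstalk_matrix(
      list("ATTO647N" = lapply(c(560, 633), function(ex) {
        simulate_scan(sc, ex, noise = FALSE)
      })),
      bgc,
      designated = data.frame(set = "edmund", channel = "Cy5",
                              dye = "ATTO647N", excitation_nm = 633))
  }
  m1 <- mk(sc1)
  m3 <- mk(sc3)
  expect_equal(m3$table$mean, 3 * m1$table$mean, tolerance = 1e-9)
})

test_that("matrix entries are invariant to seed when noise is off", {
  sc <- film_only_scene("F18")
  c1 <- simulate_scan(sc, 488, seed = 1, noise = FALSE)
  c2 <- simulate_scan(sc, 488, seed = 999, noise = FALSE)
  expect_identical(c1$data, c2$data)
})

test_that("a diagonal-dominant matrix raises no flags", {
  tab <- expand.grid(dye = c("A", "B"), excitation_nm = c(488, 633),
                     stringsAsFactors = FALSE)
  rows <- do.call(rbind, lapply(seq_len(nrow(tab)), function(i) {
    data.frame(dye = tab$dye[i], excitation_nm = tab$excitation_nm[i],
               set = "kit", channel = c("ch1", "ch2"),
               lo_nm = c(500, 600), hi_nm = c(550, 650),
               mean = c(ifelse(tab$dye[i] == "A" & tab$excitation_nm[i] == 488,
                               100, 1),
                        ifelse(tab$dye[i] == "B" & tab$excitation_nm[i] == 633,
                               80, 2)),
               sd = 0.1, n_signal = 2, n_background = 2,
               stringsAsFactors = FALSE)
  }))
  des <- data.frame(set = "kit", channel = c("ch1", "ch2"),
                    dye = c("A", "B"), excitation_nm = c(488, 633),
                    stringsAsFactors = FALSE)
  m <- structure(list(table = rows, designated = des),
                 class = "crosstalk_matrix")
  rep <- bleedthrough_report(m)
  expect_false(any(rep$flagged))
  expect_true(all(rep$ratio[rep$dye == "A" & rep$excitation_nm == 488 &
                              rep$channel == "ch1"] == 1))
})

test_that("the paper-default scenes reproduce the stated bleed-through pattern", {
  fx <- crosstalk_fixture(noise = TRUE)
  m <- build_crosstalk_matrix(fx$cubes_by_dye, fx$background_cubes)
  rep <- bleedthrough_report(m)
  g <- function(set, ch, dye, ex) {
    r <- m$table
    r$mean[r$set == set & r$channel == ch & r$dye == dye &
             r$excitation_nm == ex]
  }
  # the F18 tail outshines MitoTracker Red in the red channels
  expect_gt(g("edmund", "TexasRed", "F18", 488),
            g("edmund", "TexasRed", "MitoTracker Red", 560))
  expect_gt(g("chroma", "mCherry", "F18", 488),
            g("chroma", "mCherry", "MitoTracker Red", 560))
  expect_true(any(rep$flagged & rep$channel == "TexasRed" &
                    rep$dye == "F18" & rep$excitation_nm == 488))
  # F18 shows up in every window upon 465 or 488 nm excitation (noise-off)
  clean <- crosstalk_fixture(noise = FALSE)
  m0 <- build_crosstalk_matrix(clean$cubes_by_dye, clean$background_cubes)
  f18 <- m0$table[m0$table$dye == "F18" & m0$table$excitation_nm %in%
                    c(465, 488), ]
  expect_true(all(f18$mean > 0))
  # only ATTO647N at 633 nm tops F18 in the far-red channels 3 and 6
  for (chan in list(c("edmund", "Cy5"), c("chroma", "ATTO647N"))) {
    rows <- m$table[m$table$set == chan[1] & m$table$channel == chan[2], ]
    top <- rows[which.max(rows$mean), ]
    expect_equal(top$dye, "ATTO647N")
    expect_equal(top$excitation_nm, 633)
    expect_false(any(rep$flagged & rep$set == chan[1] &
                       rep$channel == chan[2]))
  }
})
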