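#' Cross-excitation emission panel
#'
#' The spectral view of excitation crosstalk: for a sample stained with a
#' single dye, the background-subtracted mean film-pixel emission spectrum
#' recorded at each of the four laser lines.  A dye excited beyond the red
#' edge of its absorption band contributes (essentially) nothing.
#'
#' @param cubes List of [spectral_cube()] objects of one single-dye scene,
#'   one per excitation wavelength.
#' @param background_cubes Dye-free reference cubes matched by excitation
#'   (missing match is an error).
#' @return Named list (excitation wavelength as name) of background-subtracted
#'   [emission_spectrum()] objects.
#' @export
cross_excitation_panel <- function(cubes, background_cubes) {
  stopifnot(is.list(cubes), length(cubes) >= 1L)
  if (inherits(background_cubes, "spectral_cube")) {
    background_cubes <- list(background_cubes)
  }
  bg_ex <- vapply(background_cubes, `[[`, numeric(1), "excitation_nm")
  out <- list()
  for (cube in cubes) {
    stopifnot(inherits(cube, "spectral_cube"))
    b <- which(abs(bg_ex - cube$excitation_nm) < 0.25)
    if (!length(b)) {
      stop("no background cube recorded at excitation ",
           cube$excitation_nm, " nm")
    }
    bg_cube <- background_cubes[[b[1]]]
    mean_film <- function(cb) {
      flat <- matrix(cb$data, nrow = cube_nx(cb) * cube_ny(cb))
      min_nm <- cube_lp_edge(cb)
      keep <- vapply(seq_len(nrow(flat)), function(p) {
        sp <- emission_spectrum(cb$wavelength, pmax(flat[p, ], 0))
        identical(as.character(classify_pixel(sp, min_nm = min_nm)), "film")
      }, logical(1))
      if (!any(keep)) keep <- rep(TRUE, nrow(flat))
      colMeans(flat[keep, , drop = FALSE])
    }
    diff <- mean_film(cube) - mean_film(bg_cube)
    out[[as.character(cube$excitation_nm)]] <-
      emission_spectrum(cube$wavelength, diff, subtracted = TRUE)
  }
  out
}

#' Default designated (dye, excitation) pairing per filter channel
#'
#' The intended assignment of the model system: the FITC channels belong to
#' F18 excited at 488 nm, the Texas Red / mCherry channels to MitoTracker Red
#' at 560 nm, and the Cy5 / ATTO647N channels to ATTO647N at 633 nm.
#'
#' @return Data frame: `set`, `channel`, `dye`, `excitation_nm`.
#' @export
default_designated <- function() {
  data.frame(
    set = c("edmund", "edmund", "edmund", "chroma", "chroma", "chroma"),
    channel = c("FITC", "TexasRed", "Cy5", "FITC", "mCherry", "ATTO647N"),
    dye = c("F18", "MitoTracker Red", "ATTO647N",
            "F18", "MitoTracker Red", "ATTO647N"),
    excitation_nm = c(488, 560, 633, 488, 560, 633),
    stringsAsFactors = FALSE
  )
}

#' Build the crosstalk matrix
#'
#' The full emission bleed-through bookkeeping: for every single-dye scene,
#' every excitation line, and every filter channel, the two-pixel
#' background-subtracted signal estimate.  The `designated` table marks which
#' (dye, excitation) pair each channel is meant for.
#'
#' @param cubes_by_dye Named list (dye label) of lists of [spectral_cube()]
#'   objects, one per excitation, all sharing geometry.
#' @param background_cubes Dye-free reference cubes (one per excitation).
#' @param filtersets A [filter_set()] or list of sets (default: both packaged
#'   kits, channels 1--6).
#' @param designated Designation table as in [default_designated()].
#' @param ... Passed to [channel_signal_table()].
#' @return An object of class `crosstalk_matrix`: a list with the long-format
#'   signal `table` and the `designated` map.
#' @export
build_crosstalk_matrix <- function(cubes_by_dye, background_cubes,
                                   filtersets = list(
                                     filter_set_preset("edmund"),
                                     filter_set_preset("chroma")),
                                   designated = default_designated(), ...) {
  stopifnot(is.list(cubes_by_dye), length(cubes_by_dye) >= 1L,
            !is.null(names(cubes_by_dye)))
  rows <- list()
  for (dye in names(cubes_by_dye)) {
    cubes <- cubes_by_dye[[dye]]
    if (inherits(cubes, "spectral_cube")) cubes <- list(cubes)
    names(cubes) <- rep(dye, length(cubes))
    tab <- channel_signal_table(cubes, background_cubes, filtersets, ...)
    names(tab)[names(tab) == "label"] <- "dye"
    rows[[dye]] <- tab
  }
  table <- do.call(rbind, rows)
  rownames(table) <- NULL
  key <- function(d) paste(d$set, d$channel, sep = ":")
  miss <- setdiff(key(designated), key(table))
  if (length(miss)) {
    stop("designated pairs reference channels absent from the matrix: ",
         paste(miss, collapse = ", "))
  }
  structure(list(table = table, designated = designated),
            class = "crosstalk_matrix")
}

#' @export
print.crosstalk_matrix <- function(x, ...) {
  cat(sprintf("<crosstalk_matrix> %d dyes x %d excitations x %d channels\n",
              length(unique(x$table$dye)),
              length(unique(x$table$excitation_nm)),
              length(unique(paste(x$table$set, x$table$channel)))))
  print(utils::head(x$table, 12))
  if (nrow(x$table) > 12) cat("...\n")
  invisible(x)
}

#' Emission bleed-through report
#'
#' For each filter channel, compares every (dye, excitation) signal with the
#' channel's designated pair: entries whose mean exceeds the designated mean
#' are flagged as bleed-through that would cause false positives.  Ratios are
#' reported on background-subtracted means with negative nets clipped to zero
#' (`clipped` column) to avoid noise-driven nonsense ratios.
#'
#' @param matrix A `crosstalk_matrix` from [build_crosstalk_matrix()].
#' @return Data frame: `set`, `channel`, `dye`, `excitation_nm`, `mean`,
#'   `designated_dye`, `designated_excitation_nm`, `designated_mean`,
#'   `ratio` (off-target / designated), `flagged`, `clipped`.
#' @export
bleedthrough_report <- function(matrix) {
  stopifnot(inherits(matrix, "crosstalk_matrix"))
  tab <- matrix$table
  des <- matrix$designated
  out <- list()
  for (i in seq_len(nrow(des))) {
    d <- des[i, ]
    chan_rows <- tab[tab$set == d$set & tab$channel == d$channel, ]
    ref <- chan_rows[chan_rows$dye == d$dye &
                       abs(chan_rows$excitation_nm - d$excitation_nm) < 0.25, ]
    if (nrow(ref) != 1L) {
      stop("designated pair (", d$dye, ", ", d$excitation_nm,
           " nm) not found exactly once in channel ", d$set, ":", d$channel)
    }
    ref_mean <- max(ref$mean, 0)
    is_des <- chan_rows$dye == d$dye &
      abs(chan_rows$excitation_nm - d$excitation_nm) < 0.25
    net <- pmax(chan_rows$mean, 0)
    out[[i]] <- data.frame(
      set = d$set, channel = d$channel,
      dye = chan_rows$dye, excitation_nm = chan_rows$excitation_nm,
      mean = chan_rows$mean,
      designated_dye = d$dye, designated_excitation_nm = d$excitation_nm,
      designated_mean = ref$mean,
      ratio = if (ref_mean > 0) net / ref_mean else
        ifelse(net > 0, Inf, 0),
      flagged = !is_des & chan_rows$mean > ref$mean,
      clipped = chan_rows$mean < 0,
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
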