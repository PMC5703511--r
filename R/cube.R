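#' Spectral image cube
#'
#' One raster scan at one excitation setting: an `nx x ny` pixel image whose
#' every pixel holds a full emission spectrum.  The default scan geometry of
#' the model system is 10 x 10 pixels over 5 x 5 um at 1 s integration time
#' per pixel.
#'
#' Pixel convention: `data[x, y, k]` with `x` increasing rightward, `y`
#' downward, both 1-based in R; exported long-format tables use 0-based
#' indices with (0, 0) the top-left pixel.
#'
#' @param data Numeric array `c(nx, ny, n_wavelength)`.
#' @param wavelength Wavelength axis, nm.
#' @param pixel_size_um Pixel pitch in um (default 0.5 = 5 um / 10 px).
#' @param excitation_nm Excitation wavelength, nm.
#' @param excitation_power_uW Excitation power, uW.
#' @param integration_time_s Dwell time per pixel, s.
#' @param meta Optional named list of extra metadata (kept on round trips).
#' @return An object of class `spectral_cube`.
#' @export
spectral_cube <- function(data, wavelength, pixel_size_um = 0.5,
                          excitation_nm = NA_real_,
                          excitation_power_uW = NA_real_,
                          integration_time_s = 1,
                          meta = list()) {
  check_wavelength_axis(wavelength)
  data <- as.array(data)
  if (length(dim(data)) != 3L) stop("cube data must be a 3-d array (x, y, wavelength)")
  if (dim(data)[3] != length(wavelength)) {
    stop("cube has ", dim(data)[3], " spectral planes but the axis has ",
         length(wavelength), " wavelengths")
  }
  if (any(dim(data)[1:2] < 1L)) stop("cube needs nx, ny >= 1")
  structure(
    list(data = data, wavelength = as.numeric(wavelength),
         pixel_size_um = pixel_size_um, excitation_nm = excitation_nm,
         excitation_power_uW = excitation_power_uW,
         integration_time_s = integration_time_s, meta = meta),
    class = "spectral_cube"
  )
}

#' @export
print.spectral_cube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<spectral_cube> %d x %d px (%.2f um/px), %d wavelengths %.0f-%.0f nm, ex %.0f nm\n",
    d[1], d[2], x$pixel_size_um, d[3], min(x$wavelength), max(x$wavelength),
    x$excitation_nm))
  invisible(x)
}

#' Number of pixels along x / y
#' @param cube A [spectral_cube()].
#' @return Integer.
#' @export
cube_nx <- function(cube) dim(cube$data)[1]

#' @rdname cube_nx
#' @export
cube_ny <- function(cube) dim(cube$data)[2]

#' Extract the spectrum of one pixel
#'
#' @param cube A [spectral_cube()].
#' @param x,y 1-based pixel indices.
#' @param subtracted Passed to [emission_spectrum()]; use `TRUE` for cubes that
#'   may contain negative samples (read noise, background-subtracted data).
#' @return An [emission_spectrum()].
#' @export
cube_pixel_spectrum <- function(cube, x, y, subtracted = TRUE) {
  stopifnot(inherits(cube, "spectral_cube"))
  emission_spectrum(cube$wavelength, cube$data[x, y, ], subtracted = subtracted)
}

#' Virtual filter-channel image
#'
#' Applies [integrate_band()] to every pixel of a cube: the image a filter
#' based microscope would have recorded through the given bandpass channel.
#'
#' @param cube A [spectral_cube()].
#' @param channel A [filter_channel()].
#' @return `nx x ny` numeric matrix of band intensities (a.u.).
#' @export
extract_channel_image <- function(cube, channel) {
  stopifnot(inherits(cube, "spectral_cube"),
            inherits(channel, "filter_channel"))
  wl <- cube$wavelength
  if (channel$hi_nm <= wl[1] || channel$lo_nm >= wl[length(wl)]) {
    warning("filter window ", channel$name,
            " does not overlap the cube's wavelength axis; returning zeros")
    return(matrix(0, cube_nx(cube), cube_ny(cube)))
  }
  w <- band_weights(wl, channel$lo_nm, channel$hi_nm) * channel$transmission
  d <- dim(cube$data)
  flat <- matrix(cube$data, nrow = d[1] * d[2], ncol = d[3])
  matrix(as.vector(flat %*% w), nrow = d[1], ncol = d[2])
}

#' Corner-to-corner diagonal intensity profile
#'
#' Pixel intensities along the main diagonal of a square channel image, the
#' standard way of displaying the contrast between a corner zeolite and the
#' surrounding film.
#'
#' @param image Square numeric matrix.
#' @return Numeric vector of length `nrow(image)`.
#' @export
diagonal_profile <- function(image) {
  if (!is.matrix(image)) stop("image must be a matrix")
  if (nrow(image) != ncol(image)) {
    stop("diagonal_profile requires a square image (got ",
         nrow(image), " x ", ncol(image), ")")
  }
  diag(image)
}

## ---- cube io: multi-frame TIFF + JSON sidecar -------------------------------

#' Write / read a spectral cube (multi-frame TIFF + JSON sidecar)
#'
#' The stack stores one 32-bit frame per wavelength sample; because TIFF
#' samples live in \[0, 1\], the sidecar records an affine `intensity_offset` /
#' `intensity_scale` used to restore the original values (lossless to single
#' float precision).  The sidecar also carries the wavelength axis and the
#' acquisition metadata.
#'
#' @param cube A [spectral_cube()].
#' @param path TIFF path.
#' @param sidecar JSON sidecar path (default `paste0(path, ".json")`).
#' @return `write_cube()` returns `path` invisibly; `read_cube()` a
#'   [spectral_cube()].  Reading stops if the frame count and the sidecar
#'   wavelength count disagree.
#' @export
write_cube <- function(cube, path, sidecar = paste0(path, ".json")) {
  stopifnot(inherits(cube, "spectral_cube"))
  lo <- min(cube$data)
  hi <- max(cube$data)
  scale <- if (hi > lo) hi - lo else 1
  norm <- (cube$data - lo) / scale
  frames <- lapply(seq_along(cube$wavelength), function(k) {
    t(norm[, , k])  # TIFF rows are y
  })
  tiff::writeTIFF(frames, path, bits.per.sample = 32L, compression = "none",
                  reduce = FALSE)
  side <- list(
    wavelengths_nm = cube$wavelength,
    pixel_size_um = cube$pixel_size_um,
    excitation_nm = cube$excitation_nm,
    excitation_power_uW = cube$excitation_power_uW,
    integration_time_s = cube$integration_time_s,
    intensity_offset = lo,
    intensity_scale = scale,
    meta = cube$meta
  )
  jsonlite::write_json(side, sidecar, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_cube
#' @export
read_cube <- function(path, sidecar = paste0(path, ".json")) {
  side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  frames <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(frames)) frames <- list(frames)
  wl <- as.numeric(side$wavelengths_nm)
  if (length(frames) != length(wl)) {
    stop("cube/sidecar mismatch: stack has ", length(frames),
         " frames but sidecar lists ", length(wl), " wavelengths")
  }
  ny <- nrow(frames[[1]])
  nx <- ncol(frames[[1]])
  data <- array(0, dim = c(nx, ny, length(wl)))
  for (k in seq_along(frames)) data[, , k] <- t(frames[[k]])
  data <- data * side$intensity_scale + side$intensity_offset
  spectral_cube(data, wl,
                pixel_size_um = side$pixel_size_um,
                excitation_nm = side$excitation_nm,
                excitation_power_uW = side$excitation_power_uW,
                integration_time_s = side$integration_time_s,
                meta = if (length(side$meta)) as.list(side$meta) else list())
}

#' Write / read a spectral cube as a long-format TSV
#'
#' Columns `x`, `y` (0-based pixel indices, (0, 0) top-left, x rightward,
#' y downward), `wavelength_nm`, `intensity`.  Metadata travels in `#`-prefixed
#' header lines.  Exact-precision alternative to the TIFF route.
#'
#' @param cube A [spectral_cube()].
#' @param path TSV path.
#' @return `write_cube_tsv()` returns `path` invisibly; `read_cube_tsv()` a
#'   [spectral_cube()].
#' @export
write_cube_tsv <- function(cube, path) {
  stopifnot(inherits(cube, "spectral_cube"))
  d <- dim(cube$data)
  grid <- expand.grid(x = seq_len(d[1]) - 1L, y = seq_len(d[2]) - 1L,
                      k = seq_len(d[3]))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# pixel_size_um\t%.10g", cube$pixel_size_um),
    sprintf("# excitation_nm\t%.10g", cube$excitation_nm),
    sprintf("# excitation_power_uW\t%.10g", cube$excitation_power_uW),
    sprintf("# integration_time_s\t%.10g", cube$integration_time_s),
    "x\ty\twavelength_nm\tintensity"
  ), con)
  write.table(
    data.frame(x = grid$x, y = grid$y,
               wavelength_nm = cube$wavelength[grid$k],
               intensity = format(as.vector(cube$data), digits = 17,
                                  trim = TRUE, scientific = FALSE)),
    con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

#' @rdname write_cube_tsv
#' @export
read_cube_tsv <- function(path) {
  hdr <- grep("^#", readLines(path, n = 20L), value = TRUE)
  meta_of <- function(key, default = NA_real_) {
    ln <- grep(paste0("^#\\s*", key, "\t"), hdr, value = TRUE)
    if (length(ln)) as.numeric(sub(".*\t", "", ln[1])) else default
  }
  d <- read.table(path, sep = "\t", header = TRUE, comment.char = "#")
  wl <- sort(unique(d$wavelength_nm))
  nx <- max(d$x) + 1L
  ny <- max(d$y) + 1L
  data <- array(NA_real_, dim = c(nx, ny, length(wl)))
  k <- match(d$wavelength_nm, wl)
  data[cbind(d$x + 1L, d$y + 1L, k)] <- d$intensity
  if (anyNA(data)) stop("long-format cube table is incomplete")
  spectral_cube(data, wl,
                pixel_size_um = meta_of("pixel_size_um", 0.5),
                excitation_nm = meta_of("excitation_nm"),
                excitation_power_uW = meta_of("excitation_power_uW"),
                integration_time_s = meta_of("integration_time_s", 1))
}
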