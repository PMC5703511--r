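#' Two-pixel background-subtracted signal estimate
#'
#' The model system's signal statistic: the average of the background pixels
#' is subtracted from each signal pixel separately, and the mean and sample
#' standard deviation (n - 1 denominator) of these net values are reported.
#' With the standard two signal pixels the sd equals `|net1 - net2| / sqrt(2)`.
#'
#' @param signal_pixels Channel intensities of the signal pixels (>= 1).
#' @param background_pixels Channel intensities of the background pixels.
#' @return An object of class `signal_estimate`: `mean`, `sd` (`NA` when only
#'   one signal pixel), `n_signal`, `n_background`.
#' @export
#' @examples
#' fluorescent_signal(c(10, 12), c(4, 4))  # mean 7, sd sqrt(2)
fluorescent_signal <- function(signal_pixels, background_pixels) {
  if (!length(signal_pixels)) stop("signal_pixels must be non-empty")
  if (!length(background_pixels)) stop("background_pixels must be non-empty")
  net <- signal_pixels - mean(background_pixels)
  structure(
    list(mean = mean(net),
         sd = if (length(net) > 1L) sd(net) else NA_real_,
         n_signal = length(signal_pixels),
         n_background = length(background_pixels)),
    class = "signal_estimate"
  )
}

#' @export
print.signal_estimate <- function(x, ...) {
  cat(sprintf("<signal_estimate> mean %.4g +/- %.4g a.u. (n = %d signal / %d background px)\n",
              x$mean, x$sd, x$n_signal, x$n_background))
  invisible(x)
}

#' Spectral narrowness statistic
#'
#' Lanthanide-bearing zeolite pixels are told apart from dye-film pixels by
#' their uniquely narrow emission lines.  The statistic is the maximum excess
#' of the spectrum over a running-median baseline (window `baseline_nm`),
#' divided by the total integrated intensity: near zero for a smooth dye
#' band, large when a sharp line protrudes.
#'
#' A detection long-pass filter imprints a sharp cut-on step on every
#' recorded spectrum; the running median mistakes that step for a narrow
#' feature, so the statistic is evaluated only above `min_nm` (normally the
#' long-pass edge for the cube's excitation line, [lp_edge_nm()]), where the
#' spectrum is genuinely smooth unless a line protrudes.
#'
#' @param spectrum An [emission_spectrum()].
#' @param baseline_nm Running-median window, nm.
#' @param min_nm Ignore wavelengths below this value (`NULL` = use all).
#' @return Scalar statistic (1/nm scale).
#' @export
narrowness_statistic <- function(spectrum, baseline_nm = 31, min_nm = NULL) {
  stopifnot(inherits(spectrum, "emission_spectrum"))
  wl <- spectrum$wavelength
  intensity <- pmax(spectrum$intensity, 0)
  if (!is.null(min_nm)) {
    keep <- wl >= min_nm
    if (sum(keep) < 5L) return(0)
    wl <- wl[keep]
    intensity <- intensity[keep]
  }
  total <- trapz(wl, intensity)
  if (total <= 0) return(0)
  step <- stats::median(diff(wl))
  k <- max(3L, round(baseline_nm / step))
  if (k %% 2L == 0L) k <- k + 1L
  k <- min(k, if (length(intensity) %% 2L) length(intensity)
           else length(intensity) - 1L)
  baseline <- runmed(intensity, k, endrule = "median")
  max(intensity - baseline) / total
}

#' Classify a pixel spectrum as zeolite or film
#'
#' Labels a pixel `"zeolite"` when its [narrowness_statistic()] exceeds
#' `threshold`, `"film"` otherwise.  The default threshold (0.015 /nm) sits
#' between the smooth-band floor of the broad dyes (~0.003 at realistic
#' noise) and the value of a zeolite rim pixel whose line emission is of the
#' same order as the film signal (~0.03); note a pure 8 nm line spectrum
#' cannot exceed ~0.06 because the line's own area dominates the denominator.
#' An all-zero spectrum is film, with a warning.
#'
#' @inheritParams narrowness_statistic
#' @param threshold Decision threshold on the statistic.
#' @return `"zeolite"` or `"film"`, with the statistic in
#'   `attr(x, "statistic")`.
#' @export
classify_pixel <- function(spectrum, threshold = 0.015, baseline_nm = 31,
                           min_nm = NULL) {
  stopifnot(inherits(spectrum, "emission_spectrum"))
  if (all(spectrum$intensity <= 0)) {
    warning("spectrum has no positive intensity; classifying as film")
    return(structure("film", statistic = 0))
  }
  s <- narrowness_statistic(spectrum, baseline_nm = baseline_nm,
                            min_nm = min_nm)
  structure(if (s > threshold) "zeolite" else "film", statistic = s)
}

## Long-pass cut-on for a cube's excitation line, or NULL when unknown.
cube_lp_edge <- function(cube) {
  if (is.na(cube$excitation_nm)) return(NULL)
  tryCatch(lp_edge_nm(cube$excitation_nm), error = function(e) NULL)
}

#' Select signal pixels from a cube
#'
#' Default pixel choices for the two-pixel statistic: film pixels are those
#' classified as film, ranked by distance from the nearest zeolite-classified
#' pixel (farthest first, raster order breaking ties); zeolite pixels are the
#' classified zeolite pixels of maximum total intensity.
#'
#' @param cube A [spectral_cube()].
#' @param what `"film"` or `"zeolite"`.
#' @param n Number of pixels to return.
#' @param threshold,baseline_nm Passed to [classify_pixel()].
#' @return Data frame with columns `x`, `y` (1-based), `index` (linear).
#' @export
select_pixels <- function(cube, what = c("film", "zeolite"), n = 2,
                          threshold = 0.015, baseline_nm = 31) {
  stopifnot(inherits(cube, "spectral_cube"))
  what <- match.arg(what)
  nx <- cube_nx(cube)
  ny <- cube_ny(cube)
  npx <- nx * ny
  min_nm <- cube_lp_edge(cube)
  flat <- matrix(cube$data, nrow = npx)
  stats_ <- numeric(npx)
  totals <- numeric(npx)
  for (p in seq_len(npx)) {
    sp <- emission_spectrum(cube$wavelength, pmax(flat[p, ], 0))
    stats_[p] <- narrowness_statistic(sp, baseline_nm = baseline_nm,
                                      min_nm = min_nm)
    totals[p] <- trapz(cube$wavelength, pmax(flat[p, ], 0))
  }
  is_zeo <- stats_ > threshold & totals > 0
  xs <- rep(seq_len(nx), times = ny)
  ys <- rep(seq_len(ny), each = nx)
  if (what == "zeolite") {
    cand <- which(is_zeo)
    if (!length(cand)) stop("no zeolite pixels found in this cube")
    cand <- cand[order(-totals[cand], cand)]
  } else {
    cand <- which(!is_zeo)
    if (!length(cand)) stop("no film pixels found in this cube")
    if (any(is_zeo)) {
      zx <- xs[is_zeo]
      zy <- ys[is_zeo]
      dmin <- vapply(cand, function(p) {
        min(sqrt((xs[p] - zx)^2 + (ys[p] - zy)^2))
      }, numeric(1))
      cand <- cand[order(-dmin, cand)]
    }
  }
  sel <- head(cand, n)
  data.frame(x = xs[sel], y = ys[sel], index = sel)
}

#' Background-subtracted channel signal table
#'
#' For every cube and every channel of the filter set(s): extract the virtual
#' channel image, pick the signal pixels, pick background pixels from the
#' matching dye-free reference cube (same excitation), and form the
#' [fluorescent_signal()] estimate.  This is the tabulation behind the
#' per-filter signal bar charts of the model system.
#'
#' @param cubes Named list of [spectral_cube()] objects (names label the
#'   scenes, e.g. the dye present).
#' @param background_cubes List of dye-free reference cubes; matched to each
#'   cube by excitation wavelength — a missing match is an error.
#' @param filterset A [filter_set()] or list of filter sets (channels of all
#'   sets are tabulated in order).
#' @param pixels `"film"` or `"zeolite"` pixel selection (see
#'   [select_pixels()]).
#' @param n_pixels Signal/background pixels per estimate (default 2).
#' @param pixel_selector Optional override: `function(cube, what, n)`
#'   returning linear pixel indices.
#' @return Data frame: `label`, `excitation_nm`, `set`, `channel`, `lo_nm`,
#'   `hi_nm`, `mean`, `sd`, `n_signal`, `n_background`.
#' @export
channel_signal_table <- function(cubes, background_cubes, filterset,
                                 pixels = "film", n_pixels = 2,
                                 pixel_selector = NULL) {
  stopifnot(is.list(cubes), length(cubes) >= 1L)
  if (is.null(names(cubes)) || any(!nzchar(names(cubes)))) {
    stop("cubes must be a named list (scene labels)")
  }
  if (inherits(background_cubes, "spectral_cube")) {
    background_cubes <- list(background_cubes)
  }
  chans <- filter_set_frame(filterset)
  select <- function(cube, what, n) {
    if (is.null(pixel_selector)) {
      select_pixels(cube, what, n)$index
    } else {
      pixel_selector(cube, what, n)
    }
  }
  bg_ex <- vapply(background_cubes, `[[`, numeric(1), "excitation_nm")
  rows <- list()
  for (ci in seq_along(cubes)) {
    label <- names(cubes)[ci]
    cube <- cubes[[ci]]
    stopifnot(inherits(cube, "spectral_cube"))
    b <- which(abs(bg_ex - cube$excitation_nm) < 0.25)
    if (!length(b)) {
      stop("no background cube recorded at excitation ",
           cube$excitation_nm, " nm (needed for scene '", label, "')")
    }
    bg_cube <- background_cubes[[b[1]]]
    sig_idx <- select(cube, pixels, n_pixels)
    bg_idx <- select(bg_cube, "film", n_pixels)
    for (i in seq_len(nrow(chans))) {
      ch <- filter_channel(chans$channel[i], chans$lo_nm[i], chans$hi_nm[i],
                           chans$transmission[i])
      img <- extract_channel_image(cube, ch)
      bg_img <- extract_channel_image(bg_cube, ch)
      est <- fluorescent_signal(img[sig_idx], bg_img[bg_idx])
      rows[[length(rows) + 1L]] <- data.frame(
        label = label, excitation_nm = cube$excitation_nm,
        set = chans$set[i], channel = chans$channel[i],
        lo_nm = chans$lo_nm[i], hi_nm = chans$hi_nm[i],
        mean = est$mean, sd = est$sd, n_signal = est$n_signal,
        n_background = est$n_background, stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

#' Structure-to-surround contrast
#'
#' Background-subtracted signal of the structure of interest relative to its
#' surroundings: `(mean(zeolite) - background) / (mean(film) - background)`.
#' A non-positive film net signal is reported as infinite contrast with a
#' warning (attribute `flag = "infinite"`).
#'
#' @param image Channel image (matrix) or intensity vector/profile.
#' @param zeolite_pixels,film_pixels Indices into `image` (both non-empty).
#' @param background Reference level from the dye-free sample (default 0,
#'   i.e. already-subtracted data).
#' @return Scalar contrast ratio.
#' @export
contrast <- function(image, zeolite_pixels, film_pixels, background = 0) {
  if (!length(zeolite_pixels) || !length(film_pixels)) {
    stop("both pixel sets must be non-empty")
  }
  num <- mean(image[zeolite_pixels]) - background
  den <- mean(image[film_pixels]) - background
  if (den <= 0) {
    warning("film net signal is not positive; contrast is infinite")
    return(structure(Inf, flag = "infinite"))
  }
  num / den
}
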