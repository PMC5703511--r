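#' Filter set
#'
#' An ordered collection of [filter_channel()] windows emulating one
#' commercial emission filter kit.  Channels of a real kit may overlap; no
#' disjointness is enforced.
#'
#' @param name Kit label.
#' @param channels List of [filter_channel()] objects.
#' @return An object of class `filter_set`.
#' @export
filter_set <- function(name, channels) {
  stopifnot(is.character(name), length(name) == 1L, is.list(channels),
            length(channels) >= 1L)
  ok <- vapply(channels, inherits, logical(1), what = "filter_channel")
  if (!all(ok)) stop("channels must all be filter_channel objects")
  names(channels) <- vapply(channels, `[[`, character(1), "name")
  structure(list(name = name, channels = channels), class = "filter_set")
}

#' @export
print.filter_set <- function(x, ...) {
  cat(sprintf("<filter_set> %s (%d channels)\n", x$name, length(x$channels)))
  for (ch in x$channels) {
    cat(sprintf("  %-10s %.0f-%.0f nm\n", ch$name, ch$lo_nm, ch$hi_nm))
  }
  invisible(x)
}

#' Packaged emission filter kits
#'
#' The two commercial kits the model system emulates.  `"edmund"`: FITC
#' 539--556 nm, Texas Red 604--644 nm, Cy5 672--712 nm.  `"chroma"`: FITC
#' 539--550 nm, mCherry 593--667 nm, ATTO647N 669--741 nm.  The FITC windows
#' nominally start at 513 nm (Edmund) / 500 nm (Chroma), but the 532 nm
#' long-pass filter in the emission path only becomes transparent around
#' 539 nm, so both green windows start at 539 nm.
#'
#' @param name `"edmund"` or `"chroma"`.
#' @return A [filter_set()].
#' @export
#' @examples
#' filter_set_preset("edmund")
filter_set_preset <- function(name = c("edmund", "chroma")) {
  name <- match.arg(name)
  switch(name,
    edmund = filter_set("edmund", list(
      filter_channel("FITC", 539, 556),
      filter_channel("TexasRed", 604, 644),
      filter_channel("Cy5", 672, 712)
    )),
    chroma = filter_set("chroma", list(
      filter_channel("FITC", 539, 550),
      filter_channel("mCherry", 593, 667),
      filter_channel("ATTO647N", 669, 741)
    ))
  )
}

## Normalize a filter_set or list of filter_sets to a data.frame of channels.
filter_set_frame <- function(filtersets) {
  if (inherits(filtersets, "filter_set")) filtersets <- list(filtersets)
  stopifnot(is.list(filtersets), length(filtersets) >= 1L)
  rows <- list()
  idx <- 0L
  for (fs in filtersets) {
    stopifnot(inherits(fs, "filter_set"))
    for (ch in fs$channels) {
      idx <- idx + 1L
      rows[[idx]] <- data.frame(
        set = fs$name, channel = ch$name, channel_index = idx,
        lo_nm = ch$lo_nm, hi_nm = ch$hi_nm, transmission = ch$transmission,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

#' Read / write filter sets as JSON
#'
#' A JSON list of `{name, lo_nm, hi_nm, transmission}` objects, optionally
#' wrapped as `{set, channels: [...]}`.
#'
#' @param filterset A [filter_set()].
#' @param path JSON path.
#' @return `write_filter_set()` returns `path` invisibly; `read_filter_set()`
#'   a [filter_set()].
#' @export
write_filter_set <- function(filterset, path) {
  stopifnot(inherits(filterset, "filter_set"))
  obj <- list(
    set = filterset$name,
    channels = lapply(unname(filterset$channels), function(ch) {
      list(name = ch$name, lo_nm = ch$lo_nm, hi_nm = ch$hi_nm,
           transmission = ch$transmission)
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_filter_set
#' @export
read_filter_set <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!is.null(obj$channels)) {
    name <- if (!is.null(obj$set)) obj$set else "custom"
    chans <- obj$channels
  } else {
    name <- "custom"
    chans <- obj
  }
  filter_set(name, lapply(chans, function(ch) {
    filter_channel(ch$name, ch$lo_nm, ch$hi_nm,
                   if (is.null(ch$transmission)) 1 else ch$transmission)
  }))
}
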