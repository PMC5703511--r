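#' Write / read a cube manifest
#'
#' A small JSON index of the files a simulated (or measured) experiment
#' produced: one entry per artifact with its path (relative to the manifest),
#' kind (`cube`, `spectrum`, `table`), excitation wavelength, scene label and
#' role (`signal` or `background`).
#'
#' @param entries Data frame with columns `path`, `kind`, `excitation_nm`,
#'   `scene_label`, `role`.
#' @param path Manifest path.
#' @return `write_manifest()` returns `path` invisibly; `read_manifest()` the
#'   entries data frame (with the manifest's directory in
#'   `attr(x, "base_dir")`).
#' @export
write_manifest <- function(entries, path) {
  need <- c("path", "kind", "excitation_nm", "scene_label", "role")
  stopifnot(is.data.frame(entries), all(need %in% names(entries)))
  jsonlite::write_json(list(format_version = "1", entries = entries), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$entries)) stop("not a manifest: ", path)
  entries <- as.data.frame(obj$entries)
  attr(entries, "base_dir") <- dirname(normalizePath(path))
  entries
}

#' Default end-to-end pipeline configuration
#'
#' One seeded configuration driving [run_pipeline()]: which single-dye scenes
#' to simulate, which filter kits to emulate, the scan geometry, and the
#' bleaching experiment.  All scene-level defaults are those of
#' [scene_model_system()].
#'
#' @param seed Master seed; every stage derives its RNG stream from it.
#' @param dyes Film dyes, one single-dye scene each.
#' @param n_bleach_frames,bleach_pixel Single-pixel bleaching protocol
#'   (default 100 frames at 1 s on film pixel (7, 7) of the dye's designated
#'   quadrant).
#' @return Named list, the pipeline configuration.
#' @export
default_pipeline_config <- function(seed = 1L,
                                    dyes = c("F18", "MitoTracker Red",
                                             "ATTO647N"),
                                    n_bleach_frames = 100,
                                    bleach_pixel = c(7, 7)) {
  list(seed = as.integer(seed), dyes = dyes,
       filtersets = c("edmund", "chroma"),
       n_bleach_frames = n_bleach_frames, bleach_pixel = bleach_pixel,
       fraction_lost_at_s = 10)
}

designated_excitation <- function(dye) {
  switch(dye, "F18" = 488, "MitoTracker Red" = 560, "ATTO647N" = 633,
         "Eu" = 465, "Tb" = 488,
         stop("no designated excitation for '", dye, "'"))
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("[", name, "] ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the whole model-system pipeline
#'
#' Executes simulate -> channel signals -> crosstalk -> bleaching on the
#' paper-default synthetic scenes and writes every table plus a structured
#' log under `out_dir`.  Deterministic given `config$seed`: per-scan seeds
#' are derived arithmetically from it, and no timestamps enter the outputs.
#'
#' Files written: `cubes/` (TIFF + sidecars + `manifest.json`),
#' `channel_signals.tsv` (each dye at its designated excitation),
#' `crosstalk_matrix.tsv` and `bleedthrough_report.tsv` /
#' `bleedthrough_flags.json`, `bleach_traces.tsv` and `bleach_fits.json`,
#' and `run_log.json`.
#'
#' @param config See [default_pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory results (`signal_table`,
#'   `crosstalk`, `bleedthrough`, `bleach`, `manifest`).
#' @export
run_pipeline <- function(config = default_pipeline_config(), out_dir) {
  stopifnot(is.list(config), !is.null(config$seed))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cube_dir <- file.path(out_dir, "cubes")
  dir.create(cube_dir, showWarnings = FALSE)
  seed <- as.integer(config$seed)
  filtersets <- lapply(config$filtersets, filter_set_preset)

  ## --- simulate -------------------------------------------------------------
  sim <- stage("simulate", {
    scenes <- lapply(config$dyes, function(d) {
      scene_model_system(dyes = d, seed = seed)
    })
    names(scenes) <- config$dyes
    bg_scene <- background_scene(scene_model_system(dyes = config$dyes[1],
                                                    seed = seed))
    plan <- default_excitation_plan()
    cubes_by_dye <- list()
    entries <- list()
    k <- 0L
    for (d in names(scenes)) {
      cubes <- list()
      for (i in seq_len(nrow(plan))) {
        k <- k + 1L
        cube <- simulate_scan(scenes[[d]], plan$excitation_nm[i],
                              seed = seed + 100L * k)
        fn <- sprintf("%s_ex%.0f.tif", gsub("[^A-Za-z0-9]+", "_", d),
                      plan$excitation_nm[i])
        write_cube(cube, file.path(cube_dir, fn))
        entries[[length(entries) + 1L]] <- data.frame(
          path = file.path("cubes", fn), kind = "cube",
          excitation_nm = plan$excitation_nm[i], scene_label = d,
          role = "signal", stringsAsFactors = FALSE)
        cubes[[i]] <- cube
      }
      cubes_by_dye[[d]] <- cubes
    }
    background_cubes <- list()
    for (i in seq_len(nrow(plan))) {
      k <- k + 1L
      cube <- simulate_scan(bg_scene, plan$excitation_nm[i],
                            seed = seed + 100L * k)
      fn <- sprintf("background_ex%.0f.tif", plan$excitation_nm[i])
      write_cube(cube, file.path(cube_dir, fn))
      entries[[length(entries) + 1L]] <- data.frame(
        path = file.path("cubes", fn), kind = "cube",
        excitation_nm = plan$excitation_nm[i], scene_label = "background",
        role = "background", stringsAsFactors = FALSE)
      background_cubes[[i]] <- cube
    }
    manifest <- do.call(rbind, entries)
    write_manifest(manifest, file.path(out_dir, "manifest.json"))
    list(scenes = scenes, cubes_by_dye = cubes_by_dye,
         background_cubes = background_cubes, manifest = manifest)
  })

  ## --- channel signals at designated excitations ------------------------------
  signal_table <- stage("channels", {
    cubes <- list()
    for (d in config$dyes) {
      ex <- designated_excitation(d)
      i <- which(abs(default_excitation_plan()$excitation_nm - ex) < 0.25)
      cubes[[d]] <- sim$cubes_by_dye[[d]][[i]]
    }
    tab <- channel_signal_table(cubes, sim$background_cubes, filtersets)
    write.table(tab, file.path(out_dir, "channel_signals.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    tab
  })

  ## --- crosstalk --------------------------------------------------------------
  xt <- stage("crosstalk", {
    m <- build_crosstalk_matrix(sim$cubes_by_dye, sim$background_cubes,
                                filtersets)
    rep_ <- bleedthrough_report(m)
    write.table(m$table, file.path(out_dir, "crosstalk_matrix.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(rep_, file.path(out_dir, "bleedthrough_report.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    flags <- rep_[rep_$flagged, c("set", "channel", "dye", "excitation_nm",
                                  "ratio")]
    jsonlite::write_json(flags, file.path(out_dir, "bleedthrough_flags.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    list(matrix = m, report = rep_)
  })

  ## --- bleaching --------------------------------------------------------------
  bleach <- stage("bleach", {
    rows <- list()
    fits <- list()
    for (j in seq_along(config$dyes)) {
      d <- config$dyes[j]
      ex <- designated_excitation(d)
      series <- simulate_bleach_series(
        sim$scenes[[d]], pixel = config$bleach_pixel, excitation_nm = ex,
        n_frames = config$n_bleach_frames, seed = seed + 9000L + j)
      tr <- minmax_normalize(
        trace_from_series(series, default_bleach_window(d)))
      fit <- fit_decay(tr, n_components = 2)
      lost <- fraction_lost(tr, config$fraction_lost_at_s)
      rows[[d]] <- data.frame(dye = d, time_s = tr$times_s,
                              normalized_intensity = tr$intensity,
                              stringsAsFactors = FALSE)
      fits[[d]] <- list(dye = d, excitation_nm = ex,
                        window = tr$window$name,
                        amplitudes = fit$amplitudes, taus_s = fit$taus,
                        baseline = fit$baseline, rms_residual = fit$residual,
                        fraction_lost = lost,
                        fraction_lost_at_s = config$fraction_lost_at_s)
    }
    traces <- do.call(rbind, rows)
    rownames(traces) <- NULL
    write.table(traces, file.path(out_dir, "bleach_traces.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      lapply(fits, function(f) f[names(f) != "fit"]),
      file.path(out_dir, "bleach_fits.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    list(traces = traces, fits = fits)
  })

  jsonlite::write_json(
    list(package = "zeobench",
         version = as.character(utils::packageVersion("zeobench")),
         seed = seed, dyes = config$dyes,
         filtersets = config$filtersets),
    file.path(out_dir, "run_log.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(signal_table = signal_table, crosstalk = xt$matrix,
                 bleedthrough = xt$report, bleach = bleach,
                 manifest = sim$manifest))
}
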