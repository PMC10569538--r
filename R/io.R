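#' Recording container on disk
#'
#' Persists a cohort of recordings (and optional simulator ground truth) as a
#' directory: a `manifest.json` carrying `schema_version`, `master_seed` and
#' per-animal metadata (id, area, shape, optional `time_bin_ms`, stimulus
#' ids), one little-endian float64 payload (`<animal>/responses.bin`, column-
#' major) per animal, and a `ground_truth/` group with the latent, mixing and
#' noise-scale arrays when present. Numeric payloads round-trip bitwise.
#'
#' @param recordings List of [population_recording()]s.
#' @param path Directory to create/overwrite.
#' @param ground_truth Optional `ground_truth` object from [generate_cohort()].
#' @param master_seed Optional seed recorded in the manifest.
#' @return `path`, invisibly.
#' @export
write_recordings <- function(recordings, path, ground_truth = NULL,
                             master_seed = NULL) {
  if (inherits(recordings, "population_recording")) recordings <- list(recordings)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  animals <- lapply(recordings, function(r) {
    key <- r$animal_id
    dir.create(file.path(path, key), showWarnings = FALSE)
    write_float64(r$responses, file.path(path, key, "responses.bin"))
    list(key = key, animal_id = r$animal_id, area = r$area,
         time_bin_ms = r$time_bin_ms, shape = dim(r$responses),
         stimulus_ids = r$stimulus_ids)
  })
  manifest <- list(schema_version = "1.0",
                   master_seed = master_seed,
                   animals = animals,
                   has_ground_truth = !is.null(ground_truth))
  if (!is.null(ground_truth)) {
    gdir <- file.path(path, "ground_truth")
    dir.create(gdir, showWarnings = FALSE)
    if (!is.null(ground_truth$latent)) {
      write_float64(ground_truth$latent, file.path(gdir, "latent.bin"))
    }
    for (p in seq_along(ground_truth$mixing)) {
      write_float64(ground_truth$mixing[[p]], file.path(gdir, sprintf("mixing_%02d.bin", p)))
      write_float64(ground_truth$true_responses[[p]],
                    file.path(gdir, sprintf("true_responses_%02d.bin", p)))
      write_float64(ground_truth$noise_sd[[p]], file.path(gdir, sprintf("noise_sd_%02d.bin", p)))
    }
    manifest$ground_truth <- list(
      latent_shape = if (is.null(ground_truth$latent)) NULL else dim(ground_truth$latent),
      n_animals = length(ground_truth$mixing),
      mixing_shapes = lapply(ground_truth$mixing, dim),
      true_shapes = lapply(ground_truth$true_responses, dim),
      noise_lengths = lapply(ground_truth$noise_sd, length),
      nonlinearity = ground_truth$nonlinearity,
      shared_signal = ground_truth$shared_signal,
      seed = ground_truth$seed)
  }
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

write_float64 <- function(x, file) {
  con <- file(file, "wb")
  on.exit(close(con))
  writeBin(as.double(x), con, size = 8, endian = "little")
}

read_float64 <- function(file, n, shape = NULL) {
  con <- file(file, "rb")
  on.exit(close(con))
  x <- readBin(con, what = "double", n = n, size = 8, endian = "little")
  if (length(x) != n) abort(sprintf("payload %s is truncated.", file))
  if (!is.null(shape)) dim(x) <- shape
  x
}

#' Read a recording container
#'
#' @param path Directory written by [write_recordings()].
#' @return List with `recordings` (list of [population_recording()]),
#'   `ground_truth` (or `NULL`) and `master_seed`.
#' @export
read_recordings <- function(path) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf)) abort(sprintf("no manifest.json under '%s'.", path))
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE, simplifyMatrix = FALSE)
  if (is.null(manifest$schema_version)) abort("manifest lacks schema_version.")
  if (manifest$schema_version != "1.0") {
    abort(sprintf("unknown schema_version '%s'.", manifest$schema_version))
  }
  animals <- manifest$animals
  if (is.data.frame(animals)) animals <- split(animals, seq_len(nrow(animals)))
  recordings <- lapply(animals, function(a) {
    if (is.data.frame(a)) a <- as.list(a)
    shape <- unlist(a$shape)
    ids <- unlist(a$stimulus_ids)
    if (is.null(ids)) abort(sprintf("animal '%s' lacks stimulus_ids.", a$key))
    bin <- file.path(path, a$key, "responses.bin")
    if (!file.exists(bin)) abort(sprintf("missing dataset %s.", bin))
    resp <- read_float64(bin, prod(shape), shape)
    tb <- a$time_bin_ms
    if (!is.null(tb) && (length(tb) == 0 || is.na(tb))) tb <- NULL
    population_recording(resp, a$animal_id, a$area, time_bin_ms = tb,
                         stimulus_ids = ids)
  })
  names(recordings) <- NULL
  gt <- NULL
  if (isTRUE(manifest$has_ground_truth)) {
    g <- manifest$ground_truth
    gdir <- file.path(path, "ground_truth")
    latent <- NULL
    if (!is.null(g$latent_shape)) {
      ls <- unlist(g$latent_shape)
      latent <- read_float64(file.path(gdir, "latent.bin"), prod(ls), ls)
    }
    n <- g$n_animals
    mixing <- true_responses <- noise_sd <- vector("list", n)
    for (p in seq_len(n)) {
      ms <- unlist(g$mixing_shapes[[p]]); ts <- unlist(g$true_shapes[[p]])
      mixing[[p]] <- read_float64(file.path(gdir, sprintf("mixing_%02d.bin", p)), prod(ms), ms)
      true_responses[[p]] <- read_float64(file.path(gdir, sprintf("true_responses_%02d.bin", p)),
                                          prod(ts), ts)
      noise_sd[[p]] <- read_float64(file.path(gdir, sprintf("noise_sd_%02d.bin", p)),
                                    g$noise_lengths[[p]])
    }
    gt <- structure(list(latent = latent, mixing = mixing,
                         true_responses = true_responses, noise_sd = noise_sd,
                         nonlinearity = g$nonlinearity,
                         shared_signal = g$shared_signal, seed = g$seed),
                    class = "ground_truth")
  }
  list(recordings = recordings, ground_truth = gt,
       master_seed = manifest$master_seed)
}

#' Serialize a consistency result to CSV and JSON
#'
#' Writes the per-unit table to `<stem>_per_unit.csv` and a summary (median,
#' s.e.m., unit counts, metadata echo) to `<stem>_summary.json`.
#'
#' @param result A [consistency_result()] or the output of
#'   [aggregate_units()].
#' @param stem Output path stem (no extension).
#' @return Named character vector of the files written, invisibly.
#' @export
write_result <- function(result, stem) {
  if (inherits(result, "consistency_result")) {
    per_unit <- result$per_unit
    summary <- list(median = result$median, sem = result$sem,
                    n_units = result$n_units, n_dropped = result$n_dropped,
                    metadata = result$metadata)
  } else {
    per_unit <- result$per_unit
    summary <- list(median = result$median, sem = result$sem,
                    n_units = result$n_units, n_dropped = result$n_dropped)
  }
  csv <- paste0(stem, "_per_unit.csv")
  js <- paste0(stem, "_summary.json")
  utils::write.csv(per_unit, csv, row.names = FALSE)
  jsonlite::write_json(summary, js, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(per_unit = csv, summary = js))
}
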