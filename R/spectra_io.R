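#' Write a spectral map to columnar text
#'
#' First column is the wavenumber axis; one column per spectrum, in
#' raster order, with headers `L<line>P<position>` carrying the raster
#' coordinates. Values round-trip at full double precision. A `.gz`
#' extension writes a gzip-compressed file transparently.
#'
#' @param map A [spectral_map()].
#' @param path Output file path (`.csv` or `.csv.gz`).
#' @return `path`, invisibly.
#' @export
write_map <- function(map, path) {
  dt <- data.table::as.data.table(map$intensities)
  data.table::setnames(dt, paste0("L", map$coords$line, "P", map$coords$position))
  dt <- cbind(data.table::data.table(wavenumber = map$wavenumbers), dt)
  ok <- tryCatch({
    data.table::fwrite(dt, path)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    stop_sq(sprintf("cannot write map to '%s': %s", path,
                    conditionMessage(ok)), "sersquant_io_error")
  invisible(path)
}

#' Read a spectral map from columnar text
#'
#' Validates the dialect written by [write_map()]: an ascending
#' `wavenumber` column, equal-length numeric spectrum columns, and
#' headers of the form `L<line>P<position>`.
#'
#' @param path File path (plain or gzip-compressed).
#' @param well_id Well label to attach; defaults to the file stem.
#' @return A [spectral_map()].
#' @export
read_map <- function(path, well_id = NULL) {
  if (!file.exists(path))
    stop_sq(sprintf("map file '%s' does not exist", path), "sersquant_io_error")
  dt <- tryCatch({
    if (grepl("\\.gz$", path)) {
      con <- gzfile(path, "r")
      on.exit(close(con), add = TRUE)
      data.table::fread(text = readLines(con), header = TRUE, fill = FALSE)
    } else {
      data.table::fread(path, header = TRUE, fill = FALSE)
    }
  }, error = function(e) stop_sq(sprintf("cannot parse '%s': %s", path,
                                         conditionMessage(e)),
                                 "sersquant_format_error"))
  if (ncol(dt) < 2 || names(dt)[1] != "wavenumber")
    stop_sq("map file must start with a 'wavenumber' header column",
            "sersquant_format_error")
  spec_names <- names(dt)[-1]
  m <- regmatches(spec_names, regexec("^L([0-9]+)P([0-9]+)$", spec_names))
  if (any(vapply(m, length, integer(1)) != 3))
    stop_sq("spectrum headers must have the form L<line>P<position>",
            "sersquant_format_error")
  coords <- data.frame(
    line = as.integer(vapply(m, `[`, character(1), 2)),
    position = as.integer(vapply(m, `[`, character(1), 3))
  )
  w <- dt[[1]]
  if (any(!is.finite(w)) || any(diff(w) <= 0))
    stop_sq("wavenumber axis must be finite and strictly ascending",
            "sersquant_format_error")
  intens <- as.matrix(dt[, -1, with = FALSE])
  if (!is.numeric(intens) || any(!is.finite(intens)))
    stop_sq("spectrum columns must be finite numeric", "sersquant_format_error")
  if (is.null(well_id))
    well_id <- sub("\\.csv(\\.gz)?$", "", basename(path))
  spectral_map(well_id, w, intens, coords)
}

#' Write a plate (manifest + one map file per well)
#'
#' The manifest is a JSON document recording the plate design, raster
#' dimensions, axis description, per-well file paths and provenance
#' (seed), so a plate round-trips losslessly through [read_plate()].
#'
#' @param plate A `sers_plate` (see [generate_plate()]).
#' @param dir Output directory (created if needed).
#' @param compress Write gzip-compressed maps; default `TRUE`.
#' @return Path of the manifest file, invisibly.
#' @export
write_plate <- function(plate, dir, compress = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ext <- if (compress) ".csv.gz" else ".csv"
  files <- paste0("map_", plate$design$well_id, ext)
  for (i in seq_along(plate$maps))
    write_map(plate$maps[[i]], file.path(dir, files[i]))
  axis <- plate$maps[[1]]$wavenumbers
  manifest <- list(
    plate_id = "sersquant-plate",
    raster = list(lines = max(plate$maps[[1]]$coords$line),
                  per_line = max(plate$maps[[1]]$coords$position)),
    axis = list(start = axis[1], end = axis[length(axis)],
                points = length(axis)),
    seed = plate$seed,
    design = plate$design[, c("well_id", "row", "col", "sample_id",
                              "concentration", "conc_index", "is_blank")],
    files = stats::setNames(as.list(files), plate$design$well_id)
  )
  manifest_path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest_path)
}

#' Read a plate from its manifest
#'
#' @param manifest_path Path to a `manifest.json` written by
#'   [write_plate()].
#' @return A `sers_plate` (design + maps); design/map consistency
#'   (matching well ids, one existing file per well) is enforced.
#' @export
read_plate <- function(manifest_path) {
  if (!file.exists(manifest_path))
    stop_sq(sprintf("manifest '%s' does not exist", manifest_path),
            "sersquant_io_error")
  man <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  design <- man$design
  if (is.null(design) || NROW(design) == 0)
    stop_sq("manifest contains no wells", "sersquant_consistency_error")
  if (is.null(man$files) || !setequal(names(man$files), design$well_id))
    stop_sq("manifest file entries do not match design wells",
            "sersquant_consistency_error")
  attr(design, "replicate_wells") <- max(table(design$sample_id))
  class(design) <- c("plate_design", "data.frame")
  dir <- dirname(manifest_path)
  maps <- vector("list", nrow(design))
  names(maps) <- design$well_id
  for (wid in design$well_id) {
    f <- file.path(dir, man$files[[wid]])
    if (!file.exists(f))
      stop_sq(sprintf("map file '%s' for well %s is missing", f, wid),
              "sersquant_io_error")
    maps[[wid]] <- read_map(f, well_id = wid)
  }
  structure(list(design = design, maps = maps,
                 config = NULL, seed = man$seed),
            class = "sers_plate")
}
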